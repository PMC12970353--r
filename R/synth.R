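# Synthetic BED workloads and the naive plaintext oracle.
#
# The oracle deliberately shares no interval arithmetic with the production
# modules: counts come from pairwise comparisons and per-base occupancy
# arrays built by marking loops - no prefix sums anywhere.

#' Synthetic workload configuration
#'
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param chroms named vector of chromosome lengths.
#' @param n number of intervals.
#' @param len_dist `"uniform"` (lengths uniform in `[len_min, len_max]`) or
#'   `"geometric"` (1 + geometric with mean `len_mean`).
#' @param len_min,len_max,len_mean length-distribution parameters (bases).
#' @return a `synth_config`.
#' @export
synth_config <- function(seed = 1L, chroms = c(chr1 = 1e4), n = 100L,
                         len_dist = c("uniform", "geometric"),
                         len_min = 10, len_max = 100, len_mean = 50) {
  len_dist <- match.arg(len_dist)
  if (!is_count(seed)) cb_stop("cb_config_error", "seed must be an integer")
  if (!is_count(n)) cb_stop("cb_config_error", "interval count must be >= 0")
  layout <- genome_layout(chroms)
  maxlen <- if (len_dist == "uniform") len_max else len_mean
  if (maxlen >= min(layout$lengths))
    cb_stop("cb_config_error",
            "interval length scale (%.0f) must be below the shortest chromosome (%.0f)",
            maxlen, min(layout$lengths))
  if (len_dist == "uniform" && (len_min < 1 || len_min > len_max))
    cb_stop("cb_config_error", "need 1 <= len_min <= len_max")
  structure(list(seed = as.integer(seed), layout = layout, n = as.integer(n),
                 len_dist = len_dist, len_min = len_min, len_max = len_max,
                 len_mean = len_mean),
            class = "synth_config")
}

#' Generate a synthetic BED track
#'
#' Starts are independent uniform over each chromosome; lengths follow the
#' configured distribution; intervals are clipped to the chromosome and
#' emitted sorted.  Deterministic given the seed.
#'
#' @param cfg a `synth_config`.
#' @param path optional BED output path.
#' @return an `interval_set` (written to `path` when given).
#' @export
generate_bed <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  layout <- cfg$layout
  df <- with_seed(cfg$seed, {
    chrom <- sample(layout$chroms, cfg$n, replace = TRUE,
                    prob = layout$lengths / sum(layout$lengths))
    L <- unname(layout$lengths[chrom])
    len <- switch(cfg$len_dist,
      uniform = floor(stats::runif(cfg$n, cfg$len_min, cfg$len_max + 1)),
      geometric = 1 + stats::rgeom(cfg$n, 1 / cfg$len_mean))
    start <- floor(stats::runif(cfg$n, 0, pmax(1, L - len)))
    end <- pmin(L, start + len)
    data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
  })
  if (cfg$n > 0) {
    df <- df[order(match(df$chrom, layout$chroms), df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  s <- interval_set(df, layout)
  if (!is.null(path)) write_bed(s, path)
  s
}

# per-chromosome occupancy (logical) and depth arrays by naive marking
oracle_occupancy <- function(s, chrom, L) {
  occ <- logical(L)
  df <- s$df[s$df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(df))) occ[seq(df$start[i] + 1, df$end[i])] <- TRUE
  occ
}

oracle_depth_array <- function(s, chrom, L) {
  dep <- numeric(L)
  df <- s$df[s$df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    ix <- seq(df$start[i] + 1, df$end[i])
    dep[ix] <- dep[ix] + 1
  }
  dep
}

# pairwise overlap counts of each a-row against B (same chromosome,
# [s,e) overlap test)
oracle_counts <- function(adf, B) {
  bs <- split(B$df[c("start", "end")], B$df$chrom)
  vapply(seq_len(nrow(adf)), function(i) {
    b <- bs[[adf$chrom[i]]]
    if (is.null(b)) return(0)
    sum(b$start < adf$end[i] & b$end > adf$start[i])
  }, numeric(1))
}

#' Brute-force plaintext oracle
#'
#' Reference implementation of all five operations by naive per-base and
#' pairwise computation, used as ground truth in every equivalence test.
#'
#' @param op operation name.
#' @param A,B query and database `interval_set`s.
#' @param W window margin.
#' @param mode mode flag (see [query_spec()]).
#' @return output in exactly the shape [run_query()] produces.
#' @export
oracle <- function(op = c("coverage", "intersect", "window", "depth", "jaccard"),
                   A, B, W = 0, mode = NULL) {
  op <- match.arg(op)
  layout <- A$layout
  adf <- A$df
  # per-chromosome arrays are rebuilt once per call, not per interval
  occ_cache <- new.env(parent = emptyenv())
  b_occ <- function(ch) {
    if (is.null(occ_cache[[ch]]))
      occ_cache[[ch]] <- oracle_occupancy(B, ch, chrom_length(layout, ch))
    occ_cache[[ch]]
  }
  dep_cache <- new.env(parent = emptyenv())
  b_dep <- function(ch) {
    if (is.null(dep_cache[[ch]]))
      dep_cache[[ch]] <- oracle_depth_array(B, ch, chrom_length(layout, ch))
    dep_cache[[ch]]
  }
  switch(op,
    coverage = {
      covered <- vapply(seq_len(nrow(adf)), function(i) {
        occ <- b_occ(adf$chrom[i])
        sum(occ[seq(adf$start[i] + 1, adf$end[i])])
      }, numeric(1))
      count <- oracle_counts(adf, B)
      len <- adf$end - adf$start
      data.frame(chrom = adf$chrom, start = adf$start, end = adf$end,
                 count = count, covered = covered, length = len,
                 fraction = covered / len, stringsAsFactors = FALSE)
    },
    intersect = ,
    window = {
      W <- if (op == "window") W else 0
      L <- unname(layout$lengths[adf$chrom])
      ex <- data.frame(chrom = adf$chrom, start = pmax(0, adf$start - W),
                       end = pmin(L, adf$end + W), stringsAsFactors = FALSE)
      count <- oracle_counts(ex, B)
      base <- data.frame(chrom = adf$chrom, start = adf$start, end = adf$end,
                         stringsAsFactors = FALSE)
      out <- switch(mode,
        c = cbind(base, count = count),
        u = base[count > 0, , drop = FALSE],
        v = base[count == 0, , drop = FALSE])
      rownames(out) <- NULL
      out
    },
    depth = {
      rows <- lapply(seq_len(nrow(adf)), function(i) {
        dep <- b_dep(adf$chrom[i])
        pos <- seq(adf$start[i], adf$end[i] - 1)
        data.frame(chrom = adf$chrom[i], pos = pos, depth = dep[pos + 1],
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      if (is.null(out)) out <- data.frame(chrom = character(0), pos = numeric(0),
                                          depth = numeric(0))
      rownames(out) <- NULL
      out
    },
    jaccard = {
      inter <- 0; uni <- 0
      for (ch in layout$chroms) {
        L <- chrom_length(layout, ch)
        occA <- oracle_occupancy(A, ch, L)
        occB <- oracle_occupancy(B, ch, L)
        inter <- inter + sum(occA & occB)
        uni <- uni + sum(occA | occB)
      }
      structure(list(intersection = inter, union = uni,
                     jaccard = if (uni == 0) 0 else inter / uni),
                class = "jaccard_result")
    })
}

#' The worked toy fixture
#'
#' `B = {[2,5), [4,8)}`, `A = {[3,6), [0,1), [8,10)}` on one chromosome of
#' length 10, with expected outputs for every operation precomputed by the
#' brute-force oracle.
#'
#' @return list with `A`, `B`, `layout` and `expected` (named by operation).
#' @export
make_fixture <- function() {
  layout <- genome_layout(c(chrT = 10))
  B <- interval_set(data.frame(chrom = "chrT", start = c(2, 4), end = c(5, 8)),
                    layout)
  A <- interval_set(data.frame(chrom = "chrT", start = c(3, 0, 8),
                               end = c(6, 1, 10)), layout)
  expected <- list(
    coverage = oracle("coverage", A, B),
    intersect_u = oracle("intersect", A, B, mode = "u"),
    intersect_v = oracle("intersect", A, B, mode = "v"),
    window_c_w2 = oracle("window", A, B, W = 2, mode = "c"),
    depth = oracle("depth", A, B),
    jaccard = oracle("jaccard", A, B))
  list(A = A, B = B, layout = layout, expected = expected)
}
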