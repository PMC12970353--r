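# Query compilation: lower each supported operation over the query set A into
# an ordered list of logical scalar reads with reassembly tags, then into
# physical selectors.

#' Query specification
#'
#' @param op one of `"coverage"`, `"intersect"`, `"window"`, `"depth"`,
#'   `"jaccard"`.
#' @param A query `interval_set` (the private loci).
#' @param mode bedtools-style mode flag: intersect takes `"u"` or `"v"`;
#'   window takes `"c"`, `"u"` or `"v"`; other operations take no mode.
#' @param window window margin W >= 0 (window op only).
#' @return a `query_spec`.
#' @export
query_spec <- function(op = c("coverage", "intersect", "window", "depth", "jaccard"),
                       A, mode = NULL, window = 0) {
  op <- match.arg(op)
  stopifnot(inherits(A, "interval_set"))
  allowed <- switch(op, intersect = c("u", "v"), window = c("c", "u", "v"), character(0))
  if (length(allowed) == 0) {
    if (!is.null(mode))
      cb_stop("cb_spec_error", "operation '%s' takes no mode flag", op)
  } else {
    if (is.null(mode) || !mode %in% allowed)
      cb_stop("cb_spec_error", "operation '%s' requires mode in {%s}",
              op, paste(allowed, collapse = ","))
  }
  if (op == "window") {
    if (!is_count(window, 0))
      cb_stop("cb_spec_error", "window margin W must be a non-negative integer")
  } else if (!identical(window, 0)) {
    cb_stop("cb_spec_error", "window margin only applies to the window operation")
  }
  structure(list(op = op, mode = mode, window = as.numeric(window), A = A),
            class = "query_spec")
}

new_plan <- function(spec, reads, meta = NULL) {
  structure(list(spec = spec, reads = reads, meta = meta,
                 n_reads = nrow(reads), deduped = FALSE, fanout = NULL),
            class = "query_plan")
}

reads_frame <- function(segment, chrom, coord, tag) {
  data.frame(segment = segment, chrom = chrom, coord = coord, tag = tag,
             stringsAsFactors = FALSE)
}

#' Compile a query into logical reads
#'
#' Lowers the operation over the query set A into an ordered list of logical
#' scalar reads (segment, chromosome, coordinate) annotated with reassembly
#' tags.  Read counts per operation:
#'
#' * coverage: 4 per interval (`S1@s`, `S1@e`, `S2@e`, `S3@s`);
#' * intersect: 2 per interval (`S2@e`, `S3@s`);
#' * window: 2 per interval on the W-expanded, chromosome-clamped interval;
#' * depth: one `S4` read per base of each interval;
#' * jaccard: 2 per merged-A interval plus one `S1@L` per chromosome (the
#'   total coverage of B).
#'
#' @param spec a `query_spec`.
#' @param depth_cap refuse depth plans with more reads than this.
#' @return a `query_plan`.
#' @export
compile_query <- function(spec, depth_cap = 1e6) {
  stopifnot(inherits(spec, "query_spec"))
  A <- spec$A
  df <- A$df
  if (spec$op != "jaccard" && nrow(df) == 0)
    cb_stop("cb_request_error", "empty query set: nothing to compile")
  switch(spec$op,
    coverage = {
      n <- nrow(df)
      idx <- rep(seq_len(n), each = 4)
      role <- rep(c("Pcov@s", "Pcov@e", "Pstart@e", "Pend@s"), times = n)
      seg <- rep(c("S1", "S1", "S2", "S3"), times = n)
      coord <- as.numeric(t(cbind(df$start, df$end, df$end, df$start)))
      reads <- reads_frame(seg, df$chrom[idx], coord, paste0(idx, ":", role))
      new_plan(spec, reads, meta = list(intervals = df))
    },
    intersect = ,
    window = {
      W <- if (spec$op == "window") spec$window else 0
      L <- unname(A$layout$lengths[df$chrom])
      es <- pmax(0, df$start - W)
      ee <- pmin(L, df$end + W)
      n <- nrow(df)
      idx <- rep(seq_len(n), each = 2)
      seg <- rep(c("S2", "S3"), times = n)
      coord <- as.numeric(t(cbind(ee, es)))
      role <- rep(c("Pstart@e", "Pend@s"), times = n)
      reads <- reads_frame(seg, df$chrom[idx], coord,
                           paste0(idx, ":", role, ":", spec$mode))
      new_plan(spec, reads, meta = list(intervals = df,
                                        expanded = data.frame(start = es, end = ee)))
    },
    depth = {
      n <- nrow(df)
      lens <- df$end - df$start
      if (sum(lens) > depth_cap)
        cb_stop("cb_plan_size_error",
                "depth plan of %.0f reads exceeds the cap of %.0f",
                sum(lens), depth_cap)
      idx <- rep(seq_len(n), times = lens)
      coord <- unlist(lapply(seq_len(n), function(i) seq(df$start[i], df$end[i] - 1)),
                      use.names = FALSE)
      reads <- reads_frame("S4", df$chrom[idx], coord,
                           paste0(idx, ":D@", coord))
      new_plan(spec, reads, meta = list(intervals = df))
    },
    jaccard = {
      mA <- merge_intervals(A)
      mdf <- mA$df
      n <- nrow(mdf)
      if (n > 0) {
        idx <- rep(seq_len(n), each = 2)
        seg <- rep(c("S1", "S1"), times = n)
        coord <- as.numeric(t(cbind(mdf$start, mdf$end)))
        role <- rep(c("Pcov@s", "Pcov@e"), times = n)
        reads <- reads_frame(seg, mdf$chrom[idx], coord, paste0(idx, ":", role))
      } else {
        reads <- reads_frame(character(0), character(0), numeric(0), character(0))
      }
      totals <- reads_frame("S1", A$layout$chroms,
                            unname(A$layout$lengths),
                            paste0("B:", A$layout$chroms))
      reads <- rbind(reads, totals)
      new_plan(spec, reads, meta = list(merged = mdf))
    })
}

#' Deduplicate a plan's reads
#'
#' Collapses repeated logical reads to their first occurrence and records the
#' fan-out needed to reproduce the full ordered scalar stream.  Reduces
#' server work at the cost of revealing read multiplicity; disable with
#' `enabled = FALSE`.
#'
#' @param plan a `query_plan`.
#' @param enabled dedup on/off.
#' @return the plan with `reads` possibly shrunk and `fanout` set (indices of
#'   the unique read providing each original scalar).
#' @export
dedupe <- function(plan, enabled = TRUE) {
  stopifnot(inherits(plan, "query_plan"))
  if (!enabled || nrow(plan$reads) == 0) {
    plan$deduped <- FALSE
    plan$fanout <- seq_len(nrow(plan$reads))
    return(plan)
  }
  key <- paste(plan$reads$segment, plan$reads$chrom, plan$reads$coord)
  first <- !duplicated(key)
  uniq_key <- key[first]
  plan$fanout <- match(key, uniq_key)
  plan$reads <- plan$reads[first, , drop = FALSE]
  rownames(plan$reads) <- NULL
  plan$deduped <- TRUE
  plan
}

#' Lower a plan to physical selectors
#'
#' Maps each (deduped) logical read through the manifest and the
#' client-secret permutation into a physical selector, producing the
#' extraction request for the current epoch.
#'
#' @param plan a `query_plan` (after [dedupe()]).
#' @param manifest a `layout_manifest`.
#' @param map a `permutation_map`.
#' @return list with `request` (an `extraction_request`) and `plan`.
#' @export
plan_selectors <- function(plan, manifest, map) {
  if (is.null(plan$fanout)) plan <- dedupe(plan, enabled = FALSE)
  sel <- selectors_for_reads(manifest, map, plan$reads$segment,
                             plan$reads$chrom, plan$reads$coord)
  sel$ordinal <- seq_len(nrow(sel)) - 1L
  list(request = extraction_request(map$epoch, sel), plan = plan)
}

# expand the deduped scalar stream back to one scalar per original read
fanout_scalars <- function(plan, scalars) {
  if (length(scalars) != nrow(plan$reads))
    cb_stop("cb_protocol_error",
            "scalar stream length %d does not match plan reads %d",
            length(scalars), nrow(plan$reads))
  scalars[plan$fanout]
}
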