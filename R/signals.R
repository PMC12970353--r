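#' Genome layout
#'
#' Ordered chromosome names with their lengths in bases.  All interval
#' coordinates are validated against this layout; the coordinate domain of a
#' chromosome of length L is `{0, ..., L-1}` (0-based, half-open intervals).
#'
#' @param lengths named numeric vector of chromosome lengths (all >= 1).
#' @return an object of class `genome_layout`.
#' @export
genome_layout <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    cb_stop("cb_param_error", "chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    cb_stop("cb_param_error", "duplicated chromosome name in layout")
  ln <- stats::setNames(as.numeric(lengths), names(lengths))
  if (any(is.na(ln)) || any(ln < 1) || any(ln != floor(ln)))
    cb_stop("cb_param_error", "chromosome lengths must be positive integers")
  structure(list(chroms = names(ln), lengths = ln), class = "genome_layout")
}

#' Read a chromosome-length table
#'
#' Two tab-separated columns: chromosome name and length (the usual
#' "genome file" of interval toolkits).
#'
#' @param path file path.
#' @return a `genome_layout`.
#' @export
read_genome <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) cb_stop("cb_parse_error", "empty genome file '%s'", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 0L) < 2))
    cb_stop("cb_parse_error", "genome file '%s': expected 'chrom<TAB>length' lines", path)
  nm <- vapply(parts, `[[`, "", 1)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (any(is.na(len)))
    cb_stop("cb_parse_error", "genome file '%s': non-numeric length", path)
  genome_layout(stats::setNames(len, nm))
}

chrom_length <- function(layout, chrom) {
  unname(layout$lengths[chrom])
}

#' Interval set
#'
#' A set of 0-based half-open genomic intervals `[start, end)` validated
#' against a genome layout.
#'
#' @param df data frame with columns `chrom`, `start`, `end`.
#' @param layout a `genome_layout`.
#' @param sorted,merged bookkeeping flags set by [merge_intervals()].
#' @return an object of class `interval_set`.
#' @export
interval_set <- function(df, layout, sorted = FALSE, merged = FALSE) {
  stopifnot(inherits(layout, "genome_layout"))
  df <- data.frame(chrom = as.character(df$chrom),
                   start = as.numeric(df$start),
                   end = as.numeric(df$end),
                   stringsAsFactors = FALSE)
  bad_chrom <- !(df$chrom %in% layout$chroms)
  if (any(bad_chrom))
    cb_stop("cb_parse_error", "unknown chromosome '%s' (interval %d)",
            df$chrom[which(bad_chrom)[1]], which(bad_chrom)[1])
  if (any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
    cb_stop("cb_parse_error", "non-integer interval coordinates")
  if (any(df$start < 0))
    cb_stop("cb_parse_error", "negative start coordinate (interval %d)",
            which(df$start < 0)[1])
  zero <- df$start >= df$end
  if (any(zero))
    cb_stop("cb_parse_error",
            "interval %d is empty or inverted (start %.0f >= end %.0f); zero-length intervals are not supported",
            which(zero)[1], df$start[which(zero)[1]], df$end[which(zero)[1]])
  over <- df$end > unname(layout$lengths[df$chrom])
  if (any(over))
    cb_stop("cb_parse_error", "interval %d ends beyond chromosome end (%.0f > %.0f)",
            which(over)[1], df$end[which(over)[1]],
            unname(layout$lengths[df$chrom[which(over)[1]]]))
  structure(list(df = df, layout = layout, sorted = sorted, merged = merged),
            class = "interval_set")
}

#' Number of intervals
#' @param s an `interval_set`.
#' @export
n_intervals <- function(s) nrow(s$df)

#' Parse a BED file
#'
#' Reads the first three tab-separated columns (chrom, start, end) of a BED
#' file; further columns are ignored, as are blank lines, `#` comments and
#' `track`/`browser` lines.  Coordinates are validated against the layout;
#' zero-length intervals are rejected.
#'
#' @param path BED file path.
#' @param layout a `genome_layout`.
#' @return an `interval_set` in file order.
#' @export
parse_bed <- function(path, layout) {
  if (!file.exists(path)) cb_stop("cb_parse_error", "BED file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(interval_set(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0)), layout))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 0L)
  if (any(nf < 3))
    cb_stop("cb_parse_error", "%s:%d: expected at least 3 tab-separated columns",
            path, lineno[which(nf < 3)[1]])
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  if (any(is.na(start)) || any(is.na(end)))
    cb_stop("cb_parse_error", "%s:%d: non-numeric coordinate",
            path, lineno[which(is.na(start) | is.na(end))[1]])
  df <- data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
  tryCatch(interval_set(df, layout), cb_parse_error = function(e) {
    # re-raise with the file location of the offending interval
    i <- suppressWarnings(as.integer(sub(".*interval (\\d+).*", "\\1", conditionMessage(e))))
    loc <- if (!is.na(i)) sprintf("%s:%d: ", path, lineno[i]) else sprintf("%s: ", path)
    cb_stop("cb_parse_error", "%s%s", loc, conditionMessage(e))
  })
}

#' Write a BED file
#' @param s an `interval_set`.
#' @param path output path.
#' @export
write_bed <- function(s, path) {
  stopifnot(inherits(s, "interval_set"))
  utils::write.table(
    data.frame(s$df$chrom, format(s$df$start, scientific = FALSE, trim = TRUE),
               format(s$df$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge overlapping and touching intervals
#'
#' Sorts by (chrom, start) and coalesces intervals that overlap or touch
#' (`[0,1)` and `[1,2)` merge to `[0,2)`).  Total covered bases are
#' preserved.
#'
#' @param s an `interval_set`.
#' @return a sorted, overlap-free `interval_set` with `merged = TRUE`.
#' @export
merge_intervals <- function(s) {
  stopifnot(inherits(s, "interval_set"))
  df <- s$df
  if (nrow(df) == 0) return(interval_set(df, s$layout, sorted = TRUE, merged = TRUE))
  ord <- order(match(df$chrom, s$layout$chroms), df$start, df$end)
  df <- df[ord, , drop = FALSE]
  out_chrom <- character(0); out_start <- numeric(0); out_end <- numeric(0)
  cur_chrom <- df$chrom[1]; cur_s <- df$start[1]; cur_e <- df$end[1]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$chrom[i] == cur_chrom && df$start[i] <= cur_e) {
      cur_e <- max(cur_e, df$end[i])
    } else {
      out_chrom <- c(out_chrom, cur_chrom); out_start <- c(out_start, cur_s)
      out_end <- c(out_end, cur_e)
      cur_chrom <- df$chrom[i]; cur_s <- df$start[i]; cur_e <- df$end[i]
    }
  }
  out_chrom <- c(out_chrom, cur_chrom); out_start <- c(out_start, cur_s)
  out_end <- c(out_end, cur_e)
  interval_set(data.frame(chrom = out_chrom, start = out_start, end = out_end,
                          stringsAsFactors = FALSE),
               s$layout, sorted = TRUE, merged = TRUE)
}

#' Derived signal arrays
#'
#' Reduces the database track B to four per-chromosome integer arrays so that
#' every supported query becomes a handful of point reads:
#'
#' * `P_cov` (length L+1): exclusive prefix sum of the binary coverage
#'   indicator; covered bases in `[s,e)` equal `P_cov[e] - P_cov[s]`.
#' * `P_start` (length L+1): `P_start[x]` = number of intervals with start
#'   `< x`.
#' * `P_end` (length L+1): `P_end[x]` = number of intervals with end
#'   `<= x` (the shifted end prefix, so that the count of intervals
#'   overlapping `[s,e)` is `P_start[e] - P_end[s]`).
#' * `D` (length L): per-base depth, the number of intervals covering each
#'   base.
#'
#' Start/end indicators accumulate at duplicated coordinates (value k when k
#' intervals share a boundary), keeping overlap counts exact for duplicated
#' intervals.  Arrays are indexed 1-based in R: `P_cov[x + 1]` is the value
#' at coordinate x.
#'
#' @param B an `interval_set` (the database track).
#' @param layout a `genome_layout`; defaults to the layout of `B`.
#' @return an object of class `signal_arrays`: per chromosome a list with
#'   `P_cov`, `P_start`, `P_end`, `D`.
#' @export
build_signals <- function(B, layout = B$layout) {
  stopifnot(inherits(B, "interval_set"))
  per <- lapply(layout$chroms, function(ch) {
    L <- unname(layout$lengths[ch])
    df <- B$df[B$df$chrom == ch, , drop = FALSE]
    # depth via boundary deltas
    delta <- numeric(L + 1)
    if (nrow(df) > 0) {
      sa <- tabulate(df$start + 1L, nbins = L + 1)
      ea <- tabulate(df$end + 1L, nbins = L + 1)
      delta <- sa - ea
    }
    D <- cumsum(delta)[seq_len(L)]
    P_cov <- c(0, cumsum(as.numeric(D > 0)))
    start_counts <- if (nrow(df) > 0) tabulate(df$start + 1L, nbins = L) else numeric(L)
    end_counts <- if (nrow(df) > 0) tabulate(df$end, nbins = L) else numeric(L)
    P_start <- c(0, cumsum(start_counts))
    P_end <- c(0, cumsum(end_counts))
    list(P_cov = P_cov, P_start = P_start, P_end = P_end, D = D)
  })
  names(per) <- layout$chroms
  structure(list(per_chrom = per, layout = layout, m = nrow(B$df)),
            class = "signal_arrays")
}
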