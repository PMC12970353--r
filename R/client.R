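# Client side: orchestrate compile -> extract -> decrypt -> reassemble and
# emit bedtools-style outputs.

#' Run one query end to end
#'
#' Stage 2/3 of the workflow: compile the operation over A into logical
#' reads, lower them to physical selectors under the current epoch, send one
#' batched extraction request, decrypt the returned scalars, reorder them by
#' ordinal, and reconstruct the operation's output.  The result is identical
#' to running the corresponding plaintext computation on (A, B).
#'
#' @param spec a `query_spec`.
#' @param handle a `server_handle` hosting the encrypted database.
#' @param manifest client-side `layout_manifest`.
#' @param map client-side `permutation_map`.
#' @param keys secret key material.
#' @param dedup collapse duplicate reads before sending (default TRUE).
#' @param depth_cap refuse depth plans larger than this many reads.
#' @param scramble ask the server to simulate out-of-order parallel
#'   execution (tests).
#' @return operation output: a data frame (coverage, intersect, window,
#'   depth) or a `jaccard_result`.
#' @export
run_query <- function(spec, handle, manifest, map, keys, dedup = TRUE,
                      depth_cap = 1e6, scramble = FALSE) {
  if (map$epoch != manifest$epoch)
    cb_stop("cb_stale_plan_error", "manifest and permutation map epochs disagree")
  plan <- compile_query(spec, depth_cap = depth_cap)
  plan <- dedupe(plan, enabled = dedup)
  ps <- plan_selectors(plan, manifest, map)
  resp <- extract_batch(handle, ps$request, scramble = scramble)
  scalars <- decrypt_scalars(resp, keys)
  # restore request order by ordinal, then expand dedup fan-out
  scalars <- scalars[order(resp$ordinals)]
  scalars <- fanout_scalars(ps$plan, scalars)
  reconstruct(ps$plan, scalars)
}

#' Reassemble decrypted scalars into operation output
#'
#' @param plan the compiled (and possibly deduped) `query_plan`.
#' @param scalars decrypted scalar stream, one value per original read in
#'   plan order (after fan-out).
#' @return operation output, see [run_query()].
#' @export
reconstruct <- function(plan, scalars) {
  switch(plan$spec$op,
    coverage = reconstruct_coverage(plan, scalars),
    intersect = ,
    window = reconstruct_intersect_window(plan, scalars),
    depth = reconstruct_depth(plan, scalars),
    jaccard = reconstruct_jaccard(plan, scalars))
}

#' @rdname reconstruct
#' @export
reconstruct_coverage <- function(plan, scalars) {
  df <- plan$meta$intervals
  n <- nrow(df)
  if (length(scalars) != 4 * n)
    cb_stop("cb_protocol_error", "coverage expects 4 scalars per interval")
  m <- matrix(scalars, nrow = 4)          # rows: Pcov@s, Pcov@e, Pstart@e, Pend@s
  covered <- m[2, ] - m[1, ]
  count <- m[3, ] - m[4, ]
  len <- df$end - df$start
  if (any(covered < 0) || any(covered > len) || any(count < 0))
    cb_stop("cb_corruption_error",
            "reconstructed coverage violates invariants (corrupted scalar stream?)")
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             count = count, covered = covered, length = len,
             fraction = covered / len, stringsAsFactors = FALSE)
}

#' @rdname reconstruct
#' @export
reconstruct_intersect_window <- function(plan, scalars) {
  df <- plan$meta$intervals
  n <- nrow(df)
  if (length(scalars) != 2 * n)
    cb_stop("cb_protocol_error", "intersect/window expects 2 scalars per interval")
  m <- matrix(scalars, nrow = 2)          # rows: Pstart@e', Pend@s'
  count <- m[1, ] - m[2, ]
  if (any(count < 0))
    cb_stop("cb_corruption_error", "negative overlap count (corrupted scalar stream?)")
  base <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                     stringsAsFactors = FALSE)
  out <- switch(plan$spec$mode,
    c = cbind(base, count = count),
    u = base[count > 0, , drop = FALSE],
    v = base[count == 0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' @rdname reconstruct
#' @export
reconstruct_depth <- function(plan, scalars) {
  df <- plan$meta$intervals
  lens <- df$end - df$start
  if (length(scalars) != sum(lens))
    cb_stop("cb_protocol_error", "depth expects one scalar per base")
  idx <- rep(seq_len(nrow(df)), times = lens)
  pos <- unlist(lapply(seq_len(nrow(df)), function(i) seq(df$start[i], df$end[i] - 1)),
                use.names = FALSE)
  if (length(pos) == 0)
    return(data.frame(chrom = character(0), pos = numeric(0), depth = numeric(0)))
  data.frame(chrom = df$chrom[idx], pos = pos, depth = scalars,
             stringsAsFactors = FALSE)
}

#' @rdname reconstruct
#' @export
reconstruct_jaccard <- function(plan, scalars) {
  mdf <- plan$meta$merged
  n <- nrow(mdf)
  nchrom <- length(scalars) - 2 * n
  if (nchrom < 1)
    cb_stop("cb_protocol_error", "jaccard scalar stream too short")
  inter <- 0
  if (n > 0) {
    m <- matrix(scalars[seq_len(2 * n)], nrow = 2)   # Pcov@s, Pcov@e per merged A interval
    inter <- sum(m[2, ] - m[1, ])
  }
  b_total <- sum(scalars[2 * n + seq_len(nchrom)])   # P_cov(L) per chromosome
  a_total <- if (n > 0) sum(mdf$end - mdf$start) else 0
  union <- a_total + b_total - inter
  jac <- if (union == 0) 0 else inter / union
  structure(list(intersection = inter, union = union, jaccard = jac),
            class = "jaccard_result")
}

#' @export
print.jaccard_result <- function(x, ...) {
  cat("intersection\tunion\tjaccard\n")
  cat(sprintf("%.0f\t%.0f\t%s\n", x$intersection, x$union,
              format(x$jaccard, digits = 7)))
  invisible(x)
}

#' Format an operation output as TSV
#'
#' Coverage emits the bedtools-coverage column order (interval, overlap
#' count, covered bases, interval length, fraction); window/intersect emit
#' the original A intervals (plus a count column under `-c`); depth emits
#' `chrom pos depth` (0-based).  Fractions are rendered with 7 significant
#' digits.
#'
#' @param x operation output from [run_query()].
#' @param path output file or `""` for stdout.
#' @export
write_output <- function(x, path = "") {
  if (inherits(x, "jaccard_result")) {
    lines <- c("intersection\tunion\tjaccard",
               sprintf("%.0f\t%.0f\t%s", x$intersection, x$union,
                       format(x$jaccard, digits = 7)))
    writeLines(lines, if (nzchar(path)) path else stdout())
    return(invisible(x))
  }
  y <- x
  if ("fraction" %in% names(y))
    y$fraction <- format(y$fraction, digits = 7)
  utils::write.table(y, if (nzchar(path)) path else "", sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(x)
}

# ------------------------------------------------------------------- bench

#' Benchmark one provision + query run
#'
#' Measures wall time per phase (build/encrypt, server extraction, decrypt),
#' bytes moved (ciphertext database size = upload; extracted ciphertexts =
#' download), peak RSS where available, and the noise-budget trace of the
#' extraction kernel (fresh, after one rotation, after masking).  Metrics
#' are reported, never asserted against any reference hardware.
#'
#' @param B database `interval_set`.
#' @param spec a `query_spec`.
#' @param keys key material (with secret).
#' @param secret_seed permutation seed.
#' @param out optional JSON path for the report.
#' @return a `bench_report` list.
#' @export
bench <- function(B, spec, keys, secret_seed = 1L, out = NULL) {
  rss <- function() {
    kb <- suppressWarnings(tryCatch(
      as.numeric(strsplit(grep("^VmRSS", readLines("/proc/self/status"),
                               value = TRUE), "[[:space:]]+")[[1]][2]),
      error = function(e) NA_real_))
    kb * 1024
  }
  t_enc <- system.time(built <- build_database(B, keys, secret_seed))[["elapsed"]]
  upload <- sum(vapply(built$db$chunks,
                       function(ch) length(serialize_chunk(ch)), numeric(1)))
  handle <- host_db(built$db, public_part(keys))
  plan <- dedupe(compile_query(spec))
  ps <- plan_selectors(plan, built$manifest, built$map)
  t_srv <- system.time(resp <- extract_batch(handle, ps$request))[["elapsed"]]
  download <- response_bytes(resp)
  t_dec <- system.time({
    scalars <- decrypt_scalars(resp, keys)
    scalars <- scalars[order(resp$ordinals)]
    output <- reconstruct(ps$plan, fanout_scalars(ps$plan, scalars))
  })[["elapsed"]]
  # noise trace of the kernel on a fresh chunk
  probe <- encrypt_chunk(rep(1, keys$slot_count), keys)
  trace <- c(fresh = noise_budget(probe, keys))
  rot <- rotate_slots(probe, 1L, keys)
  trace <- c(trace, after_rotation = noise_budget(rot, keys))
  msk <- mask_front(rot, keys)
  trace <- c(trace, after_masking = noise_budget(msk, keys))
  report <- list(
    op = spec$op, mode = spec$mode, backend = keys$backend,
    n_database = n_intervals(B), n_query = n_intervals(spec$A),
    n_extractions = nrow(ps$plan$reads),
    phases = list(
      encryption = list(seconds = t_enc, bytes = upload),
      server = list(seconds = t_srv, bytes = download),
      decryption = list(seconds = t_dec, bytes = 0)),
    peak_rss_bytes = rss(),
    noise_trace = as.list(trace))
  class(report) <- "bench_report"
  if (!is.null(out))
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE, digits = NA)
  report
}
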