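# Encrypted database store: concatenate signal arrays into a global vector,
# chunk to the SIMD batching capacity, shuffle chunk order with a
# client-secret permutation, encrypt, and map logical reads to physical
# (chunk, slot) selectors.

SEGMENTS <- c(S1 = "P_cov", S2 = "P_start", S3 = "P_end", S4 = "D")

#' Concatenate signal arrays and cut into chunks
#'
#' Builds the per-chromosome global vectors (segments S1 = coverage prefix,
#' S2 = start prefix, S3 = end prefix, S4 = depth, in that fixed order),
#' concatenates them across chromosomes in layout order, and partitions the
#' result into fixed-size chunks aligned with the HE batching capacity.  The
#' last chunk is zero-padded.  Chunks may straddle segment and chromosome
#' boundaries; addressing is purely offset-based.
#'
#' @param signals a `signal_arrays` object.
#' @param chunk_size slots per chunk (the backend's `slot_count`).
#' @param plain_modulus optional plaintext modulus t; when given, any signal
#'   value >= t raises a capacity error naming the chromosome (a chromosome
#'   longer than t cannot be represented).
#' @return list with `chunks` (list of numeric vectors) and `manifest`
#'   (a `layout_manifest`).
#' @export
concat_and_chunk <- function(signals, chunk_size, plain_modulus = NULL) {
  stopifnot(inherits(signals, "signal_arrays"))
  if (!is_count(chunk_size, 1))
    cb_stop("cb_param_error", "chunk_size must be a positive integer")
  segs <- list()
  global <- numeric(0)
  off <- 0
  for (ch in signals$layout$chroms) {
    arrs <- signals$per_chrom[[ch]]
    for (sid in names(SEGMENTS)) {
      a <- arrs[[SEGMENTS[[sid]]]]
      if (!is.null(plain_modulus) && length(a) && max(a) >= plain_modulus)
        cb_stop("cb_capacity_error",
                "signal values on chromosome '%s' reach %.0f, exceeding the plaintext modulus %.0f",
                ch, max(a), plain_modulus)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, segment = sid, offset = off, length = length(a),
        stringsAsFactors = FALSE)
      global <- c(global, a)
      off <- off + length(a)
    }
  }
  total <- length(global)
  chunk_count <- max(1L, as.integer(ceiling(total / chunk_size)))
  padding <- chunk_count * chunk_size - total
  padded <- c(global, numeric(padding))
  chunks <- split(padded, rep(seq_len(chunk_count), each = chunk_size))
  names(chunks) <- NULL
  manifest <- structure(list(
    segments = do.call(rbind, segs),
    chunk_size = as.integer(chunk_size),
    chunk_count = chunk_count,
    total_length = total,
    padding = padding,
    fingerprint = NA_character_,
    epoch = NA_integer_
  ), class = "layout_manifest")
  list(chunks = chunks, manifest = manifest)
}

#' Client-secret chunk permutation
#'
#' Fisher-Yates shuffle of chunk order under a client-secret seed.  Chunk
#' contents are untouched; only the order changes.  The permutation map is
#' kept client-side and never uploaded.
#'
#' @param chunks list of plaintext chunks.
#' @param secret_seed integer seed (from a cryptographically strong source in
#'   deployment; a fixed integer in tests).
#' @return list with `chunks` (permuted) and `map` (a `permutation_map` with
#'   `pi[k]` = 1-based physical position of logical chunk k).
#' @export
permute_chunks <- function(chunks, secret_seed) {
  n <- length(chunks)
  pi <- with_seed(secret_seed, sample.int(n))
  permuted <- vector("list", n)
  for (k in seq_len(n)) permuted[[pi[k]]] <- chunks[[k]]
  map <- structure(list(pi = pi, epoch = NA_integer_,
                        seed_ref = sprintf("client-seed-%d", as.integer(secret_seed))),
                   class = "permutation_map")
  list(chunks = permuted, map = map)
}

#' Encrypt the permuted chunks
#'
#' One ciphertext per chunk; decrypting physical chunk `pi[k]` with the
#' secret key recovers logical chunk k.
#'
#' @param permuted list of permuted plaintext chunks.
#' @param keys key material (public part suffices to encrypt).
#' @param manifest the `layout_manifest` from [concat_and_chunk()].
#' @param map the `permutation_map`.
#' @param epoch integer epoch id of this encryption.
#' @return an `encrypted_db`: list of `cipher_chunk` indexed by physical id,
#'   plus fingerprint and epoch.
#' @export
encrypt_database <- function(permuted, keys, manifest, map, epoch = 1L) {
  stopifnot(inherits(keys, "he_keys"))
  if (manifest$chunk_size != keys$slot_count)
    cb_stop("cb_param_error", "chunk_size %d does not match backend slot count %d",
            manifest$chunk_size, keys$slot_count)
  chunks <- lapply(permuted, encrypt_chunk, keys = keys)
  structure(list(chunks = chunks, fingerprint = keys$fingerprint,
                 epoch = as.integer(epoch), backend = keys$backend,
                 chunk_size = manifest$chunk_size),
            class = "encrypted_db")
}

#' One-shot database build
#'
#' Convenience wrapper running the full client-side provisioning path:
#' signals -> global vector -> chunks -> secret permutation -> encryption.
#'
#' @param B database `interval_set`.
#' @param keys key material.
#' @param secret_seed seed of the client-secret permutation.
#' @param layout genome layout (defaults to that of `B`).
#' @param epoch epoch id (1 for a first build).
#' @return list with `db` (encrypted_db), `manifest`, `map`, `signals`.
#' @export
build_database <- function(B, keys, secret_seed, layout = B$layout, epoch = 1L) {
  signals <- build_signals(B, layout)
  cc <- concat_and_chunk(signals, keys$slot_count, keys$plain_modulus)
  pm <- permute_chunks(cc$chunks, secret_seed)
  cc$manifest$fingerprint <- keys$fingerprint
  cc$manifest$epoch <- as.integer(epoch)
  pm$map$epoch <- as.integer(epoch)
  db <- encrypt_database(pm$chunks, keys, cc$manifest, pm$map, epoch = epoch)
  list(db = db, manifest = cc$manifest, map = pm$map, signals = signals)
}

#' Refresh the hosted database
#'
#' Re-randomizes the chunk permutation under a new secret seed and re-encrypts
#' the permuted chunks, bumping the epoch id.  Previously compiled plans are
#' invalidated by the epoch check; the decrypted logical content is unchanged.
#'
#' @param signals plaintext `signal_arrays` (the client retains or re-derives
#'   them).
#' @param keys key material.
#' @param new_seed fresh permutation seed.
#' @param old_epoch epoch being replaced.
#' @return same shape as [build_database()].
#' @export
refresh_database <- function(signals, keys, new_seed, old_epoch) {
  cc <- concat_and_chunk(signals, keys$slot_count, keys$plain_modulus)
  pm <- permute_chunks(cc$chunks, new_seed)
  epoch <- as.integer(old_epoch) + 1L
  cc$manifest$fingerprint <- keys$fingerprint
  cc$manifest$epoch <- epoch
  pm$map$epoch <- epoch
  db <- encrypt_database(pm$chunks, keys, cc$manifest, pm$map, epoch = epoch)
  list(db = db, manifest = cc$manifest, map = pm$map, signals = signals)
}

# segment length rule: prefix segments hold L+1 readable coordinates (0..L),
# the depth segment holds L (0..L-1)
segment_row <- function(manifest, segment, chrom) {
  seg <- manifest$segments
  row <- seg[seg$segment == segment & seg$chrom == chrom, , drop = FALSE]
  if (nrow(row) != 1)
    cb_stop("cb_addressing_error", "no segment %s for chromosome '%s'", segment, chrom)
  row
}

#' Map a logical read to a physical selector
#'
#' Translates (segment, chromosome, coordinate) through the layout manifest
#' to a global index, then through the client-secret permutation to the
#' physical (chunk id, slot offset) the server is asked for.  The selector
#' carries only physical addresses and the request ordinal.
#'
#' @param manifest a `layout_manifest`.
#' @param map a `permutation_map`.
#' @param segment one of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @param chrom chromosome name.
#' @param coordinate 0-based coordinate; for prefix segments in `[0, L]`,
#'   for the depth segment in `[0, L)`.
#' @param ordinal client-side reassembly key.
#' @return a `selector`: list(chunk, slot, ordinal), chunk and slot 0-based.
#' @export
logical_to_selector <- function(manifest, map, segment, chrom, coordinate, ordinal = 0L) {
  row <- segment_row(manifest, segment, chrom)
  if (!is_count(coordinate) || coordinate >= row$length)
    cb_stop("cb_addressing_error",
            "coordinate %s out of range for segment %s of '%s' (length %d)",
            format(coordinate), segment, chrom, row$length)
  gidx <- row$offset + coordinate
  logical_chunk <- gidx %/% manifest$chunk_size
  slot <- gidx %% manifest$chunk_size
  phys <- map$pi[logical_chunk + 1L] - 1L
  structure(list(chunk = as.integer(phys), slot = as.integer(slot),
                 ordinal = as.integer(ordinal)), class = "selector")
}

# vectorized selector compilation used by the query planner
selectors_for_reads <- function(manifest, map, segment, chrom, coordinate) {
  seg <- manifest$segments
  key <- paste(seg$segment, seg$chrom)
  idx <- match(paste(segment, chrom), key)
  if (anyNA(idx))
    cb_stop("cb_addressing_error", "read against unknown segment/chromosome")
  if (any(coordinate < 0) || any(coordinate >= seg$length[idx]))
    cb_stop("cb_addressing_error", "read coordinate out of segment range")
  gidx <- seg$offset[idx] + coordinate
  logical_chunk <- gidx %/% manifest$chunk_size
  data.frame(chunk = map$pi[logical_chunk + 1L] - 1L,
             slot = as.integer(gidx %% manifest$chunk_size))
}

# ------------------------------------------------------------ store on disk

#' Write the server-side store
#'
#' Materializes what the server hosts: numbered ciphertext blobs, the public
#' parameter/key bundle and the epoch id.  No manifest, no permutation map
#' and no secret key are ever written here.
#'
#' @param db an `encrypted_db`.
#' @param dir target directory (created if needed).
#' @param keys key material; only its public part is stored.
#' @export
write_store <- function(db, dir, keys) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(backend = db$backend, fingerprint = db$fingerprint,
               epoch = db$epoch, chunk_count = length(db$chunks),
               chunk_size = db$chunk_size)
  jsonlite::write_json(meta, file.path(dir, "params.json"), auto_unbox = TRUE)
  save_keys(keys, file.path(dir, "public.bin"), secret_path = NULL)
  for (i in seq_along(db$chunks)) {
    writeBin(serialize_chunk(db$chunks[[i]]),
             file.path(dir, sprintf("chunk_%06d.bin", i - 1L)))
  }
  invisible(dir)
}

#' Client-side state serialization
#'
#' The layout manifest and permutation map (and, separately, key files) live
#' only in the client directory.
#'
#' @param manifest a `layout_manifest`.
#' @param map a `permutation_map`.
#' @param path JSON file path.
#' @export
write_client_state <- function(manifest, map, path) {
  obj <- list(segments = manifest$segments, chunk_size = manifest$chunk_size,
              chunk_count = manifest$chunk_count,
              total_length = manifest$total_length, padding = manifest$padding,
              fingerprint = manifest$fingerprint, epoch = manifest$epoch,
              pi = map$pi, seed_ref = map$seed_ref)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_client_state
#' @export
read_client_state <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  manifest <- structure(list(
    segments = as.data.frame(obj$segments, stringsAsFactors = FALSE),
    chunk_size = as.integer(obj$chunk_size),
    chunk_count = as.integer(obj$chunk_count),
    total_length = as.numeric(obj$total_length),
    padding = as.numeric(obj$padding),
    fingerprint = obj$fingerprint,
    epoch = as.integer(obj$epoch)), class = "layout_manifest")
  map <- structure(list(pi = as.integer(obj$pi), epoch = as.integer(obj$epoch),
                        seed_ref = obj$seed_ref), class = "permutation_map")
  list(manifest = manifest, map = map)
}
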