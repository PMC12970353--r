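# Server side: host the encrypted chunk store and run the fixed
# rotate-and-mask kernel per selector.  The server never holds a secret key,
# never decrypts, and executes the identical operation sequence for every
# query class.

#' Extraction request / response
#'
#' The only messages exchanged between client and server: an ordered list of
#' selectors in, extracted encrypted scalars out (same ordinals, same order).
#'
#' @param epoch epoch id the request was compiled against.
#' @param selectors data frame with columns `chunk`, `slot`, `ordinal`
#'   (0-based chunk/slot).
#' @return an `extraction_request`.
#' @export
extraction_request <- function(epoch, selectors) {
  if (is.null(selectors) || nrow(selectors) == 0)
    cb_stop("cb_request_error", "empty extraction request")
  stopifnot(all(c("chunk", "slot", "ordinal") %in% names(selectors)))
  structure(list(epoch = as.integer(epoch), selectors = selectors),
            class = "extraction_request")
}

#' Host an encrypted store
#'
#' Opens a store directory written by [write_store()] and returns a hosting
#' handle with on-demand chunk loading (small bounded cache, so peak working
#' memory is a constant number of chunks regardless of database or request
#' size).  Nothing is decrypted: the handle carries only the public key
#' bundle.
#'
#' @param dir store directory.
#' @param max_cached maximum number of ciphertext chunks held in memory.
#' @return a `server_handle`.
#' @export
load_db <- function(dir, max_cached = 4L) {
  pj <- file.path(dir, "params.json")
  if (!file.exists(pj)) cb_stop("cb_store_error", "no params.json in store '%s'", dir)
  meta <- jsonlite::read_json(pj, simplifyVector = TRUE)
  pub <- file.path(dir, "public.bin")
  if (!file.exists(pub)) cb_stop("cb_store_error", "no public key bundle in store '%s'", dir)
  keys <- load_keys(pub, secret_path = NULL, backend = meta$backend)
  if (!identical(keys$fingerprint, meta$fingerprint))
    cb_stop("cb_store_error", "public bundle does not match store parameters")
  files <- file.path(dir, sprintf("chunk_%06d.bin", seq_len(meta$chunk_count) - 1L))
  missing <- !file.exists(files)
  if (any(missing))
    cb_stop("cb_store_error", "store '%s' is missing chunk %d of %d",
            dir, which(missing)[1] - 1L, meta$chunk_count)
  h <- new.env(parent = emptyenv())
  h$dir <- dir
  h$keys <- keys                       # public part only
  h$epoch <- as.integer(meta$epoch)
  h$chunk_count <- as.integer(meta$chunk_count)
  h$chunk_size <- as.integer(meta$chunk_size)
  h$backend <- meta$backend
  h$files <- files
  h$cache <- list()
  h$max_cached <- as.integer(max_cached)
  h$peak_cached <- 0L
  class(h) <- "server_handle"
  h
}

#' In-memory hosting (loopback transport)
#'
#' Hosts an `encrypted_db` object directly, for in-process use and tests.
#' The handle is built from the public key part only.
#'
#' @param db an `encrypted_db`.
#' @param public_keys public key material (`public_part(keys)`); passing keys
#'   that still contain a secret is rejected, mirroring the deployment rule
#'   that the server never receives secret material.
#' @param max_cached bound on simultaneously held chunks (kept for symmetry;
#'   the in-memory host references chunks it already owns).
#' @return a `server_handle`.
#' @export
host_db <- function(db, public_keys, max_cached = 4L) {
  stopifnot(inherits(db, "encrypted_db"))
  if (isTRUE(public_keys$has_secret))
    cb_stop("cb_param_error", "refusing to host with secret key material; use public_part()")
  if (!identical(public_keys$fingerprint, db$fingerprint))
    cb_stop("cb_store_error", "key parameters do not match the encrypted database")
  h <- new.env(parent = emptyenv())
  h$dir <- NULL
  h$keys <- public_keys
  h$epoch <- db$epoch
  h$chunk_count <- length(db$chunks)
  h$chunk_size <- db$chunk_size
  h$backend <- db$backend
  h$chunks <- db$chunks
  h$cache <- list()
  h$max_cached <- as.integer(max_cached)
  h$peak_cached <- 0L
  class(h) <- "server_handle"
  h
}

get_chunk <- function(h, chunk_id) {
  if (chunk_id < 0 || chunk_id >= h$chunk_count)
    cb_stop("cb_addressing_error", "chunk id %d out of range [0, %d)",
            chunk_id, h$chunk_count)
  if (!is.null(h$dir)) {
    key <- as.character(chunk_id)
    hit <- h$cache[[key]]
    if (!is.null(hit)) return(hit)
    raw <- readBin(h$files[chunk_id + 1L], "raw",
                   file.size(h$files[chunk_id + 1L]))
    ch <- deserialize_chunk(raw, h$keys)
    if (length(h$cache) >= h$max_cached) h$cache[[1]] <- NULL  # evict oldest
    h$cache[[key]] <- ch
    h$peak_cached <- max(h$peak_cached, length(h$cache))
    ch
  } else {
    h$peak_cached <- max(h$peak_cached, 1L)
    h$chunks[[chunk_id + 1L]]
  }
}

#' Blind extraction of one scalar
#'
#' The fixed server-side kernel: load the referenced ciphertext chunk, rotate
#' the requested slot to the front, multiply by the plaintext unit mask.  The
#' identical sequence runs for every selector regardless of which query class
#' it serves; the server cannot tell coverage reads from Jaccard reads.
#'
#' @param handle a `server_handle`.
#' @param selector a `selector` (or list with `chunk`, `slot`).
#' @return a `cipher_chunk` holding the requested scalar in slot 0.
#' @export
extract <- function(handle, selector) {
  if (selector$slot < 0 || selector$slot >= handle$chunk_size)
    cb_stop("cb_addressing_error", "slot offset %d out of range [0, %d)",
            selector$slot, handle$chunk_size)
  ch <- get_chunk(handle, selector$chunk)
  mask_front(bring_to_front(ch, selector$slot, handle$keys), handle$keys)
}

#' Batched blind extraction
#'
#' Executes the kernel once per selector, streaming: chunks are loaded on
#' demand under a constant-size cache, and the response preserves request
#' order (ordinals) even when execution order is scrambled.
#'
#' @param handle a `server_handle`.
#' @param req an `extraction_request`.
#' @param scramble execute in a random internal order (simulating parallel
#'   completion) and restore request order in the response; default FALSE.
#' @return an `extraction_response`: epoch, `ordinals`, and `results` (list
#'   of cipher chunks in request order).
#' @export
extract_batch <- function(handle, req, scramble = FALSE) {
  stopifnot(inherits(req, "extraction_request"))
  if (req$epoch != handle$epoch)
    cb_stop("cb_stale_plan_error",
            "request epoch %d does not match hosted epoch %d (stale plan)",
            req$epoch, handle$epoch)
  sel <- req$selectors
  n <- nrow(sel)
  if (any(sel$chunk < 0) || any(sel$chunk >= handle$chunk_count))
    cb_stop("cb_addressing_error", "selector chunk id out of range")
  if (any(sel$slot < 0) || any(sel$slot >= handle$chunk_size))
    cb_stop("cb_addressing_error", "selector slot offset out of range")
  exec_order <- if (scramble) sample.int(n) else seq_len(n)

  if (handle$backend == "mock" && !is.null(handle$chunks)) {
    # functional fast path for the plaintext mock: identical semantics and
    # identical op accounting, vectorized over the batch
    half <- handle$chunk_size / 2
    keys <- handle$keys
    keys$ops$rotations <- keys$ops$rotations +
      sum(rotation_ops(sel$slot %% half, handle$chunk_size)) + sum(sel$slot >= half)
    keys$ops$plain_mults <- keys$ops$plain_mults + n
    v0 <- numeric(n)
    noise <- integer(n)
    for (i in exec_order) {
      ch <- handle$chunks[[sel$chunk[i] + 1L]]
      v0[i] <- ch$v[sel$slot[i] + 1L]
      noise[i] <- max(0L, ch$noise - MOCK_ROTATION_COST - MOCK_MASK_COST)
    }
    res <- structure(list(epoch = handle$epoch, ordinals = sel$ordinal,
                          v0 = v0, noise = noise,
                          len = handle$chunk_size,
                          fingerprint = handle$keys$fingerprint,
                          token = handle$chunks[[1]]$token,
                          columnar = TRUE),
                     class = "extraction_response")
    return(res)
  }

  results <- vector("list", n)
  for (i in exec_order) {
    results[[i]] <- tryCatch(
      extract(handle, list(chunk = sel$chunk[i], slot = sel$slot[i])),
      error = function(e) cb_stop("cb_request_error",
                                  "extraction failed at ordinal %d: %s",
                                  sel$ordinal[i], conditionMessage(e)))
  }
  structure(list(epoch = handle$epoch, ordinals = sel$ordinal,
                 results = results, columnar = FALSE),
            class = "extraction_response")
}

#' Decrypt an extraction response into the scalar stream
#'
#' Client-side: decrypts each returned ciphertext, reads slot 0, and returns
#' scalars in request order.  Any nonzero non-front slot indicates a mask
#' contract violation and raises a corruption warning.
#'
#' @param resp an `extraction_response`.
#' @param keys secret key material.
#' @return numeric vector of scalars, one per selector, in request order.
#' @export
decrypt_scalars <- function(resp, keys) {
  stopifnot(inherits(resp, "extraction_response"))
  if (isTRUE(resp$columnar)) {
    if (!identical(resp$token, keys$secret_token))
      cb_stop("cb_corruption_error", "mock decryption with mismatched secret key")
    return(resp$v0)
  }
  vapply(resp$results, function(ch) {
    v <- decrypt_chunk(ch, keys)
    if (any(v[-1] != 0))
      warning("nonzero non-front slot in extracted scalar (mask contract violation)",
              call. = FALSE)
    v[1]
  }, numeric(1))
}

#' Serialized size of an extraction response
#'
#' Bytes the client downloads for this response (each extracted scalar ships
#' as one full ciphertext chunk).
#'
#' @param resp an `extraction_response`.
#' @return number of bytes.
#' @export
response_bytes <- function(resp) {
  if (isTRUE(resp$columnar)) {
    # nominal wire size of the plaintext mock: one chunk-sized blob per scalar
    length(resp$v0) * (resp$len * 8 + 16)
  } else {
    sum(vapply(resp$results, function(ch) length(serialize_chunk(ch)), numeric(1)))
  }
}

# ------------------------------------------------------------ dir transport

#' Filesystem mailbox transport
#'
#' Minimal request/response exchange over a shared directory: the client
#' drops `req_*.bin`, the server (this function) processes every pending
#' request against the store and writes `resp_*.bin`.
#'
#' @param db_dir store directory ([write_store()]).
#' @param mailbox shared mailbox directory.
#' @return number of requests served.
#' @export
serve_dir_once <- function(db_dir, mailbox) {
  handle <- load_db(db_dir)
  reqs <- list.files(mailbox, pattern = "^req_.*\\.bin$", full.names = TRUE)
  for (rf in reqs) {
    req <- unserialize(readBin(rf, "raw", file.size(rf)))
    resp <- tryCatch(extract_batch(handle, req), error = function(e) e)
    out <- sub("req_", "resp_", rf)
    writeBin(serialize(resp, NULL), out)
    file.remove(rf)
  }
  length(reqs)
}

#' @export
print.server_handle <- function(x, ...) {
  cat(sprintf("<server_handle %s backend, %d chunks x %d slots, epoch %d>\n",
              x$backend, x$chunk_count, x$chunk_size, x$epoch))
  invisible(x)
}
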