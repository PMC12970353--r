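#' BFV parameter set
#'
#' Describes the lattice parameters used by the homomorphic backend: the ring
#' dimension (which equals the number of SIMD slots), the bit length of the
#' batching-compatible prime plaintext modulus \eqn{t}, the security target,
#' and optionally an explicit coefficient-modulus chain.
#'
#' @param poly_degree power-of-two ring dimension N (\eqn{\ge} 4096); one
#'   ciphertext batches `poly_degree` integer slots.
#' @param plain_modulus_bits bit length of the plaintext modulus; the realized
#'   modulus is the smallest prime of that bit length congruent to 1 mod 2N,
#'   so that SIMD batching is available.
#' @param security_bits target security level; only 128 is supported, and the
#'   total coefficient-modulus size is capped accordingly.
#' @param coeff_modulus_bits integer vector of prime bit lengths composing the
#'   ciphertext modulus (the last prime is reserved for key switching); empty
#'   means the backend default chain for (`poly_degree`, 128-bit security),
#'   e.g. 43+43+44+44+44 = 218 bits at N = 8192.
#' @return an object of class `he_params`.
#' @export
he_params <- function(poly_degree = 8192L, plain_modulus_bits = 30L,
                      security_bits = 128L, coeff_modulus_bits = integer(0)) {
  if (!is_count(poly_degree, 1) || poly_degree < 4096 ||
      bitwAnd(as.integer(poly_degree), as.integer(poly_degree) - 1L) != 0L)
    cb_stop("cb_param_error", "poly_degree must be a power of two >= 4096 (got %s)",
            format(poly_degree))
  if (!is_count(plain_modulus_bits, 16) || plain_modulus_bits > 40)
    cb_stop("cb_param_error", "plain_modulus_bits must be an integer in [16, 40]")
  if (!identical(as.integer(security_bits), 128L))
    cb_stop("cb_param_error", "security_bits: only 128-bit security is supported")
  structure(list(
    poly_degree = as.integer(poly_degree),
    plain_modulus_bits = as.integer(plain_modulus_bits),
    security_bits = 128L,
    coeff_modulus_bits = as.integer(coeff_modulus_bits)
  ), class = "he_params")
}

#' Default coefficient-modulus chain
#'
#' Bit lengths of the default ciphertext-modulus primes for a given ring
#' dimension at 128-bit security (the last prime is the key-switching prime).
#'
#' @param poly_degree power-of-two ring dimension.
#' @return integer vector of prime bit lengths.
#' @export
default_coeff_bits <- function(poly_degree) {
  .bfv_default_coeff_bits(as.integer(poly_degree))
}

#' Realized batching plaintext modulus
#'
#' The smallest prime with the requested bit length that is congruent to
#' 1 mod 2N, i.e. the modulus `he_params` resolves to.
#'
#' @param poly_degree ring dimension N.
#' @param bits requested bit length.
#' @return the prime, as a double.
#' @export
batching_prime <- function(poly_degree, bits) {
  .bfv_batch_prime(as.integer(poly_degree), as.integer(bits))
}

#' Generate key material
#'
#' Creates the key material for one of the two homomorphic backends.  For the
#' real BFV backend this generates the secret key, the public encryption key
#' and the rotation (Galois) evaluation keys covering all power-of-two row
#' rotations plus the row swap - exactly what the blind-extraction kernel
#' needs.  For the mock backend it creates deterministic stub keys carrying a
#' calibrated noise ledger (fresh budget 136 bits, -3 per rotation, -35 per
#' plaintext mask).
#'
#' @param params an `he_params` object.
#' @param backend `"bfv"` (real lattice backend) or `"mock"` (plaintext model).
#' @param seed integer seed for key generation and encryption randomness.
#' @return an object of class `he_keys` holding the secret part; use
#'   [public_part()] to derive the server-safe half.
#' @export
keygen <- function(params, backend = c("bfv", "mock"), seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(inherits(params, "he_params"))
  if (!is_count(seed)) cb_stop("cb_param_error", "seed must be a non-negative integer")
  if (backend == "bfv") {
    ctx <- .bfv_context_new(params$poly_degree, params$plain_modulus_bits,
                            params$security_bits, params$coeff_modulus_bits,
                            as.numeric(seed))
    info <- .bfv_params(ctx)
    keys <- list(backend = "bfv", params = params, ctx = ctx,
                 slot_count = info$slot_count, plain_modulus = info$plain_modulus,
                 fingerprint = info$fingerprint, has_secret = TRUE,
                 ops = new.env(parent = emptyenv()))
  } else {
    t <- batching_prime(params$poly_degree, params$plain_modulus_bits)
    fingerprint <- sprintf("mock|N=%d|t=%.0f|sec=%d", params$poly_degree, t,
                           params$security_bits)
    keys <- list(backend = "mock", params = params, ctx = NULL,
                 slot_count = params$poly_degree, plain_modulus = t,
                 fingerprint = fingerprint, has_secret = TRUE,
                 secret_token = sprintf("mock-secret-%d", as.integer(seed)),
                 ops = new.env(parent = emptyenv()))
  }
  keys$ops$rotations <- 0L
  keys$ops$plain_mults <- 0L
  class(keys) <- "he_keys"
  keys
}

#' Server-safe half of the key material
#'
#' Returns key material stripped of the secret part: it can encrypt, rotate
#' and mask but not decrypt or measure noise.  This is what a hosting server
#' is provisioned with.
#'
#' @param keys an `he_keys` object.
#' @return an `he_keys` object with `has_secret = FALSE`.
#' @export
public_part <- function(keys) {
  stopifnot(inherits(keys, "he_keys"))
  if (keys$backend == "bfv") keys$ctx <- .bfv_public_clone(keys$ctx)
  keys$has_secret <- FALSE
  keys$secret_token <- NULL
  keys$ops <- new.env(parent = emptyenv())
  keys$ops$rotations <- 0L
  keys$ops$plain_mults <- 0L
  keys
}

# constants of the calibrated mock noise ledger
MOCK_FRESH_BUDGET <- 136L
MOCK_ROTATION_COST <- 3L
MOCK_MASK_COST <- 35L

new_mock_chunk <- function(v, noise, fingerprint, token, scalar = FALSE, len = NULL) {
  structure(list(v = v, noise = noise, fingerprint = fingerprint,
                 token = token, scalar = scalar, len = len),
            class = c("mock_chunk", "cipher_chunk"))
}

chunk_backend <- function(chunk) {
  if (inherits(chunk, "mock_chunk")) "mock" else if (inherits(chunk, "bfv_chunk")) "bfv"
  else cb_stop("cb_param_error", "not a cipher chunk")
}

check_chunk_keys <- function(chunk, keys) {
  if (!identical(chunk_backend(chunk), keys$backend))
    cb_stop("cb_param_error", "cipher chunk backend '%s' does not match key backend '%s'",
            chunk_backend(chunk), keys$backend)
  if (!identical(chunk$fingerprint, keys$fingerprint))
    cb_stop("cb_param_error", "cipher chunk parameter fingerprint mismatch")
}

#' Encrypt one slot batch
#'
#' Packs `slot_count` integers (all in `[0, t)`) into a single ciphertext
#' chunk.
#'
#' @param values integer vector of length `slot_count`.
#' @param keys key material from [keygen()] (public part suffices).
#' @return a `cipher_chunk`.
#' @export
encrypt_chunk <- function(values, keys) {
  stopifnot(inherits(keys, "he_keys"))
  if (length(values) != keys$slot_count)
    cb_stop("cb_param_error", "expected %d slot values, got %d",
            keys$slot_count, length(values))
  values <- as.numeric(values)
  if (any(is.na(values)) || any(values < 0) || any(values != floor(values)))
    cb_stop("cb_overflow_error", "slot values must be non-negative integers")
  if (any(values >= keys$plain_modulus))
    cb_stop("cb_overflow_error",
            "slot value %.0f exceeds the plaintext modulus capacity t = %.0f",
            max(values), keys$plain_modulus)
  if (keys$backend == "bfv") {
    blob <- .bfv_encrypt(keys$ctx, values)
    structure(list(blob = blob, fingerprint = keys$fingerprint),
              class = c("bfv_chunk", "cipher_chunk"))
  } else {
    new_mock_chunk(values, MOCK_FRESH_BUDGET, keys$fingerprint, keys$secret_token)
  }
}

#' Decrypt a ciphertext chunk
#'
#' Exact inverse of [encrypt_chunk()] while noise budget remains positive.
#' Requires the secret part of the key material; on the real backend an
#' exhausted noise budget raises a corruption error rather than returning
#' silently wrong values.
#'
#' @param chunk a `cipher_chunk`.
#' @param keys secret key material.
#' @return numeric vector of `slot_count` values in `[0, t)`.
#' @export
decrypt_chunk <- function(chunk, keys) {
  stopifnot(inherits(keys, "he_keys"))
  check_chunk_keys(chunk, keys)
  if (!isTRUE(keys$has_secret))
    cb_stop("cb_param_error", "decryption requires the secret part of the key material")
  if (keys$backend == "bfv") {
    res <- .bfv_decrypt_checked(keys$ctx, chunk$blob)
    if (res$budget <= 0L)
      cb_stop("cb_corruption_error", "noise budget exhausted; decryption would be unreliable")
    res$values
  } else {
    if (!identical(chunk$token, keys$secret_token))
      cb_stop("cb_corruption_error", "mock decryption with mismatched secret key")
    mock_chunk_values(chunk)
  }
}

mock_chunk_values <- function(chunk) {
  if (isTRUE(chunk$scalar)) c(chunk$v, numeric(chunk$len - 1L)) else chunk$v
}

#' Rotate slots left
#'
#' Cyclically rotates the two batching rows left by `steps` positions using
#' the Galois evaluation keys (the server-side primitive underlying
#' [bring_to_front()]).  One call consumes `popcount(steps)` key-switched
#' rotations.
#'
#' @param chunk a `cipher_chunk`.
#' @param steps rotation amount, `1 <= steps < slot_count/2`.
#' @param keys key material (public part suffices).
#' @return rotated `cipher_chunk`.
#' @export
rotate_slots <- function(chunk, steps, keys) {
  check_chunk_keys(chunk, keys)
  half <- keys$slot_count / 2
  if (!is_count(steps, 1) || steps >= half)
    cb_stop("cb_addressing_error", "rotation steps out of range [1, %d)", half)
  keys$ops$rotations <- keys$ops$rotations + rotation_ops(steps, keys$slot_count)
  if (keys$backend == "bfv") {
    structure(list(blob = .bfv_rotate_rows(keys$ctx, chunk$blob, as.integer(steps)),
                   fingerprint = keys$fingerprint),
              class = c("bfv_chunk", "cipher_chunk"))
  } else {
    v <- mock_chunk_values(chunk)
    idx_half <- seq_len(half)
    rot <- function(x) x[((seq_along(x) - 1 + steps) %% length(x)) + 1]
    v2 <- c(rot(v[idx_half]), rot(v[half + idx_half]))
    new_mock_chunk(v2, max(0L, chunk$noise - MOCK_ROTATION_COST),
                   chunk$fingerprint, chunk$token)
  }
}

#' Move a slot to the front
#'
#' Returns a chunk whose slot 0 holds the value previously at `offset`.  The
#' backend's internal two-row batching layout is hidden: the implementation
#' composes power-of-two row rotations (binary decomposition of the offset)
#' and a column swap when the offset lies in the second row.  A zero offset
#' skips rotation entirely (identity) but downstream masking is still
#' required.
#'
#' @param chunk a `cipher_chunk`.
#' @param offset slot index in `[0, slot_count)`.
#' @param keys key material (public part suffices).
#' @return `cipher_chunk` with the requested value in slot 0.
#' @export
bring_to_front <- function(chunk, offset, keys) {
  check_chunk_keys(chunk, keys)
  if (!is_count(offset) || offset >= keys$slot_count)
    cb_stop("cb_addressing_error", "slot offset %s out of range [0, %d)",
            format(offset), keys$slot_count)
  half <- keys$slot_count / 2
  keys$ops$rotations <- keys$ops$rotations +
    rotation_ops(offset %% half, keys$slot_count) + as.integer(offset >= half)
  if (keys$backend == "bfv") {
    structure(list(blob = .bfv_bring_to_front(keys$ctx, chunk$blob, as.integer(offset)),
                   fingerprint = keys$fingerprint),
              class = c("bfv_chunk", "cipher_chunk"))
  } else {
    v <- mock_chunk_values(chunk)
    # model the rotate semantics exactly: value at `offset` lands in slot 0
    idx_half <- seq_len(half)
    row <- offset >= half
    k <- offset %% half
    lo <- v[idx_half]; hi <- v[half + idx_half]
    if (row) { tmp <- lo; lo <- hi; hi <- tmp }
    rot <- function(x) x[((seq_along(x) - 1 + k) %% length(x)) + 1]
    v2 <- c(rot(lo), rot(hi))
    # one logical rotation in the calibrated ledger
    new_mock_chunk(v2, max(0L, chunk$noise - MOCK_ROTATION_COST),
                   chunk$fingerprint, chunk$token)
  }
}

#' Mask all slots but the first
#'
#' Multiplies by the plaintext unit vector `e0`: the result decrypts to
#' `[v0, 0, 0, ...]`.  One plaintext multiplication, no relinearization.
#'
#' @param chunk a `cipher_chunk`.
#' @param keys key material (public part suffices).
#' @return masked `cipher_chunk`.
#' @export
mask_front <- function(chunk, keys) {
  check_chunk_keys(chunk, keys)
  keys$ops$plain_mults <- keys$ops$plain_mults + 1L
  if (keys$backend == "bfv") {
    structure(list(blob = .bfv_mask_front(keys$ctx, chunk$blob),
                   fingerprint = keys$fingerprint),
              class = c("bfv_chunk", "cipher_chunk"))
  } else {
    v <- mock_chunk_values(chunk)
    new_mock_chunk(v[1], max(0L, chunk$noise - MOCK_MASK_COST),
                   chunk$fingerprint, chunk$token,
                   scalar = TRUE, len = length(v))
  }
}

#' Remaining noise budget
#'
#' Bits of invariant-noise headroom left in a ciphertext; 0 means decryption
#' is unreliable.  On the real backend this is measured with the secret key
#' (SEAL-style invariant noise); the mock backend reads its calibrated ledger.
#'
#' @param chunk a `cipher_chunk`.
#' @param keys secret key material (real backend) or mock keys.
#' @return non-negative integer number of bits.
#' @export
noise_budget <- function(chunk, keys) {
  check_chunk_keys(chunk, keys)
  if (keys$backend == "bfv") {
    if (!isTRUE(keys$has_secret))
      cb_stop("cb_param_error", "noise budget measurement requires the secret key")
    .bfv_noise_budget(keys$ctx, chunk$blob)
  } else {
    as.integer(chunk$noise)
  }
}

#' Homomorphic operation counters
#'
#' Number of key-switched rotations and plaintext multiplications performed
#' with this key material since the last reset; used to assert the kernel's
#' uniformity across query classes.
#'
#' @param keys an `he_keys` object.
#' @return named integer vector `c(rotations=, plain_mults=)`.
#' @export
op_counts <- function(keys) {
  if (keys$backend == "bfv") {
    oc <- .bfv_op_counts(keys$ctx)
    c(rotations = unname(oc["rotations"]), plain_mults = unname(oc["plain_mults"]))
  } else {
    c(rotations = keys$ops$rotations, plain_mults = keys$ops$plain_mults)
  }
}

#' @rdname op_counts
#' @export
reset_op_counts <- function(keys) {
  if (keys$backend == "bfv") .bfv_reset_op_counts(keys$ctx)
  keys$ops$rotations <- 0L
  keys$ops$plain_mults <- 0L
  invisible(keys)
}

#' Serialize / deserialize a cipher chunk
#'
#' Chunk blobs are backend-opaque bytes tagged with the parameter
#' fingerprint; deserializing under different keys or a different backend is
#' rejected.
#'
#' @param chunk a `cipher_chunk`.
#' @return a raw vector.
#' @export
serialize_chunk <- function(chunk) {
  if (inherits(chunk, "bfv_chunk")) {
    c(as.raw(1L), chunk$blob)
  } else if (inherits(chunk, "mock_chunk")) {
    c(as.raw(2L), serialize(unclass(chunk), NULL))
  } else cb_stop("cb_param_error", "not a cipher chunk")
}

#' @rdname serialize_chunk
#' @param raw raw vector from [serialize_chunk()].
#' @param keys key material whose parameters the blob must match.
#' @export
deserialize_chunk <- function(raw, keys) {
  tag <- as.integer(raw[1])
  if (tag == 1L) {
    if (keys$backend != "bfv")
      cb_stop("cb_param_error", "blob was produced by the bfv backend, keys are '%s'", keys$backend)
    blob <- raw[-1]
    if (!.bfv_blob_matches(keys$ctx, blob))
      cb_stop("cb_param_error", "ciphertext blob does not match these parameters")
    structure(list(blob = blob, fingerprint = keys$fingerprint),
              class = c("bfv_chunk", "cipher_chunk"))
  } else if (tag == 2L) {
    if (keys$backend != "mock")
      cb_stop("cb_param_error", "blob was produced by the mock backend, keys are '%s'", keys$backend)
    obj <- unserialize(raw[-1])
    chunk <- structure(obj, class = c("mock_chunk", "cipher_chunk"))
    check_chunk_keys(chunk, keys)
    chunk
  } else cb_stop("cb_param_error", "unrecognized chunk blob")
}

#' Save / load key material
#'
#' The public bundle (encryption + Galois keys) and the secret key are stored
#' as separate binary files; the secret key never needs to leave the client
#' directory.  Mock keys serialize their stub state.
#'
#' @param keys an `he_keys` object.
#' @param public_path file path for the public bundle.
#' @param secret_path file path for the secret key, or `NULL` to skip.
#' @export
save_keys <- function(keys, public_path, secret_path = NULL) {
  stopifnot(inherits(keys, "he_keys"))
  if (keys$backend == "bfv") {
    .bfv_save_public(keys$ctx, public_path)
    if (!is.null(secret_path)) {
      if (!isTRUE(keys$has_secret)) cb_stop("cb_param_error", "keys hold no secret part")
      .bfv_save_secret(keys$ctx, secret_path)
    }
  } else {
    pub <- keys[c("backend", "params", "slot_count", "plain_modulus", "fingerprint")]
    writeBin(serialize(pub, NULL), public_path)
    if (!is.null(secret_path))
      writeBin(serialize(keys$secret_token, NULL), secret_path)
  }
  invisible(NULL)
}

#' @rdname save_keys
#' @param backend backend tag the files were produced by.
#' @export
load_keys <- function(public_path, secret_path = NULL, backend = c("bfv", "mock")) {
  backend <- match.arg(backend)
  if (backend == "bfv") {
    ctx <- .bfv_load(public_path, if (is.null(secret_path)) "" else secret_path)
    info <- .bfv_params(ctx)
    keys <- list(backend = "bfv",
                 params = he_params(info$poly_degree, info$plain_modulus_bits,
                                    info$security_bits, info$coeff_modulus_bits),
                 ctx = ctx, slot_count = info$slot_count,
                 plain_modulus = info$plain_modulus,
                 fingerprint = info$fingerprint,
                 has_secret = isTRUE(info$has_secret),
                 ops = new.env(parent = emptyenv()))
  } else {
    pub <- unserialize(readBin(public_path, "raw", file.size(public_path)))
    keys <- list(backend = "mock", params = pub$params, ctx = NULL,
                 slot_count = pub$slot_count, plain_modulus = pub$plain_modulus,
                 fingerprint = pub$fingerprint, has_secret = FALSE,
                 ops = new.env(parent = emptyenv()))
    if (!is.null(secret_path)) {
      keys$secret_token <- unserialize(readBin(secret_path, "raw", file.size(secret_path)))
      keys$has_secret <- TRUE
    }
  }
  keys$ops$rotations <- 0L
  keys$ops$plain_mults <- 0L
  class(keys) <- "he_keys"
  keys
}

#' @export
print.he_keys <- function(x, ...) {
  cat(sprintf("<he_keys %s backend, N=%d, t=%.0f, %s>\n", x$backend,
              x$slot_count, x$plain_modulus,
              if (x$has_secret) "secret+public" else "public only"))
  invisible(x)
}
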