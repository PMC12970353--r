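# he_backend: parameter validation, round trips, rotation/masking semantics,
# noise accounting, key handling

test_that("parameter validation rejects unsupported settings", {
  expect_error(he_params(1000), class = "cb_param_error")      # not a power of two
  expect_error(he_params(2048), class = "cb_param_error")      # below minimum
  expect_error(he_params(8192, 50), class = "cb_param_error")  # t too wide
  expect_error(he_params(8192, 30, security_bits = 192), class = "cb_param_error")
  expect_error(keygen(he_params(8192, 30, coeff_modulus_bits = c(60, 60, 60, 60)),
                      "bfv", seed = 1))                        # exceeds 218-bit cap
  p <- he_params()
  expect_identical(p$poly_degree, 8192L)
  expect_identical(p$plain_modulus_bits, 30L)
})

test_that("realized plaintext modulus is the smallest batching prime of its bit length", {
  for (cfg in list(c(4096, 20), c(8192, 30))) {
    N <- cfg[1]; tb <- cfg[2]
    t <- batching_prime(N, tb)
    expect_true(is_prime_scalar(t))
    expect_equal(t %% (2 * N), 1)
    expect_gte(log2(t), tb - 1)
    expect_lt(log2(t), tb)
    # nothing smaller of the same bit length qualifies
    cand <- seq(2^(tb - 1) + 1, t - 1, by = 2 * N)
    cand <- cand[cand %% (2 * N) == 1]
    expect_false(any(vapply(cand, is_prime_scalar, logical(1))))
  }
})

test_that("default coefficient chain at N=8192 totals 218 bits with a key-switch prime", {
  bits <- default_coeff_bits(8192)
  expect_equal(sum(bits), 218)
  expect_equal(sum(default_coeff_bits(4096)), 109)
  k <- bfv_full()
  info <- k$params
  expect_identical(info$poly_degree, 8192L)
  expect_identical(k$slot_count, 8192L)
})

test_that("encrypt/decrypt round-trips seeded random vectors on both backends", {
  for (keys in list(bfv_small(), mock_keys())) {
    set.seed(42)
    ok <- TRUE
    for (rep in 1:100) {
      v <- sample(0:(keys$plain_modulus - 1), keys$slot_count, replace = TRUE)
      ok <- ok && identical(decrypt_chunk(encrypt_chunk(v, keys), keys), as.numeric(v))
    }
    expect_true(ok)
  }
})

test_that("encryption enforces the plaintext range", {
  keys <- mock_keys()
  t <- keys$plain_modulus
  v <- numeric(keys$slot_count)
  expect_identical(decrypt_chunk(encrypt_chunk(v, keys), keys), v)  # zero vector
  v[5] <- t
  expect_error(encrypt_chunk(v, keys), class = "cb_overflow_error")
  v[5] <- -1
  expect_error(encrypt_chunk(v, keys), class = "cb_overflow_error")
  expect_error(encrypt_chunk(numeric(10), keys), class = "cb_param_error")
  kb <- bfv_small()
  vb <- numeric(kb$slot_count); vb[1] <- kb$plain_modulus
  expect_error(encrypt_chunk(vb, kb), class = "cb_overflow_error")
})

test_that("bring_to_front moves the requested slot to position 0", {
  for (keys in list(bfv_small(), mock_keys())) {
    n <- keys$slot_count
    set.seed(3)
    v <- sample(0:999, n, replace = TRUE)
    v[18] <- 42
    ct <- encrypt_chunk(v, keys)
    # offset 17 example
    r <- bring_to_front(ct, 17, keys)
    expect_equal(decrypt_chunk(r, keys)[1], 42)
    # identity offset: slot 0 unchanged
    r0 <- bring_to_front(ct, 0, keys)
    expect_equal(decrypt_chunk(r0, keys)[1], v[1])
    # second batching row
    r2 <- bring_to_front(ct, n / 2 + 3, keys)
    expect_equal(decrypt_chunk(r2, keys)[1], v[n / 2 + 4])
    # boundary
    expect_error(bring_to_front(ct, n, keys), class = "cb_addressing_error")
  }
})

test_that("mask_front zeroes all but slot 0 and is idempotent", {
  # masking twice costs two plaintext multiplications of noise: at the small
  # parameter set that exhausts the budget, so the real-backend check runs at
  # the evaluation parameters
  for (keys in list(bfv_full(), mock_keys())) {
    v <- c(7, 9, 9, sample(0:99, keys$slot_count - 3, replace = TRUE))
    ct <- encrypt_chunk(v, keys)
    m1 <- mask_front(ct, keys)
    d1 <- decrypt_chunk(m1, keys)
    expect_equal(d1[1], 7)
    expect_true(all(d1[-1] == 0))
    d2 <- decrypt_chunk(mask_front(m1, keys), keys)
    expect_identical(d2, d1)
    # zero chunk stays zero
    z <- decrypt_chunk(mask_front(encrypt_chunk(numeric(keys$slot_count), keys), keys), keys)
    expect_true(all(z == 0))
  }
})

test_that("extraction identity holds across sampled offsets (both backends)", {
  kb <- bfv_small(); pub <- bfv_small_pub()
  km <- mock_keys()
  n <- kb$slot_count
  set.seed(11)
  v <- sample(0:(2^19), n, replace = TRUE)
  cb <- encrypt_chunk(v, kb)
  cm <- encrypt_chunk(v, km)
  offsets <- c(0, 1, 2, n / 2 - 1, n / 2, n / 2 + 1, n - 1,
               sample(0:(n - 1), 20))
  for (o in offsets) {
    db <- decrypt_chunk(mask_front(bring_to_front(cb, o, pub), pub), kb)
    dm <- decrypt_chunk(mask_front(bring_to_front(cm, o, km), km), km)
    expect_equal(db[1], v[o + 1])
    expect_true(all(db[-1] == 0))
    expect_identical(dm, db)   # real-vs-mock agreement on the scalar stream
  }
})

test_that("decryption with the wrong secret key fails or differs", {
  k1 <- bfv_small()
  k2 <- keygen(he_params(4096, 20), "bfv", seed = 999)
  v <- sample(0:999, k1$slot_count, replace = TRUE)
  ct <- encrypt_chunk(v, k1)
  got <- tryCatch(decrypt_chunk(ct, k2), error = function(e) NULL)
  expect_false(identical(got, as.numeric(v)))
  # mock: wrong stub key is detected
  m1 <- mock_keys(seed = 1); m2 <- mock_keys(seed = 2)
  cm <- encrypt_chunk(v, m1)
  expect_error(decrypt_chunk(cm, m2), class = "cb_corruption_error")
})

test_that("mock noise ledger matches the calibrated trace exactly", {
  keys <- mock_keys(N = 8192, tb = 30)
  ct <- encrypt_chunk(rep(1, 8192), keys)
  expect_identical(noise_budget(ct, keys), 136L)
  r <- bring_to_front(ct, 1234, keys)
  expect_identical(noise_budget(r, keys), 133L)
  m <- mask_front(r, keys)
  expect_identical(noise_budget(m, keys), 98L)
  # clamped at zero after repeated masking
  x <- m
  for (i in 1:5) x <- mask_front(x, keys)
  expect_identical(noise_budget(x, keys), 0L)
})

test_that("noise budget is non-increasing and stays positive through the kernel", {
  keys <- bfv_small()
  ct <- encrypt_chunk(sample(0:999, keys$slot_count, replace = TRUE), keys)
  b <- noise_budget(ct, keys)
  seqb <- b
  x <- ct
  for (op in 1:3) {
    x <- rotate_slots(x, sample(1:(keys$slot_count / 2 - 1), 1), keys)
    seqb <- c(seqb, noise_budget(x, keys))
  }
  x <- mask_front(x, keys)
  seqb <- c(seqb, noise_budget(x, keys))
  expect_true(all(diff(seqb) <= 0))
  expect_gt(seqb[length(seqb)], 0)
})

test_that("chunk serialization round-trips and rejects cross-backend blobs", {
  kb <- bfv_small(); km <- mock_keys()
  v <- sample(0:999, kb$slot_count, replace = TRUE)
  cb <- encrypt_chunk(v, kb); cm <- encrypt_chunk(v, km)
  rb <- serialize_chunk(cb); rm <- serialize_chunk(cm)
  expect_identical(decrypt_chunk(deserialize_chunk(rb, kb), kb), as.numeric(v))
  expect_identical(decrypt_chunk(deserialize_chunk(rm, km), km), as.numeric(v))
  expect_error(deserialize_chunk(rb, km), class = "cb_param_error")
  expect_error(deserialize_chunk(rm, kb), class = "cb_param_error")
  # parameter fingerprint mismatch
  k2 <- bfv_full()
  expect_error(deserialize_chunk(rb, k2))
})

test_that("key files separate public and secret material", {
  keys <- bfv_small()
  pubf <- tempfile(); secf <- tempfile()
  save_keys(keys, pubf, secf)
  pub_only <- load_keys(pubf, NULL, backend = "bfv")
  expect_false(pub_only$has_secret)
  v <- sample(0:999, keys$slot_count, replace = TRUE)
  ct <- encrypt_chunk(v, pub_only)         # public part can encrypt
  expect_error(decrypt_chunk(ct, pub_only), class = "cb_param_error")
  full <- load_keys(pubf, secf, backend = "bfv")
  expect_identical(decrypt_chunk(ct, full), as.numeric(v))
  # rotations under reloaded public keys still work
  r <- mask_front(bring_to_front(ct, 5, pub_only), pub_only)
  expect_equal(decrypt_chunk(r, full)[1], v[6])
  unlink(c(pubf, secf))
})

test_that("operation counters reflect the baby-step/giant-step kernel", {
  keys <- bfv_small()
  reset_op_counts(keys)
  ct <- encrypt_chunk(numeric(keys$slot_count), keys)
  invisible(mask_front(bring_to_front(ct, 0, keys), keys))
  oc <- op_counts(keys)
  expect_equal(unname(oc["rotations"]), 0)   # offset 0 skips rotation
  expect_equal(unname(oc["plain_mults"]), 1)
  reset_op_counts(keys)
  invisible(bring_to_front(ct, keys$slot_count / 2 + 1, keys))
  oc <- op_counts(keys)
  expect_equal(unname(oc["rotations"]), 2)   # row swap + one baby step
  # never more than log2(N) rotations for any offset
  for (o in c(1, 77, keys$slot_count - 1)) {
    reset_op_counts(keys)
    invisible(bring_to_front(ct, o, keys))
    expect_lte(unname(op_counts(keys)["rotations"]), log2(keys$slot_count))
  }
})
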