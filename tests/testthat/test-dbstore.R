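# dbstore: chunking arithmetic, permutation, encryption, addressing, refresh

toy_manifest <- function(chunk_size = 4) {
  fx <- fixture()
  concat_and_chunk(build_signals(fx$B), chunk_size)
}

identity_map <- function(n, epoch = 1L) {
  structure(list(pi = seq_len(n), epoch = as.integer(epoch), seed_ref = "id"),
            class = "permutation_map")
}

test_that("concat_and_chunk partitions the global vector deterministically", {
  cc <- toy_manifest(4)
  # L = 10 fixture: 11 + 11 + 11 + 10 = 43 values -> 11 chunks of 4
  expect_equal(cc$manifest$total_length, 43)
  expect_equal(cc$manifest$chunk_count, 11)
  expect_equal(cc$manifest$padding, 1)
  expect_equal(length(cc$chunks), 11)
  expect_true(all(vapply(cc$chunks, length, 0L) == 4))
  # segment order fixed S1..S4, contiguous
  seg <- cc$manifest$segments
  expect_equal(seg$segment, c("S1", "S2", "S3", "S4"))
  expect_equal(seg$offset, c(0, 11, 22, 33))
  expect_equal(seg$length, c(11, 11, 11, 10))
  # last chunk zero-padded
  expect_equal(cc$chunks[[11]][4], 0)
})

test_that("global index arithmetic maps coordinates to (chunk, slot)", {
  cc <- toy_manifest(4)
  map <- identity_map(11)
  sel <- logical_to_selector(cc$manifest, map, "S1", "chrT", 9, ordinal = 1L)
  expect_equal(sel$chunk, 2L)   # 9 = 2*4 + 1
  expect_equal(sel$slot, 1L)
  # with a non-trivial permutation the physical chunk moves
  map2 <- identity_map(11)
  map2$pi <- c(3L, 1L, 2L, 4:11)            # logical 3 -> physical 2
  sel2 <- logical_to_selector(cc$manifest, map2, "S1", "chrT", 9)
  expect_equal(sel2$chunk, 1L)
  # prefix segments address 0..L, depth only 0..L-1
  expect_silent(logical_to_selector(cc$manifest, map, "S1", "chrT", 10))
  expect_error(logical_to_selector(cc$manifest, map, "S1", "chrT", 11),
               class = "cb_addressing_error")
  expect_error(logical_to_selector(cc$manifest, map, "S4", "chrT", 10),
               class = "cb_addressing_error")
})

test_that("capacity errors name the chromosome when values reach t", {
  fx <- fixture()
  sig <- build_signals(fx$B)
  err <- tryCatch(concat_and_chunk(sig, 4, plain_modulus = 2),
                  error = function(e) e)
  expect_s3_class(err, "cb_capacity_error")
  expect_match(conditionMessage(err), "chrT")
})

test_that("permute_chunks is a seeded Fisher-Yates over chunk order", {
  chunks <- as.list(1:11)
  p1 <- permute_chunks(chunks, 1)
  p1b <- permute_chunks(chunks, 1)
  p2 <- permute_chunks(chunks, 2)
  expect_identical(p1$map$pi, p1b$map$pi)          # reproducible
  expect_false(identical(p1$map$pi, p2$map$pi))    # seed-sensitive
  expect_setequal(p1$map$pi, 1:11)                 # bijection
  # contents untouched, only order: applying pi then inverting restores
  restored <- p1$chunks[p1$map$pi]
  expect_identical(restored, chunks)
  # single chunk: identity
  expect_identical(permute_chunks(list(9), 5)$map$pi, 1L)
})

test_that("encrypted database round-trips through the permutation (both backends)", {
  fx <- fixture()
  for (keys in list(mock_keys(), bfv_small())) {
    built <- build_database(fx$B, keys, secret_seed = 3)
    cc <- concat_and_chunk(build_signals(fx$B), keys$slot_count)
    for (k in seq_along(cc$chunks)) {
      phys <- built$map$pi[k]
      dec <- decrypt_chunk(built$db$chunks[[phys]], keys)
      expect_identical(dec, cc$chunks[[k]])
    }
  }
})

test_that("exhaustive addressing correctness on the toy database", {
  fx <- fixture()
  keys <- mock_keys()
  built <- build_database(fx$B, keys, secret_seed = 5)
  handle <- host_db(built$db, public_part(keys))
  sig <- build_signals(fx$B)$per_chrom$chrT
  arrays <- list(S1 = sig$P_cov, S2 = sig$P_start, S3 = sig$P_end, S4 = sig$D)
  for (seg in names(arrays)) {
    a <- arrays[[seg]]
    for (coord in seq_along(a) - 1) {
      sel <- logical_to_selector(built$manifest, built$map, seg, "chrT", coord)
      got <- decrypt_chunk(extract(handle, sel), keys)[1]
      expect_equal(got, a[coord + 1])
    }
  }
})

test_that("tampering with a ciphertext blob is detectable by decrypt mismatch", {
  keys <- bfv_small()
  v <- sample(0:999, keys$slot_count, replace = TRUE)
  ct <- encrypt_chunk(v, keys)
  raw <- serialize_chunk(ct)
  raw[5000] <- as.raw(bitwXor(as.integer(raw[5000]), 255L))
  got <- tryCatch(decrypt_chunk(deserialize_chunk(raw, keys), keys),
                  error = function(e) NULL)
  # integrity is NOT provided: tampering yields garbage or an error, never
  # silently the original plaintext
  expect_false(identical(got, as.numeric(v)))
})

test_that("refresh produces a new epoch, new layout, same logical content", {
  fx <- fixture()
  keys <- mock_keys()
  # a multi-chunk database so distinct seeds give distinct permutations
  B <- generate_bed(synth_config(seed = 41, chroms = c(chrR = 5000), n = 40))
  b1 <- build_database(B, keys, secret_seed = 1)
  expect_gt(b1$manifest$chunk_count, 1)
  b2 <- refresh_database(b1$signals, keys, new_seed = 2, old_epoch = b1$db$epoch)
  expect_equal(b2$db$epoch, b1$db$epoch + 1L)
  expect_false(identical(b1$map$pi, b2$map$pi))
  # logical content identical across epochs
  cc <- concat_and_chunk(b1$signals, keys$slot_count)
  for (k in seq_along(cc$chunks)) {
    expect_identical(decrypt_chunk(b2$db$chunks[[b2$map$pi[k]]], keys),
                     cc$chunks[[k]])
  }
  # stale plan: request compiled under epoch 1 against epoch-2 server
  A <- interval_set(data.frame(chrom = "chrR", start = 10, end = 60), B$layout)
  h2 <- host_db(b2$db, public_part(keys))
  plan <- dedupe(compile_query(query_spec("coverage", A)))
  ps <- plan_selectors(plan, b1$manifest, b1$map)
  expect_error(extract_batch(h2, ps$request), class = "cb_stale_plan_error")
  # fresh randomness: re-encrypting the same content yields different blobs
  kb <- bfv_small()
  c1 <- encrypt_chunk(numeric(kb$slot_count), kb)
  c2 <- encrypt_chunk(numeric(kb$slot_count), kb)
  expect_false(identical(serialize_chunk(c1), serialize_chunk(c2)))
})

test_that("reads never target padding and padding decrypts to zero", {
  fx <- fixture()
  keys <- mock_keys()
  built <- build_database(fx$B, keys, secret_seed = 4)
  # all addressable reads stay below total_length
  seg <- built$manifest$segments
  max_gidx <- max(seg$offset + seg$length) - 1
  expect_lt(max_gidx, built$manifest$total_length)
  # padding slots of the last logical chunk decrypt to zero
  last_phys <- built$map$pi[built$manifest$chunk_count]
  v <- decrypt_chunk(built$db$chunks[[last_phys]], keys)
  used <- built$manifest$total_length -
    (built$manifest$chunk_count - 1) * built$manifest$chunk_size
  if (used < built$manifest$chunk_size)
    expect_true(all(v[(used + 1):built$manifest$chunk_size] == 0))
})

test_that("client state round-trips through JSON", {
  fx <- fixture()
  keys <- mock_keys()
  built <- build_database(fx$B, keys, secret_seed = 6)
  f <- tempfile(fileext = ".json")
  write_client_state(built$manifest, built$map, f)
  st <- read_client_state(f)
  expect_equal(st$manifest$segments, built$manifest$segments)
  expect_identical(st$map$pi, as.integer(built$map$pi))
  expect_equal(st$manifest$epoch, built$manifest$epoch)
  unlink(f)
})
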