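# client: reconstruction, output dialects, end-to-end equivalence, bench

test_that("reconstruct_coverage turns boundary scalars into rows", {
  fx <- fixture()
  A1 <- interval_set(data.frame(chrom = "chrT", start = 3, end = 6), fx$layout)
  plan <- dedupe(compile_query(query_spec("coverage", A1)), enabled = FALSE)
  row <- reconstruct_coverage(plan, c(1, 4, 2, 0))
  expect_equal(row$count, 2)
  expect_equal(row$covered, 3)
  expect_equal(row$fraction, 1.0)
  # interval fully outside coverage
  row0 <- reconstruct_coverage(plan, c(6, 6, 2, 2))
  expect_equal(c(row0$count, row0$covered, row0$fraction), c(0, 0, 0))
  # corruption guards
  expect_error(reconstruct_coverage(plan, c(1, 9, 2, 0)), class = "cb_corruption_error")
  expect_error(reconstruct_coverage(plan, c(1, 4)), class = "cb_protocol_error")
})

test_that("intersect/window modes filter on the reconstructed count", {
  fx <- fixture()
  A1 <- interval_set(data.frame(chrom = "chrT", start = 0, end = 1), fx$layout)
  for (md in c("c", "u", "v")) {
    plan <- dedupe(compile_query(query_spec("window", A1, mode = md, window = 2)),
                   enabled = FALSE)
    out <- reconstruct_intersect_window(plan, c(1, 0))   # Pstart@3=1, Pend@0=0
    if (md == "c") {
      expect_equal(out$count, 1)
      expect_equal(out$start, 0)                          # original coordinates
    } else if (md == "u") expect_equal(nrow(out), 1)
    else expect_equal(nrow(out), 0)
  }
})

test_that("jaccard reconstruction matches hand-computed examples", {
  layout <- genome_layout(c(z = 20))
  A <- interval_set(data.frame(chrom = "z", start = 0, end = 4), layout)
  B <- interval_set(data.frame(chrom = "z", start = 2, end = 6), layout)
  keys <- mock_keys()
  pr <- provision(B, keys)
  got <- run_op(pr, A, "jaccard")
  expect_equal(got$intersection, 2)
  expect_equal(got$union, 6)
  expect_equal(got$jaccard, 1 / 3, tolerance = 1e-12)
  # A = B -> 1 ; disjoint -> 0
  prA <- provision(A, keys)
  expect_equal(run_op(prA, A, "jaccard")$jaccard, 1.0)
  C <- interval_set(data.frame(chrom = "z", start = 10, end = 14), layout)
  expect_equal(run_op(pr, C, "jaccard")$jaccard, 0.0)
})

test_that("the fixture pipeline reproduces every documented output", {
  fx <- fixture()
  for (keys in list(mock_keys(), bfv_small())) {
    pr <- provision(fx$B, keys)
    expect_same_output(run_op(pr, fx$A, "coverage"), fx$expected$coverage)
    expect_same_output(run_op(pr, fx$A, "depth"), fx$expected$depth)
    expect_same_output(run_op(pr, fx$A, "intersect", "u"), fx$expected$intersect_u)
    expect_same_output(run_op(pr, fx$A, "intersect", "v"), fx$expected$intersect_v)
    expect_same_output(run_op(pr, fx$A, "window", "c", 2), fx$expected$window_c_w2)
    expect_same_output(run_op(pr, fx$A, "jaccard"), fx$expected$jaccard)
  }
  # depth rows as documented
  dep <- fx$expected$depth
  expect_equal(dep$depth[dep$pos %in% 3:5], c(1, 2, 1))
})

test_that("encrypted pipeline equals the oracle on random instances (mock)", {
  for (seed in 1:6) {
    pair <- random_pair(seed)
    keys <- mock_keys()
    pr <- provision(pair$B, keys, seed = seed)
    for (sp in all_op_specs()) {
      got <- run_op(pr, pair$A, sp$op, sp$mode, if (is.null(sp$W)) 0 else sp$W)
      want <- oracle(sp$op, pair$A, pair$B, W = if (is.null(sp$W)) 0 else sp$W,
                     mode = sp$mode)
      expect_same_output(got, want)
    }
  }
})

test_that("disjoint query sets split cleanly between -u and -v", {
  fx <- fixture()
  layout <- fx$layout
  A <- interval_set(data.frame(chrom = "chrT", start = c(0, 8), end = c(1, 10)),
                    layout)
  keys <- mock_keys()
  pr <- provision(fx$B, keys)
  u <- run_op(pr, A, "intersect", "u")
  v <- run_op(pr, A, "intersect", "v")
  expect_equal(nrow(u), 0)          # A disjoint from B
  expect_identical(v[c("chrom", "start", "end")], A$df)
})

test_that("-u and -v outputs partition A for intersect and window", {
  for (seed in 11:14) {
    pair <- random_pair(seed, two_chrom = FALSE)
    keys <- mock_keys()
    pr <- provision(pair$B, keys, seed = seed)
    for (cfg in list(list(op = "intersect", W = 0), list(op = "window", W = 5))) {
      u <- run_op(pr, pair$A, cfg$op, "u", cfg$W)
      v <- run_op(pr, pair$A, cfg$op, "v", cfg$W)
      expect_equal(nrow(u) + nrow(v), n_intervals(pair$A))
      recombined <- rbind(u, v)
      recombined <- recombined[order(recombined$start, recombined$end), ]
      rownames(recombined) <- NULL
      orig <- pair$A$df[order(pair$A$df$start, pair$A$df$end), ]
      rownames(orig) <- NULL
      expect_identical(recombined, orig)
    }
  }
})

test_that("jaccard is symmetric in the roles of A and B", {
  for (seed in 21:23) {
    pair <- random_pair(seed)
    keys <- mock_keys()
    j1 <- run_op(provision(pair$B, keys, seed), pair$A, "jaccard")
    j2 <- run_op(provision(pair$A, keys, seed), pair$B, "jaccard")
    expect_equal(j1$jaccard, j2$jaccard, tolerance = 1e-12)
    expect_equal(j1$intersection, j2$intersection)
  }
})

test_that("download volume scales with plan size, not database size", {
  keys <- mock_keys()
  small <- generate_bed(synth_config(seed = 1, chroms = c(s = 2000), n = 10))
  big <- generate_bed(synth_config(seed = 2, chroms = c(s = 2000), n = 400,
                                   len_min = 2, len_max = 10))
  A <- generate_bed(synth_config(seed = 3, chroms = c(s = 2000), n = 20,
                                 len_min = 5, len_max = 20))
  bytes <- vapply(list(small, big), function(B) {
    pr <- provision(B, keys)
    plan <- dedupe(compile_query(query_spec("coverage", A)))
    ps <- plan_selectors(plan, pr$built$manifest, pr$built$map)
    response_bytes(extract_batch(pr$handle, ps$request))
  }, numeric(1))
  expect_equal(bytes[1], bytes[2])    # same plan, same download, any DB size
  # linear in the number of reads
  pr <- provision(small, keys)
  b1 <- {
    ps <- plan_selectors(dedupe(compile_query(query_spec("intersect", A, mode = "u")),
                                enabled = FALSE), pr$built$manifest, pr$built$map)
    response_bytes(extract_batch(pr$handle, ps$request))
  }
  b2 <- {
    ps <- plan_selectors(dedupe(compile_query(query_spec("coverage", A)),
                                enabled = FALSE), pr$built$manifest, pr$built$map)
    response_bytes(extract_batch(pr$handle, ps$request))
  }
  expect_equal(b2 / b1, 2)            # 4 reads vs 2 reads per interval
})

test_that("scrambled parallel execution does not change any output", {
  pair <- random_pair(31)
  keys <- mock_keys()
  pr <- provision(pair$B, keys)
  a <- run_op(pr, pair$A, "coverage")
  b <- run_op(pr, pair$A, "coverage", scramble = TRUE)
  expect_identical(a, b)
})

test_that("bench reports phases, volumes and the calibrated noise trace", {
  fx <- fixture()
  keys <- mock_keys(N = 8192, tb = 30)
  out <- tempfile(fileext = ".json")
  rep <- bench(fx$B, query_spec("coverage", fx$A), keys, secret_seed = 2, out = out)
  expect_true(all(c("phases", "noise_trace", "n_extractions") %in% names(rep)))
  expect_equal(rep$noise_trace$fresh, 136L)
  expect_equal(rep$noise_trace$after_rotation, 133L)
  expect_equal(rep$noise_trace$after_masking, 98L)
  expect_gte(rep$phases$encryption$bytes, rep$phases$server$bytes / 100)
  expect_true(file.exists(out))
  js <- jsonlite::read_json(out)
  expect_equal(js$noise_trace$fresh, 136L)
  unlink(out)
})

test_that("write_output renders the documented dialects", {
  fx <- fixture()
  keys <- mock_keys()
  pr <- provision(fx$B, keys)
  f <- tempfile()
  write_output(run_op(pr, fx$A, "coverage"), f)
  lines <- readLines(f)
  expect_equal(length(lines), 3)
  expect_equal(strsplit(lines[1], "\t")[[1]],
               c("chrT", "3", "6", "2", "3", "3", "1"))
  write_output(run_op(pr, fx$A, "jaccard"), f)
  expect_match(readLines(f)[1], "intersection\tunion\tjaccard")
  unlink(f)
})
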