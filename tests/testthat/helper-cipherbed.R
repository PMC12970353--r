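# shared fixtures; expensive key material is generated once per session

.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# real backend at the small parameter set used by most unit tests
bfv_small <- function() memo("bfv_small", keygen(he_params(4096, 20), "bfv", seed = 7))
bfv_small_pub <- function() memo("bfv_small_pub", public_part(bfv_small()))

# real backend at the evaluation parameters (N = 8192, 30-bit t)
bfv_full <- function() memo("bfv_full", keygen(he_params(8192, 30), "bfv", seed = 7))
bfv_full_pub <- function() memo("bfv_full_pub", public_part(bfv_full()))

mock_keys <- function(N = 4096, tb = 20, seed = 7)
  keygen(he_params(N, tb), "mock", seed = seed)

fixture <- function() memo("fixture", make_fixture())

# a random (A, B) pair over a small genome
random_pair <- function(seed, L = 3000, nB = 50, nA = 30, two_chrom = TRUE) {
  chroms <- if (two_chrom) c(cA = L, cB = round(L / 2)) else c(cA = L)
  B <- generate_bed(synth_config(seed = seed, chroms = chroms, n = nB))
  A <- generate_bed(synth_config(seed = seed + 5000, chroms = chroms, n = nA,
                                 len_min = 5, len_max = 60))
  list(A = A, B = B)
}

# provision a database and in-memory server in one go
provision <- function(B, keys, seed = 11) {
  built <- build_database(B, keys, secret_seed = seed)
  handle <- host_db(built$db, public_part(keys))
  list(built = built, handle = handle, keys = keys)
}

run_op <- function(pr, A, op, mode = NULL, W = 0, ...) {
  run_query(query_spec(op, A, mode = mode, window = W), pr$handle,
            pr$built$manifest, pr$built$map, pr$keys, ...)
}

expect_same_output <- function(got, want) {
  if (inherits(want, "jaccard_result")) {
    expect_equal(got$intersection, want$intersection)
    expect_equal(got$union, want$union)
    expect_equal(got$jaccard, want$jaccard, tolerance = 1e-12)
  } else {
    expect_identical(got, want)
  }
}

all_op_specs <- function() {
  c(list(list(op = "coverage"), list(op = "depth"), list(op = "jaccard"),
         list(op = "intersect", mode = "u"), list(op = "intersect", mode = "v")),
    unlist(lapply(c(0, 5, 50), function(W)
      lapply(c("c", "u", "v"), function(md) list(op = "window", mode = md, W = W))),
      recursive = FALSE))
}

is_prime_scalar <- function(n) {
  if (n < 2) return(FALSE)
  if (n %% 2 == 0) return(n == 2)
  d <- 3
  while (d * d <= n) {
    if (n %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}
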