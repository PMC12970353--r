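Package: cipherbed
Title: Privacy-Preserving BED Interval Analytics over Homomorphic Encryption
Version: 0.1.0
Authors@R:
    person("cipherbed", "developers", email = "cipherbed@example.org", role = c("aut", "cre"))
Description: Client/server toolkit for running bedtools-style interval queries
    (coverage, intersect, window, depth, Jaccard) against an encrypted interval
    database hosted on an honest-but-curious server.  The database track is
    reduced to prefix-sum and depth arrays, packed into SIMD batches, shuffled
    with a client-secret permutation, and encrypted under the BFV lattice
    scheme.  Queries are answered by a blind rotate-and-mask extraction kernel
    that returns single encrypted scalars, which the client decrypts and
    reassembles into standard outputs.  Ships a full BFV backend (batching,
    Galois rotations, plaintext masking, noise-budget instrumentation)
    implemented in C++, a calibrated plaintext mock backend, a synthetic BED
    workload generator, and a brute-force plaintext oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
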