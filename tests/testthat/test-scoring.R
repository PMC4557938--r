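test_that("the average reference is the per-function mean of raw counts", {
  m <- matrix(c(1L, 2L, 3L, 0L, 0L, 6L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("f1", "f2")))
  expect_equal(average_reference(m), c(f1 = 2, f2 = 2))
  expect_equal(average_reference(m[1, , drop = FALSE]), c(f1 = 1, f2 = 0))

  set.seed(12)
  big <- matrix(rpois(200, 3), 10, 20,
                dimnames = list(paste0("g", 1:10), paste0("f", 1:20)))
  oracle <- vapply(seq_len(20), function(j) mean(big[, j]), numeric(1))
  expect_equal(unname(average_reference(big)), oracle)
})

test_that("the log transform maps absent functions to zero", {
  expect_equal(log_transform(c(0, 1, 7)), c(0, 1, 3))
  expect_error(log_transform(c(0, 1), pseudocount = 0), "undefined")
  expect_equal(log_transform(c(2, 4), pseudocount = 0), c(1, 2))
})

test_that("scores vanish when a genome equals the reference and match the
           hand-worked chain example", {
  M <- build_ein(data.frame(
    reaction_id = c("r1", "r2"), ec = c("e1", "e2"),
    substrates = I(list("A", "B")), products = I(list("B", "C")),
    reversible = FALSE))
  prof <- matrix(c(3L, 1L), 1, 2, dimnames = list("g1", c("e1", "e2")))
  s <- prmt_scores(M, prof, reference = c(e1 = 1, e2 = 1))
  expect_equal(unclass(s)["g1", ], c(A = -1, B = 1, C = 0))

  # genome identical to the reference: all-zero score vector
  s0 <- prmt_scores(M, prof, reference = c(e1 = 3, e2 = 1))
  expect_equal(unname(unclass(s0)["g1", ]), c(0, 0, 0))
})

test_that("matrix-form scoring equals the naive double-loop oracle", {
  set.seed(99)
  for (rep in 1:10) {
    n_g <- sample(2:10, 1); n_f <- sample(3:20, 1); n_c <- sample(2:15, 1)
    M <- interaction_matrix(
      matrix(sample(-2:2, n_c * n_f, replace = TRUE), n_c, n_f,
             dimnames = list(paste0("C", 1:n_c), paste0("f", 1:n_f))),
      mode = "ein") |> suppressWarnings()
    prof <- matrix(rpois(n_g * n_f, 2), n_g, n_f,
                   dimnames = list(paste0("g", 1:n_g), paste0("f", 1:n_f)))
    s <- prmt_scores(M, prof)
    expect_lt(max(abs(unclass(s) - score_oracle(unclass(M), prof))), 1e-9)
  }
})

test_that("pairwise scores are antisymmetric", {
  set.seed(7)
  M <- suppressWarnings(interaction_matrix(
    matrix(sample(-1:1, 24, replace = TRUE), 6, 4,
           dimnames = list(paste0("C", 1:6), paste0("f", 1:4))), "ein"))
  prof <- matrix(rpois(8, 3), 2, 4,
                 dimnames = list(c("x", "y"), paste0("f", 1:4)))
  sxy <- prmt_scores(M, prof["x", , drop = FALSE],
                     reference = prof["y", ])
  syx <- prmt_scores(M, prof["y", , drop = FALSE],
                     reference = prof["x", ])
  expect_equal(unname(unclass(sxy)["x", ]), -unname(unclass(syx)["y", ]))
})

test_that("PRTT is the binary special case of PRMT", {
  set.seed(13)
  vals <- matrix(rbinom(30, 1, 0.4), 5, 6,
                 dimnames = list(paste0("L", 1:5), paste0("K", 1:6)))
  vals[1, 1] <- 1  # avoid an all-zero first column warning in a known spot
  T_bin <- suppressWarnings(interaction_matrix(vals, "transportome"))
  M_bin <- suppressWarnings(interaction_matrix(vals, "ein"))
  prof <- matrix(rpois(18, 2), 3, 6,
                 dimnames = list(paste0("g", 1:3), paste0("K", 1:6)))
  expect_equal(unclass(prtt_scores(T_bin, prof)),
               unclass(prmt_scores(M_bin, prof)), ignore_attr = TRUE)
})

test_that("scores are invariant under function and compound reordering", {
  set.seed(17)
  M <- suppressWarnings(interaction_matrix(
    matrix(sample(-1:1, 20, replace = TRUE), 5, 4,
           dimnames = list(paste0("C", 1:5), paste0("f", 1:4))), "ein"))
  prof <- matrix(rpois(12, 2), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("f", 1:4)))
  s <- unclass(prmt_scores(M, prof))
  pf <- sample(4); pc <- sample(5)
  M2 <- suppressWarnings(interaction_matrix(
    unclass(M)[pc, pf, drop = FALSE], "ein"))
  s2 <- unclass(prmt_scores(M2, prof[, pf]))
  expect_equal(s2[, rownames(M)], s[, rownames(M)])
})

test_that("functions missing from all genomes are treated as zero counts", {
  M <- suppressWarnings(interaction_matrix(
    matrix(c(1, -1, 0, 1), 2, 2,
           dimnames = list(c("A", "B"), c("f1", "f_missing"))), "ein"))
  prof <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("g1", "g2"), "f1"))
  expect_warning(s <- prmt_scores(M, prof), "f_missing")
  # f_missing contributes nothing; only f1 differs from its mean of 2
  d1 <- log2(1 + 1) - log2(2 + 1)
  expect_equal(unclass(s)["g1", ], c(A = d1, B = -d1))
})

test_that("score tables round-trip", {
  set.seed(3)
  s <- structure(matrix(rnorm(6), 2, 3,
                        dimnames = list(c("g1", "g2"), c("A", "B", "C"))),
                 class = c("score_table", "matrix", "array"), kind = "prmt")
  f <- tempfile()
  write_score_table(s, f)
  expect_equal(unclass(read_score_table(f)), unclass(s), ignore_attr = TRUE)
})
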