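# Toy models for axiom checks: closed-form prediction functions acting on a
# (rows x features) matrix, mimicking the multi-class probability output.

softmax_model <- function(W) {
  function(X) {
    Z <- X %*% W
    E <- exp(Z - apply(Z, 1L, max))
    E / rowSums(E)
  }
}

test_that("dummy axiom: ignored features receive zero attribution", {
  W <- matrix(c(2, -1, 0, 0.5, 1, 0), 3, 2)  # feature 3 ignored
  f <- softmax_model(W)
  X <- matrix(c(0.9, 0.1, 0.7), 1, 3)
  att <- shapley_attributions(f, X, baseline = c(0.5, 0.5, 0.5),
                              n_permutations = 64L, seed = 2L)
  expect_equal(max(abs(att[1, 3, ])), 0)
  expect_gt(max(abs(att[1, 1, ])), 0.01)
})

test_that("symmetry axiom: exchangeable features get equal attributions", {
  W <- matrix(c(1.2, 1.2, -0.4, -0.4), 2, 2)  # columns identical per class
  f <- softmax_model(W)
  X <- matrix(c(0.8, 0.8), 1, 2)              # equal inputs too
  att <- shapley_attributions(f, X, baseline = c(0.3, 0.3),
                              n_permutations = 256L, seed = 5L)
  expect_lt(max(abs(att[1, 1, ] - att[1, 2, ])), 0.01)
  ex <- shapley_attributions(f, X, baseline = c(0.3, 0.3), exact = TRUE)
  expect_equal(ex[1, 1, ], ex[1, 2, ], tolerance = 1e-12)
})

test_that("sampling converges toward the exact enumeration", {
  W <- matrix(c(1.5, -0.5, 0.2, -1, 2, 0.3, 0.5, 0.5, -2), 3, 3)
  f <- softmax_model(W)
  X <- matrix(c(0.9, 0.1, 0.5, 0.2, 0.8, 0.3), 2, 3, byrow = TRUE)
  base <- rep(0.5, 3)
  ex <- shapley_attributions(f, X, baseline = base, exact = TRUE)
  err_for <- function(n_perm) {
    s <- shapley_attributions(f, X, baseline = base, n_permutations = n_perm,
                              seed = 11L)
    max(abs(s - ex))
  }
  e_small <- err_for(32L)
  e_large <- err_for(512L)
  expect_lt(e_large, e_small)
  expect_lt(e_large, 0.02)
})

test_that("mean_attribution averages and export round-trips", {
  att <- array(c(1, 3, 2, 4, -1, -3, -2, -4), dim = c(2, 2, 2),
               dimnames = list(c("s1", "s2"), c("cg1", "cg2"),
                               c("A", "B")))
  m <- mean_attribution(att)
  expect_equal(unclass(m),
               matrix(c(2, 3, -2, -3), 2, 2,
                      dimnames = list(c("cg1", "cg2"), c("A", "B"))),
               ignore_attr = TRUE)
  # single sample -> identity
  one <- mean_attribution(att[1L, , , drop = FALSE])
  expect_equal(unclass(one)[, "A"], att[1L, , "A"])
  # opposite attributions cancel to zero
  opp <- att; opp[2L, , ] <- -att[1L, , ]
  expect_true(all(mean_attribution(opp) == 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_table(m, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), 2L)
  expect_equal(back$A, unname(unclass(m)[, "A"]), tolerance = 1e-6)
  # top-ranked CpG per class matches the column argmax
  expect_identical(back$cpg_id[back$rank_A == 1L],
                   rownames(m)[which.max(unclass(m)[, "A"])])
})

test_that("width and argument validation", {
  f <- softmax_model(diag(2))
  X <- matrix(0.5, 1, 2)
  expect_error(shapley_attributions(f, X, baseline = c(0.5, 0.5, 0.5)),
               "baseline width")
  expect_error(shapley_attributions(f, X, n_permutations = 0L),
               "n_permutations")
  expect_error(shapley_attributions(f, matrix(0.5, 1, 13), exact = TRUE),
               "12 features")
})
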