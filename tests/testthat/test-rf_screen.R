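test_that("a perfectly separating probe ranks first among noise", {
  set.seed(17)
  n <- 200L
  X <- matrix(runif(n * 51), n, 51)
  colnames(X) <- sprintf("cg%03d", 1:51)
  y <- rep(c(0L, 1L), each = n / 2)
  X[, 25] <- 0.3 + 0.4 * y + runif(n, -0.05, 0.05)  # separating probe
  X <- beta_matrix(X)
  r <- fit_importances(X, y, n_trees = 100L, seed = 3L)
  expect_identical(r$cpg_id[1L], "cg025")
  expect_gt(r$importance[1L], 0.5)
  expect_equal(sum(r$importance), 1, tolerance = 1e-6)
  # determinism
  r2 <- fit_importances(X, y, n_trees = 100L, seed = 3L)
  expect_identical(r, r2)
})

test_that("constant probes receive an importance of exactly zero", {
  set.seed(5)
  X <- matrix(runif(400), 100, 4,
              dimnames = list(NULL, c("cgA", "cgB", "cgC", "cgD")))
  X[, 2] <- 0.5
  y <- as.integer(X[, 1] > 0.5)
  r <- fit_importances(beta_matrix(X), y, n_trees = 50L, seed = 1L)
  expect_identical(r$importance[r$cpg_id == "cgB"], 0)
  expect_error(fit_importances(beta_matrix(X), rep(1L, 100)), "both classes")
})

test_that("filter_nonzero drops exact zeros, preserves order, is idempotent", {
  r <- structure(data.frame(cpg_id = c("a", "c", "b"),
                            importance = c(0.5, 0.2, 0)),
                 n_input = 3L, class = c("importance_ranking", "data.frame"))
  f <- filter_nonzero(r)
  expect_identical(f$cpg_id, c("a", "c"))
  expect_identical(attr(f, "n_input"), 3L)
  expect_identical(filter_nonzero(f), f)
  allzero <- structure(data.frame(cpg_id = "a", importance = 0),
                       n_input = 1L,
                       class = c("importance_ranking", "data.frame"))
  expect_error(filter_nonzero(allzero), "all importances")
  # equal importances are ordered by cpg_id
  set.seed(9)
  X <- beta_matrix(matrix(runif(40 * 6), 40, 6,
                          dimnames = list(NULL, paste0("cg", 6:1))))
  rr <- fit_importances(X, rep(c(0L, 1L), 20), n_trees = 5L, seed = 2L)
  ties <- rr$importance == 0
  expect_identical(rr$cpg_id[ties], sort(rr$cpg_id[ties]))
})

test_that("evaluate_subset separates informative from noise subsets", {
  co <- generate_binary_cohort(cohort_config(
    n_samples_per_class = 100L, n_cpgs = 120L,
    n_informative_per_class = 10L, effect_delta = 0.35, precision = 50,
    seed = 41L))
  planted <- co$truth$cpg_id
  noise <- setdiff(colnames(co$beta), planted)[1:10]
  m_planted <- evaluate_subset(co$beta, co$labels, planted,
                               n_trees = 100L, seed = 6L)
  m_noise <- evaluate_subset(co$beta, co$labels, noise,
                             n_trees = 100L, seed = 6L)
  expect_gte(m_planted[["accuracy"]], m_noise[["accuracy"]])
  expect_gte(m_planted[["accuracy"]], 0.9)
  # single pure-noise probe: MCC within 3 sigma of 0 (null sd ~ 1/sqrt(n))
  m_null <- evaluate_subset(co$beta, co$labels, noise[1L],
                            n_trees = 100L, seed = 6L)
  expect_lt(abs(m_null[["mcc"]]), 3 / sqrt(40))
  expect_error(evaluate_subset(co$beta, co$labels, character(0)), "empty")
  expect_error(evaluate_subset(co$beta, co$labels, "cgNOPE"), "not in")
})
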