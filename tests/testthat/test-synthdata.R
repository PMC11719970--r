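test_that("binary cohort has planted effects of the configured size", {
  cfg <- cohort_config(n_samples_per_class = 200L, n_cpgs = 500L,
                       n_informative_per_class = 40L, effect_delta = 0.3,
                       precision = 50, seed = 7L)
  co <- generate_binary_cohort(cfg)
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  expect_false(anyNA(co$beta))
  expect_equal(unname(table(co$labels)), array(c(200L, 200L)),
               ignore_attr = TRUE)
  # sample-mean oracle: class-mean difference at every planted probe is
  # within 0.05 of +/- effect_delta
  d <- colMeans(co$beta[co$labels == 1, co$truth$cpg_id]) -
    colMeans(co$beta[co$labels == 0, co$truth$cpg_id])
  expect_true(all(abs(abs(d) - 0.3) < 0.05))
  # zero-effect config leaves classes indistinguishable at planted sites
  cfg0 <- cohort_config(n_samples_per_class = 50L, n_cpgs = 100L,
                        n_informative_per_class = 10L, effect_delta = 0,
                        seed = 3L)
  co0 <- generate_binary_cohort(cfg0)
  d0 <- colMeans(co0$beta[co0$labels == 1, co0$truth$cpg_id]) -
    colMeans(co0$beta[co0$labels == 0, co0$truth$cpg_id])
  expect_lt(max(abs(d0)), 0.1)  # pure sampling noise at n = 50, s = 50
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_samples_per_class = 30L, n_cpgs = 50L,
                       n_informative_per_class = 5L, seed = 11L)
  expect_identical(generate_binary_cohort(cfg), generate_binary_cohort(cfg))
  mcfg <- cohort_config(n_samples_per_class = 20L, n_cpgs = 60L,
                        n_informative_per_class = 5L, seed = 11L)
  expect_identical(generate_multiclass_cohort(mcfg),
                   generate_multiclass_cohort(mcfg))
})

test_that("multiclass cohort honours counts, subtypes and the age mixture", {
  cfg <- cohort_config(n_samples_per_class = c(409L, 386L, 367L, 381L),
                       n_cpgs = 300L, n_informative_per_class = 10L,
                       n_subtypes_per_class = c(breast_cancer = 4L),
                       seed = 19L)
  co <- generate_multiclass_cohort(cfg)
  expect_identical(unname(table(co$labels)[degenerative_classes()]),
                   array(c(409L, 386L, 367L, 381L)), ignore_attr = TRUE)
  # four distinct subtype indices among breast-cancer samples, one elsewhere
  bc <- names(co$labels)[co$labels == "breast_cancer"]
  expect_identical(sort(unique(co$subtype_of[bc])), 1:4)
  other <- names(co$labels)[co$labels == "neurodegenerative"]
  expect_identical(unique(co$subtype_of[other]), 1L)
  # truth CpGs disjoint across classes, none for healthy
  expect_false(anyDuplicated(co$truth$cpg_id) > 0)
  expect_false("healthy" %in% co$truth$class |
                 any(!co$truth$class %in% degenerative_classes()))
  # ages only for healthy samples; component sample means within 2 years of
  # the configured mixture means (oracle: split at the midpoint)
  expect_identical(sort(names(co$ages)),
                   sort(names(co$labels)[co$labels == "healthy"]))
  comp <- ifelse(co$ages < mean(cfg$healthy_age_means), 1L, 2L)
  expect_lt(abs(mean(co$ages[comp == 1]) - 33.74), 2)
  expect_lt(abs(mean(co$ages[comp == 2]) - 62.38), 2)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(effect_delta = 1.2), "effect_delta")
  expect_error(cohort_config(precision = 0), "precision")
  expect_error(cohort_config(n_samples_per_class = 1L), "2 samples")
  expect_error(cohort_config(background_mean_range = c(0, 0.5)),
               "background_mean_range")
  cfg <- cohort_config(n_cpgs = 20L, n_informative_per_class = 10L)
  expect_error(generate_multiclass_cohort(cfg), "exceed")
})

test_that("write_cohort produces readable delimited artifacts", {
  dir <- withr::local_tempdir()
  co <- generate_multiclass_cohort(cohort_config(
    n_samples_per_class = 10L, n_cpgs = 30L, n_informative_per_class = 3L,
    seed = 2L))
  write_cohort(co, dir)
  beta <- read_beta_matrix(file.path(dir, "beta.tsv"))
  expect_equal(beta, co$beta, tolerance = 1e-6)
  labs <- read_labels(file.path(dir, "labels.tsv"))
  expect_identical(unname(labs), unname(co$labels))
  ages <- read_ages(file.path(dir, "ages.tsv"))
  expect_equal(ages, co$ages, tolerance = 1e-3)
})
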