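# Synthetic beta-matrix cohorts with the statistical structure the pipeline
# assumes: a shared background of probe means, class-specific shifts at
# planted informative CpGs, optional within-class subtypes, and a healthy
# population with a bimodal age distribution plus age-drifting probes.
#
# Noise model: beta values are drawn from Beta(m*s, (1-m)*s), the
# mean/precision parameterization natural for methylation fractions; m is
# the probe's class-conditional mean and s the concentration. All means are
# clamped to [0.01, 0.99] before sampling so the Beta parameters stay valid.

clamp_mean <- function(m) pmin(pmax(m, 0.01), 0.99)

# Random +/-1 shift direction per probe, but forced toward the direction
# that keeps m +/- delta inside (0.01, 0.99) when only one fits, so planted
# effects are not silently truncated by clamping.
shift_signs <- function(m, delta) {
  s <- sample(c(-1, 1), length(m), replace = TRUE)
  up_ok <- m + delta <= 0.99
  down_ok <- m - delta >= 0.01
  s[!up_ok & down_ok] <- -1
  s[up_ok & !down_ok] <- 1
  s
}

#' Configuration for a synthetic methylation cohort
#'
#' @param n_samples_per_class Samples per class: a scalar, or (for the
#'   four-class generator) a vector of four counts in the canonical class
#'   order of [degenerative_classes()].
#' @param n_cpgs Total probe count.
#' @param n_informative_per_class Planted marker CpGs per (disease) class.
#' @param effect_delta Mean beta shift at planted markers, in `[0, 1)`; the
#'   shift direction (hyper- vs hypo-methylation) is drawn per probe.
#' @param precision Beta-distribution concentration `s > 0`; noise sd at a
#'   probe with mean m is roughly `sqrt(m (1 - m) / (s + 1))`.
#' @param background_mean_range Interval in (0, 1) for class-independent
#'   probe means.
#' @param n_subtypes_per_class Subtype count per class: a scalar applied to
#'   all classes or a named vector (e.g. `c(breast_cancer = 4)`). Each
#'   subtype adds a secondary shift of `effect_delta / 2` at its own probe
#'   subset, mimicking multi-community classes.
#' @param healthy_age_means Pair of mean ages (years) of the two healthy
#'   age components; defaults to the bimodal split at 33.74 and 62.38 years.
#' @param healthy_age_sd Age standard deviation within each component.
#' @param age_assoc_fraction Fraction of probes whose mean drifts linearly
#'   with age (healthy samples only; ages are unobserved elsewhere).
#' @param age_slope_sd Standard deviation of the per-probe drift slope, in
#'   beta units per year.
#' @param seed Integer seed; identical configs and seeds give bit-identical
#'   cohorts.
#' @return Validated configuration of class `cohort_config`.
#' @export
cohort_config <- function(n_samples_per_class = 200L,
                          n_cpgs = 1000L,
                          n_informative_per_class = 40L,
                          effect_delta = 0.3,
                          precision = 50,
                          background_mean_range = c(0.1, 0.9),
                          n_subtypes_per_class = 1L,
                          healthy_age_means = c(33.74, 62.38),
                          healthy_age_sd = 8,
                          age_assoc_fraction = 0.1,
                          age_slope_sd = 0.004,
                          seed = 1L) {
  if (any(n_samples_per_class < 2L)) stopf("need at least 2 samples per class")
  assert_count(n_cpgs, "n_cpgs")
  assert_count(n_informative_per_class, "n_informative_per_class", min = 0L)
  if (effect_delta < 0 || effect_delta >= 1) {
    stopf("`effect_delta` must be in [0, 1)")
  }
  if (precision <= 0) stopf("`precision` must be > 0")
  if (length(background_mean_range) != 2L ||
      background_mean_range[1L] <= 0 || background_mean_range[2L] >= 1 ||
      diff(background_mean_range) < 0) {
    stopf("`background_mean_range` must be an interval inside (0, 1)")
  }
  if (any(n_subtypes_per_class < 1L)) stopf("subtype counts must be >= 1")
  if (length(healthy_age_means) != 2L) stopf("`healthy_age_means` must be a pair")
  if (healthy_age_sd <= 0) stopf("`healthy_age_sd` must be > 0")
  if (age_assoc_fraction < 0 || age_assoc_fraction > 1) {
    stopf("`age_assoc_fraction` must be in [0, 1]")
  }
  structure(list(n_samples_per_class = n_samples_per_class,
                 n_cpgs = as.integer(n_cpgs),
                 n_informative_per_class = as.integer(n_informative_per_class),
                 effect_delta = effect_delta,
                 precision = precision,
                 background_mean_range = background_mean_range,
                 n_subtypes_per_class = n_subtypes_per_class,
                 healthy_age_means = healthy_age_means,
                 healthy_age_sd = healthy_age_sd,
                 age_assoc_fraction = age_assoc_fraction,
                 age_slope_sd = age_slope_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

subtype_count <- function(config, class_name) {
  nst <- config$n_subtypes_per_class
  if (is.null(names(nst))) return(as.integer(nst[1L]))
  if (class_name %in% names(nst)) as.integer(nst[[class_name]]) else 1L
}

new_cohort <- function(beta, labels, ages, truth, subtype_of, config) {
  structure(list(beta = beta, labels = labels, ages = ages, truth = truth,
                 subtype_of = subtype_of, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples x %d CpGs, classes: %s\n",
              nrow(x$beta), ncol(x$beta),
              paste(sprintf("%s(%d)", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Generate a binary healthy/disease cohort
#'
#' Class 0 is healthy, class 1 is disease. Background probes share one mean
#' per probe across classes; planted marker probes have the disease-class
#' mean shifted by `effect_delta` with a per-probe random sign.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: `beta` (samples x probes matrix), `labels`
#'   (named `0`/`1` vector), `ages` (`NULL`), `truth` (data.frame of planted
#'   `cpg_id`, `class`), `subtype_of`, and the config.
#' @export
generate_binary_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_per <- as.integer(config$n_samples_per_class[1L])
  p <- config$n_cpgs
  n_inf <- config$n_informative_per_class
  if (n_inf > p) stopf("more planted markers than probes")
  with_seed(config$seed, {
    m_bg <- runif(p, config$background_mean_range[1L],
                  config$background_mean_range[2L])
    planted <- sort(sample.int(p, n_inf))
    signs <- shift_signs(m_bg[planted], config$effect_delta)
    m_disease <- m_bg
    m_disease[planted] <- m_bg[planted] + signs * config$effect_delta
    n <- 2L * n_per
    mean_mat <- rbind(matrix(m_bg, n_per, p, byrow = TRUE),
                      matrix(m_disease, n_per, p, byrow = TRUE))
    mean_mat <- clamp_mean(mean_mat)
    s <- config$precision
    vals <- matrix(rbeta(n * p, as.vector(mean_mat) * s,
                         (1 - as.vector(mean_mat)) * s), n, p)
    sample_ids <- sprintf("S%05d", seq_len(n))
    cpg_ids <- sprintf("cg%08d", seq_len(p))
    beta <- beta_matrix(vals, sample_ids, cpg_ids)
    labels <- structure(rep(c(0L, 1L), each = n_per), names = sample_ids)
    truth <- data.frame(cpg_id = cpg_ids[planted],
                        class = rep("disease", n_inf),
                        stringsAsFactors = FALSE)
    new_cohort(beta, labels, NULL, truth,
               structure(rep(1L, n), names = sample_ids), config)
  })
}

#' Generate a four-class degenerative-disease cohort
#'
#' Classes follow [degenerative_classes()]. Each disease class receives its
#' own disjoint set of planted marker CpGs shifted by `effect_delta`;
#' healthy samples are the unshifted reference. Subtypes add a secondary
#' `effect_delta / 2` shift at subtype-specific probe subsets. Healthy
#' samples get ages from a two-component normal mixture, and a fraction of
#' probes drifts linearly with age so the healthy population is
#' age-separable.
#'
#' @param config A [cohort_config()]; `n_samples_per_class` may be a vector
#'   of four counts in canonical class order.
#' @return A `synthetic_cohort` with `ages` set for healthy samples.
#' @export
generate_multiclass_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  classes <- degenerative_classes()
  counts <- config$n_samples_per_class
  if (length(counts) == 1L) counts <- rep(counts, 4L)
  if (length(counts) != 4L) stopf("need one or four per-class sample counts")
  counts <- as.integer(counts)
  p <- config$n_cpgs
  n_inf <- config$n_informative_per_class
  disease_classes <- classes[classes != "healthy"]
  if (n_inf * length(disease_classes) > p) {
    stopf("planted markers (%d per class) exceed probe count %d",
          n_inf, p)
  }
  with_seed(config$seed, {
    m_bg <- runif(p, config$background_mean_range[1L],
                  config$background_mean_range[2L])
    cpg_ids <- sprintf("cg%08d", seq_len(p))

    # disjoint planted markers per disease class
    pool <- sample.int(p, n_inf * length(disease_classes))
    planted <- split(pool, rep(disease_classes, each = n_inf))
    class_means <- list(healthy = m_bg)
    truth <- list()
    for (cl in disease_classes) {
      idx <- sort(planted[[cl]])
      signs <- shift_signs(m_bg[idx], config$effect_delta)
      m <- m_bg
      m[idx] <- m[idx] + signs * config$effect_delta
      class_means[[cl]] <- m
      truth[[cl]] <- data.frame(cpg_id = cpg_ids[idx], class = cl,
                                stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    n <- sum(counts)
    sample_ids <- sprintf("S%05d", seq_len(n))
    labels <- structure(rep(classes, counts), names = sample_ids)

    # subtype-specific secondary shifts (delta / 2), disjoint within a class
    nonplanted <- setdiff(seq_len(p), pool)
    subtype_of <- structure(rep(1L, n), names = sample_ids)
    mean_rows <- matrix(0, n, p)
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      rows <- which(labels == cl)
      n_st <- subtype_count(config, cl)
      m_cl <- class_means[[cl]]
      if (n_st == 1L) {
        mean_rows[rows, ] <- matrix(m_cl, length(rows), p, byrow = TRUE)
        next
      }
      if (n_st * n_inf > length(nonplanted)) {
        stopf("not enough background probes for %d subtypes of class '%s'",
              n_st, cl)
      }
      st_pool <- sample(nonplanted, n_st * max(1L, n_inf))
      st_sets <- split(st_pool, rep(seq_len(n_st), each = max(1L, n_inf)))
      assign_st <- sample(rep_len(seq_len(n_st), length(rows)))
      subtype_of[rows] <- assign_st
      for (st in seq_len(n_st)) {
        m_st <- m_cl
        idx <- st_sets[[st]]
        m_st[idx] <- m_st[idx] +
          shift_signs(m_cl[idx], config$effect_delta / 2) *
          config$effect_delta / 2
        mean_rows[rows[assign_st == st], ] <-
          matrix(m_st, sum(assign_st == st), p, byrow = TRUE)
      }
    }

    # healthy ages: two-component normal mixture + linear age drift at a
    # designated age-associated probe subset
    healthy_rows <- which(labels == "healthy")
    comp <- sample(1:2, length(healthy_rows), replace = TRUE)
    ages_healthy <- rnorm(length(healthy_rows),
                          mean = config$healthy_age_means[comp],
                          sd = config$healthy_age_sd)
    ages <- structure(ages_healthy, names = sample_ids[healthy_rows])
    n_age_probes <- floor(config$age_assoc_fraction * p)
    if (n_age_probes > 0L && length(healthy_rows) > 0L) {
      age_probes <- sort(sample.int(p, n_age_probes))
      slopes <- rnorm(n_age_probes, 0, config$age_slope_sd)
      centered <- ages_healthy - mean(config$healthy_age_means)
      mean_rows[healthy_rows, age_probes] <-
        mean_rows[healthy_rows, age_probes] + outer(centered, slopes)
    }

    mean_rows <- clamp_mean(mean_rows)
    s <- config$precision
    vals <- matrix(rbeta(n * p, as.vector(mean_rows) * s,
                         (1 - as.vector(mean_rows)) * s), n, p)
    beta <- beta_matrix(vals, sample_ids, cpg_ids)
    new_cohort(beta, labels, ages, truth, subtype_of, config)
  })
}

#' Write a synthetic cohort to a directory of delimited text files
#'
#' Writes `beta.tsv` (samples x probes), `labels.tsv`, `truth.tsv`
#' (two columns: cpg_id, class), `subtypes.tsv`, and `ages.tsv` when ages
#' are present.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(sample_id = names(cohort$subtype_of),
                           subtype = cohort$subtype_of),
    file.path(dir, "subtypes.tsv"), sep = "\t")
  if (!is.null(cohort$ages)) {
    data.table::fwrite(
      data.table::data.table(sample_id = names(cohort$ages),
                             age_years = round(cohort$ages, 4)),
      file.path(dir, "ages.tsv"), sep = "\t")
  }
  invisible(dir)
}
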