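# End-to-end orchestration: simulate -> split -> rf-filter -> scan/select ->
# cluster (raw betas) -> multi-class train/test -> embed-cluster ->
# attribute. Every stage derives its own seed from the global one by stable
# hashing of the stage name, artifacts are plain delimited text plus JSON
# metric reports, and a run manifest records config and seeds so a rerun
# reproduces every artifact byte for byte.

#' Pipeline configuration
#'
#' Defaults describe a desk-scale synthetic run that exercises every stage
#' in a few minutes on one CPU.
#'
#' @param out_dir Artifact directory.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param cohort [cohort_config()] for the simulated four-class cohort.
#' @param rf_trees Stage-1 ensemble size.
#' @param scan_enabled If `FALSE`, skip the feature-count scan and fall back
#'   to the full nonzero ranking (logged).
#' @param scan_start,scan_step,scan_max Feature-count grid settings; the
#'   grid is capped at `min(scan_max, nonzero ranking length)`.
#' @param scan_folds,scan_tol Cross-validation folds and selection
#'   tolerance of the scan.
#' @param msdcnn [msdcnn_config()] used by the scan.
#' @param resdegnet [resdegnet_config()] for the multi-class model.
#' @param train_fraction Train share of the stratified train/test split
#'   (default 0.8).
#' @param cluster_k_max,cluster_window,cluster_resolution K-scan settings.
#' @param shap_permutations,shap_max_samples Attribution settings: sampled
#'   orderings per sample and the (seeded) cap on attributed training
#'   samples.
#' @return Configuration of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("methylscreen_run_"),
                            seed = 1L,
                            cohort = cohort_config(
                              n_samples_per_class = 80L, n_cpgs = 300L,
                              n_informative_per_class = 12L,
                              effect_delta = 0.35, precision = 50,
                              seed = seed),
                            rf_trees = 200L,
                            scan_enabled = TRUE,
                            scan_start = 20L, scan_step = 20L,
                            scan_max = 100L, scan_folds = 5L,
                            scan_tol = 0.005,
                            msdcnn = msdcnn_config(
                              filters_per_block = c(8L, 16L),
                              dense_units = 32L, epochs = 12L,
                              patience = 3L, padding = "same", seed = seed),
                            resdegnet = resdegnet_config(
                              block_channels = c(8L, 16L, 32L),
                              epochs = 40L, seed = seed),
                            train_fraction = 0.8,
                            cluster_k_max = 50L, cluster_window = 4L,
                            cluster_resolution = 1,
                            shap_permutations = 8L,
                            shap_max_samples = 40L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("`train_fraction` must be in (0, 1); the test share is its complement")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 rf_trees = as.integer(rf_trees),
                 scan_enabled = isTRUE(scan_enabled),
                 scan_start = as.integer(scan_start),
                 scan_step = as.integer(scan_step),
                 scan_max = as.integer(scan_max),
                 scan_folds = as.integer(scan_folds), scan_tol = scan_tol,
                 msdcnn = msdcnn, resdegnet = resdegnet,
                 train_fraction = train_fraction,
                 cluster_k_max = as.integer(cluster_k_max),
                 cluster_window = as.integer(cluster_window),
                 cluster_resolution = cluster_resolution,
                 shap_permutations = as.integer(shap_permutations),
                 shap_max_samples = as.integer(shap_max_samples)),
            class = "pipeline_config")
}

pipeline_stages <- function() {
  c("simulate", "split", "rf-filter", "scan", "cluster", "classify",
    "embed-cluster", "attribute")
}

log_stage <- function(stage, seed, fmt, ...) {
  message(sprintf("[%s] [%s] [seed %d] %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, seed,
                  sprintf(fmt, ...)))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Run the full pipeline (or a prefix of it)
#'
#' Executes the stages in order, writing every artifact as plain delimited
#' text or JSON under `cfg$out_dir`. A failing stage writes a `FAILED`
#' marker naming the stage and aborts; earlier artifacts are retained.
#' Reruns with the same config and seed are byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @param through Last stage to execute (default `"attribute"` = all); one
#'   of `simulate`, `split`, `rf-filter`, `scan`, `cluster`, `classify`,
#'   `embed-cluster`, `attribute`.
#' @return Invisibly, a list of in-memory stage results plus `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), through = "attribute") {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- pipeline_stages()
  through <- match.arg(through, stages)
  last <- match(through, stages)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  res <- list(out_dir = cfg$out_dir)
  stage_seeds <- vapply(stages, function(s) derive_seed(cfg$seed, s), 0L)

  run_stage <- function(stage, fun) {
    tryCatch(fun(stage_seeds[[stage]]),
             error = function(e) {
               writeLines(c(stage, conditionMessage(e)), failed_marker)
               stopf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e))
             })
  }

  # -- simulate ---------------------------------------------------------
  res$cohort <- run_stage("simulate", function(seed) {
    cc <- cfg$cohort
    cc$seed <- seed
    cohort <- generate_multiclass_cohort(cc)
    write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
    log_stage("simulate", seed, "%d samples x %d probes written",
              nrow(cohort$beta), ncol(cohort$beta))
    cohort
  })
  if (last < match("split", stages)) return(finish_run(cfg, res, stage_seeds, through))
  cohort <- res$cohort

  # -- split ------------------------------------------------------------
  res$split <- run_stage("split", function(seed) {
    sp <- stratified_split(cohort$labels, cfg$train_fraction, seed = seed)
    data.table::fwrite(
      data.table::data.table(
        sample_id = rownames(cohort$beta),
        role = ifelse(seq_len(nrow(cohort$beta)) %in% sp$train, "train",
                      "test")),
      file.path(cfg$out_dir, "split.tsv"), sep = "\t")
    log_stage("split", seed, "train %d / test %d", length(sp$train),
              length(sp$test))
    sp
  })
  if (last < match("rf-filter", stages)) return(finish_run(cfg, res, stage_seeds, through))
  sp <- res$split
  y_bin <- as.integer(cohort$labels != "healthy")
  beta_tr <- cohort$beta[sp$train, , drop = FALSE]

  # -- rf-filter --------------------------------------------------------
  res$ranking <- run_stage("rf-filter", function(seed) {
    ranking <- fit_importances(beta_tr, y_bin[sp$train],
                               n_trees = cfg$rf_trees, seed = seed)
    nonzero <- filter_nonzero(ranking)
    data.table::fwrite(as.data.frame(nonzero),
                       file.path(cfg$out_dir, "importance.tsv"), sep = "\t")
    log_stage("rf-filter", seed, "%d probes -> %d with nonzero importance",
              attr(ranking, "n_input"), nrow(nonzero))
    nonzero
  })
  if (last < match("scan", stages)) return(finish_run(cfg, res, stage_seeds, through))
  nonzero <- res$ranking

  # -- scan / select ----------------------------------------------------
  res$selected <- run_stage("scan", function(seed) {
    if (!cfg$scan_enabled) {
      log_stage("scan", seed,
                "scan disabled; falling back to all %d nonzero probes",
                nrow(nonzero))
      selected <- nonzero$cpg_id
    } else {
      total <- min(cfg$scan_max, nrow(nonzero))
      grid <- make_grid(min(cfg$scan_start, total), cfg$scan_step, total)
      scan <- scan_features(beta_tr, y_bin[sp$train], nonzero, grid,
                            k_folds = cfg$scan_folds, cfg = cfg$msdcnn,
                            tol = cfg$scan_tol, seed = seed)
      data.table::fwrite(scan$summary,
                         file.path(cfg$out_dir, "scan_summary.tsv"),
                         sep = "\t")
      res$scan <<- scan
      selected <- nonzero$cpg_id[seq_len(scan$selected_count)]
      log_stage("scan", seed, "selected %d of %d features",
                scan$selected_count, max(grid))
    }
    writeLines(selected, file.path(cfg$out_dir, "selected_cpgs.txt"))
    selected
  })
  if (last < match("cluster", stages)) return(finish_run(cfg, res, stage_seeds, through))
  selected <- res$selected
  beta_sel <- cohort$beta[, selected, drop = FALSE]

  # -- cluster raw betas ------------------------------------------------
  res$cluster_raw <- run_stage("cluster", function(seed) {
    ks <- k_scan(beta_sel, k_max = min(cfg$cluster_k_max,
                                       nrow(beta_sel) - 1L),
                 window = cfg$cluster_window,
                 resolution = cfg$cluster_resolution, seed = seed)
    data.table::fwrite(
      data.table::data.table(k = ks$k, n_communities = ks$n_communities),
      file.path(cfg$out_dir, "kscan_raw.tsv"), sep = "\t")
    data.table::fwrite(
      data.table::data.table(sample_id = names(ks$assignment$membership),
                             community = ks$assignment$membership,
                             label = cohort$labels,
                             subtype = cohort$subtype_of),
      file.path(cfg$out_dir, "communities_raw.tsv"), sep = "\t")
    log_stage("cluster", seed, "stable K = %d with %d communities%s",
              ks$stable_k, ks$stable_count,
              if (ks$stable) "" else " (unstable)")
    ks
  })
  if (last < match("classify", stages)) return(finish_run(cfg, res, stage_seeds, through))

  # -- multi-class train / test -----------------------------------------
  res$model <- run_stage("classify", function(seed) {
    rcfg <- cfg$resdegnet
    rcfg$seed <- seed
    model <- build_resdegnet(length(selected), rcfg)
    model <- train_multiclass(model, beta_sel[sp$train, , drop = FALSE],
                              cohort$labels[sp$train])
    data.table::fwrite(model$cv_report,
                       file.path(cfg$out_dir, "multiclass_cv.tsv"),
                       sep = "\t")
    pred <- predict_classes(model, beta_sel[sp$test, , drop = FALSE])
    m <- multiclass_metrics(cohort$labels[sp$test], pred, model$classes)
    write_json_artifact(as.list(m),
                        file.path(cfg$out_dir, "multiclass_test.json"))
    data.table::fwrite(
      data.table::data.table(sample_id = rownames(beta_sel)[sp$test],
                             label = cohort$labels[sp$test],
                             predicted = pred),
      file.path(cfg$out_dir, "predictions_test.tsv"), sep = "\t")
    log_stage("classify", seed, "independent-test accuracy %.4f",
              m[["accuracy"]])
    model
  })
  if (last < match("embed-cluster", stages)) return(finish_run(cfg, res, stage_seeds, through))
  model <- res$model

  # -- embed-cluster ----------------------------------------------------
  res$cluster_embed <- run_stage("embed-cluster", function(seed) {
    emb <- extract_embeddings(model, beta_sel[sp$test, , drop = FALSE])
    ks <- k_scan(emb, k_max = min(cfg$cluster_k_max, nrow(emb) - 1L),
                 window = cfg$cluster_window,
                 resolution = cfg$cluster_resolution, seed = seed)
    data.table::fwrite(
      data.table::data.table(k = ks$k, n_communities = ks$n_communities),
      file.path(cfg$out_dir, "kscan_embed.tsv"), sep = "\t")
    data.table::fwrite(
      data.table::data.table(sample_id = names(ks$assignment$membership),
                             community = ks$assignment$membership,
                             label = cohort$labels[sp$test]),
      file.path(cfg$out_dir, "communities_embed.tsv"), sep = "\t")
    log_stage("embed-cluster", seed, "stable K = %d with %d communities%s",
              ks$stable_k, ks$stable_count,
              if (ks$stable) "" else " (unstable)")
    ks
  })
  if (last < match("attribute", stages)) return(finish_run(cfg, res, stage_seeds, through))

  # -- attribute --------------------------------------------------------
  res$attribution <- run_stage("attribute", function(seed) {
    tr_beta <- beta_sel[sp$train, , drop = FALSE]
    n_keep <- min(cfg$shap_max_samples, nrow(tr_beta))
    keep <- with_seed(derive_seed(seed, "subsample"),
                      sort(sample.int(nrow(tr_beta), n_keep)))
    att <- shapley_attributions(model, tr_beta[keep, , drop = FALSE],
                                baseline = colMeans(tr_beta),
                                n_permutations = cfg$shap_permutations,
                                seed = seed)
    m <- mean_attribution(att)
    export_heatmap_table(m, file.path(cfg$out_dir, "attribution.tsv"))
    log_stage("attribute", seed, "attributed %d samples x %d probes",
              n_keep, ncol(tr_beta))
    m
  })
  finish_run(cfg, res, stage_seeds, through)
}

finish_run <- function(cfg, res, stage_seeds, through) {
  manifest <- list(
    package = "methylscreen",
    version = as.character(utils::packageVersion("methylscreen")),
    r_version = R.version.string,
    seed = cfg$seed,
    stage_seeds = as.list(stage_seeds),
    through = through,
    config = config_as_list(cfg))
  write_json_artifact(manifest, file.path(cfg$out_dir, "manifest.json"))
  invisible(res)
}

config_as_list <- function(x) {
  if (inherits(x, "pipeline_config") || inherits(x, "cohort_config") ||
      inherits(x, "msdcnn_config") || inherits(x, "resdegnet_config")) {
    return(lapply(unclass(x), config_as_list))
  }
  if (is.list(x)) return(lapply(x, config_as_list))
  x
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `rf-filter`, `scan`, `cluster`, `classify`,
#' `embed-cluster`, `attribute`, `run-all`. Each runs the pipeline from the
#' start through the named stage (stages are deterministic and cheap at
#' synthetic scale, so prefixes are recomputed rather than resumed).
#' Options: `--config FILE` (JSON overrides for [pipeline_config()]),
#' `--seed N`, `--out DIR`, `--threads N` (accepted; execution is
#' single-threaded), `--strict-io` (accepted; simulated inputs are always
#' validated strictly).
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the [run_pipeline()] result.
#' @export
methylscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    stopf("usage: methylscreen <%s|run-all> [--config FILE] [--seed N] [--out DIR]",
          paste(pipeline_stages(), collapse = "|"))
  }
  sub <- args[[1L]]
  through <- if (sub == "run-all") "attribute" else {
    if (!sub %in% pipeline_stages()) stopf("unknown subcommand '%s'", sub)
    if (sub == "split") stopf("'split' is not a standalone subcommand")
    sub
  }
  opt <- list(config = NULL, seed = NULL, out = NULL)
  i <- 2L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a %in% c("--config", "--seed", "--out", "--threads")) {
      if (i == length(args)) stopf("missing value for %s", a)
      val <- args[[i + 1L]]
      if (a == "--config") opt$config <- val
      if (a == "--seed") opt$seed <- as.integer(val)
      if (a == "--out") opt$out <- val
      i <- i + 2L
    } else if (a == "--strict-io") {
      i <- i + 1L
    } else {
      stopf("unknown option '%s'", a)
    }
  }
  overrides <- if (!is.null(opt$config)) {
    jsonlite::read_json(opt$config, simplifyVector = TRUE)
  } else {
    list()
  }
  if (!is.null(opt$seed)) overrides$seed <- opt$seed
  if (!is.null(opt$out)) overrides$out_dir <- opt$out
  for (nm in c("cohort", "msdcnn", "resdegnet")) {
    if (!is.null(overrides[[nm]])) {
      ctor <- switch(nm, cohort = cohort_config, msdcnn = msdcnn_config,
                     resdegnet = resdegnet_config)
      overrides[[nm]] <- do.call(ctor, as.list(overrides[[nm]]))
    }
  }
  cfg <- do.call(pipeline_config, overrides)
  run_pipeline(cfg, through = through)
}
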