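#' Run configuration for the end-to-end analysis
#'
#' @param cohort_dir Directory with the cohort files (see
#'   [write_fixture_files()] / [read_cohort_dir()]).
#' @param out_dir Output directory for reports.
#' @param fdeam_cutpoint f_deam cutpoint in percent (default 13.1; call
#'   HR-deficient strictly below it).
#' @param hrdsum_cutpoint HRDsum cutpoint (default 42; call HR-deficient
#'   at or above it).
#' @param min_tmb Minimum TMB for a defined f_deam (default 10).
#' @param purities Purity levels of the dilution experiment.
#' @param reps Replicates per purity level.
#' @param seed RNG seed for all stochastic steps.
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort_dir, out_dir,
                       fdeam_cutpoint = 13.1, hrdsum_cutpoint = 42,
                       min_tmb = 10, purities = c(0.6, 0.4, 0.2, 0.1, 0.05),
                       reps = 1, seed = 1) {
  stopifnot(is.finite(fdeam_cutpoint), is.finite(hrdsum_cutpoint),
            all(purities > 0), all(purities <= 1))
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir,
                 fdeam_cutpoint = fdeam_cutpoint,
                 hrdsum_cutpoint = hrdsum_cutpoint, min_tmb = min_tmb,
                 purities = purities, reps = reps, seed = seed),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' End-to-end analysis: classify, score, evaluate, dilute
#'
#' Orchestrates the full analysis on a cohort directory: classifies the
#' cause of HRD from the gene-alteration and methylation tables (or uses
#' the shipped labels when no alteration table exists), computes per-sample
#' catalogs, f_deam, TMB and HRDsum, evaluates both biomarkers (AUC,
#' paired DeLong test, optimal and fixed cutpoints, Spearman correlation,
#' inter-test kappa, 96-channel differential table), and runs the
#' tumor-purity dilution experiment. All outputs are plain text
#' (TSV/JSON); identical configuration and seed give identical outputs.
#'
#' Written files: `classifications.tsv`, `labels.tsv`, `biomarkers.tsv`,
#' `differential.tsv`, `purity_experiment.tsv`, `evaluation.json`,
#' `log.txt` (the exclusion ledger and the defaults in effect).
#'
#' @param config A [run_config()] or path to its YAML.
#' @return Invisibly, a list with the evaluation summary and the paths of
#'   all written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  cohort <- read_cohort_dir(config$cohort_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("fdeam_cutpoint=%g (call positive below, strict)",
                         config$fdeam_cutpoint),
                 sprintf("hrdsum_cutpoint=%g (call positive at or above)",
                         config$hrdsum_cutpoint),
                 sprintf("min_tmb=%d", config$min_tmb),
                 sprintf("seed=%d", config$seed))

  # 1. cause-of-HRD classification -> benchmark labels
  sample_ids <- vapply(cohort$samples, function(s) s$sample_id, character(1))
  if (!is.null(cohort$alterations)) {
    classifications <- classify_hr_cohort(cohort$alterations,
                                          cohort$methylation,
                                          sample_ids = sample_ids)
    labels_df <- build_benchmark_labels(classifications)
  } else {
    classifications <- NULL
    labels_df <- data.frame(sample = sample_ids,
                            label = vapply(cohort$samples,
                                           function(s) s$label, character(1)),
                            reason = "label supplied with cohort",
                            stringsAsFactors = FALSE)
    log_lines <- c(log_lines, "no alteration table: using shipped labels")
  }
  n_excl <- sum(labels_df$label == "excluded")
  log_lines <- c(log_lines,
                 sprintf("benchmark: %d positive, %d negative, %d excluded",
                         sum(labels_df$label == "positive"),
                         sum(labels_df$label == "negative"), n_excl))
  if (length(setdiff(c("positive", "negative"), labels_df$label)) > 0) {
    stop("benchmark cohort contains only one class after labeling",
         call. = FALSE)
  }

  # 2. per-sample biomarkers
  label_of <- stats::setNames(labels_df$label, labels_df$sample)
  scored <- score_cohort(cohort, min_tmb = config$min_tmb)
  scored$label <- unname(label_of[scored$sample])
  bench <- scored[scored$label %in% c("positive", "negative"), , drop = FALSE]
  n_na <- sum(is.na(bench$fdeam))
  log_lines <- c(log_lines,
                 sprintf("f_deam NA (TMB < %d): %d sample(s)",
                         config$min_tmb, n_na))

  # 3. evaluation
  roc_f <- suppressMessages(roc_auc(bench$fdeam, bench$label,
                                    "lower_predicts_positive"))
  roc_h <- suppressMessages(roc_auc(bench$hrdsum, bench$label,
                                    "higher_predicts_positive"))
  dl <- suppressMessages(delong_paired(bench$fdeam, bench$hrdsum, bench$label,
                                       "lower_predicts_positive",
                                       "higher_predicts_positive"))
  opt_f <- suppressMessages(optimize_cutpoint(bench$fdeam, bench$label,
                                              "lower_predicts_positive"))
  fix_f <- suppressMessages(evaluate_at_cutpoint(bench$fdeam, bench$label,
                                                 config$fdeam_cutpoint,
                                                 "lower_predicts_positive"))
  fix_h <- suppressMessages(evaluate_at_cutpoint(bench$hrdsum, bench$label,
                                                 config$hrdsum_cutpoint,
                                                 "higher_predicts_positive"))
  sp <- spearman_cor(bench$fdeam, bench$hrdsum)
  calls_f <- bench$fdeam < config$fdeam_cutpoint
  calls_h <- bench$hrdsum >= config$hrdsum_cutpoint
  kap <- cohens_kappa(calls_f, calls_h)
  catalogs <- lapply(cohort$samples, function(s) {
    build_catalog(s$variants, s$sample_id)
  })
  names(catalogs) <- sample_ids
  pos_ids <- labels_df$sample[labels_df$label == "positive"]
  neg_ids <- labels_df$sample[labels_df$label == "negative"]
  diff_tab <- differential_channels(catalogs[pos_ids], catalogs[neg_ids])

  # 4. purity dilution experiment
  pur <- run_purity_experiment(
    list(samples = cohort$samples[sample_ids %in% c(pos_ids, neg_ids)],
         annotation = cohort$annotation),
    purities = config$purities, fdeam_cutpoint = config$fdeam_cutpoint,
    hrdsum_cutpoint = config$hrdsum_cutpoint, reps = config$reps,
    seed = config$seed, min_tmb = config$min_tmb)

  # 5. write outputs
  paths <- list()
  wt <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(classifications)) {
    paths$classifications <- wt(classifications, "classifications.tsv")
  }
  paths$labels <- wt(labels_df, "labels.tsv")
  paths$biomarkers <- wt(scored, "biomarkers.tsv")
  paths$differential <- wt(diff_tab, "differential.tsv")
  paths$purity <- wt(pur, "purity_experiment.tsv")
  evaluation <- list(
    auc_fdeam = roc_f$auc, auc_hrdsum = roc_h$auc, delong_p = dl$p_value,
    optimal_fdeam_cutpoint = opt_f$threshold,
    optimal_fdeam_balanced_accuracy = opt_f$balanced_accuracy,
    fdeam_at_cutpoint = as.list(fix_f[1, c("threshold", "sensitivity",
                                           "specificity", "balanced_accuracy")]),
    hrdsum_at_cutpoint = as.list(fix_h[1, c("threshold", "sensitivity",
                                            "specificity", "balanced_accuracy")]),
    spearman_R = sp$R, spearman_p = sp$p_value, kappa = kap,
    n_significant_channels = sum(diff_tab$significant),
    n_fdeam_na = n_na, n_excluded = n_excl, seed = config$seed)
  paths$evaluation <- file.path(config$out_dir, "evaluation.json")
  jsonlite::write_json(evaluation, paths$evaluation, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$log <- file.path(config$out_dir, "log.txt")
  writeLines(log_lines, paths$log)
  invisible(list(evaluation = evaluation, purity = pur, paths = paths))
}
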