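#' Study configuration for the end-to-end pipeline
#'
#' @param synthetic a [synthetic_config()], or `NULL` when `table_path`
#'   supplies the data.
#' @param table_path CSV path of a cohort ([read_feature_table()] layout);
#'   ignored when `synthetic` is given.
#' @param preprocess a [preprocess_config()].
#' @param screen a [screen_config()].
#' @param thresholds a [ratio_thresholds()].
#' @param nn an [nn_config()].
#' @param marker_names named character vector (`A`, `D`, `trp`, `cod`) of
#'   the ratio-marker metabolite names; defaults to the reference compound
#'   names of the four markers.
#' @param split_fraction training fraction of the external-validation split.
#' @param split_seed seed of the batch-level split.
#' @param out_dir optional directory to serialize the report into.
#' @return A list of class `study_config`.
#' @export
study_config <- function(synthetic = synthetic_config(),
                         table_path = NULL,
                         preprocess = preprocess_config(),
                         screen = screen_config(),
                         thresholds = ratio_thresholds(),
                         nn = nn_config(),
                         marker_names = c(
                           A = "Codonopyrrolidium A",
                           D = "Codonopyrrolidium D",
                           trp = "Tryptophan",
                           cod = "Codonopsinol A"),
                         split_fraction = 2 / 3,
                         split_seed = 20260218,
                         out_dir = NULL) {
  if (is.null(synthetic) && is.null(table_path))
    stop("either a synthetic config or a table path is required")
  structure(list(synthetic = synthetic, table_path = table_path,
                 preprocess = preprocess, screen = screen,
                 thresholds = thresholds, nn = nn,
                 marker_names = marker_names,
                 split_fraction = split_fraction, split_seed = split_seed,
                 out_dir = out_dir), class = "study_config")
}

.stage_stop <- function(stage, ...) stop("[", stage, "] ", ..., call. = FALSE)

#' Run the full origin-discrimination study
#'
#' Orchestrates the pipeline: generate (or load) the cohort, append pooled
#' QC runs, percentile-normalize, frequency-filter, run the ANOVA +
#' fold-change screen, select the reference metabolite, cluster the screened
#' table, apply the ratio cascade to every sample, compare PLS-DA / LDA / NN
#' by leave-one-out cross-validation on the screened log areas, retrain the
#' network on a stratified two-thirds batch split with external validation
#' on the held-out third, and cross-tabulate the ratio calls against the
#' network predictions. Deterministic given the configured seeds.
#'
#' @param config a [study_config()].
#' @param models character subset of `c("NN", "LDA", "PLSDA")` to compare by
#'   LOOCV (default all three).
#' @return A list of class `study_report` with elements `table` (the
#'   preprocessed cohort), `qc_rsd_pct`, `screen` (per-metabolite results),
#'   `screened` (passed metabolite names), `reference`, `hca_purity`,
#'   `ratio` (a `ratio_report`), `loocv` (named list of `cv_report`s),
#'   `split_sizes`, `external` (`cv_report` of the retrained network on the
#'   validation third), `importance` (input-weight feature ranking),
#'   `agreement` (ratio vs NN cross-tabulation and rate).
#' @export
run_study <- function(config = study_config(),
                      models = c("NN", "LDA", "PLSDA")) {
  stopifnot(inherits(config, "study_config"))
  models <- match.arg(models, several.ok = TRUE)

  # --- data ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    cohort <- generate_qc(cohort, config$synthetic)
  } else {
    cohort <- read_feature_table(config$table_path)
  }
  for (m in config$marker_names)
    if (!m %in% cohort$metabolite_names)
      .stage_stop("ratio_classifier", "marker metabolite '", m,
                  "' absent from table")

  # --- preprocessing ------------------------------------------------------
  norm <- percentile_normalize(cohort, config$preprocess)
  norm <- frequency_filter(norm, config$preprocess)
  qc_idx <- norm$group == "QC"
  qc_rsd <- if (any(qc_idx)) {
    qc_areas <- norm$areas[qc_idx, , drop = FALSE]
    apply(qc_areas, 2, function(x) 100 * stats::sd(x) / mean(x))
  } else NULL

  # --- differential screen ------------------------------------------------
  screen <- anova_screen(norm, config$screen)
  screened <- screen$metabolite[screen$passed]
  if (length(screened) < 2)
    .stage_stop("diff_screen", "fewer than 2 metabolites passed the screen")
  reference <- select_reference(norm)
  cohort_origin <- drop_qc(norm)
  cl <- hca(subset_metabolites(cohort_origin, screened), k = 3)
  purity <- cluster_purity(cl$sample_cluster, cohort_origin$group)

  # --- ratio cascade (raw areas: ratios are scale-free) --------------------
  ratio <- evaluate_ratios(drop_qc(cohort), config$marker_names, reference,
                           config$thresholds)

  # --- model comparison by LOOCV ------------------------------------------
  X <- log_areas(subset_metabolites(cohort_origin, screened))
  y <- cohort_origin$group
  factories <- list(NN = nn_factory(config$nn), LDA = lda_factory(),
                    PLSDA = plsda_factory())
  cv <- lapply(factories[models], function(f) loocv(f, X, y))

  # --- external validation of the retrained network ------------------------
  split <- split_train_validate(cohort_origin, config$split_fraction,
                                config$split_seed)
  Xtr <- log_areas(subset_metabolites(split$train, screened))
  Xva <- log_areas(subset_metabolites(split$validation, screened))
  nn_new <- nn_train(Xtr, split$train$group, config$nn)
  va_pred <- nn_predict(nn_new, Xva)
  external <- cv_report(true = split$validation$group,
                        predicted = va_pred$label,
                        confidence = va_pred$confidence,
                        sample_id = split$validation$sample_id)

  # --- cross-method agreement ----------------------------------------------
  nn_full <- nn_train(X, y, config$nn)
  nn_calls <- nn_predict(nn_full, X)
  nn_calls$sample_id <- cohort_origin$sample_id
  agreement <- cross_method_agreement(ratio$decisions, nn_calls)

  report <- structure(list(
    table = norm, qc_rsd_pct = qc_rsd, screen = screen,
    screened = screened, reference = reference, hca_purity = purity,
    hca = cl, ratio = ratio, loocv = cv,
    split_sizes = c(train = nrow(split$train$areas),
                    validation = nrow(split$validation$areas)),
    external = external,
    importance = weight_importance(nn_full),
    agreement = agreement), class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' Agreement between the ratio cascade and a model's predictions
#'
#' Cross-tabulates the ratio calls against the model labels over the shared
#' samples and reports the agreement rate over the samples the ratio method
#' decided (CP/CM/CT); `NA` when it decided none.
#'
#' @param ratio_decisions the `decisions` data frame of a `ratio_report`
#'   (columns `sample_id`, `call`).
#' @param predictions data frame with `sample_id` and `label` columns.
#' @return A list: `table` (call x label contingency), `agreement_rate`,
#'   `n_decided`.
#' @export
cross_method_agreement <- function(ratio_decisions, predictions) {
  if (!setequal(ratio_decisions$sample_id, predictions$sample_id))
    stop("ratio decisions and predictions cover different samples")
  m <- merge(ratio_decisions[, c("sample_id", "call")],
             predictions[, c("sample_id", "label")], by = "sample_id")
  decided <- m$call %in% c("CP", "CM", "CT")
  list(table = table(ratio = m$call, model = m$label),
       agreement_rate = if (any(decided))
         mean(m$call[decided] == m$label[decided]) else NA_real_,
       n_decided = sum(decided))
}

#' Serialize a study report
#'
#' Writes the per-metabolite screen, the per-sample ratio decisions,
#' external-validation predictions, the feature-importance ranking and a
#' JSON summary into a directory.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$screen, file.path(dir, "screen.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ratio$decisions,
                   file.path(dir, "ratio_decisions.csv"), row.names = FALSE)
  utils::write.csv(report$external$samples,
                   file.path(dir, "external_validation.csv"),
                   row.names = FALSE)
  utils::write.csv(report$importance, file.path(dir, "importance.csv"),
                   row.names = FALSE)
  summary <- list(
    n_screened = length(report$screened),
    reference = report$reference,
    hca_purity = report$hca_purity,
    ratio_accuracy_pct = report$ratio$accuracy_pct,
    ratio_undecided = report$ratio$n_indeterminate + report$ratio$n_conflict,
    loocv_accuracy_pct = lapply(report$loocv, `[[`, "overall_accuracy_pct"),
    loocv_min_confidence = lapply(report$loocv, `[[`, "min_confidence"),
    external_accuracy_pct = report$external$overall_accuracy_pct,
    external_min_confidence = report$external$min_confidence,
    agreement_rate = report$agreement$agreement_rate)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n",
      " screened metabolites: ", length(x$screened),
      " (reference: ", x$reference, ")\n",
      " HCA purity (k=3): ", round(x$hca_purity, 3), "\n",
      " ratio method: ", round(x$ratio$accuracy_pct, 2), "% over ",
      x$ratio$n_decided, " decided samples\n", sep = "")
  for (m in names(x$loocv))
    cat("  LOOCV ", m, ": ", round(x$loocv[[m]]$overall_accuracy_pct, 2),
        "% (min conf ", round(x$loocv[[m]]$min_confidence, 4), ")\n",
        sep = "")
  cat(" external validation: ",
      round(x$external$overall_accuracy_pct, 2), "% (min conf ",
      round(x$external$min_confidence, 4), ") on ",
      nrow(x$external$samples), " samples\n",
      " ratio/NN agreement: ", round(x$agreement$agreement_rate, 4), "\n",
      sep = "")
  invisible(x)
}
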