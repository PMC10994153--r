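#' Run the full OGTT curve-analysis pipeline
#'
#' Orchestrates every stage on a cohort table: penalized-spline smoothing
#' of the five-point glucose and insulin series (one cross-validated lambda
#' per analyte), functional PCA with standardized scores, rule-based shape
#' classification, the cross-sectional association battery (Spearman matrix
#' with Bonferroni control, shape-class group tests, demographic-adjusted
#' linear models) and — when follow-up data are present — paired change
#' tests and the seven-predictor dysglycemia ROC/AUC comparison on the
#' longitudinal subset (follow-up interval >= 6 months; shorter intervals
#' are excluded and logged).
#'
#' @param config an [ogtt_config()].
#' @param input either the string \code{"synthetic"} (generate a cohort
#'   with [generate_cohort()] using \code{n} and the config seed) or a path
#'   to a cohort file in the wide dialect.
#' @param n synthetic cohort size when \code{input = "synthetic"}.
#' @param verbose log each stage with counts (default TRUE).
#' @return list of class \code{ogtt_results} with elements \code{cohort},
#'   \code{lambda} (per analyte), \code{curves}, \code{fpca},
#'   \code{scores} (per-participant raw and standardized, both analytes),
#'   \code{shapes}, \code{associations}, \code{group_tests},
#'   \code{adjusted_models}, \code{paired_tests}, \code{prediction} and
#'   \code{config}.
#' @export
run_pipeline <- function(config = ogtt_config(), input = "synthetic",
                         n = 500L, verbose = TRUE) {
  stopifnot(inherits(config, "ogtt_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "input"
  withCallingHandlers(
    run_pipeline_impl(config, input, n, say, function(s) stage <<- s),
    error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
}

run_pipeline_impl <- function(config, input, n, say, set_stage) {
  set_stage("input")
  cohort <- if (identical(input, "synthetic")) {
    generate_cohort(generator_params(n = n, seed = config$seed))
  } else {
    read_cohort(input)
  }
  say("input: %d participants", nrow(cohort))

  set_stage("smoothing")
  times <- c(0, 30, 60, 90, 120)
  basis <- build_basis(times, n_basis = config$n_basis,
                       quadrature_step = config$quadrature_step)
  G <- as.matrix(cohort[gcols("glucose")])
  I <- as.matrix(cohort[gcols("insulin")])
  lam_g <- select_lambda(G, basis, config$lambda_grid)
  lam_i <- select_lambda(I, basis, config$lambda_grid)
  curves <- list(
    glucose = fit_curves(G, basis, as.numeric(lam_g), analyte = "glucose",
                         ids = cohort$id),
    insulin = fit_curves(I, basis, as.numeric(lam_i), analyte = "insulin",
                         ids = cohort$id))
  say("smoothing: lambda_glucose = %.4g, lambda_insulin = %.4g",
      as.numeric(lam_g), as.numeric(lam_i))

  set_stage("fpca")
  fpca <- lapply(curves, fit_fpca, n_components = config$n_fpc)
  raw <- lapply(names(curves), function(a) fpc_scores(fpca[[a]], curves[[a]]))
  names(raw) <- names(curves)
  std <- lapply(raw, standardize_scores)
  scores <- data.frame(id = cohort$id,
                       stats::setNames(as.data.frame(raw$glucose), paste0("g_", colnames(raw$glucose))),
                       stats::setNames(as.data.frame(std$glucose), paste0("g_", colnames(std$glucose))),
                       stats::setNames(as.data.frame(raw$insulin), paste0("i_", colnames(raw$insulin))),
                       stats::setNames(as.data.frame(std$insulin), paste0("i_", colnames(std$insulin))),
                       stringsAsFactors = FALSE)
  say("fpca: first %d components explain %.2f%% (glucose) / %.2f%% (insulin)",
      config$n_fpc, 100 * sum(fpca$glucose$variance_explained),
      100 * sum(fpca$insulin$variance_explained))

  set_stage("shape classification")
  shapes <- classify_shapes(G, delta = config$shape_delta)
  say("shapes: %s", paste(sprintf("%s %d", levels(shapes), table(shapes)),
                          collapse = ", "))

  set_stage("cross-sectional statistics")
  dummies <- shape_dummies(shapes)
  feat <- data.frame(matrix(NA_real_, nrow(cohort), 3,
                            dimnames = list(NULL, paste0("shape_", names(dummies)))))
  feat[shapes != "inconclusive", ] <- dummies
  std_cols <- grep("_std$", names(scores), value = TRUE)
  features <- cbind(feat, scores[std_cols])
  targets <- cohort[c(gcols("glucose"), gcols("insulin"), "hba1c",
                      "total_chol", "ldl", "hdl", "triglycerides",
                      "sbp", "dbp", "bmi_percentile", "waist_cm")]
  assoc <- spearman_matrix(features, targets, alpha = config$bonferroni_alpha,
                           n_comparisons = config$n_comparisons)
  vars <- cohort[c("age", "sex", "race", "ethnicity", "hba1c", "triglycerides",
                   "bmi_percentile", "waist_cm")]
  vars$sex <- factor(vars$sex); vars$race <- factor(vars$race)
  vars$ethnicity <- factor(vars$ethnicity)
  grp <- group_difference_tests(vars, shapes)
  adj <- adjusted_fpc_models(
    scores[std_cols],
    cohort[c("hba1c", "triglycerides", "bmi_percentile")],
    data.frame(age = cohort$age, sex = factor(cohort$sex),
               race = factor(cohort$race), ethnicity = factor(cohort$ethnicity)),
    drop_single_level = TRUE)
  say("associations: %d pairs, %d significant at %.3g/%d",
      nrow(assoc), sum(assoc$significant), config$bonferroni_alpha,
      config$n_comparisons)

  set_stage("longitudinal prediction")
  prediction <- NULL
  paired <- NULL
  long <- which(cohort$has_followup %in% TRUE &
                  is.finite(cohort$fu_glucose_0))
  short <- long[cohort$followup_interval[long] < 6]
  if (length(short)) {
    say("longitudinal: excluded %d participant(s) with follow-up interval < 6 months",
        length(short))
    long <- setdiff(long, short)
  }
  if (length(long) >= 10L) {
    lab_fu <- label_dysglycemia(cohort$fu_glucose_0[long],
                                cohort$fu_glucose_120[long],
                                config$fpg_gt, config$pg2h_gt)
    if (any(lab_fu, na.rm = TRUE) && !all(lab_fu, na.rm = TRUE)) {
      lab_base <- label_dysglycemia(cohort$glucose_0[long],
                                    cohort$glucose_120[long],
                                    config$fpg_gt, config$pg2h_gt)
      paired <- paired_change_tests(
        data.frame(fpg = cohort$glucose_0[long],
                   pg2h = cohort$glucose_120[long],
                   hba1c = cohort$hba1c[long],
                   bmi_percentile = cohort$bmi_percentile[long]),
        data.frame(fpg = cohort$fu_glucose_0[long],
                   pg2h = cohort$fu_glucose_120[long],
                   hba1c = cohort$fu_hba1c[long],
                   bmi_percentile = cohort$fu_bmi_percentile[long]),
        dysglycemia = data.frame(baseline = lab_base, followup = lab_fu))
      pdata <- data.frame(
        fpg = cohort$glucose_0[long], pg2h = cohort$glucose_120[long],
        hba1c = cohort$hba1c[long], shape = shapes[long],
        scores[long, std_cols], outcome = lab_fu)
      prediction <- fit_predictor_models(pdata)
      say("prediction: %d participants, %d events; best AUC %.3f (%s)",
          length(long), sum(lab_fu, na.rm = TRUE),
          max(prediction$summary$auc),
          prediction$summary$predictor[which.max(prediction$summary$auc)])
    } else {
      say("prediction skipped: follow-up outcome has a single class")
    }
  } else {
    say("prediction skipped: fewer than 10 longitudinal participants")
  }

  structure(
    list(cohort = cohort, lambda = c(glucose = as.numeric(lam_g),
                                     insulin = as.numeric(lam_i)),
         curves = curves, fpca = fpca, scores = scores, shapes = shapes,
         associations = assoc, group_tests = grp, adjusted_models = adj,
         paired_tests = paired, prediction = prediction, config = config),
    class = "ogtt_results")
}

#' @export
print.ogtt_results <- function(x, ...) {
  cat(sprintf("OGTT pipeline results: %d participants\n", nrow(x$cohort)))
  cat(sprintf("  lambda: glucose %.4g, insulin %.4g\n",
              x$lambda["glucose"], x$lambda["insulin"]))
  for (a in names(x$fpca)) {
    cat(sprintf("  %s FPCs explain %s%% (total %.2f%%)\n", a,
                paste(format(100 * x$fpca[[a]]$variance_explained, digits = 3),
                      collapse = " / "),
                100 * sum(x$fpca[[a]]$variance_explained)))
  }
  cat("  shapes:", paste(sprintf("%s %d", levels(x$shapes), table(x$shapes)),
                         collapse = ", "), "\n")
  if (!is.null(x$prediction)) print(x$prediction)
  invisible(x)
}

#' Export the main result tables of a pipeline run
#'
#' Convenience wrapper around [write_results()] writing the score table,
#' shape labels, association table, group tests, adjusted models, paired
#' tests and AUC summary.
#'
#' @param results an \code{ogtt_results}.
#' @param out_dir output directory.
#' @return invisibly, the manifest data.frame.
#' @export
export_results <- function(results, out_dir) {
  stopifnot(inherits(results, "ogtt_results"))
  tables <- list(
    scores = results$scores,
    shapes = data.frame(id = results$cohort$id,
                        shape = as.character(results$shapes),
                        attr(results$shapes, "evidence")),
    associations = results$associations,
    group_tests = results$group_tests,
    adjusted_models = results$adjusted_models)
  if (!is.null(results$paired_tests)) tables$paired_tests <- results$paired_tests
  if (!is.null(results$prediction)) tables$auc_summary <- results$prediction$summary
  write_results(tables, out_dir, config = results$config)
}
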