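# End-to-end pipeline ------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the generator block with the thresholds and options of the
#' downstream stages plus the master seed.  Unknown keys are rejected.
#'
#' @param generator a [cohort_config()].
#' @param qc list: `enabled`, `hr_jump_pct`, `hr_window_s`,
#'   `cuff_rise_mmhg`, `avg_beats`.
#' @param classifier list: `k`, `folds`, `repeats`.
#' @param uncertainty list: `form`, `degree`, `sbp_grid` (min, max, step).
#' @param seed master seed.
#' @param beats beat-synthesis mode passed to [generate_cohort()].
#' @param cuff_curves simulate cuff curves?
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(),
                            qc = list(), classifier = list(),
                            uncertainty = list(), seed = 1L,
                            beats = "rest", cuff_curves = FALSE) {
  qc_def <- list(enabled = TRUE, hr_jump_pct = 30, hr_window_s = 3,
                 cuff_rise_mmhg = 8, avg_beats = 4)
  cl_def <- list(k = 13, folds = 5, repeats = 20)
  un_def <- list(form = "exponential", degree = 2,
                 sbp_grid = c(100, 180, 1))
  merge_block <- function(def, user, nm) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stop("unknown ", nm, " option(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    utils::modifyList(def, user)
  }
  structure(list(
    generator = generator,
    qc = merge_block(qc_def, qc, "qc"),
    classifier = merge_block(cl_def, classifier, "classifier"),
    uncertainty = merge_block(un_def, uncertainty, "uncertainty"),
    seed = as.integer(seed), beats = beats,
    cuff_curves = isTRUE(cuff_curves)
  ), class = "pipeline_config")
}

# stable hash of the configuration: canonical JSON -> md5
.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else x
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(.strip_classes(config),
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes generate -> qc -> stress statistics -> load classifier ->
#' BP-uncertainty propagation, writes every stage's outputs to `out_dir`
#' and returns a manifest (config hash, seed, per-stage record counts and
#' headline results).  Two runs with the same configuration and seed
#' produce identical outputs and manifests.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if needed.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("peprun")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "generate"
  manifest <- list(seed = config$seed, config_hash = .config_hash(config),
                   package_version = as.character(utils::packageVersion("pepstress")),
                   stages = list())
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- run_stage("generate", generate_cohort(
    config$generator, seed = config$seed, beats = config$beats,
    cuff_curves = config$cuff_curves))
  manifest$stages$generate <- list(
    n_subjects = nrow(cohort$subjects),
    n_measurements = nrow(cohort$measurements),
    n_beats = if (is.null(cohort$beats)) 0L else nrow(cohort$beats))

  if (isTRUE(config$qc$enabled)) {
    qcres <- run_stage("qc", qc_cohort(
      cohort, hr_jump_pct = config$qc$hr_jump_pct,
      hr_window_s = config$qc$hr_window_s,
      cuff_rise_mmhg = config$qc$cuff_rise_mmhg,
      avg_window = config$qc$avg_beats))
    cohort <- qcres$cohort
    rep <- qcres$report
    manifest$stages$qc <- list(n_input = rep$n_input, n_valid = rep$n_valid,
                               n_excluded_hr = rep$n_excluded_hr_artifact,
                               n_excluded_cuff = rep$n_excluded_cuff)
    jsonlite::write_json(rep[c("n_input", "n_excluded_hr_artifact",
                               "n_excluded_cuff", "n_valid", "thresholds")],
                         file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    manifest$stages$qc <- list(skipped = TRUE,
                               n_valid = nrow(cohort$measurements))
  }

  stats_out <- run_stage("stats", {
    ps <- phase_summaries(cohort$measurements, seed = config$seed)
    sr <- stratified_hr_regression(cohort$measurements)
    cs <- correlate_surrogates(cohort$measurements)
    sl <- per_subject_slopes(cohort$measurements)
    an <- covariates_and_anthropometrics(cohort$subjects, cohort$measurements)
    list(ps = ps, sr = sr, cs = cs, sl = sl, an = an)
  })
  utils::write.csv(stats_out$ps, file.path(out_dir, "phase_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_out$sl$slopes, file.path(out_dir, "slopes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(stratified = stats_out$sr, surrogates = stats_out$cs$fits,
         hr_poly_r_squared = stats_out$cs$hr_poly_r_squared,
         anthropometrics = stats_out$an),
    file.path(out_dir, "regressions.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  manifest$stages$stats <- list(
    n_phases = nrow(stats_out$ps),
    r2_rest = stats_out$sr$r_squared[stats_out$sr$stratum == "rest"],
    r2_mental = stats_out$sr$r_squared[stats_out$sr$stratum == "mental"],
    r2_physical = stats_out$sr$r_squared[stats_out$sr$stratum == "physical"])

  knn <- run_stage("classify", {
    feats <- build_features(cohort$measurements)
    evaluate_knn(feats, k = config$classifier$k,
                 folds = config$classifier$folds,
                 repeats = config$classifier$repeats, seed = config$seed)
  })
  jsonlite::write_json(
    list(k = knn$k, folds = knn$folds, repeats = knn$repeats,
         ppv_macro = knn$ppv_macro, sensitivity_macro = knn$sensitivity_macro,
         ppv = as.list(knn$ppv), sensitivity = as.list(knn$sensitivity),
         confusion = knn$confusion),
    file.path(out_dir, "classifier_report.json"), auto_unbox = TRUE,
    digits = NA, matrix = "rowmajor")
  manifest$stages$classify <- list(ppv_macro = knn$ppv_macro,
                                   sensitivity_macro = knn$sensitivity_macro)

  unc <- run_stage("uncertainty", {
    model <- pwv_bp_model(form = config$uncertainty$form)
    fit <- fit_pep_sbp(cohort$measurements, degree = config$uncertainty$degree)
    g <- config$uncertainty$sbp_grid
    band <- suppressWarnings(
      build_uncertainty_band(model, fit, sbp_grid = seq(g[1], g[2], by = g[3])))
    cmp <- compare_neglect_vs_estimate(model, fit, cohort$measurements)
    list(band = band, cmp = cmp)
  })
  utils::write.csv(as.data.frame(unc$band), file.path(out_dir, "band.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unc$cmp$summary,
                       file.path(out_dir, "strategy_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest$stages$uncertainty <- list(
    n_grid = nrow(unc$band),
    median_err_estimate = unc$cmp$summary$median_abs_err[
      unc$cmp$summary$strategy == "estimate"],
    median_err_neglect = unc$cmp$summary$median_abs_err[
      unc$cmp$summary$strategy == "neglect"])

  write_cohort_csv(cohort, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
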