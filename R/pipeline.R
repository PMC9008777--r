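## End-to-end orchestration of the two study designs. Everything written to
## the output directory is recomputable from the inputs and configuration
## alone; re-running with the same inputs reproduces the artifacts byte for
## byte.

.writeRunSummary <- function(path, entries) {
  writeLines(c("# EndoCt run summary",
               vapply(names(entries), function(nm)
                 paste0(nm, "\t", paste(entries[[nm]], collapse = ",")),
                 character(1))),
             path)
  invisible(path)
}

.writeTable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) .fmtNum(v))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the discovery-style analysis end to end
#'
#' QC (discovery preset: reading filters, sample exclusion, inclusive 50\%
#' missingness filter, Ct-40 imputation) -> normalization comparison ->
#' smallest-SD-after-global-mean candidate list -> four-algorithm stability
#' ranking with comprehensive ordering -> age/sex sensitivity analysis (when
#' covariates are available). Any stage error aborts with the stage name.
#'
#' @param input reading records (`data.frame`) or a [CtExperiment-class].
#' @param qc a [qcConfig()] list (discovery preset by default).
#' @param controls optional control ids for the endogenous-control
#'   normalization arm of the comparison.
#' @param candidates stability candidates; default: the miRNAs passing the
#'   `sd_cutoff` in the SD-after-global-mean list.
#' @param sd_cutoff strict SD cutoff (delta-Ct cycles) for the candidate
#'   list.
#' @param top_n top-set size for the sensitivity concordance check.
#' @param sampleData covariates when `input` is records.
#' @param outdir optional directory; when given, all tables, the QC report
#'   and a key/value run summary are written there.
#' @return a list with `experiment`, `qc_report`, `comparison`,
#'   `candidate_list`, `stability`, and `sensitivity` (`NULL` without
#'   covariates).
#' @export
runDiscovery <- function(input, qc = qcConfig("discovery"), controls = NULL,
                         candidates = NULL, sd_cutoff = 2, top_n = 4L,
                         sampleData = NULL, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  qcres <- stage("qc", runQC(input, qc, sampleData = sampleData))
  x <- qcres$experiment
  methods <- c("raw", "global_mean", "mean_unimputed", "mcr", "quantile")
  if (!is.null(controls)) methods <- c(methods, "endogenous_control")
  comparison <- stage("normalization",
                      compareNormalizations(x, methods, controls = controls))
  sel <- stage("candidate_selection", selectByGlobalMeanSD(x, sd_cutoff))
  if (is.null(candidates)) candidates <- sel$mirna_id
  if (!length(candidates))
    stop("stage 'candidate_selection' failed: no candidate passed the SD ",
         "cutoff (", sd_cutoff, ")", call. = FALSE)
  stability <- stage("stability", rankCandidates(x, candidates))
  sens <- NULL
  if (all(c("age", "sex") %in% names(colData(x))))
    sens <- stage("sensitivity",
                  sensitivityReport(x, candidates = stability@candidates,
                                    top_n = top_n))
  out <- list(experiment = x, qc_report = qcres$report,
              comparison = comparison, candidate_list = sel,
              stability = stability, sensitivity = sens)
  if (!is.null(outdir)) .writeDiscoveryArtifacts(out, outdir, qc, sd_cutoff)
  out
}

.writeDiscoveryArtifacts <- function(res, outdir, qc, sd_cutoff) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeQCReport(res$qc_report, file.path(outdir, "qc_report.txt"))
  .writeTable(res$comparison, file.path(outdir, "normalization_comparison.csv"))
  .writeTable(res$candidate_list, file.path(outdir, "candidate_list.csv"))
  .writeTable(rankingTable(res$stability), file.path(outdir, "stability_ranking.csv"))
  .writeTable(res$stability@values, file.path(outdir, "stability_values.csv"))
  writeCtMatrix(res$experiment, file.path(outdir, "ct_matrix_postqc.csv"))
  entries <- list(
    preset = qc$preset,
    amp_score_min = qc$amp_score_min, cq_conf_min = qc$cq_conf_min,
    missingness_max = qc$missingness_max,
    missingness_inclusive = qc$missingness_inclusive,
    sample_min_detected = qc$sample_min_detected, impute_ct = qc$impute_ct,
    sd_cutoff = sd_cutoff,
    n_samples = ncol(res$experiment), n_mirnas = nrow(res$experiment),
    top_candidates = utils::head(
      res$stability@candidates[order(res$stability@comprehensiveRank)], 4))
  if (!is.null(res$sensitivity)) {
    entries$sensitivity_sd_top_concordant <-
      res$sensitivity$sd_arm$top_concordant
    entries$sensitivity_rank_correlation <-
      res$sensitivity$stability_arm$rank_correlation
  }
  .writeRunSummary(file.path(outdir, "run_summary.txt"), entries)
}

#' Run the validation-style analysis end to end
#'
#' Triplicate-aware QC (validation preset: amplification-score filter only,
#' replicate averaging, exclusive 50\% missingness filter, Ct-40 imputation)
#' -> four-algorithm stability ranking -> combination-control evaluation.
#'
#' @param records replicate-level reading records.
#' @param qc a [qcConfig()] list (validation preset by default).
#' @param controls ids of the controls whose combination is evaluated.
#' @param candidates stability candidates (default: the full post-QC panel).
#' @param sampleData optional covariates.
#' @param outdir optional artifact directory.
#' @return a list with `experiment`, `qc_report`, `stability`, and
#'   `combination` (`NULL` when fewer than two controls survive QC).
#' @export
runValidation <- function(records, qc = qcConfig("validation"),
                          controls = NULL, candidates = NULL,
                          sampleData = NULL, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  qcres <- stage("qc", runQC(records, qc, sampleData = sampleData))
  x <- qcres$experiment
  stability <- stage("stability", rankCandidates(x, candidates))
  combo <- NULL
  if (!is.null(controls)) {
    surviving <- intersect(controls, rownames(x))
    lost <- setdiff(controls, surviving)
    if (length(lost))
      message("control(s) not sufficiently detected, excluded: ",
              paste(lost, collapse = ", "))
    if (length(surviving) >= 2L)
      combo <- stage("combination",
                     evaluateCombination(x, surviving, candidates))
  }
  out <- list(experiment = x, qc_report = qcres$report,
              stability = stability, combination = combo)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeQCReport(qcres$report, file.path(outdir, "qc_report.txt"))
    .writeTable(rankingTable(stability),
                file.path(outdir, "stability_ranking.csv"))
    if (!is.null(combo)) {
      .writeTable(rankingTable(combo$result),
                  file.path(outdir, "stability_ranking_with_combination.csv"))
      .writeTable(combo$comparison, file.path(outdir, "combination_report.csv"))
    }
    .writeRunSummary(file.path(outdir, "run_summary.txt"), list(
      preset = qc$preset, amp_score_min = qc$amp_score_min,
      missingness_max = qc$missingness_max,
      missingness_inclusive = qc$missingness_inclusive,
      impute_ct = qc$impute_ct,
      n_samples = ncol(x), n_mirnas = nrow(x),
      top_candidates = utils::head(
        stability@candidates[order(stability@comprehensiveRank)], 4)))
  }
  out
}
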