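## Quality control: per-reading quality filters, triplicate aggregation,
## sample- and miRNA-level missingness filters, and non-detect imputation.
## The pipeline applies them in that order (readings -> samples -> miRNAs ->
## imputation); runQC() enforces the ordering.

#' QC configuration presets
#'
#' Two named presets encode the two profiling designs so their differing
#' rules are explicit and cannot be mixed silently:
#' \describe{
#'   \item{`discovery`}{array profiling: readings with amplification score
#'     < 1.1 or Cq confidence < 0.7 become non-detects; miRNAs missing in
#'     \emph{at least} 50\% of samples are dropped (inclusive threshold).}
#'   \item{`validation`}{single-tube triplicate qPCR: only the amplification
#'     score filter (< 1.1) applies, and miRNAs are dropped only when
#'     missing in \emph{more than} 50\% of samples (exclusive threshold).}
#' }
#' Boundary readings (score exactly 1.1, confidence exactly 0.7) are
#' retained: the filters are strict inequalities.
#'
#' @param preset `"discovery"` or `"validation"`.
#' @param amp_score_min minimum amplification score (strict).
#' @param cq_conf_min minimum Cq confidence (strict); `NA` disables the
#'   filter (validation preset).
#' @param missingness_max miRNA missingness threshold, fraction in (0, 1].
#' @param missingness_inclusive drop at `>=` threshold (`TRUE`, discovery)
#'   or `>` threshold (`FALSE`, validation).
#' @param sample_min_detected minimum detected-miRNA count per sample; a
#'   value < 1 is read as a fraction of the panel. Samples below it are
#'   excluded as low-expression samples.
#' @param impute_ct Ct assigned to surviving non-detects (cycles).
#' @return a named list of thresholds.
#' @export
qcConfig <- function(preset = c("discovery", "validation"),
                     amp_score_min = 1.1,
                     cq_conf_min = if (preset == "discovery") 0.7 else NA_real_,
                     missingness_max = 0.5,
                     missingness_inclusive = (preset == "discovery"),
                     sample_min_detected = 0.25,
                     impute_ct = 40) {
  preset <- match.arg(preset)
  cfg <- list(preset = preset, amp_score_min = amp_score_min,
              cq_conf_min = cq_conf_min, missingness_max = missingness_max,
              missingness_inclusive = missingness_inclusive,
              sample_min_detected = sample_min_detected,
              impute_ct = impute_ct)
  stopifnot(cfg$amp_score_min > 0,
            is.na(cfg$cq_conf_min) || cfg$cq_conf_min > 0,
            cfg$missingness_max > 0, cfg$missingness_max <= 1,
            cfg$sample_min_detected > 0, cfg$impute_ct > 0)
  cfg
}

#' Filter readings on amplification quality
#'
#' A reading whose amplification score falls below `amp_score_min`, or whose
#' Cq confidence falls below `cq_conf_min` (when that filter is enabled), is
#' converted to a non-detect; its Ct is discarded but the row is kept so
#' replicate aggregation still sees it.
#'
#' @param records reading records ([readCtLong()]).
#' @param cfg a [qcConfig()] list.
#' @return `list(records = <filtered records>, report = <QCReport>)`.
#' @export
filterReadings <- function(records, cfg = qcConfig("discovery")) {
  if (all(is.na(records$amp_score)))
    stop("amp_score column is required for reading-level QC", call. = FALSE)
  use_cq <- !is.na(cfg$cq_conf_min)
  if (use_cq && all(is.na(records$cq_conf)))
    stop("config requires cq_conf but the column is absent", call. = FALSE)
  was_detected <- !is.na(records$ct)
  fail_amp <- was_detected & !is.na(records$amp_score) &
    records$amp_score < cfg$amp_score_min
  fail_cq <- if (use_cq) {
    was_detected & !fail_amp & !is.na(records$cq_conf) &
      records$cq_conf < cfg$cq_conf_min
  } else rep(FALSE, nrow(records))
  records$ct[fail_amp | fail_cq] <- NA_real_
  rep <- QCReport(
    readingsRemoved = c(amp_score = sum(fail_amp), cq_conf = sum(fail_cq)),
    thresholds = list(amp_score_min = cfg$amp_score_min,
                      cq_conf_min = cfg$cq_conf_min))
  list(records = records, report = rep)
}

#' Average technical replicates
#'
#' Collapses to one record per sample x miRNA: the Ct is the arithmetic mean
#' of the detected replicate Cts. Partially detected replicate sets keep the
#' mean of the detected ones; a fully non-detect set stays a non-detect.
#' Quality scores are averaged over detected replicates for bookkeeping.
#'
#' @param records reading records.
#' @return replicate-aggregated records (replicate column set to 1).
#' @export
aggregateReplicates <- function(records) {
  key <- paste(records$sample_id, records$mirna_id, sep = "\r")
  meanDet <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  first <- !duplicated(key)
  out <- records[first, c("sample_id", "mirna_id"), drop = FALSE]
  grp <- factor(match(key, key[first]), levels = seq_len(sum(first)))
  agg <- function(v) vapply(split(v, grp), meanDet, numeric(1),
                            USE.NAMES = FALSE)
  out$replicate <- 1L
  out$ct <- agg(records$ct)
  out$amp_score <- agg(records$amp_score)
  out$cq_conf <- agg(records$cq_conf)
  rownames(out) <- NULL
  out
}

#' Exclude samples with overall low miRNA detection
#'
#' Samples whose detected-miRNA count is below the configured minimum are
#' removed; samples at the boundary are kept. An absolute count is used as
#' is; a value < 1 is read as a fraction of the \emph{analyzable} panel —
#' the miRNAs that would pass the configured missingness filter — not of
#' the full assay panel, most of which is typically never detected in
#' plasma.
#'
#' @param x a pre-imputation [CtExperiment-class].
#' @param cfg a [qcConfig()] list.
#' @return `list(experiment = <CtExperiment>, report = <QCReport>)`.
#' @export
dropLowDetectionSamples <- function(x, cfg = qcConfig("discovery")) {
  n_det <- colSums(detected(x))
  thr <- cfg$sample_min_detected
  if (thr < 1) {
    miss <- rowMeans(!detected(x))
    analyzable <- if (cfg$missingness_inclusive) sum(miss < cfg$missingness_max)
                  else sum(miss <= cfg$missingness_max)
    thr <- thr * analyzable
  }
  drop <- n_det < thr
  if (all(drop))
    stop("all samples fall below the detection threshold (", thr, ")",
         call. = FALSE)
  rep <- QCReport(
    samplesRemoved = data.frame(sample_id = colnames(x)[drop],
                                n_detected = as.integer(n_det[drop])),
    thresholds = list(sample_min_detected = cfg$sample_min_detected))
  list(experiment = x[, !drop], report = rep)
}

#' Exclude miRNAs with high missingness
#'
#' Drops a miRNA when its non-detect fraction reaches the threshold:
#' at `>=` in inclusive (discovery) mode, only at `>` in exclusive
#' (validation) mode — so a miRNA missing in exactly half the samples is
#' dropped in discovery but kept in validation.
#'
#' @inheritParams dropLowDetectionSamples
#' @return `list(experiment = <CtExperiment>, report = <QCReport>)`.
#' @export
filterHighMissingnessMirnas <- function(x, cfg = qcConfig("discovery")) {
  miss <- rowMeans(!detected(x))
  drop <- if (cfg$missingness_inclusive) miss >= cfg$missingness_max
          else miss > cfg$missingness_max
  rep <- QCReport(
    mirnasRemoved = data.frame(mirna_id = rownames(x)[drop],
                               missing_frac = miss[drop],
                               row.names = NULL),
    thresholds = list(missingness_max = cfg$missingness_max,
                      missingness_inclusive = cfg$missingness_inclusive))
  list(experiment = x[!drop, ], report = rep)
}

#' Impute surviving non-detects at a fixed Ct
#'
#' Replaces every remaining non-detect with `impute_ct` (40 cycles by
#' default, the panel's maximal cycle number) and records the affected cells
#' in an `imputed` assay; the original `detected` mask is untouched, so the
#' imputation is reversible.
#'
#' @inheritParams dropLowDetectionSamples
#' @return `list(experiment = <imputed CtExperiment>, report = <QCReport>)`.
#' @export
imputeNondetects <- function(x, cfg = qcConfig("discovery")) {
  m <- ctMatrix(x)
  max_det <- suppressWarnings(max(m, na.rm = TRUE))
  if (is.finite(max_det) && cfg$impute_ct < max_det)
    warning("impute_ct (", cfg$impute_ct, ") is below the largest detected ",
            "Ct (", round(max_det, 2), ")", call. = FALSE)
  nd <- is.na(m)
  m[nd] <- cfg$impute_ct
  prior <- imputed(x)
  assays(x)$ct <- m
  assays(x)$imputed <- if (is.null(prior)) nd else (nd | prior)
  validObject(x)
  rep <- QCReport(cellsImputed = sum(nd),
                  thresholds = list(impute_ct = cfg$impute_ct))
  list(experiment = x, report = rep)
}

#' Run the full QC pipeline
#'
#' Applies the filters in the fixed order reading filters -> replicate
#' aggregation -> low-detection sample exclusion -> miRNA missingness filter
#' -> non-detect imputation, and returns the imputed experiment together
#' with a reconciled [QCReport-class]. Re-running on its own output is a
#' no-op. When given an already-pivoted [CtExperiment-class] the
#' reading-level steps are skipped.
#'
#' @param x reading records (`data.frame`) or a [CtExperiment-class].
#' @param cfg a [qcConfig()] list.
#' @param sampleData optional covariates (records input only).
#' @return `list(experiment = <CtExperiment>, report = <QCReport>)`.
#' @export
runQC <- function(x, cfg = qcConfig("discovery"), sampleData = NULL) {
  reports <- list()
  if (is.data.frame(x)) {
    fr <- filterReadings(x, cfg)
    reports <- c(reports, fr$report)
    x <- ctFromRecords(aggregateReplicates(fr$records), sampleData)
  }
  ds <- dropLowDetectionSamples(x, cfg)
  dm <- filterHighMissingnessMirnas(ds$experiment, cfg)
  im <- imputeNondetects(dm$experiment, cfg)
  report <- do.call(.combineReports,
                    c(reports, list(ds$report, dm$report, im$report)))
  list(experiment = im$experiment, report = report)
}
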