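#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- assays<- colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CtExperiment: a Ct matrix with an explicit non-detect mask
#'
#' Container for RT-qPCR cycle-threshold (Ct) data, following the
#' Bioconductor convention of features (miRNAs) as rows and samples as
#' columns. Three assays are used:
#' \describe{
#'   \item{`ct`}{numeric Ct values in cycles; `NA` marks a non-detect until
#'     imputation has run.}
#'   \item{`detected`}{logical mask; `FALSE` where the reaction never crossed
#'     threshold. This mask is never altered by imputation, so the original
#'     missingness structure stays available downstream.}
#'   \item{`imputed`}{logical mask, present only after
#'     [imputeNondetects()]; `TRUE` where a non-detect was replaced by the
#'     imputation Ct.}
#' }
#' Sample covariates (age in years, sex) live in `colData`.
#'
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
  an <- assayNames(object)
  if (!all(c("ct", "detected") %in% an))
    return("assays 'ct' and 'detected' are required")
  ct <- assay(object, "ct")
  det <- assay(object, "detected")
  if (!is.logical(det) || !identical(dim(ct), dim(det)))
    return("'detected' must be a logical mask with the shape of 'ct'")
  if (anyDuplicated(rownames(object)))
    return("duplicate miRNA ids")
  if (anyDuplicated(colnames(object)))
    return("duplicate sample ids")
  if ("imputed" %in% an) {
    imp <- assay(object, "imputed")
    if (!is.logical(imp) || !identical(dim(imp), dim(ct)))
      return("'imputed' must be a logical mask with the shape of 'ct'")
    if (any(imp & det))
      return("a cell cannot be both detected and imputed")
    if (!identical(is.na(ct), (!det & !imp)))
      return("NA cells must be exactly the non-detect, non-imputed cells")
  } else {
    if (!identical(is.na(ct), !det))
      return("pre-imputation, NA cells must match the non-detect mask")
  }
  TRUE
})

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of Ct values, miRNAs in rows, samples in columns,
#'   with `NA` at non-detect cells. Row and column names are required and are
#'   reordered lexicographically (canonical ordering).
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample
#'   covariates, with rownames (or a `sample_id` column) matching the columns
#'   of `ct`.
#' @return a [CtExperiment-class] object.
#' @examples
#' m <- matrix(c(20, 25, NA, 30), 2, 2,
#'             dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' CtExperiment(m)
#' @export
CtExperiment <- function(ct, sampleData = NULL) {
  if ((nrow(ct) > 0L && is.null(rownames(ct))) ||
      (ncol(ct) > 0L && is.null(colnames(ct))))
    stop("'ct' needs miRNA rownames and sample colnames", call. = FALSE)
  if (any(!is.na(ct) & ct <= 0))
    stop("Ct values must be positive (cycles)", call. = FALSE)
  ct <- ct[.canonicalSort(rownames(ct) %||% character(0)),
           .canonicalSort(colnames(ct) %||% character(0)), drop = FALSE]
  cd <- DataFrame(row.names = colnames(ct))
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% names(sampleData)) {
      rownames(sampleData) <- sampleData$sample_id
      sampleData$sample_id <- NULL
    }
    missing <- setdiff(colnames(ct), rownames(sampleData))
    if (length(missing))
      stop("sampleData lacks samples: ", paste(missing, collapse = ", "),
           call. = FALSE)
    cd <- DataFrame(sampleData[colnames(ct), , drop = FALSE])
  }
  new("CtExperiment",
      SummarizedExperiment(
        assays = list(ct = ct, detected = !is.na(ct)),
        colData = cd))
}

#' NormalizedCt: a normalization-tagged delta-Ct matrix
#'
#' Result of one normalization strategy, on the delta-Ct scale (cycles;
#' values may be negative). The method tag and its parameters (control set,
#' restricted set, ...) travel with the values so every normalized matrix is
#' self-describing.
#'
#' @slot method one of `"raw"`, `"global_mean"`, `"mean_unimputed"`,
#'   `"mcr"`, `"quantile"`, `"endogenous_control"`.
#' @slot params named list of method parameters.
#' @export
setClass("NormalizedCt",
         contains = "SummarizedExperiment",
         representation(method = "character", params = "list"))

setValidity("NormalizedCt", function(object) {
  ok <- c("raw", "global_mean", "mean_unimputed", "mcr", "quantile",
          "endogenous_control")
  if (length(object@method) != 1L || !object@method %in% ok)
    return(paste("method must be one of:", paste(ok, collapse = ", ")))
  if (!"delta_ct" %in% assayNames(object))
    return("assay 'delta_ct' is required")
  TRUE
})

.newNormalizedCt <- function(values, method, params, template) {
  new("NormalizedCt",
      SummarizedExperiment(assays = list(delta_ct = values),
                           colData = colData(template)),
      method = method, params = params)
}

#' QCReport: auditable record of quality-control decisions
#'
#' Every QC operation reports exactly what it removed or altered and the
#' thresholds it applied, so that the surviving matrix can be reconciled
#' against the input cell by cell.
#'
#' @slot readingsRemoved named integer; readings converted to non-detect,
#'   counted by reason (`amp_score`, `cq_conf`).
#' @slot samplesRemoved data.frame with `sample_id` and `n_detected`.
#' @slot mirnasRemoved data.frame with `mirna_id` and `missing_frac`.
#' @slot cellsImputed integer count of imputed cells.
#' @slot thresholds named list of the thresholds in force.
#' @export
setClass("QCReport",
         representation(readingsRemoved = "integer",
                        samplesRemoved = "data.frame",
                        mirnasRemoved = "data.frame",
                        cellsImputed = "integer",
                        thresholds = "list"))

QCReport <- function(readingsRemoved = integer(),
                     samplesRemoved = data.frame(sample_id = character(),
                                                 n_detected = integer()),
                     mirnasRemoved = data.frame(mirna_id = character(),
                                                missing_frac = numeric()),
                     cellsImputed = 0L,
                     thresholds = list()) {
  new("QCReport", readingsRemoved = readingsRemoved,
      samplesRemoved = samplesRemoved, mirnasRemoved = mirnasRemoved,
      cellsImputed = as.integer(cellsImputed), thresholds = thresholds)
}

## Merge the partial reports emitted by successive QC stages.
.combineReports <- function(...) {
  reps <- list(...)
  rr <- integer()
  for (r in reps) {
    for (nm in names(r@readingsRemoved)) {
      rr[nm] <- (if (nm %in% names(rr)) rr[[nm]] else 0L) +
        r@readingsRemoved[[nm]]
    }
  }
  QCReport(readingsRemoved = rr,
           samplesRemoved = do.call(rbind, lapply(reps, slot, "samplesRemoved")),
           mirnasRemoved = do.call(rbind, lapply(reps, slot, "mirnasRemoved")),
           cellsImputed = sum(vapply(reps, slot, integer(1), "cellsImputed")),
           thresholds = do.call(c, lapply(reps, slot, "thresholds")))
}

#' StabilityResult: per-candidate stability values and rankings
#'
#' Output of the four reference-stability algorithms plus the comprehensive
#' geometric-mean-of-ranks ordering.
#'
#' @slot candidates character; candidate miRNA ids (canonical order).
#' @slot values data.frame, one row per candidate: `genorm_m`,
#'   `deltact_stability`, `bestkeeper_sd`, `bestkeeper_r`,
#'   `normfinder_stability`.
#' @slot ranks integer matrix, candidates x methods (`genorm`, `deltact`,
#'   `bestkeeper`, `normfinder`), dense ranks with ties sharing the smaller
#'   rank.
#' @slot comprehensive named numeric; geometric mean of the four ranks.
#' @slot comprehensiveRank named integer; final ordering (ties in the
#'   geometric mean broken by mean rank, then id).
#' @slot excluded character; candidates dropped (e.g. residual non-detects).
#' @export
setClass("StabilityResult",
         representation(candidates = "character",
                        values = "data.frame",
                        ranks = "matrix",
                        comprehensive = "numeric",
                        comprehensiveRank = "integer",
                        excluded = "character"))

setValidity("StabilityResult", function(object) {
  k <- length(object@candidates)
  if (nrow(object@values) != k || nrow(object@ranks) != k)
    return("values/ranks do not cover the candidate set")
  num <- c("genorm_m", "deltact_stability", "bestkeeper_sd",
           "normfinder_stability")
  v <- unlist(object@values[num])
  if (any(v < 0, na.rm = TRUE))
    return("stability values must be >= 0")
  g <- exp(rowMeans(log(object@ranks)))
  if (max(abs(g - object@comprehensive)) > 1e-8)
    return("comprehensive is not the geometric mean of the four ranks")
  TRUE
})
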