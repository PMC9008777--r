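#' @include AllClasses.R
NULL

#' Re-exported generics
#'
#' Re-exports of the SummarizedExperiment/S4Vectors generics most useful on
#' [CtExperiment-class] objects, so users need not attach those packages.
#'
#' @name reexports
#' @aliases metadata colData assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom SummarizedExperiment colData assay assayNames
#' @export metadata
#' @export colData
#' @export assay
#' @export assayNames
NULL

#' Accessors for CtExperiment and NormalizedCt
#'
#' `ctMatrix()` returns the Ct matrix (miRNAs x samples), `detected()` the
#' non-detect mask, `imputed()` the imputation mask (or `NULL` before
#' imputation), `isImputed()` whether imputation has run, `deltaCt()` the
#' normalized values, `normMethod()`/`normParams()` the normalization tag.
#'
#' @param x a [CtExperiment-class] or [NormalizedCt-class] object.
#' @return the corresponding matrix, mask, or tag.
#' @name ct-accessors
NULL

#' @rdname ct-accessors
#' @export
setGeneric("ctMatrix", function(x) standardGeneric("ctMatrix"))

#' @rdname ct-accessors
#' @export
setMethod("ctMatrix", "CtExperiment", function(x) assay(x, "ct"))

#' @rdname ct-accessors
#' @export
setGeneric("detected", function(x) standardGeneric("detected"))

#' @rdname ct-accessors
#' @export
setMethod("detected", "CtExperiment", function(x) assay(x, "detected"))

#' @rdname ct-accessors
#' @export
setGeneric("imputed", function(x) standardGeneric("imputed"))

#' @rdname ct-accessors
#' @export
setMethod("imputed", "CtExperiment", function(x) {
  if ("imputed" %in% assayNames(x)) assay(x, "imputed") else NULL
})

#' @rdname ct-accessors
#' @export
setGeneric("isImputed", function(x) standardGeneric("isImputed"))

#' @rdname ct-accessors
#' @export
setMethod("isImputed", "CtExperiment",
          function(x) "imputed" %in% assayNames(x))

#' @rdname ct-accessors
#' @export
setGeneric("deltaCt", function(x) standardGeneric("deltaCt"))

#' @rdname ct-accessors
#' @export
setMethod("deltaCt", "NormalizedCt", function(x) assay(x, "delta_ct"))

#' @rdname ct-accessors
#' @export
setGeneric("normMethod", function(x) standardGeneric("normMethod"))

#' @rdname ct-accessors
#' @export
setMethod("normMethod", "NormalizedCt", function(x) x@method)

#' @rdname ct-accessors
#' @export
setGeneric("normParams", function(x) standardGeneric("normParams"))

#' @rdname ct-accessors
#' @export
setMethod("normParams", "NormalizedCt", function(x) x@params)

#' Accessors for StabilityResult
#'
#' `stabilityValues()` returns the per-candidate values of the four
#' algorithms, `stabilityRanks()` the per-method dense ranks,
#' `comprehensiveRank()` the final geometric-mean ordering, and
#' `rankingTable()` the method-by-rank table (candidates listed best first,
#' tied candidates sharing one cell separated by `"|"`).
#'
#' @param x a [StabilityResult-class] object.
#' @name stability-accessors
NULL

#' @rdname stability-accessors
#' @export
setGeneric("stabilityValues", function(x) standardGeneric("stabilityValues"))

#' @rdname stability-accessors
#' @export
setMethod("stabilityValues", "StabilityResult", function(x) x@values)

#' @rdname stability-accessors
#' @export
setGeneric("stabilityRanks", function(x) standardGeneric("stabilityRanks"))

#' @rdname stability-accessors
#' @export
setMethod("stabilityRanks", "StabilityResult", function(x) x@ranks)

#' @rdname stability-accessors
#' @export
setGeneric("comprehensiveRanking",
           function(x) standardGeneric("comprehensiveRanking"))

#' @rdname stability-accessors
#' @export
setMethod("comprehensiveRanking", "StabilityResult",
          function(x) x@comprehensiveRank)

#' @rdname stability-accessors
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname stability-accessors
#' @export
setMethod("rankingTable", "StabilityResult", function(x) {
  rows <- list(
    `Delta CT`      = x@ranks[, "deltact"],
    BestKeeper      = x@ranks[, "bestkeeper"],
    NormFinder      = x@ranks[, "normfinder"],
    geNorm          = x@ranks[, "genorm"],
    `Comprehensive` = x@comprehensiveRank)
  k <- length(x@candidates)
  tab <- lapply(rows, function(r) {
    cells <- vapply(sort(unique(r)), function(v) {
      paste(x@candidates[r == v], collapse = "|")
    }, character(1))
    c(cells, rep(NA_character_, k - length(cells)))
  })
  out <- as.data.frame(do.call(rbind, tab), stringsAsFactors = FALSE)
  names(out) <- paste0("Rank", seq_len(k))
  cbind(Method = names(rows), out, row.names = NULL)
})

setMethod("show", "CtExperiment", function(object) {
  cat("CtExperiment:", nrow(object), "miRNAs x", ncol(object), "samples\n")
  det <- assay(object, "detected")
  cat(sprintf("  detected cells: %d/%d (%.1f%%)\n", sum(det), length(det),
              100 * mean(det)))
  cat("  imputed:", if (isImputed(object)) "yes" else "no", "\n")
  if (ncol(colData(object)))
    cat("  sample covariates:", paste(names(colData(object)), collapse = ", "),
        "\n")
})

setMethod("show", "NormalizedCt", function(object) {
  cat("NormalizedCt (", object@method, "): ", nrow(object), " miRNAs x ",
      ncol(object), " samples\n", sep = "")
  if (length(object@params)) {
    for (nm in names(object@params)) {
      v <- object@params[[nm]]
      if (is.character(v) && length(v) > 6) v <- c(v[1:6], "...")
      cat("  ", nm, ": ", paste(v, collapse = ","), "\n", sep = "")
    }
  }
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  if (length(object@readingsRemoved)) {
    cat("  readings converted to non-detect:\n")
    for (nm in names(object@readingsRemoved))
      cat("    ", nm, ": ", object@readingsRemoved[[nm]], "\n", sep = "")
  }
  cat("  samples removed:", nrow(object@samplesRemoved), "\n")
  cat("  miRNAs removed:", nrow(object@mirnasRemoved), "\n")
  cat("  cells imputed:", object@cellsImputed, "\n")
  if (length(object@thresholds))
    cat("  thresholds:",
        paste(names(object@thresholds), unlist(object@thresholds),
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult:", length(object@candidates), "candidates\n")
  ord <- order(object@comprehensiveRank)
  top <- utils::head(object@candidates[ord], 4)
  cat("  comprehensive top:", paste(top, collapse = ", "), "\n")
  if (length(object@excluded))
    cat("  excluded (non-detects):", paste(object@excluded, collapse = ", "),
        "\n")
})
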