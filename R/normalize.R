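## The five normalization strategies compared by the package. All operate on
## the Ct scale (efficiency-2 amplification is assumed throughout, so a
## delta-Ct is a log2 expression ratio) and return a method-tagged
## NormalizedCt.

#' Global mean normalization
#'
#' Subtracts, within each sample, the mean Ct of all analyzed miRNAs from
#' each raw Ct. Requires a fully imputed (or fully detected) matrix; after
#' normalization every sample's mean delta-Ct is zero.
#'
#' @param x an imputed [CtExperiment-class].
#' @return a [NormalizedCt-class] with method `"global_mean"`.
#' @export
globalMeanNormalize <- function(x) {
  m <- ctMatrix(x)
  .assertNoNondetects(m, "global mean normalization")
  out <- sweep(m, 2L, colMeans(m))
  .newNormalizedCt(out, "global_mean", list(), x)
}

#' Mean-centering of unimputed data
#'
#' Like global mean normalization, but each sample's reference mean uses only
#' the miRNAs detected in that sample; non-detect cells stay non-detect
#' (`NA`). On a fully detected matrix this is identical to
#' [globalMeanNormalize()].
#'
#' @param x a [CtExperiment-class] (pre-imputation mask is used).
#' @return a [NormalizedCt-class] with method `"mean_unimputed"`.
#' @export
meanCenterUnimputed <- function(x) {
  m <- ctMatrix(x)
  det <- detected(x)
  if (any(colSums(det) == 0L))
    stop("sample(s) with zero detected miRNAs: ",
         paste(colnames(m)[colSums(det) == 0L], collapse = ", "),
         call. = FALSE)
  mm <- m
  mm[!det] <- NA
  ref <- colMeans(mm, na.rm = TRUE)
  out <- sweep(mm, 2L, ref)
  .newNormalizedCt(out, "mean_unimputed", list(), x)
}

#' Mean-centering restricted (MCR) normalization
#'
#' Subtracts the per-sample mean of the restricted set: the miRNAs detected
#' in every sample (zero missingness before imputation). The restricted set
#' is derived from the pre-imputation `detected` mask and recorded in the
#' result's parameters.
#'
#' @param x an imputed [CtExperiment-class].
#' @return a [NormalizedCt-class] with method `"mcr"`.
#' @export
mcrNormalize <- function(x) {
  m <- ctMatrix(x)
  .assertNoNondetects(m, "MCR normalization")
  restricted <- rownames(x)[rowSums(!detected(x)) == 0L]
  if (!length(restricted))
    stop("no miRNA is detected in every sample; the restricted set is ",
         "empty — consider endogenousControlNormalize()", call. = FALSE)
  ref <- colMeans(m[restricted, , drop = FALSE])
  out <- sweep(m, 2L, ref)
  .newNormalizedCt(out, "mcr", list(restricted = restricted), x)
}

#' Quantile normalization
#'
#' Forces every sample's Ct distribution to the across-sample average
#' distribution (the mean of each order statistic): on tie-free data every
#' sample ends up with exactly the same multiset of values. Ties within a
#' sample receive the mean of the reference values their ranks span —
#' consequential here because imputed non-detects form large blocks of tied
#' 40s, which this rule maps to one deterministic value per sample. Applied
#' after imputation; on tie-free data the operation is idempotent.
#'
#' @param x an imputed [CtExperiment-class].
#' @return a [NormalizedCt-class] with method `"quantile"`.
#' @export
quantileNormalizeCt <- function(x) {
  m <- ctMatrix(x)
  .assertNoNondetects(m, "quantile normalization")
  ref <- rowMeans(apply(m, 2L, sort))     # mean order statistics
  out <- apply(m, 2L, function(v) {
    o <- order(v)
    grp <- cumsum(!duplicated(v[o]))      # tie groups along the sorted column
    res <- numeric(length(v))
    res[o] <- stats::ave(ref, grp)        # mean of the spanned ref values
    res
  })
  dimnames(out) <- dimnames(m)
  .newNormalizedCt(out, "quantile", list(ties = "mean of spanned values"), x)
}

#' Endogenous control normalization
#'
#' The classic delta-Ct: subtracts, in each sample, the control Ct from every
#' raw Ct. With several controls the per-sample reference is the arithmetic
#' mean of the control Cts (the geometric mean in linear abundance space,
#' the qPCR convention for multi-gene normalization factors). A single
#' control's own normalized trace is identically zero.
#'
#' @param x a [CtExperiment-class] whose control rows are fully detected or
#'   imputed.
#' @param controls character vector of control miRNA ids.
#' @return a [NormalizedCt-class] with method `"endogenous_control"`.
#' @export
endogenousControlNormalize <- function(x, controls) {
  ref <- combineControls(x, controls)
  out <- sweep(ctMatrix(x), 2L, ref)
  imp <- imputed(x)
  flag <- !is.null(imp) && any(imp[controls, , drop = FALSE])
  .newNormalizedCt(out, "endogenous_control",
                   list(controls = controls, controls_imputed = flag), x)
}

#' Combine controls into a per-sample pseudo-control trace
#'
#' Returns the per-sample arithmetic mean Ct over the control set — the
#' virtual reference used by [endogenousControlNormalize()] and, as a
#' virtual candidate, by [evaluateCombination()]. Averaging independent-noise
#' controls shrinks the trace's technical variance below each member's.
#'
#' @inheritParams endogenousControlNormalize
#' @return named numeric vector, one value per sample (cycles).
#' @export
combineControls <- function(x, controls) {
  stopifnot(length(controls) >= 1L)
  unknown <- setdiff(controls, rownames(x))
  if (length(unknown))
    stop("unknown control id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m <- ctMatrix(x)[controls, , drop = FALSE]
  if (anyNA(m))
    stop("control(s) contain non-detects; impute or choose fully detected ",
         "controls", call. = FALSE)
  colMeans(m)
}

#' Dispatch one normalization strategy by name
#'
#' @param x a [CtExperiment-class].
#' @param method strategy name (see [NormalizedCt-class]); `"raw"` returns
#'   the Ct values untouched, tagged as raw baseline.
#' @param controls control ids, for `"endogenous_control"` only.
#' @return a [NormalizedCt-class].
#' @export
normalizeCt <- function(x, method = c("global_mean", "mean_unimputed", "mcr",
                                      "quantile", "endogenous_control",
                                      "raw"),
                        controls = NULL) {
  method <- match.arg(method)
  switch(method,
         raw = .newNormalizedCt(ctMatrix(x), "raw", list(), x),
         global_mean = globalMeanNormalize(x),
         mean_unimputed = meanCenterUnimputed(x),
         mcr = mcrNormalize(x),
         quantile = quantileNormalizeCt(x),
         endogenous_control = {
           if (is.null(controls))
             stop("endogenous_control requires 'controls'", call. = FALSE)
           endogenousControlNormalize(x, controls)
         })
}
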