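## Covariate sensitivity: residualize miRNA levels on age and sex and check
## that the endogenous-control selection is unchanged.

#' Residualize miRNA values on sample covariates
#'
#' Per miRNA, ordinary least squares of the values on an intercept, age
#' (years) and a sex indicator; the values are replaced by the residuals
#' (per-miRNA mean zero by construction). With `keep_level = TRUE` the
#' per-miRNA mean is added back, preserving the Ct scale — required when
#' the residualized values feed stability algorithms whose index needs
#' positive values (BestKeeper's geometric mean); the pairwise and
#' model-based stability values are unaffected by per-miRNA constants.
#' A degenerate covariate (e.g. a single-sex cohort) is dropped with a
#' warning. Residualizing twice equals residualizing once.
#'
#' @param x a [CtExperiment-class] (fully imputed) or [NormalizedCt-class].
#' @param covariates data.frame with `age` and `sex` for every sample, in
#'   column order of `x`; defaults to `colData(x)`.
#' @param keep_level add the per-miRNA mean back to the residuals.
#' @return an object of the same class as `x` with values replaced by
#'   residuals; the per-miRNA coefficients are stored in
#'   `metadata(x)$residual_model`.
#' @export
residualizeCt <- function(x, covariates = NULL, keep_level = FALSE) {
  m <- if (is(x, "NormalizedCt")) deltaCt(x) else ctMatrix(x)
  .assertNoNondetects(m, "residualization")
  if (is.null(covariates)) covariates <- as.data.frame(colData(x))
  need <- setdiff(c("age", "sex"), names(covariates))
  if (length(need))
    stop("covariates must provide: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(covariates) != ncol(m))
    stop("covariates must cover every sample", call. = FALSE)
  sex_ind <- as.numeric(factor(covariates$sex)) - 1
  X <- cbind(intercept = 1, age = covariates$age, sex = sex_ind)
  degenerate <- apply(X[, -1, drop = FALSE], 2L, function(v)
    stats::sd(v) == 0 || anyNA(v))
  if (any(degenerate)) {
    warning("dropping degenerate covariate(s): ",
            paste(names(degenerate)[degenerate], collapse = ", "),
            call. = FALSE)
    X <- X[, c(TRUE, !degenerate), drop = FALSE]
  }
  qrX <- qr(X)
  Y <- t(m)                                # samples x miRNAs
  res <- qr.resid(qrX, Y)
  coefs <- t(qr.coef(qrX, Y))              # miRNAs x coefficients
  out <- t(res)
  if (keep_level) out <- out + rowMeans(m)
  model <- list(covariates = colnames(X)[-1], coefficients = coefs,
                keep_level = keep_level)
  if (is(x, "NormalizedCt")) {
    assay(x, "delta_ct") <- out
  } else {
    assays(x)$ct <- out
    assays(x)$detected <- !is.na(out)
    if ("imputed" %in% assayNames(x)) assays(x)$imputed <- is.na(out)
  }
  metadata(x)$residual_model <- model
  x
}

#' Covariate sensitivity report
#'
#' Re-runs both endogenous-control selection criteria with age/sex effects
#' regressed out and reports how much the answers move. Two arms, matching
#' the two selection criteria: the smallest-SD-after-global-mean list is
#' recomputed on residualized \emph{global-mean-normalized} levels, and the
#' four-algorithm stability ranking on residualized \emph{raw} Ct values
#' (level-preserving residuals). Concordance is summarized as top-N set
#' equality plus a Spearman rank correlation; no significance test is
#' attached — the statistic is descriptive.
#'
#' @param x a post-QC, imputed [CtExperiment-class].
#' @param covariates data.frame with `age` and `sex` (default
#'   `colData(x)`).
#' @param candidates candidate panel for the stability arm (default: all).
#' @param top_n size of the top set compared (default 4).
#' @return a list with `sd_arm` and `stability_arm`, each holding the
#'   original and residualized orderings, `top_concordant` and
#'   `rank_correlation`.
#' @export
sensitivityReport <- function(x, covariates = NULL, candidates = NULL,
                              top_n = 4L) {
  ## Arm 1: SD-after-global-mean on residualized normalized levels.
  sd_orig <- selectByGlobalMeanSD(x)
  gm_res <- residualizeCt(globalMeanNormalize(x), covariates)
  sds <- perMirnaSD(gm_res)
  ord <- order(sds, names(sds), method = "radix")
  sd_res <- data.frame(mirna_id = names(sds)[ord], sd = unname(sds[ord]),
                       row.names = NULL)
  sd_arm <- list(
    original = sd_orig, residualized = sd_res,
    top_concordant = setequal(utils::head(sd_orig$mirna_id, top_n),
                              utils::head(sd_res$mirna_id, top_n)),
    rank_correlation = stats::cor(match(sd_orig$mirna_id, sd_res$mirna_id),
                                  seq_len(nrow(sd_orig)),
                                  method = "spearman"))
  ## Arm 2: four-algorithm ranking on residualized raw Ct.
  st_orig <- rankCandidates(x, candidates)
  x_res <- residualizeCt(x, covariates, keep_level = TRUE)
  st_res <- rankCandidates(x_res, candidates)
  r1 <- st_orig@comprehensiveRank
  r2 <- st_res@comprehensiveRank[names(r1)]
  stability_arm <- list(
    original = st_orig, residualized = st_res,
    top_concordant = setequal(names(sort(r1))[seq_len(min(top_n, length(r1)))],
                              names(sort(r2))[seq_len(min(top_n, length(r2)))]),
    rank_correlation = stats::cor(r1, r2, method = "spearman"))
  list(sd_arm = sd_arm, stability_arm = stability_arm, top_n = top_n)
}
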