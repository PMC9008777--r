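## Per-miRNA variability across samples: the benchmark used to compare
## normalization strategies (a good normalizer shrinks the technical spread
## of every miRNA).

#' Per-miRNA standard deviation across samples
#'
#' Sample standard deviation (n - 1 denominator) of each miRNA across
#' samples, on the raw Ct or delta-Ct scale.
#'
#' @param x a [CtExperiment-class], [NormalizedCt-class], or numeric matrix
#'   (miRNAs x samples).
#' @param na.rm drop non-detect cells (only meaningful for the unimputed
#'   mean-centering output, which retains them).
#' @return named numeric vector of SDs (cycles).
#' @export
perMirnaSD <- function(x, na.rm = FALSE) {
  m <- if (is(x, "NormalizedCt")) deltaCt(x)
       else if (is(x, "CtExperiment")) ctMatrix(x)
       else x
  if (ncol(m) < 2L)
    stop("at least 2 samples are required to compute an SD", call. = FALSE)
  if (!na.rm) .assertNoNondetects(m, "perMirnaSD")
  .rowSds(m, na.rm = na.rm)
}

.sdSummary <- function(sds) {
  q <- stats::quantile(sds, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
  data.frame(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
             mean = mean(sds), n_mirnas = length(sds))
}

#' Compare normalization strategies by per-miRNA SD
#'
#' For each strategy (the raw baseline is always included) the distribution
#' of per-miRNA SDs is summarized — min, quartiles (linear-interpolation
#' convention), max, mean — on two panels: all analyzed miRNAs, and the
#' restricted panel of miRNAs with zero pre-imputation missingness. The two
#' panels mirror the all-miRNA and consistently-detected views of a
#' normalization benchmark.
#'
#' @param x a post-QC, imputed [CtExperiment-class].
#' @param methods strategies to compare (see [normalizeCt()]).
#' @param controls control ids, used when `"endogenous_control"` is among
#'   the methods.
#' @return a `data.frame` with one row per method x panel.
#' @export
compareNormalizations <- function(x,
                                  methods = c("raw", "global_mean",
                                              "mean_unimputed", "mcr",
                                              "quantile"),
                                  controls = NULL) {
  restricted <- rownames(x)[rowSums(!detected(x)) == 0L]
  rows <- lapply(unique(c("raw", methods)), function(meth) {
    nm <- normalizeCt(x, meth, controls = controls)
    sds <- perMirnaSD(nm, na.rm = (meth == "mean_unimputed"))
    all_panel <- cbind(method = meth, subset = "all_analyzed",
                       .sdSummary(sds))
    if (length(restricted) >= 1L) {
      r <- cbind(method = meth, subset = "restricted",
                 .sdSummary(sds[restricted]))
      rbind(all_panel, r)
    } else all_panel
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
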