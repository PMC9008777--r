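## Internal helpers shared across modules.

#' Dense ranks, ties sharing the smaller rank
#'
#' Ranks a numeric vector ascending so that tied values share the same rank
#' and the next distinct value gets the next integer (1, 1, 2, ...), the
#' convention used by reference-stability tables where a tied top pair is
#' followed by rank 2.
#'
#' @param x numeric vector.
#' @return integer vector of ranks, named as `x`.
#' @export
denseRank <- function(x) {
  stopifnot(is.numeric(x), !anyNA(x))
  r <- match(x, sort(unique(x)))
  names(r) <- names(x)
  r
}

#' Geometric mean
#' @param x positive numeric vector.
#' @return the geometric mean of `x`.
#' @export
geomMean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Locale-independent lexicographic sort; canonical ordering of ids.
.canonicalSort <- function(ids) sort(ids, method = "radix")

## Column (per-sample) means / row (per-miRNA) sd on a miRNA x sample matrix.
.rowSds <- function(m, na.rm = FALSE) apply(m, 1L, stats::sd, na.rm = na.rm)

.assertNoNondetects <- function(m, what) {
  if (anyNA(m)) {
    stop(what, " requires a fully detected or imputed Ct matrix; ",
         "run imputeNondetects() (or choose meanCenterUnimputed) first.",
         call. = FALSE)
  }
}

.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}
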