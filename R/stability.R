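## Reference-stability algorithms: geNorm, comparative delta-Ct, BestKeeper,
## NormFinder, and the comprehensive geometric-mean-of-ranks ordering used
## to pick endogenous controls. All four run on raw Ct values after QC
## (BestKeeper in particular is expression-level sensitive, so feeding it
## normalized values would be meaningless).

.candidateMatrix <- function(x, candidates = NULL) {
  m <- if (is(x, "CtExperiment")) ctMatrix(x) else x
  if (is.null(rownames(m)))
    rownames(m) <- paste0("candidate", seq_len(nrow(m)))
  if (!is.null(candidates)) {
    unknown <- setdiff(candidates, rownames(m))
    if (length(unknown))
      stop("unknown candidate id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    m <- m[candidates, , drop = FALSE]
  }
  m
}

## Pairwise SD matrix: V[j, l] = sample SD over samples of ct[j, ] - ct[l, ].
.pairwiseSD <- function(m) {
  k <- nrow(m)
  V <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(k - 1L)) {
    d <- sweep(m[(j + 1L):k, , drop = FALSE], 2L, m[j, ])
    s <- apply(d, 1L, stats::sd)
    V[j, (j + 1L):k] <- s
    V[(j + 1L):k, j] <- s
  }
  V
}

#' geNorm expression stability (M) with iterative exclusion
#'
#' For each candidate j, `M_j` is the mean over all partners l of the sample
#' SD of the pairwise difference `ct_j - ct_l`. The least stable candidate
#' (largest M) is removed and M recomputed among the survivors, until two
#' remain; those two cannot be separated by the method and share rank 1,
#' the next-removed candidate takes rank 2, and so on (dense ranks).
#' Because it works on pairwise differences, M is invariant to per-sample
#' offsets. A tie in M at removal is broken by dropping the id that sorts
#' last.
#'
#' @param x a [CtExperiment-class] or raw-Ct matrix (candidates x samples),
#'   with no non-detects among the candidates.
#' @param candidates optional candidate ids (default: all rows).
#' @return a list with `M` (the M value each candidate held when excluded;
#'   for the final pair, their M in the last round), `ranking` (dense
#'   ranks), and `exclusion_order` (first removed first).
#' @export
geNorm <- function(x, candidates = NULL) {
  m <- .candidateMatrix(x, candidates)
  if (nrow(m) < 3L)
    stop("geNorm requires at least 3 candidates", call. = FALSE)
  if (ncol(m) < 2L) stop("at least 2 samples required", call. = FALSE)
  .assertNoNondetects(m, "geNorm")
  V <- .pairwiseSD(m)
  alive <- rownames(m)
  M_out <- numeric(0)
  excluded <- character(0)
  lastM <- NULL
  while (length(alive) > 2L) {
    M <- rowMeans(V[alive, alive, drop = FALSE]) *
      length(alive) / (length(alive) - 1L)  # mean over partners l != j
    lastM <- M
    worst <- max(M)
    cand <- names(M)[M == worst]
    drop_id <- cand[order(cand, method = "radix")][length(cand)]
    M_out[drop_id] <- M[[drop_id]]
    excluded <- c(excluded, drop_id)
    alive <- setdiff(alive, drop_id)
  }
  ## The final pair cannot be separated; report the M each held in the last
  ## informative (3-candidate) round.
  M_out[alive] <- lastM[alive]
  ranking <- integer(0)
  ranking[alive] <- 1L
  if (length(excluded))
    ranking[rev(excluded)] <- 1L + seq_along(excluded)
  ids <- rownames(m)
  list(M = M_out[ids], ranking = ranking[ids], exclusion_order = excluded)
}

#' Comparative delta-Ct stability
#'
#' The mean, over every partner l, of the sample SD of the pairwise
#' difference `ct_j - ct_l` — identical by construction to the first-pass
#' geNorm M, but without the iterative exclusion. Ranked ascending.
#'
#' @inheritParams geNorm
#' @return a list with `stability` (cycles) and `ranking` (dense ranks).
#' @export
deltaCtStability <- function(x, candidates = NULL) {
  m <- .candidateMatrix(x, candidates)
  if (nrow(m) < 2L)
    stop("comparative delta-Ct requires at least 2 candidates", call. = FALSE)
  .assertNoNondetects(m, "comparative delta-Ct")
  V <- .pairwiseSD(m)
  k <- nrow(m)
  stab <- rowMeans(V) * k / (k - 1L)
  list(stability = stab, ranking = denseRank(stab))
}

#' BestKeeper stability
#'
#' Ranks candidates ascending by the sample SD of their raw Ct — unlike the
#' pairwise methods, this is \emph{not} invariant to per-sample technical
#' offsets, which is exactly why it can disagree with them. The BestKeeper
#' index (per-sample geometric mean of all candidate Cts) and each
#' candidate's Pearson correlation with it are reported descriptively.
#'
#' @inheritParams geNorm
#' @return a list with `sd`, `r` (correlation with the index; `NA` when the
#'   index has zero variance), `index`, and `ranking`.
#' @export
bestKeeper <- function(x, candidates = NULL) {
  m <- .candidateMatrix(x, candidates)
  if (nrow(m) < 2L)
    stop("BestKeeper requires at least 2 candidates", call. = FALSE)
  .assertNoNondetects(m, "BestKeeper")
  sds <- .rowSds(m)
  index <- exp(colMeans(log(m)))
  r <- if (stats::sd(index) == 0) {
    rep(NA_real_, nrow(m))
  } else {
    apply(m, 1L, function(v) {
      if (stats::sd(v) == 0) NA_real_ else stats::cor(v, index)
    })
  }
  names(r) <- rownames(m)
  list(sd = sds, r = r, index = index, ranking = denseRank(sds))
}

#' NormFinder stability (single group)
#'
#' Model-based decomposition `ct_ij = mu_j + t_i + e_ij`: after
#' double-centering removes the gene means and the per-sample technical
#' offsets, the per-gene residual variance is bias-corrected for the
#' contamination every gene receives from the sample means,
#' `sigma2_j = max(0, k/(k-2) * (s2_j - mean(s2)/(k-1)))`, and the stability
#' value is `sqrt(sigma2_j)` — an estimate of the gene's own error SD. The
#' correction requires at least 3 genes. Cohorts here are a single group;
#' the multi-group inter-group term is not implemented.
#'
#' @inheritParams geNorm
#' @param groups optional grouping factor; only a single group is supported.
#' @return a list with `stability` (cycles) and `ranking` (dense ranks).
#' @export
normFinder <- function(x, candidates = NULL, groups = NULL) {
  m <- .candidateMatrix(x, candidates)
  k <- nrow(m); n <- ncol(m)
  if (k < 3L)
    stop("NormFinder's bias correction requires at least 3 candidates ",
         "(k/(k-2) is undefined below that)", call. = FALSE)
  if (n < 3L) stop("at least 3 samples required", call. = FALSE)
  .assertNoNondetects(m, "NormFinder")
  if (!is.null(groups) && length(unique(groups)) > 1L)
    stop("multi-group NormFinder is not implemented; cohorts are analyzed ",
         "as a single group", call. = FALSE)
  z <- sweep(sweep(m, 1L, rowMeans(m)), 2L, colMeans(m)) + mean(m)
  s2 <- rowSums(z^2) / (n - 1L)
  sigma2 <- pmax(0, (k / (k - 2)) * (s2 - mean(s2) / (k - 1)))
  stab <- sqrt(sigma2)
  list(stability = stab, ranking = denseRank(stab))
}

#' Comprehensive geometric-mean ranking
#'
#' Combines the four per-method rankings into one: each candidate's score is
#' the geometric mean of its four ranks, and the final ordering is ascending
#' in that score, ties broken by mean rank, then by id. A candidate ranked 1
#' by every method is always final rank 1.
#'
#' @param ranks integer matrix, candidates x 4 methods, each column a
#'   complete ranking of the same candidate set.
#' @return a list with `geomean` and `ranking` (a full permutation).
#' @export
comprehensiveRank <- function(ranks) {
  stopifnot(is.matrix(ranks), ncol(ranks) == 4L)
  if (is.null(rownames(ranks)))
    stop("ranks must carry candidate ids as rownames", call. = FALSE)
  if (anyNA(ranks))
    stop("all four methods must rank every candidate", call. = FALSE)
  g <- apply(ranks, 1L, geomMean)
  ord <- order(g, rowMeans(ranks), rownames(ranks), method = "radix")
  ranking <- integer(nrow(ranks))
  ranking[ord] <- seq_len(nrow(ranks))
  names(ranking) <- rownames(ranks)
  list(geomean = g, ranking = ranking)
}

#' Rank endogenous-control candidates by all four algorithms
#'
#' Runs geNorm, comparative delta-Ct, BestKeeper and NormFinder on the raw
#' post-QC Ct values of the candidates, assigns per-method dense ranks, and
#' computes the comprehensive geometric-mean ordering. Candidates with any
#' remaining non-detect are excluded with a warning (insufficiently detected
#' candidates cannot be assessed).
#'
#' @param x a [CtExperiment-class] or raw-Ct matrix.
#' @param candidates candidate ids (default: all rows).
#' @return a [StabilityResult-class].
#' @export
rankCandidates <- function(x, candidates = NULL) {
  m <- .candidateMatrix(x, candidates)
  bad <- rownames(m)[apply(m, 1L, anyNA)]
  if (length(bad)) {
    warning("excluding candidate(s) with non-detects: ",
            paste(bad, collapse = ", "), call. = FALSE)
    m <- m[setdiff(rownames(m), bad), , drop = FALSE]
  }
  ids <- rownames(m)
  gn <- geNorm(m)
  dc <- deltaCtStability(m)
  bk <- bestKeeper(m)
  nf <- normFinder(m)
  ranks <- cbind(genorm = gn$ranking, deltact = dc$ranking,
                 bestkeeper = bk$ranking, normfinder = nf$ranking)
  comp <- comprehensiveRank(ranks)
  new("StabilityResult",
      candidates = ids,
      values = data.frame(candidate = ids,
                          genorm_m = unname(gn$M),
                          deltact_stability = unname(dc$stability),
                          bestkeeper_sd = unname(bk$sd),
                          bestkeeper_r = unname(bk$r),
                          normfinder_stability = unname(nf$stability),
                          row.names = NULL),
      ranks = ranks,
      comprehensive = comp$geomean,
      comprehensiveRank = comp$ranking,
      excluded = bad)
}

#' Evaluate a combination control against its members
#'
#' Appends the pseudo-control trace of `controls` (their per-sample mean Ct,
#' see [combineControls()]) as a virtual candidate and re-runs the full
#' ranking. With a single member the virtual candidate would duplicate an
#' existing one, so the plain ranking is returned unchanged.
#'
#' @param x a [CtExperiment-class].
#' @param controls ids of the controls to combine.
#' @param candidates candidate panel (default: all rows of `x`).
#' @return a list with `result` (the [StabilityResult-class] including the
#'   virtual candidate), `combination` (its id), and `comparison` (per
#'   member: both comprehensive ranks and whether the combination is
#'   strictly better).
#' @export
evaluateCombination <- function(x, controls, candidates = NULL) {
  m <- .candidateMatrix(x, candidates)
  if (length(controls) == 1L || length(unique(controls)) == 1L) {
    res <- rankCandidates(m)
    cr <- res@comprehensiveRank
    comparison <- data.frame(member = controls[1],
                             member_rank = cr[[controls[1]]],
                             combo_rank = cr[[controls[1]]],
                             combo_better = FALSE)
    return(list(result = res, combination = controls[1],
                comparison = comparison))
  }
  trace <- combineControls(x, controls)
  combo_id <- paste(controls, collapse = "+")
  aug <- rbind(m, matrix(trace, 1L, dimnames = list(combo_id, names(trace))))
  res <- rankCandidates(aug)
  cr <- res@comprehensiveRank
  comparison <- data.frame(member = controls,
                           member_rank = cr[controls],
                           combo_rank = cr[[combo_id]],
                           combo_better = cr[[combo_id]] < cr[controls],
                           row.names = NULL)
  list(result = res, combination = combo_id, comparison = comparison)
}

#' Candidate controls closest to the global mean
#'
#' The smallest-SD-after-global-mean criterion: globally mean-normalize,
#' compute each miRNA's SD across samples, and sort ascending — the miRNAs
#' whose expression tracks the per-sample mean most closely head the list.
#' Optionally truncated to SD strictly below a cutoff (2 delta-Ct cycles is
#' the conventional presentation cutoff).
#'
#' @param x an imputed [CtExperiment-class].
#' @param sd_cutoff keep only candidates with SD strictly below this value
#'   (`NULL` keeps all).
#' @return a `data.frame` (`mirna_id`, `sd`) sorted ascending by SD.
#' @export
selectByGlobalMeanSD <- function(x, sd_cutoff = NULL) {
  sds <- perMirnaSD(globalMeanNormalize(x))
  ord <- order(sds, names(sds), method = "radix")
  out <- data.frame(mirna_id = names(sds)[ord], sd = unname(sds[ord]),
                    row.names = NULL)
  if (!is.null(sd_cutoff)) out <- out[out$sd < sd_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
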