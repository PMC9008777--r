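## Synthetic Ct data generator. Additive Gaussian model on the Ct
## (log2-abundance) scale:
##
##   Ct_ijr = mu_j + t_i + gamma_j * (age_i - mean(age)) + delta_j * sex_i
##            + eps_ij + eta_ijr
##
## with per-sample technical offsets t ~ N(0, tau) (extraction / RT
## efficiency), per-miRNA biological+technical noise eps ~ N(0, sigma_j),
## and replicate noise eta ~ N(0, replicate_sd). A reading is censored to a
## non-detect with probability logistic((Ct - lod) / dropout_slope) — a hard
## threshold at the detection limit when the slope is 0 — so missingness is
## driven by Ct magnitude (missing-not-at-random), the way non-detects
## behave in real dilute plasma samples. Full ground truth is returned for
## parameter-recovery tests.

#' Generator configuration
#'
#' @param n_samples,n_mirnas panel dimensions.
#' @param mu per-miRNA mean Ct (cycles): a numeric vector (recycled), `NULL`
#'   (drawn uniform on 18-33), `list(range = c(lo, hi))` for a uniform draw,
#'   or `list(expressed_frac =, expressed_range =, background_range =)` for
#'   a two-component mixture of well-expressed and near/below-LOD miRNAs.
#' @param sigma per-miRNA noise SD (cycles): numeric vector, `NULL` (uniform
#'   on 0.3-1.5), or `list(range =)`.
#' @param tau SD of the per-sample technical offset (cycles).
#' @param lod detection-limit Ct (cycles).
#' @param dropout_slope logistic width of the censoring curve (cycles);
#'   0 gives a hard threshold at `lod`.
#' @param covariate_effects optional `list(age =, sex =)` of per-miRNA
#'   coefficients (recycled); age effects apply to centered age.
#' @param age_mean,age_sd,female_frac sampled cohort covariates (a
#'   middle-aged, mixed-sex hypertensive cohort by default).
#' @param replicates readings per sample x miRNA (1 or 3).
#' @param replicate_sd replicate-level noise SD (cycles).
#' @param qc_fail_frac fraction of detected readings synthesized with an
#'   amplification score (and, independently, Cq confidence) below the QC
#'   thresholds.
#' @param planted optional `list(mu =, sigma =)` overriding miRNA 1 to plant
#'   a designated stable endogenous-control candidate (truth-flagged).
#' @param seed integer; fixes the entire dataset bit-for-bit.
#' @return validated configuration list for [simulateCtData()].
#' @export
simConfig <- function(n_samples = 30L, n_mirnas = 150L,
                      mu = NULL, sigma = NULL, tau = 1.5,
                      lod = 33, dropout_slope = 0.5,
                      covariate_effects = NULL,
                      age_mean = 48, age_sd = 10, female_frac = 0.44,
                      replicates = 1L, replicate_sd = 0.25,
                      qc_fail_frac = 0, planted = NULL, seed = NULL) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_mirnas = as.integer(n_mirnas),
              mu = mu, sigma = sigma, tau = tau, lod = lod,
              dropout_slope = dropout_slope,
              covariate_effects = covariate_effects,
              age_mean = age_mean, age_sd = age_sd,
              female_frac = female_frac,
              replicates = as.integer(replicates),
              replicate_sd = replicate_sd,
              qc_fail_frac = qc_fail_frac, planted = planted, seed = seed)
  stopifnot(cfg$n_samples >= 1L, cfg$n_mirnas >= 1L,
            cfg$tau >= 0, cfg$lod > 0, cfg$lod <= 40,
            cfg$dropout_slope >= 0, cfg$replicates >= 1L,
            cfg$replicate_sd >= 0,
            cfg$qc_fail_frac >= 0, cfg$qc_fail_frac < 1)
  cfg
}

.drawParam <- function(spec, n, default_range) {
  if (is.null(spec)) return(stats::runif(n, default_range[1], default_range[2]))
  if (is.numeric(spec)) return(rep_len(spec, n))
  if (is.list(spec) && !is.null(spec$range))
    return(stats::runif(n, spec$range[1], spec$range[2]))
  if (is.list(spec) && !is.null(spec$expressed_frac)) {
    expressed <- stats::runif(n) < spec$expressed_frac
    v <- stats::runif(n, spec$background_range[1], spec$background_range[2])
    v[expressed] <- stats::runif(sum(expressed), spec$expressed_range[1],
                                 spec$expressed_range[2])
    return(v)
  }
  stop("unrecognized parameter specification", call. = FALSE)
}

#' Generate a synthetic Ct dataset with ground truth
#'
#' @param cfg a [simConfig()] list.
#' @param format `"experiment"` for a [CtExperiment-class] (requires
#'   `replicates = 1`) or `"records"` for a long reading table (one row per
#'   reaction, with synthesized amplification-quality fields).
#' @return `list(data = <CtExperiment or records>, truth = <list>)`; the
#'   truth holds every realized parameter (`mu`, `sigma`, `tau` offsets `t`,
#'   covariates and effects, censoring parameters, planted candidate id),
#'   sufficient to recompute the dataset from the seed.
#' @examples
#' sim <- simulateCtData(simConfig(n_samples = 10, n_mirnas = 20, seed = 1))
#' sim$data
#' @export
simulateCtData <- function(cfg = simConfig(),
                           format = c("experiment", "records")) {
  format <- match.arg(format)
  if (format == "experiment" && cfg$replicates != 1L)
    stop("replicate-level data must be generated as records; aggregate ",
         "with aggregateReplicates()", call. = FALSE)
  if (!is.null(cfg$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(cfg$seed)
  }
  n <- cfg$n_samples; p <- cfg$n_mirnas; R <- cfg$replicates
  mirnas <- sprintf("mir%04d", seq_len(p))
  samples <- sprintf("sample%03d", seq_len(n))
  mu <- .drawParam(cfg$mu, p, c(18, 33))
  sigma <- .drawParam(cfg$sigma, p, c(0.3, 1.5))
  stopifnot(all(sigma >= 0))
  planted_id <- NULL
  if (!is.null(cfg$planted)) {
    mu[1] <- cfg$planted$mu
    sigma[1] <- cfg$planted$sigma
    planted_id <- mirnas[1]
  }
  gamma <- delta <- rep(0, p)
  if (!is.null(cfg$covariate_effects)) {
    if (!is.null(cfg$covariate_effects$age))
      gamma <- rep_len(cfg$covariate_effects$age, p)
    if (!is.null(cfg$covariate_effects$sex))
      delta <- rep_len(cfg$covariate_effects$sex, p)
  }
  t_i <- stats::rnorm(n, 0, cfg$tau)
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  sex <- ifelse(stats::runif(n) < cfg$female_frac, "F", "M")
  sex_ind <- as.numeric(sex == "F")
  age_c <- age - mean(age)
  eps <- matrix(stats::rnorm(p * n, 0, sigma), p, n)      # sigma recycles by row
  base <- mu + outer(gamma, age_c) + outer(delta, sex_ind) +
    matrix(t_i, p, n, byrow = TRUE) + eps
  dimnames(base) <- list(mirnas, samples)

  censor <- function(ct) {
    pnd <- if (cfg$dropout_slope == 0) as.numeric(ct > cfg$lod)
           else stats::plogis((ct - cfg$lod) / cfg$dropout_slope)
    stats::runif(length(ct)) < pnd
  }
  truth <- list(mu = stats::setNames(mu, mirnas),
                sigma = stats::setNames(sigma, mirnas),
                tau = cfg$tau, t = stats::setNames(t_i, samples),
                age = stats::setNames(age, samples),
                sex = stats::setNames(sex, samples),
                gamma = stats::setNames(gamma, mirnas),
                delta = stats::setNames(delta, mirnas),
                lod = cfg$lod, dropout_slope = cfg$dropout_slope,
                replicate_sd = cfg$replicate_sd,
                planted = planted_id, seed = cfg$seed,
                latent_ct = base)
  sampleData <- data.frame(sample_id = samples, age = age, sex = sex)

  if (format == "experiment") {
    ct <- base
    ct[matrix(censor(as.vector(ct)), p, n)] <- NA_real_
    x <- CtExperiment(ct, sampleData = sampleData)
    metadata(x)$truth <- truth
    return(list(data = x, truth = truth))
  }

  rec <- expand.grid(replicate = seq_len(R), mirna_id = mirnas,
                     sample_id = samples, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  latent <- base[cbind(match(rec$mirna_id, mirnas),
                       match(rec$sample_id, samples))] +
    stats::rnorm(nrow(rec), 0, cfg$replicate_sd)
  nd <- censor(latent)
  rec$ct <- ifelse(nd, NA_real_, latent)
  n_rec <- nrow(rec)
  amp <- stats::runif(n_rec, 1.1, 2.0)
  amp_fail <- stats::runif(n_rec) < cfg$qc_fail_frac
  amp[amp_fail] <- stats::runif(sum(amp_fail), 0.5, 1.1 - 1e-9)
  cq <- stats::runif(n_rec, 0.7, 1.0)
  cq_fail <- stats::runif(n_rec) < cfg$qc_fail_frac
  cq[cq_fail] <- stats::runif(sum(cq_fail), 0.3, 0.7 - 1e-9)
  amp[nd] <- stats::runif(sum(nd), 0, 1)
  cq[nd] <- stats::runif(sum(nd), 0, 0.7)
  rec$amp_score <- amp
  rec$cq_conf <- cq
  rec <- rec[, c("sample_id", "mirna_id", "replicate", "ct", "amp_score",
                 "cq_conf")]
  truth$qc_fail <- list(amp = amp_fail, cq = cq_fail)
  list(data = rec, truth = truth, sampleData = sampleData)
}

#' Discovery-style array preset
#'
#' Configuration emulating a genome-wide circulating-miRNA array profiling
#' study: a 754-miRNA panel on 30 samples where only a small, well-expressed
#' fraction survives the 50\%-missingness filter (an analyzable panel on the
#' order of 10^2 miRNAs), heavy detection-limit censoring of the rest,
#' per-sample technical offsets of 2 cycles, and one planted
#' maximally-stable miRNA (sigma = 0.1 cycles, mean Ct near the expressed
#' panel's center) that a correct selection procedure should recover as the
#' top endogenous-control candidate.
#'
#' @param seed integer seed.
#' @return a [simConfig()] list.
#' @export
discoveryPreset <- function(seed = NULL) {
  simConfig(n_samples = 30L, n_mirnas = 754L,
            mu = list(expressed_frac = 0.10, expressed_range = c(22, 32),
                      background_range = c(33, 46)),
            sigma = list(range = c(0.5, 2)),
            tau = 2, lod = 33, dropout_slope = 0.5,
            replicates = 1L, qc_fail_frac = 0.02,
            planted = list(mu = 25, sigma = 0.1), seed = seed)
}
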