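make_records <- function(ct, amp = 1.5, cq = 0.9) {
  data.frame(sample_id = "s1", mirna_id = paste0("m", seq_along(ct)),
             replicate = 1L, ct = ct,
             amp_score = rep_len(amp, length(ct)),
             cq_conf = rep_len(cq, length(ct)))
}

test_that("reading filters apply strict inequalities at the printed cutoffs", {
  rec <- make_records(c(20, 21, 22, 23),
                      amp = c(1.05, 1.1, 1.5, 1.5),
                      cq = c(0.9, 0.7, 0.69, 0.9))
  out <- filterReadings(rec, qcConfig("discovery"))
  # amp_score 1.05 -> non-detect; boundary (1.1, 0.7) retained;
  # cq_conf 0.69 with good amp -> non-detect
  expect_equal(is.na(out$records$ct), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$report@readingsRemoved[["amp_score"]], 1L)
  expect_equal(out$report@readingsRemoved[["cq_conf"]], 1L)

  # validation mode ignores cq_conf
  val <- filterReadings(rec, qcConfig("validation"))
  expect_equal(is.na(val$records$ct), c(TRUE, FALSE, FALSE, FALSE))

  # requiring cq_conf without the column is an error
  rec$cq_conf <- NA_real_
  expect_error(filterReadings(rec, qcConfig("discovery")), "cq_conf")
})

test_that("replicate aggregation averages detected Cts only", {
  rec <- data.frame(sample_id = "s1", mirna_id = rep(c("m1", "m2", "m3"), each = 3),
                    replicate = rep(1:3, 3),
                    ct = c(30, 31, 32,  30, NA, 32,  NA, NA, NA),
                    amp_score = 1.5, cq_conf = 0.9)
  agg <- aggregateReplicates(rec)
  expect_equal(nrow(agg), 3L)
  expect_equal(agg$ct[agg$mirna_id == "m1"], 31)
  expect_equal(agg$ct[agg$mirna_id == "m2"], 31)  # mean of detected only
  expect_true(is.na(agg$ct[agg$mirna_id == "m3"]))
})

test_that("low-detection samples are excluded at the configured count", {
  set.seed(3)
  m <- random_ct_matrix(30, 4)
  m[6:30, 1] <- NA          # sample s01: 5 detected
  m[21:30, 2] <- NA         # sample s02: exactly 20 detected
  x <- CtExperiment(m)
  cfg <- qcConfig("discovery", sample_min_detected = 20)
  out <- dropLowDetectionSamples(x, cfg)
  expect_equal(out$report@samplesRemoved$sample_id, "s01")
  expect_equal(out$report@samplesRemoved$n_detected, 5L)
  expect_true("s02" %in% colnames(out$experiment))  # boundary kept

  # nothing to remove leaves the matrix unchanged
  full <- CtExperiment(random_ct_matrix(30, 4))
  out2 <- dropLowDetectionSamples(full, cfg)
  expect_identical(ctMatrix(out2$experiment), ctMatrix(full))

  cfg_all <- qcConfig("discovery", sample_min_detected = 31)
  expect_error(dropLowDetectionSamples(full, cfg_all), "all samples")
})

test_that("miRNA missingness filter is inclusive in discovery, exclusive in validation", {
  set.seed(4)
  m <- random_ct_matrix(3, 10)
  m["g01", 1:5] <- NA   # missing in exactly 50%
  m["g02", 1:4] <- NA   # missing in 40%
  x <- CtExperiment(m)
  disc <- filterHighMissingnessMirnas(x, qcConfig("discovery"))
  expect_false("g01" %in% rownames(disc$experiment))
  expect_true("g02" %in% rownames(disc$experiment))
  expect_equal(disc$report@mirnasRemoved$missing_frac, 0.5)
  val <- filterHighMissingnessMirnas(x, qcConfig("validation"))
  expect_true("g01" %in% rownames(val$experiment))
})

test_that("imputation assigns the configured Ct and preserves the mask", {
  set.seed(5)
  m <- random_ct_matrix(6, 5)
  nd <- sample(length(m), 8)
  m[nd] <- NA
  x <- CtExperiment(m)
  out <- imputeNondetects(x, qcConfig("discovery"))
  y <- out$experiment
  expect_true(isImputed(y))
  expect_false(anyNA(ctMatrix(y)))
  expect_true(all(ctMatrix(y)[!detected(y)] == 40))
  expect_equal(out$report@cellsImputed, 8L)           # conservation
  expect_identical(detected(y), detected(x))          # original mask kept

  # fully detected matrix is unchanged
  full <- CtExperiment(random_ct_matrix(4, 4))
  out2 <- imputeNondetects(full, qcConfig("discovery"))
  expect_identical(ctMatrix(out2$experiment), ctMatrix(full))

  # imputing below the observed maximum warns but proceeds
  low <- qcConfig("discovery", impute_ct = 20)
  expect_warning(imputeNondetects(x, low), "below the largest")
})

test_that("runQC is idempotent and its report reconciles with the matrix", {
  sim <- simulateCtData(simConfig(n_samples = 20, n_mirnas = 80, tau = 1.5,
                                  mu = list(range = c(24, 38)), seed = 21))
  qc1 <- runQC(sim$data, qcConfig("discovery"))
  x1 <- qc1$experiment
  # report bookkeeping: every input cell is accounted for
  expect_equal(qc1$report@cellsImputed, sum(!detected(x1)))
  expect_equal(nrow(qc1$report@mirnasRemoved) + nrow(x1), nrow(sim$data))
  expect_equal(nrow(qc1$report@samplesRemoved) + ncol(x1), ncol(sim$data))
  # idempotence
  qc2 <- runQC(x1, qcConfig("discovery"))
  expect_identical(ctMatrix(qc2$experiment), ctMatrix(x1))
  expect_equal(qc2$report@cellsImputed, 0L)
  expect_equal(nrow(qc2$report@mirnasRemoved), 0L)
})
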