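test_that("global mean normalization centers every sample exactly", {
  # two samples (20,30) and (22,32): row means 25 and 27
  m <- matrix(c(20, 30, 22, 32), 2, 2,
              dimnames = list(c("m1", "m2"), c("s1", "s2")))
  out <- globalMeanNormalize(CtExperiment(m))
  expect_equal(unname(deltaCt(out)), matrix(c(-5, 5, -5, 5), 2, 2))

  const <- CtExperiment(matrix(25, 3, 4, dimnames = list(paste0("m", 1:3),
                                                         paste0("s", 1:4))))
  expect_true(all(deltaCt(globalMeanNormalize(const)) == 0))

  set.seed(10)
  x <- CtExperiment(random_ct_matrix(5, 3))
  expect_lt(max(abs(colMeans(deltaCt(globalMeanNormalize(x))))), 1e-12)

  withna <- random_ct_matrix(3, 3); withna[1, 1] <- NA
  expect_error(globalMeanNormalize(CtExperiment(withna)), "impute")
})

test_that("unimputed mean-centering uses detected values only", {
  m <- matrix(c(20, NA, 30), 3, 1, dimnames = list(paste0("m", 1:3), "s1"))
  m <- cbind(m, s2 = c(21, 26, 31))  # second sample so SDs are possible
  colnames(m) <- c("s1", "s2")
  out <- meanCenterUnimputed(CtExperiment(m))
  expect_equal(unname(deltaCt(out)[, "s1"]), c(-5, NA, 5))

  # fully detected: identical to global mean
  set.seed(11)
  x <- CtExperiment(random_ct_matrix(6, 4))
  expect_equal(deltaCt(meanCenterUnimputed(x)),
               deltaCt(globalMeanNormalize(x)))

  # a sample with a single detected value centers it at zero
  m1 <- matrix(c(24, NA, NA, 20, 25, 30), 3, 2,
               dimnames = list(paste0("m", 1:3), c("s1", "s2")))
  out1 <- meanCenterUnimputed(CtExperiment(m1))
  expect_equal(unname(deltaCt(out1)["m1", "s1"]), 0)

  none <- matrix(c(NA, NA, 20, 25), 2, 2,
                 dimnames = list(c("m1", "m2"), c("s1", "s2")))
  expect_error(meanCenterUnimputed(CtExperiment(none)), "zero detected")
})

test_that("MCR normalization subtracts the mean of always-detected miRNAs", {
  # all miRNAs detected: degenerates to global mean
  set.seed(12)
  x <- CtExperiment(random_ct_matrix(5, 4))
  expect_equal(deltaCt(mcrNormalize(x)), deltaCt(globalMeanNormalize(x)))

  # restricted set of one: reduces to single-control delta-Ct
  m <- random_ct_matrix(3, 4)
  m["g02", 1] <- NA; m["g03", 2] <- NA
  xm <- imputeNondetects(CtExperiment(m), qcConfig("discovery"))$experiment
  out <- mcrNormalize(xm)
  expect_equal(normParams(out)$restricted, "g01")
  expect_equal(deltaCt(out),
               sweep(ctMatrix(xm), 2, ctMatrix(xm)["g01", ]))

  # brute-force recomputation of restricted means on a 6 x 4 panel
  m2 <- random_ct_matrix(6, 4)
  m2["g03", 2] <- NA; m2["g05", 4] <- NA
  xm2 <- imputeNondetects(CtExperiment(m2), qcConfig("discovery"))$experiment
  restr <- c("g01", "g02", "g04", "g06")
  ref <- apply(ctMatrix(xm2)[restr, ], 2, mean)
  expect_equal(deltaCt(mcrNormalize(xm2)),
               ctMatrix(xm2) - rep(ref, each = 6))

  # empty restricted set is an error pointing at endogenous controls
  m3 <- random_ct_matrix(2, 2)
  m3[1, 1] <- NA; m3[2, 2] <- NA
  xm3 <- imputeNondetects(CtExperiment(m3), qcConfig("discovery"))$experiment
  expect_error(mcrNormalize(xm3), "endogenous")
})

test_that("quantile normalization maps samples onto the average distribution", {
  m <- matrix(c(2, 4, 6, 3, 5, 7), 3, 2,
              dimnames = list(paste0("m", 1:3), c("s1", "s2")))
  out <- deltaCt(quantileNormalizeCt(CtExperiment(m)))
  expect_equal(unname(out), matrix(c(2.5, 4.5, 6.5, 2.5, 4.5, 6.5), 3, 2))

  # identical samples are a fixed point
  mm <- matrix(c(20, 25, 30), 3, 4, dimnames = list(paste0("m", 1:3),
                                                    paste0("s", 1:4)))
  expect_equal(deltaCt(quantileNormalizeCt(CtExperiment(mm))), mm)

  # tie-free data: every output sample carries the same multiset of values,
  # and the operation is idempotent
  set.seed(13)
  m2 <- random_ct_matrix(10, 5)
  q0 <- deltaCt(quantileNormalizeCt(CtExperiment(m2)))
  sorted <- apply(q0, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-10)
  expect_equal(deltaCt(quantileNormalizeCt(CtExperiment(q0))), q0,
               tolerance = 1e-12)

  # ties (imputed 40-blocks) get the mean of the spanned reference values —
  # checked against an independent oracle
  m3 <- m2
  m3[sample(length(m3), 12)] <- NA
  x3 <- imputeNondetects(CtExperiment(m3), qcConfig("discovery"))$experiment
  expect_equal(deltaCt(quantileNormalizeCt(x3)), oracle_quantile(ctMatrix(x3)),
               tolerance = 1e-12)
})

test_that("endogenous control normalization is the classic delta-Ct", {
  set.seed(14)
  x <- CtExperiment(random_ct_matrix(5, 4))
  out <- endogenousControlNormalize(x, "g03")
  expect_true(all(deltaCt(out)["g03", ] == 0))
  expect_equal(deltaCt(out), sweep(ctMatrix(x), 2, ctMatrix(x)["g03", ]))

  # two controls: per-sample reference is their arithmetic mean
  m <- random_ct_matrix(3, 2)
  m["g01", 1] <- 20; m["g02", 1] <- 22
  x2 <- CtExperiment(m)
  expect_equal(unname(combineControls(x2, c("g01", "g02"))[1]), 21)

  expect_error(endogenousControlNormalize(x, "nope"), "unknown control")
})

test_that("combining controls reduces to members in degenerate cases", {
  set.seed(15)
  x <- CtExperiment(random_ct_matrix(4, 6))
  expect_equal(combineControls(x, "g02"), ctMatrix(x)["g02", ])
  m <- ctMatrix(x); m["g03", ] <- m["g02", ]
  xd <- CtExperiment(m)
  expect_equal(combineControls(xd, c("g02", "g03")), ctMatrix(xd)["g02", ])
})

test_that("per-sample technical offsets are removed exactly", {
  set.seed(16)
  m <- random_ct_matrix(6, 5)
  x <- CtExperiment(m)
  t_i <- rnorm(5, 0, 3)
  xs <- CtExperiment(sweep(m, 2, -t_i))
  for (f in list(globalMeanNormalize, meanCenterUnimputed, mcrNormalize,
                 function(z) endogenousControlNormalize(z, c("g01", "g04"))))
    expect_equal(deltaCt(f(xs)), deltaCt(f(x)), tolerance = 1e-12)
})
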