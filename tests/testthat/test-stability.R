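# The worked 3-gene instance used throughout: per-sample Cts
#   g1 = (20, 21, 22), g2 = (25, 26, 27), g3 = (30, 30, 30)
# pairwise SDs V12 = 0, V13 = V23 = 1, so first-pass M = (0.5, 0.5, 1.0).
three_gene <- function() {
  matrix(c(20, 25, 30, 21, 26, 30, 22, 27, 30), 3, 3,
         dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
}

test_that("geNorm reproduces the hand-computed M values and tied top pair", {
  gn <- geNorm(three_gene())
  expect_equal(gn$M, c(g1 = 0.5, g2 = 0.5, g3 = 1.0))
  expect_equal(gn$exclusion_order, "g3")
  expect_equal(gn$ranking, c(g1 = 1L, g2 = 1L, g3 = 2L))

  expect_error(geNorm(three_gene()[1:2, ]), "3 candidates")
})

test_that("tied geNorm pair is presented jointly in the ranking table", {
  res <- rankCandidates(three_gene())
  tab <- rankingTable(res)
  genorm_row <- tab[tab$Method == "geNorm", ]
  expect_equal(genorm_row$Rank1, "g1|g2")
  expect_equal(genorm_row$Rank2, "g3")
  expect_true(is.na(genorm_row$Rank3))
})

test_that("pairwise stabilities cancel per-sample offsets; two constant-shifted genes have V = 0", {
  m <- three_gene()
  dc <- deltaCtStability(m[c("g1", "g2"), ])
  expect_equal(unname(dc$stability), c(0, 0))  # g2 = g1 + 5

  shifted <- sweep(m, 2, c(-3, 11, 0.5))
  expect_equal(geNorm(shifted)$M, geNorm(m)$M, tolerance = 1e-12)
  expect_equal(deltaCtStability(shifted)$stability,
               deltaCtStability(m)$stability, tolerance = 1e-12)
})

test_that("comparative delta-Ct equals first-pass geNorm M and the brute-force oracle", {
  expect_equal(deltaCtStability(three_gene())$stability,
               c(g1 = 0.5, g2 = 0.5, g3 = 1.0))
  set.seed(30)
  for (i in 1:10) {
    m <- random_ct_matrix(6, 8)
    dc <- deltaCtStability(m)$stability
    expect_equal(dc, oracle_pairwise_stability(m), tolerance = 1e-12)
    gn <- geNorm(m)
    first_out <- gn$exclusion_order[1]
    expect_equal(gn$M[[first_out]], dc[[first_out]], tolerance = 1e-12)
  }
})

test_that("BestKeeper ranks by raw-Ct SD and is not offset-invariant", {
  bk <- bestKeeper(three_gene())
  expect_equal(unname(bk$sd), c(1, 1, 0))
  expect_equal(bk$ranking, c(g1 = 2L, g2 = 2L, g3 = 1L))  # contrast with geNorm

  # candidate identical to the index
  m <- three_gene()[c("g1", "g1"), ]
  rownames(m) <- c("a", "b")
  expect_equal(unname(bestKeeper(m)$r), c(1, 1))

  # constant candidate: SD 0 and rank 1, correlation undefined
  bk3 <- bestKeeper(three_gene())
  expect_true(is.na(bk3$r[["g3"]]))
  expect_equal(bk3$ranking[["g3"]], 1L)
})

test_that("NormFinder recovers exact stabilities on constructed instances", {
  # model-exact input mu_j + t_i: every stability is zero
  set.seed(35)
  m <- matrix(c(20, 25, 30), 3, 4) + matrix(rnorm(4, 0, 2), 3, 4, byrow = TRUE)
  dimnames(m) <- list(paste0("g", 1:3), paste0("s", 1:4))
  expect_equal(unname(normFinder(m)$stability), c(0, 0, 0), tolerance = 1e-10)

  # constructed double-centered residuals with s^2 = (1, 1, 4):
  # sigma2_hat = 3 * (s2 - 2/2) -> stabilities (0, 0, 3)
  z <- outer(c(1, 1, -2), c(1, 0, -1))
  ct <- z + c(24, 26, 28) + matrix(c(0.5, -1, 0.5), 3, 3, byrow = TRUE)
  dimnames(ct) <- list(paste0("g", 1:3), paste0("s", 1:3))
  expect_equal(unname(normFinder(ct)$stability), c(0, 0, 3), tolerance = 1e-10)

  expect_error(normFinder(three_gene()[1:2, ]), "at least 3 candidates")
  expect_error(normFinder(three_gene(), groups = c(1, 1, 2)), "multi-group")
})

test_that("NormFinder is offset-invariant and tracks planted gene noise", {
  set.seed(31)
  m <- random_ct_matrix(5, 40, tau = 2, sigma = c(0.1, 0.5, 1, 1.5, 2))
  nf <- normFinder(m)
  shifted <- sweep(m, 2, rnorm(40, 0, 5))
  expect_equal(normFinder(shifted)$stability, nf$stability, tolerance = 1e-10)
  expect_equal(unname(nf$ranking), 1:5)
})

test_that("comprehensive ranking is the geometric mean of the four ranks", {
  ranks <- rbind(a = c(1, 1, 1, 1), b = c(2, 8, 2, 2), c = c(3, 3, 3, 3))
  colnames(ranks) <- c("genorm", "deltact", "bestkeeper", "normfinder")
  cr <- comprehensiveRank(ranks)
  expect_equal(unname(cr$geomean), c(1, 64^0.25, 3))
  expect_equal(cr$geomean[["b"]], 2.8284271, tolerance = 1e-6)
  expect_equal(cr$ranking, c(a = 1L, b = 2L, c = 3L))  # 2.83 beats 3

  expect_error(comprehensiveRank(ranks[, 1:3]))
})

test_that("rankCandidates integrates the four methods deterministically", {
  set.seed(32)
  # one candidate strictly best under all methods: tiny noise, no offsets
  m <- random_ct_matrix(5, 20, tau = 0, sigma = c(0.05, 1, 1.5, 2, 2.5))
  res <- rankCandidates(m)
  expect_equal(comprehensiveRanking(res)[["g01"]], 1L)
  expect_equal(unname(res@comprehensive["g01"]), 1)

  # permutation invariance
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  res_p <- rankCandidates(perm)
  expect_equal(comprehensiveRanking(res_p)[names(comprehensiveRanking(res))],
               comprehensiveRanking(res))
  expect_equal(stabilityRanks(res_p)[rownames(stabilityRanks(res)), ],
               stabilityRanks(res))

  # candidates with non-detects are excluded with a warning
  m_na <- m; m_na["g03", 2] <- NA
  expect_warning(res_na <- rankCandidates(m_na), "g03")
  expect_false("g03" %in% res_na@candidates)
  expect_equal(res_na@excluded, "g03")
})

test_that("evaluateCombination appends a virtual candidate and compares ranks", {
  set.seed(33)
  x <- CtExperiment(random_ct_matrix(6, 25, tau = 2,
                                     sigma = c(0.4, 0.4, 1.5, 1.8, 2, 2.2)))
  ev <- evaluateCombination(x, c("g01", "g02"))
  expect_true(ev$combination %in% ev$result@candidates)
  expect_equal(nrow(ev$comparison), 2L)
  expect_equal(length(ev$result@candidates), 7L)

  # single member: identical to the plain ranking
  ev1 <- evaluateCombination(x, "g01")
  plain <- rankCandidates(ctMatrix(x))
  expect_equal(comprehensiveRanking(ev1$result), comprehensiveRanking(plain))
  expect_false(ev1$comparison$combo_better)

  # combining a candidate with itself changes nothing either
  ev2 <- evaluateCombination(x, c("g01", "g01"))
  expect_equal(comprehensiveRanking(ev2$result), comprehensiveRanking(plain))
})

test_that("smallest-SD-after-global-mean selection orders and truncates", {
  # plant a row equal to the per-sample panel mean: rows a, b, (a+b)/2
  a <- c(20, 22, 24, 26); b <- c(30, 29, 28, 27)
  m <- rbind(gA = a, gB = b, gMean = (a + b) / 2)
  colnames(m) <- paste0("s", 1:4)
  sel <- selectByGlobalMeanSD(CtExperiment(m))
  expect_equal(sel$mirna_id[1], "gMean")
  expect_equal(sel$sd[1], 0)

  # strict truncation at the cutoff
  set.seed(34)
  x <- CtExperiment(random_ct_matrix(12, 15, tau = 0,
                                     sigma = seq(0.2, 4, length.out = 12)))
  all_sel <- selectByGlobalMeanSD(x)
  cut_sel <- selectByGlobalMeanSD(x, sd_cutoff = 2)
  expect_true(all(cut_sel$sd < 2))
  expect_equal(cut_sel$mirna_id, all_sel$mirna_id[all_sel$sd < 2])
})
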