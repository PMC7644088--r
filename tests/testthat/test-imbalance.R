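test_that("the Wald statistic follows its closed form", {
  r <- waldScan(c(0.5, 0.8), thetaBar = 0.5, varTheta = 0.0081)
  expect_equal(r$W, c(0, 0.09 / 0.0081))
  expect_equal(r$p[1], 1)
  expect_equal(r$p[2], pchisq(0.09 / 0.0081, 1, lower.tail = FALSE))
  expect_lt(abs(r$p[2] - 8.6e-4), 5e-5)
  expect_error(waldScan(c(0.5, 0.5)), "positive")
})

test_that("Benjamini-Hochberg matches the hand step-up computation", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  bh <- bhCorrect(p)
  expect_equal(bh$q, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bhCorrect(rep(1, 6))$significant))
  # order invariance
  set.seed(81)
  p2 <- runif(40)^2
  perm <- sample(40)
  direct <- bhCorrect(p2)
  permuted <- bhCorrect(p2[perm])
  expect_equal(permuted$q[order(perm)], direct$q)
  # independent step-up oracle, computed from the definition
  m <- length(p2)
  o <- order(p2)
  qOracle <- rev(cummin(rev(p2[o] * m / seq_len(m))))
  expect_equal(direct$q[o], pmin(qOracle, 1))
  expect_error(bhCorrect(numeric(0)), "empty")
})

test_that("region chaining matches a brute-force interval merge", {
  rec <- data.frame(
    chrom = c(rep("1", 6), "2"),
    bp = c(1e6, 1.5e6, 2e6, 2.4e6, 3e6, 13e6, 1e6),
    thetaSite = 0.8, p = 1e-5,
    significant = TRUE)
  reg <- clusterRegions(rec, minCluster = 5, maxGapBp = 2e6)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$nSnps, 5)
  expect_equal(reg$startBp, 1e6)
  expect_equal(reg$endBp, 3e6)
  expect_equal(reg$meanAncestryPct, 80)
  # below min_cluster: no region
  expect_equal(nrow(clusterRegions(rec[1:4, ])), 0)

  # randomized brute-force chaining oracle
  set.seed(82)
  rnd <- data.frame(
    chrom = sample(c("1", "2"), 200, replace = TRUE),
    bp = sample.int(5e7, 200),
    thetaSite = runif(200), p = runif(200)^3)
  rnd$significant <- rnd$p < 0.05
  got <- clusterRegions(rnd, minCluster = 3, maxGapBp = 3e6)
  sig <- rnd[rnd$significant, ]
  sig <- sig[order(sig$chrom, sig$bp), ]
  chains <- list(); cur <- sig[1, , drop = FALSE]
  for (i in seq_len(nrow(sig))[-1]) {
    if (sig$chrom[i] == cur$chrom[nrow(cur)] &&
        sig$bp[i] - cur$bp[nrow(cur)] <= 3e6) {
      cur <- rbind(cur, sig[i, ])
    } else {
      chains[[length(chains) + 1]] <- cur
      cur <- sig[i, , drop = FALSE]
    }
  }
  chains[[length(chains) + 1]] <- cur
  keep <- Filter(function(ch) nrow(ch) >= 3, chains)
  expect_equal(nrow(got), length(keep))
  expect_equal(got$nSnps, vapply(keep, nrow, integer(1)))
  expect_equal(got$startBp, vapply(keep, function(ch) min(ch$bp),
                                   numeric(1)))
})

test_that("binomial imbalance tails match exact enumeration", {
  # two lines, total imbalance: 2 of 4 equally likely outcomes
  expect_equal(binomialImbalanceProbability(2, 1.0), 0.5)
  # full enumeration at n = 10, 80% imbalance
  expect_equal(binomialImbalanceProbability(10, 0.8), 112 / 1024)
  # monotone decreasing in fraction and in panel size
  expect_gt(binomialImbalanceProbability(122, 0.7),
            binomialImbalanceProbability(122, 0.8))
  expect_gt(binomialImbalanceProbability(60, 0.8),
            binomialImbalanceProbability(122, 0.8))
  expect_equal(binomialImbalanceProbability(10, 0.8, oneSided = TRUE),
               56 / 1024)
  expect_error(binomialImbalanceProbability(10, 0.4), "fraction")
})

test_that("expected distorted SNP counts scale linearly", {
  expect_equal(expectedDistortedSnps(0, 1e-6), 0)
  expect_equal(expectedDistortedSnps(1e6, 1e-6), 1)
  # at the 122-line panel's 80% imbalance probability, 200k SNPs give
  # an expectation under 2e-6 genome-wide
  e <- expectedDistortedSnps(2e5, binomialImbalanceProbability(122, 0.8))
  expect_gt(e, 1e-6)
  expect_lt(e, 2e-6)
})

test_that("a simulated transmission-biased locus tops the Wald scan", {
  sel <- simulateRiPanel(panelSpec(
    nStrains = 100,
    chromosomes = data.frame(label = paste0("chr", 1:3), lengthCm = 70,
                             nSnps = 150),
    selection = data.frame(chrom = "chr2", snp = 75, favored = "alt",
                           s = 0.9),
    seed = 83))
  fr <- siteAncestryFrequency(sel$panel,
                              list(all = seq_len(nSnps(sel$panel))),
                              rep("all", 100))
  rec <- waldScan(fr$thetaSite, snpInfo = snpInfo(sel$panel))
  selIdx <- 150 + 75
  expect_gte(rec$W[selIdx], max(rec$W) - 1e-12)
  # p-values away from the selected chromosome remain calibrated or
  # conservative under the global-variance convention
  offChrom <- rec$p[rec$chrom != "chr2"]
  expect_lt(genomicInflation(offChrom), 1.2)
})
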