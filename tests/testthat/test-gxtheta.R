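test_that("with identity kinship the LRT equals the nested-OLS statistic", {
  set.seed(61)
  n <- 80
  for (rep in 1:5) {
    x <- rbinom(n, 1, 0.5)
    th <- runif(n)
    y <- rnorm(n) + 0.3 * x
    res <- gxthetaTest(y, x, th, K = diag(n))
    f1 <- stats::lm.fit(cbind(1, x, th, th * x), y)
    f0 <- stats::lm.fit(cbind(1, x, th), y)
    lrtOLS <- n * log(sum(f0$residuals^2) / sum(f1$residuals^2))
    expect_equal(res$lrt, lrtOLS, tolerance = 1e-6)
    expect_equal(res$pGxt, pchisq(lrtOLS, 1, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("the LRT is invariant to affine y rescaling and theta centering", {
  sim <- riPanelSmall()
  set.seed(62)
  x <- dosages(sim$panel)[, 30]
  th <- sim$trueTheta
  y <- rnorm(nSamples(sim$panel))
  base <- gxthetaTest(y, x, th, K = sim$K)$lrt
  expect_equal(gxthetaTest(5 * y - 2, x, th, K = sim$K)$lrt, base,
               tolerance = 1e-6)
  expect_equal(gxthetaTest(y, x, th - mean(th), K = sim$K)$lrt, base,
               tolerance = 1e-6)
  expect_equal(gxthetaTest(y, x, th, K = sim$K, centerTheta = TRUE)$lrt,
               base, tolerance = 1e-6)
})

test_that("degenerate inputs raise informative errors", {
  n <- 30
  y <- rnorm(n); th <- runif(n)
  expect_error(gxthetaTest(y, rep(1, n), th, K = diag(n)), "invariant")
  expect_error(gxthetaTest(y, rbinom(n, 1, 0.5), rep(0.5, n),
                           K = diag(n)),
               "ancestry variance")
  # theta*x collinear with existing columns: x nonzero for one sample
  x <- c(1, rep(0, n - 1))
  expect_error(gxthetaTest(y, x, th, K = diag(n), snpId = "badSnp"),
               "badSnp")
})

test_that("exact per-SNP refitting agrees with the held-covariance fit", {
  sim <- riPanelSmall()
  set.seed(63)
  x <- dosages(sim$panel)[, 10]
  y <- simulatePhenotype(x, sim$trueTheta, sim$K, beta = 0.4)
  a <- gxthetaTest(y, x, sim$trueTheta, K = sim$K)
  b <- gxthetaTest(y, x, sim$trueTheta, K = sim$K, exact = TRUE)
  expect_gte(b$lrt, 0)
  # the approximation and the exact fit agree closely under the null fit
  expect_lt(abs(a$lrt - b$lrt), 0.5)
})

test_that("null interaction p-values are uniform (KS) and calibrated", {
  sim <- riPanel100()
  Km <- kinshipValues(sim$K)
  elig <- which(snpMaf(sim$panel) > 0.25)
  d <- dosages(sim$panel)
  set.seed(64)
  p <- replicate(600, {
    y <- simulatePhenotype(rep(0, 100), NULL, Km, cholCov = sim$cholK)
    x <- d[, sample(elig, 1)]
    gxthetaTest(y / sd(y), x, sim$trueTheta, K = Km,
                eigenK = sim$eigenK)$pGxt
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  t1 <- mean(p < 0.05)
  expect_lt(abs(t1 - 0.05), 3 * sqrt(0.05 * 0.95 / 600))
})

test_that("a pure main effect does not inflate the interaction test", {
  sim <- riPanel100()
  Km <- kinshipValues(sim$K)
  elig <- which(snpMaf(sim$panel) > 0.25)
  d <- dosages(sim$panel)
  set.seed(65)
  pI <- replicate(400, {
    x <- d[, sample(elig, 1)]
    y <- simulatePhenotype(x, NULL, Km, beta = 1, cholCov = sim$cholK)
    gxthetaTest(y / sd(y), x, sim$trueTheta, K = Km,
                eigenK = sim$eigenK)$pGxt
  })
  expect_lt(mean(pI < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("interaction power grows with the interaction effect size", {
  sim <- riPanel100()
  Km <- kinshipValues(sim$K)
  elig <- which(snpMaf(sim$panel) > 0.25)
  d <- dosages(sim$panel)
  powerAt <- function(b, reps = 200) {
    set.seed(66)
    replicate(reps, {
      x <- d[, sample(elig, 1)]
      y <- simulatePhenotype(x, sim$trueTheta, Km, betaGxt = b,
                             cholCov = sim$cholK)
      gxthetaTest(y / sd(y), x, sim$trueTheta, K = Km,
                  eigenK = sim$eigenK)$pGxt
    })
  }
  # on the [0,1] ancestry scale the interaction non-centrality is about
  # 0.5 * n * var(theta) * betaGxt^2 after GLS attenuation, so power is
  # modest at small effects and saturates by betaGxt ~ 5
  p08 <- powerAt(0.8); p3 <- powerAt(3); p5 <- powerAt(5)
  expect_lt(mean(p08), 0.5)           # shifted off the uniform null
  expect_gt(mean(p3 < 0.05), mean(p08 < 0.05))
  expect_gt(mean(p5 < 0.05), 0.9)
  expect_lt(median(p5), 1e-3)
})

test_that("genome scans are deterministic, recover spiked SNPs, and stay calibrated", {
  sim <- riPanelSmall()
  d <- dosages(sim$panel)
  set.seed(67)
  # permuted-phenotype null scan
  yNull <- simulatePhenotype(rep(0, 40), NULL, sim$K)[sample(40)]
  s1 <- genomeScan(yNull, sim$panel, sim$trueTheta, K = sim$K)
  s2 <- genomeScan(yNull, sim$panel, sim$trueTheta, K = sim$K)
  expect_identical(s1$results, s2$results)
  expect_equal(s1$summary$nSnpsTested,
               nSnps(filterMaf(sim$panel, 0.05)))

  # spike a strong interaction at a known SNP
  j <- which(snpMaf(sim$panel) > 0.4)[5]
  y <- simulatePhenotype(d[, j], sim$trueTheta, sim$K, betaGxt = 6,
                         sigmaG2 = 0.1, sigmaE2 = 0.1)
  sSpike <- genomeScan(y, sim$panel, sim$trueTheta, K = sim$K)
  top <- sSpike$results$snp_id[which.min(sSpike$results$p_gxt)]
  # LD neighbours are near-perfect proxies; the hit must be at or next
  # to the spiked SNP
  jTop <- match(top, snpInfo(sim$panel)$snpId)
  expect_lte(abs(jTop - j), 2)
  expect_output(print(sSpike), "Gxtheta scan")
})

test_that("permuted-phenotype scans pool to a calibrated inflation factor", {
  sim <- riPanel100()
  Km <- kinshipValues(sim$K)
  # a single scan's lambda fluctuates widely because linked SNPs share
  # p-values; pooling a few permutations restores enough effectively
  # independent loci to bound it
  set.seed(70)
  pooled <- unlist(lapply(1:4, function(i) {
    y <- simulatePhenotype(rep(0, 100), NULL, Km,
                           cholCov = sim$cholK)[sample(100)]
    genomeScan(y, sim$panel, sim$trueTheta, K = sim$K)$results$p_gxt
  }))
  lam <- genomicInflation(pooled)
  expect_gt(lam, 0.8)
  expect_lt(lam, 1.2)
})

test_that("missing phenotypes are dropped pairwise and scans align samples", {
  sim <- riPanelSmall()
  y <- simulatePhenotype(rep(0, 40), NULL, sim$K, seed = 68)
  y[1:5] <- NA
  s <- genomeScan(y, sim$panel, sim$trueTheta, K = sim$K)
  expect_true(all(s$results$n_used == 35))
  expect_error(genomeScan(c(rep(NA, 38), 1, 2), sim$panel,
                          sim$trueTheta, K = sim$K),
               "fewer than 3")
})

test_that("genomic inflation matches its definition and is monotone", {
  expect_equal(genomicInflation(0.5), 1)
  set.seed(69)
  u <- runif(1e5)
  expect_equal(genomicInflation(u), 1, tolerance = 0.02)
  expect_gt(genomicInflation(u / 2), genomicInflation(u))
  expect_error(genomicInflation(numeric(0)), "no finite")
})

test_that("replication counting reproduces the exact binomial tail", {
  # 305 of 1486 discovery associations replicating at alpha = 0.05:
  # fraction prints as 21% and the binomial tail is far below 2.2e-16
  r <- replicationBinomial(1486, 305, 0.05)
  expect_equal(round(100 * r$fraction), 21)
  expect_lte(r$binomialP, 2.2e-16)
  # replication exactly at the chance rate is not significant
  rNull <- replicationBinomial(1000, 50, 0.05)
  expect_gte(rNull$binomialP, 0.4)
  # hand enumeration over Binomial(10, 0.05)
  pHand <- sum(sapply(3:10, function(k)
    choose(10, k) * 0.05^k * 0.95^(10 - k)))
  expect_equal(replicationBinomial(10, 3, 0.05)$binomialP, pHand,
               tolerance = 1e-12)
  expect_error(replicationBinomial(0, 0), "positive")

  # scan-level interface matches the count-level interface
  a <- data.frame(snp_id = paste0("s", 1:20), p_gxt = runif(20))
  b <- data.frame(snp_id = paste0("s", 20:1), p_gxt = runif(20))
  rr <- replicationRate(a, b, alpha = 0.5)
  expect_equal(rr$nTotal, 20L)
  expect_equal(rr$nReplicated,
               sum(b$p_gxt[match(a$snp_id, b$snp_id)] < 0.5))
})
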