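test_that("informative sites are exactly the differing homozygous sites", {
  expect_length(informativeSites(rep(1, 10), rep(1, 10))$sites, 0)
  s <- informativeSites(c(1, 1, 0, 1), c(0, 1, 1, 1))
  expect_equal(s$sites, c(1L, 3L))
  expect_equal(s$refDosage, c(1, 0))
  # heterozygous or missing parent calls are skipped
  s2 <- informativeSites(c(1, 0.5, NA, 1), c(0, 0, 0, 0))
  expect_equal(s2$sites, c(1L, 4L))

  set.seed(21)
  pa <- sample(c(0, 1), 200, replace = TRUE)
  pb <- sample(c(0, 1), 200, replace = TRUE)
  # brute-force oracle: elementwise inequality scan
  oracle <- which(sapply(seq_len(200), function(i) pa[i] != pb[i]))
  expect_equal(informativeSites(pa, pb)$sites, oracle)
})

test_that("theta is the mean reference-founder dosage over informative sites", {
  pa <- c(1, 1, 0, 0, 1)
  pb <- c(0, 0, 1, 1, 1)
  sites <- informativeSites(pa, pb)
  info <- data.frame(snpId = paste0("s", 1:5), chrom = "1",
                     bp = 1:5 * 10L)
  # offspring identical to the reference parent has theta 1
  g <- GenotypePanel(rbind(pa, pb, (pa + pb) / 2), info,
                     c("refLike", "altLike", "f1"))
  anc <- computeTheta(g, sites)
  expect_equal(theta(anc), c(1, 0, 0.5))
  expect_equal(anc@nSites, rep(4L, 3))
  # missing cells are excluded per individual
  gm <- GenotypePanel(rbind(c(1, NA, 1, 0, 1)), info, "m")
  expect_equal(theta(computeTheta(gm, sites)),
               mean(c(1, 0, 1)))  # site 3 ref founder carries 0 -> flip
  gz <- GenotypePanel(rbind(c(NA, NA, NA, NA, 1)), info, "z")
  expect_error(computeTheta(gz, sites), "z")
  expect_error(computeTheta(g, informativeSites(pa, pa)), "no ancestry")
})

test_that("theta is permutation invariant and founder-swap maps to 1-theta", {
  sim <- riPanelSmall()
  pa <- rep(1, nSnps(sim$panel)); pb <- rep(0, nSnps(sim$panel))
  anc <- computeTheta(sim$panel, informativeSites(pa, pb, "A"))
  set.seed(31)
  perm <- sample(nSnps(sim$panel))
  ancPerm <- computeTheta(sim$panel[, perm],
                          informativeSites(pa[perm], pb[perm], "A"))
  expect_equal(theta(ancPerm), theta(anc))
  ancSwap <- computeTheta(sim$panel, informativeSites(pa, pb, "B"))
  expect_equal(theta(ancSwap), 1 - theta(anc))
})

test_that("called theta matches simulator truth and panel mean is near 0.5", {
  sim <- riPanel100()
  pa <- rep(1, nSnps(sim$panel)); pb <- rep(0, nSnps(sim$panel))
  anc <- computeTheta(sim$panel, informativeSites(pa, pb))
  # every SNP is informative in a single cross: calls equal truth exactly
  expect_equal(theta(anc), sim$trueTheta, tolerance = 1 / nSnps(sim$panel))
  se <- sd(sim$trueTheta) / sqrt(length(sim$trueTheta))
  expect_lt(abs(mean(theta(anc)) - 0.5), 3 * se + 1e-12)
})

test_that("per-site frequency respects cross eligibility", {
  info <- data.frame(snpId = paste0("s", 1:3), chrom = "1",
                     bp = 1:3 * 10L)
  g <- GenotypePanel(rbind(c(1, 1, 1), c(1, 0, 1),
                           c(0, 1, 1), c(0, 1, 1)),
                     info, c("a", "b", "c", "d"))
  memb <- c("c1", "c1", "c2", "c2")
  # s2 segregates only in cross 1: cross-2 strains are excluded from it
  elig <- list(c1 = 1:2, c2 = integer(0))
  fr <- siteAncestryFrequency(g, elig, memb)
  expect_equal(fr$thetaSite, c(1, 0.5, NA))   # s3 eligible nowhere
  expect_equal(fr$nEligible, c(2, 2, 0))
  # balanced single-cross site
  fr1 <- siteAncestryFrequency(
    GenotypePanel(cbind(c(1, 1, 0, 0)),
                  data.frame(snpId = "s", chrom = "1", bp = 1L)),
    list(all = 1L), rep("all", 4))
  expect_equal(fr1$thetaSite, 0.5)
  expect_error(siteAncestryFrequency(g, elig, c("c1", "c1", "cX", "c2")),
               "cX")
})

test_that("panel-mean theta equals site-frequency mean when fully observed", {
  sim <- riPanelSmall()
  pa <- rep(1, nSnps(sim$panel)); pb <- rep(0, nSnps(sim$panel))
  anc <- computeTheta(sim$panel, informativeSites(pa, pb))
  fr <- siteAncestryFrequency(sim$panel,
                              list(all = seq_len(nSnps(sim$panel))),
                              rep("all", nSamples(sim$panel)))
  expect_equal(mean(theta(anc)), mean(fr$thetaSite))
})

test_that("a selected locus shifts its site frequency above the panel mean", {
  sel <- simulateRiPanel(panelSpec(
    nStrains = 80,
    chromosomes = data.frame(label = paste0("chr", 1:2), lengthCm = 60,
                             nSnps = 100),
    selection = data.frame(chrom = "chr1", snp = 50, favored = "ref",
                           s = 0.9),
    seed = 99))
  fr <- colMeans(dosages(sel$panel))
  se <- sqrt(0.25 / 80)
  expect_gt(fr[50], 0.5 + 3 * se)
  # away from the selected chromosome the frequencies stay near 0.5;
  # sites within a chromosome are in strong LD, so the mean frequency
  # has roughly the sampling error of a few independent blocks (~0.03)
  other <- fr[101:200]
  expect_lt(abs(mean(other) - 0.5), 0.15)
})
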