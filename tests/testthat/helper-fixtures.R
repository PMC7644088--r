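# Shared fixtures, built once per test run and memoised.  All panels are
# generated in code from fixed seeds; no data files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) assign(name, builder(), envir = .fx)
  .fx[[name]]
}

# the default study panel: 100 RI strains, 5 x 80 cM x 400 SNPs
riPanel100 <- function() fixture("ri100", function() {
  sim <- simulateRiPanel(panelSpec(nStrains = 100, seed = 42))
  sim$K <- computeGrm(sim$panel)
  sim$eigenK <- eigen(kinshipValues(sim$K), symmetric = TRUE)
  sim$cholK <- phenotypeCovChol(sim$K)
  sim
})

# small, fast panel for unit-level checks
riPanelSmall <- function() fixture("riSmall", function() {
  sim <- simulateRiPanel(panelSpec(
    nStrains = 40,
    chromosomes = data.frame(label = paste0("chr", 1:3), lengthCm = 60,
                             nSnps = 120),
    seed = 7))
  sim$K <- computeGrm(sim$panel)
  sim
})

# two-cross panel with a distinct ancestry GRM
multiCross100 <- function() fixture("mc100", function() {
  mc <- simulateMultiCrossRiPanel(panelSpec(nStrains = 50, seed = 42),
                                  nCrosses = 2, segProb = 0.7)
  mc$K <- computeGrm(mc$panel)
  mc$KA <- ancestryGrm(mc$panel, mc$eligibility, mc$membership)
  mc$eigenK <- eigen(kinshipValues(mc$K), symmetric = TRUE)
  mc
})

# tiny deterministic genotype table used by io / filter tests
toyPanel <- function() {
  GenotypePanel(
    rbind(a = c(1, 1, 0, 0.5, 1),
          b = c(0, 1, 0, 0.5, NA),
          c = c(1, 1, 1, 0,   0),
          d = c(0, 1, 1, 1,   1)),
    data.frame(snpId = paste0("s", 1:5),
               chrom = c("1", "1", "1", "2", "2"),
               bp = c(100L, 200L, 300L, 100L, 250L)),
    c("a", "b", "c", "d"))
}
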