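# Transmission-ratio-distortion (allelic imbalance) scan.
#
# In a balanced biparental panel each locus is expected to show 50%
# founder ancestry.  Per-site founder frequencies theta_i are tested with
# the Wald statistic W = (thetaBar - theta_i)^2 / var(theta), where the
# denominator is the GLOBAL variance of theta_i across all sites: this
# assumes most sites are null and is conservative when that assumption is
# violated.  Discoveries are controlled by Benjamini-Hochberg at 5% and
# chained into distortion regions.

#' Wald scan for per-site ancestry-frequency distortion
#'
#' @param thetaSites numeric vector of per-site founder-ancestry
#'   frequencies in \[0,1\] (NA sites are carried through as NA).
#' @param thetaBar panel mean frequency; computed as the mean over sites
#'   when NULL (the per-SNP mean convention).
#' @param varTheta variance used in the denominator; the global variance
#'   of `thetaSites` when NULL.  Must be positive.
#' @param snpInfo optional data.frame (snpId, chrom, bp) carried into the
#'   output.
#' @param qTarget Benjamini-Hochberg FDR target for the significance
#'   flags (default 0.05).
#' @return data.frame: per site `thetaSite`, `W`, `p`, `q`,
#'   `significant`, plus any `snpInfo` columns.
#' @export
waldScan <- function(thetaSites, thetaBar = NULL, varTheta = NULL,
                     snpInfo = NULL, qTarget = 0.05) {
  ts <- as.numeric(thetaSites)
  obs <- !is.na(ts)
  if (!any(obs)) stop("no observed site frequencies")
  if (is.null(thetaBar)) thetaBar <- mean(ts[obs])
  if (is.null(varTheta)) varTheta <- stats::var(ts[obs])
  if (!is.finite(varTheta) || varTheta <= 0)
    stop("var(theta) must be positive")
  W <- (thetaBar - ts)^2 / varTheta
  p <- pchisq(W, 1, lower.tail = FALSE)
  bh <- bhCorrect(p[obs], qTarget)
  q <- rep(NA_real_, length(ts)); sig <- rep(NA, length(ts))
  q[obs] <- bh$q; sig[obs] <- bh$significant
  out <- data.frame(thetaSite = ts, W = W, p = p, q = q,
                    significant = sig)
  if (!is.null(snpInfo)) out <- cbind(as.data.frame(snpInfo), out)
  out
}

#' Benjamini-Hochberg step-up correction
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` returning both the
#' adjusted q-values and the significance mask at `qTarget`.
#'
#' @param p p-values in (0,1\].
#' @param qTarget FDR target (default 0.05).
#' @return list with `q` and `significant`.
#' @export
bhCorrect <- function(p, qTarget = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  q <- p.adjust(p, method = "BH")
  list(q = q, significant = q <= qTarget)
}

#' Chain significant distortion sites into regions
#'
#' Greedy single-linkage chaining of significant SNPs along each
#' chromosome: consecutive significant SNPs at most `maxGapBp` apart join
#' one chain; chains with at least `minCluster` members are reported.
#' The 2 Mb default gap reflects a typical RI-panel linkage
#' disequilibrium block size.
#'
#' @param records data.frame with columns `chrom`, `bp`, `thetaSite`,
#'   `p`, `significant` (e.g. [waldScan()] output plus coordinates),
#'   sorted or sortable by (chrom, bp).
#' @param minCluster minimum SNPs per region (default 5).
#' @param maxGapBp maximum within-region gap in bp (default 2e6).
#' @return data.frame: chrom, startBp, endBp, nSnps, meanAncestryPct,
#'   meanP.
#' @export
clusterRegions <- function(records, minCluster = 5, maxGapBp = 2e6) {
  need <- c("chrom", "bp", "thetaSite", "p", "significant")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  sig <- records[which(records$significant), , drop = FALSE]
  empty <- data.frame(chrom = character(), startBp = integer(),
                      endBp = integer(), nSnps = integer(),
                      meanAncestryPct = numeric(), meanP = numeric())
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$chrom, sig$bp), , drop = FALSE]
  newChain <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                        diff(sig$bp) > maxGapBp)
  chain <- cumsum(newChain)
  out <- do.call(rbind, lapply(split(sig, chain), function(ch) {
    if (nrow(ch) < minCluster) return(NULL)
    data.frame(chrom = ch$chrom[1], startBp = min(ch$bp),
               endBp = max(ch$bp), nSnps = nrow(ch),
               meanAncestryPct = 100 * mean(ch$thetaSite),
               meanP = mean(ch$p))
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

.logSumExp <- function(lx) {
  m <- max(lx)
  m + log(sum(exp(lx - m)))
}

#' Exact binomial tail probability of a founder-allele imbalance
#'
#' Models founder-allele balance across n independent inbred lines as
#' Bernoulli(p0) per line and returns the exact two-sided tail
#' probability of an imbalance at least as extreme as `fraction`:
#' P(X >= ceiling(fraction n)) + P(X <= floor((1-fraction) n)), summed in
#' log space.  `oneSided = TRUE` returns the upper tail only.
#'
#' @param nLines number of lines (>= 1).
#' @param fraction imbalance fraction in (0.5, 1\].
#' @param p0 per-line founder probability under the null (default 0.5).
#' @param oneSided upper tail only.
#' @return tail probability.
#' @export
binomialImbalanceProbability <- function(nLines, fraction, p0 = 0.5,
                                         oneSided = FALSE) {
  stopifnot(nLines >= 1)
  if (fraction <= 0.5 || fraction > 1)
    stop("fraction must lie in (0.5, 1]")
  kUp <- ceiling(fraction * nLines - 1e-9)
  kDown <- nLines - kUp
  upper <- exp(.logSumExp(dbinom(kUp:nLines, nLines, p0, log = TRUE)))
  if (oneSided) return(upper)
  lower <- exp(.logSumExp(dbinom(0:kDown, nLines, p0, log = TRUE)))
  upper + lower
}

#' Expected number of distorted SNPs genome-wide
#'
#' nSnps x perSnpProbability: the expectation under independence of
#' sites.  Linked sites are positively dependent, so this is an
#' approximation of the genome-wide expectation, not of its variance.
#'
#' @param nSnps number of SNPs scanned (>= 0).
#' @param perSnpProbability per-site tail probability, e.g. from
#'   [binomialImbalanceProbability()].
#' @return expected count.
#' @export
expectedDistortedSnps <- function(nSnps, perSnpProbability) {
  stopifnot(nSnps >= 0, perSnpProbability >= 0, perSnpProbability <= 1)
  nSnps * perSnpProbability
}
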