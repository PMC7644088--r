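# The Gxtheta likelihood-ratio test and genome scan.
#
# Per SNP the alternative model is
#   y = mu + C g + beta_G x + delta theta + beta_Gxt (theta * x) + u + e
# and the null drops only the interaction term.  Variance components are
# estimated once per trait under the no-SNP covariate model and the fitted
# covariance is held fixed for all per-SNP generalized least squares fits
# (EMMAX-style); with the scale profiled per model the LRT statistic is
# n * log(RSS_null / RSS_alt), which for K = I is exactly the classic
# nested-OLS likelihood-ratio statistic.  `exact = TRUE` re-optimizes the
# variance components under both fixed-effect models for every SNP.

.P_FLOOR <- 1e-300

.thetaVec <- function(anc) {
  if (is(anc, "AncestryEstimate")) theta(anc) else as.numeric(anc)
}

# GLS fits of null/alt whitened designs; returns LRT + alt coefficients
.gxtCore <- function(yw, baseW, xw, txw, snpId = "x") {
  n <- length(yw)
  Xn <- cbind(baseW, x = xw)
  Xa <- cbind(Xn, tx = txw)
  p <- ncol(Xa)
  fa <- stats::lm.fit(Xa, yw)
  if (fa$rank < p)
    stop("interaction regressor collinear with model columns at SNP ",
         snpId)
  f0 <- stats::lm.fit(Xn, yw)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(fa$residuals^2)
  lrt <- n * (log(rss0) - log(rss1))
  if (lrt < 0) {
    if (lrt < -1e-8) stop("negative LRT beyond tolerance")
    lrt <- 0
  }
  piv <- fa$qr$pivot
  xtxinv <- chol2inv(qr.R(fa$qr))[order(piv), order(piv), drop = FALSE]
  s2 <- rss1 / (n - p)
  co <- fa$coefficients
  seG <- sqrt(s2 * xtxinv[p - 1, p - 1])
  zG <- co[[p - 1]] / seG
  list(betaG = co[[p - 1]], delta = co[["theta"]], betaGxt = co[[p]],
       lrt = lrt,
       pGxt = max(pchisq(lrt, 1, lower.tail = FALSE), .P_FLOOR),
       pG = max(2 * pnorm(-abs(zG)), .P_FLOOR))
}

#' Test one SNP for interaction with global ancestry (the Gxtheta test)
#'
#' Likelihood-ratio test of beta_Gxt = 0 in the kinship-corrected model
#' `y = mu + C + beta_G x + delta theta + beta_Gxt theta*x + u + e`,
#' with `Var(u) = sigmaG2 K (+ sigmaTheta2 KA)`.  The statistic is referred
#' to chi-square with 1 df; the main-effect p-value is the Wald z of
#' beta_G in the alternative model.
#'
#' @param y numeric trait vector (no missing values among analyzed
#'   samples).
#' @param x SNP dosage vector on \[0,1\]; must not be constant.
#' @param anc an [AncestryEstimate-class] or numeric theta vector; must
#'   not be constant.
#' @param covariates optional covariate matrix (e.g. sex); no intercept.
#' @param K a [Kinship-class] or matrix.
#' @param KA optional second (ancestry) GRM.
#' @param vc optional precomputed [fitVarianceComponents()] result for
#'   this trait (saves refitting in simulation loops).
#' @param exact re-optimize variance components under both null and
#'   alternative fixed-effect models (slower, no EMMAX approximation).
#' @param eigenK optional precomputed `eigen(K, symmetric = TRUE)` shared
#'   across simulation replicates.
#' @param centerTheta center theta at its mean before building the
#'   regressors.  The LRT is invariant to this choice; it affects only
#'   the main-effect Wald statistic (centering removes most of the
#'   collinearity between x and theta*x) and the interpretation of
#'   beta_G and delta.  Default FALSE: delta absorbs the location.
#' @param snpId label used in messages and output.
#' @return list with `snpId`, `betaG`, `delta`, `betaGxt`, `lrt`, `pGxt`,
#'   `pG`, `nUsed`.
#' @export
gxthetaTest <- function(y, x, anc, covariates = NULL, K, KA = NULL,
                        vc = NULL, exact = FALSE, eigenK = NULL,
                        centerTheta = FALSE, snpId = "x") {
  y <- as.numeric(y); x <- as.numeric(x)
  th <- .thetaVec(anc)
  if (centerTheta) th <- th - mean(th)
  n <- length(y)
  stopifnot(length(x) == n, length(th) == n)
  if (stats::var(x) == 0) stop("SNP ", snpId, " is invariant among samples")
  if (stats::var(th) == 0)
    stop("theta is constant; the Gxtheta test is undefined without ",
         "ancestry variance")
  covTh <- cbind(covariates, theta = th)
  if (exact) {
    vcN <- fitVarianceComponents(y, cbind(covTh, x = x), K, KA,
                                 eigenK = eigenK)
    vcA <- fitVarianceComponents(y, cbind(covTh, x = x, tx = th * x),
                                 K, KA, eigenK = eigenK)
    lrt <- 2 * (vcA$logLik - vcN$logLik)
    if (lrt < 0) lrt <- max(lrt, 0)
    M <- vcA$whiten
    res <- .gxtCore(drop(M %*% y), M %*% .designMatrix(n, covTh),
                    drop(M %*% x), drop(M %*% (th * x)), snpId)
    res$lrt <- lrt
    res$pGxt <- max(pchisq(lrt, 1, lower.tail = FALSE), .P_FLOOR)
  } else {
    if (is.null(vc))
      vc <- fitVarianceComponents(y, covTh, K, KA, eigenK = eigenK)
    M <- vc$whiten
    res <- .gxtCore(drop(M %*% y), M %*% .designMatrix(n, covTh),
                    drop(M %*% x), drop(M %*% (th * x)), snpId)
  }
  c(list(snpId = snpId), res, list(nUsed = n))
}

#' Genome-wide Gxtheta scan for one trait
#'
#' Runs the Gxtheta test at every MAF-passing SNP of a panel and
#' summarizes calibration (genomic inflation of the main-effect and
#' interaction p-value sets) and hits at the configured significance
#' threshold.  Samples with missing trait values are dropped pairwise;
#' dosages are mean-imputed for testing; SNPs constant among analyzed
#' samples are skipped.
#'
#' @param y numeric trait vector aligned to the panel samples (NAs
#'   dropped); at least 3 non-missing values required.
#' @param g a [GenotypePanel-class].
#' @param anc an [AncestryEstimate-class] or theta vector for all panel
#'   samples.
#' @param K optional precomputed [Kinship-class] (computed from `g` when
#'   NULL).
#' @param KA optional ancestry GRM for the two-GRM model.
#' @param covariates optional covariate matrix for all panel samples.
#' @param mafMin minor-allele-frequency threshold (default 0.05, the
#'   genome-scan convention).
#' @param threshold genome-wide significance threshold on the interaction
#'   p-value (default 4.2e-6, the RI-panel convention; 8.06e-6 is the
#'   advanced-intercross convention).
#' @param fdr use per-scan Benjamini-Hochberg control at 5% instead of the
#'   fixed threshold.
#' @param centerTheta see [gxthetaTest()].
#' @return list of class `gxthetaScan` with `results` (data.frame: snp_id,
#'   chrom, bp, beta_g, delta, beta_gxt, lrt, p_gxt, p_g, n_used,
#'   significant) and `summary` (lambdaGC, lambdaGxtC, nSnpsTested,
#'   threshold, nHits).
#' @export
genomeScan <- function(y, g, anc, K = NULL, KA = NULL, covariates = NULL,
                       mafMin = 0.05, threshold = 4.2e-6, fdr = FALSE,
                       centerTheta = FALSE) {
  stopifnot(is(g, "GenotypePanel"))
  y <- as.numeric(y)
  th <- .thetaVec(anc)
  if (centerTheta) th <- th - mean(th, na.rm = TRUE)
  stopifnot(length(y) == nSamples(g), length(th) == nSamples(g))
  nAll <- nSamples(g)
  use <- which(!is.na(y) & !is.na(th))
  if (length(use) < 3) stop("fewer than 3 non-missing trait values")
  g <- g[use, ]
  y <- y[use]; th <- th[use]
  if (!is.null(covariates))
    covariates <- as.matrix(covariates)[use, , drop = FALSE]
  if (stats::var(th) == 0)
    stop("theta is constant; the Gxtheta test is undefined without ",
         "ancestry variance")
  subsetK <- function(K) {
    m <- .asKmat(K)
    if (nrow(m) == length(use)) m
    else if (nrow(m) == nAll) m[use, use, drop = FALSE]
    else stop("kinship must be aligned to panel samples")
  }
  Km <- if (is.null(K)) .asKmat(computeGrm(g)) else subsetK(K)
  KAm <- if (is.null(KA)) NULL else subsetK(KA)
  gKeep <- filterMaf(g, mafMin = mafMin)
  if (nSnps(gKeep) == 0) {
    warning("no SNPs pass the MAF filter; empty scan")
    return(structure(list(results = data.frame(),
                          summary = list(lambdaGC = NA, lambdaGxtC = NA,
                                         nSnpsTested = 0L,
                                         threshold = threshold,
                                         nHits = 0L)),
                     class = "gxthetaScan"))
  }
  D <- meanImpute(gKeep)
  poly <- apply(D, 2, stats::var) > 0
  D <- D[, poly, drop = FALSE]
  info <- snpInfo(gKeep)[poly, , drop = FALSE]
  n <- length(y)
  vc <- fitVarianceComponents(y, cbind(covariates, theta = th), Km, KAm)
  M <- vc$whiten
  yw <- drop(M %*% y)
  baseW <- M %*% .designMatrix(n, cbind(covariates, theta = th))
  Xw <- M %*% D
  TXw <- M %*% (th * D)
  m <- ncol(D)
  out <- data.frame(snp_id = info$snpId, chrom = info$chrom, bp = info$bp,
                    beta_g = NA_real_, delta = NA_real_,
                    beta_gxt = NA_real_, lrt = NA_real_, p_gxt = NA_real_,
                    p_g = NA_real_, n_used = n)
  for (j in seq_len(m)) {
    r <- tryCatch(.gxtCore(yw, baseW, Xw[, j], TXw[, j], info$snpId[j]),
                  error = function(e) NULL)
    if (is.null(r)) next
    out$beta_g[j] <- r$betaG; out$delta[j] <- r$delta
    out$beta_gxt[j] <- r$betaGxt; out$lrt[j] <- r$lrt
    out$p_gxt[j] <- r$pGxt; out$p_g[j] <- r$pG
  }
  ok <- !is.na(out$p_gxt)
  out$significant <- FALSE
  if (fdr) {
    out$significant[ok] <- p.adjust(out$p_gxt[ok], "BH") <= 0.05
  } else {
    out$significant[ok] <- out$p_gxt[ok] < threshold
  }
  summ <- list(lambdaGC = genomicInflation(out$p_g[ok]),
               lambdaGxtC = genomicInflation(out$p_gxt[ok]),
               nSnpsTested = sum(ok), threshold = threshold,
               nHits = sum(out$significant))
  structure(list(results = out, summary = summ, vc = vc),
            class = "gxthetaScan")
}

#' @export
print.gxthetaScan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Gxtheta scan: %d SNPs tested, lambda_GC=%.3f lambda_GxtC=%.3f, %d hit(s) at %.3g\n",
    s$nSnpsTested, s$lambdaGC, s$lambdaGxtC, s$nHits, s$threshold))
  invisible(x)
}

#' Genomic inflation factor of a set of p-values
#'
#' lambda = median of the chi-square(1) quantiles implied by the p-values,
#' divided by the chi-square(1) median (~0.4549).  Values near 1 indicate
#' calibrated statistics.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return lambda (positive scalar).
#' @export
genomicInflation <- function(p) {
  p <- p[is.finite(p)]
  if (!length(p)) stop("no finite p-values")
  stats::median(qchisq(p, 1, lower.tail = FALSE)) /
    qchisq(0.5, 1, lower.tail = FALSE)
}

#' Exact binomial replication test
#'
#' One-sided (greater) exact binomial test that `nReplicated` of `nTotal`
#' discovery-cohort associations re-attain p < alpha in a second cohort
#' more often than the chance rate alpha.
#'
#' @param nTotal number of discovery associations examined.
#' @param nReplicated number with replication-cohort p < alpha.
#' @param alpha nominal replication level (default 0.05).
#' @return list with `nTotal`, `nReplicated`, `fraction`, `binomialP`.
#' @export
replicationBinomial <- function(nTotal, nReplicated, alpha = 0.05) {
  if (nTotal <= 0) stop("nTotal must be positive")
  stopifnot(nReplicated >= 0, nReplicated <= nTotal)
  p <- pbinom(nReplicated - 1, nTotal, alpha, lower.tail = FALSE)
  list(nTotal = as.integer(nTotal), nReplicated = as.integer(nReplicated),
       fraction = nReplicated / nTotal, binomialP = p)
}

#' Cross-cohort replication rate of Gxtheta associations
#'
#' Matches the discovery-cohort association keys (snp_id, falling back to
#' row order when absent) into the replication cohort's scan and counts
#' those with interaction p < alpha there, with an exact one-sided
#' binomial test against chance replication at rate alpha.
#'
#' @param resultsA discovery associations: a `gxthetaScan` or data.frame
#'   with columns `snp_id` and `p_gxt` (all rows are treated as the
#'   discovery set).
#' @param resultsB replication cohort scan (same types).
#' @param alpha replication significance level.
#' @return As [replicationBinomial()].
#' @export
replicationRate <- function(resultsA, resultsB, alpha = 0.05) {
  a <- if (inherits(resultsA, "gxthetaScan")) resultsA$results else resultsA
  b <- if (inherits(resultsB, "gxthetaScan")) resultsB$results else resultsB
  idx <- match(a$snp_id, b$snp_id)
  if (anyNA(idx)) stop("association keys missing from replication cohort")
  pb <- b$p_gxt[idx]
  replicationBinomial(length(idx), sum(pb < alpha, na.rm = TRUE), alpha)
}
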