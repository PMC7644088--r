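# Phenotype simulation and power machinery.
#
# Four generative models are supported, all with the SNP (or
# SNP-by-ancestry) fixed effect plus a zero-mean multivariate normal:
#   main-1K : y = beta * x          + mvn(0, sigmaG2 K + sigmaE2 I)
#   main-2K : y = beta * x          + mvn(0, sigmaG2 K + sigmaTheta2 KA + sigmaE2 I)
#   int-1K  : y = betaGxt * theta*x + mvn(0, sigmaG2 K + sigmaE2 I)
#   int-2K  : y = betaGxt * theta*x + mvn(0, sigmaG2 K + sigmaTheta2 KA + sigmaE2 I)
# with sigmaG2 = 0.4 and, when the ancestry variance term is present,
# sigmaTheta2 = 0.2; the residual takes the remainder so the variance
# fractions sum to 1.

#' Cholesky factor of a phenotype covariance
#'
#' Precomputes chol(sigmaG2 K + sigmaTheta2 KA + sigmaE2 I) for reuse
#' across simulation replicates.
#'
#' @param K genotype GRM ([Kinship-class] or matrix).
#' @param KA optional ancestry GRM (required when sigmaTheta2 > 0).
#' @param sigmaG2,sigmaTheta2,sigmaE2 variance components.
#' @return upper-triangular Cholesky factor, or NULL when all variance
#'   components are zero.
#' @export
phenotypeCovChol <- function(K, KA = NULL, sigmaG2 = 0.4,
                             sigmaTheta2 = 0, sigmaE2 = 0.6) {
  if (sigmaTheta2 > 0 && is.null(KA))
    stop("sigmaTheta2 > 0 requires an ancestry GRM (KA)")
  n <- nrow(.asKmat(K))
  S <- sigmaG2 * .asKmat(K)
  if (sigmaTheta2 > 0) S <- S + sigmaTheta2 * .asKmat(KA)
  diag(S) <- diag(S) + sigmaE2
  if (all(S == 0)) return(NULL)
  tryCatch(chol(S),
           error = function(e)
             stop("phenotype covariance is not positive definite: ",
                  conditionMessage(e)))
}

#' Simulate one phenotype from the mixed-model generative process
#'
#' y = beta * x + betaGxt * theta * x + mvn(0, sigmaG2 K + sigmaTheta2 KA
#' + sigmaE2 I).  Setting a seed makes the draw reproducible; otherwise
#' the current RNG stream is consumed (one n-vector of standard normals
#' per call).
#'
#' @param x SNP dosage vector.
#' @param anc [AncestryEstimate-class] or theta vector (used only when
#'   betaGxt != 0).
#' @param K,KA GRMs, see [phenotypeCovChol()].
#' @param beta main SNP effect size.
#' @param betaGxt SNP-by-ancestry interaction effect size.
#' @param sigmaG2,sigmaTheta2,sigmaE2 variance components (defaults 0.4,
#'   0, 0.6).
#' @param cholCov optional precomputed [phenotypeCovChol()] result.
#' @param seed optional integer seed.
#' @return numeric phenotype vector.
#' @export
simulatePhenotype <- function(x, anc = NULL, K, KA = NULL, beta = 0,
                              betaGxt = 0, sigmaG2 = 0.4,
                              sigmaTheta2 = 0, sigmaE2 = 0.6,
                              cholCov = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(x)
  n <- length(x)
  fixed <- beta * x
  if (betaGxt != 0) {
    th <- .thetaVec(anc)
    stopifnot(length(th) == n)
    fixed <- fixed + betaGxt * th * x
  }
  if (is.null(cholCov) && (sigmaG2 > 0 || sigmaTheta2 > 0 || sigmaE2 > 0))
    cholCov <- phenotypeCovChol(K, KA, sigmaG2, sigmaTheta2, sigmaE2)
  if (is.null(cholCov)) return(fixed)
  fixed + drop(crossprod(cholCov, rnorm(n)))
}

#' Build a composite SNP from a set of interacting SNPs
#'
#' On a fully inbred panel (dosages in \{0,1\}), the composite carries
#' the minor allele exactly in the strains that carry the minor allele at
#' every input SNP, and the major allele elsewhere; it is returned as the
#' minor-allele carrier indicator.  In panels descended from a common
#' reference founder the "minor" allele is conventionally the
#' non-reference-founder allele (dosage 0), the default here; set
#' `minorAllele = "rarer"` to use each SNP's less frequent allele
#' instead.  Within the usual 25-75% frequency window the two coincide
#' for about half the SNPs; the non-reference convention makes every
#' member push the composite carriers in the same (low-ancestry)
#' direction, which is what a higher-order epistatic architecture on a
#' common genetic background looks like.
#'
#' @param snps numeric matrix (strains x SNPs) or list of dosage vectors,
#'   values in \{0,1\}.
#' @param minorAllele "nonref" (default) or "rarer".
#' @return numeric 0/1 vector with attribute `monomorphic` (TRUE when no
#'   strain, or every strain, carries all minor alleles).
#' @export
compositeSnp <- function(snps, minorAllele = c("nonref", "rarer")) {
  minorAllele <- match.arg(minorAllele)
  if (is.list(snps)) snps <- do.call(cbind, snps)
  snps <- as.matrix(snps)
  if (ncol(snps) < 1) stop("need at least one SNP")
  if (!all(snps %in% c(0, 1)))
    stop("composite SNPs require an inbred panel with dosages in {0,1}")
  carrier <- rep(TRUE, nrow(snps))
  for (j in seq_len(ncol(snps))) {
    minorVal <- if (minorAllele == "nonref") 0
                else if (mean(snps[, j]) < 0.5) 1 else 0
    carrier <- carrier & (snps[, j] == minorVal)
  }
  out <- as.numeric(carrier)
  attr(out, "monomorphic") <- length(unique(out)) == 1L
  out
}

#' Calibrate an effect size to a target association non-centrality
#'
#' Returns beta such that the 1-df generalized least squares association
#' test of `x` (under covariance sigmaG2 K + sigmaE2 I, adjusting for the
#' covariates) has non-centrality parameter `targetChi2`:
#' beta = sqrt(targetChi2 / q) with q the V-inverse quadratic form of the
#' covariate-residualized regressor.  Realized statistics then fluctuate
#' around 1 + targetChi2.
#'
#' @param x regressor (e.g. a composite SNP indicator); must be
#'   polymorphic.
#' @param K genotype GRM.
#' @param targetChi2 target non-centrality (>= 0).
#' @param sigmaG2,sigmaE2 covariance components.
#' @param covariates optional covariate matrix (intercept always
#'   included).
#' @param cholCov optional precomputed chol of sigmaG2 K + sigmaE2 I.
#' @return calibrated beta (0 when targetChi2 = 0).
#' @export
calibrateBetaToChisq <- function(x, K, targetChi2 = 20, sigmaG2 = 0.4,
                                 sigmaE2 = 0.6, covariates = NULL,
                                 cholCov = NULL) {
  stopifnot(targetChi2 >= 0)
  x <- as.numeric(x)
  if (stats::var(x) == 0) stop("regressor has zero variance")
  if (targetChi2 == 0) return(0)
  if (is.null(cholCov))
    cholCov <- phenotypeCovChol(K, NULL, sigmaG2, 0, sigmaE2)
  X <- .designMatrix(length(x), covariates)
  xw <- backsolve(cholCov, x, transpose = TRUE)
  Xw <- backsolve(cholCov, X, transpose = TRUE)
  q <- sum(stats::lm.fit(Xw, xw)$residuals^2)
  if (q <= .Machine$double.eps) stop("target non-centrality unreachable: ",
                                     "regressor explained by covariates")
  sqrt(targetChi2 / q)
}

.eligibleSnps <- function(D, mafWindow) {
  f <- colMeans(D)
  which(f > mafWindow[1] & f < mafWindow[2])
}

#' Power curves for the main-effect and interaction tests
#'
#' At each effect-size grid point, draws a random SNP from the allele
#' frequency window, simulates a phenotype under the chosen generative
#' model, standardizes it to unit variance, runs the Gxtheta test, and
#' records the rejection fractions of the main-effect and interaction
#' tests at level alpha.
#'
#' @param g a [GenotypePanel-class] (fully observed; missing cells are
#'   mean-imputed once up front).
#' @param anc [AncestryEstimate-class] or theta vector.
#' @param K genotype GRM.
#' @param KA ancestry GRM (needed for 2K generation and/or two-GRM
#'   analysis).
#' @param model generative model: "int-1K", "int-2K", "main-1K" or
#'   "main-2K".
#' @param grid effect sizes (default 20 points on \[0,1\]; the full-scale
#'   convention is 200 points 0.005 apart).
#' @param nReps simulated phenotypes per grid point (default 200; 1000 at
#'   full scale).
#' @param alpha rejection level (nominal 0.05 by default; a genome-wide
#'   threshold may be supplied instead).
#' @param sigmaG2,sigmaTheta2 variance components (0.4 and, for 2K
#'   generation, 0.2); the residual is the remainder to 1.
#' @param mafWindow reference-allele frequency window for SNP draws,
#'   default (0.25, 0.75).
#' @param twoGrmFit analyze with both GRMs; defaults to TRUE for the 2K
#'   models.
#' @param seed integer seed for the whole curve (one stream: SNP draws
#'   and phenotype noise interleaved).
#' @return data.frame: effect, mainPower, gxtPower, mainSE, gxtSE, nReps.
#' @export
powerCurve <- function(g, anc, K, KA = NULL,
                       model = c("int-1K", "int-2K", "main-1K", "main-2K"),
                       grid = seq(0, 1, length.out = 20), nReps = 200,
                       alpha = 0.05, sigmaG2 = 0.4, sigmaTheta2 = 0.2,
                       mafWindow = c(0.25, 0.75), twoGrmFit = NULL,
                       seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  twoK <- grepl("2K$", model)
  interaction <- grepl("^int", model)
  if (is.null(twoGrmFit)) twoGrmFit <- twoK
  sTh <- if (twoK) sigmaTheta2 else 0
  sE <- 1 - sigmaG2 - sTh
  stopifnot(sE >= 0)
  th <- .thetaVec(anc)
  D <- meanImpute(g)
  elig <- .eligibleSnps(D, mafWindow)
  if (!length(elig)) stop("no SNPs in the allele-frequency window")
  Km <- .asKmat(K)
  KAm <- if (is.null(KA)) NULL else .asKmat(KA)
  cc <- phenotypeCovChol(Km, KAm, sigmaG2, sTh, sE)
  eK <- eigen(Km, symmetric = TRUE)
  fitKA <- if (twoGrmFit) KAm else NULL
  out <- data.frame(effect = grid, mainPower = NA_real_,
                    gxtPower = NA_real_, mainSE = NA_real_,
                    gxtSE = NA_real_, nReps = nReps)
  for (i in seq_along(grid)) {
    eff <- grid[i]
    rejM <- logical(nReps); rejI <- logical(nReps)
    for (r in seq_len(nReps)) {
      j <- elig[sample.int(length(elig), 1)]
      x <- D[, j]
      y <- simulatePhenotype(x, th, Km, KAm,
                             beta = if (interaction) 0 else eff,
                             betaGxt = if (interaction) eff else 0,
                             cholCov = cc)
      y <- y / stats::sd(y)
      res <- gxthetaTest(y, x, th, K = Km, KA = fitKA,
                         vc = NULL, snpId = colnames(D)[j],
                         eigenK = if (is.null(fitKA)) eK else NULL)
      rejM[r] <- res$pG < alpha
      rejI[r] <- res$pGxt < alpha
    }
    pm <- mean(rejM); pi <- mean(rejI)
    out$mainPower[i] <- pm; out$gxtPower[i] <- pi
    out$mainSE[i] <- sqrt(pm * (1 - pm) / nReps)
    out$gxtSE[i] <- sqrt(pi * (1 - pi) / nReps)
  }
  out
}

#' Higher-order epistasis experiment via composite SNPs
#'
#' For each number of interacting partner SNPs, repeatedly: draw a test
#' SNP and that many additional partner SNPs from the allele-frequency
#' window; form the composite SNP (minor-allele AND); calibrate its
#' effect size so the composite association non-centrality equals
#' `targetChi2`; simulate the phenotype; and test the ORIGINAL test SNP
#' for main and interaction effects.  Monomorphic composites are redrawn
#' within a budget.  With zero partners the composite is the test SNP
#' itself.
#'
#' Because the interacting architecture distributes the interaction
#' signal over every participating locus, the chance of detecting the
#' epistatic system at SOME involved SNP grows with the number of
#' partners even as the test SNP's own signal dilutes; the
#' `anyGxtPower` column records the fraction of replicates in which at
#' least one involved SNP (test or partner) attains interaction
#' p < alpha.
#'
#' @param g inbred [GenotypePanel-class] (dosages \{0,1\}).
#' @param anc ancestry estimate or theta vector.
#' @param K genotype GRM.
#' @param partners grid of partner counts (default 1:10; 0 allowed).
#' @param nReps replicates per grid point (default 500; 10000 at full
#'   scale).
#' @param alpha detection level.
#' @param targetChi2 composite non-centrality target (default 20).
#' @param sigmaG2,sigmaE2 covariance components of the generator.
#' @param mafWindow allele-frequency window for draws.
#' @param redrawBudget redraw attempts per replicate before skipping.
#' @param seed integer seed.
#' @return data.frame: nPartners, mainPower, gxtPower (test-SNP rejection
#'   rates), anyGxtPower (interaction detected at any involved SNP),
#'   mainSE, gxtSE, anyGxtSE, mainLambda, gxtLambda (genomic inflation of
#'   the test-SNP p-value distributions, the QQ-style
#'   deflation/inflation diagnostic), nUsed (replicates with a
#'   polymorphic composite).
#' @export
epistasisExperiment <- function(g, anc, K, partners = 1:10, nReps = 500,
                                alpha = 0.05, targetChi2 = 20,
                                sigmaG2 = 0.4, sigmaE2 = 0.6,
                                mafWindow = c(0.25, 0.75),
                                redrawBudget = 50, seed = NULL) {
  stopifnot(all(partners >= 0), all(partners <= 10))
  if (!is.null(seed)) set.seed(seed)
  th <- .thetaVec(anc)
  D <- meanImpute(g)
  if (!all(D %in% c(0, 1)))
    stop("epistasis experiment requires a fully inbred panel")
  elig <- .eligibleSnps(D, mafWindow)
  if (length(elig) < max(partners) + 1)
    stop("too few SNPs in the allele-frequency window")
  Km <- .asKmat(K)
  cc <- phenotypeCovChol(Km, NULL, sigmaG2, 0, sigmaE2)
  eK <- eigen(Km, symmetric = TRUE)
  X1 <- .designMatrix(nrow(D))
  X1w <- backsolve(cc, X1, transpose = TRUE)
  out <- data.frame(nPartners = partners, mainPower = NA_real_,
                    gxtPower = NA_real_, anyGxtPower = NA_real_,
                    mainSE = NA_real_, gxtSE = NA_real_,
                    anyGxtSE = NA_real_, mainLambda = NA_real_,
                    gxtLambda = NA_real_, nUsed = NA_integer_)
  for (i in seq_along(partners)) {
    k <- partners[i]
    pM <- numeric(0); pI <- numeric(0); anyI <- logical(0)
    for (r in seq_len(nReps)) {
      comp <- NULL
      for (a in seq_len(redrawBudget)) {
        pick <- elig[sample.int(length(elig), k + 1)]
        cs <- compositeSnp(D[, pick, drop = FALSE])
        if (!attr(cs, "monomorphic")) { comp <- cs; break }
      }
      if (is.null(comp)) next
      cw <- backsolve(cc, comp, transpose = TRUE)
      q <- sum(stats::lm.fit(X1w, cw)$residuals^2)
      beta <- sqrt(targetChi2 / q)
      y <- beta * comp + drop(crossprod(cc, rnorm(nrow(D))))
      y <- y / stats::sd(y)
      vc <- fitVarianceComponents(y, cbind(theta = th), Km,
                                  eigenK = eK)
      pInv <- vapply(pick, function(j)
        gxthetaTest(y, D[, j], th, K = Km, vc = vc)$pGxt, numeric(1))
      res <- gxthetaTest(y, D[, pick[1]], th, K = Km, vc = vc)
      pM <- c(pM, res$pG)
      pI <- c(pI, pInv[1])
      anyI <- c(anyI, any(pInv < alpha))
    }
    if (!length(pM))
      stop("no polymorphic composites obtained at nPartners = ", k)
    nu <- length(pM)
    pm <- mean(pM < alpha); pi <- mean(pI < alpha); pa <- mean(anyI)
    out$mainPower[i] <- pm; out$gxtPower[i] <- pi
    out$anyGxtPower[i] <- pa
    out$mainSE[i] <- sqrt(pm * (1 - pm) / nu)
    out$gxtSE[i] <- sqrt(pi * (1 - pi) / nu)
    out$anyGxtSE[i] <- sqrt(pa * (1 - pa) / nu)
    out$mainLambda[i] <- genomicInflation(pM)
    out$gxtLambda[i] <- genomicInflation(pI)
    out$nUsed[i] <- nu
  }
  out
}
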