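# Variance-component machinery for the mixed model
#   y = C b + u + e,  Var(u) = sigmaG2 K (+ sigmaTheta2 KA),  Var(e) = sigmaE2 I
# fitted by maximum likelihood.  Single-GRM fits eigendecompose K once and
# profile the likelihood over the heritability ratio in 1-D; two-GRM fits
# optimize the two variance ratios with the residual scale profiled out.

.asKmat <- function(K) {
  if (is(K, "Kinship")) kinshipValues(K) else as.matrix(K)
}

.designMatrix <- function(n, covariates = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match y")
    X <- cbind(X, covariates)
  }
  X
}

# profile ML log-likelihood at heritability ratio h for rotated data;
# weights are h * lambda_i + (1 - h)
.profileLL1 <- function(h, lam, yr, Xr) {
  w <- h * lam + (1 - h)
  sw <- 1 / sqrt(w)
  fit <- stats::lm.fit(Xr * sw, yr * sw)
  rss <- sum(fit$residuals^2)
  n <- length(yr)
  -0.5 * (n * log(2 * pi) + n * log(rss / n) + n + sum(log(w)))
}

.ll2K <- function(a, b, K, KA, y, X) {
  n <- length(y)
  V <- a * K + b * KA
  diag(V) <- diag(V) + 1
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  ll <- -0.5 * (n * log(2 * pi) + n * log(rss / n) + n +
                2 * sum(log(diag(R))))
  list(ll = ll, rss = rss, R = R)
}

#' Fit mixed-model variance components by maximum likelihood
#'
#' Single-GRM path: eigendecompose K once, rotate, and profile the ML
#' likelihood over the heritability ratio h = sigmaG2/(sigmaG2 + sigmaE2)
#' by 1-D optimization.  Two-GRM path: optimize the ratios
#' (sigmaG2/sigmaE2, sigmaTheta2/sigmaE2) by L-BFGS-B with the residual
#' scale profiled out.  Returned scales are ML estimates (residual sums of
#' squares divided by n).
#'
#' @param y numeric trait vector (no missing values).
#' @param covariates optional covariate matrix (no intercept column; one
#'   is added).
#' @param K a [Kinship-class] or matrix aligned to `y`.
#' @param KA optional second (ancestry) GRM for the two-GRM model.
#' @param eigenK optional precomputed `eigen(K, symmetric = TRUE)`; the
#'   single-GRM path eigendecomposes K only once per trait, and
#'   simulation loops can share one decomposition across traits.
#' @return list of class `gxthetaVC`: `sigmaG2`, `sigmaTheta2` (NA for the
#'   single-GRM fit), `sigmaE2`, `h2`, `logLik`, and a `whiten` matrix M
#'   such that M y has iid unit-scale-free errors under the fitted
#'   covariance (used by the per-SNP generalized least squares tests).
#' @export
fitVarianceComponents <- function(y, covariates = NULL, K, KA = NULL,
                                  eigenK = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- .designMatrix(n, covariates)
  if (n < ncol(X) + 2) stop("too few samples for the fixed effects")
  K <- .asKmat(K)
  if (nrow(K) != n) stop("kinship dimension does not match y")
  if (is.null(KA)) {
    e <- if (is.null(eigenK)) eigen(K, symmetric = TRUE) else eigenK
    lam <- pmax(e$values, 0)
    Ut <- t(e$vectors)
    yr <- drop(Ut %*% y)
    Xr <- Ut %*% X
    opt <- stats::optimize(.profileLL1, c(1e-6, 1 - 1e-6), lam = lam,
                           yr = yr, Xr = Xr, maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    # guard the boundaries: pure-noise and pure-genetic limits
    cand <- c(opt$maximum, 1e-6, 1 - 1e-6)
    lls <- vapply(cand, .profileLL1, numeric(1), lam = lam, yr = yr,
                  Xr = Xr)
    h <- cand[which.max(lls)]
    ll <- max(lls)
    if (!is.finite(ll)) stop("non-finite likelihood in variance fit")
    w <- h * lam + (1 - h)
    sw <- 1 / sqrt(w)
    fit <- stats::lm.fit(Xr * sw, yr * sw)
    s2 <- sum(fit$residuals^2) / n
    M <- Ut * sw  # rows scaled: diag(1/sqrt(w)) %*% Ut
    out <- list(sigmaG2 = h * s2, sigmaTheta2 = NA_real_,
                sigmaE2 = (1 - h) * s2, h2 = h, logLik = ll,
                whiten = M, model = "1K")
  } else {
    KA <- .asKmat(KA)
    if (nrow(KA) != n) stop("second GRM dimension does not match y")
    obj <- function(p) -.ll2K(exp(p[1]), exp(p[2]), K, KA, y, X)$ll
    best <- NULL
    for (start in list(c(0, 0), c(-3, -3))) {
      o <- tryCatch(
        stats::optim(start, obj, method = "L-BFGS-B",
                     lower = log(1e-8), upper = log(1e4),
                     control = list(factr = 1e10, maxit = 40)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("two-GRM variance optimization failed")
    a <- exp(best$par[1]); b <- exp(best$par[2])
    res <- .ll2K(a, b, K, KA, y, X)
    if (!is.finite(res$ll)) stop("non-finite likelihood in variance fit")
    s2e <- res$rss / n
    M <- backsolve(res$R, diag(n), transpose = TRUE)  # (R')^{-1}
    out <- list(sigmaG2 = a * s2e, sigmaTheta2 = b * s2e, sigmaE2 = s2e,
                h2 = a * s2e / ((a + b) * s2e + s2e), logLik = res$ll,
                whiten = M, model = "2K")
  }
  class(out) <- "gxthetaVC"
  out
}

#' @export
print.gxthetaVC <- function(x, ...) {
  cat(sprintf(
    "Variance components (%s, ML): sigmaG2=%.4f sigmaTheta2=%s sigmaE2=%.4f logLik=%.3f\n",
    x$model, x$sigmaG2,
    ifelse(is.na(x$sigmaTheta2), "-", sprintf("%.4f", x$sigmaTheta2)),
    x$sigmaE2, x$logLik))
  invisible(x)
}
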