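#' Filter SNPs by allele frequency window
#'
#' Per-SNP reference-allele frequency f is the mean observed dosage
#' (missing cells excluded).  SNPs are retained when f lies in
#' \[mafMin, mafMax\] (or the open interval with `strict = TRUE`); the
#' default upper bound is the mirror 1 - mafMin, so the default window is
#' the usual symmetric minor-allele-frequency cut.  Genome scans
#' conventionally use `mafMin = 0.05`; simulation SNP draws use the
#' f in (0.25, 0.75) window, i.e. `mafMin = 0.25, strict = TRUE`.
#'
#' @param g a [GenotypePanel-class].
#' @param mafMin lower bound on f.
#' @param mafMax upper bound on f, default `1 - mafMin`.
#' @param strict use open interval bounds.
#' @return The filtered [GenotypePanel-class]; warns if no SNP survives.
#' @export
filterMaf <- function(g, mafMin = 0.05, mafMax = 1 - mafMin,
                      strict = FALSE) {
  stopifnot(is(g, "GenotypePanel"), mafMin >= 0, mafMin <= mafMax)
  f <- snpFreq(g)
  keep <- if (strict) f > mafMin & f < mafMax
          else f >= mafMin & f <= mafMax
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("no SNPs pass the MAF filter")
  g[, keep]
}

#' Per-SNP allele frequencies
#'
#' @param g a [GenotypePanel-class].
#' @return `snpFreq`: mean observed reference-allele dosage per SNP
#'   (NaN when all cells missing).  `snpMaf`: min(f, 1-f).
#' @export
snpFreq <- function(g) colMeans(dosages(g), na.rm = TRUE)

#' @rdname snpFreq
#' @export
snpMaf <- function(g) {
  f <- snpFreq(g)
  pmin(f, 1 - f)
}

#' Mean-impute missing dosages
#'
#' Replaces each missing cell with the mean of the observed dosages at
#' that SNP (the convention of the pyLMM association lineage).  Imputed
#' values need not lie on the \{0, 0.5, 1\} grid, so the result is a
#' plain numeric matrix; association and GRM code consume it directly.
#' The operation is idempotent.
#'
#' @param g a [GenotypePanel-class] or numeric dosage matrix.
#' @return numeric matrix with no missing values.
#' @export
meanImpute <- function(g) {
  d <- if (is(g, "GenotypePanel")) dosages(g) else as.matrix(g)
  nMiss <- colSums(is.na(d))
  if (!any(nMiss > 0)) return(d)
  allMiss <- which(nMiss == nrow(d))
  if (length(allMiss))
    stop("SNP(s) with all dosages missing: ",
         paste(colnames(d)[allMiss], collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  d
}
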