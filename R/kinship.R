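#' Compute a genetic relationship matrix from panel genotypes
#'
#' K = Z Z'/m over the m retained SNPs, where Z is the column-centered
#' (and, when `standardize = TRUE`, unit-variance-scaled) mean-imputed
#' dosage matrix.  Under standardization the mean diagonal is ~1.
#' Restricting `sites` to the ancestry-informative SNP indices yields the
#' ancestry GRM K^A used by the two-GRM model.
#'
#' @param g a [GenotypePanel-class] or numeric dosage matrix
#'   (samples x SNPs).
#' @param standardize scale each SNP column to unit variance.
#' @param sites optional integer vector of SNP columns to use.
#' @param label label stored on the result ("K" or "KA").
#' @return A [Kinship-class].
#' @export
computeGrm <- function(g, standardize = FALSE, sites = NULL, label = "K") {
  ids <- if (is(g, "GenotypePanel")) sampleIds(g) else rownames(g)
  d <- meanImpute(g)
  if (!is.null(sites)) d <- d[, sites, drop = FALSE]
  if (ncol(d) < 2) stop("need at least 2 SNPs to form a GRM")
  z <- scale(d, center = TRUE, scale = FALSE)
  if (standardize) {
    sds <- apply(d, 2, sd)
    zero <- sds == 0
    if (any(zero)) {
      warning(sum(zero), " zero-variance SNP(s) dropped from GRM")
      z <- z[, !zero, drop = FALSE]
      sds <- sds[!zero]
      if (ncol(z) < 2) stop("fewer than 2 SNPs left after dropping")
    }
    z <- sweep(z, 2, sds, "/")
  }
  Kinship(tcrossprod(z) / ncol(z), ids, label)
}

#' Ancestry GRM from cross-specific informative sites
#'
#' Relatedness in ancestry space: the GRM of the ancestry-call matrix, in
#' which each individual's dosage is observed only at the sites that are
#' ancestry-informative (segregating) in its own cross; ineligible cells
#' are treated as missing and mean-imputed before the cross-product.
#' For a single-cross panel this reduces to the genotype GRM restricted
#' to the informative sites.
#'
#' @param g a [GenotypePanel-class] oriented so dosage 1 is the reference
#'   founder's allele.
#' @param eligibility named list mapping cross label to informative SNP
#'   indices (see [siteAncestryFrequency()]).
#' @param membership per-individual cross labels.
#' @param standardize as in [computeGrm()].
#' @return A [Kinship-class] labelled "KA".
#' @export
ancestryGrm <- function(g, eligibility, membership, standardize = FALSE) {
  stopifnot(is(g, "GenotypePanel"))
  membership <- as.character(membership)
  if (length(membership) != nSamples(g))
    stop("membership length must equal the number of samples")
  A <- matrix(NA_real_, nSamples(g), nSnps(g),
              dimnames = dimnames(dosages(g)))
  for (cr in names(eligibility)) {
    rows <- which(membership == cr)
    cols <- eligibility[[cr]]
    A[rows, cols] <- dosages(g)[rows, cols]
  }
  keep <- colSums(!is.na(A)) > 0
  if (sum(keep) < 2) stop("fewer than 2 sites observed in any cross")
  computeGrm(A[, keep, drop = FALSE], standardize = standardize,
             label = "KA")
}
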