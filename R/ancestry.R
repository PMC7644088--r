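#' Call ancestry-informative sites from two parental genotype rows
#'
#' An ancestry-informative site is one at which the two (inbred, hence
#' homozygous) parental lines carry different alleles.  Sites where either
#' parent is heterozygous or missing are skipped.  The returned orientation
#' records, per informative site, whether the designated reference founder
#' (`refParent`) carries the reference (dosage 1) allele; downstream code
#' uses it to express offspring dosages as reference-founder ancestry.
#'
#' @param parentA,parentB numeric dosage vectors (one genotype row each),
#'   values in \{0, 0.5, 1, NA\}.
#' @param refParent which parent is the designated reference founder,
#'   `"A"` or `"B"`.
#' @return list with `sites` (integer indices of informative sites) and
#'   `refDosage` (dosage carried by the reference founder at each site,
#'   0 or 1).  Zero informative sites yields empty vectors.
#' @export
informativeSites <- function(parentA, parentB, refParent = c("A", "B")) {
  refParent <- match.arg(refParent)
  if (length(parentA) != length(parentB))
    stop("parental genotype rows differ in length")
  ok <- !is.na(parentA) & !is.na(parentB) &
        parentA %in% c(0, 1) & parentB %in% c(0, 1)
  idx <- which(ok & parentA != parentB)
  ref <- if (refParent == "A") parentA[idx] else parentB[idx]
  list(sites = idx, refDosage = as.numeric(ref))
}

#' Orient dosages toward the reference founder at informative sites
#'
#' @param d dosage matrix (samples x SNPs) on the raw reference-allele
#'   scale.
#' @param sites result of [informativeSites()].
#' @return samples x n_sites matrix of reference-founder ancestry dosage
#'   (1 = both alleles from the reference founder).
#' @keywords internal
.orientToFounder <- function(d, sites) {
  sub <- d[, sites$sites, drop = FALSE]
  flip <- sites$refDosage == 0
  if (any(flip)) sub[, flip] <- 1 - sub[, flip, drop = FALSE]
  sub
}

#' Compute per-individual global ancestry theta
#'
#' Theta is the unweighted mean, over ancestry-informative SNPs, of the
#' reference-founder allele dosage of an individual: the fraction of
#' informative SNPs inherited from the designated founder.  Heterozygous
#' cells contribute 0.5; missing cells are excluded individual by
#' individual.
#'
#' @param g a [GenotypePanel-class] (offspring panel).
#' @param sites result of [informativeSites()] on the two founders.
#' @return An [AncestryEstimate-class].
#' @export
computeTheta <- function(g, sites) {
  stopifnot(is(g, "GenotypePanel"))
  if (length(sites$sites) == 0)
    stop("no ancestry-informative sites; cannot compute theta")
  sub <- .orientToFounder(dosages(g), sites)
  nObs <- rowSums(!is.na(sub))
  if (any(nObs == 0))
    stop("individual(s) with zero observed informative sites: ",
         paste(sampleIds(g)[nObs == 0], collapse = ", "))
  AncestryEstimate(rowMeans(sub, na.rm = TRUE), sampleIds(g), nObs)
}

#' Per-site founder-ancestry frequency across a (possibly multi-cross) panel
#'
#' For each site, the mean reference-founder dosage over the individuals
#' belonging to crosses in which that site is ancestry-informative
#' (segregating); individuals of crosses where the site is invariant are
#' excluded, mirroring the rule that only strains not invariant for a
#' locus enter its frequency.  For a single-cross panel pass one
#' membership level and one eligibility set.
#'
#' @param g a [GenotypePanel-class], already oriented so dosage 1 is the
#'   reference founder's allele.
#' @param eligibility named list mapping cross label to the integer SNP
#'   indices informative in that cross.
#' @param membership character/factor of per-individual cross labels
#'   (length = nSamples).
#' @return data.frame with `snpIndex`, `thetaSite` (frequency in \[0,1\],
#'   NA when no individual is eligible) and `nEligible`.
#' @export
siteAncestryFrequency <- function(g, eligibility, membership) {
  stopifnot(is(g, "GenotypePanel"))
  membership <- as.character(membership)
  if (length(membership) != nSamples(g))
    stop("membership length must equal the number of samples")
  unknown <- setdiff(unique(membership), names(eligibility))
  if (length(unknown))
    stop("cross label(s) without eligibility set: ",
         paste(unknown, collapse = ", "))
  d <- dosages(g)
  m <- nSnps(g)
  num <- numeric(m); den <- numeric(m)
  for (cr in names(eligibility)) {
    rows <- which(membership == cr)
    if (!length(rows)) next
    cols <- eligibility[[cr]]
    sub <- d[rows, cols, drop = FALSE]
    num[cols] <- num[cols] + colSums(sub, na.rm = TRUE)
    den[cols] <- den[cols] + colSums(!is.na(sub))
  }
  out <- data.frame(snpIndex = seq_len(m),
                    thetaSite = ifelse(den > 0, num / den, NA_real_),
                    nEligible = den)
  out
}
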