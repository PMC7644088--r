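#' @import methods
#' @importFrom stats optimize optim pchisq pnorm pbinom dbinom median var
#'   sd qchisq p.adjust rnorm runif rpois rbinom setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

.MISSING_OK <- c(0, 0.5, 1)

#' GenotypePanel: a mapping-panel dosage matrix with SNP coordinates
#'
#' The central genotype container: an n-samples by m-SNPs matrix of
#' reference-founder allele dosages on the \[0,1\] scale (homozygous
#' alternate = 0, heterozygous = 0.5, homozygous reference = 1, missing =
#' `NA`), together with per-SNP metadata (id, chromosome, basepair) and
#' sample identifiers.  Fully inbred panels occupy \{0,1\}; advanced
#' intercross lines additionally carry 0.5.  The \[0,1\] dosage scale is
#' deliberate: global ancestry proportions live on the same scale, so the
#' main-effect and interaction coefficients of the Gxtheta model are
#' directly commensurable.
#'
#' @slot dosages numeric matrix, samples x SNPs, values in \{0, 0.5, 1, NA\}.
#' @slot snpInfo data.frame with columns `snpId`, `chrom`, `bp`
#'   (1-based integer positions; chromosome labels are opaque strings).
#' @slot sampleIds character vector of unique sample identifiers.
#'
#' @examples
#' g <- GenotypePanel(matrix(c(1, 0, 1, 0.5), 2, 2),
#'                    snpInfo = data.frame(snpId = c("s1", "s2"),
#'                                         chrom = "1", bp = c(100L, 200L)),
#'                    sampleIds = c("a", "b"))
#' nSamples(g); nSnps(g)
#' @export
setClass("GenotypePanel",
  representation(dosages = "matrix", snpInfo = "data.frame",
                 sampleIds = "character"))

setValidity("GenotypePanel", function(object) {
  d <- object@dosages
  msg <- character()
  if (nrow(d) != length(object@sampleIds))
    msg <- c(msg, "number of dosage rows must equal length(sampleIds)")
  if (ncol(d) != nrow(object@snpInfo))
    msg <- c(msg, "number of dosage columns must equal nrow(snpInfo)")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  if (!all(c("snpId", "chrom", "bp") %in% names(object@snpInfo)))
    msg <- c(msg, "snpInfo needs columns snpId, chrom, bp")
  else if (any(object@snpInfo$bp < 0, na.rm = TRUE))
    msg <- c(msg, "basepair positions must be non-negative")
  obs <- d[!is.na(d)]
  if (length(obs) && !all(obs %in% .MISSING_OK))
    msg <- c(msg, "dosages must be in {0, 0.5, 1} or NA")
  if (length(msg)) msg else TRUE
})

#' @rdname GenotypePanel-class
#' @param dosages samples x SNPs numeric matrix of dosages.
#' @param snpInfo data.frame of SNP metadata (`snpId`, `chrom`, `bp`).
#' @param sampleIds character vector of sample identifiers; defaults to the
#'   rownames of `dosages` or `S1..Sn`.
#' @return A [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(dosages, snpInfo, sampleIds = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(dosages))) rownames(dosages)
                 else paste0("S", seq_len(nrow(dosages)))
  snpInfo <- as.data.frame(snpInfo, stringsAsFactors = FALSE)
  snpInfo$snpId <- as.character(snpInfo$snpId)
  snpInfo$chrom <- as.character(snpInfo$chrom)
  snpInfo$bp <- as.integer(snpInfo$bp)
  rownames(snpInfo) <- NULL
  dimnames(dosages) <- list(sampleIds, snpInfo$snpId)
  new("GenotypePanel", dosages = dosages, snpInfo = snpInfo,
      sampleIds = as.character(sampleIds))
}

#' Kinship: a genetic relationship matrix
#'
#' Symmetric positive semi-definite relatedness matrix used as the
#' covariance structure of the random polygenic effect.  The `label`
#' distinguishes the genome-wide genotype GRM ("K") from the
#' ancestry-informative-site GRM ("KA") used by the two-GRM model.
#'
#' @slot values n x n numeric matrix.
#' @slot sampleIds character vector aligned to rows/columns.
#' @slot label character scalar, e.g. "K" or "KA".
#' @export
setClass("Kinship",
  representation(values = "matrix", sampleIds = "character",
                 label = "character"))

setValidity("Kinship", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "kinship must be square")
  if (nrow(v) != length(object@sampleIds))
    msg <- c(msg, "sampleIds must match matrix dimension")
  if (max(abs(v - t(v))) > 1e-10)
    msg <- c(msg, "kinship must be symmetric to within 1e-10")
  else {
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, max(abs(ev))))
      msg <- c(msg, "kinship must be numerically positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Kinship-class
#' @param values square symmetric numeric matrix.
#' @param sampleIds sample identifiers; defaults to rownames.
#' @param label "K" for a genotype GRM, "KA" for an ancestry GRM.
#' @return A [Kinship-class] object.
#' @export
Kinship <- function(values, sampleIds = NULL, label = "K") {
  values <- as.matrix(values)
  values <- (values + t(values)) / 2
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(values))) rownames(values)
                 else paste0("S", seq_len(nrow(values)))
  dimnames(values) <- list(sampleIds, sampleIds)
  new("Kinship", values = values, sampleIds = as.character(sampleIds),
      label = label)
}

#' AncestryEstimate: per-individual global ancestry proportions
#'
#' Holds theta, the fraction of ancestry-informative SNPs at which an
#' individual carries the designated reference founder's allele, and the
#' number of informative sites each estimate is based on.
#'
#' @slot theta numeric in \[0,1\], one value per individual.
#' @slot sampleIds character identifiers aligned to `theta`.
#' @slot nSites integer count of informative sites used per individual.
#' @export
setClass("AncestryEstimate",
  representation(theta = "numeric", sampleIds = "character",
                 nSites = "integer"))

setValidity("AncestryEstimate", function(object) {
  msg <- character()
  if (length(object@theta) != length(object@sampleIds))
    msg <- c(msg, "theta and sampleIds lengths differ")
  if (length(object@nSites) != length(object@theta))
    msg <- c(msg, "nSites and theta lengths differ")
  if (any(object@theta < 0 | object@theta > 1, na.rm = TRUE))
    msg <- c(msg, "theta must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @rdname AncestryEstimate-class
#' @param theta numeric vector of ancestry proportions in \[0,1\].
#' @param sampleIds sample identifiers.
#' @param nSites number of informative sites behind each estimate.
#' @return An [AncestryEstimate-class] object.
#' @export
AncestryEstimate <- function(theta, sampleIds = names(theta),
                             nSites = NA_integer_) {
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_along(theta))
  nSites <- as.integer(rep_len(nSites, length(theta)))
  new("AncestryEstimate", theta = as.numeric(theta),
      sampleIds = as.character(sampleIds), nSites = nSites)
}
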