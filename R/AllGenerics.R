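#' @rdname GenotypePanel-class
#' @param x,object a GenotypePanel, Kinship or AncestryEstimate.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname GenotypePanel-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname GenotypePanel-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname GenotypePanel-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname GenotypePanel-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname AncestryEstimate-class
#' @param x an AncestryEstimate.
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
#' @rdname Kinship-class
#' @param x a Kinship.
#' @export
setGeneric("kinshipValues", function(x) standardGeneric("kinshipValues"))

#' @rdname GenotypePanel-class
#' @export
setMethod("nSamples", "GenotypePanel", function(x) nrow(x@dosages))
#' @rdname GenotypePanel-class
#' @export
setMethod("nSnps", "GenotypePanel", function(x) ncol(x@dosages))
#' @rdname GenotypePanel-class
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosages)
#' @rdname GenotypePanel-class
#' @export
setMethod("snpInfo", "GenotypePanel", function(x) x@snpInfo)
#' @rdname GenotypePanel-class
#' @export
setMethod("sampleIds", "GenotypePanel", function(x) x@sampleIds)
#' @rdname AncestryEstimate-class
#' @export
setMethod("sampleIds", "AncestryEstimate", function(x) x@sampleIds)
#' @rdname Kinship-class
#' @export
setMethod("sampleIds", "Kinship", function(x) x@sampleIds)
#' @rdname AncestryEstimate-class
#' @export
setMethod("theta", "AncestryEstimate", function(x) x@theta)
#' @rdname Kinship-class
#' @export
setMethod("kinshipValues", "Kinship", function(x) x@values)
#' @rdname Kinship-class
#' @export
setMethod("nSamples", "Kinship", function(x) nrow(x@values))
#' @rdname AncestryEstimate-class
#' @export
setMethod("nSamples", "AncestryEstimate", function(x) length(x@theta))

#' Subset a GenotypePanel by samples (i) and/or SNPs (j)
#'
#' @param x a GenotypePanel.
#' @param i sample index (integer, logical or character ids).
#' @param j SNP index (integer, logical or character snp ids).
#' @param ... ignored.
#' @param drop ignored; the result is always a GenotypePanel.
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nSnps(x))
  if (is.character(i)) i <- match(i, x@sampleIds)
  if (is.character(j)) j <- match(j, x@snpInfo$snpId)
  GenotypePanel(x@dosages[i, j, drop = FALSE],
                x@snpInfo[j, , drop = FALSE],
                x@sampleIds[i])
})

setMethod("show", "GenotypePanel", function(object) {
  d <- object@dosages
  miss <- mean(is.na(d))
  het <- mean(d == 0.5, na.rm = TRUE)
  cat(sprintf("GenotypePanel: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(d), ncol(d), length(unique(object@snpInfo$chrom))))
  cat(sprintf("  missing: %.1f%%  heterozygous: %.1f%%\n",
              100 * miss, 100 * het))
})

setMethod("show", "Kinship", function(object) {
  cat(sprintf("Kinship '%s': %d x %d, mean diagonal %.3f\n",
              object@label, nrow(object@values), ncol(object@values),
              mean(diag(object@values))))
})

setMethod("show", "AncestryEstimate", function(object) {
  cat(sprintf(
    "AncestryEstimate: %d individuals, mean theta %.3f (sd %.3f)\n",
    length(object@theta), mean(object@theta), stats::sd(object@theta)))
})
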