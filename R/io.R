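#' Read a genotype TSV into a GenotypePanel
#'
#' Expects columns `snp_id  chrom  bp  <sample1> ... <sampleN>` (one row per
#' SNP).  Cells are either numeric dosages in \{0, 0.5, 1, NA\} or
#' allele-pair codes such as `A/A`, `A/B`, `B/B`, which are recoded to
#' reference-founder dosage via `refCode` (the code letter of the reference
#' founder; `A/A` with `refCode = "A"` becomes 1, `A/B` 0.5, `B/B` 0).
#' Lines starting with `#` are treated as provenance comments and skipped.
#'
#' @param path path to the TSV file.
#' @param refCode single-character allele code of the reference founder,
#'   required when cells are allele pairs; ignored for numeric dosage files.
#' @param sep field separator, default tab.
#' @return A [GenotypePanel-class], samples x SNPs.
#' @export
readGenotypes <- function(path, refCode = NULL, sep = "\t") {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  tab <- read.delim(path, sep = sep, header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  if (ncol(tab) < 4)
    stop("genotype table needs snp_id, chrom, bp plus at least one sample")
  info <- data.frame(snpId = as.character(tab[[1]]),
                     chrom = as.character(tab[[2]]),
                     bp = as.integer(tab[[3]]),
                     stringsAsFactors = FALSE)
  cells <- as.matrix(tab[, -(1:3), drop = FALSE])
  samples <- colnames(cells)
  if (is.numeric(cells)) {
    dos <- cells
  } else {
    dos <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    pair <- grepl("/", cells) & !is.na(cells)
    if (any(pair)) {
      if (is.null(refCode))
        stop("allele-pair codes present but no refCode given")
      dos[pair] <- .recodePairs(cells[pair], refCode)
    }
    bad <- !is.na(cells) & is.na(dos)
    if (any(bad))
      stop("unknown allele code(s): ",
           paste(unique(cells[bad])[1:min(3, sum(bad))], collapse = ", "))
  }
  obs <- dos[!is.na(dos)]
  if (length(obs) && !all(obs %in% c(0, 0.5, 1)))
    stop("dosages must be 0, 0.5, 1 or NA after recoding")
  GenotypePanel(t(dos), info, samples)
}

.recodePairs <- function(codes, refCode) {
  parts <- strsplit(codes, "/", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("malformed allele pair(s): ",
         codes[which(lengths(parts) != 2)[1]])
  letters <- unique(unlist(parts))
  if (!refCode %in% letters || length(letters) > 2)
    stop("unknown allele code(s): ",
         paste(setdiff(letters, refCode), collapse = ", "))
  vapply(parts, function(p) sum(p == refCode) / 2, numeric(1))
}

#' Write a GenotypePanel to TSV
#'
#' Inverse of [readGenotypes()]; emits numeric dosages with SNPs as rows.
#' An optional `#`-prefixed provenance header records the generating
#' command and seed.
#'
#' @param g a [GenotypePanel-class].
#' @param path output file.
#' @param header optional character vector of provenance lines (written
#'   prefixed with `# `).
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(g, path, header = NULL) {
  stopifnot(is(g, "GenotypePanel"))
  out <- cbind(snp_id = snpInfo(g)$snpId, chrom = snpInfo(g)$chrom,
               bp = snpInfo(g)$bp,
               as.data.frame(t(dosages(g)), check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(colnames(out), collapse = "\t"), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a phenotype (or covariate) TSV
#'
#' Expects `sample_id  <trait1> ... <traitT>`; returns a data.frame with
#' sample ids as rownames and numeric trait columns.  At least three
#' non-missing values per trait are required downstream; this reader only
#' parses.
#'
#' @param path path to the TSV file.
#' @return data.frame of traits, rownames = sample ids.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- read.delim(path, header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  out <- as.data.frame(lapply(tab[-1], as.numeric), check.names = FALSE)
  rownames(out) <- ids
  out
}

#' Sort SNPs by chromosome and basepair position
#'
#' @param g a [GenotypePanel-class].
#' @return The panel with SNP columns ordered by (chrom, bp).
#' @export
sortSnps <- function(g) {
  o <- order(snpInfo(g)$chrom, snpInfo(g)$bp)
  g[, o]
}
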