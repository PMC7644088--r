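# Seeded forward simulators for two-founder mapping panels.
#
# Meiosis follows the Haldane (no-interference) model: crossover counts
# per chromosome are Poisson with mean L/100 for map length L in cM,
# crossover positions uniform on the map, starting phase random.
# Haplotypes are founder-label vectors (1 = reference founder) over the
# SNP grid; genotype dosage is the mean of the two haplotype labels, so
# fully inbred strains occupy {0,1} and intercross individuals
# {0, 0.5, 1}.  Physical coordinates use 2 Mb per cM, roughly the
# mouse-genome average.

.BP_PER_CM <- 2e6

#' Specify a synthetic mapping panel
#'
#' The default geometry (100 strains, 5 chromosomes of 80 cM carrying 400
#' evenly spaced SNPs each) is large enough for calibrated statistical
#' tests yet simulates in seconds.
#'
#' @param nStrains number of strains (RI / haploid) or individuals (AIL).
#' @param chromosomes data.frame with columns `label`, `lengthCm`,
#'   `nSnps`.
#' @param type panel type: "RI", "AIL" or "haploid".
#' @param nGenerations AIL generation count (F1 = generation 1;
#'   default 50).
#' @param selection optional data.frame with columns `chrom`, `snp`
#'   (index within chromosome), `favored` ("ref" or "alt") and `s`
#'   (viability selection coefficient in \[0,1\]): offspring carrying at
#'   least one disfavored allele at the locus are rejected with
#'   probability `s`.
#' @param seed integer seed consumed by the simulator.
#' @return list of class `panelSpec`.
#' @export
panelSpec <- function(nStrains = 100,
                      chromosomes = data.frame(
                        label = paste0("chr", 1:5),
                        lengthCm = 80, nSnps = 400),
                      type = c("RI", "AIL", "haploid"),
                      nGenerations = 50, selection = NULL, seed = 1) {
  type <- match.arg(type)
  stopifnot(nStrains >= 1, all(chromosomes$lengthCm >= 0),
            all(chromosomes$nSnps >= 1), nGenerations >= 1)
  if (!is.null(selection))
    stopifnot(all(c("chrom", "snp", "favored", "s") %in% names(selection)),
              all(selection$s >= 0 & selection$s <= 1))
  structure(list(nStrains = nStrains, chromosomes = chromosomes,
                 type = type, nGenerations = nGenerations,
                 selection = selection, seed = seed),
            class = "panelSpec")
}

# SNP grid bookkeeping: global indices, map positions, chromosome ranges
.snpGrid <- function(chromosomes) {
  idx <- 0L
  chrs <- vector("list", nrow(chromosomes))
  info <- vector("list", nrow(chromosomes))
  for (i in seq_len(nrow(chromosomes))) {
    m <- chromosomes$nSnps[i]
    L <- chromosomes$lengthCm[i]
    mapPos <- (seq_len(m) - 0.5) / m * L
    chrs[[i]] <- list(range = idx + seq_len(m), mapPos = mapPos, L = L)
    info[[i]] <- data.frame(
      snpId = sprintf("%s_s%04d", chromosomes$label[i], seq_len(m)),
      chrom = chromosomes$label[i],
      bp = as.integer(round(mapPos * .BP_PER_CM)) + 1L)
    idx <- idx + m
  }
  list(chrs = chrs, info = do.call(rbind, info), m = idx)
}

# one recombinant gamete for a single chromosome
.recombine <- function(h1, h2, mapPos, L) {
  k <- rpois(1, L / 100)
  start <- runif(1) < 0.5
  if (k == 0) return(if (start) h1 else h2)
  xo <- sort(runif(k, 0, L))
  phase <- (findInterval(mapPos, xo) + start) %% 2L == 0L
  out <- h1
  out[phase] <- h2[phase]
  out
}

# whole-genome gamete; frozen chromosomes (all-identical haplotypes in the
# mating pair) skip recombination draws
.gamete <- function(ind, grid, frozen = NULL) {
  out <- numeric(grid$m)
  for (i in seq_along(grid$chrs)) {
    ch <- grid$chrs[[i]]
    r <- ch$range
    if (!is.null(frozen) && frozen[i]) {
      out[r] <- ind$h1[r]
    } else {
      out[r] <- .recombine(ind$h1[r], ind$h2[r], ch$mapPos, ch$L)
    }
  }
  out
}

# viability selection: TRUE = offspring survives
.survives <- function(h1, h2, sel, selIdx) {
  if (is.null(sel)) return(TRUE)
  for (j in seq_len(nrow(sel))) {
    i <- selIdx[j]
    fav <- if (sel$favored[j] == "ref") 1 else 0
    if (h1[i] != fav || h2[i] != fav) {
      if (runif(1) < sel$s[j]) return(FALSE)
    }
  }
  TRUE
}

.selIdx <- function(sel, grid, chromosomes) {
  if (is.null(sel)) return(integer())
  as.integer(vapply(seq_len(nrow(sel)), function(j) {
    ci <- match(sel$chrom[j], chromosomes$label)
    if (is.na(ci)) stop("selection chromosome not in spec: ", sel$chrom[j])
    grid$chrs[[ci]]$range[sel$snp[j]]
  }, numeric(1)))
}

# draw one (possibly selected) offspring of parents p1, p2
.offspring <- function(p1, p2, grid, frozen, sel, selIdx,
                       maxAttempts = 200) {
  for (a in seq_len(maxAttempts)) {
    h1 <- .gamete(p1, grid, frozen)
    h2 <- .gamete(p2, grid, frozen)
    if (.survives(h1, h2, sel, selIdx)) break
  }
  list(h1 = h1, h2 = h2)
}

#' Simulate a recombinant inbred panel
#'
#' Each strain is derived independently: an F1 x F1 cross gives an F2
#' sibling pair, which is then sib-mated with per-meiosis recombination
#' until every locus is fixed (cap `fixCap` generations; residual
#' heterozygous blocks are then force-fixed by a coin flip per contiguous
#' block and counted).  Optional viability selection rejects offspring
#' carrying a disfavored allele with probability s at each selected
#' locus.  Genotypes are fully homozygous; dosage 1 marks the reference
#' founder's allele.
#'
#' @param spec a [panelSpec()] with `type = "RI"`.
#' @param fixCap generation cap before force-fixing (default 60).
#' @return list with `panel` (a [GenotypePanel-class]), `trueTheta`
#'   (per-strain reference-founder SNP fraction), `blockMap` (strains x
#'   SNPs founder-label matrix), and `nForcedBlocks` (force-fix
#'   incidence).
#' @export
simulateRiPanel <- function(spec, fixCap = 60) {
  stopifnot(inherits(spec, "panelSpec"), spec$type == "RI")
  set.seed(spec$seed)
  grid <- .snpGrid(spec$chromosomes)
  sel <- spec$selection
  selIdx <- .selIdx(sel, grid, spec$chromosomes)
  nChr <- length(grid$chrs)
  hap <- matrix(NA_real_, spec$nStrains, grid$m)
  nForced <- 0L
  f1 <- list(h1 = rep(1, grid$m), h2 = rep(0, grid$m))
  for (s in seq_len(spec$nStrains)) {
    # F2 siblings from the F1 x F1 cross
    p1 <- .offspring(f1, f1, grid, NULL, sel, selIdx)
    p2 <- .offspring(f1, f1, grid, NULL, sel, selIdx)
    for (gen in seq_len(fixCap)) {
      frozen <- vapply(grid$chrs, function(ch) {
        r <- ch$range
        all(p1$h1[r] == p1$h2[r]) && all(p2$h1[r] == p2$h2[r]) &&
          all(p1$h1[r] == p2$h1[r])
      }, logical(1))
      if (all(frozen)) break
      o1 <- .offspring(p1, p2, grid, frozen, sel, selIdx)
      o2 <- .offspring(p1, p2, grid, frozen, sel, selIdx)
      p1 <- o1; p2 <- o2
    }
    h <- p1$h1
    het <- p1$h1 != p1$h2
    if (any(het)) {
      # force-fix residual heterozygous runs, one coin flip per block
      blocks <- rle(het)
      pos <- cumsum(c(1, blocks$lengths))
      for (bi in which(blocks$values)) {
        r <- pos[bi]:(pos[bi + 1] - 1)
        if (runif(1) < 0.5) h[r] <- p1$h2[r]
        nForced <- nForced + 1L
      }
    }
    hap[s, ] <- h
  }
  ids <- sprintf("RI%03d", seq_len(spec$nStrains))
  panel <- GenotypePanel(hap, grid$info, ids)
  list(panel = panel, trueTheta = rowMeans(hap), blockMap = hap,
       nForcedBlocks = nForced)
}

#' Simulate an advanced intercross line (AIL)
#'
#' F1 individuals (all heterozygous) are propagated by random-pair mating
#' for `nGenerations` generations with constant population size; emitted
#' dosages lie in \{0, 0.5, 1\}.  Viability selection as in
#' [simulateRiPanel()].
#'
#' @param spec a [panelSpec()] with `type = "AIL"`; `nStrains` is the
#'   (even) population size, at least 20.
#' @return list with `panel`, `trueTheta` (mean founder fraction over
#'   both haplotypes).
#' @export
simulateAilPanel <- function(spec) {
  stopifnot(inherits(spec, "panelSpec"), spec$type == "AIL")
  n <- spec$nStrains
  if (n < 20 || n %% 2 != 0)
    stop("AIL population size must be an even number >= 20")
  set.seed(spec$seed)
  grid <- .snpGrid(spec$chromosomes)
  sel <- spec$selection
  selIdx <- .selIdx(sel, grid, spec$chromosomes)
  pop <- replicate(n, list(h1 = rep(1, grid$m), h2 = rep(0, grid$m)),
                   simplify = FALSE)
  if (spec$nGenerations > 1) {
    for (gen in 2:spec$nGenerations) {
      perm <- sample(n)
      nxt <- vector("list", n)
      for (pr in seq_len(n / 2)) {
        p1 <- pop[[perm[2 * pr - 1]]]
        p2 <- pop[[perm[2 * pr]]]
        nxt[[2 * pr - 1]] <- .offspring(p1, p2, grid, NULL, sel, selIdx)
        nxt[[2 * pr]] <- .offspring(p1, p2, grid, NULL, sel, selIdx)
      }
      pop <- nxt
    }
  }
  dos <- t(vapply(pop, function(i) (i$h1 + i$h2) / 2, numeric(grid$m)))
  ids <- sprintf("AIL%04d", seq_len(n))
  list(panel = GenotypePanel(dos, grid$info, ids),
       trueTheta = rowMeans(dos))
}

#' Simulate a two-parent haploid cross (yeast-style segregant panel)
#'
#' One meiosis per progeny from the F1 diploid; haploid genotypes with
#' dosage in \{0, 1\}.
#'
#' @param spec a [panelSpec()] with `type = "haploid"`.
#' @return list with `panel`, `trueTheta`.
#' @export
simulateHaploidCross <- function(spec) {
  stopifnot(inherits(spec, "panelSpec"), spec$type == "haploid")
  set.seed(spec$seed)
  grid <- .snpGrid(spec$chromosomes)
  f1 <- list(h1 = rep(1, grid$m), h2 = rep(0, grid$m))
  dos <- t(vapply(seq_len(spec$nStrains),
                  function(i) .gamete(f1, grid), numeric(grid$m)))
  ids <- sprintf("SEG%04d", seq_len(spec$nStrains))
  list(panel = GenotypePanel(dos, grid$info, ids),
       trueTheta = rowMeans(dos))
}

#' Simulate a multi-cross RI panel sharing a common reference founder
#'
#' Emulates the structure of a composite RI resource in which several
#' sub-panels share one common founder but differ in their second
#' founder: each SNP segregates (parents differ) only in a random subset
#' of crosses, and where the second founder carries the reference allele
#' the cross is invariant at that site (all dosages 1).  This is the
#' geometry under which the ancestry GRM (informative sites per cross)
#' differs from the genome-wide GRM, and under which per-site frequency
#' computations must exclude invariant crosses.
#'
#' @param spec a [panelSpec()] with `type = "RI"`; `nStrains` is the
#'   per-cross strain count.
#' @param nCrosses number of sub-panels.
#' @param segProb probability each SNP segregates in a given cross
#'   (independently; resampled so every SNP segregates somewhere).
#' @return list with `panel` (all crosses stacked), `membership`
#'   (per-strain cross label), `eligibility` (per-cross informative SNP
#'   indices), `parents` (per-cross second-founder dosage rows; the
#'   common reference founder is all 1), `trueTheta`, and `blockMap`.
#' @export
simulateMultiCrossRiPanel <- function(spec, nCrosses = 2, segProb = 0.7) {
  stopifnot(inherits(spec, "panelSpec"), spec$type == "RI", nCrosses >= 1)
  set.seed(spec$seed)
  grid <- .snpGrid(spec$chromosomes)
  seg <- matrix(runif(grid$m * nCrosses) < segProb, grid$m, nCrosses)
  none <- rowSums(seg) == 0
  if (any(none)) seg[cbind(which(none), sample(nCrosses, sum(none),
                                               replace = TRUE))] <- TRUE
  panels <- vector("list", nCrosses)
  for (cr in seq_len(nCrosses)) {
    sub <- spec
    sub$seed <- spec$seed + cr  # independent sub-panel streams
    panels[[cr]] <- simulateRiPanel(sub)
  }
  block <- do.call(rbind, lapply(panels, `[[`, "blockMap"))
  membership <- rep(paste0("cross", seq_len(nCrosses)),
                    each = spec$nStrains)
  dos <- block
  for (cr in seq_len(nCrosses)) {
    rows <- which(membership == paste0("cross", cr))
    inv <- which(!seg[, cr])
    if (length(inv)) dos[rows, inv] <- 1  # second founder shares ref allele
  }
  eligibility <- lapply(seq_len(nCrosses), function(cr) which(seg[, cr]))
  names(eligibility) <- paste0("cross", seq_len(nCrosses))
  parents <- lapply(seq_len(nCrosses),
                    function(cr) ifelse(seg[, cr], 0, 1))
  names(parents) <- paste0("cross", seq_len(nCrosses))
  ids <- sprintf("%s_RI%03d", membership,
                 rep(seq_len(spec$nStrains), nCrosses))
  list(panel = GenotypePanel(dos, grid$info, ids),
       membership = membership, eligibility = eligibility,
       parents = parents,
       trueTheta = rowMeans(block), blockMap = block)
}
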