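## Pairwise identical-by-descent segment detection among inbred genomes.
## Segments are maximal runs of identical, non-missing, homozygous
## genotypes at SNP panel sites; coordinates snap to the outermost matching
## panel SNPs, so segment lengths are reproducible from the panel alone.

#' Minor allele frequency per site
#'
#' Computed over non-missing strain genotypes (two alleles per strain);
#' the all-hom-ref reference strain can optionally be counted as an
#' additional sample.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param countReference Count the implicit reference strain (two
#'   reference alleles per site) toward allele frequencies.
#' @return Numeric vector of per-site minor allele frequencies.
#' @export
minorAlleleFreq <- function(gm, countReference = FALSE) {
  gt <- genotypes(gm)
  altCount <- rowSums(gt, na.rm = TRUE)
  nAllele <- 2 * rowSums(!is.na(gt))
  if (countReference) nAllele <- nAllele + 2
  f <- altCount / nAllele
  pmin(f, 1 - f)
}

#' Restrict to the IBD inference SNP panel
#'
#' Keeps sites with minor allele frequency strictly greater than `mafMin`.
#' The default 0.05 excludes singleton (private) alleles for panels of
#' more than 20 strains; for smaller panels choose `mafMin` between the
#' singleton and doubleton frequency to preserve that property (see
#' [defaultFixtureConfig]).
#'
#' @inheritParams minorAlleleFreq
#' @param mafMin Minor allele frequency cutoff in `[0, 0.5)`.
#' @return The row-subset [GenotypeMatrix-class]; errors if empty.
#' @export
buildIbdPanel <- function(gm, mafMin = 0.05, countReference = FALSE) {
  if (mafMin < 0 || mafMin >= 0.5) stop("mafMin must be in [0, 0.5)")
  keep <- minorAlleleFreq(gm, countReference) > mafMin
  if (!any(keep)) stop("no sites remain after the MAF filter")
  gm[keep, ]
}

## maximal windows of panel indices containing at most maxMismatches
## non-matching sites, with matching endpoints. ok is a logical vector.
.maximalRuns <- function(ok, maxMismatches = 0L) {
  n <- length(ok)
  if (n == 0) return(matrix(integer(0), ncol = 2))
  bad <- which(!ok)
  b <- c(0L, bad, n + 1L)
  m <- maxMismatches
  nWin <- length(b) - m - 1L
  if (nWin < 1) {
    ## every site fits in one window
    return(if (any(ok)) cbind(which(ok)[1], max(which(ok))) else
      matrix(integer(0), ncol = 2))
  }
  lo <- b[seq_len(nWin)] + 1L
  hi <- b[seq_len(nWin) + m + 1L] - 1L
  if (m == 0L) {
    keep <- lo <= hi
    return(cbind(lo[keep], hi[keep]))
  }
  out <- matrix(integer(0), ncol = 2)
  for (j in seq_len(nWin)) {
    l <- lo[j]; h <- hi[j]
    if (l > h) next
    ## trim endpoints to matching sites
    while (l <= h && !ok[l]) l <- l + 1L
    while (h >= l && !ok[h]) h <- h - 1L
    if (l > h) next
    out <- rbind(out, c(l, h))
  }
  out <- unique(out)
  ## trimming at consecutive non-matching sites can leave nested windows
  if (nrow(out) > 1) {
    keep <- vapply(seq_len(nrow(out)), function(k)
      !any(out[, 1] <= out[k, 1] & out[, 2] >= out[k, 2] &
             (out[, 1] != out[k, 1] | out[, 2] != out[k, 2])),
      logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Detect pairwise IBD segments
#'
#' Scans the SNP panel for maximal runs of sites where both strains carry
#' identical, non-missing, homozygous genotypes. Heterozygous calls
#' (residual heterozygosity or error in nominally inbred genomes) and
#' missing calls are treated as non-matching. With `maxMismatches = 0`
#' (the default) a single non-matching site terminates a run; larger
#' budgets return maximal windows containing at most that many
#' non-matching sites. Runs whose spanned length is below `minSeedBp` are
#' discarded.
#'
#' @param panel A [GenotypeMatrix-class] (typically from [buildIbdPanel]).
#' @param strainA,strainB Strain names.
#' @param minSeedBp Minimum spanned length in bp (default 200 kb).
#' @param maxMismatches Non-matching sites tolerated inside a segment.
#' @return A `GRanges` of segments with metadata `strainA`, `strainB`,
#'   `nSites` (panel sites spanned); 1-based inclusive coordinates at the
#'   outermost matching panel SNPs.
#' @export
detectPairwiseIbd <- function(panel, strainA, strainB, minSeedBp = 2e5,
                              maxMismatches = 0L) {
  sn <- strainNames(panel)
  if (!strainA %in% sn) stop("unknown strain: ", strainA)
  if (!strainB %in% sn) stop("unknown strain: ", strainB)
  gt <- genotypes(panel)
  chrom <- siteChrom(panel)
  pos <- sitePos(panel)
  a <- gt[, strainA]
  b <- gt[, strainB]
  res <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ai <- a[sel]; bi <- b[sel]
    ok <- !is.na(ai) & !is.na(bi) & ai == bi & ai != 1L
    runs <- .maximalRuns(ok, maxMismatches)
    if (!nrow(runs)) next
    startPos <- pos[sel][runs[, 1]]
    endPos <- pos[sel][runs[, 2]]
    keep <- (endPos - startPos + 1) >= minSeedBp
    if (!any(keep)) next
    res[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(startPos[keep], endPos[keep]),
      strainA = strainA, strainB = strainB,
      nSites = runs[keep, 2] - runs[keep, 1] + 1L)
  }
  if (!length(res)) {
    return(GenomicRanges::GRanges(strainA = character(0),
                                  strainB = character(0),
                                  nSites = integer(0)))
  }
  unname(do.call(c, unname(res)))
}

#' Detect IBD segments for every strain pair
#'
#' @inheritParams detectPairwiseIbd
#' @param minKeepBp Optional retention threshold applied afterwards via
#'   [filterSegments] (e.g. 5 Mb); `NULL` keeps all.
#' @return Combined `GRanges` over all unordered strain pairs.
#' @export
detectIbdSegments <- function(panel, minSeedBp = 2e5, maxMismatches = 0L,
                              minKeepBp = NULL) {
  sn <- strainNames(panel)
  pairs <- combn(sn, 2)
  segs <- lapply(seq_len(ncol(pairs)), function(i)
    detectPairwiseIbd(panel, pairs[1, i], pairs[2, i], minSeedBp,
                      maxMismatches))
  segs <- segs[vapply(segs, length, integer(1)) > 0]
  out <- if (length(segs)) unname(do.call(c, segs)) else
    GenomicRanges::GRanges(strainA = character(0), strainB = character(0),
                           nSites = integer(0))
  if (!is.null(minKeepBp)) out <- filterSegments(out, minKeepBp)
  out
}

#' Retain long IBD segments
#'
#' Analyses of private variants are restricted to IBD territory at least
#' `minLengthBp` long (default 5 Mb), longer than any identical run
#' expected between unrelated wild genomes.
#'
#' @param segments `GRanges` of IBD segments.
#' @param minLengthBp Inclusive minimum segment length in bp.
#' @return Filtered `GRanges`.
#' @export
filterSegments <- function(segments, minLengthBp = 5e6) {
  segments[BiocGenerics::width(segments) >= minLengthBp]
}

#' Fraction of a strain's genome in IBD segments
#'
#' Union of all retained segments involving the strain (any partner),
#' divided by the genome length.
#'
#' @param segments `GRanges` of (already length-filtered) IBD segments.
#' @param strain Strain name.
#' @param genomeLength Genome length in bp.
#' @return Fraction in `[0, 1]`.
#' @export
strainIbdCoverage <- function(segments, strain, genomeLength) {
  sel <- S4Vectors::mcols(segments)$strainA == strain |
    S4Vectors::mcols(segments)$strainB == strain
  segs <- GenomicRanges::reduce(segments[sel])
  sum(as.numeric(BiocGenerics::width(segs))) / genomeLength
}

#' Longest identical-genotype run between any two samples
#'
#' Maximum spanned length (bp) of a run of consecutive sites at which two
#' samples carry identical non-missing genotypes (heterozygous matching
#' heterozygous counts as identical here, making the measure conservative
#' for outbred samples). Used to verify that a wild outgroup shows no
#' megabase-scale IBD.
#'
#' @param gm A [GenotypeMatrix-class] with at least two samples.
#' @return Length in bp of the longest run (0 if no two sites ever match).
#' @export
longestPairwiseRun <- function(gm) {
  if (ncol(gm) < 2) stop("need at least two samples")
  gt <- genotypes(gm)
  chrom <- siteChrom(gm)
  pos <- sitePos(gm)
  best <- 0
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    g <- gt[sel, , drop = FALSE]
    p <- pos[sel]
    for (i in seq_len(ncol(g) - 1)) {
      for (j in seq(i + 1, ncol(g))) {
        ok <- !is.na(g[, i]) & !is.na(g[, j]) & g[, i] == g[, j]
        r <- rle(ok)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        good <- which(r$values)
        if (length(good)) {
          span <- p[ends[good]] - p[starts[good]] + 1
          best <- max(best, span)
        }
      }
    }
  }
  best
}
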