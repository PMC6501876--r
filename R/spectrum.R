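## Folded, opportunity-standardized mutation spectra per strain.

.classLevels <- function(splitCpg) if (splitCpg) SEVEN_CLASSES else
  FOLDED_CLASSES

#' Tally folded mutation classes for a strain
#'
#' With `splitCpg`, C>T events are divided by their CpG flag into
#' `CpG>TpG` and `nonCpG>T` (seven categories).
#'
#' @param spvs SPV record data frame (see [applyFilterStack]).
#' @param strain Strain name.
#' @param splitCpg Use the seven-category classification.
#' @return Named integer vector over the class levels.
#' @export
countClasses <- function(spvs, strain, splitCpg = FALSE) {
  lv <- .classLevels(splitCpg)
  counts <- setNames(integer(length(lv)), lv)
  if (!nrow(spvs)) return(counts)
  x <- spvs[spvs$strain == strain, , drop = FALSE]
  cls <- x$folded_class
  if (splitCpg) {
    ct <- cls == "C>T"
    cls[ct] <- ifelse(!is.na(x$cpg_flag[ct]) & x$cpg_flag[ct],
                      "CpG>TpG", "nonCpG>T")
  }
  tab <- table(factor(cls, levels = lv))
  counts[] <- as.integer(tab)
  counts
}

#' Mutational opportunities in a strain's IBD territory
#'
#' Counts, over the union of the strain's retained IBD intervals on the
#' reference sequence, the bases at which each folded class could occur:
#' C-rooted classes can occur at C or G bases, T-rooted classes at A or T
#' bases. With `splitCpg`, the C>T opportunity is divided into bases that
#' are part of a CpG dinucleotide (each CG occurrence contributes its two
#' bases, covering both strands) and all remaining C/G bases.
#'
#' @param ref Reference `DNAStringSet`.
#' @param segments Retained IBD segments (`GRanges`).
#' @param strain Strain name.
#' @param splitCpg Use the seven-category classification.
#' @return Named numeric vector of opportunity counts per class.
#' @export
ibdComposition <- function(ref, segments, strain, splitCpg = FALSE) {
  sel <- S4Vectors::mcols(segments)$strainA == strain |
    S4Vectors::mcols(segments)$strainB == strain
  segs <- GenomicRanges::reduce(segments[sel])
  lv <- .classLevels(splitCpg)
  opp <- setNames(numeric(length(lv)), lv)
  if (!length(segs)) return(opp)
  nC <- nG <- nA <- nT <- nCG <- 0
  for (ch in unique(as.character(GenomicRanges::seqnames(segs)))) {
    s <- segs[as.character(GenomicRanges::seqnames(segs)) == ch]
    v <- Biostrings::Views(ref[[ch]], BiocGenerics::start(s),
                           BiocGenerics::end(s))
    lf <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    nA <- nA + sum(lf[, "A"]); nC <- nC + sum(lf[, "C"])
    nG <- nG + sum(lf[, "G"]); nT <- nT + sum(lf[, "T"])
    nCG <- nCG + sum(Biostrings::vcountPattern("CG", v))
  }
  cOpp <- nC + nG
  tOpp <- nA + nT
  if (splitCpg) {
    opp[c("C>A", "C>G")] <- cOpp
    opp["CpG>TpG"] <- 2 * nCG
    opp["nonCpG>T"] <- cOpp - 2 * nCG
    opp[c("T>A", "T>C", "T>G")] <- tOpp
  } else {
    opp[c("C>A", "C>G", "C>T")] <- cOpp
    opp[c("T>A", "T>C", "T>G")] <- tOpp
  }
  opp
}

#' Standardize class counts by mutational opportunity
#'
#' Divides each class count by its opportunity (giving a per-base rate)
#' and rescales the rates to sum to one. Classes with zero opportunity
#' and zero count get frequency zero; a positive count with zero
#' opportunity is an error.
#'
#' @param counts Named class counts.
#' @param opportunities Named opportunity counts (same classes).
#' @return Named frequencies summing to 1 (all-zero when no counts).
#' @export
standardizeSpectrum <- function(counts, opportunities) {
  stopifnot(identical(names(counts), names(opportunities)))
  if (any(opportunities == 0 & counts > 0))
    stop("positive count with zero opportunity")
  rate <- ifelse(opportunities > 0, counts / opportunities, 0)
  tot <- sum(rate)
  if (tot == 0) return(setNames(numeric(length(counts)), names(counts)))
  rate / tot
}

#' Build the per-strain spectrum matrix
#'
#' Combines class counts, IBD-territory opportunities, standardized
#' frequencies and raw count proportions for a set of strains.
#'
#' @param spvs SPV record data frame.
#' @param ref Reference `DNAStringSet`.
#' @param segments Retained IBD segments.
#' @param strains Strains to include (default: all in `spvs`).
#' @param splitCpg Use the seven-category classification.
#' @return A [SpectrumMatrix-class].
#' @export
spectrumMatrix <- function(spvs, ref, segments, strains = NULL,
                           splitCpg = FALSE) {
  if (is.null(strains)) strains <- sort(unique(spvs$strain))
  lv <- .classLevels(splitCpg)
  counts <- t(vapply(strains, function(s) countClasses(spvs, s, splitCpg),
                     numeric(length(lv))))
  opp <- t(vapply(strains, function(s)
    ibdComposition(ref, segments, s, splitCpg), numeric(length(lv))))
  freq <- t(vapply(seq_along(strains), function(k)
    standardizeSpectrum(counts[k, ], opp[k, ]), numeric(length(lv))))
  tot <- rowSums(counts)
  prop <- counts / ifelse(tot > 0, tot, 1)
  dimnames(counts) <- dimnames(opp) <- dimnames(freq) <- dimnames(prop) <-
    list(strains, lv)
  methods::new("SpectrumMatrix", counts = counts, opportunities = opp,
               frequencies = freq, proportions = prop)
}
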