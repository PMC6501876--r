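## Strain-private variant calling: singleton identification, the stringent
## quality filter stack with per-rule audit, polarization, trinucleotide
## contexts, and common-variant definition with parsimony ancestral states.

#' Identify singleton candidate sites
#'
#' A candidate strain-private variant is a site where exactly one strain
#' carries the alternative allele (heterozygous or homozygous) and every
#' other non-missing strain is homozygous reference.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Data frame with columns `siteIndex`, `strain`, `chrom`, `pos`,
#'   `zygosity` (`fixed` for hom-alt, `heterozygous` for het carriers).
#' @export
identifySingletons <- function(gm) {
  gt <- genotypes(gm)
  carriers <- rowSums(gt >= 1L, na.rm = TRUE)
  nonMissing <- rowSums(!is.na(gt))
  sel <- which(carriers == 1L & nonMissing >= 2L)
  if (!length(sel))
    return(data.frame(siteIndex = integer(), strain = character(),
                      chrom = character(), pos = integer(),
                      zygosity = character()))
  carrierIdx <- apply(gt[sel, , drop = FALSE], 1,
                      function(r) which(!is.na(r) & r >= 1L)[1])
  carrierGt <- gt[cbind(sel, carrierIdx)]
  data.frame(siteIndex = sel,
             strain = strainNames(gm)[carrierIdx],
             chrom = siteChrom(gm)[sel],
             pos = sitePos(gm)[sel],
             zygosity = ifelse(carrierGt == 2L, "fixed", "heterozygous"))
}

#' Mean sequencing depth per strain
#'
#' Average of the DP field over all processed sites per sample; used for
#' the excess-coverage cutoff of the filter stack.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return Named numeric vector.
#' @export
strainMeanDepth <- function(gm) {
  colMeans(SummarizedExperiment::assay(gm, "dp"), na.rm = TRUE)
}

#' Filter stack parameters
#'
#' Thresholds for [applyFilterStack]: site quality > 50, focal genotype
#' quality > 60, focal depth > 10 and < 1.9x the strain's mean depth,
#' < 15% missing genotypes, focal phred likelihood margin > 20,
#' heterozygous allele balance (minor-read fraction) > 0.3, and
#' heterozygous strand/allele bias test p > 0.05.
#'
#' @param qualMin,gqMin,dpMin,dpMaxFactor,missingMax,plMarginMin,balanceMin,biasAlpha
#'   Numeric thresholds.
#' @return Named list.
#' @export
spvFilterParams <- function(qualMin = 50, gqMin = 60, dpMin = 10,
                            dpMaxFactor = 1.9, missingMax = 0.15,
                            plMarginMin = 20, balanceMin = 0.3,
                            biasAlpha = 0.05) {
  list(qualMin = qualMin, gqMin = gqMin, dpMin = dpMin,
       dpMaxFactor = dpMaxFactor, missingMax = missingMax,
       plMarginMin = plMarginMin, balanceMin = balanceMin,
       biasAlpha = biasAlpha)
}

#' Chi-square test for allele and strand bias
#'
#' Goodness-of-fit test (df = 3) comparing the four per-strand allele read
#' counts (ref-forward, ref-reverse, alt-forward, alt-reverse) to the
#' counts expected under an allele fraction of 1/2 combined with the
#' observed overall forward/reverse read ratio. Cells with zero expected
#' and zero observed counts contribute nothing; a positive observation in
#' a zero-expectation cell gives p = 0.
#'
#' @param refFwd,refRev,altFwd,altRev Non-negative read counts.
#' @return Upper-tail p-value.
#' @export
chi2BiasTest <- function(refFwd, refRev, altFwd, altRev) {
  o <- c(refFwd, refRev, altFwd, altRev)
  if (any(is.na(o)) || any(o < 0)) stop("strand counts must be non-negative")
  n <- sum(o)
  if (n == 0) stop("no reads: bias test undefined")
  fwd <- (refFwd + altFwd) / n
  e <- n * c(0.5 * fwd, 0.5 * (1 - fwd), 0.5 * fwd, 0.5 * (1 - fwd))
  term <- ifelse(e > 0, (o - e)^2 / e, ifelse(o > 0, Inf, 0))
  stat <- sum(term)
  pchisq(stat, df = 3, lower.tail = FALSE)
}

#' Polarize a singleton into ancestral and derived alleles
#'
#' The major (non-private) allele is taken as ancestral: for a singleton
#' whose carrier holds the alternative allele the ancestral state is the
#' reference allele. The reference-private pattern (focal strain
#' homozygous reference while every other strain carries the alternative)
#' is not a singleton in this sense and raises an error.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param siteIndex Row index of the site.
#' @param strain Focal strain name.
#' @return Named character vector `c(ancestral=, derived=)`.
#' @export
polarizeSingleton <- function(gm, siteIndex, strain) {
  gt <- genotypes(gm)[siteIndex, ]
  focal <- gt[strain]
  others <- gt[setdiff(names(gt), strain)]
  if (is.na(focal) || focal < 1)
    stop("focal strain does not carry the alternative allele; ",
         "reference-private patterns are excluded upstream")
  if (any(others >= 1, na.rm = TRUE))
    stop("site is not private to ", strain)
  c(ancestral = refAllele(gm)[siteIndex], derived = altAllele(gm)[siteIndex])
}

#' Reference-strand trinucleotide context
#'
#' @param ref A `DNAStringSet` reference store.
#' @param chrom,pos Site coordinates (1-based). Sites at a contig edge get
#'   `NA`.
#' @return Character vector of 3-mers centred on the site.
#' @export
trinucleotideContext <- function(ref, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    len <- Biostrings::width(ref[ch])
    sel <- which(chrom == ch & pos > 1 & pos < len)
    if (!length(sel)) next
    v <- Biostrings::extractAt(ref[[ch]],
                               IRanges::IRanges(pos[sel] - 1L, width = 3L))
    out[sel] <- as.character(v)
  }
  out
}

#' Apply the strain-private variant filter stack
#'
#' Evaluates the stringent filter rules in a fixed order for each
#' singleton candidate and keeps those passing all of them:
#' site quality (`qual`), focal genotype quality (`gq`), focal depth
#' bounds (`dp`), site missingness (`missing`), segmental-duplication and
#' repeat masks (`segdup`, `repeat`), focal likelihood margin
#' (`pl_margin`), absence from the wild and wild-derived panels (`wild`),
#' location on a retained IBD segment of the focal strain (`ibd`), and for
#' heterozygous candidates allele balance (`balance`) and the
#' strand/allele bias test (`strand_bias`). The audit records the first
#' failing rule per rejected candidate, so every candidate is either a
#' survivor or appears in exactly one failure counter. Survivors are
#' polarized (major allele ancestral) and annotated with their folded
#' class, reference-strand trinucleotide context and CpG status.
#'
#' @param candidates Data frame from [identifySingletons].
#' @param gm The laboratory [GenotypeMatrix-class].
#' @param ref Reference `DNAStringSet` (for trinucleotide contexts).
#' @param repeatTrack,segdupTrack Mask `GRanges` (possibly empty).
#' @param wildMatrix,wildDerivedMatrix Outgroup genotype matrices; a
#'   candidate fails `wild` when its position carries any non-reference
#'   allele in either panel. `NULL` skips the respective check.
#' @param segments Retained (>= 5 Mb) IBD segments; must be non-empty.
#' @param params See [spvFilterParams].
#' @return List with `spvs` (data frame of SPV records: strain, chrom,
#'   pos, ancestral, derived, zygosity, folded_class,
#'   trinucleotide_context, cpg_flag) and `audit` (list with
#'   `candidates`, named `failures` vector, `survivors`).
#' @export
applyFilterStack <- function(candidates, gm, ref, repeatTrack,
                             segdupTrack, wildMatrix, wildDerivedMatrix,
                             segments, params = spvFilterParams()) {
  if (length(segments) == 0)
    stop("no IBD territory; SPV calling undefined")
  n <- nrow(candidates)
  rules <- .ruleNames()
  failures <- setNames(integer(length(rules)), rules)
  if (n == 0) {
    return(list(spvs = data.frame(), audit = list(candidates = 0L,
                                                  failures = failures,
                                                  survivors = 0L)))
  }
  i <- candidates$siteIndex
  j <- match(candidates$strain, strainNames(gm))
  het <- candidates$zygosity == "heterozygous"
  A <- function(name) SummarizedExperiment::assay(gm, name)[cbind(i, j)]
  qual <- siteQual(gm)[i]
  gq <- A("gq"); dp <- A("dp"); pl <- A("plMargin")
  adR <- A("adRef"); adA <- A("adAlt")
  rF <- A("refFwd"); rR <- A("refRev"); aF <- A("altFwd"); aR <- A("altRev")
  meanDp <- strainMeanDepth(gm)[j]
  gt <- genotypes(gm)
  missFrac <- rowMeans(is.na(gt))[i]

  altInOutgroup <- function(og) {
    if (is.null(og)) return(rep(FALSE, n))
    idx <- match(paste(candidates$chrom, candidates$pos),
                 paste(siteChrom(og), sitePos(og)))
    carried <- rep(FALSE, n)
    has <- !is.na(idx)
    if (any(has)) {
      g <- genotypes(og)[idx[has], , drop = FALSE]
      carried[has] <- rowSums(g >= 1L, na.rm = TRUE) > 0
    }
    carried
  }
  wildHit <- altInOutgroup(wildMatrix) | altInOutgroup(wildDerivedMatrix)

  onIbd <- rep(FALSE, n)
  segA <- S4Vectors::mcols(segments)$strainA
  segB <- S4Vectors::mcols(segments)$strainB
  for (s in unique(candidates$strain)) {
    ck <- which(candidates$strain == s)
    segs <- segments[segA == s | segB == s]
    if (length(segs))
      onIbd[ck] <- pointInTrack(GenomicRanges::reduce(segs),
                                candidates$chrom[ck], candidates$pos[ck])
  }

  balance <- ifelse(adR + adA > 0, pmin(adR, adA) / (adR + adA), NA)
  biasP <- rep(NA_real_, n)
  needBias <- which(het)
  for (k in needBias) {
    counts <- c(rF[k], rR[k], aF[k], aR[k])
    biasP[k] <- if (anyNA(counts) || sum(counts) == 0) NA_real_ else
      chi2BiasTest(counts[1], counts[2], counts[3], counts[4])
  }

  p <- params
  pass <- function(x) !is.na(x) & x   # NA (missing annotation) fails
  maskHit <- function(track) {
    if (is.null(track)) rep(FALSE, n) else
      pointInTrack(track, candidates$chrom, candidates$pos)
  }
  checks <- list(
    qual = pass(qual > p$qualMin),
    gq = pass(gq > p$gqMin),
    dp = pass(dp > p$dpMin & dp < p$dpMaxFactor * meanDp),
    missing = pass(missFrac < p$missingMax),
    segdup = !maskHit(segdupTrack),
    `repeat` = !maskHit(repeatTrack),
    pl_margin = pass(pl > p$plMarginMin),
    wild = !wildHit,
    ibd = onIbd,
    balance = !het | pass(balance > p$balanceMin),
    strand_bias = !het | pass(biasP > p$biasAlpha))

  firstFail <- rep(NA_character_, n)
  for (r in rev(rules)) firstFail[!checks[[r]]] <- r
  survive <- is.na(firstFail)
  tab <- table(factor(firstFail, levels = rules))
  failures[] <- as.integer(tab)

  spvs <- data.frame()
  if (any(survive)) {
    sel <- which(survive)
    anc <- refAllele(gm)[i[sel]]
    der <- altAllele(gm)[i[sel]]
    fc <- foldClass(anc, der)
    ctx <- trinucleotideContext(ref, candidates$chrom[sel],
                                candidates$pos[sel])
    spvs <- data.frame(strain = candidates$strain[sel],
                       chrom = candidates$chrom[sel],
                       pos = candidates$pos[sel],
                       ancestral = anc, derived = der,
                       zygosity = candidates$zygosity[sel],
                       folded_class = fc$folded_class,
                       trinucleotide_context = ctx,
                       cpg_flag = cpgAnnotate(ctx, fc$folded_class,
                                              fc$flipped))
  }
  list(spvs = spvs,
       audit = list(candidates = n, failures = failures,
                    survivors = sum(survive)))
}

#' Define common variants
#'
#' Common variants are biallelic SNPs whose alternative allele is carried
#' by at least two strains. Sites inside the repeat or
#' segmental-duplication masks are excluded, matching the masking applied
#' to strain-private variants.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param repeatTrack,segdupTrack Optional mask `GRanges`.
#' @return Data frame with columns siteIndex, chrom, pos, ref, alt.
#' @export
defineCommonVariants <- function(gm, repeatTrack = NULL,
                                 segdupTrack = NULL) {
  gt <- genotypes(gm)
  carriers <- rowSums(gt >= 1L, na.rm = TRUE)
  sel <- which(carriers >= 2L)
  chrom <- siteChrom(gm)[sel]
  pos <- sitePos(gm)[sel]
  keep <- rep(TRUE, length(sel))
  if (!is.null(repeatTrack))
    keep <- keep & !pointInTrack(repeatTrack, chrom, pos)
  if (!is.null(segdupTrack))
    keep <- keep & !pointInTrack(segdupTrack, chrom, pos)
  data.frame(siteIndex = sel[keep], chrom = chrom[keep], pos = pos[keep],
             ref = refAllele(gm)[sel[keep]], alt = altAllele(gm)[sel[keep]])
}

#' Parsimony ancestral states for common variants
#'
#' The ancestral allele of a common variant is the allele fixed across the
#' wild-derived outgroup panel at that site; sites segregating (or with
#' heterozygous calls) in the wild-derived panel are left undetermined
#' (`NA`). Sites absent from the wild-derived matrix are treated as fixed
#' reference there.
#'
#' @param common Data frame from [defineCommonVariants].
#' @param wildDerivedMatrix Wild-derived [GenotypeMatrix-class].
#' @return `common` with added `ancestral` and `derived` columns (`NA`
#'   when undetermined).
#' @export
polarizeCommon <- function(common, wildDerivedMatrix) {
  idx <- match(paste(common$chrom, common$pos),
               paste(siteChrom(wildDerivedMatrix),
                     sitePos(wildDerivedMatrix)))
  anc <- rep(NA_character_, nrow(common))
  absent <- is.na(idx)
  anc[absent] <- common$ref[absent]
  if (any(!absent)) {
    g <- genotypes(wildDerivedMatrix)[idx[!absent], , drop = FALSE]
    allRef <- rowSums(g != 0L, na.rm = TRUE) == 0 & rowSums(!is.na(g)) > 0
    allAlt <- rowSums(g != 2L, na.rm = TRUE) == 0 & rowSums(!is.na(g)) > 0
    a <- rep(NA_character_, sum(!absent))
    a[allRef] <- common$ref[!absent][allRef]
    a[allAlt] <- common$alt[!absent][allAlt]
    anc[!absent] <- a
  }
  common$ancestral <- anc
  common$derived <- ifelse(is.na(anc), NA_character_,
                           ifelse(anc == common$ref, common$alt, common$ref))
  common
}
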