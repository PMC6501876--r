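## Mosaic-genome simulator: laboratory-strain-like genomes assembled from a
## small founder haplotype pool, with planted strain-private mutations and
## full ground truth, plus a diverse wild outgroup. Every stochastic
## function takes an explicit seed and is reproducible.

#' Default simulation settings
#'
#' One synthetic autosome of 60 Mb carrying a SNP panel at one segregating
#' site per 2 kb, eight founder haplotypes, twelve inbred strains whose
#' genomes are founder-block mosaics with mean block length 10 Mb, 300
#' planted private mutations per strain of which 8.3% are heterozygous, a
#' folded six-class mutation spectrum with a C>T transition share of 0.50,
#' a 27-sample wild outgroup, and repeat/segmental-duplication masks
#' covering 5% and 2% of the chromosome. `panelMafMin` is the minor allele
#' frequency cutoff used when building the IBD SNP panel for this fixture;
#' 0.1 sits between the singleton (1/12) and doubleton (2/12) frequency for
#' a twelve-strain panel, preserving the property that private alleles are
#' excluded from IBD inference while doubletons are kept (the analogous
#' cutoff for a 29-strain panel is 0.05).
#'
#' @return Named list of simulation parameters.
#' @export
defaultFixtureConfig <- function() {
  list(chromName = "chrS",
       chromLength = 6e7,
       gcContent = 0.42,
       nFounders = 8,
       snpDensity = 5e-4,
       nStrains = 12,
       meanBlockLength = 1e7,
       mutationsPerStrain = 300,
       hetFraction = 0.083,
       spectrum = c("C>A" = 0.08, "C>G" = 0.06, "C>T" = 0.50,
                    "T>A" = 0.10, "T>C" = 0.20, "T>G" = 0.06),
       nWild = 27,
       extraDiversity = 0.5,
       repeatFraction = 0.05,
       segdupFraction = 0.02,
       maskMeanLength = 5e4,
       nGenes = 0,
       panelMafMin = 0.1,
       minSeedBp = 2e5,
       minKeepBp = 5e6)
}

#' Simulate a random reference sequence
#'
#' @param chromLength Sequence length in bp.
#' @param gcContent Target GC fraction; bases are drawn independently.
#' @param chromName Contig name.
#' @param seed Optional RNG seed.
#' @return A single-sequence [Biostrings::DNAStringSet].
#' @export
makeReferenceSequence <- function(chromLength, gcContent = 0.42,
                                  chromName = "chrS", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gcContent) / 2, gcContent / 2, gcContent / 2,
         (1 - gcContent) / 2)
  idx <- sample.int(4L, chromLength, replace = TRUE, prob = p)
  seq <- Biostrings::DNAStringSet(rawToChar(as.raw(c(65L, 67L, 71L, 84L)[idx])))
  names(seq) <- chromName
  seq
}

#' Build a founder haplotype pool
#'
#' Draws a reference sequence (unless one is supplied), places a panel of
#' segregating SNP positions on it, and assigns binary founder alleles so
#' that every site is polymorphic among the founders. The number of
#' founders carrying the alternative allele at a site is drawn with
#' probability proportional to 1/k (a neutral frequency spectrum), so rare
#' founder alleles predominate.
#'
#' @param nFounders Number of founder haplotypes (>= 2 unless
#'   `allowSingleFounder`).
#' @param chromLength Chromosome length in bp.
#' @param snpDensity Expected panel SNPs per bp.
#' @param gcContent GC fraction of the simulated reference.
#' @param seed RNG seed.
#' @param refSequence Optional pre-built reference (`DNAStringSet`), e.g.
#'   one carrying embedded gene models.
#' @param chromName Contig name (ignored when `refSequence` is given).
#' @param allowSingleFounder Permit the degenerate one-founder pool used
#'   only for documented edge-case tests.
#' @return A list of class `FounderPool`: `nFounders`, `chromName`,
#'   `chromLength`, `refSequence`, `snpPositions`, `refBases`, `altBases`,
#'   `founderAlleles` (founders x sites matrix of 0/1).
#' @export
buildFounderPool <- function(nFounders = 8, chromLength = 6e7,
                             snpDensity = 5e-4, gcContent = 0.42,
                             seed = NULL, refSequence = NULL,
                             chromName = "chrS",
                             allowSingleFounder = FALSE) {
  if (nFounders < 2 && !allowSingleFounder)
    stop("need at least 2 founder haplotypes")
  if (snpDensity <= 0) stop("snpDensity must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(refSequence)) {
    refSequence <- makeReferenceSequence(chromLength, gcContent, chromName)
  } else {
    chromName <- names(refSequence)[1]
    chromLength <- Biostrings::width(refSequence)[1]
  }
  nSites <- max(1L, round(chromLength * snpDensity))
  pos <- sort(sample.int(chromLength, nSites))
  refBases <- strsplit(getBasesAt(refSequence, chromName, pos), "")[[1]]
  altBases <- vapply(refBases, function(b) sample(setdiff(.BASES, b), 1),
                     character(1), USE.NAMES = FALSE)
  founderAlleles <- matrix(0L, nFounders, nSites)
  if (nFounders >= 2) {
    kChoices <- seq_len(nFounders - 1)
    k <- sample(kChoices, nSites, replace = TRUE, prob = 1 / kChoices)
    for (i in seq_len(nSites)) {
      founderAlleles[sample.int(nFounders, k[i]), i] <- 1L
    }
  }
  structure(list(nFounders = nFounders, chromName = chromName,
                 chromLength = chromLength, refSequence = refSequence,
                 snpPositions = pos, refBases = refBases,
                 altBases = altBases, founderAlleles = founderAlleles),
            class = "FounderPool")
}

## fetch single bases at many positions as one concatenated string
getBasesAt <- function(ref, chrom, pos) {
  v <- Biostrings::extractAt(ref[[chrom]], IRanges::IRanges(pos, width = 1L))
  paste(as.character(v), collapse = "")
}

#' Simulate inbred strain genomes as founder-block mosaics
#'
#' Block boundaries follow an exponential renewal process with the given
#' mean block length; the founder of each block is drawn uniformly. Strain
#' genotypes are homozygous for the covering founder's allele at every
#' panel site.
#'
#' @param pool A `FounderPool`.
#' @param nStrains Number of strains (>= 2; IBD detection needs pairs).
#' @param meanBlockLength Mean mosaic block length in bp.
#' @param seed RNG seed.
#' @param strainNames Optional strain names.
#' @return List of `MosaicStrain` lists with elements `name`, `blocks`
#'   (data.frame start/end/founder, 1-based inclusive, tiling the
#'   chromosome) and `alleles` (0/1 founder allele at each panel site).
#' @export
simulateStrainMosaics <- function(pool, nStrains = 12,
                                  meanBlockLength = 1e7, seed = NULL,
                                  strainNames = NULL) {
  if (nStrains < 2) stop("need at least 2 strains for pairwise IBD")
  if (meanBlockLength > pool$chromLength * 1e4)
    meanBlockLength <- pool$chromLength * 1e4
  if (!is.null(seed)) set.seed(seed)
  if (is.null(strainNames))
    strainNames <- sprintf("strain%02d", seq_len(nStrains))
  L <- pool$chromLength
  lapply(seq_len(nStrains), function(i) {
    bounds <- c()
    at <- 0
    repeat {
      at <- at + rexp(1, rate = 1 / meanBlockLength)
      if (at >= L) break
      bounds <- c(bounds, floor(at))
    }
    starts <- c(1, bounds + 1)
    ends <- c(bounds, L)
    founders <- sample.int(pool$nFounders, length(starts), replace = TRUE)
    blockIdx <- findInterval(pool$snpPositions, starts)
    alleles <- pool$founderAlleles[cbind(founders[blockIdx],
                                         seq_along(pool$snpPositions))]
    list(name = strainNames[i],
         blocks = data.frame(start = starts, end = ends, founder = founders),
         alleles = alleles)
  })
}

.eligibleBases <- function(foldedClass) {
  if (substr(foldedClass, 1, 1) == "C") c("C", "G") else c("A", "T")
}

.derivedFor <- function(foldedClass, ancestral) {
  der <- substr(foldedClass, 3, 3)
  ifelse(ancestral %in% c("C", "T"), der, .complement(der))
}

#' Plant strain-private mutations with known spectra
#'
#' For each strain, folded mutation classes are drawn from the strain's
#' six-class spectrum and positions uniformly over chromosome bases whose
#' reference base permits the class (C/G for C-rooted classes, A/T for
#' T-rooted classes). Positions are distinct across all mutations and
#' avoid the founder SNP panel entirely, so planted alleles can never
#' collide with another strain's alternative allele and are guaranteed
#' private. Each mutation is heterozygous with probability `hetFraction`
#' and otherwise fixed.
#'
#' @param pool A `FounderPool`.
#' @param strains Mosaic strains from [simulateStrainMosaics].
#' @param mutationsPerStrain Events planted per strain.
#' @param spectra Either a single named probability vector over
#'   [FOLDED_CLASSES] (recycled across strains) or a strains x 6 matrix;
#'   rows must sum to 1 within 1e-9.
#' @param hetFraction Probability a planted mutation is heterozygous
#'   (default 0.083; the remaining events are fixed).
#' @param seed RNG seed.
#' @return A data.frame truth table with columns `strain`, `chrom`, `pos`,
#'   `ancestral`, `derived`, `zygosity`, `folded_class`. The ancestral
#'   allele always equals the reference base at the position (which is also
#'   the base carried by every other strain there).
#' @export
plantPrivateMutations <- function(pool, strains, mutationsPerStrain = 300,
                                  spectra = NULL, hetFraction = 0.083,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nStrains <- length(strains)
  if (is.null(spectra)) spectra <- defaultFixtureConfig()$spectrum
  if (is.null(dim(spectra)))
    spectra <- matrix(spectra, nStrains, 6, byrow = TRUE,
                      dimnames = list(NULL, names(spectra)))
  if (is.null(colnames(spectra)) ||
      !identical(colnames(spectra), FOLDED_CLASSES))
    colnames(spectra) <- FOLDED_CLASSES
  if (any(abs(rowSums(spectra) - 1) > 1e-9))
    stop("each spectrum must sum to 1")
  if (mutationsPerStrain == 0)
    return(data.frame(strain = character(), chrom = character(),
                      pos = integer(), ancestral = character(),
                      derived = character(), zygosity = character(),
                      folded_class = character()))

  total <- mutationsPerStrain * nStrains
  ## oversample candidate positions (unique, off the SNP panel), then
  ## classify by reference base
  cand <- sample.int(pool$chromLength, max(10L * total, 1000L))
  cand <- setdiff(cand, pool$snpPositions)
  bases <- strsplit(getBasesAt(pool$refSequence, pool$chromName, cand),
                    "")[[1]]
  poolCG <- cand[bases %in% c("C", "G")]
  poolAT <- cand[bases %in% c("A", "T")]
  baseOf <- setNames(bases, cand)

  rows <- vector("list", nStrains)
  iCG <- iAT <- 0L
  for (s in seq_len(nStrains)) {
    counts <- as.vector(rmultinom(1, mutationsPerStrain, spectra[s, ]))
    cls <- rep(FOLDED_CLASSES, counts)
    cls <- sample(cls)
    needCG <- sum(substr(cls, 1, 1) == "C")
    needAT <- length(cls) - needCG
    if (iCG + needCG > length(poolCG) || iAT + needAT > length(poolAT))
      stop("not enough eligible sites remain for the requested spectrum")
    posCG <- poolCG[iCG + seq_len(needCG)]
    posAT <- poolAT[iAT + seq_len(needAT)]
    iCG <- iCG + needCG
    iAT <- iAT + needAT
    pos <- integer(length(cls))
    pos[substr(cls, 1, 1) == "C"] <- posCG
    pos[substr(cls, 1, 1) == "T"] <- posAT
    anc <- unname(baseOf[as.character(pos)])
    der <- .derivedFor(cls, anc)
    zyg <- ifelse(runif(length(cls)) < hetFraction, "heterozygous", "fixed")
    rows[[s]] <- data.frame(strain = strains[[s]]$name,
                            chrom = pool$chromName, pos = pos,
                            ancestral = anc, derived = der, zygosity = zyg,
                            folded_class = cls)
  }
  truth <- do.call(rbind, rows)
  truth[order(truth$pos), , drop = FALSE]
}

.qualityDefaults <- function() {
  list(qual = 200, gq = 99, dp = 40, plMargin = 100)
}

## per-call quality fields consistent with the genotype call
.fillQuality <- function(gt) {
  q <- .qualityDefaults()
  n <- nrow(gt); m <- ncol(gt)
  full <- function(v) matrix(v, n, m, dimnames = dimnames(gt))
  adRef <- full(ifelse(is.na(gt), NA, ifelse(gt == 0, q$dp,
                                             ifelse(gt == 1, q$dp / 2, 0))))
  adAlt <- full(ifelse(is.na(gt), NA, ifelse(gt == 0, 0,
                                             ifelse(gt == 1, q$dp / 2, q$dp))))
  list(gq = full(ifelse(is.na(gt), NA, q$gq)),
       dp = full(ifelse(is.na(gt), NA, q$dp)),
       plMargin = full(ifelse(is.na(gt), NA, q$plMargin)),
       adRef = adRef, adAlt = adAlt,
       refFwd = adRef / 2, refRev = adRef / 2,
       altFwd = adAlt / 2, altRev = adAlt / 2)
}

#' Assemble the laboratory-strain genotype matrix
#'
#' Combines founder-panel sites (genotypes homozygous for the covering
#' founder's allele) with planted private mutations from a truth table.
#' All per-call quality fields are generated to pass the default SPV
#' filters (site quality 200, GQ 99, DP 40, likelihood margin 100 and
#' strand-balanced allele depths); use [injectFilterFailures] to corrupt
#' targeted records for per-filter tests.
#'
#' @param pool A `FounderPool`.
#' @param strains Mosaic strains.
#' @param truth Optional truth table from [plantPrivateMutations].
#' @return A [GenotypeMatrix-class].
#' @export
strainGenotypeMatrix <- function(pool, strains, truth = NULL) {
  strainNames <- vapply(strains, `[[`, character(1), "name")
  nPanel <- length(pool$snpPositions)
  gtPanel <- matrix(0L, nPanel, length(strains),
                    dimnames = list(NULL, strainNames))
  for (s in seq_along(strains))
    gtPanel[, s] <- 2L * strains[[s]]$alleles
  chrom <- rep(pool$chromName, nPanel)
  pos <- pool$snpPositions
  ref <- pool$refBases
  alt <- pool$altBases
  gt <- gtPanel
  if (!is.null(truth) && nrow(truth)) {
    gtMut <- matrix(0L, nrow(truth), length(strains),
                    dimnames = list(NULL, strainNames))
    sIdx <- match(truth$strain, strainNames)
    gtMut[cbind(seq_len(nrow(truth)), sIdx)] <-
      ifelse(truth$zygosity == "heterozygous", 1L, 2L)
    chrom <- c(chrom, truth$chrom)
    pos <- c(pos, truth$pos)
    ref <- c(ref, truth$ancestral)
    alt <- c(alt, truth$derived)
    gt <- rbind(gt, gtMut)
  }
  q <- .fillQuality(gt)
  GenotypeMatrix(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 qual = rep(.qualityDefaults()$qual, length(pos)), gt = gt,
                 gq = q$gq, dp = q$dp, plMargin = q$plMargin,
                 adRef = q$adRef, adAlt = q$adAlt, refFwd = q$refFwd,
                 refRev = q$refRev, altFwd = q$altFwd, altRev = q$altRev)
}

#' Founder haplotypes as a wild-derived inbred panel
#'
#' Returns the founder haplotypes themselves as homozygous inbred genomes.
#' Used as the wild-derived outgroup panel: any allele inherited from the
#' founder pool is carried by at least one of these genomes, so the
#' wild-panel filter removes ancestral variants deterministically, while
#' genuinely new (planted) mutations are absent from all of them.
#'
#' @param pool A `FounderPool`.
#' @return A [GenotypeMatrix-class] with one column per founder.
#' @export
wildDerivedMatrix <- function(pool) {
  gt <- 2L * t(pool$founderAlleles)
  colnames(gt) <- sprintf("founder%02d", seq_len(pool$nFounders))
  q <- .fillQuality(gt)
  GenotypeMatrix(chrom = rep(pool$chromName, length(pool$snpPositions)),
                 pos = pool$snpPositions, ref = pool$refBases,
                 alt = pool$altBases,
                 qual = rep(.qualityDefaults()$qual,
                            length(pool$snpPositions)),
                 gt = gt, gq = q$gq, dp = q$dp, plMargin = q$plMargin,
                 adRef = q$adRef, adAlt = q$adAlt, refFwd = q$refFwd,
                 refRev = q$refRev, altFwd = q$altFwd, altRev = q$altRev)
}

#' Simulate a diverse wild outgroup
#'
#' Outgroup genotypes are drawn per site and per sample from the founder
#' allele frequencies (two independent allele draws), with additional
#' low-frequency polymorphic sites (`extraDiversity` as a fraction of the
#' panel size) private to the outgroup. Independent per-sample sampling
#' means no two samples share long identical-genotype runs, emulating the
#' absence of megabase-scale IBD in wild populations.
#'
#' @param pool A `FounderPool`.
#' @param nSamples Number of wild genomes.
#' @param extraDiversity Extra outgroup-private polymorphic sites as a
#'   fraction of the panel size (> 0 unless `allowDegenerate`).
#' @param seed RNG seed.
#' @param avoidPositions Positions that must not receive extra sites
#'   (e.g. planted mutation positions).
#' @param allowDegenerate Permit `extraDiversity = 0` (documented
#'   edge case; with a single-founder pool all samples are then identical).
#' @return A [GenotypeMatrix-class].
#' @export
simulateWildOutgroup <- function(pool, nSamples = 27, extraDiversity = 0.5,
                                 seed = NULL, avoidPositions = NULL,
                                 allowDegenerate = FALSE) {
  if (extraDiversity <= 0 && !allowDegenerate)
    stop("extraDiversity must be > 0")
  if (!is.null(seed)) set.seed(seed)
  sampleNames <- sprintf("wild%02d", seq_len(nSamples))
  freq <- colMeans(pool$founderAlleles)
  nPanel <- length(pool$snpPositions)
  gtPanel <- matrix(rbinom(nPanel * nSamples, 2,
                           rep(freq, nSamples)), nPanel, nSamples,
                    dimnames = list(NULL, sampleNames))
  chrom <- rep(pool$chromName, nPanel)
  pos <- pool$snpPositions
  ref <- pool$refBases
  alt <- pool$altBases
  gt <- gtPanel
  nExtra <- round(extraDiversity * nPanel)
  if (nExtra > 0) {
    cand <- sample.int(pool$chromLength, 3L * nExtra)
    cand <- setdiff(cand, c(pool$snpPositions, avoidPositions))
    cand <- cand[seq_len(min(nExtra, length(cand)))]
    baseStr <- strsplit(getBasesAt(pool$refSequence, pool$chromName, cand),
                        "")[[1]]
    altExtra <- vapply(baseStr, function(b) sample(setdiff(.BASES, b), 1),
                       character(1), USE.NAMES = FALSE)
    fExtra <- runif(length(cand), 0.02, 0.3)
    gtExtra <- matrix(rbinom(length(cand) * nSamples, 2,
                             rep(fExtra, nSamples)),
                      length(cand), nSamples,
                      dimnames = list(NULL, sampleNames))
    chrom <- c(chrom, rep(pool$chromName, length(cand)))
    pos <- c(pos, cand)
    ref <- c(ref, baseStr)
    alt <- c(alt, altExtra)
    gt <- rbind(gt, gtExtra)
  }
  storage.mode(gt) <- "integer"
  q <- .fillQuality(gt)
  GenotypeMatrix(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 qual = rep(.qualityDefaults()$qual, length(pos)), gt = gt,
                 gq = q$gq, dp = q$dp, plMargin = q$plMargin,
                 adRef = q$adRef, adAlt = q$adAlt, refFwd = q$refFwd,
                 refRev = q$refRev, altFwd = q$altFwd, altRev = q$altRev)
}

#' Random masked-interval track
#'
#' Draws exponential-length intervals uniformly until the merged track
#' covers approximately the requested genome fraction.
#'
#' @param chromLength Chromosome length.
#' @param fraction Target covered fraction.
#' @param meanLength Mean interval length in bp.
#' @param chromName Contig name.
#' @param seed RNG seed.
#' @return A reduced `GRanges`.
#' @export
randomIntervalTrack <- function(chromLength, fraction, meanLength = 5e4,
                                chromName = "chrS", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (fraction <= 0) return(GenomicRanges::GRanges())
  target <- fraction * chromLength
  n <- ceiling(1.2 * target / meanLength)
  starts <- sample.int(chromLength, n, replace = TRUE)
  lens <- pmax(1, round(rexp(n, 1 / meanLength)))
  ends <- pmin(starts + lens - 1, chromLength)
  GenomicRanges::reduce(GenomicRanges::GRanges(
    chromName, IRanges::IRanges(starts, ends)))
}

#' Embed single-exon ORF gene models in a reference
#'
#' Places non-overlapping forward-strand coding sequences (ATG, a run of
#' non-stop codons, and a stop codon) at random positions, writing the ORF
#' bases into the reference so that the annotated CDS and the sequence
#' agree. Keeps the codon-table consequence annotator exact without splice
#' handling.
#'
#' @param ref A `DNAStringSet` reference.
#' @param nGenes Number of gene models.
#' @param codonRange Range (min, max) of internal codons per CDS.
#' @param seed RNG seed.
#' @param avoidPositions Positions the ORFs must not cover (e.g. the SNP
#'   panel, so panel ref/alt alleles stay consistent).
#' @return List with `ref` (modified reference) and `models` (`GRanges` of
#'   CDS intervals, 1-based inclusive, with `gene_id`).
#' @export
buildGeneModels <- function(ref, nGenes = 40, codonRange = c(100, 400),
                            seed = NULL, avoidPositions = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- names(ref)[1]
  L <- Biostrings::width(ref)[1]
  codons <- mkAllCodons()
  nonStop <- setdiff(codons, c("TAA", "TAG", "TGA"))
  placed <- IRanges::IRanges()
  starts <- integer(0)
  widths <- integer(0)
  seqs <- character(0)
  tries <- 0
  while (length(starts) < nGenes && tries < nGenes * 50) {
    tries <- tries + 1
    nc <- sample(seq(codonRange[1], codonRange[2]), 1)
    w <- 3L * (nc + 2L)
    s <- sample.int(L - w, 1)
    cand <- IRanges::IRanges(s, s + w - 1L)
    if (length(placed) &&
        any(IRanges::overlapsAny(cand, placed))) next
    if (!is.null(avoidPositions) &&
        any(avoidPositions >= s & avoidPositions <= s + w - 1L)) next
    placed <- c(placed, cand)
    starts <- c(starts, s)
    widths <- c(widths, w)
    seqs <- c(seqs, paste0("ATG",
                           paste(sample(nonStop, nc, replace = TRUE),
                                 collapse = ""),
                           sample(c("TAA", "TAG", "TGA"), 1)))
  }
  if (length(starts)) {
    ord <- order(starts)
    starts <- starts[ord]; widths <- widths[ord]; seqs <- seqs[ord]
    newSeq <- Biostrings::replaceAt(
      ref[[chrom]], IRanges::IRanges(starts, width = widths),
      Biostrings::DNAStringSet(seqs))
    ref[[chrom]] <- newSeq
  }
  models <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(starts, width = widths),
    strand = "+", gene_id = sprintf("gene%03d", seq_along(starts)))
  list(ref = ref, models = models)
}

mkAllCodons <- function() {
  b <- .BASES
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Simulate replicate life-history trait measurements
#'
#' Per-strain replicate measurements of two breeding traits: dam age at
#' first litter (days) and mean interbirth interval (days). Strain means
#' are drawn around typical laboratory-mouse values with among-strain
#' variation, then replicates add within-strain noise.
#'
#' @param strainNames Character vector of strains.
#' @param nReplicates Replicates per strain and trait.
#' @param seed RNG seed.
#' @return Long data.frame with columns strain, trait, value.
#' @export
simulateTraitTable <- function(strainNames, nReplicates = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  traits <- c(dam_age_first_litter = 80, interbirth_interval = 32)
  sdBetween <- c(10, 5)
  sdWithin <- c(12, 8)
  rows <- list()
  for (t in seq_along(traits)) {
    mu <- rnorm(length(strainNames), traits[t], sdBetween[t])
    for (s in seq_along(strainNames)) {
      rows[[length(rows) + 1]] <- data.frame(
        strain = strainNames[s], trait = names(traits)[t],
        value = rnorm(nReplicates, mu[s], sdWithin[t]))
    }
  }
  do.call(rbind, rows)
}

#' Simulate a complete in-memory fixture
#'
#' Orchestrates the generator: founder pool (optionally with embedded gene
#' models), strain mosaics, planted private mutations, the laboratory
#' genotype matrix, wild and wild-derived outgroup matrices and random
#' repeat/segmental-duplication masks. All randomness derives from `seed`.
#'
#' @param seed Integer seed.
#' @param config Named list overriding entries of [defaultFixtureConfig].
#' @return List with elements `config`, `pool`, `strains`, `truth`, `gm`,
#'   `wild`, `wildDerived`, `repeatTrack`, `segdupTrack`, `geneModels`
#'   (`NULL` when `nGenes = 0`) and `ref`.
#' @export
simulateFixture <- function(seed = 1, config = list()) {
  cfg <- defaultFixtureConfig()
  cfg[names(config)] <- config
  set.seed(seed)
  seeds <- sample.int(2^31 - 1, 8)
  geneModels <- NULL
  refSequence <- NULL
  if (cfg$nGenes > 0) {
    refSequence <- makeReferenceSequence(cfg$chromLength, cfg$gcContent,
                                         cfg$chromName, seed = seeds[1])
  }
  pool <- buildFounderPool(cfg$nFounders, cfg$chromLength, cfg$snpDensity,
                           cfg$gcContent, seed = seeds[2],
                           refSequence = refSequence,
                           chromName = cfg$chromName)
  if (cfg$nGenes > 0) {
    gm0 <- buildGeneModels(pool$refSequence, cfg$nGenes, seed = seeds[3],
                           avoidPositions = pool$snpPositions)
    pool$refSequence <- gm0$ref
    ## refresh panel ref bases (ORF embedding avoided panel positions, so
    ## this is a no-op in practice, but keep the pool self-consistent)
    pool$refBases <- strsplit(getBasesAt(pool$refSequence, pool$chromName,
                                         pool$snpPositions), "")[[1]]
    geneModels <- gm0$models
  }
  strains <- simulateStrainMosaics(pool, cfg$nStrains, cfg$meanBlockLength,
                                   seed = seeds[4])
  truth <- plantPrivateMutations(pool, strains, cfg$mutationsPerStrain,
                                 cfg$spectrum, cfg$hetFraction,
                                 seed = seeds[5])
  gm <- strainGenotypeMatrix(pool, strains, truth)
  wild <- simulateWildOutgroup(pool, cfg$nWild, cfg$extraDiversity,
                               seed = seeds[6], avoidPositions = truth$pos)
  wd <- wildDerivedMatrix(pool)
  repeatTrack <- randomIntervalTrack(cfg$chromLength, cfg$repeatFraction,
                                     cfg$maskMeanLength, cfg$chromName,
                                     seed = seeds[7])
  segdupTrack <- randomIntervalTrack(cfg$chromLength, cfg$segdupFraction,
                                     cfg$maskMeanLength, cfg$chromName,
                                     seed = seeds[8])
  list(config = cfg, pool = pool, strains = strains, truth = truth,
       gm = gm, wild = wild, wildDerived = wd, repeatTrack = repeatTrack,
       segdupTrack = segdupTrack, geneModels = geneModels,
       ref = pool$refSequence)
}

#' Write a fixture to disk as standard files
#'
#' Emits the strains VCF, wild and wild-derived VCFs, reference FASTA,
#' repeat and segmental-duplication BEDs, a sparse conservation score
#' track (scored at panel sites, planted sites and random background
#' positions; panel-site scores are drawn from a conservation-depleted
#' distribution relative to background, emulating purifying selection on
#' ancestral variants), GFF3 gene models when present, a trait table and
#' the truth table.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config Overrides for [defaultFixtureConfig].
#' @return Named list of written file paths, invisibly.
#' @export
emitFixtureSet <- function(outdir, seed = 1, config = list()) {
  fx <- simulateFixture(seed, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  paths <- list(strains_vcf = p("strains.vcf"), wild_vcf = p("wild.vcf"),
                wild_derived_vcf = p("wild_derived.vcf"),
                ref_fasta = p("ref.fa"), repeats_bed = p("repeats.bed"),
                segdups_bed = p("segdups.bed"), scores = p("scores.tsv"),
                traits = p("traits.tsv"), truth = p("truth.tsv"),
                genes_gff3 = p("genes.gff3"))
  cl <- setNames(fx$config$chromLength, fx$config$chromName)
  writeGenotypesVcf(fx$gm, paths$strains_vcf, cl)
  writeGenotypesVcf(fx$wild, paths$wild_vcf, cl)
  writeGenotypesVcf(fx$wildDerived, paths$wild_derived_vcf, cl)
  writeReference(fx$ref, paths$ref_fasta)
  rtracklayer::export(fx$repeatTrack, paths$repeats_bed, format = "BED")
  rtracklayer::export(fx$segdupTrack, paths$segdups_bed, format = "BED")
  set.seed(seed + 101)
  bg <- sort(sample.int(fx$config$chromLength,
                        min(20000, fx$config$chromLength)))
  scorePos <- unique(sort(c(fx$pool$snpPositions, fx$truth$pos, bg)))
  depleted <- scorePos %in% fx$pool$snpPositions
  score <- numeric(length(scorePos))
  score[depleted] <- rbeta(sum(depleted), 0.3, 5)
  score[!depleted] <- rbeta(sum(!depleted), 0.5, 3)
  writeScoreTrack(data.frame(chrom = fx$config$chromName, pos = scorePos,
                             score = score), paths$scores)
  traits <- simulateTraitTable(vapply(fx$strains, `[[`, character(1),
                                      "name"), seed = seed + 202)
  write.table(traits, paths$traits, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fx$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fx$geneModels)) {
    rtracklayer::export(fx$geneModels, paths$genes_gff3, format = "GFF3")
  } else {
    paths$genes_gff3 <- NULL
  }
  invisible(paths)
}

#' Corrupt one planted record per filter rule
#'
#' Selects, for each of the eleven named filter rules, one clean planted
#' record that currently passes the whole stack, and perturbs exactly the
#' inputs needed to make it fail that rule first (field values set just
#' past their thresholds; track/wild/IBD rules realised by extending the
#' relevant mask, adding a wild record, or relocating the variant outside
#' the focal strain's retained IBD territory). Enables per-filter unit
#' tests and exact audit accounting.
#'
#' @param gm Laboratory [GenotypeMatrix-class].
#' @param truth Truth table.
#' @param segments Retained (>= 5 Mb) IBD segments (`GRanges` from
#'   [detectIbdSegments] + [filterSegments]).
#' @param repeatTrack,segdupTrack Mask tracks (`GRanges`).
#' @param wildMatrix Wild outgroup [GenotypeMatrix-class].
#' @param pool The `FounderPool` (needed to relocate a record).
#' @param seed RNG seed.
#' @return List with modified `gm`, `truth`, `repeatTrack`, `segdupTrack`,
#'   `wildMatrix`, and `corruptions` (data.frame rule/strain/chrom/pos).
#' @export
injectFilterFailures <- function(gm, truth, segments, repeatTrack,
                                 segdupTrack, wildMatrix, pool,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rules <- .ruleNames()
  key <- paste(siteChrom(gm), sitePos(gm))
  tKey <- paste(truth$chrom, truth$pos)
  ## eligible records: inside retained IBD of their strain, unmasked
  insideIbd <- vapply(seq_len(nrow(truth)), function(i) {
    segs <- segments[S4Vectors::mcols(segments)$strainA == truth$strain[i] |
                       S4Vectors::mcols(segments)$strainB == truth$strain[i]]
    length(segs) > 0 &&
      any(truth$pos[i] >= BiocGenerics::start(segs) &
            truth$pos[i] <= BiocGenerics::end(segs) &
            as.character(GenomicRanges::seqnames(segs)) == truth$chrom[i])
  }, logical(1))
  masked <- pointInTrack(repeatTrack, truth$chrom, truth$pos) |
    pointInTrack(segdupTrack, truth$chrom, truth$pos)
  eligible <- which(insideIbd & !masked)
  if (length(eligible) < length(rules))
    stop("not enough clean planted records to corrupt (need ",
         length(rules), ", have ", length(eligible), ")")
  pick <- sample(eligible, length(rules))
  names(pick) <- rules

  assayAt <- function(g, name, i, j, value) {
    a <- SummarizedExperiment::assay(g, name)
    a[i, j] <- value
    SummarizedExperiment::assay(g, name) <- a
    g
  }
  setHet <- function(g, i, j, adR, adA, sb) {
    a <- genotypes(g)
    a[i, j] <- 1L
    SummarizedExperiment::assay(g, "gt") <- a
    g <- assayAt(g, "adRef", i, j, adR)
    g <- assayAt(g, "adAlt", i, j, adA)
    g <- assayAt(g, "refFwd", i, j, sb[1])
    g <- assayAt(g, "refRev", i, j, sb[2])
    g <- assayAt(g, "altFwd", i, j, sb[3])
    assayAt(g, "altRev", i, j, sb[4])
  }
  rowOf <- function(k) match(tKey[pick[k]], key)
  colOf <- function(k) match(truth$strain[pick[k]], strainNames(gm))

  ## (a) site quality at the threshold (strict > required)
  i <- rowOf("qual")
  rr <- SummarizedExperiment::rowRanges(gm)
  S4Vectors::mcols(rr)$qual[i] <- 50
  SummarizedExperiment::rowRanges(gm) <- rr
  ## (b) focal GQ at threshold
  gm <- assayAt(gm, "gq", rowOf("gq"), colOf("gq"), 60)
  ## (c) focal depth at the lower bound
  gm <- assayAt(gm, "dp", rowOf("dp"), colOf("dp"), 10)
  ## (d) >= 15% missing genotypes at the site (non-focal strains)
  i <- rowOf("missing")
  others <- setdiff(seq_len(ncol(gm)), colOf("missing"))
  nMiss <- ceiling(0.15 * ncol(gm))
  a <- genotypes(gm)
  a[i, others[seq_len(nMiss)]] <- NA
  SummarizedExperiment::assay(gm, "gt") <- a
  ## (e)/(f) extend masks over the chosen sites
  addMask <- function(track, k) {
    GenomicRanges::reduce(c(track, GenomicRanges::GRanges(
      truth$chrom[pick[k]],
      IRanges::IRanges(truth$pos[pick[k]] - 5L, truth$pos[pick[k]] + 5L))))
  }
  segdupTrack <- addMask(segdupTrack, "segdup")
  repeatTrack <- addMask(repeatTrack, "repeat")
  ## (g) focal likelihood margin at threshold
  gm <- assayAt(gm, "plMargin", rowOf("pl_margin"), colOf("pl_margin"), 20)
  ## (h) make the site polymorphic in the wild panel
  k <- pick["wild"]
  nw <- ncol(wildMatrix)
  gtw <- matrix(0L, 1, nw, dimnames = list(NULL, colnames(wildMatrix)))
  gtw[1, sample.int(nw, max(1, round(nw / 3)))] <- 1L
  qf <- .fillQuality(gtw)
  wildExtra <- GenotypeMatrix(chrom = truth$chrom[k], pos = truth$pos[k],
                              ref = truth$ancestral[k],
                              alt = truth$derived[k], qual = 200, gt = gtw,
                              gq = qf$gq, dp = qf$dp,
                              plMargin = qf$plMargin, adRef = qf$adRef,
                              adAlt = qf$adAlt, refFwd = qf$refFwd,
                              refRev = qf$refRev, altFwd = qf$altFwd,
                              altRev = qf$altRev)
  wildMatrix <- BiocGenerics::rbind(wildMatrix, wildExtra)
  wildMatrix <- wildMatrix[BiocGenerics::order(
    SummarizedExperiment::rowRanges(wildMatrix)), ]
  ## (i) relocate the record outside the focal strain's retained IBD
  k <- pick["ibd"]
  focal <- truth$strain[k]
  segs <- segments[S4Vectors::mcols(segments)$strainA == focal |
                     S4Vectors::mcols(segments)$strainB == focal]
  segs <- GenomicRanges::reduce(segs)
  repeat {
    newPos <- sample.int(pool$chromLength, 1)
    onIbd <- length(segs) && any(newPos >= BiocGenerics::start(segs) &
                                   newPos <= BiocGenerics::end(segs))
    base <- getBasesAt(pool$refSequence, pool$chromName, newPos)
    okBase <- base %in% .eligibleBases(truth$folded_class[k])
    clash <- newPos %in% c(pool$snpPositions, truth$pos, sitePos(wildMatrix))
    if (!onIbd && okBase && !clash &&
        !pointInTrack(repeatTrack, pool$chromName, newPos) &&
        !pointInTrack(segdupTrack, pool$chromName, newPos)) break
  }
  i <- rowOf("ibd")
  rr <- SummarizedExperiment::rowRanges(gm)
  GenomicRanges::ranges(rr)[i] <- IRanges::IRanges(newPos, width = 1L)
  S4Vectors::mcols(rr)$ref[i] <- base
  S4Vectors::mcols(rr)$alt[i] <- .derivedFor(truth$folded_class[k], base)
  SummarizedExperiment::rowRanges(gm) <- rr
  truth$pos[k] <- newPos
  truth$ancestral[k] <- base
  truth$derived[k] <- S4Vectors::mcols(rr)$alt[i]
  ord <- BiocGenerics::order(SummarizedExperiment::rowRanges(gm))
  gm <- gm[ord, ]
  key <- paste(siteChrom(gm), sitePos(gm))
  tKey <- paste(truth$chrom, truth$pos)
  ## (j) heterozygous with poor allele balance (passes depth/quality)
  gm <- setHet(gm, rowOf("balance"), colOf("balance"), 30, 10,
               c(15, 15, 5, 5))
  truth$zygosity[pick["balance"]] <- "heterozygous"
  ## (k) heterozygous, balanced alleles but complete strand bias
  gm <- setHet(gm, rowOf("strand_bias"), colOf("strand_bias"), 20, 20,
               c(20, 0, 0, 20))
  truth$zygosity[pick["strand_bias"]] <- "heterozygous"

  corruptions <- data.frame(rule = rules, strain = truth$strain[pick],
                            chrom = truth$chrom[pick], pos = truth$pos[pick])
  list(gm = gm, truth = truth, repeatTrack = repeatTrack,
       segdupTrack = segdupTrack, wildMatrix = wildMatrix,
       corruptions = corruptions)
}
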