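test_that("singleton identification distinguishes fixed, het and common", {
  gt <- matrix(0L, 4, 5, dimnames = list(NULL, paste0("s", 1:5)))
  gt[1, 3] <- 2L            # fixed singleton
  gt[2, 2] <- 1L            # heterozygous singleton
  gt[3, c(1, 4)] <- 2L      # common variant
  gm <- toyMatrix(gt)
  cand <- identifySingletons(gm)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$strain, c("s3", "s2"))
  expect_equal(cand$zygosity, c("fixed", "heterozygous"))
})

test_that("the strand/allele bias test matches its closed form", {
  expect_equal(chi2BiasTest(10, 10, 10, 10), 1)
  # pure allele bias: all reads support the reference
  expect_lt(chi2BiasTest(20, 20, 0, 0), 0.05)
  expect_error(chi2BiasTest(0, 0, 0, 0), "no reads")
  # independent closed-form recomputation on random counts
  set.seed(55)
  for (i in 1:20) {
    o <- rmultinom(1, 80, c(0.3, 0.25, 0.25, 0.2))[, 1]
    fwd <- (o[1] + o[3]) / sum(o)
    e <- sum(o) * c(fwd / 2, (1 - fwd) / 2, fwd / 2, (1 - fwd) / 2)
    stat <- sum((o - e)^2 / e)
    expect_equal(chi2BiasTest(o[1], o[2], o[3], o[4]),
                 pchisq(stat, 3, lower.tail = FALSE))
  }
})

test_that("polarization assigns the major allele as ancestral", {
  gt <- matrix(0L, 2, 4, dimnames = list(NULL, paste0("s", 1:4)))
  gt[1, 2] <- 2L
  gt[2, ] <- c(0L, 2L, 2L, 2L)   # reference-private pattern
  gm <- toyMatrix(gt, ref = c("G", "C"), alt = c("T", "A"))
  expect_equal(polarizeSingleton(gm, 1, "s2"),
               c(ancestral = "G", derived = "T"))
  expect_error(polarizeSingleton(gm, 2, "s1"), "reference-private")
  expect_error(polarizeSingleton(gm, 1, "s2_not_there"))
})

test_that("folding maps purine events to their reverse complements", {
  purine <- foldClass(c("G", "G", "G", "A", "A", "A"),
                      c("T", "C", "A", "T", "G", "C"))
  expect_equal(purine$folded_class,
               c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_true(all(purine$flipped))
  pyr <- foldClass(c("C", "T"), c("T", "G"))
  expect_equal(pyr$folded_class, c("C>T", "T>G"))
  expect_false(any(pyr$flipped))
  expect_error(foldClass("C", "C"), "must differ")
})

test_that("CpG annotation agrees with reverse-complement enumeration", {
  # all 16 contexts around a C (C>T) and around a G (G>A, folded C>T)
  for (five in c("A", "C", "G", "T")) {
    for (three in c("A", "C", "G", "T")) {
      ctxC <- paste0(five, "C", three)
      expect_equal(cpgAnnotate(ctxC, "C>T", FALSE), three == "G",
                   label = ctxC)
      ctxG <- paste0(five, "G", three)
      # oracle: on the pyrimidine strand the context is the reverse
      # complement; CpG iff its 3' base is G
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ctxG)))
      expect_equal(cpgAnnotate(ctxG, "C>T", TRUE),
                   substr(rc, 3, 3) == "G", label = ctxG)
    }
  }
  # non-C>T classes are never CpG-flagged
  expect_false(cpgAnnotate("ACG", "C>A", FALSE))
})

test_that("trinucleotide contexts come from the reference strand", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTT"))
  expect_equal(trinucleotideContext(ref, "chr1", 3), "ACG")
  expect_equal(trinucleotideContext(ref, "chr1", c(2, 5)), c("AAC", "GTT"))
  expect_true(is.na(trinucleotideContext(ref, "chr1", 1)))
  expect_true(is.na(trinucleotideContext(ref, "chr1", 6)))
})

test_that("the corruption fixture fails exactly one record per rule and the survivor set matches a hand-applied oracle", {
  fx <- smallFixture()
  inj <- injectFilterFailures(fx$gm, fx$truth, fx$kept, fx$repeatTrack,
                              fx$segdupTrack, fx$wild, fx$pool, seed = 99)
  cand <- identifySingletons(inj$gm)
  res <- applyFilterStack(cand, inj$gm, fx$ref, inj$repeatTrack,
                          inj$segdupTrack, inj$wildMatrix, fx$wildDerived,
                          fx$kept)
  cleanRes <- applyFilterStack(identifySingletons(fx$gm), fx$gm, fx$ref,
                               fx$repeatTrack, fx$segdupTrack, fx$wild,
                               fx$wildDerived, fx$kept)
  # each named rule gains exactly one failure relative to the clean run
  diff <- res$audit$failures - cleanRes$audit$failures
  expect_equal(unname(diff[c("qual", "gq", "dp", "missing", "segdup",
                             "repeat", "pl_margin", "wild", "ibd",
                             "balance", "strand_bias")]),
               rep(1L, 11))
  expect_equal(res$audit$survivors, cleanRes$audit$survivors - 11L)
  # audit conservation: every candidate is a survivor or counted once
  expect_equal(res$audit$candidates,
               res$audit$survivors + sum(res$audit$failures))

  # independent rule-by-rule oracle over all candidates
  gm <- inj$gm
  gt <- genotypes(gm)
  meanDp <- colMeans(SummarizedExperiment::assay(gm, "dp"), na.rm = TRUE)
  wildKey <- c(
    paste(siteChrom(inj$wildMatrix),
          sitePos(inj$wildMatrix))[rowSums(genotypes(inj$wildMatrix) >= 1,
                                           na.rm = TRUE) > 0],
    paste(siteChrom(fx$wildDerived),
          sitePos(fx$wildDerived))[rowSums(genotypes(fx$wildDerived) >= 1,
                                           na.rm = TRUE) > 0])
  surviveOracle <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$siteIndex[k]
    s <- cand$strain[k]
    A <- function(a) SummarizedExperiment::assay(gm, a)[i, s]
    het <- cand$zygosity[k] == "heterozygous"
    segs <- fx$kept[S4Vectors::mcols(fx$kept)$strainA == s |
                      S4Vectors::mcols(fx$kept)$strainB == s]
    onIbd <- length(segs) > 0 &&
      any(cand$pos[k] >= BiocGenerics::start(segs) &
            cand$pos[k] <= BiocGenerics::end(segs))
    okHet <- TRUE
    if (het) {
      bal <- min(A("adRef"), A("adAlt")) / (A("adRef") + A("adAlt"))
      pBias <- chi2BiasTest(A("refFwd"), A("refRev"), A("altFwd"),
                            A("altRev"))
      okHet <- bal > 0.3 && pBias > 0.05
    }
    surviveOracle[k] <- siteQual(gm)[i] > 50 &&
      !is.na(A("gq")) && A("gq") > 60 &&
      A("dp") > 10 && A("dp") < 1.9 * meanDp[s] &&
      mean(is.na(gt[i, ])) < 0.15 &&
      !pointInTrack(inj$segdupTrack, cand$chrom[k], cand$pos[k]) &&
      !pointInTrack(inj$repeatTrack, cand$chrom[k], cand$pos[k]) &&
      A("plMargin") > 20 &&
      !(paste(cand$chrom[k], cand$pos[k]) %in% wildKey) &&
      onIbd && okHet
  }
  got <- paste(res$spvs$strain, res$spvs$pos)
  want <- paste(cand$strain[surviveOracle], cand$pos[surviveOracle])
  expect_setequal(got, want)
})

test_that("a GQ exactly at the threshold fails the strict filter", {
  fx <- smallFixture()
  inj <- injectFilterFailures(fx$gm, fx$truth, fx$kept, fx$repeatTrack,
                              fx$segdupTrack, fx$wild, fx$pool, seed = 99)
  gqRec <- inj$corruptions[inj$corruptions$rule == "gq", ]
  i <- which(sitePos(inj$gm) == gqRec$pos &
               siteChrom(inj$gm) == gqRec$chrom)
  expect_equal(unname(SummarizedExperiment::assay(inj$gm,
                                                  "gq")[i, gqRec$strain]),
               60)
  cand <- identifySingletons(inj$gm)
  res <- applyFilterStack(cand, inj$gm, fx$ref, inj$repeatTrack,
                          inj$segdupTrack, inj$wildMatrix, fx$wildDerived,
                          fx$kept)
  expect_false(paste(gqRec$strain, gqRec$pos) %in%
                 paste(res$spvs$strain, res$spvs$pos))
})

test_that("SPV calling errors without IBD territory", {
  fx <- smallFixture()
  cand <- identifySingletons(fx$gm)
  expect_error(applyFilterStack(cand, fx$gm, fx$ref, fx$repeatTrack,
                                fx$segdupTrack, fx$wild, fx$wildDerived,
                                fx$kept[0]),
               "no IBD territory")
})

test_that("common variants need two carriers and respect the masks", {
  gt <- matrix(0L, 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  gt[1, c(1, 3)] <- 2L
  gt[2, 2] <- 2L                   # singleton: not common
  gt[3, c(2, 4)] <- c(1L, 2L)      # het + hom carriers
  gm <- toyMatrix(gt, pos = c(1000L, 2000L, 3000L))
  common <- defineCommonVariants(gm)
  expect_equal(common$pos, c(1000L, 3000L))
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2900, 3100))
  expect_equal(defineCommonVariants(gm, repeatTrack = mask)$pos, 1000L)
})

test_that("parsimony ancestral states follow the wild-derived panel", {
  gt <- matrix(0L, 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  gt[, c(1, 3)] <- 2L
  gm <- toyMatrix(gt, pos = c(1000L, 2000L, 3000L),
                  ref = c("G", "G", "G"), alt = c("T", "T", "T"))
  common <- defineCommonVariants(gm)
  wdGt <- matrix(c(0L, 0L,   # fixed ref -> ancestral G
                   2L, 2L,   # fixed alt -> ancestral T
                   0L, 2L),  # segregating -> undetermined
                 3, 2, byrow = TRUE, dimnames = list(NULL, c("w1", "w2")))
  wd <- toyMatrix(wdGt, pos = c(1000L, 2000L, 3000L),
                  ref = c("G", "G", "G"), alt = c("T", "T", "T"))
  pol <- polarizeCommon(common, wd)
  expect_equal(pol$ancestral, c("G", "T", NA))
  expect_equal(pol$derived, c("T", "G", NA))
  # a site absent from the wild-derived matrix is fixed reference there
  pol2 <- polarizeCommon(common, wd[1, ])
  expect_equal(pol2$ancestral, c("G", "G", "G"))
})

test_that("SPV and common variant sets are disjoint", {
  fx <- smallFixture()
  cand <- identifySingletons(fx$gm)
  res <- applyFilterStack(cand, fx$gm, fx$ref, fx$repeatTrack,
                          fx$segdupTrack, fx$wild, fx$wildDerived, fx$kept)
  common <- defineCommonVariants(fx$gm, fx$repeatTrack, fx$segdupTrack)
  expect_length(intersect(paste(res$spvs$chrom, res$spvs$pos),
                          paste(common$chrom, common$pos)), 0)
})
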