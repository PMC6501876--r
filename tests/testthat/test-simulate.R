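test_that("founder pools are polymorphic at every site and reproducible", {
  pool <- buildFounderPool(nFounders = 4, chromLength = 2e5,
                           snpDensity = 1e-3, seed = 11)
  counts <- colSums(pool$founderAlleles)
  expect_true(all(counts >= 1 & counts <= 3))
  pool2 <- buildFounderPool(nFounders = 4, chromLength = 2e5,
                            snpDensity = 1e-3, seed = 11)
  expect_identical(pool$snpPositions, pool2$snpPositions)
  expect_identical(pool$founderAlleles, pool2$founderAlleles)
  expect_identical(as.character(pool$refSequence),
                   as.character(pool2$refSequence))
  expect_error(buildFounderPool(nFounders = 1, chromLength = 1e5),
               "at least 2")
})

test_that("with two founders every panel site is biallelic between them", {
  pool <- buildFounderPool(nFounders = 2, chromLength = 2e5,
                           snpDensity = 5e-4, seed = 3)
  expect_true(all(colSums(pool$founderAlleles) == 1))
})

test_that("realized GC content matches the target within binomial noise", {
  L <- 1e6
  ref <- makeReferenceSequence(L, gcContent = 0.5, seed = 5)
  gc <- sum(Biostrings::letterFrequency(ref, c("G", "C"))) / L
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / L))
})

test_that("mosaic blocks tile the chromosome and genotypes follow founders", {
  pool <- buildFounderPool(nFounders = 3, chromLength = 5e5,
                           snpDensity = 1e-3, seed = 7)
  strains <- simulateStrainMosaics(pool, nStrains = 4,
                                   meanBlockLength = 5e4, seed = 8)
  for (st in strains) {
    b <- st$blocks
    expect_equal(b$start[1], 1)
    expect_equal(b$end[nrow(b)], pool$chromLength)
    if (nrow(b) > 1)
      expect_equal(b$start[-1], b$end[-nrow(b)] + 1)
    blockIdx <- findInterval(pool$snpPositions, b$start)
    expect_equal(st$alleles,
                 pool$founderAlleles[cbind(b$founder[blockIdx],
                                           seq_along(pool$snpPositions))])
  }
  expect_error(simulateStrainMosaics(pool, nStrains = 1), "at least 2")
})

test_that("huge mean block length collapses strains to single founders", {
  pool <- buildFounderPool(nFounders = 3, chromLength = 2e5,
                           snpDensity = 1e-3, seed = 9)
  strains <- simulateStrainMosaics(pool, nStrains = 10,
                                   meanBlockLength = 2e5 * 100, seed = 10)
  founders <- vapply(strains, function(s)
    if (nrow(s$blocks) == 1) s$blocks$founder else NA_integer_, integer(1))
  expect_gt(mean(!is.na(founders)), 0.8)
  same <- which(founders == founders[which(!is.na(founders))[1]])
  if (length(same) >= 2)
    expect_identical(strains[[same[1]]]$alleles, strains[[same[2]]]$alleles)
})

test_that("pairwise IBD probability at a site is about 1/n_founders", {
  pool <- buildFounderPool(nFounders = 8, chromLength = 1e6,
                           snpDensity = 2e-4, seed = 21)
  strains <- simulateStrainMosaics(pool, nStrains = 12,
                                   meanBlockLength = 1e6 * 100, seed = 22)
  # with whole-chromosome blocks, strain pairs are IBD iff they drew the
  # same founder; the fraction of such pairs estimates 1/n_founders
  f <- vapply(strains, function(s) s$blocks$founder[1], integer(1))
  pairs <- combn(length(f), 2)
  frac <- mean(f[pairs[1, ]] == f[pairs[2, ]])
  expect_lt(abs(frac - 1 / 8), 0.1)
})

test_that("planting zero mutations leaves genotypes untouched", {
  pool <- buildFounderPool(nFounders = 3, chromLength = 2e5,
                           snpDensity = 5e-4, seed = 12)
  strains <- simulateStrainMosaics(pool, 3, 5e4, seed = 13)
  truth <- plantPrivateMutations(pool, strains, mutationsPerStrain = 0)
  expect_equal(nrow(truth), 0L)
  gm <- strainGenotypeMatrix(pool, strains, truth)
  expect_equal(nrow(gm), length(pool$snpPositions))
})

test_that("an all-C>T spectrum plants only at C/G bases", {
  pool <- buildFounderPool(nFounders = 3, chromLength = 5e5,
                           snpDensity = 2e-4, seed = 14)
  strains <- simulateStrainMosaics(pool, 3, 1e5, seed = 15)
  spec <- c("C>A" = 0, "C>G" = 0, "C>T" = 1, "T>A" = 0, "T>C" = 0,
            "T>G" = 0)
  truth <- plantPrivateMutations(pool, strains, 50, spec, seed = 16)
  expect_true(all(truth$ancestral %in% c("C", "G")))
  expect_true(all(truth$folded_class == "C>T"))
  # derived allele on the reference strand is complement-consistent
  expect_true(all(truth$derived[truth$ancestral == "C"] == "T"))
  expect_true(all(truth$derived[truth$ancestral == "G"] == "A"))
})

test_that("planted class counts follow the requested multinomial spectrum", {
  pool <- buildFounderPool(nFounders = 3, chromLength = 2e6,
                           snpDensity = 1e-4, seed = 17)
  strains <- simulateStrainMosaics(pool, 2, 5e5, seed = 18)
  p <- c("C>A" = 0.1, "C>G" = 0.1, "C>T" = 0.4, "T>A" = 0.1, "T>C" = 0.2,
         "T>G" = 0.1)
  truth <- plantPrivateMutations(pool, strains, 500, p, seed = 19)
  obs <- table(factor(truth$folded_class, levels = FOLDED_CLASSES))
  chisq <- sum((obs - 1000 * p)^2 / (1000 * p))
  expect_gt(pchisq(chisq, df = 5, lower.tail = FALSE), 0.001)
  # heterozygous fraction near its default 8.3%
  hf <- mean(truth$zygosity == "heterozygous")
  expect_lt(abs(hf - 0.083), 3 * sqrt(0.083 * 0.917 / 1000))
})

test_that("planted ancestral alleles equal the allele of all other strains", {
  fx <- smallFixture()
  gm <- fx$gm
  key <- paste(siteChrom(gm), sitePos(gm))
  idx <- match(paste(fx$truth$chrom, fx$truth$pos), key)
  expect_false(anyNA(idx))
  gt <- genotypes(gm)
  for (k in seq_len(nrow(fx$truth))) {
    others <- setdiff(strainNames(gm), fx$truth$strain[k])
    expect_true(all(gt[idx[k], others] == 0L))
    expect_equal(refAllele(gm)[idx[k]], fx$truth$ancestral[k])
  }
  # every planted mutation lies inside exactly one block of its strain
  strainOf <- setNames(fx$strains, vapply(fx$strains, `[[`, character(1),
                                          "name"))
  nBlocks <- vapply(seq_len(nrow(fx$truth)), function(k) {
    b <- strainOf[[fx$truth$strain[k]]]$blocks
    sum(fx$truth$pos[k] >= b$start & fx$truth$pos[k] <= b$end)
  }, numeric(1))
  expect_true(all(nBlocks == 1))
})

test_that("the wild outgroup is reproducible and shows no long runs", {
  pool <- buildFounderPool(nFounders = 8, chromLength = 5e6,
                           snpDensity = 5e-4, seed = 30)
  w1 <- simulateWildOutgroup(pool, nSamples = 10, seed = 31)
  w2 <- simulateWildOutgroup(pool, nSamples = 10, seed = 31)
  expect_identical(genotypes(w1), genotypes(w2))
  expect_lt(longestPairwiseRun(w1), 5e6)
  expect_error(simulateWildOutgroup(pool, 5, extraDiversity = 0),
               "extraDiversity")
  # flag-gated degenerate case: single founder, no extra diversity
  pool1 <- buildFounderPool(nFounders = 1, chromLength = 1e5,
                            snpDensity = 1e-4, seed = 32,
                            allowSingleFounder = TRUE)
  wd <- simulateWildOutgroup(pool1, 3, extraDiversity = 0, seed = 33,
                             allowDegenerate = TRUE)
  g <- genotypes(wd)
  expect_true(all(g == g[, 1]))
})

test_that("emitted fixture files round trip through the readers", {
  dir <- withr::local_tempdir()
  paths <- emitFixtureSet(dir, seed = 5, config = list(
    chromLength = 5e5, nStrains = 4, mutationsPerStrain = 10, nWild = 4,
    nGenes = 3, snpDensity = 2e-4))
  gm <- readGenotypes(paths$strains_vcf)
  fx <- simulateFixture(seed = 5, config = list(
    chromLength = 5e5, nStrains = 4, mutationsPerStrain = 10, nWild = 4,
    nGenes = 3, snpDensity = 2e-4))
  expect_equal(genotypes(gm), genotypes(fx$gm))
  expect_equal(sitePos(gm), sitePos(fx$gm))
  ref <- readReference(paths$ref_fasta)
  expect_equal(as.character(ref), as.character(fx$ref))
  expect_s4_class(readIntervalTrack(paths$repeats_bed), "GRanges")
  genes <- readGeneModels(paths$genes_gff3)
  expect_equal(length(genes), length(fx$geneModels))
  expect_equal(BiocGenerics::start(genes), BiocGenerics::start(fx$geneModels))
  sc <- readScoreTrack(paths$scores)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  tr <- readTraitTable(paths$traits)
  expect_setequal(unique(tr$trait),
                  c("dam_age_first_litter", "interbirth_interval"))
})
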