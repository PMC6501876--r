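test_that("the MAF panel filter matches a per-site brute-force recount", {
  set.seed(101)
  gm <- randomPanel(300, 10)
  panel <- buildIbdPanel(gm, mafMin = 0.05)
  gt <- genotypes(gm)
  keep <- logical(nrow(gm))
  for (i in seq_len(nrow(gm))) {
    g <- gt[i, ]
    g <- g[!is.na(g)]
    alt <- sum(g)
    tot <- 2 * length(g)
    maf <- min(alt / tot, 1 - alt / tot)
    keep[i] <- maf > 0.05
  }
  expect_equal(sitePos(panel), sitePos(gm)[keep])
})

test_that("MAF handles singleton and reference-only sites as specified", {
  gt <- matrix(0L, 2, 10, dimnames = list(NULL, paste0("s", 1:10)))
  gt[1, 4] <- 2L   # one alt homozygote among 10 strains: MAF 0.1
  gm <- toyMatrix(gt)
  maf <- minorAlleleFreq(gm)
  expect_equal(maf, c(0.1, 0))
  panel <- buildIbdPanel(gm, mafMin = 0.05)
  expect_equal(nrow(panel), 1L)
  # reference strain counted: 2 extra ref alleles shift the frequency
  expect_equal(minorAlleleFreq(gm, countReference = TRUE)[1], 2 / 22)
  expect_error(buildIbdPanel(gm, mafMin = 0.4), "no sites")
})

test_that("two identical strains yield one segment spanning the panel", {
  gt <- matrix(rep(c(0L, 2L), 50), 100, 2,
               dimnames = list(NULL, c("a", "b")))
  pos <- sort(sample.int(1e7, 100))
  gm <- toyMatrix(gt, pos = pos)
  segs <- detectPairwiseIbd(gm, "a", "b", minSeedBp = 2e5)
  expect_equal(length(segs), 1L)
  expect_equal(BiocGenerics::start(segs), pos[1])
  expect_equal(BiocGenerics::end(segs), pos[100])
  expect_equal(S4Vectors::mcols(segs)$nSites, 100L)
  expect_error(detectPairwiseIbd(gm, "a", "zz"), "unknown strain")
})

test_that("a single discordant site splits the run into two segments", {
  gt <- matrix(0L, 101, 2, dimnames = list(NULL, c("a", "b")))
  gt[51, 2] <- 2L
  pos <- seq(1e5, by = 1e5, length.out = 101)
  gm <- toyMatrix(gt, pos = pos)
  segs <- detectPairwiseIbd(gm, "a", "b", minSeedBp = 1e5)
  expect_equal(length(segs), 2L)
  expect_equal(BiocGenerics::start(segs), pos[c(1, 52)])
  expect_equal(BiocGenerics::end(segs), pos[c(50, 101)])
})

test_that("detection is symmetric and equals the naive scanning oracle", {
  set.seed(202)
  for (rep in 1:30) {
    gm <- randomPanel(sample(30:250, 1), sample(3:5, 1))
    sn <- strainNames(gm)
    minSeed <- sample(c(0, 1e5, 5e5), 1)
    for (pair in list(c(1, 2), c(2, 3))) {
      a <- sn[pair[1]]; b <- sn[pair[2]]
      got <- segsToDf(detectPairwiseIbd(gm, a, b, minSeedBp = minSeed))
      rev <- segsToDf(detectPairwiseIbd(gm, b, a, minSeedBp = minSeed))
      expect_equal(got, rev)
      oracle <- naiveIbdScan(gm, a, b, minSeed)
      expect_equal(got$start, oracle$start)
      expect_equal(got$end, oracle$end)
    }
  }
})

test_that("a mismatch budget returns maximal windows per the brute oracle", {
  set.seed(303)
  for (rep in 1:10) {
    gm <- randomPanel(60, 3, pMissing = 0.05, pHet = 0.05)
    got <- segsToDf(detectPairwiseIbd(gm, "s1", "s2", minSeedBp = 0,
                                      maxMismatches = 1))
    oracle <- bruteIbdWindows(gm, "s1", "s2", minSeedBp = 0, m = 1)
    expect_equal(got$start, oracle$start)
    expect_equal(got$end, oracle$end)
  }
})

test_that("segments cannot be extended without breaking the run", {
  set.seed(404)
  gm <- randomPanel(400, 4)
  gt <- genotypes(gm)
  segs <- detectPairwiseIbd(gm, "s1", "s2", minSeedBp = 0)
  pos <- sitePos(gm)
  ok <- !is.na(gt[, "s1"]) & !is.na(gt[, "s2"]) &
    gt[, "s1"] == gt[, "s2"] & gt[, "s1"] != 1L
  for (k in seq_along(segs)) {
    i <- match(BiocGenerics::start(segs)[k], pos)
    j <- match(BiocGenerics::end(segs)[k], pos)
    if (i > 1) expect_false(ok[i - 1])
    if (j < length(pos)) expect_false(ok[j + 1])
  }
})

test_that("segment length retention is inclusive at the threshold", {
  segs <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1, 1), width = c(4999999, 5000000)),
                                 strainA = "a", strainB = "b",
                                 nSites = c(10L, 10L))
  kept <- filterSegments(segs, 5e6)
  expect_equal(length(kept), 1L)
  expect_equal(BiocGenerics::width(kept), 5000000L)
  expect_equal(length(filterSegments(segs[0], 5e6)), 0L)
})

test_that("strain IBD coverage is the union over partners", {
  segs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 5e6 + 1), end = c(1e7, 2e7)),
    strainA = c("a", "a"), strainB = c("b", "c"), nSites = c(5L, 5L))
  expect_equal(strainIbdCoverage(segs, "a", 4e7), 0.5)
  expect_equal(strainIbdCoverage(segs, "d", 4e7), 0)
  # brute-force per-base union on a small case
  set.seed(7)
  starts <- sample.int(900, 10)
  ends <- pmin(starts + sample.int(120, 10), 1000)
  segs2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends),
                                  strainA = "a",
                                  strainB = sample(c("b", "c"), 10, TRUE),
                                  nSites = 1L)
  mask <- logical(1000)
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  expect_equal(strainIbdCoverage(segs2, "a", 1000), mean(mask),
               tolerance = 1e-12)
})

test_that("longest pairwise run handles edge cases", {
  gt <- matrix(c(0L, 0L, 2L, 2L, 0L, 0L, 2L, 2L), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  pos <- c(100L, 5000L, 20000L, 90000L)
  gm <- toyMatrix(gt, pos = pos)
  expect_equal(longestPairwiseRun(gm), 90000 - 100 + 1)
  expect_error(longestPairwiseRun(gm[, 1]), "two samples")
})

test_that("true shared founder blocks are recovered on the mosaic fixture", {
  fx <- smallFixture()
  panel <- buildIbdPanel(fx$gm, mafMin = fx$config$panelMafMin)
  sn <- vapply(fx$strains, `[[`, character(1), "name")
  pairs <- list(c(1, 2), c(3, 4), c(5, 6))
  for (pr in pairs) {
    a <- fx$strains[[pr[1]]]; b <- fx$strains[[pr[2]]]
    segs <- detectPairwiseIbd(panel, a$name, b$name, minSeedBp = 2e5)
    # true shared intervals: same founder in overlapping blocks
    shared <- list()
    for (i in seq_len(nrow(a$blocks))) {
      for (j in seq_len(nrow(b$blocks))) {
        if (a$blocks$founder[i] != b$blocks$founder[j]) next
        lo <- max(a$blocks$start[i], b$blocks$start[j])
        hi <- min(a$blocks$end[i], b$blocks$end[j])
        if (lo <= hi) shared[[length(shared) + 1]] <- c(lo, hi)
      }
    }
    pos <- sitePos(panel)
    for (s in shared) {
      inside <- pos[pos >= s[1] & pos <= s[2]]
      if (length(inside) < 2 || inside[length(inside)] - inside[1] < 2e5)
        next
      # every panel site of the true block falls inside one detected segment
      hit <- which(BiocGenerics::start(segs) <= inside[1] &
                     BiocGenerics::end(segs) >= inside[length(inside)])
      expect_equal(length(hit), 1L)
    }
  }
})
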