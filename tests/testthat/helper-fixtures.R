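# Shared fixtures, built once per run and cached.

# Small mosaic fixture for unit tests: 8 Mb, 8 strains, 10 genes. With an
# 8-strain panel the MAF cutoff 0.15 sits between the singleton (1/8) and
# doubleton (2/8) frequency, excluding private alleles from IBD inference.
smallFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- simulateFixture(seed = 42, config = list(
        chromLength = 8e6, nStrains = 8, mutationsPerStrain = 60,
        nWild = 10, nGenes = 10, panelMafMin = 0.15, minKeepBp = 2e6))
      panel <- buildIbdPanel(fx$gm, mafMin = fx$config$panelMafMin)
      fx$segments <- detectIbdSegments(panel, minSeedBp = fx$config$minSeedBp)
      fx$kept <- filterSegments(fx$segments, fx$config$minKeepBp)
      cache <<- fx
    }
    cache
  }
})

# Full-scale study fixture (60 Mb, 12 strains, 8 founders, 300 mutations
# per strain), shared by the acceptance-style end-to-end checks.
studyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- simulateFixture(seed = 20260922)
      panel <- buildIbdPanel(fx$gm, mafMin = fx$config$panelMafMin)
      fx$kept <- detectIbdSegments(panel, minSeedBp = fx$config$minSeedBp,
                                   minKeepBp = fx$config$minKeepBp)
      cache <<- fx
    }
    cache
  }
})

# Hand-built genotype matrix for logic tests.
toyMatrix <- function(gt, pos = NULL, ref = NULL, alt = NULL,
                      qual = NULL, ...) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  if (is.null(colnames(gt)))
    colnames(gt) <- paste0("s", seq_len(ncol(gt)))
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(qual)) qual <- rep(200, n)
  GenotypeMatrix(chrom = rep("chr1", n), pos = pos, ref = ref, alt = alt,
                 qual = qual, gt = gt, ...)
}

# Truth records inside retained IBD territory of their strain and outside
# the masks -- the territory on which end-to-end recall is defined.
cleanTruthRecords <- function(truth, kept, repeatTrack, segdupTrack) {
  inside <- rep(FALSE, nrow(truth))
  for (s in unique(truth$strain)) {
    k <- which(truth$strain == s)
    segs <- kept[S4Vectors::mcols(kept)$strainA == s |
                   S4Vectors::mcols(kept)$strainB == s]
    if (length(segs))
      inside[k] <- pointInTrack(GenomicRanges::reduce(segs),
                                truth$chrom[k], truth$pos[k])
  }
  masked <- pointInTrack(repeatTrack, truth$chrom, truth$pos) |
    pointInTrack(segdupTrack, truth$chrom, truth$pos)
  truth[inside & !masked, , drop = FALSE]
}

# Independent naive IBD scan (budget 0): walk the sites, break runs at any
# non-matching site, keep runs spanning >= minSeedBp.
naiveIbdScan <- function(panel, a, b, minSeedBp) {
  gt <- genotypes(panel)
  pos <- sitePos(panel)
  ga <- gt[, a]; gb <- gt[, b]
  segs <- list()
  runStart <- NA
  last <- NA
  for (i in seq_along(pos)) {
    match <- !is.na(ga[i]) && !is.na(gb[i]) && ga[i] == gb[i] && ga[i] != 1
    if (match) {
      if (is.na(runStart)) runStart <- i
      last <- i
    } else if (!is.na(runStart)) {
      segs[[length(segs) + 1]] <- c(runStart, last)
      runStart <- NA
    }
  }
  if (!is.na(runStart)) segs[[length(segs) + 1]] <- c(runStart, last)
  out <- do.call(rbind, segs)
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      nSites = integer()))
  df <- data.frame(start = pos[out[, 1]], end = pos[out[, 2]],
                   nSites = out[, 2] - out[, 1] + 1L)
  df[df$end - df$start + 1 >= minSeedBp, , drop = FALSE]
}

# Brute-force maximal-window oracle for a mismatch budget: every window
# with matching endpoints and <= m non-matching sites that is not
# contained in another such window.
bruteIbdWindows <- function(panel, a, b, minSeedBp, m) {
  gt <- genotypes(panel)
  pos <- sitePos(panel)
  ga <- gt[, a]; gb <- gt[, b]
  ok <- !is.na(ga) & !is.na(gb) & ga == gb & ga != 1
  idx <- which(ok)
  wins <- list()
  for (i in idx) {
    for (j in idx[idx >= i]) {
      if (sum(!ok[i:j]) <= m) wins[[length(wins) + 1]] <- c(i, j)
    }
  }
  if (!length(wins)) return(data.frame(start = integer(), end = integer()))
  w <- unique(do.call(rbind, wins))
  maximal <- vapply(seq_len(nrow(w)), function(k) {
    !any(w[, 1] <= w[k, 1] & w[, 2] >= w[k, 2] &
           (w[, 1] != w[k, 1] | w[, 2] != w[k, 2]))
  }, logical(1))
  w <- w[maximal, , drop = FALSE]
  df <- data.frame(start = pos[w[, 1]], end = pos[w[, 2]])
  df <- df[df$end - df$start + 1 >= minSeedBp, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

segsToDf <- function(segs) {
  if (!length(segs)) return(data.frame(start = integer(), end = integer()))
  df <- data.frame(start = BiocGenerics::start(segs),
                   end = BiocGenerics::end(segs))
  df[order(df$start), , drop = FALSE]
}

randomPanel <- function(nSites, nStrains, pMissing = 0.02, pHet = 0.02) {
  gt <- matrix(sample(c(0L, 2L), nSites * nStrains, replace = TRUE),
               nSites, nStrains)
  gt[runif(length(gt)) < pHet] <- 1L
  gt[runif(length(gt)) < pMissing] <- NA
  colnames(gt) <- paste0("s", seq_len(nStrains))
  pos <- sort(sample.int(nSites * 2000L, nSites))
  toyMatrix(gt, pos = pos)
}
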