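## Among-strain variation in mutation spectra: pairwise G-tests, PCA on
## standardized frequencies, and correlations with life-history traits.

#' Pairwise G-tests of spectrum heterogeneity
#'
#' For every unordered strain pair, a 2 x k G-test of the raw folded-class
#' counts (df = k - 1 for spectra observed in both strains). P-values are
#' uncorrected; the summary reports the fraction of pairs significant at
#' `alpha`.
#'
#' @param counts strains x classes count matrix (see [classCounts]).
#' @param alpha Significance level for the summary fraction.
#' @return List with `pairs` (data.frame strainA/strainB/G/df/p),
#'   `nPairs`, `fracSignificant`, `alpha`.
#' @export
pairwiseSpectrumGTests <- function(counts, alpha = 0.05) {
  strains <- rownames(counts)
  if (is.null(strains)) strains <- paste0("strain", seq_len(nrow(counts)))
  if (nrow(counts) < 2) stop("need at least two strains")
  pr <- combn(nrow(counts), 2)
  res <- lapply(seq_len(ncol(pr)), function(k) {
    i <- pr[1, k]; j <- pr[2, k]
    g <- gTest(rbind(counts[i, ], counts[j, ]))
    data.frame(strainA = strains[i], strainB = strains[j],
               G = g$G, df = g$df, p = g$p)
  })
  pairs <- do.call(rbind, res)
  list(pairs = pairs, nPairs = nrow(pairs),
       fracSignificant = mean(pairs$p < alpha), alpha = alpha)
}

#' PCA of strain mutation spectra
#'
#' Columns (classes) are zero-centred and scaled to unit variance, and
#' components are obtained by singular value decomposition of the scaled
#' matrix. Zero-variance columns are dropped with a warning (scaling is
#' undefined for them). The sign of each component is fixed so that its
#' largest-magnitude loading is positive. Scores times transposed
#' loadings reconstruct the scaled data exactly.
#'
#' @param freq strains x classes matrix of standardized frequencies.
#' @return List with `loadings` (classes x components), `scores` (strains
#'   x components), `varianceExplained` (fractions summing to 1), and
#'   `dropped` (names of zero-variance columns).
#' @export
pcaSpectra <- function(freq) {
  freq <- as.matrix(freq)
  v <- apply(freq, 2, stats::var)
  dropped <- colnames(freq)[v == 0]
  if (length(dropped))
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
  keep <- freq[, v > 0, drop = FALSE]
  pc <- prcomp(keep, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = rotation, scores = scores, varianceExplained = ve,
       dropped = dropped)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; rho is the Pearson correlation of the ranks and
#' the p-value uses the t approximation with n - 2 degrees of freedom.
#' Returns `NA` for constant input.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho`, `p`, `n`.
#' @export
spearmanCor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE), n = n)
}

#' One-way analysis of variance
#'
#' Standard between/within sums-of-squares decomposition treating the
#' group as a factor; errors when the data carry no variance at all.
#'
#' @param values Numeric measurements.
#' @param groups Group labels (e.g. strain).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
oneWayAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (stats::var(values) == 0)
    stop("total variance is zero; ANOVA undefined")
  a <- anova(lm(values ~ groups))
  list(F = a[1, "F value"], df1 = a[1, "Df"], df2 = a[2, "Df"],
       p = a[1, "Pr(>F)"])
}

#' Correlate spectra with life-history traits
#'
#' Per-strain trait values are replicate means. Reports the Spearman
#' correlation (and p) of each trait with the strain scores on the first
#' principal component of `pcaFreq` and with each class frequency column
#' of `freq` (typically the CpG-split seven-class frequencies). A trait
#' constant across strains yields `NA`.
#'
#' @param freq strains x classes frequency matrix used for the per-class
#'   correlations.
#' @param traits Long data.frame with columns strain, trait, value.
#' @param pcaFreq Frequency matrix for the PCA (default `freq`; use the
#'   six-class frequencies to mirror the main spectrum PCA).
#' @return Data frame with columns trait, feature, rho, p, n.
#' @export
traitSpectrumReport <- function(freq, traits, pcaFreq = freq) {
  freq <- as.matrix(freq)
  strains <- rownames(freq)
  pc <- pcaSpectra(pcaFreq)
  pc1 <- pc$scores[, 1]
  features <- cbind(PC1 = pc1[strains], freq)
  out <- list()
  for (tr in unique(traits$trait)) {
    sub <- traits[traits$trait == tr, ]
    mu <- tapply(sub$value, sub$strain, mean)
    mu <- mu[strains]
    for (f in colnames(features)) {
      sc <- spearmanCor(features[, f], mu)
      out[[length(out) + 1]] <- data.frame(trait = tr, feature = f,
                                           rho = sc$rho, p = sc$p,
                                           n = sc$n)
    }
  }
  do.call(rbind, out)
}
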