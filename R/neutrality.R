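## Tests of whether strain-private variants behave like unselected new
## mutations: coding-consequence composition against common variants and a
## uniform-mutation null, G-tests, bootstrap confidence intervals, and
## conservation-score CDF comparison.

.GENETIC_CODE <- Biostrings::GENETIC_CODE

## classify a single codon change; stop-loss counts as missense
## (protein-altering without a premature stop)
.codonChange <- function(refCodon, altCodon) {
  a <- .GENETIC_CODE[[refCodon]]
  b <- .GENETIC_CODE[[altCodon]]
  if (a == b) return("synonymous")
  if (b == "*") return("nonsense")
  "missense"
}

#' Read gene models from a GFF3 file
#'
#' Keeps CDS/gene features as 1-based inclusive intervals. Models are
#' expected to be forward-strand single-exon ORFs with length divisible
#' by three.
#'
#' @param path GFF3 file path.
#' @return A `GRanges` of CDS intervals.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type %in% c("CDS", "sequence_feature")))
    gr <- gr[gr$type %in% c("CDS", "sequence_feature")]
  gr
}

#' Classify the coding consequence of substitutions
#'
#' Standard codon-table comparison of the ancestral versus derived codon
#' for sites inside a gene model CDS; positions outside every model are
#' `noncoding`. Stop-gained changes are `nonsense`; stop-lost changes are
#' treated as `missense`.
#'
#' @param chrom,pos,ancestral,derived Vectors describing the
#'   substitutions (1-based positions; single bases).
#' @param geneModels `GRanges` of forward-strand single-exon CDS models.
#' @param ref Reference `DNAStringSet`.
#' @return Character vector in
#'   `{synonymous, missense, nonsense, noncoding}`.
#' @export
classifyConsequence <- function(chrom, pos, ancestral, derived, geneModels,
                                ref) {
  n <- length(pos)
  out <- rep("noncoding", n)
  if (!length(geneModels)) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  ## chromosomes absent from the models are simply noncoding
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, geneModels, ignore.strand = TRUE))
  for (h in seq_along(hits)) {
    qi <- S4Vectors::queryHits(hits)[h]
    gi <- S4Vectors::subjectHits(hits)[h]
    cdsStart <- BiocGenerics::start(geneModels)[gi]
    offset <- pos[qi] - cdsStart
    codonStart <- cdsStart + 3L * (offset %/% 3L)
    codon <- getBases(ref, chrom[qi], codonStart, codonStart + 2L)
    within <- offset %% 3L + 1L
    refCodon <- codon
    substr(refCodon, within, within) <- ancestral[qi]
    altCodon <- refCodon
    substr(altCodon, within, within) <- derived[qi]
    out[qi] <- .codonChange(refCodon, altCodon)
  }
  out
}

## per-codon tallies of (synonymous, missense, nonsense) over all 9
## single-base changes
.codonNullTable <- function() {
  codons <- mkAllCodons()
  t(vapply(codons, function(cod) {
    res <- c(synonymous = 0, missense = 0, nonsense = 0)
    for (i in 1:3) {
      for (b in setdiff(.BASES, substr(cod, i, i))) {
        alt <- cod
        substr(alt, i, i) <- b
        cls <- .codonChange(cod, alt)
        res[cls] <- res[cls] + 1
      }
    }
    res
  }, numeric(3)))
}

#' Consequence fractions under uniform mutation
#'
#' Enumerates all nine single-base changes at every CDS position of the
#' supplied gene models and returns the fractions that are synonymous,
#' missense and nonsense. This is the null expectation for new mutations
#' falling uniformly on coding sites.
#'
#' @param geneModels `GRanges` of forward-strand single-exon CDS models.
#' @param ref Reference `DNAStringSet`.
#' @return Named fractions summing to 1.
#' @export
nullConsequenceFractions <- function(geneModels, ref) {
  if (!length(geneModels)) stop("no gene models supplied")
  tab <- .codonNullTable()
  tot <- c(synonymous = 0, missense = 0, nonsense = 0)
  for (g in seq_along(geneModels)) {
    s <- getBases(ref, as.character(GenomicRanges::seqnames(geneModels))[g],
                  BiocGenerics::start(geneModels)[g],
                  BiocGenerics::end(geneModels)[g])
    if (nchar(s) %% 3 != 0) stop("CDS length not divisible by 3")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    counts <- table(factor(codons, levels = rownames(tab)))
    tot <- tot + colSums(tab * as.integer(counts))
  }
  tot / sum(tot)
}

#' G-test of independence
#'
#' Likelihood-ratio statistic `G = 2 * sum(O * ln(O / E))` with expected
#' counts from the row/column margins, `0 * ln(0) = 0`, degrees of freedom
#' `(r - 1)(c - 1)` and an upper-tail chi-square p-value.
#'
#' @param tab An r x c matrix of counts.
#' @return List with `G`, `df`, `p`.
#' @export
gTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  term <- ifelse(tab > 0, tab * log(tab / E), 0)
  G <- 2 * sum(term)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(G = G, df = df, p = pchisq(G, df, lower.tail = FALSE))
}

#' Percentile bootstrap confidence intervals for class percentages
#'
#' Resamples `nTotal` labeled variants with replacement `nReps` times
#' (equivalently, multinomial resampling of the class counts) and returns
#' the percentile interval of each class percentage.
#'
#' @param nTotal Total number of variants (must equal `sum(classCounts)`).
#' @param classCounts Named vector of class counts.
#' @param nReps Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return Matrix classes x (lower, upper), in percent.
#' @export
bootstrapFractionCI <- function(nTotal, classCounts, nReps = 1000,
                                level = 0.95, seed = NULL) {
  if (nTotal != sum(classCounts))
    stop("nTotal must equal sum(classCounts)")
  if (!is.null(seed)) set.seed(seed)
  draws <- rmultinom(nReps, nTotal, classCounts / nTotal)
  pct <- 100 * draws / nTotal
  alpha <- (1 - level) / 2
  ci <- t(apply(pct, 1, quantile, probs = c(alpha, 1 - alpha)))
  dimnames(ci) <- list(names(classCounts), c("lower", "upper"))
  ci
}

#' Compare conservation-score distributions
#'
#' Two-sample Kolmogorov-Smirnov comparison of the conservation scores at
#' strain-private versus common variants (asymptotic p-value), with
#' empirical CDFs of all supplied groups evaluated on a fixed score grid
#' for tabular output. Only scores at non-repeat-masked sites should be
#' supplied.
#'
#' @param spvScores,commonScores Numeric score vectors in `[0, 1]`.
#' @param genomeScores Optional genome-wide background scores.
#' @param grid Score grid for the CDF table.
#' @return List with `cdf` (data.frame score/spv/common[/genome]),
#'   `D` (KS statistic) and `p`.
#' @export
conservationCdfCompare <- function(spvScores, commonScores,
                                   genomeScores = NULL,
                                   grid = seq(0, 1, by = 0.05)) {
  chk <- function(x) {
    x <- x[!is.na(x)]
    if (any(x < 0 | x > 1)) stop("scores must lie in [0, 1]")
    x
  }
  spvScores <- chk(spvScores)
  commonScores <- chk(commonScores)
  ks <- suppressWarnings(ks.test(spvScores, commonScores))
  cdf <- data.frame(score = grid,
                    spv = ecdf(spvScores)(grid),
                    common = ecdf(commonScores)(grid))
  if (!is.null(genomeScores)) cdf$genome <- ecdf(chk(genomeScores))(grid)
  list(cdf = cdf, D = unname(ks$statistic), p = ks$p.value)
}
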