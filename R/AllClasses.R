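#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges
#' @importFrom stats pchisq quantile rbinom rexp rmultinom runif rnorm
#'   setNames anova lm complete.cases prcomp cor ks.test pt rbeta ecdf var
#' @importFrom utils read.table write.table head combn
NULL

.GT_ASSAYS <- c("gt", "gq", "dp", "plMargin", "adRef", "adAlt",
                "refFwd", "refRev", "altFwd", "altRev")

#' GenotypeMatrix: biallelic SNP genotypes with per-call quality
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding sites in
#' rows and strains (samples) in columns. The `gt` assay codes genotypes as
#' `0` (hom ref), `1` (het), `2` (hom alt) and `NA` (missing). Further
#' assays carry per-call quality annotations: `gq` (genotype quality), `dp`
#' (depth), `plMargin` (phred-scaled likelihood difference between the best
#' and second-best genotype), `adRef`/`adAlt` (allele depths) and
#' `refFwd`/`refRev`/`altFwd`/`altRev` (per-strand allele read counts).
#' Row ranges are single-base [GenomicRanges::GRanges] (1-based) with
#' metadata columns `ref`, `alt` and `qual` (site quality). Missing quality
#' annotations are stored as `NA` and deliberately fail any filter that
#' depends on them.
#'
#' @aliases GenotypeMatrix-class
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  missingAssays <- setdiff(.GT_ASSAYS, SummarizedExperiment::assayNames(object))
  if (length(missingAssays))
    msg <- c(msg, paste("missing assays:", paste(missingAssays, collapse = ", ")))
  rr <- SummarizedExperiment::rowRanges(object)
  need <- c("ref", "alt", "qual")
  if (!all(need %in% colnames(S4Vectors::mcols(rr))))
    msg <- c(msg, "rowRanges must carry mcols ref, alt, qual")
  else {
    ref <- S4Vectors::mcols(rr)$ref
    alt <- S4Vectors::mcols(rr)$alt
    if (any(ref == alt)) msg <- c(msg, "ref and alt alleles must differ")
    if (!all(c(ref, alt) %in% .BASES))
      msg <- c(msg, "ref/alt must be single bases A/C/G/T")
  }
  if (length(rr) && any(BiocGenerics::width(rr) != 1L))
    msg <- c(msg, "all sites must be single-base ranges")
  if (is.null(colnames(object)) && ncol(object) > 0)
    msg <- c(msg, "strain (column) names are required")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate strain names")
  gt <- SummarizedExperiment::assay(object, "gt")
  if (!all(gt %in% c(0L, 1L, 2L, NA)))
    msg <- c(msg, "gt codes must be 0/1/2/NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param chrom Chromosome name per site.
#' @param pos 1-based position per site.
#' @param ref,alt Single-base reference and alternative alleles.
#' @param qual Site quality (phred-like); `NA` allowed.
#' @param gt Integer matrix sites x strains of genotype codes 0/1/2/NA.
#' @param gq,dp,plMargin,adRef,adAlt,refFwd,refRev,altFwd,altRev Optional
#'   matrices of the same shape as `gt`; default all-`NA` (which fails
#'   quality filters that need them).
#' @return A [GenotypeMatrix-class] with rows sorted by chromosome and
#'   position.
#' @export
GenotypeMatrix <- function(chrom, pos, ref, alt, qual, gt,
                           gq = NULL, dp = NULL, plMargin = NULL,
                           adRef = NULL, adAlt = NULL,
                           refFwd = NULL, refRev = NULL,
                           altFwd = NULL, altRev = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  blank <- function(m) {
    if (is.null(m)) {
      m <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    } else {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
    }
    m
  }
  if (any(pos < 1)) stop("positions must be >= 1")
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = as.character(ref),
                               alt = as.character(alt),
                               qual = as.numeric(qual))
  assays <- list(gt = gt, gq = blank(gq), dp = blank(dp),
                 plMargin = blank(plMargin), adRef = blank(adRef),
                 adAlt = blank(adAlt), refFwd = blank(refFwd),
                 refRev = blank(refRev), altFwd = blank(altFwd),
                 altRev = blank(altRev))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = rr)
  obj <- methods::new("GenotypeMatrix", se)
  ord <- BiocGenerics::order(SummarizedExperiment::rowRanges(obj))
  obj[ord, ]
}

#' @rdname GenotypeMatrix
#' @param x A `GenotypeMatrix`.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x)
  SummarizedExperiment::assay(x, "gt"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname GenotypeMatrix
#' @export
setMethod("strainNames", "GenotypeMatrix", function(x) colnames(x))

#' @rdname GenotypeMatrix
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @rdname GenotypeMatrix
#' @export
setMethod("refAllele", "GenotypeMatrix", function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$ref)

#' @rdname GenotypeMatrix
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))

#' @rdname GenotypeMatrix
#' @export
setMethod("altAllele", "GenotypeMatrix", function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$alt)

#' @rdname GenotypeMatrix
#' @export
setGeneric("siteQual", function(x) standardGeneric("siteQual"))

#' @rdname GenotypeMatrix
#' @export
setMethod("siteQual", "GenotypeMatrix", function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$qual)

#' @rdname GenotypeMatrix
#' @export
setGeneric("siteChrom", function(x) standardGeneric("siteChrom"))

#' @rdname GenotypeMatrix
#' @export
setMethod("siteChrom", "GenotypeMatrix", function(x)
  as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x))))

#' @rdname GenotypeMatrix
#' @export
setGeneric("sitePos", function(x) standardGeneric("sitePos"))

#' @rdname GenotypeMatrix
#' @export
setMethod("sitePos", "GenotypeMatrix", function(x)
  BiocGenerics::start(SummarizedExperiment::rowRanges(x)))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix with", nrow(object), "biallelic sites x",
      ncol(object), "strains\n")
  gt <- genotypes(object)
  if (length(gt)) {
    cat(sprintf("  genotypes: %.1f%% hom ref, %.1f%% het, %.1f%% hom alt, %.1f%% missing\n",
                100 * mean(gt == 0, na.rm = TRUE) * mean(!is.na(gt)),
                100 * mean(gt == 1, na.rm = TRUE) * mean(!is.na(gt)),
                100 * mean(gt == 2, na.rm = TRUE) * mean(!is.na(gt)),
                100 * mean(is.na(gt))))
  }
  if (ncol(object))
    cat("  strains:", paste(head(colnames(object), 5), collapse = ", "),
        if (ncol(object) > 5) "..." else "", "\n")
  invisible(object)
})

#' SpectrumMatrix: per-strain folded mutation spectra
#'
#' Holds, for a set of strains, raw folded-class counts, mutational
#' opportunities (eligible base counts within each strain's IBD territory),
#' the opportunity-standardized frequencies (per-class rate divided by the
#' summed rates, so each row sums to one), and the unstandardized count
#' proportions.
#'
#' @slot counts strains x classes integer matrix of folded-class counts.
#' @slot opportunities strains x classes matrix of eligible base counts.
#' @slot frequencies strains x classes matrix; rows sum to 1.
#' @slot proportions strains x classes matrix of raw count proportions.
#' @aliases SpectrumMatrix-class
#' @export
setClass("SpectrumMatrix",
         representation(counts = "matrix", opportunities = "matrix",
                        frequencies = "matrix", proportions = "matrix"))

setValidity("SpectrumMatrix", function(object) {
  msg <- character()
  dims <- lapply(list(object@counts, object@opportunities,
                      object@frequencies, object@proportions), dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    msg <- c(msg, "all slots must share dimensions")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (any(object@frequencies < 0)) msg <- c(msg, "frequencies must be >= 0")
  rs <- rowSums(object@frequencies)
  nonzero <- rowSums(object@counts) > 0
  if (any(abs(rs[nonzero] - 1) > 1e-12))
    msg <- c(msg, "frequency rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SpectrumMatrix-class
#' @param x A `SpectrumMatrix`.
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname SpectrumMatrix-class
#' @export
setMethod("classCounts", "SpectrumMatrix", function(x) x@counts)

#' @rdname SpectrumMatrix-class
#' @export
setGeneric("opportunities", function(x) standardGeneric("opportunities"))

#' @rdname SpectrumMatrix-class
#' @export
setMethod("opportunities", "SpectrumMatrix", function(x) x@opportunities)

#' @rdname SpectrumMatrix-class
#' @export
setGeneric("classFrequencies", function(x) standardGeneric("classFrequencies"))

#' @rdname SpectrumMatrix-class
#' @export
setMethod("classFrequencies", "SpectrumMatrix", function(x) x@frequencies)

#' @rdname SpectrumMatrix-class
#' @export
setGeneric("classProportions", function(x) standardGeneric("classProportions"))

#' @rdname SpectrumMatrix-class
#' @export
setMethod("classProportions", "SpectrumMatrix", function(x) x@proportions)

setMethod("show", "SpectrumMatrix", function(object) {
  cat("SpectrumMatrix:", nrow(object@counts), "strains x",
      ncol(object@counts), "classes\n")
  cat("  total events:", sum(object@counts), "\n")
  invisible(object)
})
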