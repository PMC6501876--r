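## Readers and writers for the standard formats the pipeline touches.
## Coordinate conventions: VCF/FASTA positions are 1-based inclusive, BED
## intervals are 0-based half-open (see pos1ToBed / bedToPos1).

.gtStringToCode <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- rep(NA_integer_, length(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L
  code
}

.gtCodeToString <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0] <- "0/0"
  out[!is.na(code) & code == 1] <- "0/1"
  out[!is.na(code) & code == 2] <- "1/1"
  out
}

#' Read a multi-sample VCF into a GenotypeMatrix
#'
#' Parses a VCF 4.x file with `VariantAnnotation` and keeps biallelic SNP
#' records only; multiallelic or non-SNP records are dropped with a message
#' reporting how many were excluded. FORMAT fields `GT`, `GQ`, `DP`, `PL`,
#' `AD` and the DP4-style strand-count field `SB`
#' (ref-forward, ref-reverse, alt-forward, alt-reverse) are used when
#' present; absent fields become `NA`, which conservatively fails any
#' downstream filter that requires them. The phred-scaled likelihood margin
#' is the difference between the smallest and second-smallest PL entry.
#'
#' @param vcfPath Path to a VCF file (plain or bgzipped).
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(vcfPath) {
  vcf <- VariantAnnotation::readVcf(vcfPath)
  if (anyDuplicated(colnames(vcf)))
    stop("duplicate sample names in ", vcfPath)
  altList <- VariantAnnotation::fixed(vcf)$ALT
  refChar <- as.character(VariantAnnotation::ref(vcf))
  snp <- S4Vectors::elementNROWS(altList) == 1L & nchar(refChar) == 1L
  altChar <- rep(NA_character_, length(vcf))
  altChar[snp] <- vapply(as.list(altList[snp]), function(a) as.character(a[1]),
                         character(1))
  snp <- snp & !is.na(altChar) & nchar(altChar) == 1L &
    altChar %in% .BASES & refChar %in% .BASES
  nDropped <- sum(!snp)
  if (nDropped)
    message(nDropped, " non-biallelic-SNP record(s) excluded")
  vcf <- vcf[snp, ]
  refChar <- refChar[snp]
  altChar <- altChar[snp]

  g <- VariantAnnotation::geno(vcf)
  n <- nrow(vcf)
  ns <- ncol(vcf)
  grab <- function(name) {
    if (name %in% names(g)) {
      m <- g[[name]]
      storage.mode(m) <- "double"
      m
    } else matrix(NA_real_, n, ns, dimnames = list(NULL, colnames(vcf)))
  }
  gtm <- matrix(.gtStringToCode(as.vector(g$GT)), n, ns,
                dimnames = list(NULL, colnames(vcf)))
  plMargin <- matrix(NA_real_, n, ns, dimnames = list(NULL, colnames(vcf)))
  if ("PL" %in% names(g)) {
    pl <- g$PL
    for (j in seq_len(ns)) {
      plMargin[, j] <- vapply(seq_len(n), function(i) {
        v <- sort(unlist(pl[i, j]))
        if (length(v) < 2 || anyNA(v)) NA_real_ else v[2] - v[1]
      }, numeric(1))
    }
  }
  adRef <- adAlt <- matrix(NA_real_, n, ns, dimnames = list(NULL, colnames(vcf)))
  if ("AD" %in% names(g)) {
    ad <- g$AD
    for (j in seq_len(ns)) {
      for (i in seq_len(n)) {
        v <- unlist(ad[i, j])
        if (length(v) >= 2 && !anyNA(v)) {
          adRef[i, j] <- v[1]
          adAlt[i, j] <- v[2]
        }
      }
    }
  }
  sb <- array(NA_real_, c(n, ns, 4))
  if ("SB" %in% names(g)) sb <- g$SB
  sbSlice <- function(k) {
    m <- sb[, , k, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    colnames(m) <- colnames(vcf)
    m
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  GenotypeMatrix(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = refChar, alt = altChar,
    qual = VariantAnnotation::fixed(vcf)$QUAL,
    gt = gtm, gq = grab("GQ"), dp = grab("DP"), plMargin = plMargin,
    adRef = adRef, adAlt = adAlt,
    refFwd = sbSlice(1), refRev = sbSlice(2),
    altFwd = sbSlice(3), altRev = sbSlice(4))
}

#' Write a GenotypeMatrix as a multi-sample VCF
#'
#' Emits VCF 4.2 with FORMAT `GT:GQ:DP:PL:AD:SB`. PL triples are
#' reconstructed from the stored likelihood margin (best genotype 0, second
#' best `margin`, third `2 * margin`), so a write/read round trip restores
#' the margin exactly.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param path Output file path.
#' @param contigLengths Optional named vector of contig lengths for the
#'   header; defaults to the maximum position per chromosome.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(gm, path, contigLengths = NULL) {
  chrom <- siteChrom(gm)
  pos <- sitePos(gm)
  if (is.null(contigLengths)) {
    contigLengths <- tapply(pos, chrom, max)
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                   as.integer(contigLengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=SB,Number=4,Type=Integer,Description=\"Strand counts: ref fwd, ref rev, alt fwd, alt rev\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", strainNames(gm)), collapse = "\t"))
  gt <- genotypes(gm)
  gq <- SummarizedExperiment::assay(gm, "gq")
  dp <- SummarizedExperiment::assay(gm, "dp")
  pm <- SummarizedExperiment::assay(gm, "plMargin")
  adR <- SummarizedExperiment::assay(gm, "adRef")
  adA <- SummarizedExperiment::assay(gm, "adAlt")
  rF <- SummarizedExperiment::assay(gm, "refFwd")
  rR <- SummarizedExperiment::assay(gm, "refRev")
  aF <- SummarizedExperiment::assay(gm, "altFwd")
  aR <- SummarizedExperiment::assay(gm, "altRev")
  fmtInt <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                     scientific = FALSE))
  plField <- function(code, m) {
    out <- rep(".", length(code))
    ok <- !is.na(code) & !is.na(m)
    two <- fmtInt(2 * m)
    one <- fmtInt(m)
    out[ok & code == 0] <- paste(0, one, two, sep = ",")[ok & code == 0]
    out[ok & code == 1] <- paste(one, 0, one, sep = ",")[ok & code == 1]
    out[ok & code == 2] <- paste(two, one, 0, sep = ",")[ok & code == 2]
    out
  }
  adField <- ifelse(is.na(adR) | is.na(adA), ".",
                    paste(fmtInt(adR), fmtInt(adA), sep = ","))
  sbField <- ifelse(is.na(rF) | is.na(rR) | is.na(aF) | is.na(aR), ".",
                    paste(fmtInt(rF), fmtInt(rR), fmtInt(aF), fmtInt(aR),
                          sep = ","))
  cells <- matrix(paste(.gtCodeToString(gt), fmtInt(gq), fmtInt(dp),
                        plField(as.vector(gt), as.vector(pm)),
                        adField, sbField, sep = ":"),
                  nrow(gt), ncol(gt))
  qual <- siteQual(gm)
  body <- paste(chrom, pos, ".", refAllele(gm), altAllele(gm),
                ifelse(is.na(qual), ".", format(qual, trim = TRUE,
                                                scientific = FALSE)),
                "PASS", ".", "GT:GQ:DP:PL:AD:SB", sep = "\t")
  if (nrow(cells))
    body <- paste(body, apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED interval track
#'
#' Reads a 3+-column BED file (0-based half-open) and returns normalized
#' (sorted, merged) intervals as a `GRanges` in 1-based coordinates.
#'
#' @param bedPath Path to a BED file.
#' @param name Track name stored in `metadata(track)$name`.
#' @return A reduced [GenomicRanges::GRanges].
#' @export
readIntervalTrack <- function(bedPath, name = basename(bedPath)) {
  info <- file.info(bedPath)
  if (!is.na(info$size) && info$size == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- rtracklayer::import(bedPath, format = "BED")
    gr <- GenomicRanges::reduce(gr)
  }
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' Test points for track membership
#'
#' @param track A `GRanges` track (1-based, as returned by
#'   [readIntervalTrack]).
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Logical vector, `TRUE` where the position falls inside the track.
#' @export
pointInTrack <- function(track, chrom, pos) {
  if (length(track) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  GenomicRanges::countOverlaps(q, track, ignore.strand = TRUE) > 0
}

#' Read and query a reference genome FASTA
#'
#' `readReference()` loads a FASTA into a `DNAStringSet` keyed by the first
#' word of each header. `getBases()` fetches the 1-based inclusive
#' subsequence `start..end` and errors when the window leaves the contig.
#'
#' @param path FASTA file path.
#' @return `readReference()`: a [Biostrings::DNAStringSet].
#' @export
readReference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' @rdname readReference
#' @param ref A `DNAStringSet` reference store.
#' @param chrom Contig name.
#' @param start,end 1-based inclusive window.
#' @export
getBases <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref)) stop("unknown contig: ", chrom)
  len <- Biostrings::width(ref[chrom])
  if (any(start < 1) || any(end > len))
    stop("window ", start, "..", end, " outside contig ", chrom,
         " (length ", len, ")")
  as.character(Biostrings::subseq(ref[[chrom]], start, end))
}

#' @rdname readReference
#' @export
writeReference <- function(ref, path) {
  Biostrings::writeXStringSet(ref, path)
  invisible(path)
}

.SPV_COLS <- c("strain", "chrom", "pos", "ancestral", "derived", "zygosity",
               "folded_class", "trinucleotide_context", "cpg_flag")

#' Read and write strain-private variant tables
#'
#' Tab-delimited with columns strain, chrom, pos, ancestral, derived,
#' zygosity (`fixed`/`heterozygous`), folded_class, trinucleotide_context
#' and cpg_flag. Writing then reading restores the records exactly.
#'
#' @param spvs Data frame of SPV records.
#' @param path File path.
#' @export
writeSpvTable <- function(spvs, path) {
  stopifnot(all(.SPV_COLS %in% names(spvs)))
  write.table(spvs[, .SPV_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpvTable
#' @export
readSpvTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(strain = "character", chrom = "character",
                                  pos = "integer", ancestral = "character",
                                  derived = "character",
                                  zygosity = "character",
                                  folded_class = "character",
                                  trinucleotide_context = "character",
                                  cpg_flag = "logical"))
  df
}

#' Read a per-strain life-history trait table
#'
#' Long-format TSV with columns `strain`, `trait`, `value`; one row per
#' replicate measurement.
#'
#' @param path File path.
#' @param strains Optional character vector of strains in the genotype
#'   data; trait rows for other strains are retained with a warning.
#' @return Data frame with columns strain, trait, value.
#' @export
readTraitTable <- function(path, strains = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(strain = "character", trait = "character",
                                  value = "numeric"))
  if (!is.null(strains)) {
    extra <- setdiff(unique(df$strain), strains)
    if (length(extra))
      warning("trait table contains strain(s) absent from genotype data: ",
              paste(extra, collapse = ", "), " (retained)")
  }
  df
}

#' Read and write per-base conservation score tracks
#'
#' Plain 3-column TSV (`chrom`, `pos`, `score`) with 1-based positions and
#' scores in `[0, 1]`.
#'
#' @param path File path.
#' @return Data frame with columns chrom, pos, score.
#' @export
readScoreTrack <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(chrom = "character", pos = "integer",
                                  score = "numeric"))
  if (any(df$score < 0 | df$score > 1))
    stop("conservation scores must lie in [0, 1]")
  df
}

#' @rdname readScoreTrack
#' @param scores Data frame with columns chrom, pos, score.
#' @export
writeScoreTrack <- function(scores, path) {
  stopifnot(all(c("chrom", "pos", "score") %in% names(scores)))
  write.table(scores[, c("chrom", "pos", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up conservation scores at positions
#'
#' @param scores Score track data frame (see [readScoreTrack]).
#' @param chrom,pos Query chromosome names and 1-based positions.
#' @return Numeric vector of scores (`NA` where absent from the track).
#' @export
scoresAt <- function(scores, chrom, pos) {
  idx <- match(paste(chrom, pos), paste(scores$chrom, scores$pos))
  scores$score[idx]
}
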