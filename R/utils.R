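## Shared constants and small helpers used across the pipeline.

#' The six folded substitution classes
#'
#' Pyrimidine-rooted substitution classes obtained by mapping
#' purine-ancestral events onto their reverse complements. Used whenever the
#' mutated strand is unknown.
#'
#' @format Character vector of length 6.
#' @export
FOLDED_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The seven CpG-split substitution classes
#'
#' As [FOLDED_CLASSES] but with C>T divided into transitions at CpG
#' dinucleotides (`CpG>TpG`, hypermutable through deamination of methylated
#' cytosine) and all other C>T events (`nonCpG>T`).
#'
#' @format Character vector of length 7.
#' @export
SEVEN_CLASSES <- c("C>A", "C>G", "nonCpG>T", "CpG>TpG", "T>A", "T>C", "T>G")

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.complement <- function(base) unname(.COMPLEMENT[base])

.checkBase <- function(x, what) {
  if (!all(x %in% .BASES))
    stop(what, " must be one of A/C/G/T", call. = FALSE)
}

#' Fold a substitution into its pyrimidine-rooted class
#'
#' Events with a purine ancestral allele (A or G) are mapped onto the
#' reverse-complement strand, e.g. G>A becomes C>T and A>C becomes T>G.
#' Folding an already pyrimidine-rooted event is the identity.
#'
#' @param ancestral,derived Character vectors of single bases (A/C/G/T).
#' @return A data.frame with columns `folded_class` (one of
#'   [FOLDED_CLASSES]) and `flipped` (`TRUE` when the event was mapped to
#'   the opposite strand).
#' @examples
#' foldClass("G", "A")  # C>T, flipped
#' @export
foldClass <- function(ancestral, derived) {
  .checkBase(ancestral, "ancestral")
  .checkBase(derived, "derived")
  if (length(ancestral) != length(derived))
    stop("ancestral and derived must have equal length")
  if (any(ancestral == derived))
    stop("ancestral and derived allele must differ")
  flip <- ancestral %in% c("A", "G")
  anc <- ifelse(flip, .complement(ancestral), ancestral)
  der <- ifelse(flip, .complement(derived), derived)
  cls <- paste0(anc, ">", der)
  stopifnot(all(cls %in% FOLDED_CLASSES))
  data.frame(folded_class = cls, flipped = flip)
}

#' Flag C>T events at CpG dinucleotides
#'
#' A C>T event is a CpG transition when the base 3' of the mutated C on the
#' pyrimidine strand is G. For events recorded on the reference strand this
#' means: context `.CG` when the ancestral allele is the reference-strand C,
#' and context `C G.`-style (5' C) when the event was folded from a G>A on
#' the reference strand.
#'
#' @param context Reference-strand trinucleotide context centred on the
#'   site (character vector of 3-mers; `NA` allowed).
#' @param foldedClass Folded class per event (see [foldClass]).
#' @param flipped Whether the event was folded from the purine strand.
#' @return Logical vector; `FALSE` for non-C>T classes, `NA` when the
#'   context is unavailable.
#' @export
cpgAnnotate <- function(context, foldedClass, flipped) {
  n <- length(context)
  stopifnot(length(foldedClass) == n, length(flipped) == n)
  out <- rep(FALSE, n)
  ct <- foldedClass == "C>T"
  three <- substr(context, 3, 3)
  five <- substr(context, 1, 1)
  out[ct & !flipped] <- three[ct & !flipped] == "G"
  out[ct & flipped] <- five[ct & flipped] == "C"
  out[ct & is.na(context)] <- NA
  out
}

#' Convert between 1-based and BED coordinates
#'
#' `pos1ToBed()` maps a 1-based inclusive position to the 0-based half-open
#' BED interval covering it; `bedToPos1()` maps a BED start back to the
#' 1-based position. The two are inverse of each other.
#'
#' @param pos 1-based position(s).
#' @param start 0-based BED start(s).
#' @return `pos1ToBed()`: data.frame with `start`, `end`; `bedToPos1()`:
#'   integer vector of 1-based positions.
#' @export
pos1ToBed <- function(pos) data.frame(start = pos - 1L, end = pos)

#' @rdname pos1ToBed
#' @export
bedToPos1 <- function(start) as.integer(start + 1L)

## first differing rule name, used by the filter audit
.ruleNames <- function() {
  c("qual", "gq", "dp", "missing", "segdup", "repeat", "pl_margin",
    "wild", "ibd", "balance", "strand_bias")
}
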