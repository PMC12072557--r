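#' @import methods
#' @importFrom IRanges IRanges start end width
NULL

DNA_BASES4 <- c("A", "C", "G", "T")
DNA_ALPHABET5 <- c(DNA_BASES4, "N")

#' CodingSequence: a validated nucleotide sequence
#'
#' Container for a single nucleotide sequence over the alphabet `{A,C,G,T,N}`,
#' optionally flagged as an in-frame coding sequence (CDS).  CDS coordinates
#' used throughout the package are 1-based, position 1 being the A of the
#' initiator ATG, matching HGVS c.-notation.
#'
#' @slot id single character identifier.
#' @slot seq uppercase sequence string over `A,C,G,T,N`.
#' @slot isCds logical; when `TRUE` the length must be a positive multiple of 3.
#' @slot source free-text provenance.
#'
#' @examples
#' cs <- CodingSequence("demo", "ATGGCTAAA")
#' seqString(cs)
#' cdsLength(cs)
#' @export
setClass("CodingSequence",
  representation(id = "character", seq = "character",
                 isCds = "logical", source = "character"),
  prototype(id = NA_character_, seq = "", isCds = FALSE, source = ""))

setValidity("CodingSequence", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) != 1L)
    msg <- c(msg, "'seq' must be a single string")
  else {
    bad <- setdiff(unique(strsplit(object@seq, "")[[1L]]), DNA_ALPHABET5)
    if (length(bad))
      msg <- c(msg, sprintf("sequence of '%s' contains characters outside {A,C,G,T,N}: %s",
                            object@id, paste(bad, collapse = ",")))
  }
  if (isTRUE(object@isCds)) {
    n <- nchar(object@seq)
    if (n == 0L || n %% 3L != 0L)
      msg <- c(msg, sprintf("CDS '%s' has length %d, not a positive multiple of 3",
                            object@id, n))
  }
  if (length(msg)) msg else TRUE
})

#' @param id sequence identifier.
#' @param seq nucleotide string; lowercase accepted, `U` mapped to `T`.
#' @param isCds logical, whether the record is an in-frame CDS.
#' @param source free-text provenance string.
#' @rdname CodingSequence-class
#' @export
CodingSequence <- function(id, seq, isCds = FALSE, source = "") {
  seq <- toupper(as.character(seq))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  new("CodingSequence", id = as.character(id), seq = seq,
      isCds = isTRUE(isCds), source = as.character(source))
}

#' @describeIn CodingSequence-class sequence identifier.
#' @param x a `CodingSequence`.
#' @export
seqId <- function(x) x@id

#' @describeIn CodingSequence-class the sequence as a character string.
#' @export
seqString <- function(x) x@seq

#' @describeIn CodingSequence-class whether the record is an in-frame CDS.
#' @export
isCds <- function(x) x@isCds

#' @describeIn CodingSequence-class provenance string.
#' @export
seqSource <- function(x) x@source

#' @describeIn CodingSequence-class sequence length in nucleotides.
#' @export
cdsLength <- function(x) nchar(x@seq)

setMethod("show", "CodingSequence", function(object) {
  n <- nchar(object@seq)
  head <- if (n > 48L) paste0(substr(object@seq, 1L, 48L), "...") else object@seq
  cat(sprintf("CodingSequence '%s': %d nt%s\n  %s\n", object@id, n,
              if (object@isCds) sprintf(" (%d codons, CDS)", n %/% 3L) else "",
              head))
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

#' ExonModel: exon coordinates of a transcript on a genomic sequence
#'
#' Ordered, non-overlapping exons in 1-based inclusive genomic coordinates with
#' a strand.  Used for strand-aware CDS extraction and for mapping genomic
#' variant positions into CDS coordinates.
#'
#' @slot chrom chromosome / contig name.
#' @slot exons an [IRanges::IRanges] of exons, sorted ascending, non-overlapping.
#' @slot strand `"+"` or `"-"`.
#'
#' @examples
#' em <- ExonModel("chr10", starts = c(3, 9), ends = c(5, 11), strand = "+")
#' modelCdsLength(em)
#' @export
setClass("ExonModel",
  representation(chrom = "character", exons = "IRanges", strand = "character"))

setValidity("ExonModel", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  if (!identical(object@strand, "+") && !identical(object@strand, "-"))
    msg <- c(msg, "'strand' must be '+' or '-'")
  s <- start(object@exons); e <- end(object@exons)
  if (length(s) == 0L) msg <- c(msg, "at least one exon required")
  if (any(s < 1L)) msg <- c(msg, "exon starts must be >= 1")
  if (any(e < s)) msg <- c(msg, "exon end < start")
  if (length(s) > 1L) {
    if (is.unsorted(s, strictly = TRUE))
      msg <- c(msg, "exons must be sorted ascending by start")
    else if (any(s[-1L] <= e[-length(e)]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' @param chrom chromosome name.
#' @param starts,ends 1-based inclusive exon coordinates.
#' @param strand `"+"` or `"-"`.
#' @rdname ExonModel-class
#' @export
ExonModel <- function(chrom, starts, ends, strand = "+") {
  new("ExonModel", chrom = as.character(chrom),
      exons = IRanges::IRanges(start = as.integer(starts), end = as.integer(ends)),
      strand = strand)
}

#' @describeIn ExonModel-class exon ranges as an `IRanges`.
#' @param x an `ExonModel`.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn ExonModel-class strand of the model.
#' @export
exonStrand <- function(x) x@strand

#' @describeIn ExonModel-class chromosome name.
#' @export
exonChrom <- function(x) x@chrom

#' @describeIn ExonModel-class total exonic (CDS) length.
#' @export
modelCdsLength <- function(x) sum(width(x@exons))

setMethod("show", "ExonModel", function(object) {
  cat(sprintf("ExonModel on %s (%s strand): %d exon(s), %d nt\n",
              object@chrom, object@strand, length(object@exons),
              modelCdsLength(object)))
})

#' LocalAlignmentResult: Smith-Waterman local alignment summary
#'
#' Result of an affine-gap Smith-Waterman local alignment: optimal score,
#' 1-based inclusive spans on both sequences, identity statistics and the
#' gapped alignment strings.  Percent identity is computed over all alignment
#' columns, gap columns included.
#'
#' @slot score optimal local alignment score (>= 0).
#' @slot aSpan,bSpan integer length-2 vectors, 1-based inclusive; `NA` when the
#'   alignment is empty.
#' @slot alignedColumns,identicalColumns alignment column counts.
#' @slot percentIdentity `100 * identicalColumns / alignedColumns`.
#' @slot alignmentA,alignmentB gapped alignment strings.
#' @export
setClass("LocalAlignmentResult",
  representation(score = "numeric", aSpan = "integer", bSpan = "integer",
                 alignedColumns = "integer", identicalColumns = "integer",
                 percentIdentity = "numeric",
                 alignmentA = "character", alignmentB = "character"))

setValidity("LocalAlignmentResult", function(object) {
  msg <- character()
  if (object@score < 0) msg <- c(msg, "score must be >= 0")
  if (object@identicalColumns > object@alignedColumns)
    msg <- c(msg, "identicalColumns > alignedColumns")
  if (object@alignedColumns > 0L) {
    if (anyNA(object@aSpan) || anyNA(object@bSpan))
      msg <- c(msg, "non-empty alignment must carry spans")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn LocalAlignmentResult-class alignment score.
#' @param x a `LocalAlignmentResult`.
#' @export
alignmentScore <- function(x) x@score

#' @describeIn LocalAlignmentResult-class percent identity over all columns.
#' @export
percentIdentity <- function(x) x@percentIdentity

#' @describeIn LocalAlignmentResult-class identity in the \dQuote{n of m nt} form
#'   used in reports.
#' @export
identityLabel <- function(x) {
  sprintf("%.0f%% (%d of %d nt)", x@percentIdentity, x@identicalColumns,
          x@alignedColumns)
}

setMethod("show", "LocalAlignmentResult", function(object) {
  if (object@alignedColumns == 0L) {
    cat("LocalAlignmentResult: empty alignment (score 0)\n")
    return(invisible(NULL))
  }
  cat(sprintf("LocalAlignmentResult: score %.1f, %s\n", object@score,
              identityLabel(object)))
  cat(sprintf("  a[%d..%d] %s\n", object@aSpan[1L], object@aSpan[2L], object@alignmentA))
  cat(sprintf("  b[%d..%d] %s\n", object@bSpan[1L], object@bSpan[2L], object@alignmentB))
})

#' DamageReport: deamination-damage accounting for a substitution set
#'
#' Counts of TS1/TS2/other substitutions and the expected number of
#' degradation-driven substitutions in a target gene, scaled from a control
#' gene by length:
#' `expectedDamage = (nTs1 + nTs2) * targetLength / controlLength`.
#'
#' @slot nTotal,nTs1,nTs2,nNone substitution counts (`nTotal = nTs1+nTs2+nNone`).
#' @slot expectedDamage expected damage-substitution count in the target.
#' @slot controlLength,targetLength CDS lengths in nucleotides.
#' @export
setClass("DamageReport",
  representation(nTotal = "integer", nTs1 = "integer", nTs2 = "integer",
                 nNone = "integer", expectedDamage = "numeric",
                 controlLength = "integer", targetLength = "integer"))

setValidity("DamageReport", function(object) {
  msg <- character()
  if (object@nTotal != object@nTs1 + object@nTs2 + object@nNone)
    msg <- c(msg, "nTotal != nTs1 + nTs2 + nNone")
  if (object@controlLength <= 0L || object@targetLength <= 0L)
    msg <- c(msg, "lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn DamageReport-class total substitution count.
#' @param x a `DamageReport`.
#' @export
nSubstitutions <- function(x) x@nTotal

#' @describeIn DamageReport-class count of deamination-consistent (TS1+TS2)
#'   substitutions.
#' @export
nDamageTyped <- function(x) x@nTs1 + x@nTs2

#' @describeIn DamageReport-class expected damage count in the target gene.
#' @export
expectedDamage <- function(x) x@expectedDamage

setMethod("show", "DamageReport", function(object) {
  cat(sprintf("DamageReport: %d of %d substitutions consistent with deamination damage\n",
              object@nTs1 + object@nTs2, object@nTotal))
  cat(sprintf("  TS1 %d, TS2 %d, other %d\n", object@nTs1, object@nTs2, object@nNone))
  cat(sprintf("  expected damage in target (%d nt, control %d nt): %.2f\n",
              object@targetLength, object@controlLength, object@expectedDamage))
})
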