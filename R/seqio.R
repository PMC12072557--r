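#' Read a multi-record FASTA file into CodingSequence objects
#'
#' Sequences are uppercased and `U` is mapped to `T`.  Any IUPAC code other
#' than `A,C,G,T,N` is rejected; ambiguous archaic consensus bases are expected
#' to arrive already masked as `N`.
#'
#' @param path FASTA file.
#' @param cds logical; mark records as in-frame CDSs (length then validated as
#'   a multiple of 3).
#' @return list of [CodingSequence] objects, one per record.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acgt"), f)
#' readFasta(f)
#' @importFrom Biostrings readBStringSet
#' @export
readFasta <- function(path, cds = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ## read as raw strings: case/U normalization and alphabet checks are ours
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) return(list())
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("malformed FASTA header (empty id) in record ",
         which(!nzchar(ids))[1L], " of ", path)
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    stop("empty sequence for record '", ids[which(!nzchar(seqs))[1L]],
         "' in ", path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- tryCatch(
      CodingSequence(ids[i], seqs[i], isCds = cds, source = path),
      error = function(e) stop("record '", ids[i], "' in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  out
}

#' Write CodingSequence objects to FASTA
#'
#' Lines are wrapped at 60 columns.
#'
#' @param x a `CodingSequence` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @export
writeFasta <- function(x, path) {
  if (is(x, "CodingSequence")) x <- list(x)
  stopifnot(all(vapply(x, is, logical(1L), "CodingSequence")))
  set <- Biostrings::DNAStringSet(vapply(x, seqString, character(1L)))
  names(set) <- vapply(x, seqId, character(1L))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character strings over `{A,C,G,T,N}`; `N` is
#' self-complementary.  Applying the function twice returns the input.
#'
#' @param seq nucleotide string (vectorized over multiple strings).
#' @return reverse-complemented string(s).
#' @examples
#' revcomp("AAC")  # "GTT"
#' @export
revcomp <- function(seq) {
  seq <- as.character(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}")
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""),
         character(1L), USE.NAMES = FALSE)
}

complementBase <- function(b) chartr("ACGTN", "TGCAN", b)

#' Strand-aware CDS extraction from a genomic sequence
#'
#' Concatenates the exonic nucleotides of `model`; on the minus strand the
#' concatenation is reverse-complemented so the output reads 5'->3' on the
#' coding strand.  This is the intron/UTR trimming step that reduces a genomic
#' or mRNA region to the CDS of a chosen transcript model.
#'
#' @param genomicSeq genomic sequence as a character string or `CodingSequence`.
#' @param model an [ExonModel].
#' @param id identifier for the returned CDS.
#' @return a [CodingSequence] with `isCds = TRUE`.
#' @examples
#' extractCds("AAATGCCC", ExonModel("c", 3, 5, "+"))
#' @export
extractCds <- function(genomicSeq, model, id = "cds") {
  if (is(genomicSeq, "CodingSequence")) {
    if (missing(id)) id <- seqId(genomicSeq)
    genomicSeq <- seqString(genomicSeq)
  }
  stopifnot(is(model, "ExonModel"))
  n <- nchar(genomicSeq)
  s <- IRanges::start(exonRanges(model)); e <- IRanges::end(exonRanges(model))
  if (any(s < 1L) || any(e > n))
    stop("exon coordinates outside genomic sequence bounds (1..", n, ")")
  parts <- substring(genomicSeq, s, e)
  cds <- paste(parts, collapse = "")
  if (exonStrand(model) == "-") cds <- revcomp(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("extracted sequence length ", nchar(cds), " is not a multiple of 3 (frame error)")
  CodingSequence(id, cds, isCds = TRUE,
                 source = sprintf("extracted from %s (%s)", exonChrom(model),
                                  exonStrand(model)))
}

SUBSTITUTION_TSV_COLUMNS <- c("substitution", "transition_type",
                              "potential_cause", "consequence")

#' Read and write substitution tables as TSV
#'
#' The on-disk shape mirrors the published Denisovan substitution tables:
#' columns `substitution` (c.-notation), `transition_type` (`TS1`, `TS2`,
#' `none`), `potential_cause` and `consequence`, tab-delimited with a header
#' row.  `readSubstitutionTsv(writeSubstitutionTsv(x))` is lossless.
#'
#' @param records data.frame with exactly the four columns above.
#' @param path TSV file.
#' @return `readSubstitutionTsv`: data.frame with the four fixed columns.
#' @export
writeSubstitutionTsv <- function(records, path) {
  records <- as.data.frame(records)
  extra <- setdiff(names(records), SUBSTITUTION_TSV_COLUMNS)
  if (length(extra))
    stop("unknown column(s) in substitution table: ", paste(extra, collapse = ", "))
  miss <- setdiff(SUBSTITUTION_TSV_COLUMNS, names(records))
  for (m in miss) records[[m]] <- NA_character_
  records <- records[, SUBSTITUTION_TSV_COLUMNS, drop = FALSE]
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeSubstitutionTsv
#' @export
readSubstitutionTsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", fileEncoding = "UTF-8")
  extra <- setdiff(names(df), SUBSTITUTION_TSV_COLUMNS)
  if (length(extra))
    stop("unknown column(s) in ", path, ": ", paste(extra, collapse = ", "))
  miss <- setdiff(SUBSTITUTION_TSV_COLUMNS, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df[, SUBSTITUTION_TSV_COLUMNS, drop = FALSE]
}
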