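#' Map genomic positions to CDS coordinates and back
#'
#' CDS coordinates are 1-based along the coding strand (position 1 = A of the
#' initiator ATG).  On the minus strand the CDS runs from the last exonic
#' genomic position backwards.  The mapping is a bijection between exonic
#' genomic positions and `1..CDS length`; intronic or outside positions map to
#' `NA`.
#'
#' @param model an [ExonModel].
#' @param gpos vector of 1-based genomic positions.
#' @param cpos vector of 1-based CDS positions.
#' @return integer vector of mapped positions (`NA` where unmapped).
#' @examples
#' genomicToCdsPos(ExonModel("c", 3, 5, "+"), 3)   # 1
#' genomicToCdsPos(ExonModel("c", 4, 6, "-"), 6)   # 1
#' @export
genomicToCdsPos <- function(model, gpos) {
  stopifnot(is(model, "ExonModel"))
  s <- IRanges::start(exonRanges(model)); e <- IRanges::end(exonRanges(model))
  w <- e - s + 1L
  before <- c(0L, cumsum(w))[seq_along(w)]
  total <- sum(w)
  gpos <- as.numeric(gpos)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(s)) {
    hit <- !is.na(gpos) & gpos >= s[i] & gpos <= e[i]
    out[hit] <- before[i] + as.integer(gpos[hit] - s[i] + 1L)
  }
  if (exonStrand(model) == "-") out <- total - out + 1L
  out
}

#' @rdname genomicToCdsPos
#' @export
cdsToGenomicPos <- function(model, cpos) {
  stopifnot(is(model, "ExonModel"))
  s <- IRanges::start(exonRanges(model)); e <- IRanges::end(exonRanges(model))
  w <- e - s + 1L
  total <- sum(w)
  cpos <- as.integer(cpos)
  bad <- !is.na(cpos) & (cpos < 1L | cpos > total)
  if (any(bad)) stop("CDS position out of range 1..", total)
  plusIndex <- if (exonStrand(model) == "-") total - cpos + 1L else cpos
  before <- c(0L, cumsum(w))
  exonIdx <- findInterval(plusIndex - 1L, before, rightmost.closed = FALSE)
  as.integer(s[exonIdx] + (plusIndex - before[exonIdx] - 1L))
}

GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a table of single-nucleotide variant calls
#'
#' @param chrom,pos,ref,alt,genotype per-call fields; `genotype` one of
#'   `hom_ref`, `het`, `hom_alt`, `missing`.
#' @return data.frame with the five validated columns.
#' @export
variantCalls <- function(chrom, pos, ref, alt,
                         genotype = rep("hom_alt", length(pos))) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   genotype = as.character(genotype),
                   stringsAsFactors = FALSE)
  if (any(df$pos < 1L)) stop("variant positions must be >= 1")
  if (any(!df$ref %in% DNA_BASES4) || any(!df$alt %in% DNA_BASES4))
    stop("ref/alt must be single nucleotides over {A,C,G,T}")
  if (any(!df$genotype %in% GENOTYPE_LEVELS))
    stop("genotype must be one of ", paste(GENOTYPE_LEVELS, collapse = ", "))
  df
}

#' Read single-sample SNV calls from a VCF file
#'
#' Reads the `CHROM, POS, REF, ALT` columns and the `GT` field of the first
#' sample.  Multi-allelic records keep the first ALT allele with a warning;
#' indel records are skipped with a warning (SNVs only).  A VCF without
#' genotype columns is treated as all `hom_alt`.
#'
#' @param path VCF (v4.x) file.
#' @return data.frame as from [variantCalls()].
#' @export
readVariantCalls <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(variantCalls(character(), integer(), character(), character(),
                        character()))
  alt <- fix$ALT
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s): keeping first ALT allele")
    alt[multi] <- sub(",.*$", "", alt[multi])
  }
  snv <- nchar(fix$REF) == 1L & nchar(alt) == 1L &
    fix$REF %in% DNA_BASES4 & alt %in% DNA_BASES4
  if (any(!snv))
    warning(sum(!snv), " non-SNV record(s) skipped")
  gtRaw <- if (ncol(v@gt %||% matrix(nrow = 0, ncol = 0)) >= 2L) {
    vcfR::extract.gt(v, element = "GT")[, 1L]
  } else rep("1/1", nrow(fix))
  gt <- vapply(gtRaw, parseGtString, character(1L), USE.NAMES = FALSE)
  keep <- which(snv)
  variantCalls(fix$CHROM[keep], as.integer(fix$POS[keep]), fix$REF[keep],
               alt[keep], gt[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parseGtString <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return("missing")
  al <- strsplit(g, "[/|]")[[1L]]
  if (any(al == ".")) return("missing")
  al <- as.integer(al)
  if (all(al == 0L)) "hom_ref" else if (all(al > 0L)) "hom_alt" else "het"
}

#' Apply variant calls to a reference CDS (consensus building)
#'
#' Produces an individual's coding sequence from a reference CDS and its
#' genomic SNV calls, the per-gene equivalent of a samtools/bcftools consensus
#' step.  Variants on a minus-strand gene are complemented before application
#' so the output stays on the coding strand.  Homozygous-alternate calls are
#' always applied; heterozygous calls follow `hetPolicy`: `"ref"` (default,
#' not applied -- a conservative consensus that cannot create false derived
#' alleles), `"alt"` (applied), or `"mask"` (emit `N`).  Missing genotypes are
#' treated as homozygous reference with a warning.
#'
#' @param refCds reference [CodingSequence] (coding strand).
#' @param model the [ExonModel] placing the CDS on the genome.
#' @param calls data.frame from [variantCalls()] / [readVariantCalls()].
#' @param hetPolicy one of `"ref"`, `"alt"`, `"mask"`.
#' @param id identifier for the output sequence.
#' @return a [CodingSequence] of the same length as `refCds`.
#' @export
applyVariants <- function(refCds, model, calls,
                          hetPolicy = c("ref", "alt", "mask"),
                          id = paste0(seqId(refCds), "_consensus")) {
  hetPolicy <- match.arg(hetPolicy)
  stopifnot(is(refCds, "CodingSequence"), is(model, "ExonModel"))
  if (cdsLength(refCds) != modelCdsLength(model))
    stop("reference CDS length (", cdsLength(refCds),
         ") does not match exon model length (", modelCdsLength(model), ")")
  chars <- strsplit(seqString(refCds), "")[[1L]]
  minus <- exonStrand(model) == "-"
  if (nrow(calls)) {
    offChrom <- calls$chrom != exonChrom(model)
    if (any(offChrom)) {
      warning(sum(offChrom), " call(s) on other chromosomes ignored")
      calls <- calls[!offChrom, , drop = FALSE]
    }
  }
  if (nrow(calls)) {
    cpos <- genomicToCdsPos(model, calls$pos)
    outside <- is.na(cpos)
    if (any(outside)) {
      warning(sum(outside), " call(s) outside exons ignored (positions ",
              paste(utils::head(calls$pos[outside], 5L), collapse = ","), ")")
      calls <- calls[!outside, , drop = FALSE]
      cpos <- cpos[!outside]
    }
    for (i in seq_len(nrow(calls))) {
      codingRef <- chars[cpos[i]]
      genomicRef <- if (minus) complementBase(codingRef) else codingRef
      if (!identical(genomicRef, calls$ref[i]))
        stop("reference mismatch at genomic position ", calls$pos[i],
             ": VCF REF '", calls$ref[i], "' but reference has '", genomicRef, "'")
      codingAlt <- if (minus) complementBase(calls$alt[i]) else calls$alt[i]
      gt <- calls$genotype[i]
      if (gt == "missing") {
        warning("missing genotype at position ", calls$pos[i],
                ": treated as hom_ref")
        next
      }
      if (gt == "hom_ref") next
      if (gt == "het") {
        if (hetPolicy == "ref") next
        if (hetPolicy == "mask") { chars[cpos[i]] <- "N"; next }
      }
      chars[cpos[i]] <- codingAlt
    }
  }
  CodingSequence(id, paste(chars, collapse = ""), isCds = isCds(refCds),
                 source = sprintf("consensus of %s (%d calls, het=%s)",
                                  seqId(refCds), nrow(calls), hetPolicy))
}

#' Emit a minimal single-sample VCF from two equal-length CDSs
#'
#' Writes one homozygous-alternate SNV record per position where `sampleCds`
#' differs from `refCds`, mapped back to genomic coordinates through `model`
#' with strand handling; [applyVariants()] on the output reproduces
#' `sampleCds` exactly.  Positions where either sequence carries `N` are not
#' emitted.
#'
#' @param refCds,sampleCds equal-length [CodingSequence] objects (coding strand).
#' @param model the [ExonModel] placing the CDS on the genome.
#' @param path output VCF file.
#' @param sampleName sample column name.
#' @return `path`, invisibly.
#' @export
emitVcf <- function(refCds, sampleCds, model, path, sampleName = "SAMPLE") {
  stopifnot(is(refCds, "CodingSequence"), is(sampleCds, "CodingSequence"))
  if (cdsLength(refCds) != cdsLength(sampleCds))
    stop("reference and sample CDS lengths differ")
  if (cdsLength(refCds) != modelCdsLength(model))
    stop("CDS length does not match exon model")
  a <- strsplit(seqString(refCds), "")[[1L]]
  b <- strsplit(seqString(sampleCds), "")[[1L]]
  diffs <- which(a != b & a %in% DNA_BASES4 & b %in% DNA_BASES4)
  minus <- exonStrand(model) == "-"
  header <- c("##fileformat=VCFv4.2",
              "##source=paleogdh",
              sprintf("##contig=<ID=%s>", exonChrom(model)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleName), collapse = "\t"))
  lines <- header
  if (length(diffs)) {
    gpos <- cdsToGenomicPos(model, diffs)
    ref <- a[diffs]; alt <- b[diffs]
    if (minus) { ref <- complementBase(ref); alt <- complementBase(alt) }
    ord <- order(gpos)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t1/1",
                              exonChrom(model), gpos[ord], ref[ord], alt[ord]))
  }
  writeLines(lines, path)
  invisible(path)
}
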