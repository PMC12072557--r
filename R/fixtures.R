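#' Published Denisovan GLUD1/GLUD2 substitution lists
#'
#' The curated substitution lists reported for the Denisovan (*Denisova 3*)
#' genome: 10 GLUD1 substitutions relative to other human sequences (GLUD1 is
#' under purifying selection, so these are dominated by post-mortem damage)
#' and 13 GLUD2 substitutions relative to the reconstructed ancestral
#' sequence.  Returned in the package's standard substitution-table TSV shape
#' (`substitution`, `transition_type`, `potential_cause`, `consequence`).
#'
#' @return named list of two data.frames, `glud1` (10 rows) and `glud2`
#'   (13 rows).
#' @examples
#' denisovanSubstitutions()$glud1$substitution
#' @export
denisovanSubstitutions <- function() {
  glud1 <- data.frame(
    substitution = c("c.342T>C", "c.376G>A", "c.462T>C", "c.527T>C",
                     "c.771T>C", "c.909A>C", "c.942A>G", "c.1175A>G",
                     "c.1255G>A", "c.1479G>A"),
    transition_type = c("TS1", "TS2", "TS1", "TS1", "TS1", "none", "TS1",
                        "TS1", "TS2", "TS2"),
    potential_cause = c(rep("DNA degradation", 5L), "synonymous mutation",
                        rep("DNA degradation", 4L)),
    consequence = NA_character_,
    stringsAsFactors = FALSE)
  glud2 <- data.frame(
    substitution = c("c.94C>A", "c.103G>A", "c.123G>T", "c.232G>A",
                     "c.460A>C", "c.582C>T", "c.986C>T", "c.1072A>C",
                     "c.1184G>A", "c.1241A>G", "c.1371A>G", "c.1395C>T",
                     "c.1492T>G"),
    transition_type = c("none", "TS2", "none", "TS2", "none", "TS2", "TS2",
                        "none", "TS2", "TS1", "TS1", "TS2", "none"),
    potential_cause = ifelse(
      c("none", "TS2", "none", "TS2", "none", "TS2", "TS2", "none", "TS2",
        "TS1", "TS1", "TS2", "none") == "none", "mutation", "DNA degradation"),
    consequence = c("synonymous", "G35R", "synonymous", "A78T", "T154P",
                    "synonymous", "A329V", "I358L", "R395K", "D414G",
                    "synonymous", "synonymous", "S498A"),
    stringsAsFactors = FALSE)
  list(glud1 = glud1, glud2 = glud2)
}

#' Write the Denisovan substitution lists as TSV fixtures
#'
#' @param dir output directory.
#' @return paths of the two written files, invisibly.
#' @export
writeDenisovanFixtures <- function(dir = ".") {
  fx <- denisovanSubstitutions()
  p1 <- file.path(dir, "denisovan_glud1_substitutions.tsv")
  p2 <- file.path(dir, "denisovan_glud2_substitutions.tsv")
  writeSubstitutionTsv(fx$glud1, p1)
  writeSubstitutionTsv(fx$glud2, p2)
  invisible(c(p1, p2))
}

## codon constraints that make the synthetic CDSs consistent with every
## published c./p. pairing (ref base, codon and amino acid at each site)
GLUD2_CODONS <- c(
  "32" = "CGA", "35" = "GGA", "41" = "TCG", "76" = "CGT", "78" = "GCT",
  "154" = "ACA", "194" = "GGC", "329" = "GCC", "352" = "AGG", "358" = "ATA",
  "395" = "AGG", "414" = "GAT", "457" = "CCA", "465" = "GGC", "468" = "ATG",
  "496" = "TCC", "498" = "TCA", "509" = "GCC")
GLUD1_CODONS <- c(
  "114" = "GGT", "126" = "GAA", "154" = "ACT", "176" = "CTG", "257" = "GGT",
  "303" = "ACA", "314" = "CCA", "392" = "CAT", "419" = "GTT", "493" = "CTG")

#' Synthetic GLUD-like reference coding sequences
#'
#' Synthetic 559-codon (1677 nt, matching the equal GLUD1/GLUD2 CDS length)
#' stand-in coding sequences for offline analysis.  They are *not* the RefSeq
#' sequences: the backbone is an arbitrary repeating pattern of sense codons.
#' What they guarantee is codon-level consistency with the published variant
#' annotations -- at every site named by a published c.-notation the reference
#' base matches, and applying the variant reproduces the published amino-acid
#' consequence (e.g. c.460A>C gives T154P, c.1492T>G gives S498A, c.1402A>C
#' gives M468L, c.909A>C is synonymous at Thr303).  `"GLUD2"` represents the
#' reconstructed ancestral GLUD2 baseline.
#'
#' @param gene `"GLUD2"` or `"GLUD1"`.
#' @return a [CodingSequence] of 1677 nt.
#' @export
syntheticGludCds <- function(gene = c("GLUD2", "GLUD1")) {
  gene <- match.arg(gene)
  nCodons <- 559L
  backbone <- c("GCT", "GAA", "GGT", "CTG", "ATC", "CCT", "AAG", "TTC",
                "GAC", "CGT")
  codons <- rep_len(backbone, nCodons)
  codons[1L] <- "ATG"
  codons[nCodons] <- "TAA"
  fixed <- if (gene == "GLUD2") GLUD2_CODONS else GLUD1_CODONS
  codons[as.integer(names(fixed))] <- unname(fixed)
  CodingSequence(paste0(gene, "_synthetic"), paste(codons, collapse = ""),
                 isCds = TRUE,
                 source = "synthetic stand-in consistent with published variant annotations")
}

#' Apply a published substitution list to a reference CDS
#'
#' Parses the `substitution` column of a fixture table and applies every
#' change to `cds`, returning the altered sequence (e.g. reconstructing the
#' Denisovan GLUD2 CDS from the ancestral baseline).
#'
#' @param cds baseline [CodingSequence].
#' @param table data.frame with a `substitution` column of c.-notation
#'   strings.
#' @param id identifier for the output.
#' @return a [CodingSequence].
#' @export
applySubstitutionList <- function(cds, table, id = paste0(seqId(cds), "_alt")) {
  p <- parseCNotation(table$substitution)
  chars <- strsplit(seqString(cds), "")[[1L]]
  if (any(p$cds_pos > length(chars)))
    stop("substitution position beyond CDS length")
  mismatch <- chars[p$cds_pos] != p$ref_base
  if (any(mismatch))
    stop("reference mismatch for ", paste(table$substitution[mismatch],
                                          collapse = ", "))
  chars[p$cds_pos] <- p$alt_base
  CodingSequence(id, paste(chars, collapse = ""), isCds = isCds(cds),
                 source = sprintf("%s + %d substitutions", seqId(cds), nrow(p)))
}
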