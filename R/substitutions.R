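#' Classify a nucleotide substitution by its deamination signature
#'
#' Ancient DNA accumulates two complementary classes of post-mortem
#' transitions: TS1 (`A>G` / `T>C`), from deamination of adenine to
#' hypoxanthine, and TS2 (`C>T` / `G>A`), from deamination of (5-methyl)
#' cytosine to uracil/thymine.  The remaining eight transversions cannot be
#' produced by deamination and are returned as `NONE` (candidate true
#' mutations).  The classification is deterministic and partitions all twelve
#' ordered base pairs.
#'
#' @param refBase,altBase vectors of distinct bases in `{A,C,G,T}`.
#' @return character vector over `{"TS1","TS2","NONE"}`.
#' @examples
#' classifyTransition("T", "C")  # TS1
#' classifyTransition("G", "A")  # TS2
#' classifyTransition("A", "C")  # NONE
#' @export
classifyTransition <- function(refBase, altBase) {
  refBase <- toupper(refBase); altBase <- toupper(altBase)
  if (any(!refBase %in% DNA_BASES4) || any(!altBase %in% DNA_BASES4))
    stop("bases must be in {A,C,G,T}")
  if (any(refBase == altBase))
    stop("ref and alt bases must differ")
  pair <- paste0(refBase, altBase)
  out <- rep("NONE", length(pair))
  out[pair %in% c("AG", "TC")] <- "TS1"
  out[pair %in% c("CT", "GA")] <- "TS2"
  out
}

#' Parse and format HGVS-style c.-notation for SNVs
#'
#' @param x strings like `"c.909A>C"`.
#' @return `parseCNotation`: data.frame with `cds_pos`, `ref_base`, `alt_base`.
#' @export
parseCNotation <- function(x) {
  m <- regmatches(x, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", x))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad))
    stop("cannot parse c.-notation: ", paste(x[bad], collapse = ", "))
  data.frame(cds_pos = as.integer(vapply(m, `[`, character(1L), 2L)),
             ref_base = vapply(m, `[`, character(1L), 3L),
             alt_base = vapply(m, `[`, character(1L), 4L),
             stringsAsFactors = FALSE)
}

#' @param cdsPos,refBase,altBase substitution fields.
#' @rdname parseCNotation
#' @export
formatCNotation <- function(cdsPos, refBase, altBase) {
  sprintf("c.%d%s>%s", as.integer(cdsPos), refBase, altBase)
}

#' Enumerate substitutions between two aligned equal-length CDSs
#'
#' One record per position where both bases are in `{A,C,G,T}` and differ;
#' positions carrying `N` in either sequence are skipped and counted in the
#' `masked_sites` attribute.  No alignment is performed: a length mismatch is
#' an error.
#'
#' @param sample,baseline [CodingSequence] objects of equal length (the
#'   baseline is typically the reconstructed ancestral sequence).
#' @return data.frame with columns `cds_pos`, `ref_base`, `alt_base`,
#'   `c_notation`, `transition_type`, `potential_cause`, sorted by `cds_pos`;
#'   attributes `masked_sites`, `sample_id`, `baseline_id`.
#' @export
enumerateSubstitutions <- function(sample, baseline) {
  stopifnot(is(sample, "CodingSequence"), is(baseline, "CodingSequence"))
  if (cdsLength(sample) != cdsLength(baseline))
    stop("sequences have different lengths (", cdsLength(sample), " vs ",
         cdsLength(baseline), "); align them first")
  a <- strsplit(seqString(baseline), "")[[1L]]
  b <- strsplit(seqString(sample), "")[[1L]]
  ok <- a %in% DNA_BASES4 & b %in% DNA_BASES4
  pos <- which(ok & a != b)
  tt <- if (length(pos)) classifyTransition(a[pos], b[pos]) else character()
  out <- data.frame(cds_pos = pos,
                    ref_base = a[pos], alt_base = b[pos],
                    c_notation = if (length(pos))
                      formatCNotation(pos, a[pos], b[pos]) else character(),
                    transition_type = tt,
                    potential_cause = ifelse(tt == "NONE", "mutation",
                                             "DNA degradation"),
                    stringsAsFactors = FALSE)
  attr(out, "masked_sites") <- sum(!ok)
  attr(out, "sample_id") <- seqId(sample)
  attr(out, "baseline_id") <- seqId(baseline)
  out
}

#' Build a substitution table from printed c.-notation strings
#'
#' Convenience for analysing published substitution lists: parses the
#' c.-notation, classifies each change, and returns the same table shape as
#' [enumerateSubstitutions()].
#'
#' @param cNotation character vector like `c("c.342T>C", "c.909A>C")`.
#' @return data.frame as from [enumerateSubstitutions()].
#' @export
substitutionTable <- function(cNotation) {
  p <- parseCNotation(cNotation)
  tt <- classifyTransition(p$ref_base, p$alt_base)
  out <- data.frame(cds_pos = p$cds_pos, ref_base = p$ref_base,
                    alt_base = p$alt_base,
                    c_notation = formatCNotation(p$cds_pos, p$ref_base, p$alt_base),
                    transition_type = tt,
                    potential_cause = ifelse(tt == "NONE", "mutation",
                                             "DNA degradation"),
                    stringsAsFactors = FALSE)
  out[order(out$cds_pos), , drop = FALSE]
}

#' Protein consequence of a coding SNV
#'
#' Translates the affected codon before and after the change with the standard
#' nuclear genetic code.  The residue index is
#' `floor((cds_pos - 1) / 3) + 1`, i.e. numbering includes the initiator
#' methionine of the full-length precursor (so c.460 falls in residue 154).
#' Stop codons are rendered `*`.  A codon containing `N` yields an
#' undetermined consequence.
#'
#' @param cds the [CodingSequence] carrying the reference allele.
#' @param cdsPos 1-based CDS position of the change.
#' @param altBase alternate base.
#' @param refBase optional reference base; checked against the CDS if given.
#' @return list with `residue_index`, `ref_aa`, `alt_aa`, `synonymous`,
#'   `p_notation`, `undetermined`.
#' @examples
#' cds <- CodingSequence("demo", "ATGGCTAAA", isCds = TRUE)
#' proteinConsequence(cds, 4, "T")$p_notation  # "A2S"
#' @importFrom Biostrings GENETIC_CODE
#' @export
proteinConsequence <- function(cds, cdsPos, altBase, refBase = NULL) {
  stopifnot(is(cds, "CodingSequence"), isCds(cds))
  cdsPos <- as.integer(cdsPos)
  if (cdsPos < 1L || cdsPos > cdsLength(cds))
    stop("cds position ", cdsPos, " outside 1..", cdsLength(cds))
  have <- substr(seqString(cds), cdsPos, cdsPos)
  if (!is.null(refBase) && !identical(have, toupper(refBase)))
    stop("reference mismatch at c.", cdsPos, ": CDS has '", have,
         "' but record says '", refBase, "'")
  residue <- (cdsPos - 1L) %/% 3L + 1L
  cstart <- (residue - 1L) * 3L + 1L
  codonRef <- substr(seqString(cds), cstart, cstart + 2L)
  offset <- cdsPos - cstart + 1L
  codonAlt <- codonRef
  substr(codonAlt, offset, offset) <- toupper(altBase)
  if (grepl("N", codonRef, fixed = TRUE) || grepl("N", codonAlt, fixed = TRUE)) {
    return(list(residue_index = residue, ref_aa = NA_character_,
                alt_aa = NA_character_, synonymous = NA,
                p_notation = "undetermined", undetermined = TRUE))
  }
  refAa <- unname(Biostrings::GENETIC_CODE[codonRef])
  altAa <- unname(Biostrings::GENETIC_CODE[codonAlt])
  syn <- identical(refAa, altAa)
  list(residue_index = residue, ref_aa = refAa, alt_aa = altAa,
       synonymous = syn,
       p_notation = if (syn) "synonymous" else paste0(refAa, residue, altAa),
       undetermined = FALSE)
}

#' Annotate a substitution table with protein consequences
#'
#' @param subs substitution table ([enumerateSubstitutions()] /
#'   [substitutionTable()]).
#' @param cds the reference [CodingSequence] the positions refer to.
#' @return `subs` with added columns `residue_index`, `ref_aa`, `alt_aa`,
#'   `synonymous`, `p_notation`, `consequence`.
#' @export
annotateConsequences <- function(subs, cds) {
  n <- nrow(subs)
  res <- integer(n); ra <- aa <- pn <- character(n); syn <- logical(n)
  for (i in seq_len(n)) {
    pc <- proteinConsequence(cds, subs$cds_pos[i], subs$alt_base[i],
                             refBase = subs$ref_base[i])
    res[i] <- pc$residue_index
    ra[i] <- pc$ref_aa %||% NA_character_
    aa[i] <- pc$alt_aa %||% NA_character_
    syn[i] <- isTRUE(pc$synonymous)
    pn[i] <- pc$p_notation
  }
  subs$residue_index <- res
  subs$ref_aa <- ra
  subs$alt_aa <- aa
  subs$synonymous <- syn
  subs$p_notation <- pn
  subs$consequence <- pn
  subs
}

#' Expected deamination damage in a target gene, scaled from a control
#'
#' Counts TS1/TS2/other substitutions and extrapolates the number of
#' degradation-driven substitutions expected in a target gene of
#' `targetLength` from the TS-typed count observed in a control gene of
#' `controlLength`:
#' `expected = (nTS1 + nTS2) * targetLength / controlLength`.
#' A strongly conserved control (a purifying-selection gene such as GLUD1)
#' makes the TS-typed count an estimate of pure damage.
#'
#' @param subs substitution table with a `transition_type` column.
#' @param controlLength,targetLength CDS lengths in nucleotides.
#' @return a [DamageReport].
#' @export
damageReport <- function(subs, controlLength, targetLength = controlLength) {
  controlLength <- as.integer(controlLength)
  targetLength <- as.integer(targetLength)
  if (controlLength <= 0L || targetLength <= 0L)
    stop("lengths must be positive")
  tt <- subs$transition_type
  nTs1 <- sum(tt == "TS1"); nTs2 <- sum(tt == "TS2")
  nNone <- sum(!tt %in% c("TS1", "TS2"))
  new("DamageReport", nTotal = as.integer(nrow(subs)),
      nTs1 = as.integer(nTs1), nTs2 = as.integer(nTs2),
      nNone = as.integer(nNone),
      expectedDamage = (nTs1 + nTs2) * targetLength / controlLength,
      controlLength = controlLength, targetLength = targetLength)
}

#' Candidate true mutations after the deamination exclusion rule
#'
#' Applies the exclusion criterion literally: every transition-type (TS1/TS2)
#' substitution is attributed to DNA degradation and only transversions
#' (`transition_type == "NONE"`) are returned as mutation candidates.  The
#' rule is deliberately strict -- a genuine transition mutation is
#' indistinguishable from damage in a single genome -- so TS-typed records are
#' retained in the input table with `potential_cause = "DNA degradation"`
#' rather than deleted; strictness is a presentation choice.
#'
#' @param subs classified substitution table.
#' @return the subset of `subs` with `transition_type == "NONE"`.
#' @export
mutationCandidates <- function(subs) {
  subs[subs$transition_type == "NONE", , drop = FALSE]
}

#' Cross-sample presence/absence matrix of derived alleles
#'
#' Merges per-sample substitution tables (all relative to the same baseline)
#' into a site-by-sample presence/absence matrix and flags sites shared by all
#' samples versus subsets.  This is the table used to order mutations along a
#' lineage: a derived allele carried by every sample predates the sampled
#' splits, one carried by a subset arose later (or spread by gene flow).
#'
#' @param perSampleSubs named list of substitution tables, one per sample.
#' @return data.frame with one row per site: `c_notation`, `cds_pos`,
#'   `ref_base`, `alt_base`, `transition_type`, one logical column per sample,
#'   `n_samples`, `shared_by_all`.
#' @export
comparativeReport <- function(perSampleSubs) {
  if (!length(perSampleSubs)) stop("empty sample set")
  if (is.null(names(perSampleSubs)) || any(!nzchar(names(perSampleSubs))))
    stop("perSampleSubs must be a named list")
  baselines <- unique(unlist(lapply(perSampleSubs, attr, "baseline_id")))
  if (length(baselines) > 1L)
    stop("inconsistent baselines across samples: ",
         paste(baselines, collapse = ", "))
  all <- do.call(rbind, lapply(perSampleSubs, function(d)
    d[, c("cds_pos", "ref_base", "alt_base", "c_notation", "transition_type")]))
  sites <- unique(all)
  sites <- sites[order(sites$cds_pos, sites$alt_base), , drop = FALSE]
  rownames(sites) <- NULL
  for (nm in names(perSampleSubs))
    sites[[nm]] <- sites$c_notation %in% perSampleSubs[[nm]]$c_notation
  pres <- as.matrix(sites[, names(perSampleSubs), drop = FALSE])
  sites$n_samples <- rowSums(pres)
  sites$shared_by_all <- sites$n_samples == length(perSampleSubs)
  sites
}
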