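#' Assemble the substitution, damage and mutation-ordering report
#'
#' Merges per-sample substitution tables (all relative to the same baseline)
#' into (i) a per-sample damage summary with \dQuote{n of m} lines, (ii) the
#' cross-sample presence/absence matrix used to order mutations along the
#' lineage, and (iii) optional residue-region annotations of the missense
#' mutation candidates from a user-supplied residue-interval table (antenna,
#' NAD-domain and similar labels are free text).
#'
#' @param sampleSubs named list of classified substitution tables
#'   (one per sample, as from [enumerateSubstitutions()] or
#'   [substitutionTable()]).
#' @param controlSubs optional substitution table of a control gene used for
#'   the expected-damage extrapolation.
#' @param controlLength,targetLength CDS lengths (nt) for the damage scaling;
#'   both required when `controlSubs` is given.
#' @param regionAnnotation optional data.frame with columns `residue_start`,
#'   `residue_end`, `region`.
#' @param cds optional reference [CodingSequence]; when supplied, consequence
#'   columns are (re)computed on every sample table.
#' @param outDir optional directory; when given, TSV/JSON outputs are written
#'   there.
#' @return list with `samples` (annotated tables), `damage` (per-sample
#'   [DamageReport]s), `damageSummary` (data.frame with \dQuote{n of m}
#'   lines), `comparative` (presence/absence matrix), `mutationCandidates`,
#'   `expectedDamage` (control-scaled estimate or `NULL`).
#' @export
runReport <- function(sampleSubs, controlSubs = NULL, controlLength = NULL,
                      targetLength = NULL, regionAnnotation = NULL,
                      cds = NULL, outDir = NULL) {
  if (!length(sampleSubs)) stop("empty sample set: nothing to report")
  if (is.null(names(sampleSubs)) || any(!nzchar(names(sampleSubs))))
    stop("sampleSubs must be a named list")
  if (!is.null(cds))
    sampleSubs <- lapply(sampleSubs, annotateConsequences, cds = cds)
  lens <- vapply(sampleSubs, nrow, integer(1L))
  dmg <- lapply(sampleSubs, function(d) {
    L <- if (!is.null(targetLength)) targetLength else 1L
    damageReport(d, controlLength = L, targetLength = L)
  })
  damageSummary <- data.frame(
    sample = names(sampleSubs),
    n_substitutions = lens,
    n_damage_typed = vapply(dmg, nDamageTyped, integer(1L)),
    summary = vapply(seq_along(dmg), function(i)
      sprintf("%d of %d", nDamageTyped(dmg[[i]]), lens[i]), character(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  comparative <- comparativeReport(sampleSubs)
  cand <- lapply(sampleSubs, mutationCandidates)
  expected <- NULL
  if (!is.null(controlSubs)) {
    if (is.null(controlLength) || is.null(targetLength))
      stop("controlLength and targetLength required with controlSubs")
    expected <- damageReport(controlSubs, controlLength, targetLength)
  }
  if (!is.null(regionAnnotation)) {
    need <- c("residue_start", "residue_end", "region")
    if (!all(need %in% names(regionAnnotation)))
      stop("regionAnnotation needs columns: ", paste(need, collapse = ", "))
    annotateRegion <- function(d) {
      if (!"residue_index" %in% names(d)) return(d)
      d$region <- vapply(d$residue_index, function(r) {
        hit <- regionAnnotation$region[r >= regionAnnotation$residue_start &
                                         r <= regionAnnotation$residue_end]
        if (length(hit)) paste(hit, collapse = "; ") else NA_character_
      }, character(1L))
      d
    }
    sampleSubs <- lapply(sampleSubs, annotateRegion)
    cand <- lapply(cand, annotateRegion)
  }
  out <- list(samples = sampleSubs, damage = dmg,
              damageSummary = damageSummary, comparative = comparative,
              mutationCandidates = cand, expectedDamage = expected)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.table(damageSummary,
                       file.path(outDir, "damage_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comparative,
                       file.path(outDir, "comparative_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(sampleSubs)) {
      keep <- intersect(c("c_notation", "transition_type", "potential_cause",
                          "consequence"), names(sampleSubs[[nm]]))
      tab <- sampleSubs[[nm]][, keep, drop = FALSE]
      names(tab)[names(tab) == "c_notation"] <- "substitution"
      writeSubstitutionTsv(tab, file.path(outDir, paste0(nm, "_substitutions.tsv")))
    }
    summaryJson <- list(
      samples = names(sampleSubs),
      damage_summary = damageSummary,
      expected_damage_in_target = if (!is.null(expected))
        expectedDamage(expected) else NULL)
    jsonlite::write_json(summaryJson, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}
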