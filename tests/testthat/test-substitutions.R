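test_that("transition typing partitions all 12 ordered base pairs 2/2/8", {
  pairs <- expand.grid(ref = oracleBases, alt = oracleBases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  types <- classifyTransition(pairs$ref, pairs$alt)
  expect_equal(sum(types == "TS1"), 2L)
  expect_equal(sum(types == "TS2"), 2L)
  expect_equal(sum(types == "NONE"), 8L)
  expect_equal(classifyTransition("T", "C"), "TS1")
  expect_equal(classifyTransition("A", "G"), "TS1")
  expect_equal(classifyTransition("G", "A"), "TS2")
  expect_equal(classifyTransition("C", "T"), "TS2")
  expect_equal(classifyTransition("A", "C"), "NONE")
  expect_error(classifyTransition("A", "A"), "differ")
  expect_error(classifyTransition("A", "N"), "A,C,G,T")
})

test_that("enumerateSubstitutions diffs, masks N, and is anti-symmetric", {
  b <- CodingSequence("b", "ATG", isCds = TRUE)
  s <- CodingSequence("s", "ATA", isCds = TRUE)
  expect_equal(nrow(enumerateSubstitutions(b, b)), 0L)
  subs <- enumerateSubstitutions(s, b)
  expect_equal(subs$c_notation, "c.3G>A")
  expect_equal(subs$transition_type, "TS2")

  bn <- CodingSequence("b", "ANG", isCds = TRUE)
  sn <- CodingSequence("s", "ACG", isCds = TRUE)
  subsn <- enumerateSubstitutions(sn, bn)
  expect_equal(nrow(subsn), 0L)
  expect_equal(attr(subsn, "masked_sites"), 1L)

  expect_error(enumerateSubstitutions(
    CodingSequence("a", "ATGATG", isCds = TRUE), b), "different lengths")

  set.seed(13)
  x <- CodingSequence("x", randomSeq(300))
  y <- CodingSequence("y", local({
    v <- strsplit(seqString(x), "")[[1L]]
    i <- sample(300, 25)
    v[i] <- vapply(v[i], function(b) sample(setdiff(oracleBases, b), 1L), "")
    paste(v, collapse = "")
  }))
  fw <- enumerateSubstitutions(y, x)
  bw <- enumerateSubstitutions(x, y)
  expect_equal(fw$cds_pos, bw$cds_pos)
  expect_equal(fw$ref_base, bw$alt_base)
  expect_equal(fw$alt_base, bw$ref_base)
})

test_that("protein consequences translate codons and keep precursor numbering", {
  cds <- CodingSequence("demo", "ATGGCTAAA", isCds = TRUE)
  pc <- proteinConsequence(cds, 4, "T")
  expect_equal(pc$residue_index, 2L)
  expect_equal(pc$p_notation, "A2S")          # GCT -> TCT
  pc <- proteinConsequence(cds, 9, "G")
  expect_true(pc$synonymous)                  # AAA -> AAG
  expect_equal(pc$p_notation, "synonymous")
  expect_error(proteinConsequence(cds, 4, "T", refBase = "C"), "mismatch")
  # stop codons rendered '*'
  cds2 <- CodingSequence("x", "ATGTACAAA", isCds = TRUE)
  expect_equal(proteinConsequence(cds2, 6, "A")$p_notation, "Y2*")
  # N in codon -> undetermined
  cdsn <- CodingSequence("n", "ATGGNTAAA", isCds = TRUE)
  pcn <- proteinConsequence(cdsn, 4, "T")
  expect_true(pcn$undetermined)
  expect_equal(pcn$p_notation, "undetermined")
  # consequence is invariant to synonymous changes elsewhere in the CDS
  cds3 <- CodingSequence("demo2", "ATGGCTAAG", isCds = TRUE)  # syn change at 9
  expect_equal(proteinConsequence(cds3, 4, "T")$p_notation, "A2S")
})

test_that("residue numbering satisfies floor((pos-1)/3)+1 on published pairs", {
  pairs <- c("227" = 76, "460" = 154, "1055" = 352, "1072" = 358,
             "1402" = 468, "1492" = 498)
  for (p in names(pairs))
    expect_equal((as.integer(p) - 1L) %/% 3L + 1L, unname(pairs[p]))
  g2 <- syntheticGludCds("GLUD2")
  expect_equal(proteinConsequence(g2, 1402, "C")$residue_index, 468L)
  expect_equal(proteinConsequence(g2, 1402, "C")$p_notation, "M468L")
  expect_equal(proteinConsequence(g2, 1055, "A")$p_notation, "R352K")
  expect_equal(proteinConsequence(g2, 227, "A")$p_notation, "R76H")
})

test_that("damage report counts and length scaling follow the invariant", {
  fx <- denisovanSubstitutions()
  t1 <- substitutionTable(fx$glud1$substitution)
  dr <- damageReport(t1, 1677, 1677)
  expect_equal(nDamageTyped(dr), 9L)
  expect_equal(expectedDamage(dr), 9)
  # scaling by target/control length
  dr2 <- damageReport(t1, 1677, 3354)
  expect_equal(expectedDamage(dr2), 18)
  expect_equal(nSubstitutions(dr2), 10L)
  # empty input
  dr0 <- damageReport(t1[0, ], 100, 100)
  expect_equal(nSubstitutions(dr0), 0L)
  expect_equal(expectedDamage(dr0), 0)
  expect_error(damageReport(t1, 0, 10), "positive")
})

test_that("mutation candidates are exactly the transversion-typed records", {
  fx <- denisovanSubstitutions()
  t1 <- substitutionTable(fx$glud1$substitution)
  expect_equal(mutationCandidates(t1)$c_notation, "c.909A>C")
  t2 <- substitutionTable(fx$glud2$substitution)
  expect_setequal(mutationCandidates(t2)$c_notation,
                  c("c.94C>A", "c.123G>T", "c.460A>C", "c.1072A>C", "c.1492T>G"))
  allTs <- substitutionTable(c("c.5A>G", "c.9T>C"))
  expect_equal(nrow(mutationCandidates(allTs)), 0L)
})

test_that("comparative report flags shared-by-all vs subset sites", {
  base <- syntheticGludCds("GLUD2")
  human <- applySubstitutionList(base, data.frame(
    substitution = c("c.1402A>C", "c.1055G>A")), id = "modern_human")
  vind <- applySubstitutionList(base, data.frame(
    substitution = c("c.1402A>C", "c.1055G>A")), id = "vindija")
  chag <- applySubstitutionList(base, data.frame(
    substitution = c("c.1402A>C", "c.1055G>A")), id = "chagyrskaya")
  altai <- applySubstitutionList(base, data.frame(
    substitution = c("c.1402A>C", "c.227G>A")), id = "altai")
  deni <- applySubstitutionList(base, data.frame(
    substitution = c("c.1402A>C", "c.227G>A", "c.460A>C")), id = "denisova3")
  samples <- list(modern_human = human, vindija = vind, chagyrskaya = chag,
                  altai = altai, denisova3 = deni)
  subs <- lapply(samples, enumerateSubstitutions, baseline = base)
  rep <- comparativeReport(subs)
  row468 <- rep[rep$c_notation == "c.1402A>C", ]
  expect_true(row468$shared_by_all)          # M468L marks the whole human clade
  row352 <- rep[rep$c_notation == "c.1055G>A", ]
  expect_false(row352$shared_by_all)         # R352K only in moderns + younger
  expect_equal(row352$n_samples, 3)
  expect_equal(rep[rep$c_notation == "c.227G>A", "n_samples"], 2)

  # degenerate single-sample report equals that sample's record list
  one <- comparativeReport(subs["denisova3"])
  expect_equal(one$c_notation, subs$denisova3$c_notation)
  expect_true(all(one$shared_by_all))

  # disjoint sites -> nothing shared
  d1 <- substitutionTable("c.5A>C"); d2 <- substitutionTable("c.8G>T")
  attr(d1, "baseline_id") <- attr(d2, "baseline_id") <- "anc"
  two <- comparativeReport(list(a = d1, b = d2))
  expect_false(any(two$shared_by_all))

  # inconsistent baselines rejected
  attr(d2, "baseline_id") <- "other"
  expect_error(comparativeReport(list(a = d1, b = d2)), "baseline")
  expect_error(comparativeReport(list()), "empty")
})
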