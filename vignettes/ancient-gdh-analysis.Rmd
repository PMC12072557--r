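---
title: "Analysing coding-sequence evolution in ancient genomes with paleogdh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing coding-sequence evolution in ancient genomes with paleogdh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleogdh)
```

## The problem

High-coverage ancient human genomes (one Denisovan and three Neanderthal
individuals) make it possible to trace the recent evolution of individual
protein-coding genes.  The glutamate dehydrogenase paralogs are a natural
target: *GLUD1* is a strongly conserved housekeeping gene under purifying
selection, while *GLUD2* — an X-chromosomal retrocopy found only in apes — has
evolved under positive selection and is linked to brain metabolism.  Several
*GLUD1* pseudogenes, notably the RNA-expressed *GLUD1P3*, complete the family.

Working with ancient DNA adds a specific complication: post-mortem base
deamination creates apparent substitutions.  The package's core analytic move
is to separate candidate true mutations from damage *before* any evolutionary
interpretation, and to size the expected damage load from a conserved control
gene.

## Deamination classes and the exclusion rule

Deamination produces two complementary transition classes:

* **TS1** (`A>G` and `T>C`): adenine deaminates to hypoxanthine, read as G.
* **TS2** (`C>T` and `G>A`): (5-methyl)cytosine deaminates to uracil/thymine.

`classifyTransition()` assigns every ordered base pair to exactly one of
`TS1`, `TS2` or `NONE`; the four transitions split 2/2 between the damage
classes and all eight transversions are `NONE`.  The exclusion rule applied by
`mutationCandidates()` is deliberately strict: *every* transition-typed
substitution is attributed to damage, so only transversions survive as
mutation candidates.  A genuine transition mutation in a single genome is
indistinguishable from damage, which is why TS-typed records are kept in the
table (flagged `DNA degradation`) rather than deleted — strictness is a
presentation choice, and independent recurrence across genomes (or in an
outgroup) is the way a transition earns mutation status.

The control-gene extrapolation in `damageReport()` is a plain length scaling:

$$E[\text{damage in target}] = (n_{TS1} + n_{TS2}) \cdot
  \frac{L_\text{target}}{L_\text{control}}.$$

With the published 10-substitution GLUD1 control list (9 TS-typed) and the
equal 1677-nt CDS lengths of the two paralogs, the expectation is 9 damage
substitutions in GLUD2 — matching the 8 TS-typed records actually seen among
the 13 GLUD2 substitutions.

```{r damage}
fx <- denisovanSubstitutions()
t1 <- substitutionTable(fx$glud1$substitution)
damageReport(t1, controlLength = 1677, targetLength = 1677)
```

## Consequence calling and residue numbering

`proteinConsequence()` translates the affected codon before and after a
substitution with the standard nuclear code.  Residue numbering includes the
initiator methionine of the full-length precursor,
`residue = floor((pos - 1)/3) + 1`, which reproduces every published
c.-to-p. pairing (c.227→76, c.460→154, c.1055→352, c.1072→358, c.1402→468,
c.1492→498).  Positions carrying `N` give an explicit `undetermined` flag
rather than a silent guess.

So that analyses and tests run fully offline, the package ships
`syntheticGludCds()`: synthetic 559-codon stand-ins (labelled synthetic in id
and documentation) whose backbone is an arbitrary repeating pattern of sense
codons, but whose codons at every published variant position are chosen so
the reference base and the amino-acid consequence match the published
annotations.  They are suitable for exercising the consequence-calling code
path and for demonstrations; they are not the RefSeq sequences.

## Consensus building from variant calls

`applyVariants()` reimplements the per-gene consensus step: homozygous
alternate SNVs are applied to the reference CDS, with minus-strand genes
handled by complementing the genomic alleles onto the coding strand.
Heterozygous sites have no published rule, so the policy is explicit:
`het_policy = "ref"` by default (the conservative choice — a consensus cannot
gain a false derived allele), with `"alt"` and `"mask"` (emit `N`) available.
Missing genotypes are treated as homozygous reference with a logged warning.
`emitVcf()` is the exact inverse, and the round trip
`emitVcf() → readVariantCalls() → applyVariants()` is tested to be lossless on
both strands.

## Phylogenetics: K2P, NJ, pruning, ancestral states

The original analyses used external ML tree software with a K2P model.  The
package substitutes a desk-scale reimplementation of the same model family:

* `k2pDistance()` — the closed-form K2P distance
  $d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with pairwise deletion of
  ambiguous sites and an explicit saturation error when a logarithm argument
  is non-positive.
* `njTree()` — Saitou–Nei neighbor joining, consistent on additive matrices
  (exact topology and branch lengths), with negative branch estimates clamped
  to zero.
* `bootstrapSupport()` — standard nonparametric column resampling; replicate
  *r* is seeded `seed + r` so runs are reproducible.
* `pruningLoglik()` — Felsenstein pruning with per-site rescaling; `N` is a
  fully missing observation.
* `ancestralStates()` — marginal reconstruction: inside (subtree) and outside
  (rest-of-tree) partials are combined per node and site into a posterior
  over `{A,C,G,T}`; the report is the argmax, with exact ties broken
  alphabetically and flagged rather than silently resolved.
* `estimateKappa()` — bounded 1-D likelihood maximization (tolerance `1e-4`);
  a no-variation alignment returns the default `kappa = 2` with a warning and
  a boundary estimate (e.g. no observed transversions) is flagged.

Rate heterogeneity (the `+R2` free-rates component of the original model
choice) is deliberately out of scope; with four near-identical human
sequences and one outgroup the data carry no usable signal for it.  Rooting
is by a named outgroup (chimpanzee in the motivating analysis), with the root
placed at the midpoint of the outgroup edge.

The correctness story is oracle-based: pruning likelihoods are tested against
exhaustive enumeration over internal-state assignments, posteriors against a
brute-force Bayes computation, NJ against least-squares quartet fits and
random additive trees, and the transition matrix against an eigendecomposition
matrix exponential — plus cross-checks against `ape::dist.dna`, `ape::nj` and
`phangorn::pml`.

## miRNA sink scanning

`smithWaterman()` is an affine-gap (Gotoh) local aligner with deterministic
traceback (tie order diagonal > up > left; a zero cell terminates the
alignment).  A gap of length $L$ costs `gapOpen + L * gapExtend`; the default
scheme is `+1/-1` with `-2/-1` gaps, conventional nucleotide settings, since
the motivating analysis does not state its parameters.  Percent identity uses
*all* alignment columns (gaps included) as the denominator, matching the
"54 of 79 nt" span-style counts used in sink reports; this interpretation is
flagged in `identityLabel()` output.  `sinkScan()` aligns a miRNA against the
reverse complement of a transcript and maps the aligned window back to
forward-strand coordinates.  Published identity percentages for miR-27a/b
against the GLUD transcripts are treated as qualitative context: they cannot
be regenerated without the original scoring parameters and transcript
coordinates, so the acceptance surface here is oracle equivalence, not those
percentages.

## Expression correlation

`spearmanCor()` computes rho on mid-ranks with a two-sided p-value — exact by
full permutation enumeration for `n < 10` (valid under ties), t-approximate
for `n >= 10`.  `correlationScreen()` reports every unordered gene pair with
raw and Benjamini–Hochberg-adjusted p-values (both shown, neither hidden,
since a handful of pairwise tests is the typical use) and flags
`significant` (`p < 0.05`) and `trend` (`0.05 <= p < 0.1`) with configurable
thresholds.  Correlations are computed across tissue-level means
(`aggregateByTissue()`, one point per tissue, cultured-cell pseudo-tissues
excluded by label) because the motivating analysis correlates tissues, not
samples; a per-sample mode is available by passing the sample-level matrix
directly.

## The synthetic-data module

Every pipeline input can be generated with known ground truth:

* `simulateRootCds()` — a random in-frame CDS (start, no internal stops,
  terminal stop); 559 codons mirrors the GDH precursor scale.
* `evolveOnTree()` — site-independent K2P evolution along a rooted tree,
  retaining true internal sequences for reconstruction scoring.
* `applyDamage()` — post-evolution, per-site Bernoulli damage: `A/T` sites
  flip with `ts1Rate`, `C/G` sites with `ts2Rate`, applied to terminal
  sequences only (post-mortem origin).  Default study-scale rates used in the
  examples are a few per mille, chosen so a 1.7-kb gene receives a handful of
  damage events, matching the observed ~9 per control gene.
* `emitVcf()` / `simulateMirnaTarget()` / `simulateExpression()` — inputs for
  the consensus, sink-scan and correlation modules; the expression generator
  uses a Gaussian copula with Pearson latent correlation `2 sin(pi*rho/6)` so
  its *Spearman* correlation matches the target.

What the generator emulates — and what it does not.  Simulated data have
site-independent substitutions, uniform base composition, no rate
heterogeneity, no sequencing error, no coverage structure, and damage that is
independent of fragment ends.  Real ancient-DNA damage is concentrated at
read termini and real genes have codon structure and GC bias.  Green tests
therefore demonstrate algorithmic correctness under the stated model, not
robustness to every property of real archaic data.

## Numerical choices and problem sizes

* Pruning partials are rescaled per site at every internal node; posteriors
  are normalized per site, so scale factors cancel exactly.
* Posterior ties use an absolute tolerance of `1e-12`; NJ symmetry is checked
  to `1e-8`; kappa search tolerance is `1e-4` on the interval `[0.05, 100]`.
* The test-suite simulation sizes are the package's own choices for a
  laptop-scale run: 10-kb alignments for parameter- and state-recovery
  checks, 500 fuzz cases for the alignment oracle, 2000 replicates for the
  type-I-error check, and a 5-leaf archaic-like tree with branch lengths at
  the few-percent scale of closely related hominin genomes.

## Known limitations

* SNVs only: indels, multi-nucleotide variants and splice effects are out of
  scope; multi-allelic VCF records keep their first alternate allele with a
  warning.
* No multiple-sequence alignment: all sequence comparisons consume
  pre-aligned, equal-length CDSs.
* No ML topology search: the NJ topology stands in for it at desk scale.
* Clinical-database annotation and 3-D structural analysis are out of scope;
  a user-supplied residue-interval table (see
  `system.file("extdata", "gdh2_regions.tsv", package = "paleogdh")`) stands
  in for structural region labels.
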