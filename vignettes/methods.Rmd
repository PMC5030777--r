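---
title: "Methods: small RNA and degradome analysis in srnapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA and degradome analysis in srnapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

srnapipe reimplements, as a tested and reusable pipeline, the complete
post-sequencing computation of a plant small-RNA + degradome study design:
two genotypes (a late-ripening sweet orange mutant, "MT", and its wild type,
"WT"), two biological replicate sRNA libraries per genotype, and one pooled
degradome (PARE) library. This vignette is the package's own account of the
models and procedures, the tunable parameters, the synthetic data they are
exercised on, and the numerical choices made where the design was open.

## Tag annotation

The atom of computation is the *tag*: a unique read sequence with one raw
count per library (`tag_table()`). After an inclusive 18–28 nt length filter
(`length_filter()`), each tag is assigned exactly one category by a strict
priority rule:

> rRNAetc (GenBank before Rfam) > known miRNA > repeat > exon > intron,

with everything else falling through to `unann`. Two kinds of evidence feed
the rule, and they are deliberately different:

* **Sequence-database classes** (`rRNAetc`, `miRNA`) are assigned by exact
  substring match of the tag (after mapping U to T) against the user-supplied
  structural-RNA or miRNA database. No genome hit is required: a tag can be an
  rRNA fragment even if the toy genome lacks the rDNA locus.
* **Interval classes** (`repeat`, `exon`, `intron`) require at least one
  exact genome hit (both strands are searched via Biostrings dictionaries)
  overlapping a supplied interval by ≥ 1 nt on either strand. Multi-hit tags
  take the best class over all hits.

The summary table mirrors classic sequencing bookkeeping: per library,
unique and total read counts and percentages for clean reads,
genome-matching reads, and every category; category totals partition the
clean reads exactly, which the tests assert.

Coordinates are 1-based inclusive throughout, the IRanges convention shared
by every Bioconductor dependency used here; all user-facing reports are
likewise 1-based.

## Known miRNA identification

Four steps, mirroring standard conservation-based identification:

1. **Family alignment** (`align_to_mirbase()`): tags are aligned to
   mature-and-precursor databases allowing at most 2 substitutions and at
   most 3 gapped positions, budgeted separately. Alignment uses
   `pairwiseAlignment` (pattern-global, subject-local) with unit costs.
2. **Representatives** (`build_family_representatives()`): per family, the
   assigned tag with the highest summed raw count becomes the temporary
   representative; ties break to the lexicographically smaller sequence.
3. **Quantification** (`quantify_known()`): expression per representative is
   the sum of counts of tags within 2 *ungapped* mismatches (equal-length
   Hamming distance; the gapped budget applies only to family assignment —
   the two steps are distinct operations with distinct contracts). A tag
   contributes to at most one representative: its best match, ties toward
   the higher-expressed representative. Mass is conserved.
4. **Precursor validation**: identified miRNAs must fold into a hairpin
   (below); failures are pseudo-miRNAs.

A miRNA is reported for a genotype only when identified in both of its
replicate libraries (`merge_replicates()`).

## Hairpin folding, the miRNA* and novel prediction

Folding is a deterministic minimum-free-energy contract (`fold_hairpin()`),
delegated to ViennaRNA's `RNAfold`; the structure string, MFE (kcal/mol) and
a pair table are retained. The *hairpin test* requires a single stem-loop
over the mature/star span: considering only base pairs with both ends inside
that region, the bracket sequence must contain no ")(" transition, so no
multiloop separates the mature from its star. Pairs reaching outside the
span belong to the enclosing stem and are ignored — candidate windows carry
random flanking sequence whose local structure is irrelevant.

The miRNA* follows from duplex geometry: in a canonical duplex both 3' ends
protrude by exactly 2 nt, so with mature `[a, b]` and folded pairing `p()`,
the implied star is `[p(b−2), p(a)+2]` (`check_star_overhang()`). The check
*fails* (as opposed to erroring) when the mature overlaps the terminal loop,
when its duplex ends are unpaired, or when a supplied candidate star — e.g.
a blunt-ended duplex — disagrees with the implied interval. The tolerance on
the implied duplex length tracks the bulge ceiling so the star and bulge
criteria stay independent.

Novel miRNAs (`predict_novel()`) are sought among unannotated
genome-matching tags, intron tags, and tags hitting exons antisense.
Clustered hits nominate the most abundant tag as the mature; windows of
roughly 90 and 130 nt with 20 nt of slack on either side are extracted on
the tag's strand, in both arm placements, and folded. Acceptance requires
*all* of: the local hairpin test; an implied star whose sequence is observed
in the tag data (novel miRNAs must have a star; known ones need not); no
duplex internal loop or bulge above 5 nt (the literature's criterion names
no number; 5 nt is the configurable default); MFE ≤ −18 kcal/mol
(inclusive); and summed mature count ≥ 5 (inclusive). Because a hairpin is
an inverted repeat, the same locus surfaces on both strands and via its star
arm; overlapping accepted loci are collapsed keeping the highest-expressed
mature. The tests toggle each criterion individually — count 5→4, MFE past
−18 (by mismatch-weakening a stem, binary-searched against the folder),
overhang 2→0 (blunt star), bulge 5→8 — and assert each flip rejects the
locus on exactly that criterion.

## Differential expression

Raw counts are normalized to RPM (count / library total × 10⁶), exact zeros
are then imputed to 0.01 (only exact zeros; 0.005 stays 0.005), and the fold
change is M = log2(MT/WT), reported rounded to two decimals *half away from
zero* (full precision is kept internally).

Significance uses an empirical noise-distribution model: every within-group
pair of libraries contributes, per miRNA, one noise point
(Mₙ = log2 ratio, Dₙ = absolute difference); both groups contribute
(with 2+2 libraries and G miRNAs that is 2G points). A miRNA's
between-group point (M_A over group means, D_A) earns

> prob = fraction of noise points with |Mₙ| < |M_A| **and** Dₙ < D_A,

strictly-less on both axes (tie handling is unstated in the describing
literature; strict-less is the conservative choice). The call is
significant ⇔ |M_A| ≥ 1.0 (inclusive) and prob > 0.8 (strict). The widely
used NOISeq package adds resampling and smoothing on top of this empirical
counting model; this module deliberately implements only the counting model
itself. Zeros are imputed per library *before* averaging (the alternative —
average first — is unstated in the sources this design follows).

Calibration on the package's own null simulator (200 loci, log-normal means
with meanlog = log 50 and sdlog = 1.5, Poisson replicates, 20 seeds) yields
far fewer than 10% significant calls, and injected 8× fold changes on
high-abundance loci (base mean ≥ 50) are recovered with recall ≥ 0.9; both
are asserted by the acceptance tests at exactly those problem sizes.

## Degradome target calling

Degradome tags are pre-processed with the removal priority Rfam > GenBank >
polyN, where polyN means any single base strictly above 70% of the tag
(14/20 = 70% is kept; 15/20 is removed).

Complementarity scoring (`score_alignment()`) follows the Allen-style
rule set: aligning the miRNA 5'→3' against the target window antiparallel,
each mismatch costs 1.0, each G:U wobble 0.5, each gapped position 1.0, and
penalties at miRNA positions 2–13 are doubled. The implementation is a small
minimal-cost dynamic program so that gapped windows score consistently;
equal-length inputs reduce to the ungapped column-wise sum, which a
brute-force position-wise scorer confirms across all single-mismatch
variants. Perfect complementarity scores 0. The published threshold is the
only number the sources state: a pair is a target when the score is ≤ 4.5
(inclusive); whether the 2× core weighting applies before or after that
threshold cannot be pinned down, so the weights and core region are
configurable.

The cleavage site is the transcript position pairing miRNA position 10 (the
5'-most nucleotide of the downstream fragment), 1-based. Each supported site
is classified:

* category 4 — the site carries a single raw read (checked first, so the
  wording "the only raw reads at the cleavage site" is deterministic);
* category 0 — unique transcript-wide maximum;
* category 1 — shared maximum;
* category 2 — above the median; category 3 — at or below it.

The median is taken over positions with ≥ 1 read, not over all transcript
positions: otherwise a long, sparsely covered transcript would force nearly
every site into category 2. A brute-force classifier (explicit max scan and
sorted-vector median) agrees on 1000 random profiles in the acceptance test.
Per-target p-values are emitted as NA: the statistic used for that column in
the tool this emulates is unpublished, and inventing one here would be
misleading.

## PHAS locus detection

Only exactly 21-nt genome-matched tags enter. Antisense tag starts are
shifted +2 nt onto the sense register (duplex overhang geometry — the
sources are silent; 2 nt is the standard choice). Windows of
phase × cycles = 21 × 11 = 231 nt are anchored at each observed start; a
window with n distinct (strand, position) starts of which k ≥ 3 are
in-register is scored with the hypergeometric tail

P(X ≥ k), population 2 × 21 × 11 = 462 start positions, 2 × 11 = 22 of them
in-register, n draws —

and reported when P ≤ 10⁻⁴. Overlapping significant windows merge keeping
the minimum-p window's coordinates. Distinct start positions, not read
counts, enter the statistic (abundance weighting would let one
hyper-expressed tag fake phasing). The detector's p-value equals an
independent enumeration over binomial coefficients to < 10⁻¹² for n ≤ 12,
and uniformly random windows are significant at rate ≤ 10⁻³ over 10 000
simulations — both asserted.

Trigger linking: a locus gains a (miRNA, cleavage position) trigger when an
accepted degradome target alignment, lifted to genome coordinates through
the transcript map, cleaves within the locus window extended by one phase on
each side; multiple triggers are all kept, sorted by alignment score.

## The synthetic data: what it emulates, and what it does not

`simulate_study()` builds a 50 kb toy genome with planted hairpin loci
(perfect inverted repeats with up to two optional 1-nt bulges, mature on
either arm, star placed by the 2-nt-overhang geometry), sRNA libraries
(per-locus log-normal means, many low and few high, matching the heavy
tails of real miRNA abundance distributions; Poisson replicate noise —
the simplest model consistent with count data; the significance model is
tested *against* this generator, not derived from it), star tags at ~15% of
mature abundance, and random background tags carrying most of the library
mass. That last point is deliberate: in real sRNA libraries annotated
miRNAs are a few percent of clean reads, and the RPM denominator is
dominated by stable background. Without that, a strong injected fold change
on one locus would shift every other locus's RPM — a composition artifact
the demo analysis in `analysis/04_diffexp.R` would otherwise exhibit.

Degradome profiles are generated per requested category (a parameterization
exists for each of 0–4), and phased loci place n_phased tags on the 21-nt
register (antisense at register − 2) with off-register decoys.

What the generator does *not* emulate: sequencing errors and quality
scores, adapter remnants (inputs are assumed clean reads — trimming is out
of scope by design), isomiR heterogeneity, multi-locus miRNA families
sharing a mature, RNA secondary-structure effects on ligation bias, and
genome-scale repeat content. Passing tests therefore demonstrate the
*computational* contracts — priority rules, criteria, statistics, boundary
semantics — not performance on real libraries.

Every generator is a pure function of (config, seed): identical
configuration reproduces byte-identical output, and `run_all()` writes
byte-identical TSVs on re-runs, which the test suite asserts.

## Worked reference values

The package bundles the published per-miRNA RPM table of the MT/WT
comparison (19 miRNAs with probabilities and printed fold changes;
`reference_expression_table()`). Recomputing M through the pipeline
reproduces the printed value exactly for the 14 rows that are arithmetically
consistent with their own RPM pair; the other 5 differ by exactly one unit
in the second decimal, i.e. printed rounding noise in the source table —
the bundled table flags which rows are which. The boundary semantics are
exercised by two real rows: one at M = 1.15 / prob 0.99 (significant) and
one at M = 0.48 / prob 1.00 (not significant despite prob 1.00).

## Problem sizes and runtime

The shipped analysis and tests run at desk scale: 50 kb genome, 8 miRNA
loci, 3 PHAS loci, ~10⁴ reads per library; the DE calibration uses 200 loci
× 20 seeds, the classifier oracle 1000 profiles, and the phasing null 10⁴
windows. These sizes were chosen so that any laptop reproduces the full
suite in well under a minute per stage while every statistic still has
enough resolution to separate pass from fail. Scaling the config up is a
matter of `sim_config()` arguments.

## Known limitations

* Folding quality is inherited from the MFE model; suboptimal structures
  and temperature are not explored.
* `quantify_known()` requires equal-length tags for the ungapped mismatch
  rule; length isomiRs do not aggregate into the representative.
* Interval-class annotation ignores strand (overlap on either strand
  counts), as the strandedness of repeat/exon matching is unstated in the
  design this follows.
* The phasing population/success definitions follow one published variant
  of the statistic and are validated against this package's own
  enumeration oracle, not against external tools.
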