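---
title: "Models and methods behind denovoherd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind denovoherd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovoherd)
```

`denovoherd` packages four analyses that together describe the life
cycle of a deleterious mutation in an intensively selected livestock
population: its discovery in a single genome, the mapping of the causal
locus and of modifier loci from phased half-sib panels, the localisation
of recessive defects by homozygosity mapping once carrier descendants
are mated together, and the forecasting of affected births from pedigree
founder contributions. This vignette explains each model, the parameters
that matter, what the synthetic-data generators emulate, and the
numerical choices made where the design was open.

## 1. The de novo discovery screen

**Model.** A dominant congenital defect appearing in the offspring of
healthy parents is assumed to be caused by a heterozygous de novo
mutation that damages a protein. The screen is a cascade of filters on a
single genome's variant calls:

1. *Quality*: `QUAL >= 30` and `MQ >= 30`, boundaries inclusive. A
   relaxed mode (`QUAL >= 15`) exists for low-coverage genomes, where
   the standard threshold would discard true heterozygous calls.
2. *Heterozygous and private*: genotype `het`, and the
   (`chrom`, `pos`, `ref`, `alt`) key absent from a control panel of
   (by default) 1230 genomes. Panel membership is site-level presence:
   a variant seen in any control genome, at any genotype, disqualifies
   the candidate. With enough control genomes this step removes several
   orders of magnitude of segregating variation.
3. *Strand support*: calls supported by exactly one read on each strand
   are removed — the signature of a single sequencing error read twice
   on a fragment shorter than twice the read length. Records with
   unknown strand counts pass; the filter degrades gracefully when the
   caller did not export per-strand depths.
4. *Consequence*: frameshifts, in-frame insertions/deletions, stop
   gain/loss, splice donor/acceptor variants, and missense calls whose
   annotation flags them deleterious. The annotation is consumed from a
   table (a VEP-style export), never computed.
5. *Trio subtraction* (when parents are sequenced): candidates carried
   by either parent are inherited, not de novo.
6. *Density rule* (when screening healthy AI sires prospectively): a
   private deleterious variant is only classified a likely recent
   mutation if at most 10 private variants (itself included) fall
   within ±2.5 Mb. A private variant on a *rare ancestral haplotype* —
   one carried by a single animal in the dataset — sits among a cluster
   of co-located private variants; a genuinely recent mutation sits on
   a haplotype that is common in its unmutated form, so its
   neighbourhood is clean.

**Variant identity.** Panel and trio subtraction match on exact
(`chrom`, `pos`, `ref`, `alt`) after multiallelic decomposition and a
canonical trim (shared suffix, then shared prefix, position adjusted).
Without the trim, the same indel written with different padding would
silently escape subtraction.

**Choices.** The ±2.5 Mb boundary is inclusive and the candidate counts
itself (so an isolated candidate has density 1, and the rule reads
"at most 10"). The cascade is restricted to autosomes by default.
`fisher`-style per-stage bookkeeping is kept in a filter trail so the
cascade's effect is auditable; `filter_trail()` exposes it and the
non-increasing property is tested.

## 2. Sliding-window haplotype mapping

**Windows.** Haplotypes are allele strings over windows of 10
consecutive markers (~500 kb on a 50k array), sliding one marker at a
time. The one-marker step is what makes "seven consecutive significant
windows" span a 16-marker haplotype.

**Dominant (causal) mapping.** Pedigree information designates, for
each case, the haplotype assumed to carry the mutation (in a paternal
half-sib design, the paternal one), and for each control the wild-type
counterpart. A window qualifies when a single allele is carried by 100%
of case haplotypes and at most `max_control_freq` (default 0.05) of
control haplotypes; maximal runs of qualifying windows are merged into
candidate intervals. The control-frequency cut-off is exposed because
"absent or at low frequency" is a judgement call; 5% tolerates a few
recombinant or ancestral-haplotype controls without losing the
interval.

**Modifier mapping.** Mildly affected carriers are compared with
unaffected half-sibs. For every window haplotype with at least
`min_carriers` (default 3) total carriers, a two-sided Fisher exact
test is computed on the 2×2 carrier table (carrier coding — at least
one copy — matching how carrier fractions are reported; allele-dosage
coding is available behind a flag). The per-window statistic is the
minimum Fisher p across that window's alleles; the minimum-carrier
filter keeps singleton haplotypes from flooding the test list. On the
chromosome carrying the causal mutation itself, every case shares the
sire's mutant haplotype and every control its wild-type one, so any
paternal window there separates the groups perfectly; restricting that
chromosome to maternal haplotypes (`maternal_only_chroms`) removes this
artefact — the same reasoning the field applies.

**Fisher p implementation.** `fisher_window_test()` sums hypergeometric
point probabilities not exceeding the observed table's probability
(relative tie tolerance `1 + 1e-7`, as in `stats::fisher.test`). The
implementation precomputes, per pair of group sizes, the full
`(n_case+1) × (n_control+1)` lookup table and memoises it: a
permutation sweep indexes it millions of times, which a per-table call
to `stats::fisher.test` could not sustain. The tests verify agreement
with `stats::fisher.test` and with an independent from-scratch
enumeration over all tables with margins ≤ 30, to 1e-12.

**Empirical p-values.** Case/control labels are permuted uniformly at
random preserving group sizes (a flag permutes within user-supplied
strata instead, preserving family structure; free permutation is the
default since the exchangeability unit in a single half-sib family is
the individual). For each permutation the minimum Fisher p within the
scope — chromosome or genome — is recorded, and the empirical p of an
observed window is `(1 + #[minima <= observed]) / (n_perm + 1)`: the
add-one estimator never reports zero, and ties count against the
observed value (conservative). The max-statistic construction gives
family-wise calibration: on null panels the best window's empirical p
is uniform, which the acceptance suite checks by a Kolmogorov–Smirnov
test over 200 replicate panels at `n_perm = 200` (scaled down from the
10,000 used for a real scan so 200 replicates fit in minutes; the
estimator is the same at any `n_perm`).

**Ancestral-carrier search.** Verifying that a mutation is de novo
includes showing that its surrounding haplotype exists elsewhere in the
population *without* the mutation. `ancestral_carrier_search()` matches
a target allele string over a marker span against every haplotype in a
panel, measures how far each match extends identically around the span
(against a supplied reference haplotype), and partitions matches by
known mutation carrier status: matches without the mutation are
ancestral carriers.

## 3. Homozygosity mapping

`detect_roh()` reports maximal stretches of consecutive markers at
which an individual's two haplotypes agree, tolerating up to
`max_het_markers` (default 1) mismatches per run as a genotyping-error
allowance, trimmed to homozygous endpoints, and at least `min_markers`
(default 20) long. Defaults are deliberately conservative for a ~50 kb
marker spacing (20 markers ≈ 1 Mb); both are parameters because the
right values depend on array density and genotyping error. Maximal
runs can overlap when a tolerated mismatch can be bridged on either
side; consumers treat per-marker coverage, not run identity, as the
signal. `shared_ibd_segment()` intersects coverage across all affected
individuals (a `min_fraction` flag relaxes "all"); with
`require_same_allele` the homozygous allele strings must also agree,
turning "everyone autozygous here" into "everyone autozygous for the
same founder haplotype" — the IBD segment that localises a recessive
mutation. The implementation is a per-marker intersection and is tested
against an independent per-marker oracle.

## 4. Founder contributions and risk forecasting

The genetic contribution of a founder to individual *i* is
`c(i) = (c(sire) + c(dam)) / 2` with `c(founder) = 1` and unknown
parents contributing 0 — for a mutation that arose de novo in the
founder, `c(i)` is the probability that *i* carries the mutant allele
under single-path descent. A calf's risk of being a homozygous mutant
is scored `c_sire · c_dam / 4`, and the expected number of affected
calves born in a year is the sum of risks over that cohort. The formula
is implemented exactly as stated even though it is approximate when an
individual descends from the founder through multiple paths (it treats
the parents' carrier events as independent and ignores the possibility
of inheriting the mutation through both); `gene_drop()` provides the
exact Monte-Carlo counterpart, and rather than resolving the
discrepancy analytically the package quantifies it — the tests require
agreement within three binomial standard errors on low-inbreeding
pedigrees. Inbreeding coefficients use the standard recursive kinship
("tabular") method: `F(i) = kinship(sire, dam)`,
`kinship(x, x) = (1 + F(x))/2`, recursing on the topologically later
argument.

## 5. What the generators emulate

Every input the pipeline consumes can be generated with planted ground
truth; identical seeds give byte-identical outputs.

**`simulate_denovo_genome()`** emulates a proband genome over 2
chromosomes of 20 Mb: background variants drawn from a 1230-genome
control panel, Poisson-distributed private inherited variants (mean
30), one planted heterozygous de novo frameshift in a region kept free
of other private variants (so its density is 1 by construction), an
optional rare-ancestral-haplotype confound — a cluster of 25 co-located
private variants, one deleterious, within the ±2.5 Mb window — and a
fixed set of decoys that each exercise one filter (low QUAL, one read
per strand, panel-shared, homozygous, tolerated missense). Parents
carry every inherited variant and never the planted one.

**`simulate_halfsib_panel()`** emulates the modifier-mapping design: 49
mildly affected and 89 unaffected offspring of one sire, 3 chromosomes
× 120 markers at 50 kb spacing, maternal haplotypes drawn from a pool
of 16 founder haplotypes per chromosome, single uniform crossover per
meiosis. The sire's mutant haplotype carries a 40-marker causal segment
on chromosome 2; a 16-marker modifier segment on chromosome 3 is
planted maternally in exactly 12 cases and 2 controls — the ten-fold
carrier enrichment of the study design. Planted segments carry derived
alleles absent from the founder pool at every fifth marker, so no pool
haplotype can match them over any 10-marker window: they are unique to
the mutant lineage, as a haplotype radiating from one sire is. The
genome size (333 windows) was fixed by a prospective power argument:
with 49 vs 89 carriers at 12/2, the planted window's Fisher p
(7.3e-5) exceeds the discrete null tail mass of the few thousand
competing window-alleles, so genome-wide recovery is expected —
mirroring, at desk scale, the chromosome-wide significance a full
genome scan attains. Case paternal meioses avoid crossovers inside the
causal span, so every case carries the full segment (the design's
premise, not a result).

**`simulate_founder_pedigree()`** emulates the recessive-defect design:
a founder heterozygous for a mutation, generations of matings that are
consanguineous with probability 0.5, whole-haplotype gene dropping over
2 chromosomes × 400 markers (dense enough that the 20-marker ROH
minimum is a small fraction of the chromosome, as on a genome-wide
array), and appended carrier × carrier half-sib matings until the
requested 7 affected exist — emulating field ascertainment, where cases
are collected as they appear. Gametes transmitting the mutant allele
keep an intact founder-haplotype context of 30 markers either side of
the locus (crossovers there are resampled): affected individuals are
autozygous *around* the mutation, which is the generator's contract,
not an accident of the recombination model.

**What passing tests do and do not show.** The generators produce
idealised data: perfect phasing, no genotyping error outside the ROH
tolerance, uniform recombination, a single founder-haplotype pool, and
planted segments that are exactly recoverable. Green tests therefore
demonstrate that the algorithms are correct on data satisfying their
assumptions — not that real array data will behave as cleanly, where
phasing errors, map gaps and LD structure all blur windows.

## 6. Problem sizes and runtime

The test and acceptance suites run the statistical properties at fixed
desk-scale sizes chosen so the whole suite completes in minutes: 100
seeded genomes for the de novo precision/recall and confound-rejection
checks, 200 null panels × 200 permutations for calibration, 100 panels
for modifier recovery, 50 pedigrees for shared-IBD recovery, 100,000
gene drops for the 1/16 risk check. The permutation engine blocks
permutations (default 2000 at a time) through one BLAS multiply per
chromosome and a memoised Fisher lookup, so a full 10,000-permutation
scan of a default panel takes seconds.

## 7. Known limitations

- The VCF reader handles the fields this pipeline uses (GT, ADF/ADR,
  INFO MQ and DP4); it is not a general-purpose VCF toolkit.
- `dominant_scan()` requires the disease-associated haplotype of each
  case to be designated in advance; it does not infer phase-of-origin
  from the pedigree.
- The risk formula's multiple-path approximation is quantified by
  simulation, not corrected.
- Recombination in the generators is a single uniform crossover per
  chromosome per meiosis — no interference, no map heterogeneity.
- The control panel is a presence/absence index; allele frequencies in
  controls are not modelled.
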