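# denovoherd

Dominant genetic defects keep appearing in intensively selected livestock
populations even though affected animals never reproduce: de novo
mutations in the germline of elite artificial-insemination (AI) sires are
broadcast to thousands of offspring before anyone can notice. `denovoherd`
implements, as a tested R pipeline, the computational workflow used to
study this phenomenon in cattle:

1. **De novo discovery** (`screen_genome()`): filter one genome's variant
   calls down to candidate dominant de novo deleterious mutations —
   quality (QUAL ≥ 30, MQ ≥ 30, with a relaxed QUAL ≥ 15 mode for
   low-coverage genomes), heterozygosity, absence from a panel of control
   genomes, removal of calls supported by a single read per strand,
   retention of deleterious consequence classes, optional trio
   subtraction, and — when screening healthy AI sires prospectively — a
   density rule that rejects candidates with more than 10 private
   variants within ±2.5 Mb (the signature of a rare ancestral haplotype
   rather than a recent mutation).
2. **Haplotype mapping** (`dominant_scan()`, `modifier_scan()`,
   `permutation_empirical_p()`, `ancestral_carrier_search()`): sliding
   windows of 10 consecutive SNP-array markers (~500 kb) over phased
   half-sib panels; a causal locus is mapped as the haplotype shared by
   all case haplotypes and rare among controls, and modifier loci are
   mapped by a two-sided Fisher exact test on carrier counts per window
   haplotype, with chromosome-wide and genome-wide empirical p-values
   from label permutations (min-p/max-statistic null).
3. **Homozygosity mapping** (`detect_roh()`, `shared_ibd_segment()`):
   runs of homozygosity per affected individual and their intersection
   across all cases localise a recessive defect to the unique shared
   autozygous segment.
4. **Risk forecasting** (`founder_contribution()`, `mating_risk()`,
   `expected_affected()`, `gene_drop()`, `inbreeding_coefficient()`):
   founder genetic contributions `c(i) = (c(sire) + c(dam))/2`, per-calf
   homozygosity risk `c_sire · c_dam / 4`, yearly expected affected
   counts, an exact gene-dropping Monte-Carlo counterpart, and Wright's
   inbreeding coefficient by the tabular kinship method.
5. **Synthetic study designs** (`simulate_denovo_genome()`,
   `simulate_halfsib_panel()`, `simulate_founder_pedigree()`): seeded
   generators with planted ground truth for each design, so every stage
   of the pipeline is testable end-to-end with no external data.

All user-facing functions take and return tibbles (or small S3 wrappers
around them), compose with the pipe, and have broom-style `tidy()` /
`glance()` and `ggplot2::autoplot()` methods.

## Worked example

```r
library(denovoherd)

# a half-sib mapping design: 49 mildly affected vs 89 unaffected
# offspring of one carrier sire, with a planted modifier haplotype
# carried by 12 of the former and 2 of the latter
sim  <- simulate_halfsib_panel(seed = 1)
scan <- modifier_scan(sim$panel,
                      maternal_only_chroms = sim$truth$causal_chrom)
scan <- permutation_empirical_p(scan, n_perm = 10000, seed = 1)
glance(scan)
#> # A tibble: 1 × 8
#>   n_tests n_windows min_fisher_p best_chrom best_window
#>     <int>     <int>        <dbl> <chr>            <int>
#> 1    5371       333    0.0000166 3                   52
#>   best_empirical_p_chromwide best_empirical_p_genomewide n_perm
#>                        <dbl>                       <dbl>  <dbl>
#> 1                    0.00100                     0.00210  10000
```

The best window overlaps the planted modifier span on chromosome 3
(markers 53–68) and is genome-wide significant under the permutation
null. The window at the span start carries the planted allele in
exactly 12 of 49 mildly affected and 2 of 89 unaffected animals —
carrier fractions of 24.5% and 2.2%, a ten-fold enrichment — whose
exact two-sided Fisher p is:

```r
fisher_window_test(12, 49, 2, 89)
#> [1] 7.314147e-05
round(100 * c(12 / 49, 2 / 89), 1)
#> [1] 24.5  2.2
```

`dominant_scan()` on the same panel maps the causal haplotype itself:
the returned interval (chromosome 2, 2.35–3.65 Mb, 18 consecutive
qualifying windows) contains the planted causal locus at 3.0 Mb.

A de novo screen on a simulated proband genome, with its per-stage
filter trail:

```r
sim <- simulate_denovo_genome(seed = 1)
scr <- screen_genome(sim$proband, sim$panel, sim$annotations)
filter_trail(scr)
#> # A tibble: 5 × 3
#>   stage        n_in n_out
#>   <chr>       <int> <int>
#> 1 autosomes     194   194
#> 2 quality       194   193
#> 3 het_private   193    32
#> 4 strand         32    31
#> 5 consequence    31     1
tidy(scr)$pos == sim$truth$planted$pos
#> [1] TRUE
```

The one surviving candidate is exactly the planted heterozygous
frameshift. And the risk side: a son × daughter mating of a founder
carrying a de novo mutation gives each calf a 1/16 chance of being a
homozygous mutant, which the formula and a 100,000-replicate gene drop
agree on:

```r
mating_risk(ped, "F")        # ped: founder F, half-sib son S x daughter D
#> # A tibble: 1 × 5
#>   id    birth_year c_sire c_dam   risk
#>   <chr>      <int>  <dbl> <dbl>  <dbl>
#> 1 C           2006    0.5   0.5 0.0625
```

See `vignettes/denovoherd-methods.Rmd` for the models, parameter
choices and limitations.

## File formats

VCF v4.2 is read through `vcfR` (multiallelic sites are decomposed and
indels trimmed to a canonical representation). The remaining formats are
fixed TSV dialects documented in their readers: pedigrees
(`id sire dam sex birth_year`, `0`/`.` for unknown parents), marker maps
(`marker_id chrom pos`), phased haplotypes (`id hap alleles`, two rows
per individual), consequence annotations
(`chrom pos ref alt consequence sift_class`), and a plain-text
control-panel key file.

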