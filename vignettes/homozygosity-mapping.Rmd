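---
title: "Mapping a recessive trait by runs of homozygosity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive trait by runs of homozygosity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohmap)
```

## The problem

In an inbred population, an autosomal recessive disease allele reaches
affected individuals on two copies of one ancestral haplotype. Affected
siblings are therefore expected to be *autozygous* — homozygous by descent —
across a chromosomal segment containing the causal variant, while unaffected
relatives and unrelated animals either lack the segment or carry a different
haplotype there. Homozygosity mapping exploits this: scan SNP-array genotypes
for runs of homozygosity (ROH), keep the runs shared allelically by all
cases and absent or allelically different in controls, and then filter
sequencing variants inside those candidate regions under a recessive model
against a panel of control genomes. `rohmap` implements this workflow for
small cohorts typical of veterinary and livestock genetics — a handful of
affected littermates, a few relatives, and unrelated population controls.

## ROH detection model

Detection follows PLINK 1.9 `--homozyg` semantics, which this package
re-implements explicitly so that every rule is testable:

1. **Sliding windows.** For each sample and chromosome, every placement of a
   window of `window_snp` consecutive markers that lies fully inside the
   chromosome's marker list is scored. A window *passes* when it contains at
   most `window_het` heterozygous and at most `window_missing` missing calls.
   Missing calls count toward neither homozygotes nor heterozygotes; they
   only consume the missing allowance.
2. **Eligibility.** Each marker's hit fraction is the share of passing
   windows among the windows containing it (edge markers belong to fewer
   windows; chromosomes shorter than one window get fraction 0). Markers
   with a hit fraction of at least `window_threshold` are ROH-eligible.
3. **Runs.** Maximal runs of consecutive eligible markers are split wherever
   the distance between neighbouring markers exceeds `max_gap` kb. A
   surviving run is reported iff it holds at least `min_snp` markers, spans
   at least `min_kb` kb, and its density — span in kb divided by marker
   count — is at most `max_density` kb/SNP.

Segment bounds are the base-pair positions of the run's first and last
markers; all internal coordinates are 1-based and inclusive (the PLINK/VCF
convention), and lengths are `end − start + 1`. Conversion to BED's 0-based
half-open coordinates happens in exactly one place, `write_bed()`. No
segment-level heterozygote cap is applied beyond the window allowance, and
the eligibility comparison is `>=`, both matching PLINK's defaults.

## Population-dependent calibration

Two parameters cannot be fixed a priori because they depend on the array and
the population.

**Minimum run size.** Short homozygous runs arise by chance; the standard
false-positive argument caps the expected number of chance runs across
`n_snps` markers in `n_individuals` samples at `alpha`, giving

$$\mathrm{min\_snp} \;=\;
\left\lfloor \frac{\ln\!\big(\alpha / (N_s \, N_i)\big)}
                  {\ln(1 - \bar h)} \right\rfloor,$$

where $\bar h$ is the mean per-marker SNP heterozygosity
(`mean_heterozygosity()`, the heterozygote fraction among non-missing calls,
averaged over markers). Rounding is *down*: the formula value is an upper
bound on what chance can produce at level $\alpha$, and with a dense array
(e.g. $\alpha=0.05$, $N_s = 154{,}235$, $N_i = 6$, $\bar h = 0.21$, where the
formula gives 70.98) the practical choice is the integer below. `rohmap`
computes heterozygosity after QC, since the scan runs on QC'd data.

**Density and gap.** A fully homozygous individual is simulated over the
population's own map (`simulate_homozygous_individual()`): on such a sample,
any failure to cover the genome with ROH is attributable to marker spacing
alone. `optimize_density_gap()` sweeps `max_density` and `max_gap` one
dimension at a time, holding the other at a permissive unvaried value
(200 kb/SNP and 2,000 kb respectively), and records genome coverage — total
ROH length over the marker-spanned extent of the map (assembly length is
invisible to an array method, so the map extent is the honest denominator).
The chosen density is the smallest grid value reaching the maximum attained
coverage; the chosen gap is the smallest grid value beyond which no later
grid value gains more than `plateau_tol` coverage. "Gains only negligibly"
is quantified as `plateau_tol = 0.001` (0.1% absolute coverage) — small
enough that the choice lands where the split-rate curve genuinely flattens,
and configurable because the notion is inherently a judgment call.

## Pooling, allelic matching, candidate regions

Overlapping segments from different samples are pooled by transitive single
linkage (`pool_segments()`, the grouping behind `--homozyg-group`): two
segments share a pool if they overlap directly or through a chain. A pool
becomes a candidate region (`case_specific_regions()`) iff

* every case contributes a segment;
* the consensus interval — the intersection, across cases, of the interval
  each case's segments span within the pool — is non-empty and contains
  markers;
* all case pairs have an allelic match fraction of at least `min_match`
  (default 0.95, PLINK's `--homozyg-match` default) over the consensus; and
* every control either has no segment overlapping the consensus or matches
  below `min_match` against every case there ("allelically different or
  absent").

The match fraction is the share of identical unordered allele pairs among
jointly called markers, so array-level genotyping error does not defeat the
comparison the way exact identity would. Matching is evaluated over the
consensus rather than the union because only there does every case have
calls inside its own ROH. A case may contribute *several* segments to one
pool — a local cluster of missing calls can split a genuine autozygous run
in two — which is why each case counts with the interval its segments span:
intersecting raw segments would return an empty consensus in exactly the
runs where the underlying autozygosity is intact, and the marker-by-marker
allelic check still protects against bridging two unrelated haplotypes.

## Genotype QC

`apply_qc()` drops samples below a 95% call rate first, then markers below a
95% call rate or with a Hardy–Weinberg exact-test p-value under 1e-8 on the
retained samples. The HWE test (`hwe_exact_p()`) is the exact conditional
test: given the observed allele counts, the probabilities of all
heterozygote counts no more likely than the observed one are summed (plain,
not mid-p — the convention of the genotype-QC tools this pipeline mirrors;
HWE is computed on all retained samples, cases included). Minor-allele
frequency and LD pruning are deliberately *not* offered: both remove
precisely the monomorphic-leaning, correlated stretches that constitute the
ROH signal.

## Variant filtering

`recessive_filter()` implements inheritance-model filtering of the
sequencing call set. For SNVs/indels every case must be homozygous for the
alternate allele; up to 2 heterozygous and 0 homozygous-alt calls are
tolerated in the control panel, absorbing occasional genotyping errors and
carriers among controls. For SVs/MEIs the case requirement is relaxed to
het-or-hom (SV and MEI genotypes are less accurate) and the variant must be
private (0/0 allowances). Missing case genotypes fail the case requirement
(conservative: an uncalled case cannot support the model); missing control
genotypes never count against the allowances, since control panels sequenced
at modest depth are expected to have missingness. Multi-allelic VCF records
are decomposed per alternate allele before filtering because all of this
logic is per allele.

Survivors are intersected with the candidate regions (point positions for
small variants, any overlap of the `[pos, END]` span for SVs/MEIs) and
classified against a gene model with precedence
splicing > exonic > UTR > intronic > other. "Splicing" means within 2 bp of
an exon–intron boundary on the intron side — the canonical splice
dinucleotides, the minimal defensible width. A variant touching several
transcripts takes its most severe class. Segregation arithmetic
(`check_segregation()`, `frequencies()`) then verifies the top candidate:
complete segregation means every affected is hom-alt and no unaffected is;
allele frequency is `(2·hom + het) / 2n` and carrier frequency `het / n`
over a population sample, with the affected family excluded via an explicit
id list (what "the family" includes is a study decision, not something the
package can infer).

## The synthetic cohort generator

Because real array and sequencing data of this kind are not redistributable,
`simulate_population()` generates cohorts with the statistical structure the
method assumes, and the whole pipeline is tested end to end against the
generator's known truth.

* **Map:** 3 autosomes × 60 Mb with 3,000 uniformly placed markers each
  (~20 kb mean spacing). Dense genotyping arrays run at roughly 14–16 kb per
  informative marker after QC; 20 kb keeps that regime — in particular, a
  30 kb/SNP density cap comfortably exceeds the map's spacing, as it did on
  the real array — while staying desk-scale. A sparser 30 kb map would put
  the density of a genuine autozygous segment *exactly at* the 30 kb/SNP
  detection cap, making retention a coin flip, which misrepresents the
  method.
* **Genotypes:** per-marker alternate-allele frequencies are drawn from a
  symmetric Beta with shape $h/(1-2h)$, the one-parameter family whose
  expected heterozygosity $E[2p(1-p)]$ equals the target $h$ (default 0.21);
  genotypes follow Hardy–Weinberg proportions.
* **Pedigree structure:** all cases (default 4) are homozygous for one
  founder haplotype across a planted 4.3 Mb region; the two parents and a
  random half of the remaining relatives carry one copy; 20 unrelated
  controls are population draws. Outside the planted region all samples are
  independent draws — no LD, recombination map, or coalescent breed history
  is modelled, so passing tests demonstrate the logic of the method, not its
  power on real LD structure.
* **Missingness** (default 1% per genotype) is injected uniformly at random
  after planting, enough to exercise call-rate QC and window missing
  allowances.
* **Variant set:** the causal variant (hom-alt in cases, het in carriers and
  two unrelated controls — at the control allowance boundary) plus decoys
  that each violate exactly one filter rule (het in a case; outside any
  ROH; three het controls; a hom-alt control; an SV shared with five
  controls), private SV/MEI records, random background variants, and a small
  gene model making the causal variant exonic.

Everything is deterministic given the seed.

## Numerical and degenerate-input choices

* Eligibility and density comparisons carry a `1e-12` slack so that exact
  rational fractions (e.g. a hit fraction of exactly 0.05) are not lost to
  floating-point noise; the HWE tie comparison uses a `1e-9` relative slack
  for the same reason.
* Genotype classes are stored as 0/1/2/NA with code 0 anchored to the
  lexicographically smallest observed allele, so PED round trips are
  bit-exact and ROH calls are invariant to which homozygote is labelled
  "reference" (a tested property).
* An all-missing marker has no defined HWE p; it is skipped with a warning
  (call-rate pruning removes it anyway at any positive threshold).
* A pool whose case segments do not jointly overlap yields no candidate; a
  control segment with zero jointly-called markers over a consensus cannot
  be declared "allelically shared" and is flagged rather than counted
  against the pool.
* Chromosome ids are opaque ordered labels; only autosomes are expected
  (an X chromosome would need a different recessive model and should be
  excluded upstream).

## Problem sizes used by the test suite

The packaged tests run the full pipeline on the default generator (9,000
markers × 30 samples, ~4–5 s per run) across 20 seeds, compare the ROH
caller against a brute-force window/run enumeration on 200 random instances
of up to 500 markers, and compare the HWE exact test against full
enumeration for every genotype configuration with up to 200 individuals.
These sizes keep the whole suite under two minutes while covering the
parameter regime the calibration formulas operate in (minimum run size
~65–70 markers).

## Known limitations

* The generator's independence assumptions (no LD, no recombination map)
  make candidate regions cleaner than real data would be; recovery rates on
  synthetic data are an upper bound.
* The window scan reproduces PLINK 1.9's documented behaviour, but corner
  cases PLINK leaves undocumented (e.g. chromosomes shorter than one
  window) follow the conservative choice of fraction 0 / no call.
* Pathogenicity prediction, conservation analysis and transcript-level HGVS
  naming are out of scope: the pipeline ends with classified, segregating
  candidate variants.
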