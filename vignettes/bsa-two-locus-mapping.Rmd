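---
title: "Mapping two recessive loci by BSA-seq: model, simulator and design choices"
author: "bsascan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping two recessive loci by BSA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mapping problem

Most mapping-by-sequencing studies chase a single mutant locus. This
package addresses the harder, less common design: a qualitative trait
controlled by **two unlinked recessive loci with duplicate-dominant
epistasis**. The recessive phenotype (here: green seed cotyledons in a
yellow x green soybean cross) appears only in individuals homozygous for
the recessive allele at *both* loci, so an F2 segregates 15:1 and selfed
F2:3 families fall into four classes (all-dominant, 3:1, 15:1,
all-recessive) in 7:4:4:1 proportions.

Bulked-segregant analysis by sequencing (BSA-seq) pools DNA from progeny
with contrasting phenotypes and sequences each pool. Away from the causal
loci both bulks inherit parental alleles at ~50:50; near a causal locus
the recessive-phenotype bulk is fixed for the recessive-parent allele
while the dominant-phenotype bulk is depleted of it.

## The statistics

With all sites **polarized to the green-parent allele** (the "index
allele"), for bulk $b$ at site $i$:

$$\mathrm{SNPindex}_b(i) = \frac{\text{index-allele reads}}{\text{total reads}},
\qquad
\Delta(i) = \mathrm{SNPindex}_{green}(i) - \mathrm{SNPindex}_{yellow}(i).$$

At a causal locus the green bulk is fixed ($\mathrm{SNPindex} = 1$), and
conditioning on the yellow phenotype leaves the green allele at frequency
$7/15$ among yellow F2s, so $E[\Delta] = 8/15 \approx 0.533$ — *not* 1 as
in a single-locus mutant design. Each site also gets a two-sided Fisher
exact P for its 2x2 bulk x allele read-count table (probability-mass
rule, summing hypergeometric masses no larger than the observed table's).

Sites are first filtered: parents homozygous for opposite alleles,
QUAL >= 100, total depth >= 10 in both bulks (the "both" reading is the
strictest consistent one; `filter_config(depth_rule = "either")` gives
the alternative).

Because single-site indices at ~55x depth are noisy, inference is
windowed: 2-Mb windows advanced in 10-kb steps, per-window arithmetic
means of the indices and of the Fisher P. A window qualifies when its
mean green-bulk index exceeds 0.9 **and** its mean P is below 0.05;
overlapping qualifying windows merge into candidate regions.

## The simulated world

There is no public desk-scale dataset for this design, so the package
carries a first-class simulator whose defaults *are* the stated study
conditions:

| parameter | default | why |
|---|---|---|
| `n_f2` | 495 | the study's F2 population size |
| `bulk_size` | 30 | 30 lines pooled per bulk |
| `depth_bulk` | 55 | bulks averaged 59x / 53x |
| `depth_parent` | 10 | parents averaged 12x / 9x |
| `chrom_lengths` | 2 x 50 Mb | two chromosomes carry the loci; 50 Mb is a typical soybean chromosome |
| `causal_loci` | chr01:35 Mb, chr02:12 Mb | unstated; chosen once — one mid-arm, one near an end, echoing the real loci's placements |
| `cm_per_mb` | 2.5 | map density unstated; 2.5 cM/Mb is a standard euchromatic plant rate, and the Haldane map function makes every linkage quantity testable in closed form |
| `marker_spacing_bp` | 10 kb | ~1.1 M parental SNPs over a ~1 Gb genome is ~1/kb; 10 kb keeps the desk-scale scan at 10^4 sites while leaving >100 SNPs per 2-Mb window |
| `seq_error` | 0.001 | typical post-filter Illumina miscall rate; applied symmetrically |
| `f3_seeds_per_line` | 60 | per-line seed counts unstated; 60 is a realistic single-plant harvest and classifies lines at ~99% accuracy |

Meiosis is a Markov chain along the marker ladder with Haldane
transition probabilities $r = \tfrac12(1 - e^{-2d/100})$ — no crossover
interference, no segregation distortion, complete penetrance. Read
counts are Poisson total depth with binomial allele sampling. An F2 of
495 leaves fewer than 30 green individuals in almost half of draws
(Binomial(495, 1/16)); the dataset assembler re-draws the cross rather
than failing, as a breeder would grow another population.

**What the simulator does not emulate:** alignment artifacts and
repeat-induced mis-mapping (soybean is paleopolyploid; the real data lose
~5-6% of reads), indels, caller-specific QUAL behavior (QUAL is drawn
from a gamma distribution so that ~1% of sites fail the 100 threshold),
uneven recombination (real pericentromeres are recombination deserts —
one reason the real mapped intervals stay Mb-sized), and marker
ascertainment bias. A green test therefore establishes that the
*statistics and calling logic* behave as designed under the stated
sampling model — not that the pipeline reproduces the study's exact
genomic intervals, which require the archived reads.

## Numerical and design choices

* **Yates correction, unfloored.** The segregation tables this field
  publishes use the classical $(|O-E|-0.5)^2/E$ even when $|O-E| < 0.5$;
  only that convention reproduces all eleven published chi-square values
  (one population has $|O-E| = 0.0625$, printed chi2 0.0097, where the
  floored statistic gives 0). Consequently "corrected" can slightly
  exceed "uncorrected" for near-perfect fits; `floor_correction = TRUE`
  restores the never-anticonservative variant. The printed P column of
  such tables matches the *uncorrected* statistic, so both pairs are
  always reported.
* **Fisher ties.** Hypergeometric masses are compared with a relative
  tolerance of 1e-7 (the convention of reference implementations) so
  floating-point jitter does not split tied tables.
* **Window anchoring** is left-anchored at position 1 with truncation at
  the chromosome end; interior positions are covered by exactly
  window/step windows, which makes window counts auditable.
* **`min_snps_per_window` = 10 and `min_windows_per_region` = 5** are
  this package's noise guards (the study specifies neither); both are
  configurable, and the null-bulk simulation (phenotype-independent
  pools) shows zero spurious regions across seeds under the defaults.
* **Region merging** joins qualifying windows that overlap, so a dip of
  a few windows inside a broad peak does not split a region; only a gap
  of at least window/step consecutive failing windows separates regions.
* **Consensus region genotype** is the majority call over the region's
  markers (ties -> NA); breakpoints are open intervals strictly between
  flanking informative markers; contradictory fine-mapping constraints
  fail loudly with the offending line ids rather than being resolved —
  the real material was manually curated, and silent repair would hide
  genotyping errors.
* **Per-window mean P** operationalizes "windows with average P < 0.05";
  no window-level combined test is attempted, and no per-SNP
  multiple-testing correction is applied (aggregation over windows is the
  study's own answer to multiplicity).

## What the simulator taught us (all reproduced by the test suite)

* **Per-SNP Fisher tests are anticonservative under bulk drift.** With
  finite bulks (30 individuals), unlinked sites share composition noise
  across both bulks, so read-count Fisher tests reject more than 5% at
  unlinked sites in a full cross simulation. Under the pure
  read-sampling null (true frequency 0.5 in both pools) the test is
  conservative, as discreteness predicts. This is precisely why region
  calling averages over 2-Mb windows instead of trusting single sites.
* **Finite phenotyping leaks F2:3 classes.** With 60 seeds per line,
  $(15/16)^{60} \approx 2\%$ of truly 15:1 lines show no green seed and
  are classified all-dominant. The classifier is ~99% accurate per line,
  but the leak is systematic, so a 7:4:4:1 goodness-of-fit on *observed*
  classes drifts toward rejection as the number of lines grows.
* **Shrinking the bulks degrades precision before recovery.** At
  bulk_size 5 the green bulk is still fixed at the causal loci (recovery
  holds) but spurious regions appear and regions widen; at bulk depth
  10x recovery drops and called regions *narrow*, because fewer windows
  clear the 0.9 index threshold on noisy data.

## Limitations

Coordinates are 1-based inclusive throughout (BED export converts at the
boundary). The VCF reader requires per-sample AD; callers that emit only
genotype likelihoods for pools are out of scope, as are read-level
simulation, genotype imputation, multiallelic decomposition, and any
annotation of genes inside called or refined intervals.
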