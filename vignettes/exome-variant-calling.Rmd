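---
title: "Calling exome SNPs and INDELs with trainable logistic regression models"
author: "exovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling exome SNPs and INDELs with trainable logistic regression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exovar)
```

## The problem and the model

Whole-exome capture sequencing produces deep but heterogeneous coverage of
coding regions, with error patterns (3'-end quality decay, strand-biased
systematic errors, gapped mis-mapping near repeats) that differ from
whole-genome data. `exovar` separates true SNPs and short INDELs from these
errors with per-variant-type logistic regression models applied to features
compiled from the pileup at each candidate site, followed by a small set of
heuristic filters and genotyping on the adjusted variant ratio.

For a candidate with covariates $x_1,\dots,x_k$ the model reports

$$p = \frac{1}{1 + e^{-(\beta_0 + \sum_i \beta_i x_i)}},$$

the probability that the candidate is a true variant. The SNP model uses
seven terms:

* **reference/variant reads ratio** — reference-carrying over
  variant-carrying read counts (0 when no reference reads remain). The
  single most discriminative covariate: true SNPs rarely exceed a ratio of
  about 5, while recurrent errors usually sit far above it.
* **mean variant base quality** — mean phred score of the variant base over
  variant reads.
* **mean neighboring base quality (NBQ)** — mean phred of the variant base
  plus up to 5 flanking bases on each side within the read. A high-quality
  base surrounded by low-quality neighbors is suspect, and reads with many
  local errors are often mis-mapped.
* **mean distance to the 3' end** — measured in sequencing orientation,
  excluding soft clips; quality decays toward the 3' end.
* **strand direction standard** — 1 when variant evidence exists on both
  strands. True variants sample both strands; systematic errors are often
  strand-confined.
* the two **interactions** NBQ × distance-to-3' and strand × distance-to-3'.

The INDEL model uses four terms: the **normalized variant square**
NVS = (variant reads)² / total depth, which couples variant depth and
variant ratio in one coverage-normalized covariate; **mean NBQ** (flanking
bases only for deletions, which have no sequenced base; inserted bases plus
flanks for insertions); the **mean variation rate** of the variant reads —
(mismatches + gap events) / read length, a mapper-independent surrogate for
mapping quality and the dominant separator of gapped mis-alignment
artifacts; and the **read-end ratio**, the fraction of variant reads whose
event lies within 5 bp of a read end, where both sequencing quality and gap
placement are least reliable.

Candidates passing the model cutoff and the heuristic filters are genotyped
with the adjusted variant ratio $t$ = variant depth / (total depth −
color-corrected bases): heterozygous at $t \ge 0.1$, homozygous at
$t \ge 0.8$. Calls whose $t$ falls below the heterozygous bound are demoted
to filtered (`low_t`), never emitted as reference.

## Defaults and what they mean

`filter_config()` carries every tunable cutoff. The defaults are the
method's standard operating point:

| parameter | default | meaning |
|---|---|---|
| `snp_min_p` | 0.5 | minimum model probability for SNPs |
| `snp_min_var_depth` | 2 | minimum variant reads for SNPs |
| `indel_min_p` | 0.5 | minimum model probability for INDELs |
| `indel_min_p_1bp_del` | 0.88 | stricter cutoff for 1 bp deletions, the most error-prone event class |
| `indel_min_var_depth` | 2 | minimum variant reads for INDELs |
| `indel_min_total_depth` | 2 | minimum spanning depth at the anchor |
| `indel_min_var_ratio` | 0.05 | minimum variant read ratio |
| `max_variant_events` | 3 | per-read cap on mismatches + gap events |
| `mapq_mode` | `"exact255"` | mapping-quality rule; use `"min:N"` for aligners that don't reserve 255 for unique mappings |
| `min_effective_depth` | 6 | callable-region threshold |
| `het_t`, `hom_t` | 0.1, 0.8 | genotype bounds on t (inclusive) |

All boundary comparisons are inclusive ("at least"): effective depth 6 is
callable, $t = 0.8$ is homozygous, a 1 bp deletion at $p = 0.88$ passes.

Effective depth counts only A/C/G/T observations from reads passing the
per-read filters; gap and N observations are excluded. For SNPs the depth
reported with a call (and the denominator of $t$) is this effective depth;
for INDELs it is the number of passing reads spanning the anchor position.

## Coordinates, normalization, numerical choices

* Internal coordinates are 1-based closed throughout, matching the
  Bioconductor container ecosystem the package is built on
  (IRanges/GenomicRanges/Rsamtools); BED input/output converts from/to
  0-based half-open at the boundary, SAM and VCF are natively 1-based.
* INDEL candidates are keyed by their left-normalized VCF representation
  (anchor base convention), so reads whose aligners placed the same gap at
  different positions of a repeat run aggregate into one candidate. The
  walker finalizes indel candidates one read-width behind the sweep for the
  same reason.
* Soft-clipped bases are excluded from read length, NBQ windows and
  3'-distances: clips carry no alignment evidence. NBQ windows truncate at
  read boundaries and divide by the actual window size — no padding value
  would be defensible.
* Each insertion or deletion counts as one variant event regardless of
  length, both in the per-read filter and in the variation rate; "one
  mapping decision, one event".
* Logistic fits use IRLS (`stats::glm`, log-likelihood tolerance 1e-8, at
  most 100 iterations). Perfect separation and singular designs are
  rejected with diagnostics rather than returning divergent coefficients.
* Bootstrap confidence intervals are case-resampling percentile intervals
  (`boot::boot`/`boot.ci`): the simplest standard choice. A fit where more
  than 10% of bootstrap replicates fail to converge errors out — unstable
  intervals are an overfitting signal and are surfaced, never hidden.
* Precision/sensitivity and ROC curves are evaluated on the cutoff grid
  0.00–1.00 in steps of 0.01; precision is undefined (NA) at cutoffs where
  nothing is called, and those points are dropped from curve means.
* Stepwise selection is AIC-guided and bidirectional from the full model
  (`stats::step` defaults); `drop_nonsignificant()` removes the worst term
  by likelihood-ratio p-value (via `stats::drop1`) until all terms clear
  the 0.05 threshold.

## The synthetic-data generator

No public, redistributable exome truth set fits in a package, so `exovar`
ships a read simulator (`simulate_reads()`) that reproduces the
*discriminative structure* the models rely on, as a two-component mixture:

* **True variants** are planted at well-separated loci, heterozygous or
  homozygous with equal probability; carrier reads sample both strands and
  uniform read positions, with the normal quality profile.
* **Errors** are strand-biased, enriched toward the 3' end, and carry
  depressed base and neighboring-base qualities. A configurable share is
  *systematic* ("hotspots": fixed position, fixed allele, preferred strand,
  recurrent across reads), which is what makes multi-read false positives
  possible — the analogue of mapping artifacts. Roughly 15% of hotspots are
  "hard": paralog-like sites with normal base qualities whose reads carry
  extra divergence mismatches (elevated variation rate), the signature of
  mis-mapped reads. Systematic *indel* artifacts always carry that
  signature, since gapped mis-alignment is the dominant source of recurrent
  false INDELs. Hard substitution hotspots occur at low allele fraction
  (rates 0.03–0.07), reproducing the qualitative separation that true SNPs
  sit below a reference/variant ratio of ~5 while most false ones sit far
  above it.
* **Coverage** follows a smooth log-normal field (`depth_log_sd`, default
  0.5, 500 bp windows), emulating capture heterogeneity; this is what
  produces genuinely hard low-coverage true variants. Phred qualities are
  integers in [2, 40] with a linear decay (default 10 points) toward the
  3' end. The reference is i.i.d. uniform A/C/G/T from the seed.

Everything is deterministic in `seed`. What the generator does *not*
emulate: color-space chemistry, capture GC bias, PCR duplicates (reads are
emitted pre-deduplicated), alignment around complex/multi-allelic
haplotypes, and real repeat structure beyond what a random sequence
contains. Tests passing on these fixtures demonstrate the pipeline's
mechanics and the models' discriminative behavior under the stated error
structure — not calling accuracy on any particular real platform.

## The bundled default models

No published coefficient sets exist for these models, so the package ships
`inst/extdata/models/default_snp.json` and `default_indel.json` trained on
the package's own simulator (seeds 104729 and 224737; 600 planted sites on
120–200 kb references at mean depth 30, elevated error rates, candidate
tables restricted to ≥ 2 variant reads and resampled to 10% TP / 90% FP —
the class balance a realistic exome training set shows). Labels are taken
from the planted truth with 97% sensitivity: real training labels come from
an external validation call set of limited sensitivity, and a small share
of true sites mislabeled FP both mirrors that and keeps the two classes
honestly overlapping. The JSON `provenance` field records all of this;
treat the bundled models as synthetic-trained defaults and retrain on your
own labeled data (`build_training_table()` → `lr_fit()` /
`stepwise_select()` → `save_model()`) for production use on real platforms.

Model training and evaluation mirror the standard workflow: repeated
split-half cross-validation (`cross_validate()`, 100 replicates by
default) whose mean curve should hug the full-data curve at the default
cutoff when the model is not overfit, and case-resampling bootstrap
confidence intervals for every coefficient.

## Problem sizes used by the test-suite and acceptance script

The shipped tests and `scripts/acceptance.R` run the whole pipeline on
simulated data sized for quick, deterministic execution: end-to-end
recovery uses 100 SNPs + 20 INDELs on a 40 kb reference at depth 30 with a
clean error profile; parameter recovery uses n = 50,000 (single fit) and
100 datasets of n = 2,000 (bootstrap coverage); cross-validation uses 100
replicates on n = 4,000 (well-specified) versus n = 60 with 12 covariates
(deliberately overfit); the streaming checks use uniform-coverage fixtures
of 12/24/48/120 kb. These sizes were chosen as the smallest that make the
statistical assertions stable.

## Known limitations

* Color-space (2-base-encoded) data is supported only to the extent of
  honoring a supplied `color_corrected_count` in the adjusted variant
  ratio; no color-space decoding is performed.
* INDEL genotypes reuse the SNP t thresholds; no INDEL-specific bounds are
  established.
* Multi-allelic sites are emitted as separate VCF records sharing POS.
* The population merge fills missing cells as homozygous-reference only
  when an explicit per-sample depth source covers the site (depth ≥ 1);
  without one the cell is `./.`. Sites covered below the callable threshold
  are still filled `0/0` when depth ≥ 1 — the fill reflects observed
  coverage, not callability.
* `stepwise_select()` and `drop_nonsignificant()` follow AIC and
  likelihood-ratio p-values mechanically; redundant variable pairs that the
  original workflow removed by judgment must still be reviewed by the
  analyst.
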