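---
title: "Flagging genes and exons prone to splicing mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flagging genes and exons prone to splicing mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceprone)
library(dplyr)
```

## The problem

A substantial share of hereditary disease alleles act by disrupting
pre-mRNA splicing rather than (or in addition to) changing the protein.
Catalog-wide, about 13.4% of disease mutations map to the canonical
splice sites — the donor window spanning positions −3 (exonic) to +6
(intronic) and the acceptor window spanning −20 (intronic) to +3
(exonic), in transcript orientation. But that rate is far from uniform:
some genes (the mismatch-repair genes of Lynch syndrome being the
canonical example) carry several-fold more splice-site mutations (SSM)
than the catalog-wide rate predicts, and their exonic "protein-coding"
mutations disrupt splicing in assays far more often than the ~10%
background measured in pooled massively parallel splicing assays
(MaPSy). `spliceprone` implements the complete computational stack for
detecting, characterising and predicting this class of genes, together
with a synthetic-data module that emulates every external input
(disease-mutation catalogs, assay count tables, genomic feature tracks,
population variants) with known ground truth, so the whole pipeline is
testable offline.

## The sampling envelope

The core statistic is a weighted-random-sampling envelope. Let
`totalspl` and `totalmuts` be the catalog-wide SSM and total mutation
counts. Under the null, every gene draws its SSM count from

$$\mathrm{SSM}_g \sim \mathrm{Binomial}(n_g,\; w), \qquad
  w = \mathrm{totalspl}/\mathrm{totalmuts},$$

where $n_g$ is the gene's total mutation count. `mc_envelope()`
simulates this `n_reps` times per gene (default 1,000) and takes the
order statistics at the two tail fractions of `ci_level` (default
0.999, i.e. ranks `ceiling(0.0005 n_reps)` and
`ceiling(0.9995 n_reps)`) as the envelope. A gene is *Upper* (SSM-prone)
only when its observed count falls strictly outside the simulated
bounds; ties with a bound stay *Expected*. The two-sided empirical
p-value is the add-one estimate `2 * min(tails)` capped at 1.

The *normalized* mode asks whether enrichment survives correction for
splice-site density. Each gene's weight becomes

$$w_g = \frac{\mathrm{totalspl}}{\mathrm{totalmuts}}
        \cdot \frac{\mathrm{totalCDS}}{\mathrm{totalSS}}
        \cdot \frac{\mathrm{geneSS}}{\mathrm{geneCDS}},$$

with `geneSS = 2 x introns` and `geneCDS` the gene's coding length.
The formula can exceed 1 for intron-dense, short-CDS genes; such
weights are clipped to 1 with a warning. When every gene has the same
site density the normalized weights collapse to the global weight
exactly, and the two modes return identical results under the same
seed — a property the test suite asserts.

The identical machinery applies per exon to assayed exonic splicing
mutations (ESM): `exon_esm_envelope()` simulates
`Binomial(n_tested, totalESM/totalmutstested)` per exon. With the
published per-exon counts of the MLH1 panel (6/6, 5/7, and three
0-ESM exons, 36 mutations in total) and the 10% background weight,
exactly the two reported exons come out *Upper*.

Each entity draws from its own RNG substream keyed by its identifier
(a stable string hash combined with the user seed), so results are
invariant to catalog order and to adding genes.

An exact counterpart, `binomial_oracle()`, inverts the binomial CDF at
the same tail fractions. It exists for validation only: across a grid
of realistic per-gene mutation counts (n = 5–500) and weights
(0.01–0.9) the Monte Carlo bounds at 10,000 replicates agree with the
oracle within one count. At substantially larger n the 0.05%-tail
order statistic itself has sampling error above one count, so the
comparison is only meaningful in this range.

## MaPSy quantification

For pooled splicing reporters, the per-species splicing efficiency is

$$\log_2\!\frac{spl_i/\sum_j spl_j}{inp_i/\sum_j inp_j},$$

and the allele ratio between a wild-type/mutant pair in a spliceosomal
fraction is

$$\log_2\!\frac{m i_e / m i_i}{m j_e / m j_i},$$

with the major allele fixed per pair as the one splicing more
efficiently in the mRNA fraction. Both add a configurable pseudocount
(default 0.5) to every raw count before forming ratios; textbook hand
arithmetic on non-zero counts is recovered at `pseudocount = 0`.

The published analyses say only that variants "significantly altered
splicing"; the calling rule here is reconstructed from the cited
MaPSy methodology and kept configurable: a pair is an ESM when, in
both the in vivo and the in vitro assay, the mutant's allelic
imbalance exceeds 1.5-fold *and* a two-proportion chi-square test on
the (input vs spliced) × (wt vs mt) table rejects at
Benjamini–Hochberg FDR 0.05 within the panel. On null panels the
false-call rate is controlled at the FDR level; on panels generated at
the 10% ESM background with the default effect law (log2 effects
uniform on [−4, −1]) and depth 2,000, the called fraction recovers the
planted 10%.

Complex blockage profiles express the mutant allele as percent
retention relative to wild type (wild type = 100%) per fraction in
assembly order E → A → B/C → products (mRNA, lariat). A transition is
flagged blocked when retention upstream reaches 150% while some later
fraction falls below ~67%; the primary block is the flagged transition
with maximal upstream retention, and a mutant may flag several. The
normalisation to wild type = 100% is an assumption where the published
figure is not fully specified.

## Sequence scores and features

`delta_esr()` scores the up-to-six hexamer windows overlapping a
substitution (step 1, truncated at exon ends) in the wild-type and
mutant sequence and reports the difference; windows away from the
variant cancel, which the tests exploit by comparing against a
full-sequence rescan oracle.

Splice-site strength uses a position log-odds matrix
(`build_pwm()`): `log2(((count + pc)/(n + 4 pc)) / background)` per
position with Dirichlet pseudocount smoothing (default 0.5), 9
positions for donors and 23 for acceptors. The scorer sits behind a
minimal interface (score a fixed-width site sequence), so a
maximum-entropy backend could replace it without touching the
Δ-threshold analyses, which depend only on score *differences*:
Δ = score(ref) − score(alt), positive meaning the variant weakens the
site. Δ > 5 marks site-abolishing variants and Δ < −2
site-strengthening ones in the selection analyses.

The 19-feature gene table combines model-derived quantities (intron
count, exon/intron lengths, CDS and gene length, GC), hexamer
densities per exonic nucleotide, PWM site strengths, folding scores of
exons and of 140-nt splice-site flanks (70 nt either side of each
junction, folded as one window), SNP densities, conservation means and
haploinsufficiency. Thermodynamic folding is out of scope: the default
`fold_backend` is a documented dinucleotide stacking heuristic
(GC-containing stacks weigh more), and any function from sequence to
an energy-like scalar can be injected. Missing track values are
median-imputed and the affected genes recorded in an attribute.

## Classification

`train_rf()` follows the published protocol: one random 2/3–1/3
split, 500 trees, `mtry = floor(sqrt(p))`, stratified downsampling of
the majority class to the rarest class's frequency, permutation
importance (mean decrease in accuracy) on out-of-bag data. Because an
ensemble has no signs, each feature's direction of association is
reported as the sign of the difference in class-conditional means.
`train_lr()` is the additive-logit counterpart under the identical
split. Replication across seeds (the published single split repeated)
is how uncertainty should be assessed; the suite does this for the
chance-level and recovery properties. Genome-wide prediction applies
the trained forest to unlabeled genes and calls SSM-prone those with
probability strictly above 0.6.

ROC/AUC are computed internally with tie-aware threshold sweeps; the
trapezoid AUC equals the Mann–Whitney rank statistic to numerical
precision, which is asserted in tests.

## Population-variant selection analyses

Variants are stratified by minor allele frequency into rare
(MAF < 0.01%) and common (MAF > 1%); intermediates are excluded from
two-stratum comparisons. `ss_variant_density()` counts low-frequency
in-window variants per splice site and compares predicted-prone
against other genes by rank-sum test. `delta_strata_compare()`
contrasts the Δ distribution between strata and reports the depletion
factor of Δ > 5 variants among common ones (share among rare / share
among common). Gene-set overlaps use the two-sided Fisher exact test
(point-probability summation) with a fold enrichment relative to
independence, and `category_permutation()` is the Monte Carlo analogue
whose tail converges to the hypergeometric — both convergence and full
enumeration on small universes are asserted. For rank tests with both
groups at most 8, an exact two-sided p is computed by full enumeration
of assignments with midranks, since the standard exact path is
unavailable under ties.

## What the synthetic generators emulate

The generators define the study conditions and are first-class,
tested code:

* `gen_catalog()` — per-gene mutation totals from 1 + NegBin(mean 20,
  shape 2), a long-tailed stand-in for unpublished per-gene catalog
  counts; each mutation is an SSM with probability 0.134, multiplied
  for an enriched minority and clipped at 1; SSM records are placed in
  real window positions of synthetic gene models and labelled
  `splicing`; the rest are exonic, split missense:nonsense 3:1.
* `gen_mapsy_counts()` — gamma-Poisson input counts (shape 10) around
  a target depth; spliced counts Poisson around input × 0.5, the
  mutant's rate multiplied by 2^effect for the 10% of pairs that are
  true ESM.
* `gen_feature_table()` — Gaussian features with planted shifts in
  the directions the real feature table separates: 2.5× more introns
  (the strongest planted signal), higher haploinsufficiency, shorter
  and more structured exons, lower population-variant conservation.
* `gen_population_variants()` — splice-site sequences drawn from
  built-in base-frequency models (synthetic approximations of the
  donor/acceptor consensus, not estimates from any real compilation),
  one substitution each, log-uniform MAF, and rejection-thinning of
  common draws for site-abolishing variants by `1/selection_strength`.
  The depletion factor this scheme implies is computed in closed form
  and attached to the output, so recovery is checked against an
  analytic truth.

What they do *not* emulate: real nucleotide composition and motif
grammar (sequences are i.i.d. with planted site models), linkage
between features, per-exon heterogeneity of ESM effects, and
catalog-level ascertainment biases. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
models, not performance on real HGMD/ExAC data; the headline real-data
numbers (86 SSM-prone genes, 499 predicted genes, AUC 0.839) are not
reproducible without the proprietary and external resources.

## Numerical choices and problem sizes

Pseudocount 0.5 on all raw counts (the sources are silent on zeros);
strict-inequality envelope categories; add-one empirical p-values;
per-entity RNG substreams; weights clipped to [0, 1] with warnings;
median imputation with provenance recording. A position falling in
both a donor and an acceptor window (micro-exons) takes the nearer
boundary, with ties going to the donor; the sources do not address
this case. The test suite runs null-catalog calibration at 2,000 genes
× 10 seeds × 1,000 replicates, weight recovery at ≥ 10^5 pooled
alleles, envelope-versus-oracle agreement on a 10 × 10 grid at 10^4
replicates, and classifier properties at a few hundred genes per
fit — sizes at which every stochastic tolerance asserted has
comfortable Monte Carlo margin.

## Known limitations

One canonical transcript per gene (no isoform resolution, no
liftover); the ESM calling rule is a reconstruction, exposed as
configuration; the folding backend is a heuristic proxy; the ambiguity
in the sources between a 99.9% envelope and a p < 0.01 criterion is
resolved by exposing `ci_level` (default 0.999) and reporting the
empirical p alongside; and which mutation classes form the "total
mutations" denominator is taken to be all catalog records of the gene.
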