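# spliceprone

Disease mutations that disrupt pre-mRNA splicing are systematically
under-recognised: catalog-wide, about 13.4% of hereditary disease
alleles sit in the canonical splice sites (donor −3..+6, acceptor
−20..+3 in transcript orientation), and roughly 10% of exonic
"protein-coding" disease alleles turn out to disrupt splicing when
assayed. Neither rate is uniform across genes — some genes, notably
the Lynch-syndrome mismatch-repair genes, are several-fold enriched
for splicing mutations. `spliceprone` is an R package for geneticists
and method developers that implements the complete analysis stack
around this observation:

* **Enrichment envelopes** — the core statistic. Under the null each
  gene's splice-site mutation (SSM) count is
  `Binomial(n_muts, totalspl/totalmuts)`; `mc_envelope()` simulates
  this 1,000 times per gene and flags genes whose observed count falls
  strictly outside the simulated 99.9% envelope (`Upper` / `Expected` /
  `Lower`). A *normalized* mode rescales each gene's weight by its
  splice-site density, `(totalspl/totalmuts)(totalCDS/totalSS)(geneSS/geneCDS)`,
  and `exon_esm_envelope()` applies the same machinery to assayed
  exonic splicing mutations (ESM) per exon.
* **MaPSy quantification** — splicing efficiency
  `log2((spl_i/Σspl)/(inp_i/Σinp))`, allelic ratios
  `log2((mi_e/mi_i)/(mj_e/mj_i))` across spliceosomal fractions,
  ESM calling (1.5-fold in both assays + FDR-controlled count test),
  and spliceosomal complex blockage profiles (E → A → B/C → mRNA).
* **Sequence scores** — ΔESR hexamer scoring of exonic variants,
  position-weight-matrix splice-site models with ref-minus-alt Δ
  scores (Δ > 5 site-abolishing, Δ < −2 site-strengthening), and
  assembly of the 19-feature gene table.
* **Classification** — random-forest and logistic-regression
  prediction of SSM-prone genes (stratified downsampling, 2/3–1/3
  split, permutation importance, genome-wide prediction at
  probability > 0.6), with broom-style `tidy()`/`glance()` and
  `autoplot()` methods.
* **Selection statistics** — splice-site variant density per gene,
  MAF-stratified Δ-score comparisons with depletion factors, Fisher
  exact overlap tests and permutation tests for category enrichment.
* **Synthetic data** — generators for every input (catalogs, count
  tables, feature tables, population variants) with known ground
  truth, so the full pipeline runs and is tested with no external
  resources.

## Worked example

Generate a synthetic disease-mutation catalog in which 5% of genes
carry a 4-fold elevated SSM rate, tally it against the gene models,
and ask which genes exceed the sampling envelope:

```r
library(spliceprone)

sim     <- gen_catalog(n_genes = 500, seed = 42,
                       enriched_fraction = 0.05, multiplier = 4)
tallies <- tally_genes(sim$catalog, sim$models)
glance(tallies)
#>   n_genes totalspl totalmuts totalSS totalCDS global_weight
#> 1     500     1553     10365    6954   615432         0.150

env <- mc_envelope(tallies, n_reps = 1000, ci_level = 0.999, seed = 42)
glance(env)
#>   n_entities n_upper n_expected n_lower flagged_fraction
#> 1        500      13        487       0            0.026
```

The catalog-wide weight is 0.150 (the null 0.134 inflated by the
planted enriched genes), and 13 genes exceed the envelope — all 13 of
them truly enriched in the generator's ground truth:

```r
head(dplyr::filter(tidy(env), category == "Upper"), 3)
#>   gene_id   n_muts observed weight lower upper  p_emp category
#> 1 sgene0028     27       13  0.150     0    11 0.0020 Upper
#> 2 sgene0048     15        9  0.150     0     7 0.0020 Upper
#> 3 sgene0109     28       15  0.150     0    11 0.0020 Upper
```

`observed` is the gene's SSM count, `lower`/`upper` the simulated
99.9% envelope for its `n_muts`, and `p_emp` the add-one empirical
two-sided p-value. `autoplot(env)` draws the mutations-versus-SSM
scatter with the envelope ribbon.

The same machinery on the published per-exon MLH1 assay counts (six
exon-8 mutations all splicing-disruptive, 5 of 7 in exon 15, none in
exons 4/5/7) at the 10% assay background flags exactly the two
reported exons:

```r
exon_esm_envelope(mlh1_exon_tallies(), weight = 0.10, seed = 1)
#>   exon_id     n_tested observed weight lower upper  p_emp category
#> 1 MLH1_exon4         8        0    0.1     0     4 0.819  Expected
#> 2 MLH1_exon5         8        0    0.1     0     4 0.839  Expected
#> 3 MLH1_exon7         7        0    0.1     0     5 1      Expected
#> 4 MLH1_exon8         6        6    0.1     0     4 0.0020 Upper
#> 5 MLH1_exon15        7        5    0.1     0     4 0.0020 Upper
```

From there, `gen_feature_table()` / `assemble_features()` feed
`train_rf()` and `predict_genomewide()`, and
`gen_population_variants()` feeds `delta_strata_compare()` and
`ss_variant_density()`; see the methods vignette
(`vignettes/splice-mutation-enrichment.Rmd`) for the models and their
assumptions.

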