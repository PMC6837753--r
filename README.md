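# ithbench

Tools to study how reliably intra-tumor heterogeneity (ITH) can be
estimated from a single whole-exome sequencing sample, and whether ITH
summaries carry prognostic value — exercised end to end on synthetic tumor
cohorts with known clone structure.

Tumors are mosaics of subclones. From one WES sample, deconvolution tools
infer clones and their cancer cell fractions (CCFs) from the variant
allele fraction (VAF) spectrum, via the standard allele model

    E[VAF] = rho * m * CCF / (rho * CN_t + (1 - rho) * 2)

(purity `rho`, multiplicity `m`, tumor copy number `CN_t`). How much those
reconstructions can be trusted, and whether their summaries predict
survival, is the question this package makes testable. It provides:

* **Synthetic cohorts** (`simulate_cohort()`): clone structures with
  separated CCFs, purity/copy-number-dependent VAFs with binomial read
  sampling, nested protected ⊇ public mutation views, confounders, and
  censored survival optionally driven by the true ITH features.
* **Somatic SNV filtering** (`build_mutation_sets()`): per-caller FILTER
  rules, population-frequency/COSMIC rule, tumor/normal coverage rules,
  indel removal, union across the four callers.
* **ITH features** (`extract_ith_features()`, `math_score()`): the five
  clone-level summaries (clone count, major-clone SNV fraction, minimum
  clone prevalence, Shannon index, largest-clone prevalence) and the MATH
  score `100 * MAD / median` of the VAFs.
* **Agreement metrics** between subclonal reconstructions:
  `score1B()` for clone numbers,
  `score1C()` — exact weighted 1-Wasserstein distance between CCF
  distributions — and `score2A()` — co-clustering agreement averaging
  Pearson, Matthews and V-measure coefficients, each rescaled against the
  worse of the two degenerate clusterings.
* **Survival evaluation** (`rank_svm()`, `concordance_index()`): a linear
  ranking SVM minimizing a squared hinge over comparable patient pairs
  with an L2 penalty, concordance index with jackknife standard errors,
  one-sided Noether test against 0.5, 5-fold cross-validation, Fisher
  aggregation and Benjamini-Hochberg correction, plus Cox-based clinical
  variable screening.
* **Orchestration** (`run_benchmark()`): the full factorial design —
  methods x mutation views x metrics x feature sets — with deterministic,
  provenance-stamped outputs.

## A worked example

```r
library(ithbench)

cfg <- benchmark_config(
  sim = sim_config(n_samples = 30, mutations_per_sample_range = c(40, 120),
                   survival_coeffs = c(0.5, 0, 0, 0, 0), seed = 101))
res <- run_benchmark(cfg)

res$comparisons$score2A["truth", ]
#>                 truth baseline0.1.protected    baseline0.1.public
#>             1.0000000             0.2952123             0.2171465

head(res$survival[, c("feature_set", "n_features", "median_ci", "p_adj")])
#>                     feature_set n_features median_ci        p_adj
#>                           truth          5 0.6666667 2.008797e-03
#>                  truth.n_clones          1 0.7666667 2.526941e-08
#>                   truth.squared         10 0.5000000 5.441986e-03
#>           baseline0.1.protected          5 0.6666667 2.540220e-01
#>  baseline0.1.protected.n_clones          1 0.6666667 1.631456e-12
#>   baseline0.1.protected.squared         10 0.6000000 3.568630e-01
```

The score2A row says the baseline reconstructor recovers roughly a
quarter to a third of the co-clustering structure of the ground truth
once rescaled against degenerate clusterings, and less on the sparser
public view. The survival table shows the kind of pattern the package is
built to expose: with a survival signal planted on the true clone count
(0.5 per-SD log hazard), the true clone count alone reaches a median
cross-validated concordance of ~0.77, while feature sets derived from
reconstructed clones are noisier and, at this small cohort size, mostly
lose significance after correction — reconstruction error eats into the
prognostic signal.

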