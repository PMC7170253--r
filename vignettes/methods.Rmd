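---
title: "Methods: multi-cohort prognostic signature discovery with pps20"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort prognostic signature discovery with pps20}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pps20)
```

# The model and its assumptions

The package's core statistical engine is the univariate Cox
proportional-hazards model applied gene by gene: for gene $g$ with log
expression $x_{gs}$ in sample $s$, the hazard is
$\lambda_s(t) = \lambda_0(t)\,e^{\beta_g x_{gs}}$, fit by partial
likelihood with the Efron approximation for tied event times. The only
structural assumption downstream machinery relies on is proportional
hazards; no parametric baseline is assumed anywhere in the analysis
path. Wald statistics provide p-values and 95% confidence intervals,
matching the default reporting of `survival::coxph()`, which backs all
Cox fits here (the independent test oracle is a from-scratch
maximization of the Efron partial likelihood, kept free of the
`survival` package so the two routes genuinely cross-check).

Gene prioritization is deliberately not a pure p-value sort. Each
cohort's genes receive a p-value rank and a rank on the *folded* hazard
ratio $\max(\mathrm{HR}, 1/\mathrm{HR})$ — folding makes a protective
HR of 0.4 rank as strongly as an adverse HR of 2.5 — and the sum of the
two ranks ("ranksum") orders the genes. The folded-HR rank protects
against tiny-effect genes that reach small p-values purely through
abundance and stability; the p-rank protects against large but noisy
effects. Ties in either component get average ranks, which keeps the
ordering invariant under permutation of the input (the natural choice;
any deterministic alternative would make the output depend on storage
order).

Discovery then proceeds set-wise: the top $K=500$ genes per discovery
cohort are intersected (membership in at least 2 cohorts), and the
survivors are refit in a held-out tuning cohort, where retention
requires $p < 0.05$ and the sign of the entry is the tuning cohort's
hazard direction. Genes whose tuning direction contradicts the
majority discovery direction are dropped by default: a signature with
internally contradictory directions is uninterpretable. (Whether the
original analysis imposed this direction-agreement requirement is not
documented; it is exposed as `drop_sign_flips` and logged.)

# Preprocessing rules

* **CPM**: $\mathrm{CPM}_{gs} = 10^6 \, c_{gs} / \sum_g c_{gs}$,
  computed on the full library before any gene filtering.
* **Zero filter**: genes with zero counts in *strictly more than* 85%
  of samples are removed. The boundary is deliberate: a gene at exactly
  85% zeros is kept. The filter is idempotent.
* **Log transform**: $\log_2(x + 0.001)$ for CPM and RSEM-like values.
  The source material is ambiguous about the log base for the RNA-seq
  cohorts ("log" vs "Log2"); a single base (2) is used for all
  platforms so scores remain comparable across cohorts, and the base is
  configurable. Note the median-split group assignment is invariant to
  the base (a monotone rescaling), so only raw score magnitudes are
  affected.
* **Probe collapsing**: microarray probes mapping to one gene are
  averaged arithmetically on the stored scale, without rescaling.
* **Survival hygiene**: samples with a recorded time of exactly 0 are
  excluded; day-scale times may be converted to months by division
  by 30 for display. Cox fits are invariant to the time unit, so the
  conversion is cosmetic by construction.

# Scoring and dichotomization

A sign signature's score is the signed sum of log expression; missing
signature genes are dropped (never imputed), mirroring the established
handling of platform gaps, with a default guard requiring at least 50%
of the signature present. Samples are split at the cohort median, with
exact-median samples assigned to the *low* group (`score > cutoff`
defines high). Tie placement is not specified by the source analysis;
the strict-inequality rule is the package's choice, configurable via
`ties_high`, and only matters when scores tie exactly at the median —
measure-zero for continuous expression.

Two useful exact properties, both under test: adding a constant $c$ to
every gene shifts every PPS20 score by $2c$ (11 positive minus 9
negative signs) and leaves median-rule groups unchanged; and scoring is
linear in the expression matrix.

# The synthetic world

`generate_cohort()` states the world downstream tests live in:

| parameter | default | rationale |
|---|---|---|
| genes × samples | 1000 × 200 | screen-scale but desk-fast; 200 matches the mid-size of real PDAC cohorts (102–178) |
| planted genes | 10 adverse + 10 favorable | the size of the target signature |
| $|\beta|$ | 1.0 per SD of log-CPM | a strong single-gene prognostic effect |
| baseline hazard | 0.04 / month | median survival ≈ 17 months under the null, typical of resected PDAC |
| censoring target | 0.35 | between the heavier censoring of registry cohorts and near-complete follow-up of trial series |
| NB dispersion | 0.15 | a standard bulk RNA-seq value |
| library sizes | $2\times10^5$–$2\times10^6$ | scaled down with the 1000-gene panel so per-gene depth is realistic |

Counts are negative-binomial with log-normal library sizes clamped to
the configured range; gene abundances are log-normal (sdlog 1.2),
giving the usual orders-of-magnitude spread. Event times are
exponential with hazard
$\lambda_0 \exp(\sum_g \beta_g z_{gs})$, where $z_{gs}$ is the
standardized log-CPM of planted gene $g$ — standardization makes
$\beta$ comparable across abundances. Censoring is independent uniform
on $[0, M]$ with $M$ solved numerically so the expected censored
fraction matches the target given the realized event times. The
planted-gene identities derive from the config seed alone, so cohorts
drawn with different sample seeds share a common truth — the structure
a multi-cohort discovery design needs.

What the generator does *not* emulate: gene–gene correlation beyond the
planted signal, batch/platform effects, non-proportional hazards, and
informative censoring. A green recovery test therefore establishes that
the pipeline machinery is correct and well calibrated under its own
assumptions — not that it is robust to the full messiness of public
cohorts.

One empirical property of this world is worth stating because it is a
genuine statistical effect, not a bug: with 20 independent planted
effects of $|\beta| = 1$, each gene's *marginal* univariate hazard
ratio is attenuated by the other 19 effects acting as unobserved
heterogeneity (classic omitted-covariate attenuation in proportional
hazards). Per-gene screen power at the default scale is therefore about
0.65–0.90 across seeds rather than near 1, and the tests freeze the
oracle-computed value at the stated seed rather than a hoped-for bound.
Full-pipeline recovery is less affected (rank aggregation plus
intersection needs only top-half membership per cohort) and exceeds
80% with a median-split validation that separates groups in 20/20
replicates.

# Comparator adapters and the drug screen

Published signatures are re-applied in two modes. *Weighted*: the
original coefficients multiply log expression (genes missing from a
platform are dropped from the sum, generalizing the published handling
of absent probes). *Binary cut-off*: per-gene cut-offs defined on a
reference platform are transferred to a target platform via the ratio
of medians — coefficient = reference cut-off / reference median, target
cut-off = coefficient × target median — then each gene is called 0/1
against its transferred cut-off, the calls are weighted and summed, and
a fixed decision threshold (1.709 by default) splits risk groups. The
transfer is exact only when the two platforms' scales are proportional;
it is an approximation and documented as such.

The drug screen Pearson-correlates per-cell-line signature scores with
per-drug AUC over lines with both values (drugs screened in fewer than
10 lines are removed first; outlier lines can be excluded by id). On
labeling: AUC is cytotoxic *resistance* (higher = less sensitive), so
under the package's default convention a drug whose AUC correlates
*negatively* with the score preferentially kills high-score lines. The
verbal convention in parts of the literature inverts this reading; both
are implemented (`convention = "auc_sensitivity"` or `"literal"`)
because published descriptions conflict, and neither is asserted as
the original intent. No multiplicity correction is applied by default
(matching the original nominal-significance reporting);
Benjamini–Hochberg is available.

# Numerical choices and degenerate inputs

* Cox fits with a constant covariate, fewer than two events, or a
  runaway coefficient (|coef| > 50, the monotone-likelihood signature)
  are flagged `degenerate` and excluded from ranking rather than
  erroring, so genome scans complete.
* Backward Wald elimination removes the worst covariate with Wald
  $p \ge 0.10$ per step (0.10 being the conventional removal
  probability of the stepwise procedure named in the source analysis,
  whose exact entry/removal settings are unreported) and records the
  full step history.
* The group Cox fit warns when one group has no events (CI unreliable
  under monotone likelihood).
* A 2×2 chi-square requires all margins positive; the Yates-corrected
  statistic is $\sum (|O-E| - 0.5)^2 / E$.
* Paired t-tests with zero-variance differences return a degenerate
  flag instead of an error (the comparison is ill-posed, not wrong).
* All generators run under an isolated RNG scope: they set the seed
  internally and restore the caller's RNG state, making every output a
  pure function of (config, seed).

# Known limitations

* The discovery design is a fixed discovery/tuning/validation split; no
  resampling or stability selection is offered.
* No proportional-hazards diagnostics or competing-risks models.
* GEO series-matrix files are read via a skip-prefix option, not a full
  series-matrix parser; RMA normalization of CEL files is out of scope.
* Cut-off transfer across platforms inherits any non-proportionality of
  the platforms' expression scales.
* The CLI configuration format is JSON (no YAML parser is available in
  the supported dependency set).
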