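---
title: "Methods: integrated phenotypic and proteomic target screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated phenotypic and proteomic target screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The screening problem

Candidate disease genes nominated by genetic and multi-omic studies far
outnumber the targets that can be taken into development. `tierscreen`
implements a desk-scale version of a functional triage strategy for such
candidates: knock each target down with siRNA in paired cell backgrounds —
a control line and a disease-sensitized line — then ask two questions per
target:

1. **Does the perturbation move disease-relevant cellular phenotypes?**
   (viability, mitochondrial membrane potential, phagocytosis, NF-kB
   reporter activity)
2. **Does the perturbation move disease-relevant molecular programs, and in
   the direction opposite to the disease?** (quantitative proteomics,
   summarized through gene-set enrichment grouped into biological domains)

A target supported on both axes — at least one phenotypic assay hit *and*
at least one biological domain whose enrichment signature significantly
reverses the disease signature — is called **top-tier**.

# Statistical model, stage by stage

## Phenotype hit calling

Raw assay readouts arrive as replicates nested in experimental batches.
For each assay, cell line and (where applicable) LPS dose:

1. replicates are averaged within each batch;
2. a log2 fold change is computed against the control-siRNA average of the
   same batch, cell line and dose (batch-level multiplicative effects
   cancel here by construction);
3. the per-batch log2 fold changes are modelled as
   `log2fc ~ 0 + target + (1 | batch)` by REML (`lme4::lmer`). The random
   intercept absorbs the residual within-batch correlation that the shared
   control average induces across targets;
4. each cell-means coefficient is its target's estimated marginal mean and
   is tested against zero, two-sided, with a normal reference by default;
5. p-values are Benjamini-Hochberg corrected within each
   assay x cell line x dose family, and hits are declared at adjusted
   p <= 0.05 (the boundary counts as a hit).

Cell lines are analyzed separately throughout; no contrast ever mixes
backgrounds. With fewer than two batches the model downgrades to ordinary
least squares with a logged message.

**Reference distribution.** The default z reference is exact as the number
of batches grows and is the deterministic, dependency-light choice. With
very shallow designs (three batches) the batch variance is estimated from
three levels, frequently lands on the boundary at zero, and the z tests
become anti-conservative on raw p-values; the calibration tests in this
package therefore check raw p at a seven-batch design and the
BH-corrected output of the full chain at the three-batch design. For
stricter small-sample calibration, `run_config(ref_dist = "satterthwaite")`
switches to t tests with Satterthwaite degrees of freedom via lmerTest;
this mitigates but does not remove the boundary-variance effect. Hits from
few-batch designs are best read together with their effect sizes.

## Differential protein abundance

Per protein and cell line, a one-way ANOVA across all siRNA groups
(control included), followed by Tukey HSD (Tukey-Kramer for unequal group
sizes) adjusted p-values for each target-vs-control contrast. The log2
fold change is the difference of group means on the log2 intensity scale.

Numerical choices:

* missing intensities are handled complete-case per protein and group,
  with a minimum of 3 observations per group (no imputation);
* samples with fewer than the configured number of detected proteins are
  excluded first (strict "fewer than"; default 6,100 for real-scale data,
  1,600 in the scaled reference simulation);
* with exactly two usable groups the studentized range reduces to the
  pooled two-sample t contrast and the implementation uses that closed
  form; for k > 2 the tail area comes from `ptukey`;
* zero residual variance is resolved exactly: equal means give F = 0,
  p = 1; unequal means give a flagged infinite-F record with p = 0.

## Preranked enrichment

Any signed gene-level statistic (per-knockdown log2 fold change, or the
disease effect vector) ranks the genes; each gene set is scored with the
weighted Kolmogorov-Smirnov running-sum statistic: member genes push the
running sum up by `|stat|^w` (normalized over members), non-members pull
it down by `1/(N - N_hit)`; the enrichment score (ES) is the signed
extreme. The weight exponent defaults to 1 (the classic preranked
weighting); 0 gives the unweighted statistic.

Significance uses gene-label permutation — the only null available for
preranked input. The normalized enrichment score (NES) divides the ES by
the mean magnitude of same-sign permutation scores; the p-value is the
add-one estimator over same-sign permutations, so p can never fall below
`1/(1 + n_perm)`. This plain permutation scheme was chosen over adaptive
multilevel estimators for transparency and testability; its calibration is
itself under test (permutation p-values are uniform under a permuted-label
null). Permutation nulls are shared across sets of identical intersection
size (the null depends only on the size), with a deterministic per-size
seed. Exact magnitude ties between the positive and negative extreme are
broken toward the positive side. BH correction runs across all tested sets
of a run; set-size filters default to 10-500 after intersection.

## Disease concordance and reversal

Perturbation and disease enrichment signatures are compared per biological
domain (a curated grouping of terms; the vocabulary lives in
`biodomain_vocabulary()`):

* **Zero imputation.** The union of terms significant in either analysis
  is taken; a term non-significant or absent on one side enters with
  NES = 0. This keeps one-sided responses in view while preventing
  non-findings from carrying rank information.
* **Kendall tau-b.** Within each domain (and target and cell line), the
  tie-aware tau-b rank correlation of the paired NES vectors, with the
  standard tie-corrected normal approximation for the two-sided p. Tau-b
  rather than plain tau because zero imputation creates ties by
  construction. Domains with fewer than 5 paired terms, or with a constant
  vector on either side, are reported untested and stay out of the BH
  family. A significantly negative correlation is labelled a **reversal**,
  a significantly positive one **concordant**.
* **Protein-level corroboration.** Per domain, Pearson correlation between
  knockdown log2 fold changes and the disease effects of their orthologs
  (one-to-many ortholog mappings are dropped and counted; minimum 10
  proteins).
* **Quadrant counts.** Terms are classified by the sign pattern of their
  paired NES values (up/up, down/down, up/down, down/up, one-sided); the
  counts always sum to the number of terms considered.

BH families default to all (domain x target x cell line) tests of a run;
the significance threshold feeding zero imputation is the same adjusted
p <= 0.05 used everywhere else.

## Integration and the top-tier rule

Across knockdown x cell line points, Spearman's rho links each assay's
marginal-mean effect sizes to each term's NES (minimum 10 points;
LPS-induced records are excluded because proteomes are collected without
induction). The top-tier rule is explicit and configurable:

> top-tier ⇔ (>= 1 assay hit in any assay/cell line/dose) AND
> (>= 1 biodomain labelled "reversal" in any cell line)

The reversal-direction requirement reflects the therapeutic logic — a
useful perturbation should push disease-shifted programs back — and can be
relaxed (`top_tier_require_reversal = FALSE`) to accept any significant
domain correlation. Tightening any rule parameter can only shrink the set.

# The synthetic screen and what it shows

`simulate_screen()` generates every input with planted ground truth. The
reference conditions (`synthetic_reference_configs()`): 12 targets, 2 cell
lines, 4 assays (3-7 batches, 3-4 replicates per batch, one assay dosed),
2,000 proteins, 100 terms of size 10-50 over 6 domains, 5 proteome
replicates per group, 8% missing-at-random dropout plus 2 degraded
samples, and 999 permutations — sizes at which the full pipeline and its
calibration suite run comfortably on one core.

The generative model mirrors the analysis assumptions:

* assay readouts are `baseline * 2^(effect + batch + noise)` — lognormal
  noise on the raw scale, normal on log2, batch intercepts
  `Normal(0, 0.25)`;
* each gene carries a latent *disease involvement*: positive mean (+1) in
  disease-up domains, negative (-1) in disease-down domains, centred at 0
  elsewhere (SD 0.3). The disease effect vector **is** this involvement,
  and planted reversals shift the planted domains' genes by
  `-0.8 x involvement` — the coupling through a shared latent axis is what
  makes domain-level rank correlation detectable, as in real data where
  both analyses measure the same underlying biology;
* the sensitized line amplifies every planted effect 1.5-fold and carries
  a disease-like baseline proteome shift (which cancels in within-line
  contrasts);
* the targeted protein itself drops by 1.5 log2 units;
* of the 12 targets, 3 are planted with dual evidence (2 assays each at
  -1 log2, plus reversal of one disease-up and one disease-down domain),
  2 with assay effects only, 7 with nothing. Reversal-only planting is off
  by default: under the shallow three-batch design a reversal-only target
  has a non-negligible chance of a spurious assay hit, which would turn
  the planted/called identity check into a coin flip; that verdict path is
  exercised by unit tests with explicit fixtures instead.

Effect magnitudes are chosen for testability (strong enough that recovery
is a property of the method, not of a lucky seed), not to claim realism in
physical units.

**What passing tests do and do not show.** The suite demonstrates internal
correctness (brute-force oracle equivalence for every statistic), honest
null calibration, parameter recovery (mixed-model bias < 0.05 log2 units
at 50 batches over 100 targets), and end-to-end recovery of planted truth
with no false top-tier calls. It does not show robustness to features the
generator omits: intensity-dependent (non-random) dropout, plate/spatial
effects beyond batch intercepts, off-target siRNA effects, correlated
noise across proteins, or annotation error in the term-domain map. An
intensity-dependent dropout option exists in the generator but is off by
default, matching an analysis that handles missingness only by sample
exclusion.

# Known limitations

* Few-batch assays inflate the z-reference type-I error (see above);
  the BH-corrected chain stays near nominal, and the Satterthwaite switch
  tightens raw calibration, but three batches cannot estimate a batch
  variance well under any reference.
* Permutation p-values are bounded below by `1/(1 + n_perm)`; with the
  test-scale default of 999 permutations, BH-adjusted significance
  saturates for strongly enriched terms. Raise `n_perm` (the full-scale
  default is 10,000) when term-level p-values matter beyond the threshold.
* Terms are flat gene sets: no ontology-graph reasoning, no redundancy
  trimming; overlapping terms contribute correlated evidence to their
  domain's rank correlation.
* The top-tier rule is a deliberate formalization of a narrative
  criterion; its parameters are exposed rather than hidden because
  reasonable screens may weight the proteomic side differently.
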