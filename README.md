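# tierscreen

Integrated phenotypic and proteomic screening for therapeutic-target
prioritization.

## The problem

Systems-level studies of complex diseases nominate hundreds of candidate
targets; deciding which are worth development resources is the bottleneck.
One answer is a functional triage screen: knock each candidate down with
siRNA in a relevant cell model — here, paired microglia-like backgrounds, a
control line and a disease-sensitized line — and keep only the targets
that (a) move disease-relevant cellular phenotypes and (b) push
disease-relevant molecular programs in the *opposite* direction to the
disease. `tierscreen` is a tested, reusable implementation of the full
analysis chain for such a screen, for computational biologists who want to
run, audit, or adapt the statistics without re-deriving them.

## The model at its core

Five stages, each behind an exported function and a TSV interface:

1. **Hit calling.** Replicate readouts are batch-averaged, converted to
   log2 fold changes against in-batch controls, and modelled with a
   random-intercept mixed model, `log2fc ~ 0 + target + (1 | batch)`
   (REML via lme4). Marginal-mean tests with BH correction define hits at
   adjusted p ≤ 0.05.
2. **Differential abundance.** Per protein and cell line, one-way ANOVA
   across siRNA groups with Tukey HSD contrasts against control;
   `log2FC = mean(target) − mean(control)` on log2 intensities, after a
   per-sample detected-protein QC filter.
3. **Preranked GSEA.** The weighted Kolmogorov–Smirnov running-sum
   statistic on any signed ranking (knockdown log2FC, or a disease effect
   vector), gene-label permutation p-values with the add-one estimator,
   sign-stratified NES, BH across sets, and biodomain annotation of terms.
4. **Concordance.** Perturbation and disease signatures are paired with
   zero imputation (non-significant/absent side → NES 0), then scored per
   biodomain with tie-aware Kendall τ-b; significantly negative domains are
   labelled **reversal**. Protein-level Pearson correlation through an
   ortholog map corroborates at the gene level; quadrant counts classify
   terms by sign pattern.
5. **Integration.** Spearman's ρ links assay effect sizes to term NES
   across knockdowns, and the top-tier rule combines the evidence:
   *top-tier ⇔ ≥ 1 assay hit AND ≥ 1 reversal domain*.

A synthetic-data module generates every input with planted ground truth
(batch effects, cell-line sensitization, domain-coherent reversals,
DIA-like dropout), so the whole chain is validated end to end against
known answers.

## Worked example

Run the reference synthetic screen (12 targets, 2 cell lines, 4 assays,
2,000 proteins, 100 terms over 6 biodomains, 3 planted dual-evidence
targets) end to end:

```r
library(tierscreen)

cfg <- synthetic_reference_configs(seed = 1)
run_all(cfg$sim, cfg$run, "my_run")

read.delim("my_run/verdicts.tsv")[, c("target", "n_hits",
                                      "n_reversal_domains", "top_tier")]
#>  target n_hits n_reversal_domains top_tier
#>  G00333      0                  0    FALSE
#>  G00334      4                  2     TRUE
#>  G00668      0                  0    FALSE
#>  G01001      0                  0    FALSE
#>  G01002      6                  2     TRUE
#>  G01335      0                  0    FALSE
#>  G01336      6                  0    FALSE
#>  G01669      1                  0    FALSE
#>  G01670      4                  0    FALSE
#>  G01998      0                  0    FALSE
#>  G01999      0                  0    FALSE
#>  G02000      4                  2     TRUE
```

Exactly three targets combine assay hits with proteomic reversals — and
they are the three the generator planted (`my_run/sim/truth_targets.tsv`
lists `G00334`, `G01002`, `G02000` as `dual`). Note the near-misses the
rule correctly rejects: `G01336` and `G01670` have plenty of assay hits
but no reversal evidence. The reversal calls themselves, in the
sensitized line:

```r
dk <- read.delim("my_run/domain_kendall.tsv")
subset(dk, direction == "reversal" & cell_line == "psen2_kd",
       c(target, biodomain, n_terms, tau, p_adj))
#>  target                biodomain n_terms    tau   p_adj
#>  G00334          Immune Response      17 -0.676 2.5e-04
#>  G00334 Mitochondrial Metabolism      17 -0.735 8.2e-05
#>  G01002         Lipid Metabolism      17 -0.765 4.8e-05
#>  G01002                  Synapse      17 -0.838 1.7e-05
#>  G02000          Immune Response      17 -0.559 2.3e-03
#>  G02000         Oxidative Stress      15 -0.708 3.6e-04
```

Each τ is the tie-aware rank correlation between a knockdown's term-level
NES values and the disease's, within one biodomain: strongly negative
means the knockdown pushes that domain's programs against their disease
direction. A thin CLI over the same functions lives at
`inst/scripts/screenpipe.R` (subcommands `simulate`, `kd-qc`,
`phenotypes`, `proteomics-de`, `enrich`, `concordance`, `integrate`,
`run-all`).

See `vignettes/target-screening-methods.Rmd` for the statistical model,
parameter semantics, and known limitations.

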