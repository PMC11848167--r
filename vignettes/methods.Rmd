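---
title: "Models and methods behind sexdim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexdim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexdim)
```

`sexdim` analyzes sex-dependent molecular changes in case-control
single-cell RNA-seq cohorts. This vignette documents the models, the
parameters that matter, the synthetic-data generator the tests rely on,
and the numerical and design choices a maintainer should know about.

## The differential expression model

Within one stratum — the cells of a single cell type and sex — each
gene's counts across cells are modeled as Poisson with a log link:

$$y_i \sim \mathrm{Poisson}(\mu_i), \qquad
  \log \mu_i = \beta_0 + \beta_1\,\mathbb{1}[\text{AD}_i] + \log s_i,$$

with $s_i$ a per-cell size factor treated as a fixed exposure offset. The
default size factor is each cell's total count divided by the median
total; `run_de(size_factors=)` accepts externally supplied exposures. The
AD-vs-control test is the likelihood ratio of this model against the one
without the condition indicator. With a single binary covariate the MLE
is analytic — each group's fitted rate is its total count divided by its
total exposure — so the deviance

$$D = 2\left[ Y_1 \log\frac{\hat r_1}{\hat r_0}
            + Y_2 \log\frac{\hat r_2}{\hat r_0} \right]$$

is computed in closed form (no IRLS) and referred to $\chi^2_1$. Tests
confirm equality with `glm()` refits to well below $10^{-6}$.

The reported effect size is
$\mathrm{logFC} = \ln\frac{\bar x_{AD} + 1}{\bar x_{HC} + 1}$ on
size-factor-normalized means. The +1 pseudocount keeps one-sided zeros
finite, at a cost discussed under *Numerical behavior* below. The natural
log is the default base because the conventional 0.25 effect-size
threshold is defined on that scale; `logfc_base` changes it.

Filtering and correction defaults: genes detected (count > 0) in fewer
than `min_pct = 0.1` of cells in both conditions are not tested; at least
`min_cells = 3` cells per condition are required; Benjamini–Hochberg is
applied within each stratum over the genes actually tested. Cells of one
subject are treated as independent observations, as is conventional for
per-cell GLM testing; this is a known pseudoreplication caveat, and the
covariate module's pseudobulk summaries are the subject-level complement.

## Sex-pattern classification

A feature is *significant* in a sex when its adjusted p is below `fdr`
(default 0.05) and its |logFC| exceeds `min_lfc` (default 0.25; 0 for
proteins, whose abundance scale differs). The categories, applied in
order:

| both sexes significant | same sign | `sex_neutral` |
|---|---|---|
| both sexes significant | opposite signs | `sex_dimorphic` |
| one sex significant | other nominal p > `nonsig_p` (0.1) | `male_specific` / `female_specific` |
| one sex significant | other nominal p ≤ `nonsig_p` | `ambiguous` |
| neither significant | | `not_significant` |

Two deliberate choices: the effect-size floor binds only the significant
sex (the other sex is constrained only through its p-value), and the
`ambiguous` bucket is explicit so the partition is exhaustive — a gene
significant in one sex whose other-sex p sits in (0.05, 0.1] is neither
specific nor shared, and hiding it in either bucket would bias both. A
feature tested in only one sex (e.g., filtered out by `min_pct` in the
other) is flagged and classified ambiguous: absence of a test is not
evidence of non-significance. Note the specificity rule has a built-in
ceiling: under a calibrated null the other sex's nominal p exceeds 0.1
for only ~90% of truly one-sex effects, so even perfect data recover at
most ~90% of specific genes on average.

## Enrichment and the term-level specificity rule

Over-representation uses the exact hypergeometric upper tail
(`stats::phyper`), never a normal approximation. The universe defaults to
the genes actually tested in the stratum's DE run — conditioning on
testability avoids detection-bias inflation — and sets are bounded to
[5, 500] members after universe intersection. The per-sex enrichment
tables are then compared term by term with the same specificity logic as
genes: male-specific iff male adjusted p < 0.05 and female nominal
p > 0.1, shared iff significant in both. Communication-pathway enrichment
(below) instead flags terms at nominal p < 0.05, matching the looser
convention for that screen; both thresholds are arguments.

## Cell-cell communication screening

The communication layer is deliberately plumbing, not a re-implementation
of model-based ligand-activity tools: genes expressed in >10% of the
sender/receiver cells (strict inequality) are intersected with a
ligand-receptor table, pairs with at least one DEG endpoint are retained,
and candidate ligands are ranked by the number of DEGs reachable from
them by directed paths in the prior regulatory network — "most relevant"
operationalized as greatest downstream DEG influence. The default
`top_n = 30` ligands mirrors common practice for communication figures.

## Phenotype-specific GRNs by genetic algorithm

Candidate interactions are the prior-network edges retained after
filtering (tissue match, the five regulatory mechanism classes: binding,
transcription regulation, influence on expression, co-regulation of
transcription, regulation; self-loops and duplicates removed) and
restricted to DEGs. Each DEG is Booleanized from its log fold change:
up in disease means $B_{AD}=1, B_{CTRL}=0$, down the reverse. An
activation edge is consistent with a phenotype when source and target
states agree there; an inhibition edge when they differ.

The objective: a target (any node with a candidate incoming edge) is
*explained* in a phenotype if at least one selected incoming edge is
consistent there, and

$$\mathrm{fitness} = \frac{\sum_{\phi} \#\text{explained}_\phi}
       {2\,\#\text{targets}} \;-\; \lambda\,
       \frac{\#\text{selected}}{\#\text{candidate}},$$

with $\lambda = 0.01$ breaking ties toward parsimonious networks. This is
the simplest Boolean-alignment objective consistent with the construction
it emulates, stated explicitly so results are interpretable. Because all
nodes are DEGs, control states are the exact complement of disease
states, which makes consistency coincide across phenotypes; the
implementation nevertheless evaluates both, so non-complementary state
inputs remain valid.

The chromosome carries one inclusion bit per edge plus one sign bit per
unknown-sign edge — sign deduction is joint optimization, not a greedy
post-pass. GA defaults: population 200, up to 500 generations, stagnation
stop at 50, uniform crossover 0.9, per-bit mutation $1/L$, tournament
k = 3, elitism 2; all runs are reproducible from the seed. On small
instances the GA attains the exhaustive-search optimum (tested over
random ≤12-bit instances) and never falls below a greedy marginal-gain
baseline.

Rankings on the selected network: a node's *perturbagen* score is its
count of downstream-reachable nodes (full reachability, not just direct
targets — `mediator_subnetwork()` provides the upstream view); a node's
*mediator* score is ancestors × descendants, the top node being the key
mediator. Both are validated against brute-force BFS enumeration.

## Proteomics moderation

Each protein is fit per sex by least squares on
`abundance ~ condition + age` (complete-case per protein, ≥3 samples per
condition; a rank-deficient design drops age with a warning). Residual
variances are shrunk under a scaled inverse-chi-squared prior whose
hyperparameters $(d_0, s_0^2)$ are estimated by the closed-form method of
moments on $\log s^2$ (via `limma::fitFDist`); the posterior variance
$(d_0 s_0^2 + d\,s^2)/(d_0 + d)$ yields moderated t on $d + d_0$ df,
capped at the pooled residual df. Setting `d0 = 0` reproduces ordinary
per-protein t-tests exactly, `d0 = Inf` pools completely, and the whole
per-sex route matches `limma::lmFit() + eBayes()` to ~1e-8 in tests.
Protein patterns reuse the gene classification rules with effect sign in
the logFC role and no effect-size floor, and the transcript-protein
intersection reports per-category overlaps without silently dropping
unmapped identifiers.

## Covariates

Subject-level pseudobulk (mean size-factor-normalized expression over a
subject's cells of one type, ≥3 cells) avoids pseudoreplication in
covariate correlations. Spearman's rho is the Pearson correlation of
mid-ranks (average ranks on ties); p comes from the t-approximation on
n−2 df, with exact permutation enumeration available for n ≤ 8 (beyond
that the approximation is accurate and enumeration needlessly slow).
Braak stage is ordinal 0–6 and controls' undefined stage is excluded from
Braak correlations; BH is applied within each covariate × sex block.

## The synthetic-data generator

The generator emulates the structure of an aged-brain case-control atlas
cohort: four groups (controls and early/intermediate/late disease) with
sex-stratified sizes defaulting to 146 (72 M/74 F), 19 (14/5), 59
(37/22), 82 (28/54) — 306 subjects; disjoint Braak ranges (none, 0–II,
III–IV, V–VI); ages ~N(86, 6²); integer MMSE drawn below 20 for patients
and in [20, 30] for controls. Counts are negative-binomial with log-link
(Poisson at `dispersion = 0`): a lognormal gene × cell-type baseline
(default meanlog log 0.8, sdlog 0.7 — a sparse scRNA-like regime),
lognormal per-cell size factors (sdlog 0.3), and, for planted genes in
their target cell type, a multiplicative disease effect
$e^{d_s \cdot \Delta}$ whose per-sex direction $d_s$ encodes the planted
category. The default NB dispersion 0.25 deliberately violates the
Poisson DE model to exercise robustness. Per-subject cell counts are a
parameter (no published value exists to emulate); the pipeline demo uses
50 cells/subject, 500 genes, 3 cell types and runs in seconds.

What the generator does *not* emulate: ambient RNA, doublets, batch
effects, or gene-gene correlation beyond the planted network. Passing
tests therefore demonstrate correctness of the statistical machinery
under its stated models, not robustness to every artifact of real data.

### Calibration and recovery experiments

Two benchmark experiments are wired into the tests and the acceptance
script, with problem sizes chosen to finish in seconds:

* **Type-I error.** 2,000 null Poisson genes at 200 cells/condition per
  replicate, with the generator's true exposures supplied as known
  offsets; the rejection rate at p < 0.05 is pooled over eight fixed
  replicate seeds because a single replicate's binomial SE (~0.005) is
  material at this size. With offsets instead re-estimated from
  median-normalized totals the rate runs slightly high under lognormal
  exposure variation (~0.054) — an offset-estimation property worth
  knowing, not an LRT defect.
* **Category recovery.** 40 genes per planted category (|logFC| = 0.8,
  balanced up/down directions) among 2,000 genes at 500
  cells/stratum/condition, Poisson counts, baselines lognormal(log 2,
  0.3). Three design points matter. Balanced directions: one-sided
  planting shifts perturbed cells' size factors and biases all other
  genes' logFC (a compositional artifact of normalization). Well-expressed
  planted genes: the +1 pseudocount compresses observed logFC, and
  down-regulated low-baseline genes cannot clear the 0.25 floor at
  Δ = 0.8. Poisson counts: under NB overdispersion the Poisson test's
  other-sex nominal p is anticonservative, absorbing specific genes into
  `ambiguous`; recovery under overdispersion is a documented limitation
  of the nominal-p specificity rule, not of the planting. Observed
  recovery is 91–95% across seeds with zero dimorphic↔specific
  confusions.

## Numerical choices and degenerate inputs

* All-zero count rows yield a defined degenerate LRT result (deviance 0,
  p 1, flagged) rather than an error.
* DE output ordering is fully deterministic: adjusted p, then |logFC|
  descending, then gene symbol; enrichment by adjusted p, p, term;
  rankings break ties by symbol. Diffable output was a design goal —
  every TSV carries a provenance header (tool version, config hash,
  seed), the pipeline writes a checksum manifest, and reruns from the
  same config are byte-identical (the config hash excludes the output
  directory for exactly this reason).
* A perfect protein fit (zero residual variance) reports t = 0, p = 1
  via an explicit numerical-zero snap instead of a 0/0 ratio.
* GMT parsing deduplicates members with a warning and rejects duplicate
  set names; table readers validate enumerated columns against their
  vocabulary and report missing columns by name.

## Known limitations

* No negative-binomial or mixed-model DE alternative; subject-level
  random effects are not modeled in the per-cell GLM.
* The ligand ranking is reachability-based plumbing, not a calibrated
  ligand-activity model.
* No GO-DAG redundancy trimming or ranked GSEA; no TMT normalization or
  peptide rollup (proteomics input is an already-normalized matrix).
* The interaction-term alternative to stratified testing is intentionally
  out of scope: it demands more power and is fragile when log fold change
  variance is high.
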