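---
title: "Functional burden association testing: models, choices, and what the synthetic cohorts show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional burden association testing: models, choices, and what the synthetic cohorts show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Rare copy number variants (CNVs) — deletions and duplications of multi-kilobase
segments — are individually too rare for locus-level association studies outside
a handful of recurrent loci. Functional burden association testing (FunBurd)
aggregates them by biological function instead: genes are grouped into gene
sets defined by shared expression context (a tissue or a cell type), and each
sample's burden on a set is the number of set-member genes its CNVs fully
encompass. A CNV only counts against a gene it covers completely, because
partial overlap does not reliably change gene dosage. Deletions and
duplications are always analyzed separately: they move dosage in opposite
directions, and whether a trait responds monotonically to dosage is itself a
question the framework answers.

This package implements the full analysis chain — gene-set construction,
burden aggregation, the association grid, overlap-aware permutation inference,
between-trait burden correlations, constraint-normative modelling, and
dosage-response classification — together with a synthetic-cohort generator
that plants known effects so every stage can be validated end to end.

## Gene sets by Top Decile Expression Proportion

For each gene, its expression in a context is divided by its total expression
across contexts; for each context, the set contains the top decile of genes by
that proportion (`expression_proportion()`, `build_tdep_sets()`). Choices the
construction leaves open and how this package resolves them:

* **Zero-total genes** have undefined proportions and are excluded from the
  eligible universe *before* the decile is taken.
* **Set size** is `ceiling(decile * n_eligible)`; with small universes "top
  decile" must round, and ceiling keeps sets non-empty.
* **Ties** at the decile boundary are broken by proportion (descending) then
  gene identifier (ascending), so results are identical across platforms.
* **Brain / non-brain labels** are curated metadata supplied with the sets,
  never inferred from the data.

TDEP sets overlap by construction (a gene can sit in the top decile of several
contexts); the pairwise Jaccard matrix (`jaccard_matrix()`) is both a
descriptive summary and the structure that the permutation inference below
conditions on.

## The association grid

Each (gene set, trait, dosage type) cell is a regression
(`fit_funburd()`):

$$\mathrm{Trait} = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \beta_3\,\mathrm{age}
  + \beta_4\,\mathrm{sex} + \textstyle\sum_{i=1}^{10} \mathrm{PC}_i + \varepsilon$$

where $x_1$ counts distinct set-member genes fully encompassed by the sample's
CNVs of that type and $x_2$ counts the non-member genes disrupted alongside —
the adjustment that stops large multigenic CNVs from inflating $\beta_1$. By
default $x_2$ counts non-members only in CNVs that also hit a set member
(`x2_scope = "same_cnv"`); the alternative `"all_cnvs"` counts non-members
across all of the sample's CNVs of that type, and both are exposed because the
per-sample semantics of "the same CNV" is genuinely ambiguous once a sample
carries several. A gene hit by two same-type CNVs counts once: the predictor
is the number of genes disrupted, not the number of events.

Continuous traits are preprocessed the way biobank GWAS pipelines do:
missing values removed, values beyond ±6 SD dropped (`outlier_filter()`),
then the inverse rank normal transformation (`irnt()`, rank offset
$(r - 0.5)/n$ with average ranks for ties — the transformation is
rank-invariant, so the offset convention only fixes the exact quantiles).
Binary traits enter raw as 0/1 outcomes via logistic regression with the same
design; their $\beta_1$ is on the log-odds scale and is converted to the
liability scale (`liability_transform()`,
$\beta \cdot \phi(t)/(K(1-K))$, $t = \Phi^{-1}(1-K)$) only where effects must
be comparable across traits.

Cells with no burden variation (no carriers) are not dropped: they are flagged
non-estimable and carry $p = 1$, so the grid stays the complete
sets × traits × 2 rectangle and Benjamini–Hochberg FDR (`fdr_correct()`) is
applied jointly over all of it. At the full study configuration of 172 sets
and 43 traits this rectangle has 14,792 cells. Functional pleiotropy
(`pleiotropy()`) is then simply the number of traits significant for a set at
q < 0.05, per dosage type.

## Overlap-aware permutation inference (P-Jaccard)

Statistics computed across gene sets — for example the correlation between
per-set constrained fraction and per-set pleiotropy — cannot be tested by
treating sets as independent observations, because overlapping sets share
genes. The package's null (`pjaccard_correlation()`, `pjaccard_generic()`)
permutes the *gene-level* attribute over the universe and pushes it through
the unchanged set memberships. Every null replicate therefore has exactly the
observed Jaccard structure; only the attachment of attribute values to genes
is random. This is the strongest form of conditioning on overlap that still
admits a deterministic, seedable implementation. Empirical p-values use the
two-sided add-one estimator $(1 + \#\{|T^\ast| \ge |T|\})/(B + 1)$, which is
conservative and never returns zero. For statistics derived from regression
profiles rather than directly from a gene attribute (deletion–duplication
effect correlations, burden-correlation cells), the profile is first mapped to
gene-level scores (each gene takes the mean coefficient of the sets containing
it) so the same permutation scheme applies; for disjoint sets this mapping is
exact and the scheme reduces to a naive permutation test.

Calibration is checked empirically in the test suite: over 500 simulated
datasets with heavily overlapping sets and an iid gene attribute, the
rejection rate at 0.05 stays inside the binomial 95% interval around 0.05.

## Between-trait burden correlations

The burden correlation between two traits is a rare-variant analogue of
genetic correlation:

$$r_g(T_1, T_2) = \frac{\mathrm{Cov}(\beta^{(1)}, \beta^{(2)})}
 {\sqrt{h^2_{T_1}\, h^2_{T_2}}}$$

with the covariance taken across retained gene sets. The ingredients, in
order (`burden_correlations()`):

1. **Residualization** (`residualize()`): covariates are regressed out of each
   trait; binary traits use a logistic fit and the response-scale residuals
   are treated as continuous downstream (with a lightly ridge-penalized
   fallback when the logistic fit separates).
2. **Redundancy filter** (`lasso_selection()`, `filter_genesets()`): a set is
   excluded only when it is *both* highly overlapping (rank percentile of its
   maximum pairwise Jaccard similarity above 0.2 — redundancy against its best
   partner, a concrete reading of "similarity percentile") *and* zeroed out by
   cross-validated LASSO (one-SE rule, fixed fold seed) in at least 80% of
   traits. Either signal alone is not enough: high overlap with independent
   signal, or dispensability without overlap, keeps a set.
3. **Effect profiles** (`shrinkage_profile()`): a joint ridge regression of
   the residualized trait on all retained burdens. Ridge, not LASSO, because
   overlapping sets should share signal rather than have one arbitrarily
   selected; the penalty is chosen by 10-fold cross-validation with a fixed
   seed. Binary-trait profiles are liability-converted before covariances.
4. **Variance explained** (`variance_explained()`): the $R^2$ of the
   unpenalized multiple regression on the same retained burdens, the proxy
   for each trait's burden heritability in the denominator.

The retained-set list is fixed globally across traits, because the covariance
requires profiles indexed identically. $r_g$ is reported unclamped with an
`out_of_range` flag: when the $R^2$ proxies are small, sampling noise can push
it past |1|, and silently truncating would hide that.

One calibration caveat, verified on synthetic cohorts: the ratio above equals
the planted effect-vector correlation only when the total burden variance is
commensurate with the trait scale. When it is not, recovered $r_g$ is a
monotone, sign-preserving, zero-preserving transform of the planted
correlation but not equal to it in magnitude. The recovery checks therefore
assert monotonicity in the planted $\rho \in \{-0.5, 0, 0.5\}$, correct signs,
and correct bracketing of zero — not magnitude equality. Summary comparisons
between dosage types use `sign_concordance()` (percentage of trait pairs with
matching signs) and `fold_ratio()` (ratio of mean absolute correlations).

## Constraint and the normative model

Genetic constraint enters as precomputed top-decile flags for any of the
published metrics (LOEUF, pLI, missense-Z, CDS conservation, pHaplo, pTriplo,
s-het, gene length); nothing is recomputed from sequence data. A set's
constrained fraction (`constrained_fraction()`) is the share of members in the
top decile, and its correlation with pleiotropy is tested by the P-Jaccard
null with the flags as the gene attribute.

The normative model (`normative_model()`) asks how much pleiotropy a gene set
*of a given constrained fraction* should show: for each fraction on a grid,
it repeatedly samples sets of fixed size without replacement
(⌊f·size⌋ constrained + the rest unconstrained), runs the full FunBurd
analysis for each (`make_funburd_runner()`), and summarizes the pleiotropy
draws as centile curves. An observed set is then scored as an empirical
centile of the matched-fraction null (`normalized_pleiotropy()`), flagged as
an outlier outside the 5th–95th band. Choices:

* Resamples are **per fraction point** (the documented default is 100 draws
  per point; the cohort-scale set size of 1,298 genes is the documented
  default, configurable downward for small universes).
* The centile uses the **midrank convention**, which avoids 0/100 saturation
  when the null has ties — and the null *does* have heavy ties, because
  pleiotropy is a small non-negative count that is zero-inflated under the
  null. A consequence worth knowing: with heavy ties the 5–95 band covers
  *more* than the nominal 90% of null draws, so coverage checks bound it from
  below.
* Fractions outside the band grid are refused rather than extrapolated.
* The default fraction grid spans 0–0.6 in steps of 0.05, covering the
  constrained fractions real expression-defined sets exhibit.

## Dosage-response classification

Pairing each set–trait's deletion and duplication cells
(`classify_responses()`): a response is *null* when neither is
FDR-significant; otherwise its sign class is *monotonic* when the two effects
oppose (del·dup < 0 — the signature of a trait tracking gene dosage) and
*non-monotonic* otherwise, with a zero effect classed non-monotonic as the
determinate degenerate rule. The evidence tier separates *truly*
monotonic/non-monotonic responses (both types significant) from
*undetermined_del* / *undetermined_dup* (one type significant). Sign classes
are assigned to undetermined responses too, so the monotonic share can be
computed over all non-null responses. Functional overlap between variant
classes (`functional_overlap_test()`) fixes the reference list and redraws the
CNV-significant list uniformly from the set universe, with the observed
overlap normalized by the CNV-side count — the permuted side is the
denominator.

## The synthetic cohort generator

`synth_config()` / `simulate_cohort()` emulate the inputs the real analysis
consumes, at desk scale, with complete ground truth:

* **Genome**: genes laid out disjointly with equal lengths and gaps, so a CNV
  can be placed to encompass an exact contiguous run of genes.
* **Expression**: planted marker genes express >90% of their total in their
  assigned context; background genes are near-uniform. TDEP provably recovers
  markers inside their context's set, which is what the ≥95% recovery check
  exercises.
* **CNVs**: counts per sample per type are Poisson(`cnv_rate`); genes per CNV
  are 1 + Poisson(`cnv_gene_span_mean` − 1) — the simplest shapes producing
  sparse multigenic CNVs.
* **Traits**: the generative mirror of the burden regression — planted per-set
  effects on marker-set burden, a per-gene background effect, age/sex/PC
  effects, Gaussian noise; binary traits threshold the standardized liability
  at $\Phi^{-1}(1-K)$. Trait pairs with a planned burden correlation draw
  per-set effect pairs from a bivariate normal with the requested
  correlation, giving `burden_rg()` a closed-form truth to recover.
* **Constraint**: markers of effect-carrying contexts are labeled constrained
  first, then random genes fill the configured fraction — so constraint
  correlates with planted effects, as it does in real cohorts.
* **Determinism**: one RNG stream, consumed in documented order; identical
  config + seed reproduces the cohort byte for byte.

Default conditions (2,000 samples, 1,200 genes on 4 chromosomes, 8 contexts,
40 markers each, 0.2 CNVs per sample per type, 3 genes per CNV, 10%
constrained, unit noise) were chosen once as a realistic desk-scale miniature
of a biobank CNV study: CNV carriers are a few percent of samples for any
given set, which preserves the rare-variant character of the inference.

What the generator deliberately does **not** emulate: real genome coordinates,
linkage disequilibrium, array-probe noise, CNV-calling artifacts, ascertainment
bias, or correlated expression programs across contexts. Passing tests
therefore demonstrate that the statistical machinery is correct and calibrated
under the stated generative model — not that any particular biological finding
would replicate.

## Numerical choices and test scales

* Non-estimable cells: $\beta = 0$, $p = 1$, flagged — never dropped.
* Permutation p-values: add-one estimator, floor $1/(B+1)$; default
  $B = 1000$, with a warning below 100.
* Penalized fits standardize predictors internally and report coefficients on
  the original count scale; fold assignments are seeded.
* Tabular outputs are TSV at 6 significant digits; the pipeline manifest
  records seeds, checksums, grid dimensions and versions.

The validation suite runs at reduced problem sizes chosen to keep the full
suite in a few minutes while leaving every assertion statistically meaningful:
cohorts of 1,000–2,000 samples, universes of 1,200–10,000 genes, 500-dataset
calibration runs, 1,000-rep permutation nulls, 100-resample normative bands at
set size 100, and 30–50-rep recovery loops. The same machinery scales to the
full configuration (172 sets × 43 traits × 2 types) unchanged.

## Known limitations

* The P-Jaccard scheme conditions on overlap by gene-label permutation; other
  readings of "permutation conditioned on the Jaccard distance" (e.g.
  resampling sets at matched distances) exist and could give different nulls.
* Burden $r_g$ magnitudes are scale-calibrated only under commensurate burden
  and trait scales (see above); signs, zeros and orderings are robust.
* The LASSO/Jaccard redundancy filter is rank-based, so with very few sets the
  percentile threshold cannot be met and the filter retains everything (with
  a warning when fewer than two sets would survive).
* Logistic cells with very low prevalence and few carriers can be unstable;
  the non-estimable contract catches the degenerate cases but not
  near-degenerate ones — at biobank scale this matters less than at test
  scale.
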