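---
title: "Multi-view association analysis of CSF biomarkers and elements: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view association analysis of CSF biomarkers and elements: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfmetals)
```

# The scientific problem

Alzheimer's disease (AD) pathology is reflected in cerebrospinal-fluid (CSF)
biomarkers: amyloid-β~1-42~ falls, total tau and phospho-tau isoforms rise,
and markers of neurodegeneration (VILIP-1, NFL) and glial activation (S100B,
YKL-40) increase.  At the same time, both non-essential heavy metals (As, Cd,
Hg, Pb, Tl, Ni) and essential metals (Ca, Cu, Fe, Zn, ...) are implicated in
tau hyperphosphorylation and amyloid aggregation.  This package implements a
three-stage statistical pipeline for asking, in a memory-clinic cohort with
an AD / mild-cognitive-impairment (MCI) / healthy-control (HC) composition,
whether macro- and microelement concentrations measured in CSF and plasma
are associated with CSF biomarkers of AD:

1. **Correlation screen** — all biomarker × element pairs, Spearman (and
   Pearson) on pairwise-complete observations, gated at p ≤ 0.001, with
   confounder-adjusted re-testing.
2. **Factor analysis** — PCA with varimax rotation per element view,
   adequacy diagnostics (Bartlett sphericity, KMO), ≥ 0.4-loading group
   assignment, per-patient factor scores, and multiple regression of each
   biomarker on the scores.
3. **Redescription mining** — discovery of patient subgroups jointly
   described by AND-only interval rules over two or three attribute views,
   filtered by support bounds, Jaccard accuracy and an exact random-subset
   significance model.

Because the patient data this kind of study rests on are not publicly
deposited, the package's first-class module is a synthetic cohort generator
with the same structure, so every stage can be validated against known
ground truth.

# The synthetic cohort

`generate_cohort()` draws, by default, 124 AD + 50 MCI + 19 HC patients
(193 in total) with plasma elements measured in a 143-patient subset.

**Concentrations are log-normal.**  ICP-MS concentration data are strongly
right-skewed; each element attribute has a log-scale location chosen so its
median falls in the range a clinical panel reports (e.g. CSF Se ≈ 1.3 µg/L
with typical values 0.3–4, CSF K ≈ 120 mg/L), and a log-scale spread of 0.6
for trace elements, 0.25–0.35 for homeostatically regulated electrolytes.

**Correlated element blocks** are induced by a Gaussian copula: one latent
factor per block, each member loading √ρ on it.  The defaults mirror the
dominant structure such data show — a large CSF block of 16 co-varying
elements, a heavy-metal block (Al, Cd, Pb), B+Li, Hg+Mo, and analogous
plasma blocks.  The pairwise within-block correlation is exactly ρ on the
log scale.

**Biomarkers load on a latent severity score** shifted by diagnosis
(AD > MCI > HC): amyloid-β~1-42~ negatively, tau isoforms and the
neurodegeneration/glial markers positively, plus a loading on the dominant
CSF element factor.  This gives the screen and the factor regressions
recoverable signal with the sign structure real cohorts show.  MMSE is an
integer 0–30 derived from severity; APOE genotype frequencies are
enriched for ε4 in AD.

**Missingness is completely at random per attribute**, with defaults that
reproduce the varying per-assay *n* of a real panel (e.g. NFL in ~62% of
patients, CSF P in ~40%).  Missingness is applied *after* planting, so a
planted member with a masked cell simply drops out of rule supports.

**Planted redescriptions** (`planted_redescription()`) embed ground-truth
cross-view subgroups: members receive values uniformly inside every listed
interval; each non-member satisfies a view's full condition set with
probability `leak_fraction` (otherwise at least one condition is pushed
outside by redrawing from the marginal).  With subgroup size *m*, leak ε and
cohort size *n*, the expected cross-view Jaccard of the true rules is
approximately m/(m + 2εn), which the tests verify by Monte Carlo.

What the generator deliberately does **not** model: assay-noise mechanisms
(ELISA plate effects, ICP-MS drift), longitudinal measurements, informative
missingness, and any real biochemical coupling beyond the latent-factor
structure.  Passing tests on this cohort therefore show that the pipeline
recovers the *kind* of structure it targets, not that any specific
biological association is real.

# Correlation screen

`correlate()` computes Spearman as Pearson on average ranks and takes the
p-value from the t approximation with n − 2 degrees of freedom on
pairwise-complete pairs; pairs with fewer than 3 complete observations are
skipped, and zero-variance vectors raise a typed condition.
`screen_associations()` emits one record per (biomarker, element, view)
pair with both coefficients; the reported `r`/`p` follow the `method`
argument (Spearman by default).  The multiple-testing correction is
operationalized as its stated consequence, a fixed p ≤ 0.001 gate; the gate
is a parameter.  Since real reports mix r~S~ and r without a stated rule,
both are always emitted and no per-pair auto-switch is attempted.

`adjust_association()` re-tests a pair given clinical covariates by
residual-on-residual partial correlation: ranks first for Spearman,
categorical covariates one-hot encoded, complete cases per model, p from a
t reference with n − 2 − q degrees of freedom (q = covariate design
columns).  A dependence induced solely through age is de-flagged with power
≥ 0.95 at n = 193; a direct effect orthogonal to the covariates is
retained.

# Factor model

`fit_factors()` standardizes the complete-case element submatrix (CSF
phosphorus is dropped by default — it is measured in too few patients to
enter a complete-case PCA), extracts the first six principal components
(six factors being the conventional choice for this panel; an
eigenvalue > 1 rule is available via `n_factors = "kaiser"`), and applies
varimax rotation with Kaiser row normalization (tolerance 1e-10).  Column
signs are fixed so each factor's largest-magnitude loading is positive.
Rotation is orthogonal, so communalities, total explained variance and the
reduced-rank reconstruction error are invariant — asserted to 1e-8 in the
tests.

`assign_groups()` implements the ≥ 0.4 rule: an element joins the factor of
its largest absolute loading if that loading reaches the threshold,
otherwise it is listed as unassigned together with its best loading, so
sub-threshold near-misses stay visible instead of being silently promoted.
Negative loadings assign by magnitude and keep their sign in the report.

Factor scores use the regression (Thompson) method on the standardized
data — the default of mainstream statistical packages.  `kmo()` and
`bartlett_sphericity()` are implemented from their closed forms
(anti-image partial correlations; −(n−1−(2p+5)/6)·ln det R) and are
cross-checked in the tests against independently coded oracles.

`regress_on_factors()` fits one multiple linear regression per biomarker on
all factor scores simultaneously and reports standardized coefficients with
conventional per-coefficient standard errors.  Published tables of this
kind sometimes repeat one SE across factors for a biomarker, suggesting a
per-model residual quantity; the package deliberately reports the standard
per-coefficient SE and documents the divergence here.

# Redescription mining

A *redescription* is a tuple of AND-only conjunctive queries over distinct
views describing nearly the same patients; its accuracy is the Jaccard
index of the query supports, and its significance is the probability that
uniformly random subsets of the same sizes intersect at least as much.

**Rule semantics.**  Intervals are closed on both ends; a patient is
described only if every condition's attribute is measured and in range
(missing ⇒ not described).  Interval endpoints are snapped to attained data
values, so rules read like `csf_Se (1.62-3.49)`.  Clinical query attributes
(MMSE, age, APOE genotype) ride on the biomarker view, where such rules
appear in practice; only positive categorical equalities are expressible —
the complement branch of a categorical tree split is grown but not
harvested.

**Rule induction** uses multi-target variance-reduction trees (the
predictive-clustering-tree idiom): a depth-limited tree (default depth 3,
minimum node size 10) predicts a 0/1 membership-target matrix from one
view's attributes; every root-to-node path becomes a candidate query,
filtered by support bounds and rule length.  Split search scans up to 24
evenly spaced candidate thresholds per attribute — a deliberate coarseness
that regularizes against chasing individual patients.

**The alternation.**  Each of 10 runs starts from a seeded k-means
clustering (k = 8).  Runs differ in their random initialization in two
ways: the RNG stream, and — from the second run on — the attribute subspace
that is clustered (a random third of the view's attributes).  Full-view
Euclidean k-means washes out subgroups that are distinctive in only two or
three attributes; subspace initializations let different runs see different
low-dimensional structure.  For 30 iterations, rules are induced on each
view using the latest rule supports of the next view (round-robin) as tree
targets, with the partner view's initial clustering kept among the targets
as an anchor.  Each induced rule is paired with its best-matching target
rule; these *matching pairs* are candidate redescriptions alongside the
full cross-view combination scan.  A supplement forest (20 bootstrap trees
per view with random attribute subsets, each chasing a single randomly
chosen partner rule) adds diversity once per run.

**Refinement.**  Candidates are greedily improved by ANDing single
conditions from the same view's discovered-rule pool — kept only when the
Jaccard strictly increases and the support stays at or above the minimum —
followed by a support-closure pass that rewrites each interval as the
bounding box of the redescription's own support when that strictly improves
the Jaccard.  Refinement can only tighten rules, never widen them.

**Filters and significance.**  Emitted redescriptions satisfy support
bounds (protocol presets: 30–155 for CSF pairs, 30–115 for plasma pairs,
20–110 for three-view), Jaccard ≥ 0.5 and p ≤ 0.01.  For two sets the
p-value is the hypergeometric upper tail; for three sets an exact two-stage
hypergeometric convolution (used whenever n ≤ 500; seeded Monte Carlo
beyond).  Both are verified against exhaustive bitmask enumeration at
n ≤ 12.  Results are deduplicated by (support set, attribute multiset),
keeping the higher Jaccard, then the shorter rule, and sorted by p-value.

**Specificity labels.**  Per-diagnosis percentages are shares of each
diagnostic group inside the support.  A single-group label (AD, MCI, HC)
requires that group's percentage to be ≥ 1.5 × each other group's; an
adjacent two-group label (AD&MCI, HC&MCI) requires both to dominate the
third the same way; otherwise `none`.  The 1.5 dominance ratio is a package
convention — published analyses extract labelled subgroups without stating
a rule — and is a parameter.

## Known limitations of the significance model

The random-subset p-value is computed per candidate and does not account
for the size of the search: a run scores on the order of 10^4^–10^5^
cross-view rule combinations, and rules with supports near the upper bound
have a *random* expected Jaccard above 0.5 (two random 150-of-193 subsets
overlap in ~117 patients on average, J ≈ 0.64).  On cohorts whose views are
genuinely independent, the miner therefore still emits co-adapted
redescriptions whose naive p-values pass 0.01 — a property of naive
significance models in rule search generally, not of this implementation
specifically.  The package reports this honestly: the null false-discovery
audit in the acceptance suite measures hundreds of emitted redescriptions
per null cohort, and mined results on real-structure cohorts should be read
as descriptive subgroup summaries, not multiplicity-controlled discoveries.
A selection-aware null (e.g. mining permuted cohorts) would be the right
upgrade and is out of scope here.

A second limitation: subgroups whose member values are *mid-range* on every
attribute — distinctive only through their conjunction — are nearly
invisible to clustering-seeded search.  The recovery tests plant subgroups
with tail intervals, which is also the shape reported subgroups have in
practice (severe-AD and healthy extremes).

# Numerical and testing choices

Problem sizes in the test-suite simulations are chosen to keep the default
run comfortably interactive: 10 master seeds × (10 runs × 30 iterations)
for planted recovery, 20 seeds for the null audit, 20 seeds for
factor-structure recovery, ~54 000 null pairs for screen calibration, and
100 seeds for adjustment power.  Enumeration oracles run at n ≤ 12.
Tolerances: 1e-12 for enumeration equalities, 1e-10 for rotation
orthogonality, 1e-8 for closed-form statistics oracles.  Ties in ranks use
average ranks; ties in deduplication break by Jaccard, then rule length,
then lexicographic rule text, making `mine_redescriptions()` bit-identical
across repeated invocations with one seed.

# Reproducing a full analysis

```{r, eval = FALSE}
cfg <- pipeline_config(cohort = cohort_config(seed = 17),
                       out_dir = "out", seed = 17)
res <- run_pipeline(cfg)
```

The bundle contains the cohort, the correlation tables (3-decimal
correlations), factor JSONs, factor regressions, per-combination
redescription JSON/TSV (Jaccard to 5 decimals, percentages to 1), attribute
co-occurrence counts, and a manifest with every seed and parameter; two
runs with the same config are byte-identical.
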