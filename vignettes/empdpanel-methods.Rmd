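---
title: "Methods: IHC marker-panel analysis for EMPD cohorts"
author: "empdpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IHC marker-panel analysis for EMPD cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empdpanel)
```

# The setting

Extramammary Paget disease (EMPD) is a rare cutaneous adenocarcinoma of
apocrine-rich skin, most often anogenital. Cohort studies of EMPD stain a
panel of targetable or prognostic markers — B7 family immune-regulatory
ligands (B7-H3, B7-H4, PD-L1, PD-L2), cancer/testis antigens (MAGE-A,
NY-ESO-1), antigen-presenting machinery (B2M, MHC-I) and cytokeratins
(CK7, CK20) — on the *in situ*, invasive and (rarely) metastatic components
of each specimen, and then ask population-level questions: how prevalent is
each marker per component, which markers co-occur within a case, do
positivity rates differ across clinical strata, how concordant are the two
components of one case or two resections of one patient, and what structure
does the score matrix show under clustering.

`empdpanel` implements that analysis chain as a tested pipeline over a
single container, `IHCCohort` (a `SummarizedExperiment`: rows are the ten
panel markers, columns are specimen records, i.e. unique (patient,
resection, block, component) tuples).

# The scoring model

Each marker on each component is scored semi-quantitatively:

* **percent-positive category** $P \in \{0,1,2,3,4\}$ for 0, 1–25%,
  26–50%, 51–75%, 76–100% of tumor cells;
* **intensity** $I \in \{0,1,2,3\}$ for negative, weak, moderate, strong;
* **composite score** $S = P \times I \in [0,12]$.

Before block averaging $S$ can only take the values
$\{0,1,2,3,4,6,8,9,12\}$ (the 5×4 product table), and $S=0$ iff $P=0$ or
$I=0$. For specimens with two stained tumor blocks, per-marker scores are
averaged (`collapseBlocks()`), which can produce fractional scores; a case
is *positive* for a marker iff $S > 0$ strictly, so an averaged 0.5 counts
as positive (the negative category is exactly 0). `NA` means no scorable
tumor remained in the serial section; it is carried, never imputed.

**Mean expression convention.** Reports of this kind print a "mean
expression level" next to a positive-case count without defining the
denominator. Both conventions are implemented in `summarizeMarker()`:
`meanOver = "positive"` (default) averages over positive cases only,
`meanOver = "scored"` over all scored cases. Neither is asserted against
any published value.

# Coexpression categories

`classifyCase()` assigns each case exactly one category per marker set: the
positive subset in panel order (e.g. `B7-H3/B7-H4`), `negative`, or `NA` if
*any* marker of the set is unscorable. `tabulateCoexpression()` counts
categories per component. The default denominator includes the `NA` cases —
that is the convention under which published category percentages (e.g.
3/49 = 6.1% triple positive) reconcile with their stated denominators — and
`denominator = "scored"` restricts to fully scored cases. Stratified tables
use stratum-specific denominators.

# Association screen

Differences in percent positive between two covariate levels are tested by
a permutation test:

* statistic: $|100\,\bar a - 100\,\bar b|$ on positivity flags — the
  source analyses test "differences in percent positive" two-sidedly but
  never name a statistic; the absolute difference is the minimal choice
  consistent with a label-shuffle test;
* null distribution: group labels reshuffled `nIter = 1000` times
  preserving group sizes;
* p-value with add-one smoothing, $p = (1 + \#\{S^* \ge S\})/(n_{iter}+1)$,
  so $p \ge 1/(n_{iter}+1)$ and sampled permutation tests stay valid;
* eligibility: at least 3 scored cases per group and 10 total, otherwise
  the comparison is flagged ineligible and carried with `NA` p-values;
* multiplicity: Benjamini–Hochberg at 5% FDR *across markers within one
  covariate contrast* (that is the declared family); multi-level
  covariates are screened as declared pairwise contrasts, not omnibus
  tests.

Flags are sorted within groups before pooling and each (contrast, marker)
test draws its own sub-seed from the root seed, so results are reproducible
and invariant to record order. Binary TIL markers can be tested against
binary covariates with `fisherExact2x2()`.

# Concordance statistics

* per case: Spearman rank correlation between the 10-marker score vectors
  of the *in situ* and invasive components (TIL and CD8 fields never
  enter), and likewise between resections `a` and `b` of one patient;
* per marker: cosine similarity between the across-case score profiles of
  the two components (or resections);
* covariates: Kendall tau-b between CD8 density, TIL B7-H3, binarized
  vital status (1 = alive, 0 = dead pooling disease-related and unrelated
  death, unknown removed) and each marker score.

Missing values are handled by pairwise-complete deletion everywhere.
Undefined results — constant vectors (PD-L2 is constant zero in realistic
cohorts), zero vectors for cosine, fewer than two complete pairs — are
reported as explicit `NA` with an `undefined` flag, never silently 0.

# Clustering

Markers and cases are clustered independently on the raw 0–12 score matrix
(no scaling; the source convention is raw `hclust` on scores) with complete
linkage on the Manhattan metric. Missing values use the exclude-and-rescale
convention of R's `dist()`: with $p$ coordinates of which $n_p$ are
complete, $d = (p/n_p)\sum_{complete}|x_i-y_i|$. Our own agglomeration
routine is used rather than `hclust` for one reason: deterministic
tie-breaking (among equal-distance merges, the lexicographically smallest
pair of cluster creation indices merges first), which makes dendrograms
reproducible across platforms; `hclust` and a definition-level brute-force
oracle serve as cross-checks in the test suite. Complete-linkage heights
are never decreasing, and covariate annotation tracks are exported for
display only.

# The synthetic cohort generator

No per-case score table is bundled, so every downstream stage is exercised
on generated cohorts with the statistical structure the analyses assume.
The generator's stated world (defaults, `presetPaperLike()`):

* **48 patients**; clinical covariate composition matching a published
  EMPD cohort (64.6% female; 61.1/35.2/3.7% in situ/invasive/metastatic;
  exactly 6 of 48 secondary origin; 46.3% vulvar; 68.5% untreated; 43.8%
  unknown vital status). Covariates are allocated by largest-remainder
  exact counts and then permuted, so stated counts such as "6 of 48" are
  exact, not expectations.
* **Marker prevalence** per component set to the reference marginals
  (e.g. B7-H3 0.939/0.895 in situ/invasive, PD-L2 0, B2M 1.0 in situ).
* **Component coupling**: the invasive positivity state copies the in situ
  state with probability $\kappa = 0.9$, else is redrawn independently.
  The realized agreement rate is
  $\kappa + (1-\kappa)(p^2 + (1-p)^2)$ (`impliedComponentConcordance()`),
  because independent draws already agree at the $p^2+(1-p)^2$ floor; a
  copy probability cannot realize agreement below that floor, so the
  parameter is documented as the copy probability, not the agreement rate.
* **Scores**: positive components draw a composite from a mildly top-heavy
  distribution over $\{1,2,3,4,6,8,9,12\}$; each composite maps to a fixed
  (percent, intensity) factorization preferring broad staining. Duplicate
  blocks (rate 3/54) share the positivity and NA state but draw scores
  independently, emulating block-to-block jitter.
* **Missingness**: each (case, component, marker) is unscorable with
  probability 0.04 — chosen to match per-marker denominators like 43–47 of
  49 seen in this kind of cohort; the rate is shared by both blocks so
  averaging never sees mixed missingness.
* **Repeat resections**: exactly `round(0.125 n)` patients carry
  resections `a` and `b`.
* **CD8 density** is lognormal (location log 150, scale 0.8, rounded to 2
  decimals — image-analysis densities are not more precise), with an
  optional location shift per TIL B7-H3 category that induces a
  configurable positive rank dependence between the two.
* **Effects**: optional per-(marker, covariate level) prevalence offsets;
  the preset lowers B7-H4/CK7 and raises CK20 in secondary-origin disease,
  the qualitative associations such cohorts report.

What the generator deliberately does **not** emulate: the joint dependence
*among markers* beyond component coupling (unreported in the source
setting; an explicit copula would be a guess), spatial/block structure
beyond score jitter, and any survival process. A green test on synthetic
data therefore establishes that the statistics and their plumbing are
correct under the stated world — not that any particular biological
association holds.

# Numerical and design choices

* Permutation comparisons use a `>=` with a $10^{-9}$ slack so ties of the
  permuted statistic with the observed one count as extreme.
* BH adjustment wraps `stats::p.adjust`; Fisher wraps `stats::fisher.test`;
  Spearman/tau-b wrap `stats::cor` after explicit pairwise deletion and
  degeneracy checks. Each is tested against an independent hand-written
  oracle (step-up recursion, hypergeometric enumeration, pair counting).
* The CSV dialect is UTF-8, comma-separated, literal `NA`; one row per
  (patient, resection, block, component); `<marker>_pct`, `<marker>_int`
  and `<marker>_score` column triplets. Round-trips are lossless,
  including fractional averaged scores (detected on read and reflected in
  the `blocks_averaged` flag).
* Metastatic records are summarized separately and never pooled into the
  in situ / invasive marginals.
* Resection concordance pairs the component present in both resections,
  preferring in situ; patients with one resection are excluded.
* `runPipeline()` derives per-stage substreams from one root seed, so
  outputs are byte-identical across reruns and adding a stage cannot
  perturb earlier stages' randomness.

# Known limitations

* Published mean expression levels and tau-b values from the motivating
  setting require its per-case supplementary score table and are therefore
  not desk-reproducible here; they are covered by the oracle- and
  simulation-based properties in the test suite instead.
* The permutation test is two-sided by construction; a one-sided variant
  is not exposed.
* Confidence intervals for rho/tau-b are out of scope (point values only).
* Percent categories are inputs; the package never re-derives them from
  cell counts or images, and CD8 density is consumed as a number.
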