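---
title: "Methods: models, parameters and design choices in pdblood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in pdblood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdblood)
```

pdblood reimplements, as a tested package, a complete blood-transcriptomics
analysis for two-class (case/control) cohort studies: a chemometric
classification chain, three differential-expression procedures with
signature intersection, term and gene-set enrichment, a drug-network
similarity query, and RT-qPCR reference-gene selection with relative
quantification. This vignette records the models behind each stage, the
parameters that matter, the numerical decisions, and what the synthetic
cohorts do and do not establish.

## The data model

The central container, `expression_dataset`, couples a probes × samples
log2 intensity matrix with Present/Marginal/Absent detection calls, class
labels, and a probe→gene map. Linear intensities are always derived as
`2^log2`, so the two scales cannot disagree. All statistics operate on the
log2 scale; this is why the simulator is log-normal (Gaussian on log2),
and why centering — not autoscaling — is the default before PCA/PLS: on
log-intensity microarray data the variance of a probe is informative and
is conventionally retained.

## Preprocessing

Two filters mirror standard practice on probe-set summaries:

* `filter_probes()` drops probes never called Present and probes whose
  linear intensity stays below `intensity_floor` (default 100, i.e. log2
  intensity below log2(100)) in **every** sample. "Poor-quality call" is
  read as non-Present in all samples, symmetric with the all-samples
  intensity clause.
* `sam_prefilter()` keeps probes Present with intensity > 100 in at least
  `ceil(fraction × n)` arrays of the **smaller** class (default fraction
  0.5, "at least half"). This is the input filter for the SAM branch only;
  the PPLR branch deliberately runs unfiltered.

Between-array normalization is quantile normalization followed by median
global array scaling. Full RMA (background correction and median polish)
requires probe-level CEL data and is out of scope; the pipeline starts
from summarized intensities, so counts obtained on re-summarized public
data can deviate from originally reported ones. Ties in quantile
normalization receive the mean of the reference values they span, which
keeps the operation rank-preserving and idempotent in distribution.

`collapse_to_genes()` represents each gene by its probe of highest mean
log2 intensity — a common microarray convention; the source analysis never
states its collapse rule, so the choice is recorded here. Ties break to
the lexicographically smallest probe id, making the collapse
deterministic.

## The classification chain

1. **PLS-DA preselection** (`plsda_fit_select`). A NIPALS PLS1 fit of the
   class code (control = −1, case = +1) on the centered matrix; for a
   single response the first weight vector is exactly `X'y` normalized.
   Variables are ranked by VIP, whose mean square is 1 by construction, so
   VIP > 1 marks above-average importance. The selection size `keep` is a
   parameter, not a constant: the count reported in any given study (here,
   the order of 10³) is data-dependent. At most 6 latent components are
   fitted, matching the component cap used throughout the chain.
2. **Ranking-PCA** (`rpca_rank`). The cited chemometrics procedure ranks
   variables "by decreasing discriminant ability" without publishing its
   internals, so the package fixes a deterministic greedy rule: at each
   step, every remaining variable is tentatively added, PCA (≤ `max_pcs`,
   default 6) is computed on the selected set, and the candidate is scored
   by the leave-one-out NER% of an equal-prior LDA on the component
   scores. Ties break by the larger univariate between/within variance
   ratio, then by variable id. PCA is computed in sample space (the n × n
   Gram matrix updated by rank-1 additions), and the candidate loop runs
   in C++ — the package's one compiled kernel — because discovery-scale
   runs score tens of thousands of candidates. LOO is used instead of
   k-fold CV so no fold randomness enters the ranking.
3. **LDA forward selection** (`lda_forward`). Principal components enter
   by the Wilks' lambda partial-*F* test while the entry p-value is below
   `alpha` (default 0.01, the "highly significant" level). The final
   equal-prior LDA uses the pooled within-class covariance; a ridge
   epsilon is added (and logged) only if that matrix is numerically
   singular. Both training NER% and LOO NER% are reported, because it is
   often unstated which one a published NER is; the per-sample squared
   Mahalanobis distances to both centroids, with an ambiguity flag at
   `|d²_own − d²_other| < margin` (default 1), reproduce the robustness
   diagnostic in which a borderline sample sits near both classes.

Exact reproduction of a particular published variable count or PC entry
order would require the original software's tie-breaking and is treated as
context, not a target.

## Differential expression

* **SAM** (`sam_test`): `d = (x̄_case − x̄_control)/(s + s₀)` with `s` the
  pooled standard error. `s₀` is chosen on a 5 % grid of `s`-percentiles
  to minimize the coefficient of variation of the median absolute `d`
  across 20 `s`-quantile windows (the classic variance-stabilizing
  tuning). P-like values are pooled permutation tails of `|d|` under
  class-label shuffles; the FDR at each probe's `|d|` threshold is the
  median permuted exceedance count over the observed count, made monotone
  in the threshold. Significance defaults to estimated FDR ≤ 5 % (a
  `delta` cut on `|d|` can be supplied instead); the original analysis
  does not state its delta, so overlap counts against it are context only.
* **Rank Product** (`rank_product_test`): all `n_case × n_control`
  pairwise log-ratios (capped at 2000 with seeded subsampling), probes
  ranked per comparison in both directions, RP = geometric mean of ranks.
  The null follows the published convention of permuting values within
  comparisons — i.e. independent random rank columns. When the assignment
  space `(n!)^K` is at most 50 000 it is enumerated exhaustively (this is
  what makes a brute-force oracle test exact); otherwise seeded draws are
  used. Reported `fdr` is the percentage-of-false-prediction estimate
  `p·n/rank`. A known limitation: with many mutually dependent
  comparisons the within-comparison null underestimates the spread of
  observed RPs, so RP calls more nulls than SAM or PPLR at the same
  nominal level — visible in any pipeline run, and inherited from the
  published scheme rather than introduced here.
* **PPLR** (`pplr_test`): each class is summarized by its mean and
  standard error; under a normal posterior for the case-minus-control
  difference, `PPLR = Φ(Δ/σ)`, `σ² = se²_case + se²_control`. The
  p-value-like form is `1 − PPLR` for up- and `PPLR` for down-regulated
  probes, thresholded at 0.01 with no further adjustment — the conversion
  and thresholding follow the original exactly. The probe-level Bayesian
  hierarchical model it stands in for needs CEL-level data (out of
  scope), so counts from the original probe-level fit are
  approximate-reproduction context, not exact targets.

`intersect_signatures()` intersects significant sets at probe or gene
level, optionally discarding genes whose direction disagrees between
lists; a plain character vector participates like a method result, which
is how an ortholog-mapped external gene list (a cross-species comparison)
enters the same operation.

## Enrichment

`fisher_term_test()` is a one-sided hypergeometric upper tail per term;
EASE mode removes one gene from the overlap first, so single-gene overlaps
can never drive a term. Both modes exist because published legends
genuinely disagree on which was used; defaults (`min_count = 10`,
`p < 0.02`) follow the figure-level convention. The universe defaults to
the genes surviving filtering — standard over-representation practice —
not the whole array. BH adjustment is applied across all tested terms
before filtering. Note that BH is *not* idempotent in general (a
re-adjusted output can change when the adjusted profile is not flat);
tests assert the step-up arithmetic rather than a false invariant.

`gsea_es()` is the weighted Kolmogorov–Smirnov running sum: increments of
`|score|^weight` (normalized over hits) at gene-set members, `−1/(N−N_hit)`
elsewhere; ES is the signed maximum deviation, and `weight = 0` recovers
the classic KS statistic. Permutation NES/p use random gene sets of the
same size, with the p-value computed within the same-sign null — against
the full null the p-value of a signed statistic cannot be uniform.

## Drug network

The distance between two ranked signatures is
`1 − (TES_ab + TES_ba)/2`, with
`TES_ab = (ES of a's top-q in b − ES of a's bottom-q in b)/2` and
unweighted ES. It is symmetric by construction, 0 for identical
signatures and > 1 for anti-correlated ones. The extreme-set size `q`
defaults to 250 genome-scale genes and is configurable; the cited method
does not publish its value. `query_network()` ranks drugs by distance to
the disease signature and to its reversal (the candidate-therapeutic
direction); `community_enrichment()` is a hypergeometric upper tail of
community membership among the top-k drugs. Whether the originally
reported community p-values were hypergeometric is unstated; the choice
is recorded here as this package's test. Network construction and
community detection are inputs, not computed.

## RT-qPCR

With amplification efficiency `E` (default 2.0 per gene — comparative
TaqMan quantification; per-gene override supported, warning outside
[1.8, 2.2]), the raw quantity is `Q = E^(Cq_cal − Cq)` against a
calibrator defined as the mean control Cq per gene — the in-silico
analogue of a pooled healthy-control sample, which cannot be physically
pooled here. Normalized quantities divide by the geometric mean of the
reference genes' `Q`; natural logs are used for plotting and testing,
Student's *t* by default with a Welch fallback when the group variance
ratio exceeds 4, and star banding at 0.05/0.01/0.001.

Reference-gene stability: `genorm_rank()` implements the geNorm M value
(mean over partners of the SD of pairwise log2 ratios) with iterative
exclusion of the worst gene until a pair remains. `normfinder_rank()` is
a simplified variance-decomposition NormFinder: per-sample gene-centered
log quantities, per-gene inter-group bias `b` and intra-group variances,
combined as `sqrt(b² + mean intra-group variance)`. The original
NormFinder's full mixed-model estimator adds shrinkage terms that change
little at these candidate-panel sizes; the simplification is recorded as
a design decision.

## The synthetic world

`simulate_cohort()` draws the stated study design: 40 cases vs 20
controls by default, spiked probes at linear fold changes uniform in
[1.2, 1.5] (expression changes of 20–50 %), split evenly up/down so both
PPLR tails are exercised. Probe baselines are Normal(8, 1.5) on log2 —
chosen once as a realistic array intensity spread so that the detection
and intensity filters have genuine work — and within-probe noise defaults
to sd 0.25 log2 units. The within-class variance of the original probes
is not published; `probe_sd` is therefore a free parameter of the world,
not a calibrated one. Detection calls are thresholded deterministically
on linear intensity (Present ≥ threshold, Marginal ≥ half, Absent below):
the simplest mechanism that exercises the filters, at the cost of not
modelling call/intensity discordance. No batch or array effects are
simulated, and no probe-sequence-level structure exists — so a green
test establishes correctness and calibration of the statistics on an
idealized log-normal world, not robustness to the artefacts of real
arrays.

`simulate_qpcr_plate()` builds Cq values as gene baseline + shared
per-sample loading offset + group shift + noise; the loading offset is
exactly what reference-gene normalization is supposed to cancel, and the
designed per-gene noise plants a recoverable stability ordering.
`simulate_drug_network()` gives each drug a ranked profile correlated
with its community prototype at level `w` (`score = w·prototype +
sqrt(1−w²)·noise`), so `w = 1` duplicates profiles and `w = 0` makes them
independent.

Every simulator takes an explicit seed and uses no global RNG state;
identical spec + seed reproduces outputs bit for bit.

## Numerical and degenerate-input decisions

* Constant variables are excluded from PLS-DA with a warning; a
  single-class input is an error.
* Zero pooled standard errors everywhere send SAM's `s₀` to a logged
  1e-6 fallback.
* A class with one sample makes PPLR pool variance across probes
  (logged); `group_compare` errors below 2 samples per group, and returns
  p = 1 (or 0 for a noiseless certain difference) when both groups are
  exactly constant.
* `lda_forward` with no admissible PC degrades to a majority-class report
  with a warning rather than failing.
* Empty filter results warn rather than error, so pipelines fail at the
  stage that actually needs probes.
* All tie-breaks (R-PCA candidates, gene collapse, ranking order) are
  lexicographic after the scientific criterion, making every ranking
  reproducible across platforms.

## Pipeline and provenance

`run_pipeline()` chains filter → normalize → PLS-DA → Ranking-PCA → LDA →
SAM/RP/PPLR → intersection (→ enrichment when annotation sets are given),
writes per-stage TSVs, and emits a JSON manifest holding the full
configuration, the seed, and the counts at every stage — enough to
re-execute the run identically; reruns with the same inputs produce
byte-identical manifests. Stage failures abort with the stage name. A GEO
series-matrix reader (`read_series_matrix`) accepts the fenced
tab-separated form of deposited expression tables for replication runs
against public data; which detection-call source a given deposit used is
outside what the reader can know, so any call matrix is accepted.
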