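---
title: "Methods: qHTS skin sensitization pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qHTS skin sensitization pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtsSkinSens)
```

This vignette documents the models, rules and numerical choices behind
`qhtsSkinSens`, and what the synthetic-data generators do and do not
emulate.

## Concentration–response model

Raw well signals are normalized per run to percent activity against the
median of that run's DMSO wells, so 0 % is the vehicle control and 100 %
is a 2-fold signal. Each compound–run series is fitted to the
four-parameter Hill model
$y(x) = S_0 + (S_\infty - S_0)\,/\,(1 + (AC_{50}/x)^h)$ by
Levenberg–Marquardt least squares (`minpack.lm`).

Numerical choices:

* the fit is parameterized in $\log_{10} AC_{50}$, bounded to one decade
  beyond the tested range, with the Hill coefficient bounded to
  $[0.3, 8]$ — slopes outside that band are not distinguishable on a
  15-point series and destabilize the optimizer;
* three starts are taken at the 25th/50th/75th percentiles of the tested
  log-concentrations and the lowest-SSE solution kept;
* a series with fewer than 4 distinct concentrations is an error; a
  constant series, or one for which all starts fail, is returned
  unconverged and treated as inactive downstream.

### Curve classes and ranks

Curve classes follow the qHTS convention: class 1 when both asymptotes
are reached within the tested range (operationalized as the fitted
transition being ≥ 90 % complete at the top concentration and ≤ 10 %
engaged at the bottom), class 2 when the upper asymptote is not reached,
class 3 when a significant response (|activity| ≥ 30 %) occurs only at
the highest tested concentration, and class 4 for unconverged fits or
|efficacy| < 30 %. Sub-class .1 requires $r^2 \ge 0.9$ and |efficacy|
≥ 80 %.

The class-to-rank mapping (tiers 9/8 for 1.1, 7/6 for 1.2, 5/4 for 2.1,
3/2 for 2.2, 1 for class 3, 0 for class 4, split at |efficacy| = 80 %,
with inhibition negated) is a documented package convention: published
qHTS rank tables live in supplementary material of the originating
screening platform and vary between deployments. The mapping preserves
the properties downstream rules rely on — ranks span $[-9, 9]$, 0 means
inactive, and |rank| > 3 means a reproducible, high-quality curve.
Because sub-classes 1.1/2.1 already require |efficacy| ≥ 80 %, the tier
values 8 and 4 are unreachable under the defaults; they are retained so
that user-supplied classifications with laxer sub-class criteria still
map onto the full scale.

The tri-run outcome is `active` when ≥ 2 runs have |rank| > 3 in the
same direction, `inactive` when ≥ 2 runs are rank 0 and no run reaches
|rank| ≥ 5, otherwise `inconclusive`.

KeratinoSens summaries are computed on the normalized scale where fold
induction is $1 + y/100$: EC1.5 is the concentration where the fitted
curve crosses 50 % activity (solved in closed form on the monotone Hill
curve, clamped to the tested range, absent when never crossed), and Imax
is reported both as the observed and the fitted maximum because the
convention differs between laboratories. Optional cytotoxicity masking
removes KS points whose paired viability falls below 70 % of control
(threshold configurable) before fitting.

## Assay call rules

Test-guideline thresholds are implemented with the exact inequalities of
their sources: DPRA positive when cysteine depletion > 13.89 % or, with
lysine available, mean depletion > 6.38 % (negative depletions clipped
to 0 first, a common DPRA practice for measurement noise); KS positive
iff an EC1.5 exists; hCLAT positive when CD86 > 1.5 or CD54 > 2.0 fold;
IL-8 positive when fold ≥ 1.4 and the 95 % CI lower bound > 1.0. The
IL-8 interval is a two-sided t-interval on the mean fold across
replicates — the guideline wording does not fix the CI construction, and
the t-interval is the standard choice for small replicate counts.
Curve-rank calls (rank > 3, or < −3 for the depletion-mode DPRA) are
computed independently of the TG calls; their concordance is an output,
never an input.

## Defined approaches

* **2o3**: sensitizer/non-sensitizer by majority over DPRA, KS and
  hCLAT. With one source missing, a call is made only when the two
  present sources agree — the conservative reading of a majority rule;
  this is a package decision, as published descriptions do not state the
  missing-source behaviour.
* **ITSv2**: component scores are DPRA 0–3 (mean-depletion bins
  6.38 / 22.62 / 42.47, or cysteine-only bins 13.89 / 23.09 / 98.24),
  hCLAT 0–3 by MIT (≤ 10, ≤ 150, ≤ 5000 µg/mL), in silico 0–1
  (out-of-domain treated as absent). Totals map to 1A (6–7), 1B (2–5),
  NC (0–1) with three sources; with two sources, a total of 1 is
  inconclusive. A positive hCLAT without an MIT (single-concentration
  screening) scores 1, the weakest positive bin.
* **STS**: hCLAT positive → 1A if MIT ≤ 10 µg/mL else 1B (MIT
  unavailable → 1B, matching how single-concentration positives would
  be carried into a traditional potency scheme); hCLAT negative → 1B if
  DPRA positive, else NC.

Borderline ranges around the guideline thresholds are deliberately not
implemented; curve reproducibility is already captured in the curve
classification.

Percent agreement between the ITS and STS categories is reported under
two denominators: all compounds supplied (unresolved pairs counting as
disagreement) and resolved pairs only. On the published 288-compound
contingency, the diagonal is 235 and the all-compounds denominator is
the one yielding 82 %; the resolved-pairs denominator (255) yields 92 %.

## Synthetic data: what it emulates

The generators define the study conditions under which the pipeline is
validated.

* **Dose–response plates**: 15-point constant-log-step dilutions from
  2.8 nM to 92 µM, three independent runs, ≥ 8 DMSO wells per run,
  Gaussian noise of 5 % activity on every well (the plate noise model is
  a package choice; the real screen's error structure is not published).
  Actives draw $AC_{50}$ log-uniformly well inside the range,
  |efficacy| in 60–110 %, Hill slope 0.8–2.5, with activation or
  inhibition by the sign of $S_\infty - S_0$.
* **Assay panels**: generation works backwards from the ITS score
  table. For each compound a component-score combination valid for its
  true GHS class is sampled — constrained so that ITS, STS *and* the
  2o3 majority all recover the class — and quantitative values are then
  drawn strictly inside the open score bins, so boundary ties cannot
  occur and noise-free recovery is exact (this is what makes the DA
  engine testable). `flip_noise` re-draws individual sources from the
  opposite call regime; `missingness` blanks the in silico and hCLAT
  fields, the two sources limited in real screens (out-of-domain
  predictions, single-concentration hCLAT).
* **Fingerprints**: enriched bits multiply their Bernoulli odds by a
  fixed odds ratio in actives; defaults mirror a screening-scale label
  imbalance (≈ 10 % actives, 729 features).
* **Chemotypes**: primary clusters of requested sizes; extra
  memberships per compound are Poisson with mean `multiplicity − 1`.

What the generators do *not* emulate: plate positional effects and
pattern drift, correlated assay errors, structure–activity coherence
between the fingerprint world and the assay world, and real chemistry
(chemotypes are opaque identifiers). Passing recovery tests on this
synthetic world therefore validates the rule logic and the statistical
machinery, not screening-lab performance on real compounds.

## QSAR modeling grid

The split is stratified by label (70/30 by default, largest-remainder
allocation so the sizes are exact). Feature selection and rebalancing
run inside each training fold only; the held-out fold is scored with the
fold's own features and model, and out-of-fold scores are pooled per
repeat. This is what keeps the null calibration honest: on
label-shuffled data the pipeline's cross-validated AUC is 0.5 within
simulation error, which the acceptance script verifies.

Choices worth noting:

* Fisher selection uses the two-sided exact test (a flag switches to
  one-sided enrichment); per-feature AUC uses the binary-predictor
  closed form $(TPR + TNR)/2$ with direction folding
  $\max(AUC, 1-AUC)$ so depletion-coded bits remain selectable.
* ROSE and SMOTE are implemented in the package (smoothed bootstrap
  with Silverman diagonal bandwidth; kNN interpolation with neighbour
  reduction for tiny minorities). Their fractional outputs on binary
  fingerprints are kept fractional — tree and kernel models tolerate
  them, and rounding would re-impose the imbalance geometry.
* Gradient boosted trees use learning rate 0.01, maximum depth 3 and
  column subsample 0.5 with 100 rounds; the neural net has one hidden
  layer of $\sqrt{p}$ units and ≤ 500 iterations; other families run at
  their packages' defaults. Binary calls threshold the score at 0.5.
* An empty selection at a strict cutoff (possible on null folds) falls
  back to the single best-ranked feature so the downstream model stays
  defined.

Validation problem sizes (500-compound panels, 200 noisy curves,
300-compound fingerprint sets with 20 shuffled-label repeats) were
chosen to put simulation error well below the tested tolerances while
keeping the suite quick to run routinely.

## Known limitations

* The curve-rank mapping is a convention, not a reproduction of any
  specific platform's supplementary table.
* The hCLAT single-concentration mode cannot produce an MIT, so ITS
  hCLAT scores above 1 and STS 1A calls require concentration-series
  input.
* The prioritization quota function implements the stated principles
  (activity gate for clusters < 3, quotas non-decreasing in cluster
  size, exact total) but the exact quota curve used in any given
  campaign is a free parameter.
* Agreement between the package's outputs and published screening
  results can only be checked where the published inputs are available;
  the synthetic world stands in everywhere else.
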