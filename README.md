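# qhtsSkinSens

Skin sensitization — the capacity of a chemical to trigger allergic contact
dermatitis — is now routinely assessed without animal tests by combining
non-animal assays that map onto the adverse outcome pathway: peptide
reactivity (DPRA, key event 1), keratinocyte Nrf2/ARE activation
(KeratinoSens, key event 2) and dendritic-cell activation (hCLAT and IL-8,
key event 3), plus in silico hazard predictions. `qhtsSkinSens` implements
the computational chain needed to run this assessment on quantitative
high-throughput screening (qHTS) data: concentration–response processing
and activity calling, per-assay OECD test-guideline call rules, the
defined approaches that integrate the assays into hazard and GHS potency
predictions, chemotype-based compound prioritization, and a QSAR modeling
grid over binary chemotype fingerprints. A synthetic-data module generates
every input with known ground truth so the whole chain is testable end to
end.

## What it computes

**Concentration–response processing.** Raw plate signals are normalized
per run against the DMSO vehicle control,

    % activity = (V_compound − V_DMSO) / V_DMSO × 100,

with V_DMSO the median of the DMSO-only wells, then fitted to the
four-parameter Hill model

    y(x) = S0 + (Sinf − S0) / (1 + (AC50 / x)^h).

Each fit is classified into qHTS curve classes (1 complete, 2 incomplete,
3 single-point, 4 inactive; sub-class .1 for high-quality fits) and
converted to an integer curve rank in [−9, 9] (0 = inactive, negative =
inhibition); three independent runs combine into an
active/inactive/inconclusive outcome.

**Assay calls.** Both OECD test-guideline criteria (DPRA: cysteine
depletion > 13.89 % or mean cysteine/lysine depletion > 6.38 %;
KeratinoSens: induction > 1.5-fold, via EC1.5; hCLAT: CD86 > 1.5-fold or
CD54 > 2-fold; IL-8: fold ≥ 1.4 with 95 % CI lower bound > 1.0) and qHTS
curve-rank criteria (rank > 3 for activation assays, rank < −3 for the
depletion-mode DPRA) are computed independently.

**Defined approaches.** 2-out-of-3 majority hazard calls; the score-based
ITSv2 (DPRA + hCLAT + in silico, total score 0–7 mapped to GHS 1A / 1B /
NC); the sequential STS decision tree (hCLAT then DPRA, with the MIT ≤ 10
µg/mL branch for 1A); plus Venn-style cross-DA concordance, the ITS × STS
potency contingency with percent agreement, and confusion-matrix
concordance statistics (sensitivity, specificity, balanced accuracy, MCC).

**Chemotypes and QSAR.** Representative-chemotype assignment (preferring
clusters of 10–20 compounds), potency/efficacy-driven compound
prioritization with size-proportional cluster quotas, chemotype × assay
mean-curve-rank matrices, and a modeling grid over 0/1 fingerprint
matrices: Fisher / per-feature-AUC / ensemble-importance feature
selection, down/up/ROSE/SMOTE rebalancing, five classifier families
(naive Bayes, neural net, random forest, RBF SVM, gradient boosted
trees), repeated 3-fold cross-validation with fold-internal selection,
and external validation (AUC-ROC, balanced accuracy, MCC).

## Worked example

```r
library(qhtsSkinSens)

# simulate a small qHTS screen and process it
sim <- simulateDoseResponsePlates(n_compounds = 4, active_fraction = 0.5,
                                  noise_sd = 5, seed = 42)
res <- fitPlateDataset(sim$plate)
res$fits[res$fits$run == 1,
         c("compound_id", "ac50_uM", "efficacy", "r2",
           "curve_class", "curve_rank")]
#>   compound_id ac50_uM efficacy    r2 curve_class curve_rank
#> 1    CMP00001 0.18513   -74.15 0.990         1.2         -6
#> 2    CMP00002 0.00487    -8.96 0.127           4          0
#> 3    CMP00003 0.03042    -7.08 0.269           4          0
#> 4    CMP00004 0.47652   -68.71 0.976         1.2         -6
```

The two true actives are recovered as high-quality inhibition curves
(class 1.2, rank −6: sub-maximal efficacy); the flat series fall into
class 4, rank 0, and the tri-run outcomes are `active` / `inactive`
accordingly.

```r
# defined approaches on a synthetic 288-compound panel
psim <- simulateAssayPanels(n_compounds = 288, seed = 42)
da <- applyDefinedApproaches(psim$panel)
pc <- potencyContingency(da, n_total = 288)
pc$table
#>               STS
#> ITS             NC  1B  1A inconclusive
#>   NC           143   0   0            0
#>   1B             0 133   0            0
#>   1A             0   0  12            0
#>   inconclusive   0   0   0            0
pc$agreement_pct
#> [1] 100
```

On a noise-free panel the ITS and STS categories agree perfectly with
each other and with the generating ground truth; adding `flip_noise`
and `missingness` moves the panel toward the discordance patterns seen
in real screens.

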