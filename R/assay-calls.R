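#' DPRA percent peptide depletion
#'
#' Converts peptide / internal-standard area ratios into percent depletion:
#' \code{(1 - sample_ratio / control_ratio) * 100}. The internal control
#' (an alanine peptide) normalizes injection-to-injection variation.
#'
#' @param sample_ratio peptide/internal-standard area ratio of the
#'   compound-treated sample.
#' @param control_ratio same ratio for the vehicle control.
#' @return percent depletion (vectorized).
#' @export
dpraDepletion <- function(sample_ratio, control_ratio) {
  if (any(!is.finite(control_ratio)) || any(control_ratio <= 0))
    stop("invalid reference: control_ratio must be > 0")
  (1 - sample_ratio / control_ratio) * 100
}

.clip0 <- function(x) pmax(x, 0)

#' DPRA call under OECD TG 442C-style thresholds
#'
#' Positive when cysteine depletion exceeds 13.89\%, or when the lysine
#' depletion is available and the mean of cysteine and lysine depletion
#' exceeds 6.38\%. Small negative depletions (measurement noise) are
#' clipped to 0 before comparison.
#'
#' @param cys_depletion cysteine peptide depletion (\%); required.
#' @param lys_depletion lysine peptide depletion (\%) or \code{NA}.
#' @return \code{"positive"} or \code{"negative"} (vectorized).
#' @examples
#' dpraCallTG(20, 0)   # positive: cysteine rule
#' dpraCallTG(6, 8)    # positive: mean 7 > 6.38
#' @export
dpraCallTG <- function(cys_depletion, lys_depletion = NA_real_) {
  n <- max(length(cys_depletion), length(lys_depletion))
  cys <- rep_len(cys_depletion, n)
  lys <- rep_len(lys_depletion, n)
  if (any(is.na(cys)))
    stop("missing data: cysteine depletion is required for the TG call")
  cys <- .clip0(cys)
  pos <- cys > 13.89
  has_lys <- !is.na(lys)
  mean_cl <- (cys + .clip0(lys)) / 2
  pos <- pos | (has_lys & mean_cl > 6.38)
  ifelse(pos, "positive", "negative")
}

#' DPRA call under qHTS curve-rank criteria
#'
#' In the qHTS DPRA readout, peptide depletion appears as signal inhibition,
#' so actives have curve ranks in the negative range: positive when the
#' cysteine or lysine curve rank is strictly less than -3.
#'
#' @param cys_rank,lys_rank curve ranks in [-9, 9]; \code{NA} allowed.
#' @return \code{"positive"} or \code{"negative"} (vectorized).
#' @export
dpraCallCurveRank <- function(cys_rank, lys_rank = NA_real_) {
  n <- max(length(cys_rank), length(lys_rank))
  cys <- rep_len(cys_rank, n); lys <- rep_len(lys_rank, n)
  pos <- (!is.na(cys) & cys < -3) | (!is.na(lys) & lys < -3)
  ifelse(pos, "positive", "negative")
}

#' KeratinoSens call under OECD TG criteria
#'
#' Positive when luciferase induction exceeds 1.5-fold of the negative
#' control at some non-cytotoxic tested concentration, i.e. when an EC1.5
#' exists (see \code{\link{ksActivitySummary}}). The threshold is strict:
#' a maximal fold of exactly 1.5 is negative.
#'
#' @param ec15_uM EC1.5 (uM) or \code{NA} when the threshold is not crossed.
#' @return \code{"positive"} or \code{"negative"} (vectorized).
#' @export
ksCallTG <- function(ec15_uM) {
  ifelse(!is.na(ec15_uM), "positive", "negative")
}

#' Activation-assay call under qHTS curve-rank criteria
#'
#' Shared by the KS and IL-8 readouts: positive when the curve rank is
#' strictly greater than 3 (activation only; inhibition-range ranks are
#' negative calls for these assays).
#'
#' @param curve_rank curve rank in [-9, 9].
#' @return \code{"positive"} or \code{"negative"} (vectorized).
#' @export
activationCallCurveRank <- function(curve_rank) {
  stopifnot(all(abs(curve_rank[!is.na(curve_rank)]) <= 9))
  ifelse(!is.na(curve_rank) & curve_rank > 3, "positive", "negative")
}

#' hCLAT call from CD86/CD54 relative fluorescence
#'
#' Positive when CD86 RFI exceeds 1.5-fold or CD54 RFI exceeds 2-fold of
#' the vehicle baseline (strict inequalities).
#'
#' @param cd86_rfi,cd54_rfi relative fluorescence intensity (fold of
#'   vehicle); \code{NA} allowed for one of the two.
#' @return \code{"positive"} or \code{"negative"} (vectorized).
#' @export
hclatCall <- function(cd86_rfi, cd54_rfi) {
  n <- max(length(cd86_rfi), length(cd54_rfi))
  cd86 <- rep_len(cd86_rfi, n); cd54 <- rep_len(cd54_rfi, n)
  if (any(is.na(cd86) & is.na(cd54)))
    stop("missing data: both CD86 and CD54 RFI are absent")
  pos <- (!is.na(cd86) & cd86 > 1.5) | (!is.na(cd54) & cd54 > 2.0)
  ifelse(pos, "positive", "negative")
}

#' Minimum induction threshold (MIT) from an hCLAT concentration series
#'
#' The lowest tested concentration at which the CD86 or CD54 RFI exceeds
#' its threshold (1.5 / 2.0 fold). With the single-concentration qHTS
#' design, pass one concentration; the MIT is then that concentration when
#' the call is positive, \code{NA} otherwise.
#'
#' @param conc_ugml tested concentrations (ug/mL).
#' @param cd86_rfi,cd54_rfi RFI per concentration.
#' @return MIT (ug/mL) or \code{NA}.
#' @export
hclatMIT <- function(conc_ugml, cd86_rfi, cd54_rfi) {
  stopifnot(length(conc_ugml) == length(cd86_rfi),
            length(conc_ugml) == length(cd54_rfi))
  pos <- (!is.na(cd86_rfi) & cd86_rfi > 1.5) |
         (!is.na(cd54_rfi) & cd54_rfi > 2.0)
  if (!any(pos)) return(NA_real_)
  min(conc_ugml[pos])
}

#' IL-8 call under the OECD TG 442E-style fold/CI rule
#'
#' Positive when the fold induction is at least 1.4 and the lower limit of
#' the 95\% confidence interval of the mean fold exceeds 1.0.
#'
#' @param fold_induction mean fold induction over the vehicle control.
#' @param ci95_lower lower limit of the 95\% CI of the mean fold.
#' @return \code{"positive"} or \code{"negative"} (vectorized).
#' @export
il8CallTG <- function(fold_induction, ci95_lower) {
  n <- max(length(fold_induction), length(ci95_lower))
  fold <- rep_len(fold_induction, n); lo <- rep_len(ci95_lower, n)
  ifelse(!is.na(fold) & !is.na(lo) & fold >= 1.4 & lo > 1.0,
         "positive", "negative")
}

#' IL-8 fold induction with a t-based 95\% confidence interval
#'
#' Computes the mean fold induction across replicates and a two-sided
#' t-interval on the mean, then applies \code{\link{il8CallTG}}.
#'
#' @param replicate_folds numeric vector of per-replicate fold inductions
#'   (length >= 2).
#' @return list with \code{fold}, \code{ci_lower}, \code{ci_upper},
#'   \code{call}.
#' @export
il8FoldCI <- function(replicate_folds) {
  replicate_folds <- replicate_folds[is.finite(replicate_folds)]
  if (length(replicate_folds) < 2L)
    stop("inconclusive call: need >= 2 replicates for a confidence interval")
  m <- mean(replicate_folds)
  se <- sd(replicate_folds) / sqrt(length(replicate_folds))
  tcrit <- qt(0.975, df = length(replicate_folds) - 1L)
  lo <- m - tcrit * se
  list(fold = m, ci_lower = lo, ci_upper = m + tcrit * se,
       call = il8CallTG(m, lo))
}

#' Recompute all panel calls from the quantitative fields
#'
#' Applies the per-assay call rules to the quantitative columns of a
#' \code{\link{CompoundAssayPanel}}, filling the \code{*_call*} columns.
#' Curve-rank calls and TG calls are derived independently. Missing
#' quantitative inputs leave the corresponding call \code{NA}.
#'
#' @param panel a \code{CompoundAssayPanel}.
#' @return the panel with refreshed call columns.
#' @export
computePanelCalls <- function(panel) {
  stopifnot(is(panel, "CompoundAssayPanel"))
  d <- panelData(panel)
  has_cys <- !is.na(d$dpra_cys_depletion)
  d$dpra_call_tg[has_cys] <-
    dpraCallTG(d$dpra_cys_depletion[has_cys], d$dpra_lys_depletion[has_cys])
  has_rank <- !is.na(d$dpra_cys_rank) | !is.na(d$dpra_lys_rank)
  d$dpra_call_rank[has_rank] <-
    dpraCallCurveRank(d$dpra_cys_rank[has_rank], d$dpra_lys_rank[has_rank])
  has_ks <- !is.na(d$ks_imax_pct) | !is.na(d$ks_ec15_uM)
  d$ks_call_tg[has_ks] <- ksCallTG(d$ks_ec15_uM[has_ks])
  d$ks_call_rank[!is.na(d$ks_curve_rank)] <-
    activationCallCurveRank(d$ks_curve_rank[!is.na(d$ks_curve_rank)])
  has_hclat <- !is.na(d$hclat_cd86_rfi) | !is.na(d$hclat_cd54_rfi)
  d$hclat_call[has_hclat] <-
    hclatCall(d$hclat_cd86_rfi[has_hclat], d$hclat_cd54_rfi[has_hclat])
  has_il8 <- !is.na(d$il8_fold) & !is.na(d$il8_ci_lower)
  d$il8_call_tg[has_il8] <-
    il8CallTG(d$il8_fold[has_il8], d$il8_ci_lower[has_il8])
  new("CompoundAssayPanel", data = d)
}
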