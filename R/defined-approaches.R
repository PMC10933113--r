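#' 2-out-of-3 defined approach for hazard classification
#'
#' Majority call over the DPRA, KeratinoSens and hCLAT results:
#' \code{"sensitizer"} when at least two sources are positive,
#' \code{"non-sensitizer"} when at least two are negative. With exactly one
#' source absent, a call is made only when the two present sources agree;
#' otherwise \code{"inconclusive"}. Fewer than two present sources is an
#' error.
#'
#' @param dpra_call,ks_call,hclat_call \code{"positive"}, \code{"negative"}
#'   or \code{NA}.
#' @return \code{"sensitizer"}, \code{"non-sensitizer"} or
#'   \code{"inconclusive"}.
#' @examples
#' da2o3("positive", "positive", "negative")  # sensitizer
#' @export
da2o3 <- function(dpra_call, ks_call, hclat_call) {
  calls <- c(dpra_call, ks_call, hclat_call)
  stopifnot(length(calls) == 3)
  calls <- calls[!is.na(calls)]
  if (length(calls) < 2L)
    stop("missing data: 2o3 needs at least two assay calls")
  npos <- sum(calls == "positive")
  nneg <- sum(calls == "negative")
  if (npos >= 2) return("sensitizer")
  if (nneg >= 2) return("non-sensitizer")
  "inconclusive"
}

#' ITS component scores
#'
#' Scores the DPRA, hCLAT and in silico sources for the score-based
#' integrated testing strategy (ITSv2). DPRA scoring uses the mean of
#' cysteine and lysine depletion when both are available
#' (bins < 6.38 / 22.62 / 42.47 -> 0..3) or the cysteine-only bins
#' (< 13.89 / 23.09 / 98.24 -> 0..3) when lysine is missing. hCLAT is
#' scored from the minimum induction threshold: negative -> 0,
#' MIT in (150, 5000] -> 1, (10, 150] -> 2, <= 10 ug/mL -> 3; a positive
#' call without an MIT scores 1. The in silico prediction scores 1 when
#' positive, 0 when negative; out-of-domain or absent predictions are
#' omitted from the total.
#'
#' @param cys_depletion cysteine depletion (\%) or \code{NA}.
#' @param lys_depletion lysine depletion (\%) or \code{NA}.
#' @param hclat_call hCLAT call (\code{"positive"}/\code{"negative"}/NA).
#' @param hclat_mit_ugml MIT (ug/mL) or \code{NA}.
#' @param insilico \code{"positive"}, \code{"negative"},
#'   \code{"out_of_domain"} or \code{NA}.
#' @return list with \code{dpra_score}, \code{hclat_score},
#'   \code{insilico_score} (each integer or \code{NA} when the source is
#'   absent), \code{total} (sum of present scores) and \code{n_sources}.
#' @export
itsScore <- function(cys_depletion, lys_depletion = NA_real_,
                     hclat_call = NA_character_, hclat_mit_ugml = NA_real_,
                     insilico = NA_character_) {
  dpra_score <- NA_integer_
  if (!is.na(cys_depletion)) {
    cys <- max(cys_depletion, 0)
    if (!is.na(lys_depletion)) {
      m <- (cys + max(lys_depletion, 0)) / 2
      dpra_score <- as.integer(findInterval(m, c(6.38, 22.62, 42.47)))
    } else {
      dpra_score <- as.integer(findInterval(cys, c(13.89, 23.09, 98.24)))
    }
  }
  hclat_score <- NA_integer_
  if (!is.na(hclat_call)) {
    if (hclat_call == "negative") {
      hclat_score <- 0L
    } else if (is.na(hclat_mit_ugml)) {
      hclat_score <- 1L
    } else if (hclat_mit_ugml <= 10) {
      hclat_score <- 3L
    } else if (hclat_mit_ugml <= 150) {
      hclat_score <- 2L
    } else {
      hclat_score <- 1L
    }
  }
  insilico_score <- NA_integer_
  if (!is.na(insilico) && insilico %in% c("positive", "negative"))
    insilico_score <- if (insilico == "positive") 1L else 0L

  scores <- c(dpra_score, hclat_score, insilico_score)
  n_sources <- sum(!is.na(scores))
  if (n_sources == 0L)
    stop("missing data: no ITS information source present")
  list(dpra_score = dpra_score, hclat_score = hclat_score,
       insilico_score = insilico_score,
       total = sum(scores, na.rm = TRUE), n_sources = n_sources)
}

#' GHS potency category from an ITS score
#'
#' With all three sources: total 6-7 -> 1A, 2-5 -> 1B, 0-1 -> NC. With two
#' sources: 6 -> 1A, 2-5 -> 1B, 1 -> inconclusive, 0 -> NC. With fewer than
#' two sources the result is inconclusive.
#'
#' @param score list as returned by \code{\link{itsScore}}.
#' @return \code{"1A"}, \code{"1B"}, \code{"NC"} or \code{"inconclusive"}.
#' @export
itsClassify <- function(score) {
  total <- score$total; n <- score$n_sources
  if (n < 2L) return("inconclusive")
  if (n == 3L) {
    if (total >= 6) return("1A")
    if (total >= 2) return("1B")
    return("NC")
  }
  # two sources
  if (total >= 6) return("1A")
  if (total >= 2) return("1B")
  if (total == 1) return("inconclusive")
  "NC"
}

#' STS (sequential testing strategy) GHS potency category
#'
#' Decision tree on hCLAT then DPRA: a positive hCLAT maps to 1A when the
#' MIT is <= 10 ug/mL and to 1B otherwise (including when the MIT is
#' unavailable, as in single-concentration qHTS testing); a negative hCLAT
#' maps to 1B when the DPRA is positive and NC when it is negative.
#'
#' @param hclat_call \code{"positive"}/\code{"negative"}.
#' @param hclat_mit_ugml MIT (ug/mL) or \code{NA}.
#' @param dpra_call \code{"positive"}/\code{"negative"} or \code{NA}.
#' @return \code{"1A"}, \code{"1B"}, \code{"NC"} or \code{"inconclusive"}.
#' @export
stsClassify <- function(hclat_call, hclat_mit_ugml = NA_real_, dpra_call) {
  if (is.na(hclat_call) && is.na(dpra_call))
    stop("missing data: STS needs hCLAT and DPRA calls")
  if (is.na(hclat_call)) return("inconclusive")
  if (hclat_call == "positive") {
    if (!is.na(hclat_mit_ugml) && hclat_mit_ugml <= 10) return("1A")
    return("1B")
  }
  if (is.na(dpra_call)) return("inconclusive")
  if (dpra_call == "positive") return("1B")
  "NC"
}

#' Apply the 2o3, ITSv2 and STS defined approaches to a panel
#'
#' Runs all three defined approaches on each compound of a
#' \code{\link{CompoundAssayPanel}}. Out-of-domain in silico predictions
#' are treated as absent for ITS scoring. Per-compound rule failures
#' (insufficient sources) are recorded as \code{"inconclusive"} rather than
#' aborting the batch.
#'
#' @param panel a \code{CompoundAssayPanel}.
#' @return data.frame with columns \code{compound_id}, \code{call_2o3},
#'   \code{its_dpra_score}, \code{its_hclat_score}, \code{its_insilico_score},
#'   \code{its_total}, \code{ghs_its}, \code{ghs_sts}.
#' @examples
#' sim <- simulateAssayPanels(n_compounds = 5, seed = 1)
#' applyDefinedApproaches(sim$panel)
#' @export
applyDefinedApproaches <- function(panel) {
  stopifnot(is(panel, "CompoundAssayPanel"))
  d <- panelData(panel)
  if (nrow(d) == 0L)
    return(data.frame(compound_id = character(), call_2o3 = character(),
                      its_dpra_score = integer(), its_hclat_score = integer(),
                      its_insilico_score = integer(), its_total = integer(),
                      ghs_its = character(), ghs_sts = character()))
  rows <- lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    call_2o3 <- tryCatch(
      da2o3(r$dpra_call_tg, r$ks_call_tg, r$hclat_call),
      error = function(e) "inconclusive")
    insil <- r$insilico_call
    if (!is.na(insil) && insil == "out_of_domain") insil <- NA_character_
    its <- tryCatch(
      itsScore(r$dpra_cys_depletion, r$dpra_lys_depletion,
               r$hclat_call, r$hclat_mit_ugml, insil),
      error = function(e) NULL)
    if (is.null(its)) {
      its <- list(dpra_score = NA_integer_, hclat_score = NA_integer_,
                  insilico_score = NA_integer_, total = NA_integer_,
                  n_sources = 0L)
      ghs_its <- "inconclusive"
    } else ghs_its <- itsClassify(its)
    ghs_sts <- tryCatch(
      stsClassify(r$hclat_call, r$hclat_mit_ugml, r$dpra_call_tg),
      error = function(e) "inconclusive")
    data.frame(compound_id = r$compound_id, call_2o3 = call_2o3,
               its_dpra_score = its$dpra_score,
               its_hclat_score = its$hclat_score,
               its_insilico_score = its$insilico_score,
               its_total = as.integer(its$total),
               ghs_its = ghs_its, ghs_sts = ghs_sts)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.da_positive <- function(call_2o3, ghs_its, ghs_sts) {
  cbind(`2o3` = call_2o3 %in% "sensitizer",
        its = ghs_its %in% c("1A", "1B"),
        sts = ghs_sts %in% c("1A", "1B"))
}

#' Cross-DA positive/negative concordance counts (Venn summary)
#'
#' A compound counts as DA-positive under ITS or STS when its GHS category
#' is 1A or 1B, and under 2o3 when the hazard call is sensitizer. Reports
#' how many compounds are positive in all three, at least two, at least one
#' DA, and how many are negative in all three.
#'
#' @param da_results data.frame from \code{\link{applyDefinedApproaches}}.
#' @return list with \code{positive_all3}, \code{positive_ge2},
#'   \code{positive_ge1}, \code{negative_all3}, \code{n}.
#' @export
daVennCounts <- function(da_results) {
  pos <- .da_positive(da_results$call_2o3, da_results$ghs_its,
                      da_results$ghs_sts)
  neg <- cbind(da_results$call_2o3 %in% "non-sensitizer",
               da_results$ghs_its %in% "NC",
               da_results$ghs_sts %in% "NC")
  k <- rowSums(pos)
  list(positive_all3 = sum(k == 3), positive_ge2 = sum(k >= 2),
       positive_ge1 = sum(k >= 1), negative_all3 = sum(rowSums(neg) == 3),
       n = nrow(da_results))
}

#' ITS x STS potency contingency table and percent agreement
#'
#' Cross-tabulates the GHS potency categories predicted by ITS and STS and
#' reports percent agreement, defined as 100 x (number of compounds with
#' identical categories) / denominator, rounded to the nearest integer.
#' Two denominators are reported: all compounds supplied (compounds lacking
#' a resolved category in either DA count as disagreements) and only the
#' compounds with a resolved (non-inconclusive, non-missing) category in
#' both DAs.
#'
#' @param ghs_its,ghs_sts character vectors of GHS categories
#'   (\code{"1A"}, \code{"1B"}, \code{"NC"}, \code{"inconclusive"}), or a
#'   single data.frame from \code{\link{applyDefinedApproaches}} as the
#'   first argument.
#' @param n_total denominator for the headline agreement; defaults to the
#'   number of compounds supplied.
#' @return list with \code{table} (ITS rows x STS columns),
#'   \code{n_agree}, \code{agreement_pct} (denominator \code{n_total}),
#'   \code{agreement_pct_resolved} (denominator = resolved pairs).
#' @examples
#' its <- rep(c("NC", "1B", "1A"), c(101, 134, 8))
#' sts <- rep(c("NC", "1B", "1B", "1A", "1B", "1A"), c(96, 5, 133, 1, 2, 6))
#' potencyContingency(its, sts, n_total = 288)$agreement_pct
#' @export
potencyContingency <- function(ghs_its, ghs_sts = NULL, n_total = NULL) {
  if (is.data.frame(ghs_its)) {
    ghs_sts <- ghs_its$ghs_sts
    ghs_its <- ghs_its$ghs_its
  }
  stopifnot(length(ghs_its) == length(ghs_sts))
  if (is.null(n_total)) n_total <- length(ghs_its)
  lev <- c("NC", "1B", "1A", "inconclusive")
  tab <- table(ITS = factor(ghs_its, levels = lev),
               STS = factor(ghs_sts, levels = lev))
  resolved <- ghs_its %in% c("NC", "1B", "1A") &
              ghs_sts %in% c("NC", "1B", "1A")
  n_agree <- sum(resolved & ghs_its == ghs_sts)
  list(table = tab, n_agree = n_agree,
       agreement_pct = round(100 * n_agree / n_total),
       agreement_pct_resolved =
         if (any(resolved)) round(100 * n_agree / sum(resolved)) else NA_real_)
}

#' Binary agreement statistics between two call vectors
#'
#' Confusion-matrix statistics of \code{calls_a} against the reference
#' \code{calls_b}: sensitivity, specificity, balanced accuracy
#' ((sensitivity + specificity)/2) and the Matthews correlation
#' coefficient. Pairs with a missing call on either side are dropped.
#'
#' @param calls_a,calls_b character vectors of
#'   \code{"positive"}/\code{"negative"} calls; \code{calls_b} is the
#'   reference.
#' @return list with \code{sensitivity}, \code{specificity},
#'   \code{balanced_accuracy}, \code{mcc}, \code{n}.
#' @export
binaryAgreementStats <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b))
  keep <- calls_a %in% c("positive", "negative") &
          calls_b %in% c("positive", "negative")
  a <- calls_a[keep]; b <- calls_b[keep]
  if (!length(a)) stop("missing data: no overlapping calls")
  tp <- sum(a == "positive" & b == "positive")
  fn <- sum(a == "negative" & b == "positive")
  tn <- sum(a == "negative" & b == "negative")
  fp <- sum(a == "positive" & b == "negative")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = mean(c(sens, spec)), mcc = mcc, n = length(a))
}
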