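#' Normalize raw plate signals to percent activity
#'
#' Converts raw well signals to percent activity relative to the DMSO
#' vehicle control, per run:
#' \deqn{\%\,activity = \frac{V_{compound} - V_{DMSO}}{V_{DMSO}} \times 100}
#' where \eqn{V_{DMSO}} is the median of the run's DMSO-only wells. On this
#' scale 0\% equals the vehicle control and 100\% equals a 2-fold signal.
#'
#' @param plate a \code{\link{PlateDataset}}.
#' @return data.frame with columns \code{compound_id}, \code{run},
#'   \code{conc_uM}, \code{pct_activity}, sorted by compound, run and
#'   ascending concentration.
#' @examples
#' pd <- simulateDoseResponsePlates(n_compounds = 3, active_fraction = 1,
#'                                  noise_sd = 0, seed = 1)
#' head(normalizePercentActivity(pd$plate))
#' @export
normalizePercentActivity <- function(plate) {
  stopifnot(is(plate, "PlateDataset"))
  w <- plateWells(plate)
  out <- lapply(seq_len(plateRuns(plate)), function(r) {
    wr <- w[w$run == r, , drop = FALSE]
    vd <- median(wr$signal[wr$is_dmso])
    if (!is.finite(vd) || vd == 0)
      stop("normalization failure: DMSO median absent or zero in run ", r)
    cw <- wr[!wr$is_dmso, , drop = FALSE]
    data.frame(compound_id = cw$compound_id, run = r,
               conc_uM = cw$conc_uM,
               pct_activity = (cw$signal - vd) / vd * 100)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$compound_id, out$run, out$conc_uM), ]
  rownames(out) <- NULL
  out
}

#' Evaluate the four-parameter Hill model
#'
#' @param x concentration (uM)
#' @param s0,sinf,ac50,hill Hill parameters
#' @return response at \code{x}
#' @export
hillCurve <- function(x, s0, sinf, ac50, hill) {
  s0 + (sinf - s0) / (1 + (ac50 / x)^hill)
}

#' Fit a four-parameter Hill curve to a concentration-response series
#'
#' Least-squares fit of \eqn{y(x) = S_0 + (S_\infty - S_0)/(1 +
#' (AC_{50}/x)^h)} using Levenberg-Marquardt on a log10-AC50
#' parameterization, with the Hill coefficient bounded to [0.3, 8], AC50
#' bounded to [min conc / 10, max conc x 10], and multi-start from three
#' AC50 grid points. A fit is flagged unconverged when the optimizer fails
#' for every start or the response shows no dose dependence.
#'
#' @param conc_uM numeric vector of concentrations (uM), > 0.
#' @param pct_activity numeric vector of percent activities.
#' @return a \code{\link{HillFit}}.
#' @examples
#' x <- 10^seq(-3, 2, length.out = 15)
#' y <- hillCurve(x, 0, 100, 1, 1.2)
#' fitHillCurve(x, y)
#' @export
fitHillCurve <- function(conc_uM, pct_activity) {
  stopifnot(length(conc_uM) == length(pct_activity))
  ok <- is.finite(conc_uM) & is.finite(pct_activity) & conc_uM > 0
  x <- conc_uM[ok]; y <- pct_activity[ok]
  if (length(unique(x)) < 4L)
    stop("insufficient data: need >= 4 distinct concentrations")
  o <- order(x); x <- x[o]; y <- y[o]

  unconverged <- new("HillFit", s0 = NA_real_, sinf = NA_real_,
                     ac50 = NA_real_, hill = NA_real_, efficacy = 0,
                     r2 = NA_real_, converged = FALSE)
  if (diff(range(y)) < 1e-9) return(unconverged)

  lx <- log10(x)
  lo <- c(s0 = -Inf, sinf = -Inf, lac50 = min(lx) - 1, hill = 0.3)
  hi <- c(s0 = Inf, sinf = Inf, lac50 = max(lx) + 1, hill = 8)
  starts <- quantile(lx, c(0.25, 0.5, 0.75), names = FALSE)
  sst <- sum((y - mean(y))^2)

  best <- NULL; best_sse <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ s0 + (sinf - s0) / (1 + 10^((lac50 - lxx) * hill)),
        data = data.frame(y = y, lxx = lx),
        start = list(s0 = y[1], sinf = y[length(y)], lac50 = st, hill = 1),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(residuals(fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit }
  }
  if (is.null(best)) return(unconverged)

  p <- coef(best)
  r2 <- if (sst > 0) 1 - best_sse / sst else NA_real_
  new("HillFit", s0 = unname(p["s0"]), sinf = unname(p["sinf"]),
      ac50 = unname(10^p["lac50"]), hill = unname(p["hill"]),
      efficacy = unname(p["sinf"] - p["s0"]), r2 = r2, converged = TRUE)
}

#' Classify a concentration-response curve and assign a curve rank
#'
#' Assigns a qHTS curve class and integer curve rank in [-9, 9] from the
#' fitted Hill parameters and the observed series. Classes: 1 = both
#' asymptotes reached within the tested range, 2 = upper asymptote not
#' reached, 3 = significant response only at the highest tested
#' concentration, 4 = inactive (no fit or |efficacy| < 30\%). Sub-class .1
#' requires r2 >= 0.9 and |efficacy| >= 80\%, otherwise .2. Ranks by class
#' and |efficacy| tier (>= 80\% / < 80\%): 1.1 -> 9/8, 1.2 -> 7/6,
#' 2.1 -> 5/4, 2.2 -> 3/2, 3 -> 1, 4 -> 0; inhibition curves
#' (negative efficacy) take the negative rank.
#'
#' @param fit a \code{\link{HillFit}}.
#' @param conc_uM,pct_activity the observed series the fit was made on.
#' @return list with \code{curve_class} (character, one of "1.1", "1.2",
#'   "2.1", "2.2", "3", "4"), \code{curve_rank} (integer in [-9, 9]) and
#'   \code{direction} ("activation", "inhibition" or "none").
#' @export
classifyCurve <- function(fit, conc_uM, pct_activity) {
  stopifnot(is(fit, "HillFit"))
  o <- order(conc_uM)
  x <- conc_uM[o]; y <- pct_activity[o]

  # class 3: significant response only at the highest tested concentration
  n <- length(y)
  if (n >= 2 && abs(y[n]) >= 30 && all(abs(y[-n]) < 30)) {
    dir <- if (y[n] > 0) "activation" else "inhibition"
    return(list(curve_class = "3",
                curve_rank = if (dir == "activation") 1L else -1L,
                direction = dir))
  }
  if (!fit@converged || abs(fit@efficacy) < 30)
    return(list(curve_class = "4", curve_rank = 0L, direction = "none"))

  # fraction of the S0 -> Sinf transition realized at the range ends
  frac <- function(xx) 1 / (1 + (fit@ac50 / xx)^fit@hill)
  lower_reached <- frac(min(x)) <= 0.1
  upper_reached <- frac(max(x)) >= 0.9
  cls_major <- if (lower_reached && upper_reached) "1" else "2"
  high_quality <- is.finite(fit@r2) && fit@r2 >= 0.9 && abs(fit@efficacy) >= 80
  cls <- paste0(cls_major, if (high_quality) ".1" else ".2")

  tier_hi <- abs(fit@efficacy) >= 80
  base <- switch(cls,
    "1.1" = if (tier_hi) 9L else 8L,
    "1.2" = if (tier_hi) 7L else 6L,
    "2.1" = if (tier_hi) 5L else 4L,
    "2.2" = if (tier_hi) 3L else 2L)
  dir <- if (fit@efficacy > 0) "activation" else "inhibition"
  rank <- if (dir == "activation") base else -base
  list(curve_class = cls, curve_rank = rank, direction = dir)
}

#' KeratinoSens activity summary (EC1.5 and Imax)
#'
#' On the normalized percent-activity scale (0\% = DMSO, 100\% = 2-fold
#' induction), fold induction at concentration x is
#' \eqn{fold(x) = 1 + y(x)/100}, so the 1.5-fold threshold corresponds to
#' y = 50\%. EC1.5 is the smallest tested concentration at which the fitted
#' curve crosses 50\% activity (absent when the threshold is never reached
#' within the tested range); Imax is the maximal activity, reported both as
#' the observed maximum and the fitted-curve maximum.
#'
#' @param fit a \code{\link{HillFit}}.
#' @param conc_uM,pct_activity observed series.
#' @return list with \code{ec15_uM} (numeric or \code{NA}),
#'   \code{imax_obs_pct}, \code{imax_fit_pct}.
#' @export
ksActivitySummary <- function(fit, conc_uM, pct_activity) {
  stopifnot(is(fit, "HillFit"))
  imax_obs <- max(pct_activity)
  if (!fit@converged) {
    return(list(ec15_uM = NA_real_, imax_obs_pct = imax_obs,
                imax_fit_pct = NA_real_))
  }
  xmin <- min(conc_uM); xmax <- max(conc_uM)
  yfit <- function(xx) hillCurve(xx, fit@s0, fit@sinf, fit@ac50, fit@hill)
  imax_fit <- max(yfit(c(xmin, xmax)))
  ec15 <- NA_real_
  if (yfit(xmin) >= 50) {
    ec15 <- xmin
  } else if (fit@sinf > fit@s0 && yfit(xmax) >= 50) {
    # invert y(x) = 50 on the monotone fitted curve
    f <- (50 - fit@s0) / (fit@sinf - fit@s0)
    ec15 <- fit@ac50 * (f / (1 - f))^(1 / fit@hill)
    ec15 <- min(max(ec15, xmin), xmax)
  }
  list(ec15_uM = ec15, imax_obs_pct = imax_obs, imax_fit_pct = imax_fit)
}

#' Tri-run activity outcome
#'
#' Combines per-run curve ranks into an overall activity outcome. A run is
#' active when |rank| > 3. The compound is \code{"active"} when at least two
#' runs are active in the same direction; \code{"inactive"} when at least
#' two runs are rank 0 and no run shows a high-quality active curve
#' (|rank| >= 5); otherwise \code{"inconclusive"}.
#'
#' @param curve_ranks integer vector of per-run curve ranks.
#' @return one of \code{"active"}, \code{"inactive"}, \code{"inconclusive"}.
#' @export
activityOutcome <- function(curve_ranks) {
  stopifnot(length(curve_ranks) >= 1, all(abs(curve_ranks) <= 9))
  act_pos <- sum(curve_ranks > 3)
  act_neg <- sum(curve_ranks < -3)
  if (act_pos >= 2 || act_neg >= 2) return("active")
  if (sum(curve_ranks == 0) >= 2 && !any(abs(curve_ranks) >= 5))
    return("inactive")
  "inconclusive"
}

#' Fit and classify every compound series in a plate dataset
#'
#' Pipeline over a \code{\link{PlateDataset}}: normalizes to percent
#' activity, optionally masks cytotoxic concentrations using a paired
#' viability dataset, fits a Hill curve per compound and run, classifies it,
#' computes the KS activity summary, and combines runs into a tri-run
#' outcome.
#'
#' @param plate a \code{\link{PlateDataset}}.
#' @param viability optional \code{\link{PlateDataset}} measured in parallel;
#'   concentrations where viability falls below
#'   \code{viability_threshold} x 100\% of control (i.e. normalized percent
#'   activity below \code{(viability_threshold - 1) * 100}) are excluded
#'   from the fit.
#' @param viability_threshold fraction of control viability below which
#'   points are masked (default 0.7).
#' @return list with \code{fits}: data.frame of per-compound-per-run results
#'   (columns compound_id, run, s0, sinf, ac50_uM, hill, efficacy, r2,
#'   curve_class, curve_rank, ec15_uM, imax_pct), and \code{outcomes}:
#'   data.frame (compound_id, outcome).
#' @export
fitPlateDataset <- function(plate, viability = NULL,
                            viability_threshold = 0.7) {
  norm <- normalizePercentActivity(plate)
  if (!is.null(viability)) {
    vn <- normalizePercentActivity(viability)
    key <- function(d) paste(d$compound_id, d$run, signif(d$conc_uM, 8))
    viab_frac <- setNames(1 + vn$pct_activity / 100, key(vn))
    vf <- viab_frac[key(norm)]
    keep <- is.na(vf) | vf >= viability_threshold
    norm <- norm[keep, , drop = FALSE]
  }
  series <- split(norm, list(norm$compound_id, norm$run), drop = TRUE)
  rows <- lapply(series, function(s) {
    fit <- tryCatch(fitHillCurve(s$conc_uM, s$pct_activity),
                    error = function(e) NULL)
    if (is.null(fit))
      fit <- new("HillFit", s0 = NA_real_, sinf = NA_real_, ac50 = NA_real_,
                 hill = NA_real_, efficacy = 0, r2 = NA_real_,
                 converged = FALSE)
    cl <- classifyCurve(fit, s$conc_uM, s$pct_activity)
    ks <- ksActivitySummary(fit, s$conc_uM, s$pct_activity)
    data.frame(compound_id = s$compound_id[1], run = s$run[1],
               s0 = fit@s0, sinf = fit@sinf, ac50_uM = fit@ac50,
               hill = fit@hill, efficacy = fit@efficacy, r2 = fit@r2,
               curve_class = cl$curve_class, curve_rank = cl$curve_rank,
               ec15_uM = ks$ec15_uM, imax_pct = ks$imax_obs_pct)
  })
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  fits <- fits[order(fits$compound_id, fits$run), ]
  outcomes <- do.call(rbind, lapply(split(fits, fits$compound_id),
    function(d) data.frame(compound_id = d$compound_id[1],
                           outcome = activityOutcome(d$curve_rank))))
  rownames(outcomes) <- NULL
  list(fits = fits, outcomes = outcomes)
}
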