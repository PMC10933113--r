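# Small in-code fixtures shared across test files.

# A minimal single-run plate with hand-set signals: DMSO wells with median
# 100 and one compound with the given raw signals over a 4+-point series.
makeTinyPlate <- function(signals, conc = NULL, dmso_signal = rep(100, 8)) {
  if (is.null(conc)) conc <- 10^seq(-2, 1, length.out = length(signals))
  wells <- rbind(
    data.frame(compound_id = "CMP1", conc_uM = conc, signal = signals,
               run = 1L, is_dmso = FALSE),
    data.frame(compound_id = NA_character_, conc_uM = NA_real_,
               signal = dmso_signal, run = 1L, is_dmso = TRUE))
  new("PlateDataset", wells = wells, nRuns = 1L)
}

# Noise-free Hill series on a 15-point qHTS-style dilution.
makeHillSeries <- function(s0, sinf, ac50, h,
                           conc = 10^seq(log10(0.0028), log10(92),
                                         length.out = 15)) {
  list(conc = conc, y = hillCurve(conc, s0, sinf, ac50, h))
}

# Independent two-sided Fisher p-value by hypergeometric enumeration over
# all 2x2 tables with the observed margins: sum the probabilities of all
# tables no more likely than the observed one (standard tie tolerance).
enumFisherP <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
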