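#' Simulate qHTS dose-response plates with known ground truth
#'
#' Generates raw well-level signals for a titration screen: each compound is
#' tested on a constant log-step dilution series in each of \code{n_runs}
#' independent runs, together with DMSO vehicle-control wells. Active
#' compounds follow a four-parameter Hill response (activation or
#' inhibition, chosen by the sign of the simulated efficacy); inactive
#' compounds are flat at baseline. Gaussian noise on the percent-activity
#' scale is applied to every well.
#'
#' Defaults mirror a 1536-well qHTS design: a 15-point series from 2.8 nM
#' to 92 uM, three independent runs, 32 DMSO wells per run, and 5\%
#' plate noise.
#'
#' @param n_compounds number of compounds (> 0).
#' @param active_fraction fraction of compounds carrying a true
#'   dose-response (exactly \code{round(n_compounds * active_fraction)}
#'   compounds are made active).
#' @param noise_sd Gaussian noise SD in percent-activity units.
#' @param conc_range numeric length-2, (min, max) concentration in uM.
#' @param n_conc number of titration points.
#' @param n_runs number of independent runs (>= 1).
#' @param n_dmso_wells DMSO-control wells per run (>= 8).
#' @param baseline_signal raw signal of the vehicle control.
#' @param seed integer; fixes all randomness.
#' @return list with \code{plate} (a \code{\link{PlateDataset}}) and
#'   \code{truth}: data.frame with \code{compound_id}, \code{true_active},
#'   and the generating Hill parameters \code{s0}, \code{sinf},
#'   \code{ac50_uM}, \code{hill} (NA for inactives).
#' @examples
#' sim <- simulateDoseResponsePlates(10, active_fraction = 0.2, seed = 1)
#' sim$plate
#' @export
simulateDoseResponsePlates <- function(n_compounds,
                                       active_fraction = 0.2,
                                       noise_sd = 5,
                                       conc_range = c(0.0028, 92),
                                       n_conc = 15L,
                                       n_runs = 3L,
                                       n_dmso_wells = 32L,
                                       baseline_signal = 100,
                                       seed = 1L) {
  if (n_compounds < 1) stop("invalid argument: n_compounds must be >= 1")
  if (any(conc_range <= 0) || conc_range[1] >= conc_range[2])
    stop("invalid argument: conc_range must be positive and increasing")
  if (active_fraction < 0 || active_fraction > 1)
    stop("invalid argument: active_fraction must be in [0, 1]")
  if (n_runs < 1) stop("invalid argument: n_runs must be >= 1")
  set.seed(seed)

  ids <- sprintf("CMP%05d", seq_len(n_compounds))
  n_active <- round(n_compounds * active_fraction)
  active <- rep(FALSE, n_compounds)
  active[sample.int(n_compounds, n_active)] <- TRUE

  # AC50 kept well inside the tested range so asymptotes are reachable
  lmin <- log10(conc_range[1]); lmax <- log10(conc_range[2])
  ac50 <- ifelse(active,
                 10^runif(n_compounds, lmin + 1.3, lmax - 1.3), NA_real_)
  direction <- ifelse(runif(n_compounds) < 0.5, 1, -1)
  eff <- ifelse(active, direction * runif(n_compounds, 60, 110), NA_real_)
  hill <- ifelse(active, runif(n_compounds, 0.8, 2.5), NA_real_)
  s0 <- ifelse(active, 0, NA_real_)

  conc <- 10^seq(lmin, lmax, length.out = n_conc)
  grid <- expand.grid(ci = seq_len(n_compounds), conc_uM = conc,
                      run = seq_len(n_runs))
  y_true <- ifelse(active[grid$ci],
                   hillCurve(grid$conc_uM, 0, eff[grid$ci], ac50[grid$ci],
                             hill[grid$ci]),
                   0)
  y_obs <- y_true + rnorm(nrow(grid), 0, noise_sd)
  wells <- data.frame(compound_id = ids[grid$ci], conc_uM = grid$conc_uM,
                      signal = baseline_signal * (1 + y_obs / 100),
                      run = grid$run, is_dmso = FALSE)
  dmso <- data.frame(compound_id = NA_character_, conc_uM = NA_real_,
                     signal = baseline_signal *
                       (1 + rnorm(n_dmso_wells * n_runs, 0, noise_sd) / 100),
                     run = rep(seq_len(n_runs), each = n_dmso_wells),
                     is_dmso = TRUE)
  plate <- new("PlateDataset", wells = rbind(wells, dmso),
               nRuns = as.integer(n_runs))
  truth <- data.frame(compound_id = ids, true_active = active,
                      s0 = s0, sinf = s0 + eff, ac50_uM = ac50, hill = hill)
  list(plate = plate, truth = truth)
}

# Sample a quantitative DPRA block realizing a given ITS DPRA score.
# Values are drawn strictly inside the open score bins so boundary ties
# cannot occur; cys and lys depletion are set equal, making the mean-based
# and TG calls consistent by construction.
.sim_dpra <- function(score) {
  dep <- switch(as.character(score),
    "0" = runif(1, 0, 6.0),
    "1" = runif(1, 6.6, 22.4),
    "2" = runif(1, 22.9, 42.2),
    "3" = runif(1, 42.8, 97.5))
  rank <- if (score == 0) 0L else -as.integer(sample(4:9, 1))
  list(cys = dep, lys = dep, cys_rank = rank, lys_rank = rank)
}

.sim_hclat <- function(score) {
  if (score == 0)
    return(list(cd86 = runif(1, 0.6, 1.4), cd54 = runif(1, 0.6, 1.9),
                mit = NA_real_))
  mit <- switch(as.character(score),
    "1" = runif(1, 160, 4500),
    "2" = runif(1, 10.5, 149),
    "3" = runif(1, 0.5, 9.9))
  list(cd86 = runif(1, 1.6, 3.5), cd54 = runif(1, 2.1, 4.5), mit = mit)
}

.sim_ks <- function(positive) {
  if (positive)
    list(ec15 = 10^runif(1, -1, 1.6), imax = runif(1, 70, 160),
         rank = as.integer(sample(4:9, 1)))
  else
    list(ec15 = NA_real_, imax = runif(1, -10, 35), rank = 0L)
}

.sim_il8 <- function(positive) {
  if (positive) {
    fold <- runif(1, 1.5, 3)
    list(fold = fold, ci_lower = fold - runif(1, 0.05, min(0.4, fold - 1.05)))
  } else {
    fold <- runif(1, 0.8, 1.3)
    list(fold = fold, ci_lower = fold - runif(1, 0.05, 0.3))
  }
}

# Valid (hclat_score, dpra_score, insilico_score) combinations per GHS
# class, chosen so that ITS, STS and 2o3 all recover the class exactly at
# zero noise (see the methods vignette for the derivation).
.its_combos <- function(ghs) {
  if (ghs == "1A") {
    list(c(3, 3, 0), c(3, 3, 1), c(3, 2, 1))
  } else if (ghs == "1B") {
    out <- list()
    for (h in 0:2) for (d in 0:3) for (i in 0:1) {
      tot <- h + d + i
      if (tot < 2 || tot > 5) next
      if (h == 0 && d == 0) next      # STS would call NC
      out[[length(out) + 1L]] <- c(h, d, i)
    }
    out
  } else {
    list(c(0, 0, 0))
  }
}

#' Simulate assay-call panels from known GHS ground truth
#'
#' Generates per-compound DPRA depletions, KeratinoSens summaries, hCLAT
#' RFIs/MIT, IL-8 fold inductions, and in silico predictions such that, at
#' zero noise and zero missingness, the ITSv2 and STS defined approaches
#' recover the generating GHS class exactly and the 2o3 hazard call matches
#' (sensitizer for 1A/1B). Generation works backwards from the ITS score
#' table: a valid component-score combination for the class is sampled,
#' then quantitative values are drawn strictly inside the corresponding
#' score bins.
#'
#' \code{flip_noise} perturbs each assay source independently (the source
#' is re-drawn from the opposite call regime); \code{missingness} blanks
#' the in silico and hCLAT entries independently at the given rate,
#' emulating out-of-domain predictions and untested compounds.
#'
#' @param n_compounds number of compounds.
#' @param ghs_mix length-3 probabilities (1A, 1B, NC); must sum to 1.
#' @param missingness probability of blanking the in silico field and,
#'   independently, the hCLAT fields.
#' @param flip_noise per-source perturbation probability in [0, 0.5).
#' @param seed integer seed.
#' @return list with \code{panel} (a \code{\link{CompoundAssayPanel}}) and
#'   \code{truth}: data.frame with \code{compound_id}, \code{true_ghs}.
#' @examples
#' sim <- simulateAssayPanels(20, seed = 7)
#' table(sim$truth$true_ghs)
#' @export
simulateAssayPanels <- function(n_compounds,
                                ghs_mix = c(0.05, 0.45, 0.50),
                                missingness = 0,
                                flip_noise = 0,
                                seed = 1L) {
  if (n_compounds < 1) stop("invalid argument: n_compounds must be >= 1")
  if (abs(sum(ghs_mix) - 1) > 1e-8 || any(ghs_mix < 0))
    stop("invalid argument: ghs_mix must be non-negative and sum to 1")
  if (flip_noise < 0 || flip_noise >= 0.5)
    stop("invalid argument: flip_noise must be in [0, 0.5)")
  if (missingness < 0 || missingness > 1)
    stop("invalid argument: missingness must be in [0, 1]")
  set.seed(seed)

  ids <- sprintf("CMP%05d", seq_len(n_compounds))
  ghs <- sample(c("1A", "1B", "NC"), n_compounds, replace = TRUE,
                prob = ghs_mix)
  rows <- lapply(seq_len(n_compounds), function(i) {
    combos <- .its_combos(ghs[i])
    sc <- combos[[sample.int(length(combos), 1)]]
    h_score <- sc[1]; d_score <- sc[2]; i_score <- sc[3]
    sens <- ghs[i] %in% c("1A", "1B")

    # flip_noise: re-draw individual sources from the opposite regime
    if (flip_noise > 0) {
      if (runif(1) < flip_noise)
        d_score <- if (d_score > 0) 0 else sample(1:3, 1)
      if (runif(1) < flip_noise)
        h_score <- if (h_score > 0) 0 else sample(1:3, 1)
      if (runif(1) < flip_noise) i_score <- 1 - i_score
    }
    dpra <- .sim_dpra(d_score)
    hclat <- .sim_hclat(h_score)
    ks_pos <- if (flip_noise > 0 && runif(1) < flip_noise) !sens else sens
    ks <- .sim_ks(ks_pos)
    il8_pos <- if (flip_noise > 0 && runif(1) < flip_noise) !sens else sens
    il8 <- .sim_il8(il8_pos)
    insil <- if (i_score == 1) "positive" else "negative"

    if (missingness > 0) {
      if (runif(1) < missingness) insil <- NA_character_
      if (runif(1) < missingness)
        hclat <- list(cd86 = NA_real_, cd54 = NA_real_, mit = NA_real_)
    }
    data.frame(
      compound_id = ids[i],
      dpra_cys_depletion = dpra$cys, dpra_lys_depletion = dpra$lys,
      dpra_cys_rank = dpra$cys_rank, dpra_lys_rank = dpra$lys_rank,
      ks_ec15_uM = ks$ec15, ks_imax_pct = ks$imax,
      ks_curve_rank = ks$rank,
      hclat_cd86_rfi = hclat$cd86, hclat_cd54_rfi = hclat$cd54,
      hclat_mit_ugml = hclat$mit,
      il8_fold = il8$fold, il8_ci_lower = il8$ci_lower,
      insilico_call = insil)
  })
  d <- do.call(rbind, rows)
  panel <- computePanelCalls(CompoundAssayPanel(d))
  pd <- panelData(panel)
  pd$il8_call_rank <- NA_character_
  panel <- new("CompoundAssayPanel", data = pd)
  list(panel = panel,
       truth = data.frame(compound_id = ids, true_ghs = ghs))
}

#' Simulate a binary fingerprint dataset with planted enrichment
#'
#' Generates a compounds x features 0/1 matrix with binary activity labels.
#' A chosen subset of features is enriched in the active class: their
#' Bernoulli odds are multiplied by \code{odds_ratio} relative to the
#' baseline prevalence; all other features share the baseline prevalence in
#' both classes.
#'
#' @param n_compounds number of compounds.
#' @param n_features number of fingerprint bits (default 729, the ToxPrint
#'   chemotype count).
#' @param n_enriched number of planted enriched features
#'   (<= \code{n_features}).
#' @param odds_ratio odds multiplier in actives (> 0); 1 means no
#'   enrichment.
#' @param base_prevalence Bernoulli prevalence of every feature in
#'   inactives (and of non-enriched features in actives).
#' @param active_fraction fraction of active compounds (exact count
#'   \code{round(n_compounds * active_fraction)}); ignored when
#'   \code{n_active} is given.
#' @param n_active optional explicit number of actives.
#' @param seed integer seed.
#' @return list with \code{dataset} (a \code{\link{FingerprintDataset}})
#'   and \code{enriched_features}: integer indices of the planted features.
#' @examples
#' sim <- simulateFingerprintSet(200, n_features = 50, n_enriched = 5,
#'                               odds_ratio = 8, seed = 3)
#' sim$dataset
#' @export
simulateFingerprintSet <- function(n_compounds,
                                   n_features = 729L,
                                   n_enriched = 0L,
                                   odds_ratio = 1,
                                   base_prevalence = 0.1,
                                   active_fraction = 0.1,
                                   n_active = NULL,
                                   seed = 1L) {
  if (odds_ratio <= 0) stop("invalid argument: odds_ratio must be > 0")
  if (n_enriched > n_features)
    stop("invalid argument: n_enriched must be <= n_features")
  if (base_prevalence <= 0 || base_prevalence >= 1)
    stop("invalid argument: base_prevalence must be in (0, 1)")
  set.seed(seed)
  if (is.null(n_active)) n_active <- round(n_compounds * active_fraction)
  if (n_active < 1 || n_active >= n_compounds)
    stop("invalid argument: both classes must be non-empty")

  labels <- rep("inactive", n_compounds)
  labels[sample.int(n_compounds, n_active)] <- "active"
  enriched <- sort(sample.int(n_features, n_enriched))

  p0 <- base_prevalence
  p1 <- (odds_ratio * p0 / (1 - p0)) / (1 + odds_ratio * p0 / (1 - p0))
  pmat <- matrix(p0, n_compounds, n_features)
  if (n_enriched > 0)
    pmat[labels == "active", enriched] <- p1
  m <- matrix(rbinom(n_compounds * n_features, 1, as.vector(pmat)),
              n_compounds, n_features)
  rownames(m) <- sprintf("CMP%05d", seq_len(n_compounds))
  colnames(m) <- sprintf("F%04d", seq_len(n_features))
  list(dataset = FingerprintDataset(m, labels),
       enriched_features = enriched)
}

#' Simulate a chemotype membership table
#'
#' Builds a \code{\link{ChemotypeTable}} with primary clusters of the
#' requested sizes; when \code{multiplicity > 1}, compounds additionally
#' carry extra chemotype memberships (Poisson with mean
#' \code{multiplicity - 1}), reflecting that one compound can match several
#' structural chemotypes.
#'
#' @param cluster_sizes integer vector of requested primary-cluster sizes
#'   (one entry per chemotype); must be non-empty.
#' @param multiplicity mean number of chemotypes per compound (>= 1).
#' @param seed integer seed.
#' @return a \code{\link{ChemotypeTable}}. Realized cluster sizes are
#'   available via \code{\link{chemotypeClusterSizes}}; they equal
#'   \code{cluster_sizes} exactly when \code{multiplicity = 1}.
#' @examples
#' ct <- simulateChemotypeTable(c(10, 10, 25), seed = 2)
#' chemotypeClusterSizes(ct)
#' @export
simulateChemotypeTable <- function(cluster_sizes, multiplicity = 1,
                                   seed = 1L) {
  if (length(cluster_sizes) == 0 || any(cluster_sizes < 1))
    stop("invalid argument: cluster_sizes must be a non-empty positive vector")
  if (multiplicity < 1) stop("invalid argument: multiplicity must be >= 1")
  set.seed(seed)
  n_chem <- length(cluster_sizes)
  chem_ids <- sprintf("CT%04d", seq_len(n_chem))
  n_compounds <- sum(cluster_sizes)
  ids <- sprintf("CMP%05d", seq_len(n_compounds))
  primary <- rep(chem_ids, times = cluster_sizes)
  memb <- data.frame(compound_id = ids, chemotype_id = primary)
  if (multiplicity > 1 && n_chem > 1) {
    extra <- lapply(seq_len(n_compounds), function(i) {
      k <- min(rpois(1, multiplicity - 1), n_chem - 1L)
      if (k == 0) return(NULL)
      data.frame(compound_id = ids[i],
                 chemotype_id = sample(setdiff(chem_ids, primary[i]), k))
    })
    memb <- rbind(memb, do.call(rbind, extra))
  }
  memb <- memb[order(memb$compound_id, memb$chemotype_id), ]
  rownames(memb) <- NULL
  new("ChemotypeTable", memberships = memb)
}
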