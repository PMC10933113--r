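#' @import methods
#' @importFrom stats median sd var quantile rnorm runif rbinom rpois qt
#'   setNames predict fisher.test residuals coef dist
#' @importFrom utils read.delim write.table head
NULL

#' PlateDataset: raw qHTS plate wells across runs
#'
#' Container for raw well-level signals from a quantitative high-throughput
#' screen. Each well is either a compound well (with a titration
#' concentration) or a DMSO vehicle-control well. Wells are grouped by
#' independent run; normalization is performed per run against the median of
#' that run's DMSO wells.
#'
#' @slot wells data.frame with columns \code{compound_id} (character, \code{NA}
#'   for DMSO wells), \code{conc_uM} (numeric, \code{NA} for DMSO wells),
#'   \code{signal} (numeric raw plate read), \code{run} (integer run index)
#'   and \code{is_dmso} (logical vehicle-control flag).
#' @slot nRuns integer count of independent runs.
#'
#' @seealso [simulateDoseResponsePlates()], [normalizePercentActivity()]
#' @export
setClass("PlateDataset",
  representation(wells = "data.frame", nRuns = "integer"))

setValidity("PlateDataset", function(object) {
  w <- object@wells
  need <- c("compound_id", "conc_uM", "signal", "run", "is_dmso")
  if (!all(need %in% names(w)))
    return(paste("wells must have columns:", paste(need, collapse = ", ")))
  if (object@nRuns < 1L) return("nRuns must be >= 1")
  cw <- w[!w$is_dmso, , drop = FALSE]
  if (nrow(cw) && any(!is.finite(cw$conc_uM) | cw$conc_uM <= 0))
    return("compound well concentrations must be positive and finite")
  ndmso <- table(factor(w$run[w$is_dmso], levels = seq_len(object@nRuns)))
  if (any(ndmso < 8L))
    return("every run must contain at least 8 DMSO-control wells")
  TRUE
})

#' @describeIn PlateDataset number of wells
#' @param x,object a \code{PlateDataset}
#' @export
setMethod("length", "PlateDataset", function(x) nrow(x@wells))

setMethod("show", "PlateDataset", function(object) {
  w <- object@wells
  cat("PlateDataset:", length(unique(w$compound_id[!w$is_dmso])),
      "compounds,", object@nRuns, "run(s),",
      sum(w$is_dmso), "DMSO wells,", nrow(w), "wells total\n")
})

#' Accessor for plate wells
#' @param object a \code{PlateDataset}
#' @return the well-level data.frame
#' @export
plateWells <- function(object) {
  stopifnot(is(object, "PlateDataset"))
  object@wells
}

#' Number of independent runs in a plate dataset
#' @param object a \code{PlateDataset}
#' @export
plateRuns <- function(object) {
  stopifnot(is(object, "PlateDataset"))
  object@nRuns
}

#' HillFit: four-parameter Hill concentration-response fit
#'
#' Parameters of the four-parameter Hill model
#' \eqn{y(x) = S_0 + (S_\infty - S_0) / (1 + (AC_{50}/x)^h)} fitted to a
#' normalized concentration-response series (percent-activity scale).
#'
#' @slot s0 numeric baseline asymptote (\% activity).
#' @slot sinf numeric plateau asymptote (\% activity).
#' @slot ac50 numeric half-maximal concentration (uM).
#' @slot hill numeric Hill coefficient.
#' @slot efficacy numeric signed maximal response, \code{sinf - s0}.
#' @slot r2 numeric coefficient of determination on the fitted points.
#' @slot converged logical; \code{FALSE} when the optimizer failed or the
#'   fit is degenerate.
#'
#' @seealso [fitHillCurve()]
#' @export
setClass("HillFit",
  representation(s0 = "numeric", sinf = "numeric", ac50 = "numeric",
                 hill = "numeric", efficacy = "numeric", r2 = "numeric",
                 converged = "logical"))

setValidity("HillFit", function(object) {
  if (object@converged && (!is.finite(object@ac50) || object@ac50 <= 0))
    return("converged fit must have AC50 > 0")
  if (is.finite(object@efficacy) && is.finite(object@s0) &&
      is.finite(object@sinf) &&
      abs(abs(object@efficacy) - abs(object@sinf - object@s0)) > 1e-6)
    return("|efficacy| must equal |sinf - s0|")
  TRUE
})

setMethod("show", "HillFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "HillFit: S0=%.2f%% Sinf=%.2f%% AC50=%.4g uM h=%.2f r2=%.3f\n",
      object@s0, object@sinf, object@ac50, object@hill, object@r2))
  else cat("HillFit: not converged\n")
})

#' Extract Hill parameters as a named vector
#' @param fit a \code{HillFit}
#' @return named numeric vector (s0, sinf, ac50, hill, efficacy, r2)
#' @export
hillParams <- function(fit) {
  stopifnot(is(fit, "HillFit"))
  c(s0 = fit@s0, sinf = fit@sinf, ac50 = fit@ac50, hill = fit@hill,
    efficacy = fit@efficacy, r2 = fit@r2)
}

#' CompoundAssayPanel: consolidated per-compound assay results
#'
#' One row per compound, holding quantitative summaries and positive /
#' negative calls for the assays feeding the defined approaches: DPRA
#' cysteine/lysine peptide depletion, KeratinoSens (KS) Nrf2/ARE induction,
#' hCLAT CD86/CD54 surface-marker induction, IL-8 release, and an in silico
#' hazard prediction. Missing values are \code{NA}; calls are
#' \code{"positive"}/\code{"negative"} or \code{NA} (absent); the in silico
#' field additionally admits \code{"out_of_domain"}.
#'
#' @slot data data.frame with the documented panel columns (see
#'   [assayPanelColumns()]).
#'
#' @seealso [simulateAssayPanels()], [applyDefinedApproaches()]
#' @export
setClass("CompoundAssayPanel", representation(data = "data.frame"))

#' Column contract of a CompoundAssayPanel
#'
#' @return character vector of required column names.
#' @export
assayPanelColumns <- function() {
  c("compound_id",
    "dpra_cys_depletion", "dpra_lys_depletion", "dpra_cys_rank",
    "dpra_lys_rank", "dpra_call_tg", "dpra_call_rank",
    "ks_ec15_uM", "ks_imax_pct", "ks_curve_rank", "ks_call_tg",
    "ks_call_rank",
    "hclat_cd86_rfi", "hclat_cd54_rfi", "hclat_mit_ugml", "hclat_call",
    "il8_fold", "il8_ci_lower", "il8_call_tg", "il8_call_rank",
    "insilico_call")
}

setValidity("CompoundAssayPanel", function(object) {
  d <- object@data
  miss <- setdiff(assayPanelColumns(), names(d))
  if (length(miss))
    return(paste("panel is missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$compound_id)) return("duplicated compound_id")
  callcols <- grep("_call", names(d), value = TRUE)
  for (cc in setdiff(callcols, "insilico_call")) {
    bad <- !is.na(d[[cc]]) & !d[[cc]] %in% c("positive", "negative")
    if (any(bad)) return(paste("invalid values in", cc))
  }
  bad <- !is.na(d$insilico_call) &
    !d$insilico_call %in% c("positive", "negative", "out_of_domain")
  if (any(bad)) return("invalid values in insilico_call")
  TRUE
})

setMethod("show", "CompoundAssayPanel", function(object) {
  d <- object@data
  cat("CompoundAssayPanel:", nrow(d), "compounds\n")
  for (cc in c("dpra_call_tg", "ks_call_tg", "hclat_call", "insilico_call"))
    cat(sprintf("  %-14s pos=%d neg=%d absent/ood=%d\n", cc,
        sum(d[[cc]] %in% "positive"), sum(d[[cc]] %in% "negative"),
        sum(is.na(d[[cc]]) | d[[cc]] %in% "out_of_domain")))
})

#' @describeIn CompoundAssayPanel number of compounds
#' @param x,object a \code{CompoundAssayPanel}
#' @export
setMethod("length", "CompoundAssayPanel", function(x) nrow(x@data))

#' Accessor for the panel data.frame
#' @param object a \code{CompoundAssayPanel}
#' @export
panelData <- function(object) {
  stopifnot(is(object, "CompoundAssayPanel"))
  object@data
}

#' Construct a CompoundAssayPanel from a data.frame
#'
#' Missing panel columns are added as \code{NA} so that partial panels (for
#' example DPRA + hCLAT only) can still be fed to the defined approaches.
#'
#' @param data data.frame with at least \code{compound_id}.
#' @return a \code{CompoundAssayPanel}
#' @export
CompoundAssayPanel <- function(data) {
  stopifnot(is.data.frame(data), "compound_id" %in% names(data))
  for (col in setdiff(assayPanelColumns(), names(data))) {
    data[[col]] <- rep(if (grepl("_call", col)) NA_character_ else NA_real_,
                       nrow(data))
  }
  data$compound_id <- as.character(data$compound_id)
  new("CompoundAssayPanel", data = data[, assayPanelColumns(), drop = FALSE])
}

#' ChemotypeTable: compound-to-chemotype memberships
#'
#' Many-to-many mapping between compounds and structural chemotypes (for
#' example ToxPrint features used as cluster labels). One compound may carry
#' several chemotypes; cluster size is the number of member compounds.
#'
#' @slot memberships data.frame with columns \code{compound_id} and
#'   \code{chemotype_id}, one row per membership.
#'
#' @seealso [assignRepresentativeChemotype()]
#' @export
setClass("ChemotypeTable", representation(memberships = "data.frame"))

setValidity("ChemotypeTable", function(object) {
  m <- object@memberships
  if (!all(c("compound_id", "chemotype_id") %in% names(m)))
    return("memberships needs compound_id and chemotype_id columns")
  if (anyDuplicated(m[, c("compound_id", "chemotype_id")]))
    return("duplicated membership rows")
  TRUE
})

setMethod("show", "ChemotypeTable", function(object) {
  m <- object@memberships
  cat("ChemotypeTable:", length(unique(m$compound_id)), "compounds,",
      length(unique(m$chemotype_id)), "chemotypes,",
      nrow(m), "memberships\n")
})

#' Accessor for chemotype memberships
#' @param object a \code{ChemotypeTable}
#' @export
chemotypeMemberships <- function(object) {
  stopifnot(is(object, "ChemotypeTable"))
  object@memberships
}

#' Cluster sizes of a ChemotypeTable
#' @param object a \code{ChemotypeTable}
#' @return named integer vector, chemotype id -> number of member compounds
#' @export
chemotypeClusterSizes <- function(object) {
  stopifnot(is(object, "ChemotypeTable"))
  tab <- table(object@memberships$chemotype_id)
  setNames(as.integer(tab), names(tab))
}

#' FingerprintDataset: binary chemotype fingerprints with activity labels
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with features
#' (fingerprint bits) as rows and compounds as columns. The single assay
#' \code{"fingerprint"} is a 0/1 matrix; \code{colData} carries the binary
#' activity \code{label} (\code{"active"}/\code{"inactive"}).
#'
#' @seealso [simulateFingerprintSet()], [FingerprintDataset()]
#' @export
#' @import SummarizedExperiment
setClass("FingerprintDataset", contains = "SummarizedExperiment")

setValidity("FingerprintDataset", function(object) {
  if (!"fingerprint" %in% SummarizedExperiment::assayNames(object))
    return("needs an assay named 'fingerprint'")
  m <- SummarizedExperiment::assay(object, "fingerprint")
  if (!all(m %in% c(0, 1))) return("fingerprint entries must be 0/1")
  if (!"label" %in% names(SummarizedExperiment::colData(object)))
    return("colData must contain a 'label' column")
  lab <- object$label
  if (!all(lab %in% c("active", "inactive")))
    return("labels must be 'active'/'inactive'")
  if (length(unique(lab)) < 2L)
    return("both classes must be present")
  TRUE
})

#' Construct a FingerprintDataset
#'
#' @param fingerprints numeric 0/1 matrix, compounds in rows, features in
#'   columns (transposed internally to the features-by-compounds layout).
#' @param labels character vector, \code{"active"}/\code{"inactive"} per
#'   compound.
#' @param compound_ids,feature_ids optional identifier vectors; defaults are
#'   generated.
#' @return a \code{FingerprintDataset}
#' @export
FingerprintDataset <- function(fingerprints, labels,
                               compound_ids = rownames(fingerprints),
                               feature_ids = colnames(fingerprints)) {
  fingerprints <- as.matrix(fingerprints)
  if (is.null(compound_ids))
    compound_ids <- sprintf("C%05d", seq_len(nrow(fingerprints)))
  if (is.null(feature_ids))
    feature_ids <- sprintf("F%04d", seq_len(ncol(fingerprints)))
  stopifnot(length(labels) == nrow(fingerprints))
  m <- t(fingerprints)
  dimnames(m) <- list(feature_ids, compound_ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fingerprint = m),
    colData = S4Vectors::DataFrame(label = as.character(labels),
                                   row.names = compound_ids))
  new("FingerprintDataset", se)
}

#' Compounds-by-features fingerprint matrix
#' @param object a \code{FingerprintDataset}
#' @return numeric matrix, compounds in rows, features in columns
#' @export
fingerprintMatrix <- function(object) {
  stopifnot(is(object, "FingerprintDataset"))
  t(SummarizedExperiment::assay(object, "fingerprint"))
}

#' Activity labels of a FingerprintDataset
#' @param object a \code{FingerprintDataset}
#' @return character vector per compound ("active"/"inactive")
#' @export
activityLabels <- function(object) {
  stopifnot(is(object, "FingerprintDataset"))
  object$label
}

setMethod("show", "FingerprintDataset", function(object) {
  cat("FingerprintDataset:", ncol(object), "compounds x", nrow(object),
      "features;", sum(object$label == "active"), "active /",
      sum(object$label == "inactive"), "inactive\n")
})
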