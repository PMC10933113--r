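#' Read and write pipeline tables
#'
#' All pipeline containers round-trip through plain delimited text
#' (tab-separated by default) with stable, documented headers, so that
#' intermediate results can be inspected and exchanged between stages.
#'
#' @name qhtsSkinSens-io
NULL

.read_delim <- function(file, sep = "\t") {
  read.delim(file, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""))
}

.write_delim <- function(d, file, sep = "\t") {
  write.table(d, file, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(file)
}

#' @rdname qhtsSkinSens-io
#' @param object a container to write (\code{PlateDataset},
#'   \code{CompoundAssayPanel}, \code{ChemotypeTable} or
#'   \code{FingerprintDataset}).
#' @param file path to a delimited text file.
#' @param sep field separator (default tab).
#' @export
writePlateDataset <- function(object, file, sep = "\t") {
  stopifnot(is(object, "PlateDataset"))
  .write_delim(plateWells(object), file, sep)
}

#' @rdname qhtsSkinSens-io
#' @export
readPlateDataset <- function(file, sep = "\t") {
  w <- .read_delim(file, sep)
  w$is_dmso <- as.logical(w$is_dmso)
  new("PlateDataset", wells = w, nRuns = as.integer(max(w$run)))
}

#' @rdname qhtsSkinSens-io
#' @export
writeAssayPanel <- function(object, file, sep = "\t") {
  stopifnot(is(object, "CompoundAssayPanel"))
  .write_delim(panelData(object), file, sep)
}

#' @rdname qhtsSkinSens-io
#' @export
readAssayPanel <- function(file, sep = "\t") {
  CompoundAssayPanel(.read_delim(file, sep))
}

#' @rdname qhtsSkinSens-io
#' @export
writeChemotypeTable <- function(object, file, sep = "\t") {
  stopifnot(is(object, "ChemotypeTable"))
  .write_delim(chemotypeMemberships(object), file, sep)
}

#' @rdname qhtsSkinSens-io
#' @export
readChemotypeTable <- function(file, sep = "\t") {
  new("ChemotypeTable", memberships = .read_delim(file, sep))
}

#' @rdname qhtsSkinSens-io
#' @details Fingerprint files carry the compound id in the first column,
#'   the activity label in the last column (\code{label}), and one 0/1
#'   feature column in between.
#' @export
writeFingerprintSet <- function(object, file, sep = "\t") {
  stopifnot(is(object, "FingerprintDataset"))
  m <- fingerprintMatrix(object)
  d <- data.frame(compound_id = rownames(m), m, check.names = FALSE)
  d$label <- activityLabels(object)
  .write_delim(d, file, sep)
}

#' @rdname qhtsSkinSens-io
#' @export
readFingerprintSet <- function(file, sep = "\t") {
  d <- .read_delim(file, sep)
  stopifnot(names(d)[1] == "compound_id", "label" %in% names(d))
  feats <- setdiff(names(d), c("compound_id", "label"))
  m <- as.matrix(d[, feats, drop = FALSE])
  rownames(m) <- d$compound_id
  FingerprintDataset(m, d$label)
}

#' Write a defined-approach summary as JSON
#'
#' Serializes the Venn counts and the ITS x STS potency contingency of a
#' batch of defined-approach results.
#'
#' @param da_results data.frame from \code{\link{applyDefinedApproaches}}.
#' @param file output JSON path.
#' @param n_total denominator for percent agreement (defaults to the
#'   number of compounds).
#' @return the file path, invisibly.
#' @export
writeDASummary <- function(da_results, file, n_total = NULL) {
  venn <- daVennCounts(da_results)
  cont <- potencyContingency(da_results, n_total = n_total)
  out <- list(venn = venn,
              contingency = as.data.frame.matrix(unclass(cont$table)),
              n_agree = cont$n_agree,
              agreement_pct = cont$agreement_pct,
              agreement_pct_resolved = cont$agreement_pct_resolved)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(file)
}
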