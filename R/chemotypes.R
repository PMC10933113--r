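#' Assign one representative chemotype per compound
#'
#' When a compound carries several chemotypes, one is chosen by cluster-size
#' band preference: medium-sized clusters (10-20 member compounds) first,
#' then clusters with fewer than 10 members, then clusters with more than
#' 20. Ties within a band are broken deterministically by larger cluster
#' size, then lexicographic chemotype id.
#'
#' @param table a \code{\link{ChemotypeTable}}.
#' @return data.frame with columns \code{compound_id},
#'   \code{chemotype_id}, \code{cluster_size}.
#' @examples
#' ct <- simulateChemotypeTable(c(5, 15, 30), multiplicity = 2, seed = 1)
#' head(assignRepresentativeChemotype(ct))
#' @export
assignRepresentativeChemotype <- function(table) {
  stopifnot(is(table, "ChemotypeTable"))
  m <- chemotypeMemberships(table)
  sizes <- chemotypeClusterSizes(table)
  band <- function(sz) ifelse(sz >= 10 & sz <= 20, 1L,
                              ifelse(sz < 10, 2L, 3L))
  m$size <- sizes[m$chemotype_id]
  m$band <- band(m$size)
  m <- m[order(m$compound_id, m$band, -m$size, m$chemotype_id), ]
  rep_rows <- m[!duplicated(m$compound_id), ]
  out <- data.frame(compound_id = rep_rows$compound_id,
                    chemotype_id = rep_rows$chemotype_id,
                    cluster_size = unname(rep_rows$size))
  rownames(out) <- NULL
  out
}

#' Prioritize compounds for follow-up testing
#'
#' Selects a fixed total number of compounds across representative
#' chemotype clusters, favouring potency and efficacy. Within each cluster,
#' compounds are ranked by ascending AC50 then descending efficacy.
#' Clusters with fewer than 3 members contribute only compounds passing the
#' activity gate (AC50 < 10 uM and efficacy > 50\%). Per-cluster quotas are
#' proportional to cluster size (so larger clusters contribute more
#' compounds), with a minimum of one for any cluster holding a qualifying
#' candidate, then adjusted by largest remainder to hit \code{total}
#' exactly; spare capacity is redistributed to clusters with remaining
#' candidates.
#'
#' @param assignments data.frame from
#'   \code{\link{assignRepresentativeChemotype}} (columns
#'   \code{compound_id}, \code{chemotype_id}, \code{cluster_size}).
#' @param activity data.frame with columns \code{compound_id},
#'   \code{ac50_uM}, \code{efficacy}.
#' @param total requested number of selected compounds.
#' @return data.frame of selected compounds (\code{compound_id},
#'   \code{chemotype_id}, \code{ac50_uM}, \code{efficacy}), at most
#'   \code{total} rows (fewer only when candidates run out).
#' @export
prioritizeCompounds <- function(assignments, activity, total) {
  stopifnot(total >= 0)
  d <- merge(assignments, activity, by = "compound_id")
  d <- d[is.finite(d$ac50_uM) & is.finite(d$efficacy), ]
  gate <- d$ac50_uM < 10 & d$efficacy > 50
  small <- d$cluster_size < 3
  d <- d[!small | gate, , drop = FALSE]
  if (nrow(d) == 0 || total == 0) return(d[0, ])
  d <- d[order(d$chemotype_id, d$ac50_uM, -d$efficacy), ]
  clusters <- split(d, d$chemotype_id)
  avail <- vapply(clusters, nrow, 0L)
  size <- vapply(clusters, function(x) x$cluster_size[1], 0)

  if (total >= sum(avail)) {
    out <- do.call(rbind, clusters)
  } else {
    # proportional-to-size quota, minimum 1, largest remainder, capped at
    # candidate availability with redistribution of the surplus
    raw <- pmax(size / sum(size) * total, 1)
    quota <- pmin(floor(raw), avail)
    rem <- total - sum(quota)
    while (rem > 0) {
      frac <- ifelse(quota < avail, raw - floor(raw) + size / sum(size), -Inf)
      pick <- which.max(frac)
      if (!is.finite(frac[pick])) break
      quota[pick] <- quota[pick] + 1L
      raw[pick] <- raw[pick] + 1
      rem <- rem - 1L
    }
    while (rem < 0) {
      pick <- which(quota == max(quota[quota > 0]))[1]
      quota[pick] <- quota[pick] - 1L
      rem <- rem + 1L
    }
    out <- do.call(rbind, Map(function(cl, q) head(cl, q), clusters,
                              as.list(quota)))
  }
  out <- out[order(out$chemotype_id, out$ac50_uM), ]
  rownames(out) <- NULL
  out[, c("compound_id", "chemotype_id", "ac50_uM", "efficacy")]
}

#' Chemotype-by-assay mean curve-rank matrix
#'
#' Aggregates per-compound curve ranks into a chemotype x assay matrix of
#' arithmetic mean curve ranks, the summary plotted as a chemotype activity
#' heatmap. Mixed-direction members cancel in the mean by design (the sign
#' structure is informative: activation assays positive, depletion assays
#' negative).
#'
#' @param assignments data.frame with \code{compound_id},
#'   \code{chemotype_id} (one representative chemotype per compound).
#' @param curve_ranks data.frame with \code{compound_id} and one numeric
#'   column of curve ranks per assay.
#' @return numeric matrix, chemotypes x assays, entries in [-9, 9];
#'   \code{NA} for chemotypes with no member measured in an assay.
#' @export
chemotypeActivityMatrix <- function(assignments, curve_ranks) {
  stopifnot(all(c("compound_id", "chemotype_id") %in% names(assignments)),
            "compound_id" %in% names(curve_ranks))
  assays <- setdiff(names(curve_ranks), "compound_id")
  d <- merge(assignments[, c("compound_id", "chemotype_id")], curve_ranks,
             by = "compound_id")
  chems <- sort(unique(d$chemotype_id))
  out <- matrix(NA_real_, length(chems), length(assays),
                dimnames = list(chems, assays))
  for (a in assays) {
    mm <- tapply(d[[a]], d$chemotype_id, mean, na.rm = TRUE)
    out[names(mm), a] <- as.numeric(mm)
  }
  out[is.nan(out)] <- NA_real_
  out
}
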