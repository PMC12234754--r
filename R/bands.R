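#' Molecular band assignment table
#'
#' Builds a band table: one row per named molecular band with its center,
#' matching tolerance (default 15 cm^-1 — deviations below the instrument
#' resolution are not significant), region and assignment text.
#'
#' @param center band centers, cm^-1, unique, within [500, 3300].
#' @param assignment molecular label per band.
#' @param region "fingerprint" or "high_wavenumber" per band.
#' @param tolerance matching tolerance per band, cm^-1, in (0, resolution].
#' @param resolutionHint instrument resolution bounding the tolerance.
#' @return data.frame with columns center, tolerance, region, assignment.
#' @export
bandTable <- function(center, assignment, region, tolerance = 15,
                      resolutionHint = 20) {
  center <- as.numeric(center)
  if (anyDuplicated(center)) stop("band centers must be unique")
  if (any(center < 500 | center > 3300))
    stop("band centers must lie within [500, 3300] cm^-1")
  tolerance <- rep_len(as.numeric(tolerance), length(center))
  if (any(tolerance <= 0 | tolerance > resolutionHint))
    stop("tolerances must lie in (0, resolutionHint]")
  if (!all(region %in% c("fingerprint", "high_wavenumber")))
    stop("region must be 'fingerprint' or 'high_wavenumber'")
  data.frame(center = center, tolerance = tolerance,
             region = rep_len(region, length(center)),
             assignment = rep_len(as.character(assignment), length(center)),
             stringsAsFactors = FALSE)
}

#' Default band table for head-and-neck tissue
#'
#' The packaged band table (inst/extdata/band_table.tsv): protein, lipid and
#' nucleic-acid bands of the fingerprint region plus the CH2/CH3 stretches of
#' the high-wavenumber region. Band pairs closer than one resolution element
#' (1444/1448 and 1656/1665) are merged into single entries at 1448 and 1656.
#'
#' @return data.frame as from \code{\link{bandTable}}.
#' @export
defaultBandTable <- function() {
  path <- system.file("extdata", "band_table.tsv", package = "RamanCohort",
                      mustWork = TRUE)
  readBandTable(path)
}

#' Read a band table from delimited text
#'
#' @param path TSV file with columns center, tolerance, region, assignment.
#' @return data.frame as from \code{\link{bandTable}}.
#' @export
readBandTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  bandTable(tab$center, tab$assignment, tab$region, tab$tolerance)
}

#' Assign detected peaks to molecular bands
#'
#' Each peak is matched to the nearest band center lying within that band's
#' tolerance; ties are broken toward the smaller center. Each band consumes
#' at most one peak (the closest wins); unmatched peaks are labelled
#' unassigned. The result is independent of the input peak order and the
#' operation is idempotent.
#'
#' @param peaks data.frame from \code{\link{detectPeaks}} (column
#'   \code{center} required).
#' @param table band table from \code{\link{bandTable}}.
#' @return \code{peaks} with added columns \code{band} (matched band center,
#'   NA if unassigned), \code{assignment} ("unassigned" if unmatched) and
#'   \code{deviation} (peak center minus band center).
#' @export
assignBands <- function(peaks, table = defaultBandTable()) {
  if (anyDuplicated(table$center)) stop("band centers must be unique")
  np <- nrow(peaks)
  out <- peaks
  out$band <- rep(NA_real_, np)
  out$assignment <- rep("unassigned", np)
  out$deviation <- rep(NA_real_, np)
  if (np == 0 || nrow(table) == 0) return(out)
  # candidate (peak, band) pairs within tolerance, best distance first;
  # ties toward the smaller band center, then smaller peak center (stable
  # under input permutation)
  cand <- expand.grid(p = seq_len(np), b = seq_len(nrow(table)))
  cand$dist <- abs(peaks$center[cand$p] - table$center[cand$b])
  cand <- cand[cand$dist <= table$tolerance[cand$b], , drop = FALSE]
  cand <- cand[order(cand$dist, table$center[cand$b], peaks$center[cand$p]), ,
               drop = FALSE]
  usedP <- logical(np); usedB <- logical(nrow(table))
  for (k in seq_len(nrow(cand))) {
    p <- cand$p[k]; b <- cand$b[k]
    if (usedP[p] || usedB[b]) next
    usedP[p] <- TRUE; usedB[b] <- TRUE
    out$band[p] <- table$center[b]
    out$assignment[p] <- table$assignment[b]
    out$deviation[p] <- peaks$center[p] - table$center[b]
  }
  out
}
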