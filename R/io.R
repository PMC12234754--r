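# Delimited-text spectrum files (wavenumber TAB intensity, '#' headers) with
# JSON metadata sidecars — the on-disk interface of the pipeline.

#' Read a spectrum from two-column delimited text
#'
#' Lines starting with '#' are headers; blank lines are ignored; each data
#' row is \code{wavenumber <TAB> intensity}. If the axis is not increasing
#' the rows are sorted with a warning.
#'
#' @param path file path.
#' @param resolutionHint instrument resolution recorded on the axis, cm^-1.
#' @return A \code{Spectrum}.
#' @export
readSpectrumFile <- function(path, resolutionHint = 20) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) < 8)
    stop("input error: fewer than 8 data rows in ", path)
  parts <- strsplit(trimws(lines[rows]), "[\t ]+")
  bad <- which(vapply(parts, function(p)
    length(p) < 2 || anyNA(suppressWarnings(as.numeric(p[1:2]))), logical(1)))
  if (length(bad) > 0)
    stop(sprintf("parse error at line %d of %s: '%s'",
                 rows[bad[1]], path, lines[rows[bad[1]]]))
  wn <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  y <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  if (is.unsorted(wn, strictly = TRUE)) {
    warning("axis not strictly increasing in ", path, "; sorting")
    o <- order(wn)
    wn <- wn[o]; y <- y[o]
  }
  Spectrum(wavenumberAxis(wn, resolutionHint), y)
}

#' Write a spectrum to two-column delimited text
#'
#' @param s a \code{Spectrum}.
#' @param path output path.
#' @param header named character vector written as '# key: value' lines.
#' @return \code{path}, invisibly.
#' @export
writeSpectrumFile <- function(s, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  writeLines(sprintf("%.15g\t%.15g", s@axis@values, s@intensities), con)
  invisible(path)
}

#' Read / write a site-metadata JSON sidecar
#'
#' The sidecar carries the \code{SiteMetadata} fields verbatim:
#' patient_id, anatomical_group, subgroup, tissue_label, modality.
#'
#' @param path JSON file path.
#' @return \code{readSiteMetadata}: a \code{SiteMetadata}.
#' @export
readSiteMetadata <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  siteMetadata(x$patient_id, x$anatomical_group, x$tissue_label,
               subgroup = if (is.null(x$subgroup)) "" else x$subgroup,
               modality = if (is.null(x$modality)) "in_vivo" else x$modality)
}

#' @param md a \code{SiteMetadata}.
#' @rdname readSiteMetadata
#' @export
writeSiteMetadata <- function(md, path) {
  jsonlite::write_json(
    list(patient_id = md@patientId, anatomical_group = md@anatomicalGroup,
         subgroup = md@subgroup, tissue_label = md@tissueLabel,
         modality = md@modality),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write / read a measurement site directory
#'
#' One directory per site: \code{spectrum_###.tsv} files plus a
#' \code{metadata.json} sidecar.
#'
#' @param set a \code{SpectrumSet}.
#' @param dir site directory.
#' @param header named character vector of extra '#' header fields.
#' @return the directory (write) or a \code{SpectrumSet} (read).
#' @export
writeSpectrumSet <- function(set, dir, header = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSiteMetadata(set@metadata, file.path(dir, "metadata.json"))
  for (i in seq_along(set@spectra))
    writeSpectrumFile(set@spectra[[i]],
                      file.path(dir, sprintf("spectrum_%03d.tsv", i)), header)
  invisible(dir)
}

#' @rdname writeSpectrumSet
#' @export
readSpectrumSet <- function(dir) {
  md <- readSiteMetadata(file.path(dir, "metadata.json"))
  files <- sort(list.files(dir, pattern = "^spectrum_\\d+\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("input error: no spectrum files in ", dir)
  SpectrumSet(md, lapply(files, readSpectrumFile))
}

#' Parse a patient characteristics table
#'
#' Delimited text with columns No, Group, Subgroup, TNM, Histopathology; one
#' record per patient. Group values are validated against the anatomical
#' vocabulary and patient numbers must be unique. The packaged fixture
#' (inst/extdata/table1.tsv) lists the 25 histologically confirmed carcinoma
#' patients of the feasibility cohort.
#'
#' @param path TSV path; default is the packaged fixture.
#' @return data.frame with columns number, group, subgroup, tnm,
#'   histopathology.
#' @export
parsePatientTable <- function(path = system.file("extdata", "table1.tsv",
                                                 package = "RamanCohort",
                                                 mustWork = TRUE)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  names(tab) <- tolower(names(tab))
  need <- c("no", "group", "subgroup", "tnm", "histopathology")
  if (!all(need %in% names(tab)))
    stop("input error: patient table must have columns No, Group, Subgroup, ",
         "TNM, Histopathology")
  grp <- tolower(tab$group)
  bad <- setdiff(unique(grp), .ANATOMICAL_GROUPS)
  if (length(bad) > 0)
    stop("vocabulary error: unknown group value(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(tab$no))
    stop("input error: patient numbers must be unique")
  data.frame(number = as.integer(tab$no), group = grp,
             subgroup = tab$subgroup, tnm = tab$tnm,
             histopathology = tab$histopathology, stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' One sub-directory per site (\code{site_###}), the calibration inputs
#' (dark frame, measured standard, certified curve) and the ground-truth
#' manifest as JSON. All spectrum files carry the config digest in their
#' headers.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param acq the \code{AcquisitionModel} used (supplies dark and standard).
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, acq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  digest <- cohort$manifest$config_digest
  hdr <- c(config_digest = digest)
  for (i in seq_along(cohort$sites))
    writeSpectrumSet(cohort$sites[[i]],
                     file.path(dir, sprintf("site_%03d", i)), hdr)
  cert <- certifiedEmissionCurve(acq@axis)
  writeSpectrumFile(darkFrame(acq), file.path(dir, "dark.tsv"), hdr)
  writeSpectrumFile(measuredStandard(acq, cert), file.path(dir, "standard.tsv"),
                    hdr)
  writeSpectrumFile(Spectrum(acq@axis, cert@relativeSensitivity),
                    file.path(dir, "certified.tsv"), hdr)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir directory written by \code{\link{writeCohort}} (or laid out the
#'   same way).
#' @return list with \code{sites}, \code{dark}, \code{standard},
#'   \code{certified}.
#' @export
readCohort <- function(dir) {
  siteDirs <- sort(list.dirs(dir, recursive = FALSE))
  siteDirs <- siteDirs[grepl("site_\\d+$", siteDirs)]
  if (length(siteDirs) == 0) stop("input error: no site directories in ", dir)
  certS <- readSpectrumFile(file.path(dir, "certified.tsv"))
  list(sites = lapply(siteDirs, readSpectrumSet),
       dark = readSpectrumFile(file.path(dir, "dark.tsv")),
       standard = readSpectrumFile(file.path(dir, "standard.tsv")),
       certified = responseCurve(certS@axis, certS@intensities,
                                 source = "certified_polynomial"))
}

#' Calibration inputs implied by an acquisition model
#'
#' \code{darkFrame} returns the (noise-averaged) dark spectrum — the constant
#' detector offset. \code{measuredStandard} returns the dark-corrected
#' recording the instrument would make of the certified standard: the
#' certified emission scaled by the relative response.
#'
#' @param acq an \code{AcquisitionModel}.
#' @return A \code{Spectrum}.
#' @export
darkFrame <- function(acq) {
  Spectrum(acq@axis, rep(acq@darkOffset, length(acq@axis@values)))
}

#' @param certified a \code{ResponseCurve} with the certified emission.
#' @rdname darkFrame
#' @export
measuredStandard <- function(acq, certified = certifiedEmissionCurve(acq@axis)) {
  cert <- .responseOnAxis(certified, acq@axis)
  Spectrum(acq@axis, cert * acq@response@relativeSensitivity)
}
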