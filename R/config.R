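#' Stable digest of a configuration
#'
#' MD5 of the canonical JSON serialisation (names sorted recursively, fixed
#' numeric formatting), so the digest is invariant under key reordering.
#'
#' @param config a (possibly nested) named list of scalars/vectors.
#' @return character(1) hex digest.
#' @export
configDigest <- function(config) {
  canon <- .canonicalize(config)
  json <- jsonlite::toJSON(canon, auto_unbox = TRUE, digits = 12)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

.canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) x <- x[order(nm)]
    lapply(x, .canonicalize)
  } else x
}

#' Default run configuration
#'
#' The flat key-value configuration naming every preprocessing default:
#' ALS (lam, p, max iterations, tolerance), despiking (z threshold, max
#' width), QC (minimum correlation, correlation window), and the area
#' normalization window.
#'
#' @return named list of flat keys.
#' @export
defaultRunConfig <- function() {
  list(
    als.lam = 1e5, als.p = 0.01, als.max_iter = 20L, als.tol = 1e-3,
    despike.z_thresh = 8, despike.max_width = 3L,
    qc.min_correlation = 0.80, qc.window_lo = NA, qc.window_hi = NA,
    norm.window_lo = NA, norm.window_hi = NA)
}

#' Read / write a flat key-value run configuration
#'
#' Stored as YAML with flat keys; unknown keys are preserved.
#'
#' @param path file path.
#' @return \code{readRunConfig}: the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- defaultRunConfig()
  for (k in names(cfg)) out[[k]] <- cfg[[k]]
  out
}

#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Turn a flat run configuration into stage parameter objects.
.paramsFromConfig <- function(cfg) {
  win <- function(lo, hi) {
    if (is.null(lo) || is.null(hi) || is.na(lo) || is.na(hi)) NULL
    else c(lo, hi)
  }
  pipelineParams(
    als = alsParams(cfg$als.lam, cfg$als.p, cfg$als.max_iter, cfg$als.tol),
    despike = despikeParams(cfg$despike.z_thresh, cfg$despike.max_width),
    qc = qcParams(cfg$qc.min_correlation),
    normWindow = win(cfg$norm.window_lo, cfg$norm.window_hi),
    qcWindow = win(cfg$qc.window_lo, cfg$qc.window_hi))
}
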