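#' Persist a trained pipeline as structured text
#'
#' Serializes the bin edges, the four likelihood tables and the estimator
#' coefficients to a single JSON archive carrying a schema tag, so trained
#' models travel as plain text.
#'
#' @param pipeline A trained `mm_pipeline`.
#' @param path Destination path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_mm_pipeline <- function(pipeline, path) {
  stopifnot(inherits(pipeline, "mm_pipeline"))
  payload <- list(
    schema = "saxsmm/pipeline/1",
    bins = list(edges = pipeline$bins$edges, n_bins = pipeline$bins$n_bins),
    tables = purrr::map(pipeline$tables, function(t) {
      list(method = t$method, n_pairs = t$n_pairs, table = t$table)
    }),
    mow = unclass(pipeline$mow),
    vc_powerlaw = unclass(pipeline$vc_powerlaw),
    ss_index = list(points = pipeline$ss_index$points,
                    masses = pipeline$ss_index$masses,
                    center = pipeline$ss_index$center,
                    scale = pipeline$ss_index$scale,
                    k = pipeline$ss_index$k),
    meta = pipeline$meta
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a pipeline persisted by [write_mm_pipeline()]
#'
#' @param path Path to the JSON archive.
#' @return An `mm_pipeline`.
#' @export
read_mm_pipeline <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "saxsmm/pipeline/1"))
    abort(sprintf("unrecognized pipeline schema '%s'", payload$schema))
  edges <- payload$bins$edges
  bins <- structure(list(edges = edges,
                         centers = sqrt(edges[-1] * edges[-length(edges)]),
                         n_bins = as.integer(payload$bins$n_bins)),
                    class = "mm_binning")
  tables <- purrr::map(payload$tables, function(t) {
    structure(list(method = t$method, table = as.matrix(t$table),
                   n_pairs = t$n_pairs), class = "mm_likelihood")
  })
  structure(list(
    bins = bins, tables = tables,
    mow = structure(payload$mow, class = "mow_correction"),
    vc_powerlaw = structure(payload$vc_powerlaw, class = "vc_powerlaw"),
    ss_index = structure(list(points = as.matrix(payload$ss_index$points),
                              masses = payload$ss_index$masses,
                              center = payload$ss_index$center,
                              scale = payload$ss_index$scale,
                              k = as.integer(payload$ss_index$k)),
                         class = "shape_space_index"),
    meta = payload$meta
  ), class = "mm_pipeline")
}
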