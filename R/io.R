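# Readers/writers: the contour-exchange JSON format, structured reports and
# NIfTI-backed study bundles.
#
# Contour-exchange JSON:
#   {"slices":  [{"index","z_mm","thickness_mm","gap_mm","pixel_spacing_mm"}],
#    "contours":[{"slice","phase","role","points_mm":[[x,y],...]}],
#    "meta":    {"heart_rate_bpm","bsa_m2","acquisition_plane"}}
# A machine-readable schema ships in inst/extdata/contour-schema.json and
# the loader validates required fields, naming the missing one.

#' Write a contour stack to the exchange JSON format
#' @param stack a \code{\link{contour_stack}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_contours <- function(stack, path) {
  slices <- lapply(stack$slices, function(s)
    list(index = s$index, z_mm = s$z_mm, thickness_mm = s$thickness_mm,
         gap_mm = s$gap_mm, pixel_spacing_mm = s$pixel_spacing_mm))
  contours <- lapply(stack$contours, function(e)
    list(slice = e$slice, phase = e$phase, role = e$polygon$role,
         points_mm = unname(mapply(c, e$polygon$x, e$polygon$y,
                                   SIMPLIFY = FALSE))))
  doc <- list(slices = slices, contours = contours,
              meta = list(heart_rate_bpm = stack$meta$heart_rate_bpm,
                          bsa_m2 = stack$meta$bsa_m2,
                          acquisition_plane = stack$meta$acquisition_plane,
                          n_phases = stack$n_phases))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a contour stack from the exchange JSON format
#' @param path input file.
#' @return a \code{\link{contour_stack}}.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  doc <- jsonlite::read_json(path)
  if (is.null(doc$slices) || length(doc$slices) == 0)
    stop("schema-invalid contours: missing 'slices'")
  need <- function(rec, field, where) {
    if (is.null(rec[[field]]))
      stop(sprintf("schema-invalid contours: missing '%s' in %s", field, where))
    rec[[field]]
  }
  slices <- lapply(doc$slices, function(s)
    slice_geometry(need(s, "index", "slices"),
                   need(s, "z_mm", "slices"),
                   need(s, "thickness_mm", "slices"),
                   need(s, "gap_mm", "slices"),
                   unlist(need(s, "pixel_spacing_mm", "slices"))))
  meta <- doc$meta
  if (is.null(meta)) stop("schema-invalid contours: missing 'meta'")
  n_phases <- meta$n_phases
  if (is.null(n_phases))
    n_phases <- 1L + max(0L, vapply(doc$contours, function(e)
      as.integer(need(e, "phase", "contours")), integer(1)))
  sm <- study_meta(
    if (is.null(meta$heart_rate_bpm)) NA_real_ else meta$heart_rate_bpm,
    if (is.null(meta$bsa_m2)) NA_real_ else meta$bsa_m2,
    if (is.null(meta$acquisition_plane)) "short_axis" else meta$acquisition_plane)
  stack <- contour_stack(slices, n_phases, sm)
  for (e in doc$contours) {
    pts <- need(e, "points_mm", "contours")
    xy <- do.call(rbind, lapply(pts, unlist))
    poly <- contour_polygon(xy[, 1], xy[, 2], need(e, "role", "contours"))
    stack <- stack_add_contour(stack, need(e, "slice", "contours"),
                               need(e, "phase", "contours"), poly)
  }
  stack
}

#' Write a structured analysis report
#'
#' Serializes any analysis result deterministically (same input, byte
#' identical output).  The report always carries the software identity, a
#' reader-identity field and the method tags the individual results contain
#' (papillary mode, area-length method, T2 cutoff provenance, peak-velocity
#' mode, truncation count).
#'
#' @param results a result object or named list of result objects.
#' @param path output file.
#' @param format \code{"json"} or \code{"csv"} (csv flattens to key/value).
#' @param reader free-text reader identity recorded in the report.
#' @return the path, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         reader = "") {
  format <- match.arg(format)
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    } else attributes(x) <- list(names = names(x))
    x
  }
  doc <- list(software = paste0("cmrpost ",
                                as.character(utils::packageVersion("cmrpost"))),
              reader = reader, results = strip(results))
  if (format == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    flat <- unlist(doc)
    utils::write.csv(data.frame(field = names(flat), value = unname(flat)),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Load a study bundle (NIfTI images + contour JSON)
#'
#' Reads one or more NIfTI series and a contour-exchange JSON into a
#' validated bundle.  Analysis should use uncompressed or losslessly
#' compressed source data; the loader records the declared compression state
#' and warns when it is lossy.
#'
#' @param image_paths named character vector of NIfTI files (may be empty).
#' @param contours_path contour-exchange JSON path (optional).
#' @param lossy_compressed logical: the source data were lossy-compressed
#'   (recorded in provenance with a warning).
#' @param venc,te_ms optional acquisition metadata carried into the bundle.
#' @return list of class \code{study_bundle}: \code{images} (named list with
#'   \code{data} and \code{spacing_mm}), \code{stack}, \code{provenance}.
#' @export
load_study <- function(image_paths = character(0), contours_path = NULL,
                       lossy_compressed = FALSE, venc = NA_real_,
                       te_ms = NA_real_) {
  images <- list()
  for (nm in names(image_paths)) {
    p <- image_paths[[nm]]
    if (!file.exists(p)) stop("unreadable file: ", p)
    img <- RNifti::readNifti(p)
    spc <- RNifti::pixdim(img)
    if (any(!is.finite(spc)) || any(spc <= 0))
      stop("missing-metadata error: pixel spacing absent in ", p)
    images[[nm]] <- list(data = as.array(img), spacing_mm = spc)
  }
  stack <- if (!is.null(contours_path)) read_contours(contours_path) else NULL
  prov <- list(software = paste0("cmrpost ",
                                 as.character(utils::packageVersion("cmrpost"))),
               lossy_compressed = lossy_compressed,
               venc = venc, te_ms = te_ms,
               warnings = character(0))
  if (lossy_compressed) {
    w <- "source images are lossy-compressed; analysis requires uncompressed or lossless DICOM/NIfTI data"
    prov$warnings <- c(prov$warnings, w)
    warning(w)
  }
  structure(list(images = images, stack = stack, provenance = prov),
            class = "study_bundle")
}
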