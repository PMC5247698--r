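# Image and configuration I/O. Calibration is always explicit: a field on
# disk is only readable together with a micron-per-pixel value, either from
# its JSON sidecar or passed by the caller.

#' Write / read a field image with its calibration sidecar
#'
#' `write_field()` saves an [rgb_field()] as 8-bit PNG or TIFF next to a
#' JSON sidecar (`<stem>.json`) holding `um_per_px` and `field_id`; when a
#' ground truth is supplied its masks are written as single-channel PNGs
#' (`<stem>_fat_mask.png`, `<stem>_artifact_mask.png`) and the true fat
#' fraction is recorded in the sidecar. `read_field()` restores the field;
#' it refuses to guess the calibration if neither a sidecar nor `um_per_px`
#' is available.
#'
#' @param field An [rgb_field()].
#' @param path Image path ending in `.png`, `.tif` or `.tiff`.
#' @param truth Optional ground truth from [generate_field()].
#' @param um_per_px Calibration override for `read_field()`.
#' @return `write_field()` the path, invisibly; `read_field()` an
#'   [rgb_field()].
#' @export
write_field <- function(field, path, truth = NULL) {
  if (!inherits(field, "rgb_field")) stop_input("`field` must be an rgb_field")
  img <- field$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(img, path, bits.per.sample = 8L)
  else stop_input("unsupported image format: .", ext)
  stem <- sub(paste0("\\.", ext, "$"), "", path)
  sidecar <- list(um_per_px = field$um_per_px, field_id = field$field_id)
  if (!is.null(truth)) {
    sidecar$true_fat_fraction <- truth$true_fat_fraction
    png::writePNG(truth$fat_mask * 1, paste0(stem, "_fat_mask.png"))
    png::writePNG(truth$artifact_mask * 1, paste0(stem, "_artifact_mask.png"))
  }
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = 10)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path, um_per_px = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop_input("unsupported image format: .", ext)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_input("image is not RGB")
  stem <- sub(paste0("\\.", ext, "$"), "", path)
  sidecar_path <- paste0(stem, ".json")
  field_id <- basename(stem)
  if (is.null(um_per_px)) {
    if (!file.exists(sidecar_path))
      stop_input("no calibration: supply um_per_px or provide the JSON sidecar ",
                 basename(sidecar_path))
    sc <- jsonlite::read_json(sidecar_path)
    um_per_px <- sc$um_per_px
    field_id <- sc$field_id %||% field_id
  }
  rgb_field(array(as.integer(round(img * 255)), dim = dim(img)),
            um_per_px = um_per_px, field_id = field_id)
}

#' Pipeline configuration
#'
#' A single flat, typed configuration object for the end-to-end pipeline.
#' Serialises losslessly to JSON; unknown keys are rejected on load so
#' typos fail loudly.
#'
#' @param n_patients Cohort size simulated by [run_end_to_end()].
#' @param n_fields Fields sampled per biopsy (default 21, the standard
#'   protocol).
#' @param field_px Simulated field edge length in pixels.
#' @param um_per_px Calibration, microns per pixel.
#' @param segmentation A [segmentation_params()].
#' @param hexagon_convention `"circumradius"` or `"apothem"`, see
#'   [hepatocytes_per_lobule()].
#' @param cutoffs_u_l Transaminase cut-offs for the report.
#' @param seed Master seed for every stochastic stage.
#' @return An object of class `"pipeline_config"`. The mFPA bracket edges
#'   are fixed at 5/10/20% and are not configurable.
#' @export
pipeline_config <- function(n_patients = 20L, n_fields = 21L, field_px = 512L,
                            um_per_px = 0.5,
                            segmentation = segmentation_params(),
                            hexagon_convention = c("circumradius", "apothem"),
                            cutoffs_u_l = c(31, 33, 41, 67, 75),
                            seed = 1L) {
  assert_scalar_num(n_patients, "n_patients", lo = 1)
  assert_scalar_num(n_fields, "n_fields", lo = 1)
  assert_scalar_num(field_px, "field_px", lo = 64)
  assert_scalar_num(um_per_px, "um_per_px", lo = 0, strict_lo = TRUE)
  if (!inherits(segmentation, "segmentation_params"))
    stop_input("`segmentation` must be segmentation_params")
  structure(list(n_patients = as.integer(n_patients),
                 n_fields = as.integer(n_fields),
                 field_px = as.integer(field_px), um_per_px = um_per_px,
                 segmentation = segmentation,
                 hexagon_convention = match.arg(hexagon_convention),
                 bracket_edges = c(5, 10, 20),
                 cutoffs_u_l = as.numeric(cutoffs_u_l),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load / save a pipeline configuration
#'
#' JSON round-trip for [pipeline_config()]. An empty file (or empty JSON
#' object) yields all defaults; unknown keys raise an error naming them;
#' the fixed bracket edges may be present in the file but must equal
#' 5/10/20.
#'
#' @param path JSON file path.
#' @param config A [pipeline_config()].
#' @return `load_config()` a validated `pipeline_config`; `save_config()`
#'   the path, invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  raw <- if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  seg_keys <- c("channel_thresholds", "min_object_area_um2",
                "max_object_area_um2", "min_circularity", "fill_holes")
  top_keys <- c("n_patients", "n_fields", "field_px", "um_per_px",
                "segmentation", "hexagon_convention", "bracket_edges",
                "cutoffs_u_l", "seed")
  unknown <- setdiff(names(raw), top_keys)
  if (length(unknown))
    stop_input("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$segmentation)) {
    unknown <- setdiff(names(raw$segmentation), seg_keys)
    if (length(unknown))
      stop_input("unknown segmentation keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$bracket_edges) && !identical(as.numeric(raw$bracket_edges), c(5, 10, 20)))
    stop_input("bracket_edges are fixed at 5/10/20")
  seg <- do.call(segmentation_params, raw$segmentation %||% list())
  args <- raw[setdiff(names(raw), c("segmentation", "bracket_edges"))]
  args$segmentation <- seg
  do.call(pipeline_config, args)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) stop_input("not a pipeline_config")
  out <- unclass(config)
  out$segmentation <- unclass(out$segmentation)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}
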