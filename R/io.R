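#' Write an annotated section to disk
#'
#' The RGB image goes to `<basename>.png` or `<basename>.tif`, the label map
#' to `<basename>_labels.png` (single-channel, pixel value = class id).
#'
#' @param section an `annotated_section`.
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @param image_format `"png"` or `"tiff"`.
#' @return named character vector of the written paths.
#' @export
write_section <- function(section, dir, basename, image_format = c("png", "tiff")) {
  image_format <- match.arg(image_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(basename, if (image_format == "png") ".png" else ".tif"))
  lab_path <- file.path(dir, paste0(basename, "_labels.png"))
  if (image_format == "png") {
    write_image_png(section$image, img_path)
  } else {
    write_tiff_rgb(section$image, img_path)
  }
  write_labels_png(section$labels, lab_path)
  c(image = img_path, labels = lab_path)
}

#' Read an annotated section from disk
#'
#' Reads a PNG or TIFF RGB image (16-bit TIFF is rescaled deterministically
#' to 8-bit, `round(v / 257)`) and, when given, its single-channel label PNG.
#' Label ids are validated against the schema and the shapes must match.
#'
#' @param image_path RGB image path (`.png`, `.tif`, `.tiff`).
#' @param labels_path optional label PNG path.
#' @param pixel_size_um physical pixel size, or `NA`.
#' @return an `annotated_section` (without truth profile).
#' @export
read_section <- function(image_path, labels_path = NULL, pixel_size_um = NA_real_) {
  ext <- tolower(tools::file_ext(image_path))
  img <- if (ext %in% c("tif", "tiff")) {
    read_tiff_rgb(image_path)
  } else {
    a <- png::readPNG(image_path)
    if (length(dim(a)) == 2) stopf("%s is not an RGB image", image_path)
    array(as.integer(round(a[, , 1:3] * 255)), c(dim(a)[1], dim(a)[2], 3))
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- read_labels_png(labels_path)
    if (!all(dim(labels) == dim(img)[1:2])) {
      stopf("image (%s) and labels (%s) sizes differ",
            paste(dim(img)[1:2], collapse = "x"),
            paste(dim(labels), collapse = "x"))
    }
  }
  structure(list(image = img, labels = labels, pixel_size_um = pixel_size_um,
                 truth_profile = NULL,
                 provenance = sprintf("read from %s", image_path)),
            class = "annotated_section")
}

#' Write / read a pipeline configuration as YAML
#'
#' Configurations round-trip losslessly; every pipeline output embeds the
#' configuration hash so runs are traceable.
#'
#' @param config a [pipeline_config()] (or any nested list).
#' @param path YAML file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!is.character(path) || length(path) != 1 || !nzchar(path) || !file.exists(path)) {
    stopf("configuration file not found: '%s'", paste(path, collapse = ","))
  }
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}
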