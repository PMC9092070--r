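#' Construct a morphometric profile
#'
#' The ten custom parameters of one section: areas `S_R`, `S_IPL`, `S_INL`,
#' `S_OPL` (pixels), total ganglion-cell area `S_A` (pixels), ganglion-cell
#' count `A`, and mean thicknesses `H_R`, `H_IPL`, `H_INL`, `H_OPL` (pixels;
#' the mean per-column vertical extent over columns the layer occupies).
#' When `pixel_size_um` is given, micrometer-scale values are attached as
#' `S_*_um2` / `H_*_um` attributes by [as.data.frame.morphometric_profile()].
#'
#' @param S_R,S_IPL,S_INL,S_OPL,S_A areas in pixels.
#' @param A ganglion-cell count.
#' @param H_R,H_IPL,H_INL,H_OPL mean thicknesses in pixels.
#' @param pixel_size_um physical pixel size, or `NA`.
#' @param flags character vector of quality flags (e.g. `"RNFL_absent"`).
#' @return a `morphometric_profile` (named list).
#' @export
morphometric_profile <- function(S_R = 0, S_IPL = 0, S_INL = 0, S_OPL = 0,
                                 S_A = 0, A = 0,
                                 H_R = 0, H_IPL = 0, H_INL = 0, H_OPL = 0,
                                 pixel_size_um = NA_real_, flags = character(0)) {
  vals <- c(S_R = S_R, S_IPL = S_IPL, S_INL = S_INL, S_OPL = S_OPL,
            S_A = S_A, A = A, H_R = H_R, H_IPL = H_IPL, H_INL = H_INL,
            H_OPL = H_OPL)
  if (any(vals < 0)) stopf("morphometric parameters must be non-negative")
  if ((A == 0) != (S_A == 0)) stopf("invariant violated: A = 0 iff S_A = 0")
  structure(as.list(vals),
            pixel_size_um = pixel_size_um, flags = flags,
            class = "morphometric_profile")
}

#' Names of the ten morphometric parameters
#' @return character vector in canonical order.
#' @export
profile_parameters <- function() {
  c("S_R", "S_IPL", "S_INL", "S_OPL", "S_A", "A",
    "H_R", "H_IPL", "H_INL", "H_OPL")
}

#' @export
as.data.frame.morphometric_profile <- function(x, ...) {
  df <- as.data.frame(unclass(x)[profile_parameters()])
  ps <- attr(x, "pixel_size_um")
  df$units <- if (is.na(ps %||% NA)) "px" else "px+um"
  if (!is.na(ps %||% NA)) {
    for (nm in c("S_R", "S_IPL", "S_INL", "S_OPL", "S_A")) {
      df[[paste0(nm, "_um2")]] <- df[[nm]] * ps^2
    }
    for (nm in c("H_R", "H_IPL", "H_INL", "H_OPL")) {
      df[[paste0(nm, "_um")]] <- df[[nm]] * ps
    }
  }
  df
}

#' @export
print.morphometric_profile <- function(x, ...) {
  cat("Morphometric profile:\n")
  print(unlist(unclass(x)[profile_parameters()]))
  fl <- attr(x, "flags")
  if (length(fl) > 0) cat("flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Count ganglion cells with erosion filtering and adherence splitting
#'
#' Connected domains of the CELL mask that vanish under `erosion_iters`
#' erosions are discarded as segmentation specks. Each surviving domain
#' contributes an estimated cell count from the aspect ratio
#' `r = max(w, h) / min(w, h)` of its bounding box: 1 if `r <
#' adherence_ratio`, otherwise `min(round(r), max_split)` (round half away
#' from zero) — adherent clumps of cells are split by how elongated their
#' outer rectangle is. Areas (`S_A`) are measured on the original,
#' pre-erosion components.
#'
#' @param cell_mask logical matrix of CELL pixels.
#' @param config a [morpho_config()].
#' @return list with `A` (total count), `S_A` (total pixel area of surviving
#'   domains) and `detail` (per-domain data.frame with `est_count`).
#' @export
count_ganglion_cells <- function(cell_mask, config = morpho_config()) {
  cc <- connected_domains(cell_mask, config)
  d <- cc$domains
  if (nrow(d) == 0) {
    return(list(A = 0L, S_A = 0L, detail = d))
  }
  d$aspect <- pmax(d$width, d$height) / pmin(d$width, d$height)
  d$est_count <- ifelse(d$aspect < config$adherence_ratio, 1L,
                        pmin(round_half_away(d$aspect), config$max_split))
  d$est_count[!d$survives_erosion] <- 0L
  keep <- d$survives_erosion
  list(A = as.integer(sum(d$est_count)),
       S_A = as.integer(sum(d$pixel_count[keep])),
       detail = d)
}

#' Measure a layer's area and mean thickness
#'
#' Retains connected domains with at least `min_layer_area_frac` of the image
#' pixels ("only the connected domains with an area larger than a certain
#' threshold were counted"), then reports `S` (total retained pixels) and `H`
#' (mean per-column vertical pixel count over columns intersecting the
#' retained mask).
#'
#' @param layer_mask logical matrix (typically after [clean_mask()]).
#' @param config a [morpho_config()].
#' @return list with `S`, `H` and logical `absent` (TRUE when nothing
#'   remains, in which case S = H = 0).
#' @export
measure_layer <- function(layer_mask, config = morpho_config()) {
  H_img <- nrow(layer_mask); W_img <- ncol(layer_mask)
  min_px <- config$min_layer_area_frac * H_img * W_img
  mask <- layer_mask
  if (config$min_layer_area_frac > 0 && any(mask)) {
    cc <- connected_domains(mask, config)
    drop_ids <- cc$domains$id[cc$domains$pixel_count < min_px]
    if (length(drop_ids) > 0) {
      mask[cc$labels %in% drop_ids] <- FALSE
    }
  }
  if (!any(mask)) {
    return(list(S = 0L, H = 0, absent = TRUE))
  }
  counts <- colSums(mask)
  occ <- counts > 0
  list(S = as.integer(sum(counts)), H = mean(counts[occ]), absent = FALSE)
}

#' Extract the full morphometric profile of one section
#'
#' Runs the post-segmentation chain — binarize per class, morphological
#' opening, connected domains, small-object filtering — for the four layers,
#' and erosion-filtered adherence-split counting for ganglion cells, then
#' assembles the ten custom parameters.
#'
#' @param x integer label matrix, or an H x W x k score/probability array
#'   (reduced to labels by argmax, ties to the lowest class id).
#' @param config a [morpho_config()]. With `erosion_iters = 0` and
#'   `min_layer_area_frac = 0` the chain is the identity on clean label maps.
#' @param pixel_size_um physical pixel size, or `NA` for pixel units.
#' @return a [morphometric_profile()].
#' @export
profile_section <- function(x, config = morpho_config(),
                            pixel_size_um = NA_real_) {
  labels <- if (length(dim(x)) == 3) argmax_labels(x) else x
  check_labels(labels)
  flags <- character(0)

  layer_res <- list()
  for (nm in c(R = "RNFL", IPL = "IPL", INL = "INL", OPL = "OPL")) {
    mask <- binarize_class(labels, label_id(nm), config)
    mask <- clean_mask(mask, config)
    res <- measure_layer(mask, config)
    if (res$absent) flags <- c(flags, paste0(nm, "_absent"))
    layer_res[[nm]] <- res
  }
  cells <- count_ganglion_cells(binarize_class(labels, 1L, config), config)

  morphometric_profile(
    S_R = layer_res$RNFL$S, S_IPL = layer_res$IPL$S,
    S_INL = layer_res$INL$S, S_OPL = layer_res$OPL$S,
    S_A = cells$S_A, A = cells$A,
    H_R = layer_res$RNFL$H, H_IPL = layer_res$IPL$H,
    H_INL = layer_res$INL$H, H_OPL = layer_res$OPL$H,
    pixel_size_um = pixel_size_um, flags = flags
  )
}

#' Profile every section of a cohort
#'
#' @param cohort list of annotated sections (e.g. from [generate_cohort()]).
#' @param config a [morpho_config()].
#' @param source `"labels"` to profile ground-truth label maps, `"truth"` to
#'   copy the generator's exact truth profiles, or a function
#'   `f(section) -> label matrix` (e.g. a model predictor).
#' @return data.frame with `section_id`, `group` and the ten parameters.
#' @export
profile_cohort <- function(cohort, config = morpho_config(), source = "labels") {
  rows <- lapply(cohort, function(sec) {
    prof <- if (identical(source, "truth")) {
      sec$truth_profile
    } else if (is.function(source)) {
      profile_section(source(sec), config, sec$pixel_size_um %||% NA_real_)
    } else {
      profile_section(sec$labels, config, sec$pixel_size_um %||% NA_real_)
    }
    cbind(data.frame(section_id = sec$section_id %||% NA_character_,
                     group = sec$group %||% NA_character_),
          as.data.frame(prof))
  })
  do.call(rbind, rows)
}
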