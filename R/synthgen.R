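#' Specification of a synthetic retinal-section phantom
#'
#' Describes the geometry, optics and condition of one synthetic HE-like
#' retinal section. Layers are horizontal bands stacked vitreous-side-up
#' (RNFL on top, then IPL, INL, OPL), sharing a sinusoidal vertical
#' displacement per column; ganglion cells are ellipses sitting on the
#' RNFL/IPL boundary. The `msg_like` condition emulates the MSG phenotype:
#' IPL/INL/RNFL thinned and ganglion cells depleted by `msg_factors`.
#'
#' Cell centers and radii snap to the pixel grid so that the bounding box of
#' every planted cell or adherent clump is exact; this makes the ground-truth
#' cell count recoverable deterministically by the aspect-ratio splitting
#' rule (see the methods vignette).
#'
#' @param width_px,height_px canvas size in pixels.
#' @param pixel_size_um physical pixel size in micrometers, or `NA` to report
#'   morphometry in pixels.
#' @param layer_thickness_px named numeric vector of mean band thicknesses
#'   (pixels) for `RNFL`, `IPL`, `INL`, `OPL`.
#' @param curvature_amplitude_px,curvature_period_px sinusoidal undulation of
#'   the layer stack (amplitude in px, period in px).
#' @param cell_count number of ganglion cells planted (clump members count
#'   individually).
#' @param cell_radius_px nominal cell semi-axis in pixels (>= 3 whenever
#'   `cell_clump_fraction > 0`).
#' @param cell_clump_fraction fraction of cells fused into adherent clumps of
#'   2-4 cells.
#' @param vacuole_density background-labeled holes punched into IPL/OPL, per
#'   1,000 layer pixels (vacuolar degeneration).
#' @param noise_sigma,blur_sigma RGB rendering noise (gray levels) and
#'   gaussian blur (px); both affect only the image, never the labels.
#' @param condition `"control"` or `"msg_like"`.
#' @param msg_factors named multipliers applied under `msg_like`:
#'   `RNFL`, `IPL`, `INL` thickness and `cells` count.
#' @param seed integer seed; a fixed seed makes the section byte-identical.
#' @return an object of class `phantom_spec`.
#' @examples
#' sp <- phantom_spec(width_px = 200, height_px = 160, seed = 7)
#' sec <- generate_section(sp)
#' table(sec$labels)
#' @export
phantom_spec <- function(width_px = 256L,
                         height_px = 192L,
                         pixel_size_um = NA_real_,
                         layer_thickness_px = c(RNFL = 18, IPL = 30, INL = 22, OPL = 10),
                         curvature_amplitude_px = 5,
                         curvature_period_px = 180,
                         cell_count = 10L,
                         cell_radius_px = 5,
                         cell_clump_fraction = 0.25,
                         vacuole_density = 1,
                         noise_sigma = 8,
                         blur_sigma = 1,
                         condition = c("control", "msg_like"),
                         msg_factors = c(RNFL = 0.7, IPL = 0.6, INL = 0.6, cells = 0.6),
                         seed = 1L) {
  condition <- match.arg(condition)
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um,
    layer_thickness_px = layer_thickness_px,
    curvature_amplitude_px = curvature_amplitude_px,
    curvature_period_px = curvature_period_px,
    cell_count = as.integer(cell_count), cell_radius_px = cell_radius_px,
    cell_clump_fraction = cell_clump_fraction,
    vacuole_density = vacuole_density,
    noise_sigma = noise_sigma, blur_sigma = blur_sigma,
    condition = condition, msg_factors = msg_factors,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  t <- spec$layer_thickness_px
  need <- c("RNFL", "IPL", "INL", "OPL")
  if (!all(need %in% names(t))) {
    stopf("layer_thickness_px must name %s", paste(need, collapse = ", "))
  }
  if (spec$width_px < 16L || spec$height_px < 16L) {
    stopf("invariant violated: canvas must be at least 16 x 16 pixels")
  }
  if (any(t <= 0)) stopf("invariant violated: layer thicknesses must be positive")
  if (spec$cell_count < 0L) stopf("invariant violated: cell_count must be non-negative")
  if (spec$cell_clump_fraction < 0 || spec$cell_clump_fraction > 1) {
    stopf("invariant violated: cell_clump_fraction must lie in [0, 1]")
  }
  if (spec$vacuole_density < 0 || spec$noise_sigma < 0 || spec$blur_sigma < 0) {
    stopf("invariant violated: densities and sigmas must be non-negative")
  }
  eff <- effective_geometry(spec)
  needed <- sum(round(eff$thickness)) + 2 * ceiling(abs(spec$curvature_amplitude_px)) + 2
  if (needed > spec$height_px) {
    stopf(paste0("invariant violated: layer thicknesses plus curvature margins",
                 " (%d px) exceed height_px (%d)"), needed, spec$height_px)
  }
  invisible(spec)
}

# thickness / cell count after applying the condition's reduction factors
effective_geometry <- function(spec) {
  t <- spec$layer_thickness_px[c("RNFL", "IPL", "INL", "OPL")]
  n <- spec$cell_count
  if (identical(spec$condition, "msg_like")) {
    f <- spec$msg_factors
    t["RNFL"] <- t["RNFL"] * f[["RNFL"]]
    t["IPL"] <- t["IPL"] * f[["IPL"]]
    t["INL"] <- t["INL"] * f[["INL"]]
    n <- as.integer(round(n * f[["cells"]]))
  }
  list(thickness = t, cell_count = n)
}

# S (pixel count) and H (mean per-column vertical extent) of one class id
layer_stats_from_labels <- function(labels, id) {
  mask <- labels == id
  counts <- colSums(mask)
  occ <- counts > 0
  c(S = sum(counts), H = if (any(occ)) mean(counts[occ]) else 0)
}

#' Generate one synthetic annotated retinal section
#'
#' Rasterizes the phantom geometry into an exact label map, renders an
#' HE-like RGB image from it (noise and blur touch only the image), and
#' records the exact morphometric ground truth of the label map.
#'
#' @param spec a [phantom_spec()].
#' @return an `annotated_section`: list with `image` (H x W x 3 integer array,
#'   0-255), `labels` (H x W integer matrix of schema ids), `pixel_size_um`,
#'   `truth_profile` (a [morphometric_profile()] with attribute `planted`,
#'   the per-site clump multiplicities), and `provenance`.
#' @export
generate_section <- function(spec) {
  validate_phantom_spec(spec)
  eff <- effective_geometry(spec)
  H <- spec$height_px; W <- spec$width_px
  t_px <- round(eff$thickness)

  with_seed(spec$seed, {
    labels <- matrix(0L, H, W)

    phase <- runif(1, 0, 2 * pi)
    amp <- spec$curvature_amplitude_px
    disp <- round(amp * sin(2 * pi * (seq_len(W) - 1) / spec$curvature_period_px + phase))
    total <- sum(t_px)
    base_top <- floor((H - total) / 2) + 1L
    y_top <- as.integer(base_top + disp)

    layer_ids <- c(RNFL = 5L, IPL = 3L, INL = 2L, OPL = 4L)
    offset <- 0L
    for (nm in names(layer_ids)) {
      tl <- t_px[[nm]]
      if (tl >= 1L) {
        rows <- rep(y_top + offset, each = tl) + rep.int(seq_len(tl) - 1L, W)
        cols <- rep(seq_len(W), each = tl)
        labels[cbind(rows, cols)] <- layer_ids[[nm]]
      }
      offset <- offset + tl
    }

    planted <- plant_cells(labels, spec, eff, y_top, t_px)
    labels <- planted$labels
    labels <- punch_vacuoles(labels, spec)

    img <- render_section(labels, spec)

    truth <- morphometric_profile(
      S_R   = layer_stats_from_labels(labels, 5L)[["S"]],
      S_IPL = layer_stats_from_labels(labels, 3L)[["S"]],
      S_INL = layer_stats_from_labels(labels, 2L)[["S"]],
      S_OPL = layer_stats_from_labels(labels, 4L)[["S"]],
      S_A   = sum(labels == 1L),
      A     = eff$cell_count,
      H_R   = layer_stats_from_labels(labels, 5L)[["H"]],
      H_IPL = layer_stats_from_labels(labels, 3L)[["H"]],
      H_INL = layer_stats_from_labels(labels, 2L)[["H"]],
      H_OPL = layer_stats_from_labels(labels, 4L)[["H"]],
      pixel_size_um = spec$pixel_size_um
    )
    attr(truth, "planted") <- planted$multiplicities

    structure(
      list(image = img, labels = labels, pixel_size_um = spec$pixel_size_um,
           truth_profile = truth, condition = spec$condition,
           provenance = sprintf("retseg synthetic section, seed=%d, condition=%s",
                                spec$seed, spec$condition)),
      class = "annotated_section"
    )
  })
}

# Plant ganglion cells as pixel-snapped ellipses on the RNFL/IPL boundary.
# Clumps are unions of k horizontally overlapping ellipses whose joint
# bounding box has aspect ratio k + 2/(2*Rx - 1), so round(ratio) == k.
plant_cells <- function(labels, spec, eff, y_top, t_px) {
  n <- eff$cell_count
  if (n == 0L) return(list(labels = labels, multiplicities = integer(0)))
  H <- nrow(labels); W <- ncol(labels)

  n_clumped <- round(n * spec$cell_clump_fraction)
  sizes <- integer(0)
  remaining <- n_clumped
  while (remaining >= 2) {
    k <- min(sample(2:4, 1), remaining)
    sizes <- c(sizes, k)
    remaining <- remaining - k
  }
  mult <- c(sizes, rep(1L, n - sum(sizes)))
  if (length(mult) > 1) mult <- sample(mult)  # shuffle clump/single order

  m <- length(mult)
  slot <- W / m
  prev_right <- 0
  for (i in seq_len(m)) {
    k <- mult[i]
    Rx <- max(if (k > 1) 3L else 2L,
              as.integer(round(spec$cell_radius_px * runif(1, 0.85, 1.15))))
    Ry <- Rx - 1L
    s_off <- 2L * Rx - 1L
    halfw <- ((k - 1L) * s_off + 2L * Rx + 1L) %/% 2L + 1L
    cx <- as.integer(round((i - 0.5) * slot + runif(1, -slot / 10, slot / 10)))
    cx <- max(cx, prev_right + 2L + halfw)
    cx <- min(cx, W - halfw)
    if (cx - halfw < 1L) stopf("cell_count too large for width_px: cells do not fit")
    prev_right <- cx + halfw
    cy <- as.integer(y_top[cx] + t_px[["RNFL"]])  # first IPL row at this column
    x0 <- cx - as.integer(floor((k - 1L) * s_off / 2))
    for (j in seq_len(k)) {
      cxj <- x0 + (j - 1L) * s_off
      rr <- max(1L, cy - Ry):min(H, cy + Ry)
      cc <- max(1L, cxj - Rx):min(W, cxj + Rx)
      sub <- outer((rr - cy) / (Ry + 0.49), (cc - cxj) / (Rx + 0.49),
                   function(a, b) a^2 + b^2) <= 1
      idx <- which(sub, arr.ind = TRUE)
      labels[cbind(rr[idx[, 1]], cc[idx[, 2]])] <- 1L
    }
  }
  list(labels = labels, multiplicities = mult)
}

# punch Background-labeled vacuoles into IPL and OPL
punch_vacuoles <- function(labels, spec) {
  if (spec$vacuole_density <= 0) return(labels)
  H <- nrow(labels); W <- ncol(labels)
  for (id in c(3L, 4L)) {
    px <- which(labels == id)
    n_vac <- round(spec$vacuole_density * length(px) / 1000)
    if (n_vac < 1) next
    centers <- px[sample.int(length(px), min(n_vac, length(px)))]
    for (p in centers) {
      r0 <- ((p - 1L) %% H) + 1L
      c0 <- ((p - 1L) %/% H) + 1L
      rv <- sample(1:2, 1)
      rr <- max(1L, r0 - rv):min(H, r0 + rv)
      cc <- max(1L, c0 - rv):min(W, c0 + rv)
      sub <- outer((rr - r0)^2, (cc - c0)^2, "+") <= rv^2
      idx <- which(sub, arr.ind = TRUE)
      tgt <- cbind(rr[idx[, 1]], cc[idx[, 2]])
      keep <- labels[tgt] == id
      labels[tgt[keep, , drop = FALSE]] <- 0L
    }
  }
  labels
}

# HE-like rendering: palette color per label + gaussian noise + blur
render_section <- function(labels, spec) {
  H <- nrow(labels); W <- ncol(labels)
  pal <- label_palette()
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[labels + 1L, ch], H, W)
  if (spec$noise_sigma > 0) {
    img <- img + array(rnorm(H * W * 3, 0, spec$noise_sigma), c(H, W, 3))
  }
  img <- blur_rgb(img, spec$blur_sigma)
  storage.mode(img) <- "double"
  array(as.integer(round(clamp255(img))), c(H, W, 3))
}

#' Generate a seeded two-group cohort of synthetic sections
#'
#' Emits `2 * n_per_group` sections: a control group from `control_spec` and a
#' model group from `model_spec` (default: `control_spec` switched to the
#' `msg_like` condition). Between-section biological variability is emulated
#' by multiplying each section's layer thicknesses and cell count by
#' independent lognormal factors with coefficient of variation `jitter_cv`.
#' Per-section seeds derive reproducibly from `seed`.
#'
#' @param n_per_group sections per group (>= 1).
#' @param control_spec a [phantom_spec()] for the control group.
#' @param model_spec a [phantom_spec()] for the model group, or `NULL`.
#' @param seed cohort seed.
#' @param jitter_cv coefficient of variation of the per-section multiplicative
#'   jitter (0 disables jitter).
#' @return list of `annotated_section`s, each with an added `$group`
#'   (`"control"` / `"model"`) and `$section_id`.
#' @export
generate_cohort <- function(n_per_group, control_spec, model_spec = NULL,
                            seed = 1L, jitter_cv = 0.08) {
  if (n_per_group < 1) stopf("n_per_group must be >= 1")
  if (is.null(model_spec)) {
    model_spec <- control_spec
    model_spec$condition <- "msg_like"
  }
  seeds <- derive_seeds(seed, 2L * n_per_group)
  jit <- derive_seeds(seed, 1L, salt = 104729L)
  sdlog <- if (jitter_cv > 0) sqrt(log(1 + jitter_cv^2)) else 0
  jitters <- with_seed(jit, {
    replicate(2L * n_per_group,
              list(layers = exp(rnorm(4, 0, sdlog)), cells = exp(rnorm(1, 0, sdlog))),
              simplify = FALSE)
  })
  out <- vector("list", 2L * n_per_group)
  for (i in seq_len(2L * n_per_group)) {
    base <- if (i <= n_per_group) control_spec else model_spec
    sp <- base
    sp$layer_thickness_px <- base$layer_thickness_px * jitters[[i]]$layers
    sp$cell_count <- max(0L, as.integer(round(base$cell_count * jitters[[i]]$cells)))
    sp$seed <- seeds[i]
    sec <- generate_section(sp)
    sec$group <- if (i <= n_per_group) "control" else "model"
    sec$section_id <- sprintf("%s_%03d", sec$group,
                              if (i <= n_per_group) i else i - n_per_group)
    out[[i]] <- sec
  }
  class(out) <- c("section_cohort", "list")
  out
}
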