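# Binary mathematical morphology and connected-component analysis on
# logical H x W matrices. Conventions used throughout: 8-connectivity,
# 0-based row/col indexing and half-open bounding boxes in reported domains.

#' Post-segmentation processing configuration
#'
#' Parameters of the graphical post-processing chain (thresholding,
#' binarization, erosion/dilation, connected domains, small-object filtering
#' and adherent-cell splitting).
#'
#' @param prob_threshold threshold applied to per-class probability maps
#'   (`>=` convention); the argmax label path needs none.
#' @param struct_elem `"square"` (3x3, 8-neighbourhood) or `"cross"` (3x3,
#'   4-neighbourhood) structuring element.
#' @param erosion_iters erosions (and matching dilations) applied by
#'   [clean_mask()], and the survival test depth for cell filtering; 0
#'   disables morphological filtering.
#' @param min_layer_area_frac connected layer domains smaller than this
#'   fraction of the image are discarded ("area larger than a certain
#'   threshold"); 0 disables.
#' @param adherence_ratio bounding-box aspect ratio (max/min) at or above
#'   which a cell domain is treated as an adherent clump and split.
#' @param max_split cap on the estimated per-clump cell count.
#' @return a `morpho_config` list.
#' @export
morpho_config <- function(prob_threshold = 0.5,
                          struct_elem = c("square", "cross"),
                          erosion_iters = 1L,
                          min_layer_area_frac = 0.001,
                          adherence_ratio = 1.8,
                          max_split = 6L) {
  struct_elem <- match.arg(struct_elem)
  if (prob_threshold <= 0 || prob_threshold >= 1) stopf("prob_threshold must be in (0,1)")
  if (erosion_iters < 0) stopf("erosion_iters must be >= 0")
  if (min_layer_area_frac < 0) stopf("min_layer_area_frac must be >= 0")
  if (adherence_ratio < 1) stopf("adherence_ratio must be >= 1")
  structure(list(prob_threshold = prob_threshold, struct_elem = struct_elem,
                 erosion_iters = as.integer(erosion_iters),
                 min_layer_area_frac = min_layer_area_frac,
                 adherence_ratio = adherence_ratio,
                 max_split = as.integer(max_split)),
            class = "morpho_config")
}

struct_offsets <- function(elem) {
  if (elem == "square") {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(0, -1, 1, 0, 0), dc = c(0, 0, 0, -1, 1))
  }
}

# shift a logical matrix so out[r, c] = m[r + dr, c + dc]; outside -> pad
shift_mask <- function(m, dr, dc, pad = FALSE) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(pad, H, W)
  rs <- max(1, 1 - dr):min(H, H - dr)
  cs <- max(1, 1 - dc):min(W, W - dc)
  if (length(rs) > 0 && length(cs) > 0) {
    out[rs, cs] <- m[rs + dr, cs + dc, drop = FALSE]
  }
  out
}

#' Binary erosion
#' @param mask logical matrix.
#' @param elem `"square"` or `"cross"`.
#' @param iters number of erosions.
#' @return eroded logical matrix (pixels outside the image count as background).
#' @export
erode_mask <- function(mask, elem = "square", iters = 1L) {
  off <- struct_offsets(elem)
  for (i in seq_len(iters)) {
    acc <- matrix(TRUE, nrow(mask), ncol(mask))
    for (j in seq_len(nrow(off))) {
      acc <- acc & shift_mask(mask, off$dr[j], off$dc[j], pad = FALSE)
    }
    mask <- acc
  }
  mask
}

#' Binary dilation
#' @inheritParams erode_mask
#' @return dilated logical matrix.
#' @export
dilate_mask <- function(mask, elem = "square", iters = 1L) {
  off <- struct_offsets(elem)
  for (i in seq_len(iters)) {
    acc <- matrix(FALSE, nrow(mask), ncol(mask))
    for (j in seq_len(nrow(off))) {
      acc <- acc | shift_mask(mask, -off$dr[j], -off$dc[j], pad = FALSE)
    }
    mask <- acc
  }
  mask
}

#' Extract a binary mask for one class
#'
#' From an integer label map: `mask = (labels == class_id)`. From a per-class
#' probability/score stack (H x W x k array): `mask = (p_class >= prob_threshold)`.
#'
#' @param x label matrix or H x W x k numeric array of class probabilities.
#' @param class_id schema id of the class.
#' @param config a [morpho_config()] (supplies `prob_threshold`).
#' @return logical H x W matrix.
#' @export
binarize_class <- function(x, class_id, config = morpho_config()) {
  if (length(dim(x)) == 3) {
    k <- dim(x)[3]
    if (class_id < 0 || class_id >= k) stopf("invalid class id %s", class_id)
    x[, , class_id + 1L] >= config$prob_threshold
  } else {
    if (!class_id %in% 0:(n_label_classes() - 1L)) stopf("invalid class id %s", class_id)
    x == class_id
  }
}

#' Morphological opening of a mask
#'
#' `erosion_iters` erosions followed by the same number of dilations with the
#' configured structuring element: removes specks smaller than the element
#' while approximately preserving large bodies.
#'
#' @param mask logical matrix.
#' @param config a [morpho_config()].
#' @return cleaned logical matrix.
#' @export
clean_mask <- function(mask, config = morpho_config()) {
  n <- config$erosion_iters
  if (n == 0L) return(mask)
  dilate_mask(erode_mask(mask, config$struct_elem, n), config$struct_elem, n)
}

#' Connected domains of a binary mask
#'
#' Labels 8-connected components and reports, per domain: pixel count,
#' 0-based half-open bounding box, width/height, and whether the domain
#' survives `erosion_iters` erosions of the whole mask (used as the
#' small-object filter for cell counting).
#'
#' @param mask logical matrix.
#' @param config a [morpho_config()] (structuring element and erosion depth
#'   for the survival flag).
#' @return list with `labels` (integer matrix, 0 = background) and `domains`
#'   (data.frame: `id`, `pixel_count`, `row_min`, `col_min`, `row_max`,
#'   `col_max`, `width`, `height`, `survives_erosion`).
#' @export
connected_domains <- function(mask, config = morpho_config()) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  pix <- which(mask)
  empty <- data.frame(id = integer(0), pixel_count = integer(0),
                      row_min = integer(0), col_min = integer(0),
                      row_max = integer(0), col_max = integer(0),
                      width = integer(0), height = integer(0),
                      survives_erosion = logical(0))
  if (length(pix) == 0) return(list(labels = lab, domains = empty))

  # two-pass union-find over foreground pixels in raster order
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nxt <- 0L
  ord <- pix[order((pix - 1L) %% H, (pix - 1L) %/% H)]  # by row, then col
  for (p in ord) {
    r <- ((p - 1L) %% H) + 1L
    c <- ((p - 1L) %/% H) + 1L
    nb <- integer(0)
    if (r > 1L) {
      if (c > 1L && lab[r - 1L, c - 1L] > 0L) nb <- c(nb, lab[r - 1L, c - 1L])
      if (lab[r - 1L, c] > 0L) nb <- c(nb, lab[r - 1L, c])
      if (c < W && lab[r - 1L, c + 1L] > 0L) nb <- c(nb, lab[r - 1L, c + 1L])
    }
    if (c > 1L && lab[r, c - 1L] > 0L) nb <- c(nb, lab[r, c - 1L])
    if (length(nb) == 0) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      keep <- min(roots)
      lab[r, c] <- keep
      for (rt in roots) parent[rt] <- keep
    }
  }
  roots <- vapply(seq_len(nxt), find, integer(1))
  relabel <- integer(nxt)
  relabel[sort(unique(roots))] <- seq_along(unique(roots))
  lab[pix] <- relabel[roots[lab[pix]]]

  ids <- seq_len(max(relabel))
  rows <- ((pix - 1L) %% H) + 1L
  cols <- ((pix - 1L) %/% H) + 1L
  comp <- lab[pix]
  rmin <- tapply(rows, comp, min); rmax <- tapply(rows, comp, max)
  cmin <- tapply(cols, comp, min); cmax <- tapply(cols, comp, max)
  cnt <- tabulate(comp, nbins = length(ids))

  surv <- rep(TRUE, length(ids))
  if (config$erosion_iters > 0L) {
    er <- erode_mask(mask, config$struct_elem, config$erosion_iters)
    kept <- unique(lab[which(er)])
    surv <- ids %in% kept
  }
  domains <- data.frame(
    id = ids, pixel_count = cnt,
    row_min = as.integer(rmin) - 1L, col_min = as.integer(cmin) - 1L,
    row_max = as.integer(rmax), col_max = as.integer(cmax),
    width = as.integer(cmax - cmin + 1L), height = as.integer(rmax - rmin + 1L),
    survives_erosion = surv, row.names = NULL
  )
  list(labels = lab, domains = domains)
}
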