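# Shared fixtures and independent oracles for the test suite.

# small, fast phantom used widely in unit tests
tiny_spec <- function(seed = 1L, ...) {
  args <- modifyList(list(
    width_px = 96L, height_px = 80L,
    layer_thickness_px = c(RNFL = 10, IPL = 16, INL = 12, OPL = 6),
    curvature_amplitude_px = 3, curvature_period_px = 70,
    cell_count = 4L, cell_radius_px = 4, cell_clump_fraction = 0.25,
    vacuole_density = 1, noise_sigma = 6, blur_sigma = 0.8, seed = seed
  ), list(...))
  do.call(phantom_spec, args)
}

# small network config for shape / gradient tests
tiny_net_config <- function(...) {
  args <- modifyList(list(
    encoder_widths = c(4L, 4L, 8L, 8L, 8L), sge_groups = 2L,
    convs_per_stage = 1L
  ), list(...))
  do.call(seg_model_config, args)
}

# brute-force per-pixel metrics oracle, independent of the package path:
# explicit double loop over pixels and classes
oracle_metrics <- function(pred, truth, k) {
  N <- length(truth)
  TP <- FP <- FN <- TN <- numeric(k)
  for (c in 0:(k - 1)) {
    for (i in seq_len(N)) {
      p <- pred[i] == c
      t <- truth[i] == c
      if (p && t) TP[c + 1] <- TP[c + 1] + 1
      else if (p && !t) FP[c + 1] <- FP[c + 1] + 1
      else if (!p && t) FN[c + 1] <- FN[c + 1] + 1
      else TN[c + 1] <- TN[c + 1] + 1
    }
  }
  correct <- sum(pred == truth)
  present <- (TP + FN) > 0
  defined <- (TP + FP + FN) > 0
  iou_c <- ifelse(defined, TP / (TP + FP + FN), NA)
  list(TP = TP, FP = FP, FN = FN, TN = TN,
       PA = correct / N,
       MPA = mean((TP / (TP + FN))[present]),
       IOU = iou_c,
       MIOU = mean(iou_c[defined]))
}

# independent BFS flood-fill connected components (8-connectivity)
oracle_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (mask[r0, c0] && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= H && c >= 1 && c <= W &&
              mask[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- cur
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# canonical component summary for comparing two labelings up to renaming
component_signature <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  sig <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    c(n = nrow(w), rmin = min(w[, 1]), rmax = max(w[, 1]),
      cmin = min(w[, 2]), cmax = max(w[, 2]))
  })
  sig <- do.call(rbind, sig)
  sig[order(sig[, "rmin"], sig[, "cmin"], sig[, "n"]), , drop = FALSE]
}

profile_values <- function(profile) {
  unlist(unclass(profile)[profile_parameters()])
}
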