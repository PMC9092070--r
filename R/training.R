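#' Data-augmentation policy
#'
#' Random horizontal flipping with probability 0.5, random scaling in
#' [0.5, 1.5], random RGB->HSV color jitter, and random rotation by 0-15
#' degrees. Geometric transforms are applied identically to the image and
#' its label map (labels resampled nearest-neighbour only); HSV jitter
#' touches the image alone. Collapsing every range to the identity yields a
#' byte-identical pass-through.
#'
#' @param hflip_prob probability of a horizontal flip.
#' @param scale_range length-2 scaling interval.
#' @param rotation_range_deg length-2 rotation interval in degrees.
#' @param hsv_jitter enable color jitter.
#' @param hue_delta,sat_range,val_range jitter magnitudes: additive hue shift
#'   in [-hue_delta, hue_delta] (hue wraps in [0,1)) and multiplicative
#'   saturation/value factors.
#' @return an `augmentation_policy`.
#' @export
augmentation_policy <- function(hflip_prob = 0.5,
                                scale_range = c(0.5, 1.5),
                                rotation_range_deg = c(0, 15),
                                hsv_jitter = TRUE,
                                hue_delta = 0.03,
                                sat_range = c(0.8, 1.2),
                                val_range = c(0.8, 1.2)) {
  structure(list(hflip_prob = hflip_prob, scale_range = scale_range,
                 rotation_range_deg = rotation_range_deg,
                 hsv_jitter = isTRUE(hsv_jitter), hue_delta = hue_delta,
                 sat_range = sat_range, val_range = val_range),
            class = "augmentation_policy")
}

#' Identity augmentation policy (no-op)
#' @return an `augmentation_policy` whose draws always return the input.
#' @export
identity_policy <- function() {
  augmentation_policy(hflip_prob = 0, scale_range = c(1, 1),
                      rotation_range_deg = c(0, 0), hsv_jitter = FALSE)
}

#' Augment one annotated section
#'
#' Draws one random transform from the policy and applies it. Scaling
#' resamples to `round(size * f)` and then center-crops (f > 1) or pads
#' (f < 1) back to the original frame; padding and rotation-exposed corners
#' are filled with the Background label and its palette color.
#'
#' @param section an `annotated_section` (needs `$image`, `$labels`).
#' @param policy an [augmentation_policy()].
#' @param draw_seed seed of this augmentation draw.
#' @return the augmented section; label maps contain only valid schema ids.
#' @export
augment <- function(section, policy, draw_seed = 1L) {
  img <- section$image
  lab <- section$labels
  H <- nrow(lab); W <- ncol(lab)
  bg_col <- label_palette()[1, ]

  with_seed(draw_seed, {
    if (policy$hflip_prob > 0 && runif(1) < policy$hflip_prob) {
      img <- img[, W:1, , drop = FALSE]
      lab <- lab[, W:1, drop = FALSE]
    }
    f <- runif(1, policy$scale_range[1], policy$scale_range[2])
    if (abs(f - 1) > 1e-12) {
      nh <- max(16L, round(H * f)); nw <- max(16L, round(W * f))
      img_s <- resize_rgb(img, nh, nw, "bilinear")
      lab_s <- resize_nearest(lab, nh, nw)
      img_o <- array(0, c(H, W, 3))
      for (ch in 1:3) img_o[, , ch] <- bg_col[ch]
      lab_o <- matrix(0L, H, W)
      # center-crop or center-pad back to the original frame
      r0s <- max(1L, (nh - H) %/% 2L + 1L); c0s <- max(1L, (nw - W) %/% 2L + 1L)
      r0d <- max(1L, (H - nh) %/% 2L + 1L); c0d <- max(1L, (W - nw) %/% 2L + 1L)
      hh <- min(H, nh); ww <- min(W, nw)
      img_o[r0d:(r0d + hh - 1L), c0d:(c0d + ww - 1L), ] <-
        img_s[r0s:(r0s + hh - 1L), c0s:(c0s + ww - 1L), , drop = FALSE]
      lab_o[r0d:(r0d + hh - 1L), c0d:(c0d + ww - 1L)] <-
        lab_s[r0s:(r0s + hh - 1L), c0s:(c0s + ww - 1L), drop = FALSE]
      img <- img_o; lab <- lab_o
    }
    ang <- runif(1, policy$rotation_range_deg[1], policy$rotation_range_deg[2])
    if (abs(ang) > 1e-12) {
      rot <- rotate_indices(H, W, ang)
      for (ch in 1:3) img[, , ch] <- rotate_matrix(img[, , ch], rot, bg_col[ch])
      lab <- rotate_matrix(lab, rot, 0L)
    }
    if (policy$hsv_jitter) {
      hsv <- rgb_to_hsv_img(img)
      h <- hsv$h + runif(1, -policy$hue_delta, policy$hue_delta)
      s <- pmin(1, hsv$s * runif(1, policy$sat_range[1], policy$sat_range[2]))
      v <- pmin(1, hsv$v * runif(1, policy$val_range[1], policy$val_range[2]))
      img <- hsv_to_rgb_img(h, s, v, H, W)
    }
  })
  out <- section
  out$image <- array(as.integer(round(clamp255(img))), c(H, W, 3))
  out$labels <- matrix(as.integer(lab), H, W)
  out$truth_profile <- NULL  # geometry changed; exact truth no longer applies
  out
}

#' Split sections into disjoint train and test subsets
#'
#' @param sections list of annotated sections.
#' @param train_n,test_n subset sizes; `train_n + test_n <= length(sections)`.
#' @param seed split seed (identical seed reproduces the partition).
#' @return list with `train` and `test` lists.
#' @export
split_dataset <- function(sections, train_n, test_n, seed = 1L) {
  n <- length(sections)
  if (train_n + test_n > n) {
    stopf("cannot draw %d + %d sections from %d available", train_n, test_n, n)
  }
  idx <- with_seed(seed, sample.int(n, train_n + test_n))
  list(train = sections[idx[seq_len(train_n)]],
       test = sections[idx[train_n + seq_len(test_n)]])
}

#' Training configuration
#'
#' Mirrors the published regimen at configurable scale: Adam, batch size 4,
#' initial learning rate 0.001, decay step 1 and decay factor 0.92. The
#' learning rate during epoch `e` (1-based) is
#' `learning_rate * lr_decay_factor^(e / lr_decay_step)` — monotone
#' non-increasing.
#'
#' @param epochs training epochs (published value 100; desk-scale runs use
#'   far fewer).
#' @param batch_size gradient-accumulation batch size.
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay_step,lr_decay_factor exponential decay schedule.
#' @param class_weights optional length-6 per-class loss weights (e.g. to
#'   upweight the thin OPL and sparse CELL classes); `NULL` = unweighted
#'   cross-entropy.
#' @param augmentation `NULL` or an [augmentation_policy()] applied to each
#'   training section once per epoch.
#' @param seed seed controlling shuffling and augmentation draws.
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 4L,
                         learning_rate = 0.001, lr_decay_step = 1L,
                         lr_decay_factor = 0.92,
                         class_weights = NULL,
                         augmentation = NULL, seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay_step = as.integer(lr_decay_step),
                 lr_decay_factor = lr_decay_factor,
                 class_weights = class_weights,
                 augmentation = augmentation, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule of a configuration
#' @param config a [train_config()].
#' @param epochs number of epochs (default from config).
#' @return numeric vector: the learning rate in effect during each epoch.
#' @export
learning_rate_schedule <- function(config, epochs = config$epochs) {
  e <- seq_len(epochs)
  config$learning_rate * config$lr_decay_factor^(e / config$lr_decay_step)
}

# one Adam update over all parameters; state carries m, v and step t
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  params
}

# mean MPA / MIOU of a model over a list of sections
evaluate_sections <- function(model, sections) {
  mpa <- miou <- numeric(length(sections))
  for (i in seq_along(sections)) {
    pred <- predict_labels(sections[[i]]$image, model)
    tl <- confusion_tally(pred, sections[[i]]$labels)
    mpa[i] <- as.numeric(mean_pixel_accuracy(tl))
    miou[i] <- mean_iou(tl)
  }
  c(MPA = mean(mpa), MIOU = mean(miou))
}

#' Train a segmentation model
#'
#' Minimizes per-pixel multi-class cross-entropy with Adam, the exponential
#' learning-rate decay schedule, per-epoch shuffling and optional
#' augmentation. Logs per-epoch loss, learning rate and held-out MPA/MIOU;
#' the best-by-MIOU weights are retained alongside the final ones.
#'
#' @param model a [seg_model()].
#' @param train_set,test_set lists of annotated sections (images divisible by
#'   16 in both dimensions).
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (final), `best` (best-by-MIOU weights),
#'   `history` (data.frame: epoch, lr, loss, test_MPA, test_MIOU).
#' @export
train_model <- function(model, train_set, test_set, config = train_config(),
                        verbose = FALSE) {
  if (length(train_set) == 0) stopf("empty training set")
  for (sec in c(train_set, test_set)) {
    check_divisible16(nrow(sec$labels), ncol(sec$labels))
  }
  lrs <- learning_rate_schedule(config)
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- list()
  state$v <- list()
  history <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                        test_MPA = numeric(0), test_MIOU = numeric(0))
  best <- list(miou = -Inf, params = model$params, bn = model$bn)

  for (e in seq_len(config$epochs)) {
    lr <- lrs[e]
    epoch_secs <- train_set
    if (!is.null(config$augmentation)) {
      aseeds <- derive_seeds(config$seed, length(train_set), salt = 7919L + e)
      epoch_secs <- lapply(seq_along(train_set), function(i) {
        augment(train_set[[i]], config$augmentation, aseeds[i])
      })
    }
    ord <- with_seed(config$seed + e, sample.int(length(epoch_secs)))
    losses <- numeric(0)
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + config$batch_size - 1L, length(ord))]
      i <- i + config$batch_size
      acc <- NULL
      bloss <- 0
      for (bi in batch) {
        sec <- epoch_secs[[bi]]
        st <- new.env(parent = emptyenv())
        st$tape <- list()
        st$bn <- list()
        scores <- forward_net(model, preprocess_image(sec$image),
                              train = TRUE, st = st)
        for (nm in names(st$bn)) model$bn[[nm]] <- st$bn[[nm]]
        ce <- softmax_ce(scores, sec$labels, config$class_weights)
        if (!is.finite(ce$loss)) {
          stopf("training aborted: non-finite loss at epoch %d", e)
        }
        bloss <- bloss + ce$loss
        g <- backward_net(model, st, ce$dscores / length(batch))
        if (is.null(acc)) {
          acc <- g
        } else {
          for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
        }
      }
      losses <- c(losses, bloss / length(batch))
      model$params <- adam_step(model$params, acc, state, lr)
    }
    ev <- if (length(test_set) > 0) evaluate_sections(model, test_set)
          else c(MPA = NA_real_, MIOU = NA_real_)
    history <- rbind(history, data.frame(
      epoch = e, lr = lr, loss = mean(losses),
      test_MPA = ev[["MPA"]], test_MIOU = ev[["MIOU"]]))
    if (is.finite(ev[["MIOU"]]) && ev[["MIOU"]] > best$miou) {
      best <- list(miou = ev[["MIOU"]], params = model$params, bn = model$bn)
    }
    if (verbose) {
      message(sprintf("epoch %3d  lr %.6f  loss %.4f  MPA %.3f  MIOU %.3f",
                      e, lr, mean(losses), ev[["MPA"]], ev[["MIOU"]]))
    }
  }
  best_model <- model
  best_model$params <- best$params
  best_model$bn <- best$bn
  list(model = model, best = if (is.finite(best$miou)) best_model else model,
       history = history)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is R's native serialization of the model (architecture
#' config, weights, batch-norm statistics) — the standard serialized format
#' for this framework.
#'
#' @param model a [seg_model()].
#' @param path file path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "seg_model")) stopf("%s is not a seg_model checkpoint", path)
  m
}
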