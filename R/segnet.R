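#' Configuration of the attention-augmented segmentation U-Net
#'
#' A VGG-style encoder of exactly 5 scales (the original image plus four
#' twofold max-pool downsamplings), 3x3 same-padding convolutions with batch
#' normalization and ReLU, an optional Spatial Group-wise Enhance (SGE)
#' attention block after every encoder stage, and a decoder of twofold
#' transposed-convolution upsamplings with U-shaped skip concatenations and a
#' final 1x1 convolution to per-class scores.
#'
#' @param n_classes number of output classes (default 6).
#' @param encoder_widths channel counts of the 5 encoder stages. The default
#'   is scaled down from VGG-16 for desk-scale training; pass
#'   `c(64, 128, 256, 512, 512)` with `convs_per_stage = c(2, 2, 3, 3, 3)`
#'   for the full VGG-16 skeleton.
#' @param sge_groups channel groups of each SGE block; every encoder width
#'   must be divisible by it when SGE is enabled.
#' @param sge_enabled `FALSE` gives the plain U-Net baseline.
#' @param convs_per_stage convolutions per encoder stage (scalar or length-5).
#' @param sge_eps variance guard of the SGE standardization.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @return a `seg_model_config`.
#' @export
seg_model_config <- function(n_classes = 6L,
                             encoder_widths = c(32L, 64L, 128L, 256L, 512L),
                             sge_groups = 8L,
                             sge_enabled = TRUE,
                             convs_per_stage = c(2L, 2L, 3L, 3L, 3L),
                             sge_eps = 1e-5,
                             bn_momentum = 0.1) {
  if (length(encoder_widths) != 5) {
    stopf("exactly 5 scales are required: encoder_widths must have length 5")
  }
  if (length(convs_per_stage) == 1) convs_per_stage <- rep(convs_per_stage, 5)
  if (sge_enabled && any(encoder_widths %% sge_groups != 0)) {
    stopf("every encoder width must be divisible by sge_groups (%d)", sge_groups)
  }
  structure(list(n_classes = as.integer(n_classes),
                 encoder_widths = as.integer(encoder_widths),
                 sge_groups = as.integer(sge_groups),
                 sge_enabled = isTRUE(sge_enabled),
                 convs_per_stage = as.integer(convs_per_stage),
                 sge_eps = sge_eps, bn_momentum = bn_momentum,
                 same_padding = TRUE),
            class = "seg_model_config")
}

# conv unit parameter names for stage construction
conv_unit_names <- function(prefix) {
  list(W = paste0(prefix, "_W"), g = paste0(prefix, "_bng"),
       b = paste0(prefix, "_bnb"))
}

#' Initialize a segmentation model
#'
#' He-normal initialization for convolution kernels; batch-norm gains 1 and
#' shifts 0; SGE affines start at (scale 0, shift 1), which makes every SGE
#' block act as the constant gate `sigmoid(1)` at initialization.
#'
#' @param config a [seg_model_config()].
#' @param seed integer seed for the weight draw (fixed seed gives
#'   bit-identical models).
#' @return a `seg_model`: list with `config`, `params` (named list of
#'   arrays) and `bn` (running statistics per batch-norm layer).
#' @export
seg_model <- function(config = seg_model_config(), seed = 1L) {
  w <- config$encoder_widths
  params <- list()
  bn <- list()
  add_conv <- function(prefix, cin, cout) {
    nm <- conv_unit_names(prefix)
    params[[nm$W]] <<- array(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                             c(3, 3, cin, cout))
    params[[nm$g]] <<- rep(1, cout)
    params[[nm$b]] <<- rep(0, cout)
    bn[[prefix]] <<- list(mean = rep(0, cout), var = rep(1, cout))
  }
  with_seed(seed, {
    cin <- 3L
    for (s in 1:5) {
      for (j in seq_len(config$convs_per_stage[s])) {
        add_conv(sprintf("enc_s%d_c%d", s, j), cin, w[s])
        cin <- w[s]
      }
      if (config$sge_enabled) {
        params[[sprintf("sge_s%d_gamma", s)]] <- rep(0, config$sge_groups)
        params[[sprintf("sge_s%d_beta", s)]] <- rep(1, config$sge_groups)
      }
    }
    cur <- w[5]
    for (s in 4:1) {
      params[[sprintf("dec_s%d_t_W", s)]] <-
        array(rnorm(4 * cur * w[s], 0, sqrt(2 / (4 * cur))), c(2, 2, cur, w[s]))
      params[[sprintf("dec_s%d_t_b", s)]] <- rep(0, w[s])
      cin <- 2L * w[s]
      for (j in 1:2) {
        add_conv(sprintf("dec_s%d_c%d", s, j), cin, w[s])
        cin <- w[s]
      }
      cur <- w[s]
    }
    params[["final_W"]] <- matrix(rnorm(w[1] * config$n_classes, 0, sqrt(2 / w[1])),
                                  w[1], config$n_classes)
    params[["final_b"]] <- rep(0, config$n_classes)
  })
  structure(list(config = config, params = params, bn = bn),
            class = "seg_model")
}

#' Total number of trainable parameters
#' @param model a [seg_model()].
#' @return integer parameter count (running statistics excluded).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' SGE parameter overhead of a configuration
#'
#' Each SGE block carries exactly one scale and one shift per group, i.e.
#' `2 * sge_groups` parameters per block and five blocks per encoder.
#'
#' @param config a [seg_model_config()].
#' @return integer overhead vs the `sge_enabled = FALSE` baseline.
#' @export
sge_param_count <- function(config) {
  if (!config$sge_enabled) return(0L)
  2L * config$sge_groups * 5L
}

#' Spatial Group-wise Enhance block (functional form)
#'
#' Applies SGE attention to a feature map: group channels, pool each group
#' globally to a descriptor, gate each position by the sigmoid of the
#' standardized descriptor-feature similarity after a per-group affine.
#' Output shape equals input shape. With `scale_param = 0`,
#' `shift_param = 1` the block multiplies its input by `sigmoid(1)` exactly.
#'
#' @param features H x W x C numeric array.
#' @param groups number of channel groups (must divide C).
#' @param scale_param,shift_param per-group affine (scalar or length-`groups`).
#' @param eps variance guard of the standardization.
#' @return H x W x C array.
#' @export
sge_block <- function(features, groups, scale_param = 0, shift_param = 1,
                      eps = 1e-5) {
  gamma <- rep(scale_param, length.out = groups)
  beta <- rep(shift_param, length.out = groups)
  sge_fwd(features, groups, gamma, beta, eps)$y
}

# normalize a 0..255 RGB array to the network input range
preprocess_image <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stopf("expected an H x W x 3 RGB array")
  }
  array(as.numeric(image) / 255 - 0.5, dim(image))
}

check_divisible16 <- function(H, W) {
  if (H %% 16 != 0 || W %% 16 != 0) {
    stopf(paste0("image size %dx%d is not divisible by 16; pad the image to a",
                 " multiple of 16 before segmentation"), H, W)
  }
}

# ---- forward / backward ---------------------------------------------------

# Runs one conv+BN+ReLU unit. `st` is the mutable forward state environment
# (tape, bn updates) or NULL in pure-eval mode.
run_conv_unit <- function(model, prefix, x, train, st) {
  nm <- conv_unit_names(prefix)
  xcol <- if (is.null(st)) NULL else im2col3(x)
  z <- conv3_fwd(x, model$params[[nm$W]], xcol)
  bnst <- model$bn[[prefix]]
  bo <- bn_fwd(z, model$params[[nm$g]], model$params[[nm$b]],
               bnst$mean, bnst$var, train,
               model$config$bn_momentum)
  y <- relu_fwd(bo$y)
  if (!is.null(st)) {
    if (train) st$bn[[prefix]] <- list(mean = bo$rmean, var = bo$rvar)
    st$tape[[length(st$tape) + 1L]] <- list(
      op = "conv_unit", prefix = prefix, xcol = xcol, hw_in = dim(x),
      bn_cache = list(xhat = bo$xhat, invstd = bo$invstd), bny = bo$y)
  }
  y
}

run_sge <- function(model, stage, x, st) {
  gname <- sprintf("sge_s%d_gamma", stage)
  bname <- sprintf("sge_s%d_beta", stage)
  out <- sge_fwd(x, model$config$sge_groups, model$params[[gname]],
                 model$params[[bname]], model$config$sge_eps)
  if (!is.null(st)) {
    st$tape[[length(st$tape) + 1L]] <- list(
      op = "sge", stage = stage, x = x, cache = out$cache)
  }
  out$y
}

forward_encoder <- function(model, x, train = FALSE, st = NULL) {
  cfg <- model$config
  maps <- vector("list", 5)
  for (s in 1:5) {
    for (j in seq_len(cfg$convs_per_stage[s])) {
      x <- run_conv_unit(model, sprintf("enc_s%d_c%d", s, j), x, train, st)
    }
    if (cfg$sge_enabled) x <- run_sge(model, s, x, st)
    maps[[s]] <- x
    if (s < 5) {
      po <- pool_fwd(x)
      if (!is.null(st)) {
        st$tape[[length(st$tape) + 1L]] <- list(
          op = "pool", k = po$k, H = dim(x)[1], W = dim(x)[2], scale = s)
      }
      x <- po$y
    }
  }
  maps
}

forward_decoder <- function(model, maps, train = FALSE, st = NULL) {
  cfg <- model$config
  y <- maps[[5]]
  for (s in 4:1) {
    tW <- model$params[[sprintf("dec_s%d_t_W", s)]]
    tb <- model$params[[sprintf("dec_s%d_t_b", s)]]
    up <- tconv_fwd(y, tW, tb)
    skip <- maps[[s]]
    if (!all(dim(up)[1:2] == dim(skip)[1:2])) {
      stopf("skip connection shape mismatch at scale %d", s - 1L)
    }
    if (!is.null(st)) {
      st$tape[[length(st$tape) + 1L]] <- list(
        op = "tconv", stage = s, x = y)
      st$tape[[length(st$tape) + 1L]] <- list(
        op = "concat", stage = s, c1 = dim(up)[3], c2 = dim(skip)[3])
    }
    d <- dim(up)
    cat_arr <- array(0, c(d[1], d[2], d[3] + dim(skip)[3]))
    cat_arr[, , seq_len(d[3])] <- up
    cat_arr[, , d[3] + seq_len(dim(skip)[3])] <- skip
    y <- cat_arr
    for (j in 1:2) {
      y <- run_conv_unit(model, sprintf("dec_s%d_c%d", s, j), y, train, st)
    }
  }
  scores <- conv1_fwd(y, model$params[["final_W"]], model$params[["final_b"]])
  if (!is.null(st)) {
    st$tape[[length(st$tape) + 1L]] <- list(op = "final", x = y)
  }
  scores
}

forward_net <- function(model, x, train = FALSE, st = NULL) {
  maps <- forward_encoder(model, x, train, st)
  forward_decoder(model, maps, train, st)
}

# Backward pass over a recorded tape. `dscores` is the gradient at the score
# map; returns named gradients for every parameter plus encoder-map grads.
backward_net <- function(model, st, dscores) {
  grads <- new.env(parent = emptyenv())
  addg <- function(name, g) {
    cur <- grads[[name]]
    grads[[name]] <- if (is.null(cur)) g else cur + g
  }
  # gradient flowing into each stored encoder map (for skip connections)
  skip_grad <- vector("list", 5)
  dy <- NULL
  for (i in rev(seq_along(st$tape))) {
    rec <- st$tape[[i]]
    if (rec$op == "final") {
      o <- conv1_bwd(rec$x, model$params[["final_W"]], dscores)
      addg("final_W", o$dW); addg("final_b", o$db)
      dy <- o$dx
    } else if (rec$op == "conv_unit") {
      nm <- conv_unit_names(rec$prefix)
      dr <- relu_bwd(rec$bny, dy)
      bo <- bn_bwd(rec$bn_cache, model$params[[nm$g]], dr)
      addg(nm$g, bo$dgamma); addg(nm$b, bo$dbeta)
      co <- conv3_bwd(rec$xcol, rec$hw_in, model$params[[nm$W]], bo$dx)
      addg(nm$W, co$dW)
      dy <- co$dx
    } else if (rec$op == "sge") {
      gname <- sprintf("sge_s%d_gamma", rec$stage)
      bname <- sprintf("sge_s%d_beta", rec$stage)
      # the SGE output is both the stored encoder map (skip) and the pooled
      # input of the next stage: merge the two gradient paths here
      sg <- skip_grad[[rec$stage]]
      if (!is.null(sg)) dy <- dy + sg
      o <- sge_bwd(rec$x, model$config$sge_groups, model$params[[gname]],
                   rec$cache, dy)
      addg(gname, o$dgamma); addg(bname, o$dbeta)
      dy <- o$dx
    } else if (rec$op == "pool") {
      dy <- pool_bwd(rec$k, dy, rec$H, rec$W)
      if (!model$config$sge_enabled) {
        sg <- skip_grad[[rec$scale]]
        if (!is.null(sg)) dy <- dy + sg
      }
    } else if (rec$op == "concat") {
      dskip <- dy[, , rec$c1 + seq_len(rec$c2), drop = FALSE]
      stage <- rec$stage
      skip_grad[[stage]] <- if (is.null(skip_grad[[stage]])) dskip else
        skip_grad[[stage]] + dskip
      dy <- dy[, , seq_len(rec$c1), drop = FALSE]
    } else if (rec$op == "tconv") {
      o <- tconv_bwd(rec$x, model$params[[sprintf("dec_s%d_t_W", rec$stage)]], dy)
      addg(sprintf("dec_s%d_t_W", rec$stage), o$dW)
      addg(sprintf("dec_s%d_t_b", rec$stage), o$db)
      dy <- o$dx
      # the deepest encoder map (scale 4) feeds the decoder directly
      if (rec$stage == 4L) {
        sg <- skip_grad[[5]]
        if (!is.null(sg)) dy <- dy + sg
      }
    }
  }
  as.list(grads)
}

# ---- exported spec operations --------------------------------------------

#' Encode an image into feature maps at 5 scales
#'
#' VGG-style convolution stages with 2x2 stride-2 max pooling between them
#' (and SGE attention after each stage when enabled). Scale `s` has spatial
#' size `input / 2^s`.
#'
#' @param image H x W x 3 RGB array (0-255); H and W must be divisible by 16.
#' @param model a [seg_model()].
#' @return list of 5 feature maps (H/2^s x W/2^s x C_s arrays), scales 0..4.
#' @export
encode <- function(image, model) {
  check_divisible16(dim(image)[1], dim(image)[2])
  forward_encoder(model, preprocess_image(image), train = FALSE)
}

#' Decode encoder feature maps into a per-class score map
#'
#' Repeated twofold transposed-convolution upsampling, concatenation with the
#' same-scale encoder map (skip connection) and convolution stages, ending in
#' a 1x1 convolution to `n_classes` scores at full resolution.
#'
#' @param encoder_maps list of 5 feature maps from [encode()].
#' @param model a [seg_model()].
#' @return H x W x n_classes score array.
#' @export
decode <- function(encoder_maps, model) {
  if (length(encoder_maps) != 5) stopf("expected 5 encoder maps")
  forward_decoder(model, encoder_maps, train = FALSE)
}

#' Argmax label map of a score array
#'
#' Ties are broken toward the lowest class id.
#'
#' @param scores H x W x k score array.
#' @return H x W integer label matrix.
#' @export
argmax_labels <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, d[1] * d[2], d[3])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Predict the label map of an RGB section image
#'
#' @param image H x W x 3 RGB array (0-255), divisible by 16 in both
#'   dimensions.
#' @param model a [seg_model()].
#' @return H x W integer label matrix over the 6-class schema.
#' @export
predict_labels <- function(image, model) {
  argmax_labels(decode(encode(image, model), model))
}
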