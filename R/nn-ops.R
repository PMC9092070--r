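# Minimal CPU neural-network primitives on H x W x C arrays, with explicit
# backward passes. Convolutions are computed as 9 (3x3) or 4 (2x2 transposed)
# shifted BLAS matrix products; everything is double precision and
# deterministic. No deep-learning framework exists in this R environment,
# so these primitives are first-class, gradient-checked code.

# out[r, c, ] = x[r + dr, c + dc, ], zero outside
shift_arr <- function(x, dr, dc) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  out <- array(0, d)
  rs <- max(1, 1 - dr):min(H, H - dr)
  cs <- max(1, 1 - dc):min(W, W - dc)
  if (length(rs) > 0 && length(cs) > 0) {
    out[rs, cs, ] <- x[rs + dr, cs + dc, , drop = FALSE]
  }
  out
}

# ---- 3x3 same-padding convolution -----------------------------------------
# im2col with cached padded-grid index vectors: one BLAS gemm per direction.

.conv_idx_cache <- new.env(parent = emptyenv())

conv3_indices <- function(H, W) {
  key <- paste0(H, "x", W)
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L
  inner <- as.vector(outer(2:(H + 1L), (2:(W + 1L) - 1L) * Hp, "+"))
  idx9 <- vector("list", 9)
  for (j in 1:3) for (i in 1:3) {
    di <- i - 2L; dj <- j - 2L
    idx9[[i + (j - 1L) * 3L]] <-
      as.vector(outer((2L + di):(H + 1L + di), ((2L + dj):(W + 1L + dj) - 1L) * Hp, "+"))
  }
  out <- list(inner = inner, idx9 = idx9, npad = Hp * (W + 2L))
  .conv_idx_cache[[key]] <- out
  out
}

# column layout of the im2col matrix matches array(W, c(3,3,Cin,Cout))
# flattening: within each input channel, the 9 kernel offsets are contiguous
im2col3 <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  cin <- d[3]
  ix <- conv3_indices(d[1], d[2])
  xp <- matrix(0, ix$npad, cin)
  xp[ix$inner, ] <- x
  xcol <- matrix(0, HW, 9L * cin)
  for (k in 1:9) {
    xcol[, seq(k, by = 9L, length.out = cin)] <- xp[ix$idx9[[k]], ]
  }
  xcol
}

conv3_fwd <- function(x, W, xcol = NULL) {
  d <- dim(x)
  cout <- dim(W)[4]
  if (is.null(xcol)) xcol <- im2col3(x)
  y <- xcol %*% matrix(W, 9L * d[3], cout)
  dim(y) <- c(d[1], d[2], cout)
  y
}

# backward from the cached im2col matrix; `hw_in` = c(H, W, Cin) of the input
conv3_bwd <- function(xcol, hw_in, W, dy) {
  H <- hw_in[1]; Wd <- hw_in[2]; cin <- hw_in[3]
  cout <- dim(W)[4]
  HW <- H * Wd
  dyf <- matrix(dy, HW, cout)
  dW <- crossprod(xcol, dyf)
  dim(dW) <- dim(W)
  dxcol <- dyf %*% t(matrix(W, 9L * cin, cout))
  ix <- conv3_indices(H, Wd)
  dxp <- matrix(0, ix$npad, cin)
  for (k in 1:9) {
    dxp[ix$idx9[[k]], ] <- dxp[ix$idx9[[k]], ] +
      dxcol[, seq(k, by = 9L, length.out = cin)]
  }
  dx <- dxp[ix$inner, ]
  dim(dx) <- c(H, Wd, cin)
  list(dx = dx, dW = dW)
}

# ---- batch normalization (spatial, per channel) ---------------------------

bn_fwd <- function(x, gamma, beta, rmean, rvar, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xf <- matrix(x, n, d[3])
  if (train) {
    mu <- colMeans(xf)
    v <- colMeans(xf^2) - mu^2          # population variance
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xf, 2, mu), 2, invstd, "*")
  yf <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = array(yf, d), xhat = xhat, invstd = invstd,
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(cache, gamma, dy) {
  d <- dim(dy)
  n <- d[1] * d[2]
  dyf <- matrix(dy, n, d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dyf * xhat)
  dbeta <- colSums(dyf)
  dxhat <- sweep(dyf, 2, gamma, "*")
  dxf <- sweep(dxhat - matrix(colMeans(dxhat), n, d[3], byrow = TRUE) -
                 xhat * matrix(colMeans(dxhat * xhat), n, d[3], byrow = TRUE),
               2, cache$invstd, "*")
  list(dx = array(dxf, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU -----------------------------------------------------------------

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x, dy) dy * (x > 0)

# ---- 2x2 stride-2 max pooling ---------------------------------------------

pool_fwd <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  cands <- list(x[ro, co, , drop = FALSE], x[re, co, , drop = FALSE],
                x[ro, ce, , drop = FALSE], x[re, ce, , drop = FALSE])
  m <- cands[[1]]
  k <- array(1L, dim(m))
  for (i in 2:4) {
    sel <- cands[[i]] > m      # strict: ties keep the earliest candidate
    m[sel] <- cands[[i]][sel]
    k[sel] <- i
  }
  list(y = m, k = k)
}

pool_bwd <- function(k, dy, H, W) {
  C <- dim(dy)[3]
  dx <- array(0, c(H, W, C))
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  blocks <- list(list(ro, co), list(re, co), list(ro, ce), list(re, ce))
  for (i in 1:4) {
    tmp <- dy
    tmp[k != i] <- 0
    dx[blocks[[i]][[1]], blocks[[i]][[2]], ] <- tmp
  }
  dx
}

# ---- 2x2 stride-2 transposed convolution ----------------------------------

tconv_fwd <- function(x, W, b) {
  d <- dim(x)
  HW <- d[1] * d[2]
  cout <- dim(W)[4]
  xf <- matrix(x, HW, d[3])
  y <- array(0, c(2L * d[1], 2L * d[2], cout))
  for (i in 1:2) for (j in 1:2) {
    y[seq(i, 2L * d[1], 2L), seq(j, 2L * d[2], 2L), ] <-
      array(xf %*% matrix(W[i, j, , ], d[3], cout), c(d[1], d[2], cout))
  }
  sweep(y, 3, b, "+")
}

tconv_bwd <- function(x, W, dy) {
  d <- dim(x)
  HW <- d[1] * d[2]
  cout <- dim(W)[4]
  xf <- matrix(x, HW, d[3])
  dxf <- matrix(0, HW, d[3])
  dW <- array(0, dim(W))
  db <- numeric(cout)
  for (i in 1:2) for (j in 1:2) {
    sub <- matrix(dy[seq(i, 2L * d[1], 2L), seq(j, 2L * d[2], 2L), , drop = FALSE],
                  HW, cout)
    Wk <- matrix(W[i, j, , ], d[3], cout)
    dxf <- dxf + sub %*% t(Wk)
    dW[i, j, , ] <- crossprod(xf, sub)
    db <- db + colSums(sub)
  }
  list(dx = array(dxf, d), dW = dW, db = db)
}

# ---- 1x1 convolution ------------------------------------------------------

conv1_fwd <- function(x, W, b) {
  d <- dim(x)
  yf <- sweep(matrix(x, d[1] * d[2], d[3]) %*% W, 2, b, "+")
  array(yf, c(d[1], d[2], ncol(W)))
}

conv1_bwd <- function(x, W, dy) {
  d <- dim(x)
  dyf <- matrix(dy, d[1] * d[2], ncol(W))
  xf <- matrix(x, d[1] * d[2], d[3])
  list(dx = array(dyf %*% t(W), d), dW = crossprod(xf, dyf), db = colSums(dyf))
}

# ---- Spatial Group-wise Enhance attention ---------------------------------

# Per channel group: global-average-pool the group to a descriptor g, take
# the position-wise inner product of g with the group's features, standardize
# that similarity map over positions (zero mean, unit variance, eps guard),
# apply the group's affine (scale gamma, shift beta), gate through a sigmoid
# and multiply the gate into the original group features.
sge_fwd <- function(x, groups, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  C <- d[3]
  if (C %% groups != 0) {
    stopf("channel count %d not divisible by sge groups %d", C, groups)
  }
  cg <- C %/% groups
  xf <- matrix(x, n, C)
  yf <- matrix(0, n, C)
  cache <- vector("list", groups)
  for (g in seq_len(groups)) {
    cols <- ((g - 1L) * cg + 1L):(g * cg)
    Xg <- xf[, cols, drop = FALSE]
    gvec <- colMeans(Xg)
    cmap <- drop(Xg %*% gvec)
    mu <- mean(cmap)
    v <- mean(cmap^2) - mu^2
    invstd <- 1 / sqrt(v + eps)
    chat <- (cmap - mu) * invstd
    a <- gamma[g] * chat + beta[g]
    s <- 1 / (1 + exp(-a))
    yf[, cols] <- Xg * s
    cache[[g]] <- list(gvec = gvec, chat = chat, invstd = invstd, s = s)
  }
  list(y = array(yf, d), cache = cache)
}

sge_bwd <- function(x, groups, gamma, cache, dy) {
  d <- dim(x)
  n <- d[1] * d[2]
  C <- d[3]
  cg <- C %/% groups
  xf <- matrix(x, n, C)
  dyf <- matrix(dy, n, C)
  dxf <- matrix(0, n, C)
  dgamma <- numeric(groups)
  dbeta <- numeric(groups)
  for (g in seq_len(groups)) {
    cols <- ((g - 1L) * cg + 1L):(g * cg)
    Xg <- xf[, cols, drop = FALSE]
    dYg <- dyf[, cols, drop = FALSE]
    cc <- cache[[g]]
    s <- cc$s
    # product rule: through the gated copy of X, and through the gate itself
    dXg <- dYg * s
    ds <- rowSums(dYg * Xg)
    da <- ds * s * (1 - s)
    dgamma[g] <- sum(da * cc$chat)
    dbeta[g] <- sum(da)
    dchat <- gamma[g] * da
    dc <- cc$invstd * (dchat - mean(dchat) - cc$chat * mean(dchat * cc$chat))
    # c_p = X_p . g with g = colMeans(X)
    dXg <- dXg + outer(dc, cc$gvec) +
      matrix(crossprod(Xg, dc) / n, n, cg, byrow = TRUE)
    dxf[, cols] <- dXg
  }
  list(dx = array(dxf, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- softmax cross-entropy over pixels ------------------------------------

softmax_ce <- function(scores, labels, class_weights = NULL) {
  d <- dim(scores)
  n <- d[1] * d[2]
  K <- d[3]
  sf <- matrix(scores, n, K)
  mx <- sf[, 1]
  for (k in 2:K) mx <- pmax(mx, sf[, k])
  sf <- sf - mx
  es <- exp(sf)
  probs <- es / rowSums(es)
  idx <- cbind(seq_len(n), as.integer(labels) + 1L)
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[as.integer(labels) + 1L]
  wsum <- sum(w)
  loss <- -sum(w * log(pmax(probs[idx], 1e-12))) / wsum
  dprobs <- probs
  dprobs[idx] <- dprobs[idx] - 1
  dscores <- array(dprobs * (w / wsum), d)
  list(loss = loss, dscores = dscores, probs = probs)
}
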