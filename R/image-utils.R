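# Shared raster helpers. Images are numeric/integer arrays dim c(H, W, 3)
# with values in 0..255; label maps are integer H x W matrices.

# 1-D gaussian kernel, radius 3*sigma (odd length)
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable gaussian blur of a single channel (matrix), replicate padding
blur_channel <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  if (length(k) == 1) return(m)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  # rows
  mp <- m[c(rep(1L, r), 1:H, rep(H, r)), , drop = FALSE]
  acc <- matrix(0, H, W)
  for (i in seq_along(k)) acc <- acc + k[i] * mp[i:(i + H - 1L), , drop = FALSE]
  # cols
  mp <- acc[, c(rep(1L, r), 1:W, rep(W, r)), drop = FALSE]
  acc <- matrix(0, H, W)
  for (i in seq_along(k)) acc <- acc + k[i] * mp[, i:(i + W - 1L), drop = FALSE]
  acc
}

blur_rgb <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- img
  for (ch in 1:3) out[, , ch] <- blur_channel(img[, , ch], sigma)
  out
}

# nearest-neighbour source indices mapping a length-`n_dst` axis onto 1..n_src
nn_index <- function(n_src, n_dst) {
  src <- (seq_len(n_dst) - 0.5) * (n_src / n_dst) + 0.5
  pmin(pmax(round(src), 1L), n_src)
}

# nearest-neighbour resize of a matrix (used for label maps and channels)
resize_nearest <- function(m, new_h, new_w) {
  m[nn_index(nrow(m), new_h), nn_index(ncol(m), new_w), drop = FALSE]
}

# bilinear resize of one channel
resize_bilinear <- function(m, new_h, new_w) {
  H <- nrow(m); W <- ncol(m)
  ys <- (seq_len(new_h) - 0.5) * (H / new_h) + 0.5
  xs <- (seq_len(new_w) - 0.5) * (W / new_w) + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xs), 1L), W); x1 <- pmin(x0 + 1L, W)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a * outer(rep(1, new_h), 1 - wx) + b * outer(rep(1, new_h), wx)
  bot <- c_ * outer(rep(1, new_h), 1 - wx) + d * outer(rep(1, new_h), wx)
  top * outer(1 - wy, rep(1, new_w)) + bot * outer(wy, rep(1, new_w))
}

resize_rgb <- function(img, new_h, new_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  out <- array(0, c(new_h, new_w, 3))
  for (ch in 1:3) {
    out[, , ch] <- if (method == "bilinear") {
      resize_bilinear(img[, , ch], new_h, new_w)
    } else {
      resize_nearest(img[, , ch], new_h, new_w)
    }
  }
  out
}

# rotate by `deg` about the center via inverse mapping, nearest-neighbour.
# Pixels mapping outside the source are filled with `fill`.
rotate_indices <- function(H, W, deg) {
  th <- deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  dy <- g$r - cy; dx <- g$c - cx
  # inverse rotation of destination coordinates
  sr <- round(cy + cos(th) * dy + sin(th) * dx)
  sc <- round(cx - sin(th) * dy + cos(th) * dx)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  list(idx = cbind(sr, sc), ok = ok, dst = cbind(g$r, g$c))
}

rotate_matrix <- function(m, rot, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  out[rot$dst[rot$ok, , drop = FALSE]] <- m[rot$idx[rot$ok, , drop = FALSE]]
  out
}

# RGB (0..255 array) -> HSV channels, h in [0,1), s,v in [0,1]
rgb_to_hsv_img <- function(img) {
  flat <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(flat, maxColorValue = 255)
  list(h = hsv[1, ], s = hsv[2, ], v = hsv[3, ])
}

hsv_to_rgb_img <- function(h, s, v, H, W) {
  h <- (h %% 1) * 6
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0, c(H, W, 3))
  out[, , 1] <- matrix(r * 255, H, W)
  out[, , 2] <- matrix(g * 255, H, W)
  out[, , 3] <- matrix(b * 255, H, W)
  out
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)
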