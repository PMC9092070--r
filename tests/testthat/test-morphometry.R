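test_that("binarize_class handles label maps, probability maps and the >= rule", {
  lab <- matrix(c(0L, 3L, 3L, 0L), 2, 2)
  expect_identical(binarize_class(lab, 3L), lab == 3L)
  expect_false(any(binarize_class(lab, 5L)))
  # probability map identically at the threshold -> all TRUE (>= convention)
  p <- array(0.5, c(2, 2, 6))
  expect_true(all(binarize_class(p, 2L, morpho_config(prob_threshold = 0.5))))
  # random probability map equals the per-pixel comparison oracle
  set.seed(6)
  pr <- array(runif(4 * 4 * 6), c(4, 4, 6))
  cfg <- morpho_config(prob_threshold = 0.7)
  expect_identical(binarize_class(pr, 4L, cfg), pr[, , 5] >= 0.7)
  expect_error(binarize_class(lab, 9L), "invalid class")
})

test_that("clean_mask removes specks and restores solid squares", {
  m <- matrix(FALSE, 30, 30)
  m[5, 5] <- TRUE               # isolated pixel
  m[10:29, 10:29] <- TRUE       # solid 20x20 square
  out <- clean_mask(m, morpho_config(erosion_iters = 1))
  expect_false(out[5, 5])
  expect_identical(out[10:29, 10:29], matrix(TRUE, 20, 20))
  expect_equal(sum(out), 400)
  # empty in, empty out; zero iterations are the identity
  expect_false(any(clean_mask(matrix(FALSE, 5, 5))))
  expect_identical(clean_mask(m, morpho_config(erosion_iters = 0)), m)
})

test_that("erosion and dilation agree with direct set morphology on a fixture", {
  m <- matrix(FALSE, 12, 12)
  m[4:9, 4:9] <- TRUE
  er <- erode_mask(m, "square", 1)
  expected <- matrix(FALSE, 12, 12)
  expected[5:8, 5:8] <- TRUE
  expect_identical(er, expected)
  di <- dilate_mask(m, "square", 1)
  expect_equal(sum(di), 8 * 8)
  # cross element erodes corners less aggressively than the square
  er_cross <- erode_mask(m, "cross", 1)
  expect_gte(sum(er_cross), sum(er))
})

test_that("connected_domains uses 8-connectivity and matches a flood-fill oracle", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE
  m[3, 3] <- TRUE  # diagonal touch -> one component
  cc <- connected_domains(m, morpho_config(erosion_iters = 0))
  expect_equal(nrow(cc$domains), 1L)
  expect_equal(cc$domains$pixel_count, 2L)

  m2 <- matrix(FALSE, 30, 40)
  for (k in 0:4) m2[5:7, (k * 8 + 2):(k * 8 + 4)] <- TRUE
  cc2 <- connected_domains(m2, morpho_config(erosion_iters = 0))
  expect_equal(nrow(cc2$domains), 5L)
  expect_true(all(cc2$domains$pixel_count == 9L))
  # bounding boxes are 0-based half-open
  expect_equal(cc2$domains$row_min[1], 4L)
  expect_equal(cc2$domains$row_max[1], 7L)
  expect_equal(cc2$domains$height[1], 3L)

  for (seed in c(3, 17)) {
    set.seed(seed)
    mr <- matrix(runif(64 * 64) < 0.35, 64, 64)
    got <- connected_domains(mr, morpho_config(erosion_iters = 0))$labels
    expect_identical(component_signature(got), component_signature(oracle_components(mr)))
  }
})

test_that("survives_erosion flags components by erosion survival", {
  m <- matrix(FALSE, 20, 20)
  m[2, 2] <- TRUE               # speck: dies under one erosion
  m[8:14, 8:14] <- TRUE         # block: survives
  cc <- connected_domains(m, morpho_config(erosion_iters = 1))
  d <- cc$domains[order(cc$domains$pixel_count), ]
  expect_identical(d$survives_erosion, c(FALSE, TRUE))
})

test_that("ganglion-cell counting filters specks and splits adherent clumps", {
  cfg <- morpho_config()
  # five disjoint discs
  m <- matrix(FALSE, 40, 100)
  for (k in 0:4) {
    cx <- 10 + k * 18
    for (r in 1:40) for (c in max(1, cx - 4):min(100, cx + 4)) {
      if ((r - 20)^2 / 16 + (c - cx)^2 / 16 <= 1) m[r, c] <- TRUE
    }
  }
  res <- count_ganglion_cells(m, cfg)
  expect_equal(res$A, 5L)
  expect_equal(res$S_A, sum(m))
  # a clump with bounding box 30 wide x 10 high (r = 3) contributes 3
  m2 <- matrix(FALSE, 30, 60)
  m2[11:20, 11:40] <- TRUE
  expect_equal(count_ganglion_cells(m2, cfg)$A, 3L)
  # 1-px specks are erosion-filtered and excluded from A and S_A
  m3 <- m2
  m3[2, c(5, 25, 45)] <- TRUE
  res3 <- count_ganglion_cells(m3, cfg)
  expect_equal(res3$A, 3L)
  expect_equal(res3$S_A, sum(m2))
  # empty mask
  empty <- count_ganglion_cells(matrix(FALSE, 5, 5), cfg)
  expect_equal(empty$A, 0L)
  expect_equal(empty$S_A, 0L)
  # max_split caps degenerate elongated components
  m4 <- matrix(FALSE, 20, 200)
  m4[9:11, 10:190] <- TRUE
  expect_equal(count_ganglion_cells(m4, cfg)$A, morpho_config()$max_split)
})

test_that("measure_layer reports exact S and column-mean thickness", {
  cfg <- morpho_config(min_layer_area_frac = 0)
  m <- matrix(FALSE, 60, 200)
  m[21:40, ] <- TRUE
  res <- measure_layer(m, cfg)
  expect_equal(res$S, 4000L)
  expect_equal(res$H, 20)
  # sinusoidal vertical displacement leaves per-column extent unchanged
  m2 <- matrix(FALSE, 60, 200)
  for (c in 1:200) {
    y0 <- 21 + round(5 * sin(2 * pi * c / 60))
    m2[y0:(y0 + 19), c] <- TRUE
  }
  res2 <- measure_layer(m2, cfg)
  expect_equal(res2$H, 20)
  expect_equal(res2$S, 4000L)
  # area/thickness consistency on vertically convex masks
  expect_equal(res2$S, res2$H * 200)
})

test_that("the small-domain filter drops specks before measuring", {
  m <- matrix(FALSE, 50, 120)
  m[20:29, 11:110] <- TRUE    # 100 x 10 band
  m[45, 3:5] <- TRUE          # 3-pixel speck (0.05% of the image)
  cfg <- morpho_config(erosion_iters = 0, min_layer_area_frac = 0.001)
  res <- measure_layer(m, cfg)
  expect_equal(res$S, 1000L)
  expect_equal(res$H, 10)
  # with the filter off, the speck contributes
  res0 <- measure_layer(m, morpho_config(erosion_iters = 0, min_layer_area_frac = 0))
  expect_equal(res0$S, 1003L)
})

test_that("profile_section is the identity on clean ground truth", {
  cfg0 <- morpho_config(erosion_iters = 0, min_layer_area_frac = 0)
  for (seed in c(1, 23, 77)) {
    sec <- generate_section(tiny_spec(seed = seed))
    prof <- profile_section(sec$labels, cfg0)
    expect_identical(profile_values(prof), profile_values(sec$truth_profile))
  }
})

test_that("an all-Background label map yields a flagged all-zero profile", {
  prof <- profile_section(matrix(0L, 32, 32))
  expect_true(all(profile_values(prof) == 0))
  expect_setequal(attr(prof, "flags"),
                  c("RNFL_absent", "IPL_absent", "INL_absent", "OPL_absent"))
})

test_that("filters act monotonically on S and A", {
  sec <- generate_section(tiny_spec(seed = 41))
  fracs <- c(0, 0.001, 0.01, 0.05)
  S <- vapply(fracs, function(f) {
    profile_section(sec$labels, morpho_config(erosion_iters = 0,
                                              min_layer_area_frac = f))$S_OPL
  }, numeric(1))
  expect_true(all(diff(S) <= 0))
  iters <- 0:3
  A <- vapply(iters, function(it) {
    profile_section(sec$labels, morpho_config(erosion_iters = it,
                                              min_layer_area_frac = 0))$A
  }, numeric(1))
  expect_true(all(diff(A) <= 0))
})

test_that("upscaling a mask scales S by ~4 and H by ~2", {
  sec <- generate_section(tiny_spec(seed = 10, vacuole_density = 0))
  mask <- sec$labels == 3L
  big <- mask[rep(seq_len(nrow(mask)), each = 2), rep(seq_len(ncol(mask)), each = 2)]
  cfg <- morpho_config(erosion_iters = 0, min_layer_area_frac = 0)
  small_m <- measure_layer(mask, cfg)
  big_m <- measure_layer(big, cfg)
  expect_equal(big_m$S / small_m$S, 4, tolerance = 0.01)
  expect_equal(big_m$H / small_m$H, 2, tolerance = 0.01)
})

test_that("micrometer conversion scales areas and thicknesses", {
  sec <- generate_section(tiny_spec(seed = 2))
  prof <- profile_section(sec$labels,
                          morpho_config(erosion_iters = 0, min_layer_area_frac = 0),
                          pixel_size_um = 0.5)
  df <- as.data.frame(prof)
  expect_equal(df$S_IPL_um2, df$S_IPL * 0.25)
  expect_equal(df$H_IPL_um, df$H_IPL * 0.5)
  expect_equal(df$units, "px+um")
})
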