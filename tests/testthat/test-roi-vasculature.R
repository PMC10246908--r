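test_that("tumor segmentation matches ground truth on clean scenes", {
  p <- small_scene_params(5)
  s <- generate_scene(p)
  A <- unmix(s$image, p$mixing_matrix)
  # fixed threshold between background (0) and tumor level (100)
  tum <- segment_tumor_roi(A$DsRed, 2,
                           threshold_spec = list(mode = "fixed", value = 50))
  gt <- s$truth$tumor_mask$mask
  expect_equal(sum(tum$mask & gt) / sum(tum$mask | gt), 1)
  # Otsu mode lands between the modes of a bimodal image
  img <- matrix(c(rep(10, 500), rep(200, 500)), 25, 40)
  thr <- ivhypoxia:::resolve_threshold(img, list(mode = "otsu"))
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  # constant image below a fixed threshold: empty mask + warning
  expect_warning(
    m0 <- segment_tumor_roi(matrix(1, 32, 32), 1,
                            threshold_spec = list(mode = "fixed", value = 5)),
    "empty")
  expect_false(any(m0$mask))
  expect_true("empty" %in% m0$flags)
})

test_that("gfp metrics equal the quoted ratios and a brute-force loop", {
  m <- region_mask(matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2, 3),
                   1, "tumor_roi")
  gfp <- matrix(c(0, 0, 10, 10, 99, 99), 2, 3)
  out <- gfp_metrics(gfp, m, 5)
  expect_equal(out$gfp_positive_fraction, 0.5)
  expect_equal(out$mean_gfp_intensity, 5)
  expect_equal(out$n_tumor_pixels, 4)
  # random image vs explicit loop
  set.seed(2)
  img <- matrix(runif(400, 0, 10), 20, 20)
  msk <- matrix(runif(400) < 0.4, 20, 20)
  msk[1] <- TRUE
  rm <- region_mask(msk, 1, "tumor_roi")
  got <- gfp_metrics(img, rm, 5)
  npos <- 0; tot <- 0; n <- 0
  for (i in 1:20) for (j in 1:20) if (msk[i, j]) {
    n <- n + 1; tot <- tot + img[i, j]
    if (img[i, j] > 5) npos <- npos + 1
  }
  expect_equal(got$gfp_positive_fraction, npos / n)
  expect_equal(got$mean_gfp_intensity, tot / n)
  # all above threshold -> fraction 1; empty mask errors
  expect_equal(gfp_metrics(img + 100, rm, 5)$gfp_positive_fraction, 1)
  empty <- region_mask(matrix(FALSE, 20, 20), 1, "tumor_roi")
  expect_error(gfp_metrics(img, empty, 5), "empty")
})

test_that("ROI expansion is an exact Euclidean disk dilation", {
  # single pixel, 1 um/px, 100 um -> lattice disk pixel count
  m <- matrix(FALSE, 256, 256)
  m[128, 128] <- TRUE
  ex <- expand_roi(region_mask(m, 1, "tumor_roi"), 100)
  g <- expand.grid(dx = -100:100, dy = -100:100)
  expect_equal(sum(ex$mask), sum(g$dx^2 + g$dy^2 <= 100^2))
  # identity at distance 0; superset invariant; error on negative
  rm <- region_mask(m, 1, "tumor_roi")
  expect_equal(expand_roi(rm, 0)$mask, m)
  expect_error(expand_roi(rm, -1), ">= 0")
  set.seed(3)
  rnd <- region_mask(matrix(runif(64 * 64) < 0.05, 64, 64), 2, "tumor_roi")
  ex2 <- expand_roi(rnd, 30)
  expect_true(all(ex2$mask[rnd$mask]))
  # dilating twice by 100 covers dilation by 200 on a convex mask
  disk <- ring_fixture(120, 20)$tumor
  once <- expand_roi(expand_roi(disk, 30), 30)
  twice <- expand_roi(disk, 60)
  expect_true(all(once$mask[twice$mask]))
})

test_that("vessel segmentation recovers clean tubes and respects floors", {
  p <- small_scene_params(7)
  s <- generate_scene(p)
  A <- unmix(s$image, p$mixing_matrix)
  vm <- segment_vessels(A$APC, 2)
  gt <- s$truth$vessel_mask$mask
  dice <- 2 * sum(vm$mask & gt) / (sum(vm$mask) + sum(gt))
  expect_gte(dice, 0.8)
  # mask subset of pixels above the global background percentile
  floor_val <- quantile(A$APC, 0.75)
  expect_true(all(A$APC[vm$mask] > floor_val))
  # zero image -> empty mask; oversized window errors
  expect_false(any(segment_vessels(matrix(0, 64, 64), 1)$mask))
  expect_error(segment_vessels(matrix(runif(64^2), 64, 64), 1,
                               adaptive_window_px = 999L), "window")
})

test_that("vascular density equals the brute-force count ratio", {
  set.seed(4)
  v <- region_mask(matrix(runif(400) < 0.2, 20, 20), 1, "vessel")
  e <- region_mask(matrix(runif(400) < 0.6, 20, 20), 1,
                   "expanded_tumor_roi")
  expect_equal(vascular_density(v, e),
               sum(v$mask & e$mask) / sum(e$mask))
  full <- region_mask(matrix(TRUE, 20, 20), 1, "vessel")
  expect_equal(vascular_density(full, e), 1)
  none <- region_mask(matrix(FALSE, 20, 20), 1, "vessel")
  expect_equal(vascular_density(none, e), 0)
  empty <- region_mask(matrix(FALSE, 20, 20), 1, "expanded_tumor_roi")
  expect_error(vascular_density(v, empty), "empty")
})

test_that("vessel distance map is the exact EDT in um", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  d <- vessel_distance_map(region_mask(m, 1, "vessel"))
  expect_equal(d[5, 4], 1)         # 4-adjacent
  expect_equal(d[4, 4], sqrt(2))   # diagonal
  expect_equal(d[5, 5], 0)
  # random masks vs brute force, scaled pixels
  set.seed(5)
  for (i in 1:5) {
    mk <- matrix(runif(32 * 32) < 0.05, 32, 32)
    if (!any(mk)) mk[1, 1] <- TRUE
    dm <- vessel_distance_map(region_mask(mk, 1.7, "vessel"))
    expect_equal(dm, brute_force_edt(mk, 1.7), tolerance = 1e-12)
  }
  expect_warning(dInf <- vessel_distance_map(
    region_mask(matrix(FALSE, 8, 8), 1, "vessel")), "empty")
  expect_true(all(is.infinite(dInf)))
})

test_that("cell sampling hits the exact grid inside the mask", {
  full <- region_mask(matrix(TRUE, 100, 100), 1, "tumor_roi")
  gfp <- matrix(runif(1e4), 100, 100)
  dmap <- matrix(1, 100, 100)
  cells <- sample_cells(full, gfp, dmap, 20)
  expect_equal(nrow(cells), 25)    # 5 x 5 grid
  expect_true(all(cells$x_px %% 20 == 0 & cells$y_px %% 20 == 0))
  # samples lie inside the mask and carry the right values
  set.seed(6)
  msk <- matrix(runif(1e4) < 0.3, 100, 100)
  rm <- region_mask(msk, 1, "tumor_roi")
  cs <- sample_cells(rm, gfp, dmap, 10)
  expect_true(all(msk[cbind(cs$y_px + 1, cs$x_px + 1)]))
  expect_equal(cs$gfp_intensity, gfp[cbind(cs$y_px + 1, cs$x_px + 1)])
  # empty mask -> empty frame; sub-pixel spacing errors
  expect_equal(nrow(sample_cells(region_mask(matrix(FALSE, 10, 10), 1,
                                             "tumor_roi"),
                                 matrix(0, 10, 10), matrix(0, 10, 10))), 0)
  expect_error(sample_cells(full, gfp, dmap, 0.2), "smaller than one pixel")
})

test_that("bivariate histogram is a normalized brute-force 2D binning", {
  set.seed(7)
  cells <- data.frame(x_px = 0, y_px = 0,
                      gfp_intensity = runif(1000, 0, 100),
                      distance_um = runif(1000, 0, 300),
                      gfp_level = NA_character_)
  de <- seq(0, 300, by = 50); ie <- seq(0, 100, by = 20)
  h <- bivariate_histogram(cells, de, ie)
  expect_equal(sum(h), 1)
  # brute force
  bf <- matrix(0, 6, 5)
  for (k in seq_len(1000)) {
    bi <- min(6, 1 + floor(cells$distance_um[k] / 50))
    bj <- min(5, 1 + floor(cells$gfp_intensity[k] / 20))
    bf[bi, bj] <- bf[bi, bj] + 1
  }
  expect_equal(h, bf / sum(bf))
  # single cell -> single unit bin
  one <- cells[1, ]
  h1 <- bivariate_histogram(one, de, ie)
  expect_equal(sum(h1 == 1), 1)
  expect_equal(sum(h1), 1)
  expect_error(bivariate_histogram(cells[0, ], de, ie), "no cell")
})

test_that("GFP level classification follows the half-open convention", {
  cells <- data.frame(gfp_intensity = c(0, 4.999, 5, 9.999, 10, 50))
  out <- classify_gfp_levels(cells, 5, 10)
  expect_equal(out$gfp_level,
               c("low", "low", "moderate", "moderate", "high", "high"))
  alllow <- classify_gfp_levels(data.frame(gfp_intensity = c(1, 2)), 5, 10)
  expect_true(all(alllow$gfp_level == "low"))
  expect_error(classify_gfp_levels(cells, 10, 5), "low_cut")
  # counts match a brute-force comparison loop
  set.seed(8)
  x <- data.frame(gfp_intensity = runif(500, 0, 20))
  got <- table(classify_gfp_levels(x, 5, 12)$gfp_level)
  n <- c(low = 0, moderate = 0, high = 0)
  for (v in x$gfp_intensity)
    n[if (v < 5) "low" else if (v < 12) "moderate" else "high"] <-
      n[if (v < 5) "low" else if (v < 12) "moderate" else "high"] + 1
  expect_equal(as.numeric(got[c("high", "low", "moderate")]),
               as.numeric(n[c("high", "low", "moderate")]))
})

test_that("hypoxia gradients are recovered through the full pipeline", {
  run_scene <- function(seed, grad) {
    p <- small_scene_params(seed, gfp_gradient = grad, gaussian_sigma = 2)
    s <- generate_scene(p)
    A <- unmix(s$image, p$mixing_matrix)
    tum <- segment_tumor_roi(A$DsRed, 2)
    vs <- segment_vessels(A$APC, 2)
    dm <- vessel_distance_map(vs)
    cells <- sample_cells(tum, A$GFP, dm)
    fin <- is.finite(cells$distance_um)
    cor(cells$gfp_intensity[fin], cells$distance_um[fin])
  }
  r_inc <- vapply(1:5, run_scene, 0, grad = gfp_gradient_satexp(100, 100))
  r_flat <- vapply(1:5, run_scene, 0, grad = gfp_gradient_flat(50))
  expect_gt(mean(r_inc), 0.3)
  expect_lt(abs(mean(r_flat)), 0.1)
})
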