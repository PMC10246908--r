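test_that("alignment score matches its closed form and bounds", {
  expect_equal(alignment_score(2, 2), 0)
  expect_equal(alignment_score(5, 0), 100)
  expect_equal(alignment_score(2, 1), 50)
  expect_error(alignment_score(0, 0), "positive")
  expect_error(alignment_score(1, 2), "b <= a")
  # bounds and strict monotonicity in b/a
  ratios <- seq(0, 1, by = 0.05)
  scores <- vapply(ratios, function(q) alignment_score(1, q), 0)
  expect_true(all(scores >= 0 & scores <= 100))
  expect_true(all(diff(scores) < 0))
})

test_that("polar ellipse fit hits the degenerate and isotropic anchors", {
  th <- seq(0.5, 179.5, by = 1)
  p1 <- numeric(180); p1[40] <- 7
  f1 <- polar_ellipse_fit(th, p1)
  expect_equal(f1$alignment, 100)
  expect_equal(f1$b, 0)
  f2 <- polar_ellipse_fit(th, rep(3, 180))
  expect_equal(f2$alignment, 0, tolerance = 1e-6)
  # all-zero power: flagged degenerate
  f0 <- polar_ellipse_fit(th, numeric(180))
  expect_true(is.na(f0$tilt_deg))
  expect_equal(f0$alignment, 0)
})

test_that("stripe orientations are recovered within 3 degrees", {
  for (ang in c(0, 15, 37, 45, 90, 137)) {
    fs <- fiber_orientation(stripe_patch(64, ang))
    d <- abs(fs$orientation_deg - ang)
    expect_lt(min(d, 180 - d), 3)
    expect_gte(fs$alignment_score, 70)
  }
  # rotation equivariance: rotating the stripes by phi shifts the estimate
  base <- 7
  for (phi in c(15, 30, 45)) {
    f0 <- fiber_orientation(stripe_patch(64, base))
    f1 <- fiber_orientation(stripe_patch(64, base + phi))
    d <- abs((f1$orientation_deg - f0$orientation_deg) - phi) %% 180
    expect_lt(min(d, 180 - d), 3)
  }
  # constant patch: flagged invalid, alignment 0
  fc <- fiber_orientation(matrix(5, 64, 64))
  expect_true(is.na(fc$orientation_deg))
  expect_equal(fc$alignment_score, 0)
  expect_true("invalid_orientation" %in% fc$flags)
  expect_error(fiber_orientation(matrix(0, 16, 16)), ">= 32")
})

test_that("alignment increases with fiber concentration kappa", {
  set.seed(10)
  kappas <- c(0, 1, 4, 16, Inf)
  mean_align <- vapply(kappas, function(k) {
    mean(vapply(1:10, function(i) {
      f <- render_fiber_field(64, 60, 30, k, length_px = 25, width_px = 2)
      fiber_orientation(f)$alignment_score
    }, 0))
  }, 0)
  expect_true(all(diff(mean_align) >= 0))
})

test_that("relative orientation folds to [0, 90]", {
  expect_equal(relative_orientation(30, 30), 0)
  expect_equal(relative_orientation(170, 10), 20)
  expect_equal(relative_orientation(0, 90), 90)
  set.seed(11)
  a <- runif(100, 0, 180); b <- runif(100, 0, 180)
  r <- relative_orientation(a, b)
  expect_true(all(r >= 0 & r <= 90))
})

test_that("edge orientation recovers straight-line directions", {
  expect_lt(abs(edge_orientation(straight_line(0), c(60, 60))), 3)
  d45 <- edge_orientation(straight_line(45), c(60, 60))
  expect_lt(abs(d45 - 45), 3)
  d90 <- edge_orientation(straight_line(90), c(60, 60))
  expect_lt(abs(d90 - 90), 3)
  expect_error(edge_orientation(straight_line(0), c(500, 500)),
               "fewer than 2")
})

test_that("interface extraction traces the tumor-collagen boundary", {
  fx <- ring_fixture()
  lines <- extract_interface(fx$tumor, fx$shg, collagen_search_um = 25)
  expect_length(lines, 1)
  expect_true(lines[[1]]$closed)
  expect_lt(abs(lines[[1]]$arc_length_um - 2 * pi * 60) / (2 * pi * 60),
            0.05)
  # collagen on one half only -> open polyline covering ~half the contour
  shg_half <- fx$shg
  shg_half[, 1:100] <- 0
  half <- extract_interface(fx$tumor, shg_half, collagen_search_um = 25)
  expect_gte(length(half), 1)
  expect_false(half[[1]]$closed)
  main <- half[[which.max(vapply(half, `[[`, 0, "arc_length_um"))]]
  # covers the collagen-bearing half plus at most the 25-um search radius
  # around each end; brute-force bound from the full closed contour length
  full_len <- lines[[1]]$arc_length_um
  expect_gt(main$arc_length_um, 0.45 * full_len)
  expect_lt(main$arc_length_um, 0.5 * full_len + 2 * 25 + 10)
  # brute-force retention rule: every kept vertex within 25 um of collagen
  v <- main$vertices + 1
  expect_true(all(fx$tumor$mask[v]))
  coll_idx <- which(shg_half > 0, arr.ind = TRUE)
  for (k in sample(nrow(v), 20)) {
    d <- sqrt(min((coll_idx[, 1] - v[k, 1])^2 +
                  (coll_idx[, 2] - v[k, 2])^2))
    expect_lte(d, 25 + 1e-9)
  }
  # zero SHG everywhere -> empty list; empty tumor errors
  expect_length(extract_interface(fx$tumor, fx$shg * 0), 0)
  empty <- region_mask(matrix(FALSE, 10, 10), 1, "tumor_roi")
  expect_error(extract_interface(empty, matrix(0, 10, 10)), "empty")
})

test_that("ROI placement steps the interface at the prescribed pitch", {
  # open line of arc length 1000 um, spacing 100 -> 11 centers
  v <- cbind(rep(50, 2001), seq(0, 1000, by = 0.5))
  open_line <- structure(list(vertices = v, arc_length_um = 1000,
                              closed = FALSE, pixel_size_um = 1),
                         class = "interface_line")
  ctr <- place_rois(open_line)
  expect_equal(nrow(ctr), 11)
  expect_equal(ctr$arc_pos_um, seq(0, 1000, by = 100))
  # closed circle of circumference 1000 -> 10 centers (wraparound rule)
  t <- seq(0, 2 * pi, length.out = 4001)[-4001]
  r <- 1000 / (2 * pi)
  vc <- cbind(200 + r * sin(t), 200 + r * cos(t))
  closed_line <- structure(list(vertices = vc, arc_length_um = 1000,
                                closed = TRUE, pixel_size_um = 1),
                           class = "interface_line")
  cc <- place_rois(closed_line)
  expect_equal(nrow(cc), 10)
  # short line -> single flagged center at the midpoint
  sh <- structure(list(vertices = cbind(rep(10, 101), seq(0, 50, 0.5)),
                       arc_length_um = 50, closed = FALSE,
                       pixel_size_um = 1), class = "interface_line")
  s1 <- place_rois(sh)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$flag, "short_line")
  expect_equal(s1$col_px, 25)
})

test_that("peritumoral table means equal brute-force disk loops", {
  fx <- ring_fixture()
  n <- 200
  gfp <- matrix(7, n, n)                 # uniform GFP inside tumor
  img <- spectral_image(list(GFP = gfp, SHG = fx$shg), 1, c("GFP", "SHG"))
  lines <- extract_interface(fx$tumor, fx$shg, collagen_search_um = 25)
  pt <- peritumoral_table(img, fx$tumor, lines[[1]])
  expect_true(all(abs(pt$mean_gfp - 7) < 1e-12))
  # tangential ring: fibers locally parallel to the tumor edge
  expect_true(mean(pt$relative_orientation_deg < 20) >= 0.75)
  # brute-force disk loop for mean_shg and mean_gfp at each center
  for (i in seq_len(nrow(pt))) {
    cr <- round(pt$center_row_px[i]) + 1
    cc <- round(pt$center_col_px[i]) + 1
    acc_s <- 0; n_s <- 0; acc_g <- 0; n_g <- 0
    for (dr in -50:50) for (dc in -50:50) {
      if (dr^2 + dc^2 > 50^2) next
      r <- cr + dr; c <- cc + dc
      if (r < 1 || r > n || c < 1 || c > n) next
      acc_s <- acc_s + fx$shg[r, c]; n_s <- n_s + 1
      if (fx$tumor$mask[r, c]) { acc_g <- acc_g + gfp[r, c]; n_g <- n_g + 1 }
    }
    expect_equal(pt$mean_shg[i], acc_s / n_s, tolerance = 1e-12)
    expect_equal(pt$mean_gfp[i], acc_g / n_g, tolerance = 1e-12)
  }
  # disk disjoint from tumor -> flagged, mean_gfp NA
  far <- data.frame(row_px = 5, col_px = 5, arc_pos_um = 0, flag = "")
  pf <- peritumoral_table(img, fx$tumor, lines[[1]], centers = far)
  expect_true(is.na(pf$mean_gfp))
  expect_match(pf$flags, "no_tumor_overlap")
})

test_that("hypoxia-coupled collagen yields positive GFP-SHG association", {
  rs <- vapply(1:4, function(s) {
    p <- scene_params(image_size_px = c(256L, 256L), pixel_size_um = 2,
                      tumor_radius_um = 150, n_vessels = 3, n_fibers = 500,
                      fiber_band_um = 120, fiber_kappa = 0,
                      fiber_density_coupling = "hypoxia", seed = 200 + s)
    sc <- generate_scene(p)
    A <- unmix(sc$image, p$mixing_matrix)
    tum <- sc$truth$tumor_mask
    lines <- extract_interface(tum, A$SHG, collagen_search_um = 30)
    main <- lines[[which.max(vapply(lines, `[[`, 0, "arc_length_um"))]]
    img <- spectral_image(list(GFP = A$GFP, SHG = A$SHG), 2,
                          c("GFP", "SHG"))
    pt <- peritumoral_table(img, tum, main)
    ok <- !is.na(pt$mean_gfp)
    cor(pt$mean_gfp[ok], pt$mean_shg[ok])
  }, 0)
  expect_gt(mean(rs), 0)
})
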