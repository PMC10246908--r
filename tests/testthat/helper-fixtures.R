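# Shared fixtures and independent oracles, built in code at test time.

# Sinusoidal stripe pattern: stripes run along theta_deg (degrees from the
# +x/column axis toward +y/row), intensity varies along the normal.
stripe_patch <- function(n, theta_deg, wavelength = 8) {
  th <- theta_deg * pi / 180
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  phase <- (c * cos(th + pi / 2) + r * sin(th + pi / 2)) *
    2 * pi / wavelength
  0.5 + 0.5 * cos(phase)
}

# Brute-force Euclidean distance to the nearest TRUE pixel (oracle).
brute_force_edt <- function(mask, pixel_size_um = 1) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  if (nrow(idx) == 0) return(out)
  for (r in seq_len(nrow(mask)))
    for (c in seq_len(ncol(mask)))
      out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
  out * pixel_size_um
}

# Straight interface line through (60, 60) at a given orientation.
straight_line <- function(theta_deg, half_len = 55, pixel_size_um = 1) {
  th <- theta_deg * pi / 180
  t <- seq(-half_len, half_len, by = 0.5)
  v <- cbind(60 + t * sin(th), 60 + t * cos(th))  # 0-based (row, col)
  structure(list(vertices = v, arc_length_um = 2 * half_len * pixel_size_um,
                 closed = FALSE, pixel_size_um = pixel_size_um),
            class = "interface_line")
}

# Small fast scene for pipeline tests.
small_scene_params <- function(seed, n_vessels = 4, n_fibers = 0, ...) {
  scene_params(image_size_px = c(192L, 192L), pixel_size_um = 2,
               tumor_radius_um = 130, n_vessels = n_vessels,
               n_fibers = n_fibers, seed = seed, ...)
}

# Disk tumor mask + tangential collagen ring fixture.
ring_fixture <- function(n = 200, r_tumor = 60, ring = c(60, 80)) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad <- sqrt((rr - (n / 2 + 0.5))^2 + (cc - (n / 2 + 0.5))^2)
  list(tumor = region_mask(rad <= r_tumor, 1, "tumor_roi"),
       shg = (rad > ring[1] & rad < ring[2]) * 10,
       rad = rad)
}
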