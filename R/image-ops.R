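#' Exact Euclidean distance transform
#'
#' Distance from every pixel to the nearest `TRUE` pixel of a binary mask,
#' computed exactly (squared-distance lower-envelope algorithm, then square
#' root). If the mask has no `TRUE` pixel the result is `Inf` everywhere.
#'
#' @param mask logical matrix.
#' @param pixel_size_um physical pixel size; distances are returned in the
#'   same unit (set to 1 for pixel units).
#' @return numeric matrix of distances (um).
#' @export
distance_transform <- function(mask, pixel_size_um = 1) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  storage.mode(mask) <- "logical"
  d2 <- edt_sq_cpp(mask)
  d2[d2 >= 1e19] <- Inf
  sqrt(d2) * pixel_size_um
}

#' Morphological dilation with a Euclidean disk
#'
#' A pixel belongs to the dilated mask iff some mask pixel lies within
#' `radius_px` (Euclidean, lattice-point metric). Equivalent to thresholding
#' the exact distance transform, so the disk is exact, not an octagonal
#' approximation.
#'
#' @param mask logical matrix.
#' @param radius_px dilation radius in pixels (>= 0).
#' @return logical matrix, always a superset of `mask`.
#' @export
disk_dilate <- function(mask, radius_px) {
  stopifnot(radius_px >= 0)
  if (radius_px == 0 || !any(mask)) {
    storage.mode(mask) <- "logical"
    return(mask)
  }
  d2 <- edt_sq_cpp(mask)
  d2 <= radius_px^2 + 1e-9
}

#' Otsu's threshold
#'
#' Maximizes between-class variance on a 256-bin histogram; returns a value
#' strictly between the two classes.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  rng[1] + k / n_bins * diff(rng)
}

# Sliding-window mean over a w x w window (w odd), truncated at the image
# border (mean over the in-frame part of the window). Summed-area tables.
box_mean <- function(img, w) {
  stopifnot(w %% 2 == 1)
  nr <- nrow(img); nc <- ncol(img)
  if (w > nr && w > nc) return(matrix(mean(img), nr, nc))
  h <- (w - 1L) / 2L
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(img, 2L, cumsum), 1L, cumsum) |> t()
  r0 <- pmax(seq_len(nr) - h, 1L); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h, 1L); c1 <- pmin(seq_len(nc) + h, nc)
  cnt <- outer(r1 - r0 + 1L, c1 - c0 + 1L)
  tot <- S[cbind(rep(r1 + 1L, nc), rep(c1 + 1L, each = nr))] -
    S[cbind(rep(r0, nc), rep(c1 + 1L, each = nr))] -
    S[cbind(rep(r1 + 1L, nc), rep(c0, each = nr))] +
    S[cbind(rep(r0, nc), rep(c0, each = nr))]
  matrix(tot, nr, nc) / cnt
}

# Gaussian blur by FFT (circular boundary); adequate for synthetic latent
# fields where the wrap-around is part of the stated noise model.
gaussian_blur_fft <- function(img, sigma) {
  if (sigma <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)] / nr
  fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)] / nc
  H <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  Re(fft(fft(img) * H, inverse = TRUE)) / (nr * nc)
}

#' Remove small connected components from a binary mask
#'
#' @param mask logical matrix.
#' @param min_px minimum component area (8-connectivity) to keep.
#' @return logical matrix.
#' @export
remove_small_objects <- function(mask, min_px = 50L) {
  storage.mode(mask) <- "logical"
  if (!any(mask) || min_px <= 1) return(mask)
  lab <- label_components_cpp(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

# Keys bicubic kernel, a = -0.5 (the classic "bicubic interpolation" kernel).
cubic_kernel <- function(x) {
  a <- -0.5
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# 1D resampling weight matrix (out_n x in_n) for shrinking by `scale` (>1)
# or general resampling. When shrinking, the kernel is stretched by the
# scale factor (antialiasing), as image-resize routines conventionally do.
resample_weights <- function(in_n, out_n, scale) {
  stretch <- max(1, scale)
  centers <- (seq_len(out_n) - 0.5) * scale + 0.5   # input coordinate
  support <- 2 * stretch
  W <- matrix(0, out_n, in_n)
  for (i in seq_len(out_n)) {
    lo <- max(1L, floor(centers[i] - support))
    hi <- min(in_n, ceiling(centers[i] + support))
    idx <- lo:hi
    w <- cubic_kernel((idx - centers[i]) / stretch)
    s <- sum(w)
    if (s == 0) { w <- rep(1, length(idx)); s <- length(idx) }
    W[i, idx] <- w / s
  }
  W
}

# Offsets (dr, dc) of lattice points inside a disk of radius r_px.
disk_offsets <- function(r_px) {
  r <- ceiling(r_px)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r_px^2 + 1e-9, , drop = FALSE]
}

# Pixels (row, col) of a disk centered at (r0, c0), clipped to the image.
disk_pixels <- function(r0, c0, r_px, nr, nc) {
  off <- disk_offsets(r_px)
  rr <- r0 + off$dr; cc <- c0 + off$dc
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  list(r = rr[ok], c = cc[ok], n_total = nrow(off))
}
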