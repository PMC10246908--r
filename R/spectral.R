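#' Multichannel spectral image
#'
#' Container for a set of co-registered 2D channels sharing one physical
#' pixel size. Channels are stored as a named list of numeric matrices.
#'
#' @param channels named list of numeric matrices, all the same dimensions.
#' @param pixel_size_um physical pixel size, um per pixel.
#' @param channel_names optional names overriding `names(channels)`.
#' @return object of class `spectral_image`.
#' @export
spectral_image <- function(channels, pixel_size_um,
                           channel_names = names(channels)) {
  stopifnot(is.list(channels), length(channels) >= 1, pixel_size_um > 0)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(channels))
  stopifnot(length(channel_names) == length(channels))
  dims <- vapply(channels, dim, integer(2))
  if (!all(dims == dims[, 1]))
    stop("all channels must share dimensions")
  names(channels) <- channel_names
  structure(list(channels = channels, channel_names = channel_names,
                 pixel_size_um = pixel_size_um),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<spectral_image> %d x %d px, %.4g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) dim(x$channels[[1]])

#' Spectral coefficient (unmixing) matrix
#'
#' Fluorophore-by-channel matrix R of the linear mixing model S = A x R,
#' where S holds measured channel intensities and A fluorophore abundances
#' (both as row vectors per pixel). Rows are normalized to unit sum so each
#' row gives a fluorophore's relative contribution to every channel.
#'
#' @param values numeric F x C matrix with non-negative entries and positive
#'   row sums; rows are renormalized to sum to 1.
#' @param fluorophore_names,channel_names dimension names.
#' @return object of class `unmix_matrix`.
#' @export
unmix_matrix <- function(values,
                         fluorophore_names = rownames(values),
                         channel_names = colnames(values)) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("unmix_matrix entries must be non-negative")
  rs <- rowSums(values)
  if (any(rs <= 0)) stop("each unmix_matrix row needs a positive sum")
  values <- values / rs
  if (is.null(fluorophore_names))
    fluorophore_names <- paste0("f", seq_len(nrow(values)))
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(values)))
  dimnames(values) <- list(fluorophore_names, channel_names)
  structure(list(values = values, fluorophore_names = fluorophore_names,
                 channel_names = channel_names),
            class = "unmix_matrix")
}

#' @export
print.unmix_matrix <- function(x, ...) {
  cat("<unmix_matrix> fluorophores x channels:\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Estimate the unmixing matrix from single-fluorophore controls
#'
#' Each control image contains signal from exactly one fluorophore across
#' all channels. Its coefficient row is the mean channel intensity vector
#' over bright pixels (above a percentile of the control's brightest
#' channel, to exclude background), normalized to unit sum.
#'
#' @param controls list of [spectral_image] objects, one per fluorophore,
#'   all sharing the same channel set.
#' @param fluorophore_names names for the rows; defaults to
#'   `names(controls)`.
#' @param background_quantile pixels whose brightest-channel intensity is at
#'   or below this quantile are treated as background (default 0.5).
#' @return an [unmix_matrix].
#' @export
estimate_unmix_matrix <- function(controls,
                                  fluorophore_names = names(controls),
                                  background_quantile = 0.5) {
  stopifnot(is.list(controls), length(controls) >= 1)
  ch <- controls[[1]]$channel_names
  for (ctl in controls)
    if (!identical(ctl$channel_names, ch))
      stop("control images have mismatched channel sets")
  if (is.null(fluorophore_names))
    fluorophore_names <- paste0("f", seq_along(controls))
  rows <- lapply(controls, function(ctl) {
    mats <- ctl$channels
    peak_ch <- which.max(vapply(mats, function(m) mean(m), 0))
    bright <- mats[[peak_ch]]
    if (all(bright == 0)) stop("control image has all-zero signal")
    sel <- bright > quantile(bright, background_quantile)
    if (!any(sel)) sel <- bright == max(bright)
    vapply(mats, function(m) mean(m[sel]), 0)
  })
  unmix_matrix(do.call(rbind, rows), fluorophore_names, ch)
}

#' Mix fluorophore abundances into channel signals
#'
#' Forward model S = A x R: per pixel, channel signals are the abundance
#' row vector times the coefficient matrix.
#'
#' @param abundances named list of abundance matrices (one per fluorophore,
#'   ordered as the rows of `R`).
#' @param R an [unmix_matrix].
#' @param pixel_size_um pixel size for the returned image.
#' @return a [spectral_image] with one channel per column of `R`.
#' @export
mix_abundances <- function(abundances, R, pixel_size_um = 1) {
  stopifnot(inherits(R, "unmix_matrix"),
            length(abundances) == nrow(R$values))
  d <- dim(abundances[[1]])
  A <- vapply(abundances, as.numeric, numeric(prod(d)))
  S <- A %*% R$values
  chans <- lapply(seq_len(ncol(S)), function(j) matrix(S[, j], d[1], d[2]))
  spectral_image(chans, pixel_size_um, R$channel_names)
}

#' Solve the linear mixing model for fluorophore abundances
#'
#' Per pixel, solves S = A x R for A by linear least squares on the row
#' system; negative abundances are clipped to zero by default (physical
#' non-negativity), or a full non-negative least-squares solution can be
#' requested.
#'
#' @param image a [spectral_image]; its channel count must equal `ncol(R)`.
#' @param R an [unmix_matrix] with full row rank.
#' @param method `"clip"` (least squares, then clamp negatives at 0) or
#'   `"nnls"` (Lawson-Hanson non-negative least squares, applied only to
#'   pixels whose unconstrained solution is negative).
#' @return named list of abundance matrices, one per fluorophore.
#' @export
unmix <- function(image, R, method = c("clip", "nnls")) {
  method <- match.arg(method)
  stopifnot(inherits(image, "spectral_image"), inherits(R, "unmix_matrix"))
  Rm <- R$values
  f <- nrow(Rm); c <- ncol(Rm)
  if (length(image$channels) != c)
    stop("image channel count does not match ncol(R)")
  G <- Rm %*% t(Rm)                       # F x F Gram matrix
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (f > c || min(ev) <= max(ev) * 1e-12)
    stop(sprintf(
      "unmixing matrix is rank-deficient (condition number %.3g)",
      sqrt(max(ev) / max(min(ev), .Machine$double.xmin))))
  d <- dim(image)
  S <- vapply(image$channels, as.numeric, numeric(prod(d)))
  A <- S %*% t(Rm) %*% solve(G)           # unconstrained least squares
  if (method == "nnls") {
    bad <- which(rowSums(A < -1e-12) > 0)
    for (i in bad) A[i, ] <- nnls_small(Rm, S[i, ])
  }
  A[A < 0] <- 0
  out <- lapply(seq_len(f), function(k) matrix(A[, k], d[1], d[2]))
  names(out) <- R$fluorophore_names
  out
}

# Lawson-Hanson active-set NNLS for one pixel: minimize ||a R - s|| s.t.
# a >= 0. Tiny problems (F <= 8), so a plain R implementation is fine.
nnls_small <- function(R, s, tol = 1e-10) {
  f <- nrow(R)
  P <- logical(f)
  a <- numeric(f)
  w <- drop(R %*% (s - drop(a %*% R)))    # gradient of 0.5||aR - s||^2
  iter <- 0
  while (any(!P & w > tol) && iter < 30 * f) {
    iter <- iter + 1
    j <- which.max(ifelse(P, -Inf, w))
    P[j] <- TRUE
    repeat {
      Rp <- R[P, , drop = FALSE]
      z <- numeric(f)
      z[P] <- drop(solve(Rp %*% t(Rp), Rp %*% s))
      if (all(z[P] > tol)) { a <- z; break }
      neg <- P & z <= tol
      alpha <- min(a[neg] / (a[neg] - z[neg]))
      a <- a + alpha * (z - a)
      P[P & a <= tol] <- FALSE
      a[!P] <- 0
    }
    w <- drop(R %*% (s - drop(a %*% R)))
  }
  a
}

#' Write / read an unmixing matrix as CSV
#'
#' Header row holds channel names; first column holds fluorophore names.
#' @param R an [unmix_matrix].
#' @param path CSV file path.
#' @export
write_unmix_matrix <- function(R, path) {
  stopifnot(inherits(R, "unmix_matrix"))
  df <- data.frame(fluorophore = R$fluorophore_names, R$values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_unmix_matrix
#' @export
read_unmix_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  unmix_matrix(as.matrix(df[, -1, drop = FALSE]),
               fluorophore_names = df[[1]],
               channel_names = colnames(df)[-1])
}
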