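#' Alignment score from ellipse axes
#'
#' `(1 - b/a) * 100`: 0 for an isotropic (circular) angular power
#' distribution, 100 for one fully concentrated at a single orientation.
#'
#' @param a major semi-axis (> 0).
#' @param b minor semi-axis (0 <= b <= a).
#' @return score in [0, 100].
#' @export
alignment_score <- function(a, b) {
  if (a <= 0) stop("major axis a must be positive")
  if (b < 0 || b > a) stop("require 0 <= b <= a")
  (1 - b / a) * 100
}

#' Fit an ellipse to an angular power distribution
#'
#' The binned angular distribution is projected onto a polar point cloud
#' (one point per bin at radius = summed power, doubled to [0, 360) by the
#' point symmetry of a real image's power spectrum) and an ellipse is
#' fitted via second central moments. The major-axis tilt gives the
#' dominant direction of spectral power; axes give the alignment score.
#'
#' @param theta_deg bin center angles in degrees, `[0, 180)`.
#' @param power non-negative summed power per bin.
#' @return list: `tilt_deg` (major axis, `[0, 180)`, `NA` if the cloud is
#'   degenerate), `a`, `b` (semi-axes, `b <= a`), `alignment` in [0, 100].
#' @export
polar_ellipse_fit <- function(theta_deg, power) {
  stopifnot(length(theta_deg) == length(power), all(power >= -1e-12))
  th <- c(theta_deg, theta_deg + 180) * pi / 180
  r <- c(power, power)
  x <- r * cos(th); y <- r * sin(th)
  # centroid is 0 by construction (antipodal pairs)
  n <- length(x)
  sxx <- sum(x * x) / n; syy <- sum(y * y) / n; sxy <- sum(x * y) / n
  tr <- sxx + syy
  if (tr <= 0)
    return(list(tilt_deg = NA_real_, a = 0, b = 0, alignment = 0))
  disc <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  tilt <- (atan2(2 * sxy, sxx - syy) / 2) %% pi
  a <- sqrt(l1); b <- sqrt(l2)
  list(tilt_deg = tilt * 180 / pi, a = a, b = b,
       alignment = alignment_score(a, b))
}

#' Dominant fiber orientation and alignment from an image patch
#'
#' FFT power-spectrum orientation analysis: (1) subtract the patch mean
#' and apply a radial Hann window; (2) 2D FFT, power spectrum, DC zeroed;
#' (3) restrict to the centered circular region of radius half the patch
#' side; (4) sum power into 1-degree angular bins over [0, 180);
#' (5) fit an ellipse to the polar distribution by second moments
#' ([polar_ellipse_fit()]); (6) rotate the major-axis tilt by 90 degrees,
#' since fibers at angle theta concentrate spectral power perpendicular to
#' theta. Angles are measured from the +x (column) axis toward +y (row),
#' reported in [0, 180).
#'
#' @param patch square numeric matrix, side >= 32 px.
#' @return list of class `fiber_stats`: `orientation_deg` (`NA` and flag
#'   `"invalid_orientation"` for a constant patch), `a`, `b`,
#'   `alignment_score`, `flags`.
#' @export
fiber_orientation <- function(patch) {
  stopifnot(is.matrix(patch))
  n <- nrow(patch)
  if (ncol(patch) != n) stop("patch must be square")
  if (n < 32) stop("patch side must be >= 32 px")
  if (diff(range(patch)) == 0)
    return(structure(list(orientation_deg = NA_real_, a = 0, b = 0,
                          alignment_score = 0,
                          flags = "invalid_orientation"),
                     class = "fiber_stats"))
  ctr <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad <- sqrt((row - ctr)^2 + (col - ctr)^2)
  w <- ifelse(rad <= n / 2, 0.5 * (1 + cos(pi * rad / (n / 2))), 0)
  z <- (patch - mean(patch)) * w
  P <- Mod(fft(z))^2
  P[1, 1] <- 0
  # signed frequency index per axis
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  ky <- matrix(k, n, n)          # rows: y frequency
  kx <- matrix(k, n, n, byrow = TRUE)
  keep <- ky^2 + kx^2 <= (n / 2)^2 & (ky != 0 | kx != 0)
  ang <- (atan2(ky[keep], kx[keep]) * 180 / pi) %% 180
  bin <- pmin(180L, 1L + as.integer(floor(ang)))
  pw <- numeric(180)
  agg <- tapply(P[keep], bin, sum)
  pw[as.integer(names(agg))] <- agg
  fit <- polar_ellipse_fit(seq(0.5, 179.5, by = 1), pw)
  orient <- if (is.na(fit$tilt_deg)) NA_real_ else
    (fit$tilt_deg + 90) %% 180
  structure(list(orientation_deg = orient, a = fit$a, b = fit$b,
                 alignment_score = fit$alignment,
                 flags = if (is.na(orient)) "invalid_orientation"
                         else character()),
            class = "fiber_stats")
}

#' @export
print.fiber_stats <- function(x, ...) {
  cat(sprintf("<fiber_stats> orientation %.1f deg, alignment %.1f%s\n",
              x$orientation_deg, x$alignment_score,
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Orientation difference folded to [0, 90]
#'
#' Acute angle between two orientations (each mod 180):
#' `min(|d|, 180 - |d|)`.
#'
#' @param fiber_deg,edge_deg orientations in degrees.
#' @return angle in [0, 90].
#' @export
relative_orientation <- function(fiber_deg, edge_deg) {
  d <- abs((fiber_deg - edge_deg) %% 180)
  pmin(d, 180 - d)
}

# Moore-neighbour boundary tracing of one 8-connected component: walk the
# outer boundary clockwise, keeping the background "backtrack" pixel, and
# stop when the initial (position, backtrack) state recurs.
# Returns an ordered m x 2 matrix of (row, col) boundary pixels.
trace_boundary <- function(comp) {
  idx <- which(comp, arr.ind = TRUE)
  start <- idx[order(idx[, 2], idx[, 1])[1], ]   # leftmost, then topmost
  # clockwise on screen (rows increase downward): N NE E SE S SW W NW
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  nr <- nrow(comp); nc <- ncol(comp)
  fg <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    comp[p[1], p[2]]
  cur <- start
  b_dir <- 7L                                    # backtrack: W of start
  path <- matrix(start, 1, 2)
  first_state <- c(start, b_dir)
  repeat {
    found <- FALSE
    for (s in 1:8) {
      d <- ((b_dir - 1L + s) %% 8L) + 1L
      p <- cur + dirs[d, ]
      if (fg(p)) {
        # backtrack for the new pixel: the background neighbour scanned
        # just before p, expressed as a direction from p
        prev_d <- ((b_dir - 1L + s - 1L) %% 8L) + 1L
        bg <- cur + dirs[prev_d, ]
        delta <- bg - p
        b_dir <- which(dirs[, 1] == delta[1] & dirs[, 2] == delta[2])
        cur <- p
        found <- TRUE
        break
      }
    }
    if (!found) break                            # isolated pixel
    if (all(c(cur, b_dir) == first_state) && nrow(path) > 1) break
    path <- rbind(path, cur)
    if (nrow(path) > 4 * sum(comp) + 8) break    # safety
  }
  # the walk re-appends the start before the stop state recurs
  if (nrow(path) > 1 && all(path[nrow(path), ] == path[1, ]))
    path <- path[-nrow(path), , drop = FALSE]
  unname(path)
}

#' Extract the tumor-collagen interface
#'
#' Traces the outer contour of each tumor component and retains the
#' contour stretches that have SHG collagen signal above threshold within
#' `collagen_search_um`, returning ordered polylines along the
#' tumor-collagen interface.
#'
#' @param tumor a [region_mask] (non-empty).
#' @param shg numeric SHG intensity matrix.
#' @param collagen_search_um search radius for collagen near the boundary.
#' @param shg_threshold collagen positivity threshold; default Otsu over
#'   the positive SHG intensities.
#' @return list of `interface_line` objects (fields `vertices` (m x 2
#'   0-based (row, col)), `arc_length_um`, `closed`, `pixel_size_um`);
#'   empty list when no boundary pixel is near collagen.
#' @export
extract_interface <- function(tumor, shg, collagen_search_um = 20,
                              shg_threshold = NULL) {
  stopifnot(inherits(tumor, "region_mask"), all(dim(shg) == dim(tumor$mask)))
  if (!any(tumor$mask)) stop("tumor mask is empty")
  px <- tumor$pixel_size_um
  if (is.null(shg_threshold)) {
    pos <- shg[shg > 0]
    shg_threshold <- if (length(pos)) otsu_threshold(pos) / 2 else Inf
  }
  coll <- shg > shg_threshold
  dist_coll <- if (any(coll)) distance_transform(coll, px) else
    matrix(Inf, nrow(shg), ncol(shg))
  lab <- label_components_cpp(tumor$mask)
  out <- list()
  for (comp_id in seq_len(max(lab))) {
    comp <- lab == comp_id
    path <- trace_boundary(comp)
    near <- dist_coll[path] <= collagen_search_um
    if (!any(near)) next
    m <- nrow(path)
    if (all(near)) {
      runs <- list(seq_len(m))
      closed_flags <- TRUE
    } else {
      # maximal circular runs of TRUE
      r <- rle(near)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- lapply(which(r$values), function(i) starts[i]:ends[i])
      # merge wraparound run
      if (length(runs) > 1 && near[1] && near[m]) {
        runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
        runs[[length(runs)]] <- NULL
      }
      closed_flags <- FALSE
    }
    for (rn in runs) {
      v <- path[rn, , drop = FALSE]
      if (nrow(v) < 2) next
      seg <- sqrt(rowSums((v[-1, , drop = FALSE] -
                           v[-nrow(v), , drop = FALSE])^2))
      len <- sum(seg)
      if (closed_flags)
        len <- len + sqrt(sum((v[1, ] - v[nrow(v), ])^2))
      out[[length(out) + 1L]] <- structure(
        list(vertices = v - 1, arc_length_um = len * px,
             closed = closed_flags, pixel_size_um = px),
        class = "interface_line")
    }
  }
  out
}

#' @export
print.interface_line <- function(x, ...) {
  cat(sprintf("<interface_line> %d vertices, %.1f um, %s\n",
              nrow(x$vertices), x$arc_length_um,
              if (x$closed) "closed" else "open"))
  invisible(x)
}

# Point at arc-length position s along a polyline (0-based vertex coords).
interp_along <- function(vertices, cum_len, s) {
  i <- findInterval(s, cum_len, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(cum_len) - 1L)
  seg <- cum_len[i + 1] - cum_len[i]
  t <- if (seg > 0) (s - cum_len[i]) / seg else 0
  vertices[i, ] + t * (vertices[i + 1, ] - vertices[i, ])
}

#' Place peritumoral ROI centers along an interface line
#'
#' Centers at arc-length positions 0, `spacing_um`, ... along the line;
#' for closed lines, trailing centers within `spacing_um / 2` of the start
#' are dropped. A line shorter than `diameter_um` yields a single flagged
#' center at its midpoint.
#'
#' @param line an `interface_line` from [extract_interface()].
#' @param diameter_um ROI diameter (default 100).
#' @param spacing_um center-to-center spacing (default 100).
#' @return data.frame with `row_px`, `col_px` (0-based, possibly
#'   fractional), `arc_pos_um`, `flag`.
#' @export
place_rois <- function(line, diameter_um = 100, spacing_um = 100) {
  stopifnot(inherits(line, "interface_line"))
  px <- line$pixel_size_um
  v <- line$vertices
  if (line$closed) v <- rbind(v, v[1, ])
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg)) * px
  L <- cum[length(cum)]
  if (L < diameter_um) {
    p <- interp_along(v, cum, L / 2)
    return(data.frame(row_px = p[1], col_px = p[2], arc_pos_um = L / 2,
                      flag = "short_line"))
  }
  pos <- seq(0, L, by = spacing_um)
  if (line$closed)
    pos <- pos[!(pos > 0 & (L - pos) < spacing_um / 2)]
  pts <- t(vapply(pos, function(s) interp_along(v, cum, s), numeric(2)))
  data.frame(row_px = pts[, 1], col_px = pts[, 2], arc_pos_um = pos,
             flag = "")
}

#' Local orientation of the tumor edge
#'
#' Rasterizes the interface-line stretch within `window_um / 2` of a
#' center into a patch and runs the same FFT orientation analysis as for
#' fibers, returning the dominant edge direction.
#'
#' @param line an `interface_line`.
#' @param center numeric (row, col), 0-based pixel coordinates.
#' @param window_um window size (default 100, one ROI diameter).
#' @return orientation in degrees, [0, 180).
#' @export
edge_orientation <- function(line, center, window_um = 100) {
  stopifnot(inherits(line, "interface_line"))
  px <- line$pixel_size_um
  half_px <- window_um / 2 / px
  v <- line$vertices
  d <- sqrt((v[, 1] - center[1])^2 + (v[, 2] - center[2])^2)
  keep <- d <= half_px
  if (sum(keep) < 2) stop("fewer than 2 interface vertices in window")
  vv <- v[keep, , drop = FALSE]
  side <- max(32L, 2L * ceiling(half_px) + 1L)
  ctr <- (side - 1) / 2
  r0 <- vv[-nrow(vv), 1] - center[1] + ctr
  c0 <- vv[-nrow(vv), 2] - center[2] + ctr
  r1 <- vv[-1, 1] - center[1] + ctr
  c1 <- vv[-1, 2] - center[2] + ctr
  # drop jumps across disjoint kept stretches
  ok <- sqrt((r1 - r0)^2 + (c1 - c0)^2) <= 2
  patch <- draw_segments_cpp(side, side, r0[ok], c0[ok], r1[ok], c1[ok],
                             2, rep(1, sum(ok)))
  fs <- fiber_orientation(patch)
  fs$orientation_deg
}

#' Peritumoral ROI table: local GFP, SHG, and fiber statistics
#'
#' For each 100-um ROI disk centered on the tumor-collagen interface:
#' mean GFP over the pixels overlapping the tumor ROI, mean SHG over the
#' whole disk, fiber orientation/alignment from the SHG patch, and the
#' fiber orientation relative to the local tumor edge.
#'
#' @param image a [spectral_image] with `GFP` and `SHG` channels (use
#'   unmixed abundances where crosstalk matters).
#' @param tumor a [region_mask].
#' @param line the `interface_line` the centers sit on.
#' @param centers data.frame from [place_rois()]; default places them.
#' @param diameter_um ROI diameter (default 100).
#' @param edge_window_um window for [edge_orientation()] (default 100).
#' @return data.frame: `center_row_px`, `center_col_px`, `mean_gfp`
#'   (`NA` when the disk misses the tumor), `mean_shg`, `orientation_deg`,
#'   `alignment_score`, `edge_deg`, `relative_orientation_deg`, `flags`.
#' @export
peritumoral_table <- function(image, tumor, line, centers = NULL,
                              diameter_um = 100, edge_window_um = 100) {
  stopifnot(inherits(image, "spectral_image"),
            inherits(tumor, "region_mask"))
  gfp <- image$channels[["GFP"]]
  shg <- image$channels[["SHG"]]
  if (is.null(gfp) || is.null(shg))
    stop("image needs GFP and SHG channels")
  px <- image$pixel_size_um
  if (is.null(centers)) centers <- place_rois(line, diameter_um, diameter_um)
  r_px <- diameter_um / 2 / px
  nr <- nrow(gfp); nc <- ncol(gfp)
  side <- max(32L, 2L * ceiling(r_px) + 1L)
  rows <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    cr <- round(centers$row_px[i]) + 1L   # to 1-based
    ccol <- round(centers$col_px[i]) + 1L
    dp <- disk_pixels(cr, ccol, r_px, nr, nc)
    flags <- centers$flag[i]
    if (length(dp$r) < dp$n_total / 2)
      flags <- paste0(flags, if (nzchar(flags)) ";", "partial_disk")
    in_tumor <- tumor$mask[cbind(dp$r, dp$c)]
    mean_gfp <- if (any(in_tumor))
      mean(gfp[cbind(dp$r, dp$c)][in_tumor]) else NA_real_
    if (!any(in_tumor))
      flags <- paste0(flags, if (nzchar(flags)) ";", "no_tumor_overlap")
    mean_shg <- mean(shg[cbind(dp$r, dp$c)])
    # square SHG patch around the center, mean-padded at borders
    patch <- matrix(NA_real_, side, side)
    pr <- (cr - (side - 1L) / 2L):(cr + (side - 1L) / 2L)
    pc <- (ccol - (side - 1L) / 2L):(ccol + (side - 1L) / 2L)
    okr <- pr >= 1 & pr <= nr; okc <- pc >= 1 & pc <= nc
    patch[okr, okc] <- shg[pr[okr], pc[okc]]
    patch[is.na(patch)] <- mean(patch, na.rm = TRUE)
    fs <- fiber_orientation(patch)
    edge <- tryCatch(edge_orientation(line, c(centers$row_px[i],
                                              centers$col_px[i]),
                                      edge_window_um),
                     error = function(e) NA_real_)
    rel <- if (is.na(fs$orientation_deg) || is.na(edge)) NA_real_ else
      relative_orientation(fs$orientation_deg, edge)
    rows[[i]] <- data.frame(
      center_row_px = centers$row_px[i], center_col_px = centers$col_px[i],
      mean_gfp = mean_gfp, mean_shg = mean_shg,
      orientation_deg = fs$orientation_deg,
      alignment_score = fs$alignment_score,
      edge_deg = edge, relative_orientation_deg = rel,
      flags = flags, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
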