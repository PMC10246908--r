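#' Binary region mask with provenance
#'
#' @param mask logical matrix.
#' @param pixel_size_um physical pixel size.
#' @param kind one of `"tumor_roi"`, `"expanded_tumor_roi"`, `"vessel"`,
#'   `"viable_tumor"`.
#' @param flags optional character vector of quality flags.
#' @return object of class `region_mask`.
#' @export
region_mask <- function(mask, pixel_size_um,
                        kind = c("tumor_roi", "expanded_tumor_roi",
                                 "vessel", "viable_tumor"),
                        flags = character()) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, pixel_size_um = pixel_size_um, kind = kind,
                 flags = flags),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask:%s> %d x %d px, %d positive (%.1f%%)%s\n",
              x$kind, nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask),
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

# Resolve a threshold specification against an intensity image.
# spec: list(mode = "fixed", value =) | list(mode = "otsu") |
#       list(mode = "percentile", background =, probs = 0.99)
resolve_threshold <- function(img, spec) {
  if (is.numeric(spec)) return(spec)
  mode <- spec$mode %||% "otsu"
  switch(mode,
         fixed = spec$value,
         otsu = {
           # Otsu on log intensity handles the heavy-tailed fluorescence
           # histograms better than the linear scale
           lg <- log1p(pmax(img, 0))
           expm1(otsu_threshold(lg))
         },
         percentile = quantile(spec$background,
                               spec$probs %||% 0.99, names = FALSE),
         stop("unknown threshold mode: ", mode))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment the tumor ROI from the DsRed channel
#'
#' Thresholds DsRed intensity (above background) and removes small
#' components, giving the binary tumor-cell region of interest.
#'
#' @param dsred numeric matrix (DsRed intensity, typically unmixed).
#' @param pixel_size_um pixel size.
#' @param threshold_spec a number (fixed threshold), or a list:
#'   `list(mode = "fixed", value =)`, `list(mode = "otsu")` (default; Otsu
#'   on log intensity), or `list(mode = "percentile", background =, probs =)`
#'   taking a percentile (default 0.99) of user-supplied background pixels.
#' @param min_area_px minimum connected-component area kept (default 50).
#' @return a [region_mask] of kind `tumor_roi`; flagged `"empty"` (with a
#'   warning) if no pixel survives.
#' @export
segment_tumor_roi <- function(dsred, pixel_size_um = 1,
                              threshold_spec = list(mode = "otsu"),
                              min_area_px = 50L) {
  stopifnot(is.matrix(dsred), length(dsred) > 0)
  thr <- resolve_threshold(dsred, threshold_spec)
  mask <- dsred > thr
  mask <- remove_small_objects(mask, min_area_px)
  flags <- character()
  if (!any(mask)) {
    warning("tumor segmentation produced an empty mask")
    flags <- "empty"
  }
  region_mask(mask, pixel_size_um, "tumor_roi", flags)
}

#' GFP-positive fraction and mean GFP intensity over the tumor ROI
#'
#' The positive fraction is the number of tumor-ROI pixels whose GFP
#' intensity exceeds the threshold divided by the total tumor-ROI pixel
#' count; the mean is the sum of tumor-ROI GFP intensities divided by the
#' same count.
#'
#' @param gfp numeric matrix (GFP intensity).
#' @param tumor a [region_mask] (non-empty).
#' @param gfp_threshold positivity threshold (background-derived).
#' @return list: `gfp_positive_fraction`, `mean_gfp_intensity`,
#'   `n_tumor_pixels`.
#' @export
gfp_metrics <- function(gfp, tumor, gfp_threshold) {
  stopifnot(inherits(tumor, "region_mask"),
            all(dim(gfp) == dim(tumor$mask)))
  n <- sum(tumor$mask)
  if (n == 0) stop("tumor mask is empty")
  v <- gfp[tumor$mask]
  list(gfp_positive_fraction = sum(v > gfp_threshold) / n,
       mean_gfp_intensity = sum(v) / n,
       n_tumor_pixels = n)
}

#' Expand a tumor ROI by Euclidean dilation
#'
#' Morphologically dilates the mask by `distance_um` beyond its boundary
#' (exact Euclidean disk of radius `round(distance_um / pixel_size_um)`
#' pixels), producing the expanded tumor ROI that captures peritumoral
#' vessels within the nominal oxygen diffusion limit.
#'
#' @param tumor a [region_mask].
#' @param distance_um dilation distance, default 100 um.
#' @return a [region_mask] of kind `expanded_tumor_roi` (superset of input).
#' @export
expand_roi <- function(tumor, distance_um = 100) {
  stopifnot(inherits(tumor, "region_mask"))
  if (distance_um < 0) stop("distance_um must be >= 0")
  r_px <- round(distance_um / tumor$pixel_size_um)
  region_mask(disk_dilate(tumor$mask, r_px), tumor$pixel_size_um,
              "expanded_tumor_roi")
}

#' Segment vessels from the APC-CD31 channel
#'
#' Simple linear iterative clustering (SLIC) superpixels on the intensity
#' channel, followed by adaptive thresholding of superpixel mean
#' intensities: a superpixel is vessel-positive when its mean exceeds the
#' local sliding-window mean minus `offset`. A global background floor
#' (intensity percentile) removes spurious low-signal detections, so the
#' output is always a subset of pixels above that floor.
#'
#' @param apc numeric matrix (APC-CD31 intensity).
#' @param pixel_size_um pixel size.
#' @param n_superpixels target superpixel count; default image area / 256.
#' @param compactness SLIC spatial regularization (on [0, 1]-scaled
#'   intensity), default 0.1.
#' @param adaptive_window_px sliding-window side for the local mean
#'   (odd; default 51).
#' @param offset subtracted from the local mean threshold (default 0).
#' @param bg_quantile global intensity floor percentile (default 0.75).
#' @return a [region_mask] of kind `vessel`.
#' @export
segment_vessels <- function(apc, pixel_size_um = 1, n_superpixels = NULL,
                            compactness = 0.1, adaptive_window_px = 51L,
                            offset = 0, bg_quantile = 0.75) {
  stopifnot(is.matrix(apc))
  nr <- nrow(apc); nc <- ncol(apc)
  if (adaptive_window_px > max(nr, nc))
    stop("adaptive window larger than image")
  if (adaptive_window_px %% 2 == 0)
    adaptive_window_px <- adaptive_window_px + 1L
  rng <- range(apc)
  if (diff(rng) == 0)
    return(region_mask(matrix(FALSE, nr, nc), pixel_size_um, "vessel",
                       flags = "constant_image"))
  if (is.null(n_superpixels)) n_superpixels <- max(16, (nr * nc) / 256)
  step <- sqrt(nr * nc / n_superpixels)
  scaled <- (apc - rng[1]) / diff(rng)
  lab <- slic_cpp(scaled, step, compactness, 10L)
  sp_mean_val <- rep(NA_real_, max(lab))
  agg <- tapply(as.numeric(apc), as.numeric(lab), mean)
  sp_mean_val[as.integer(names(agg))] <- agg
  sp_mean <- matrix(sp_mean_val[lab], nr, nc)
  local_mean <- box_mean(sp_mean, adaptive_window_px)
  # background floor: percentile of the image, but never below 2% of the
  # intensity range (a sparse clean image has a zero percentile, and a
  # zero floor lets numerical residue through)
  floor_val <- max(quantile(apc, bg_quantile, names = FALSE),
                   rng[1] + 0.02 * diff(rng))
  mask <- (sp_mean > local_mean - offset) & sp_mean > floor_val &
    apc > floor_val
  region_mask(mask, pixel_size_um, "vessel")
}

#' Vascular density within the expanded tumor ROI
#'
#' Number of vessel-positive pixels inside the expanded ROI divided by the
#' total expanded-ROI pixel count.
#'
#' @param vessels,expanded [region_mask] objects sharing dimensions.
#' @return numeric in [0, 1].
#' @export
vascular_density <- function(vessels, expanded) {
  stopifnot(inherits(vessels, "region_mask"),
            inherits(expanded, "region_mask"),
            all(dim(vessels$mask) == dim(expanded$mask)))
  n <- sum(expanded$mask)
  if (n == 0) stop("expanded ROI is empty")
  sum(vessels$mask & expanded$mask) / n
}

#' Distance map to the nearest vessel
#'
#' Exact Euclidean distance transform of the vessel mask complement, in um;
#' 0 on vessel pixels. For points outside the vessel mask the nearest mask
#' pixel lies on the vessel wall, so this is the distance to the vessel
#' wall.
#'
#' @param vessels a [region_mask] of kind `vessel`.
#' @return numeric matrix of distances (um); all-`Inf` with a warning when
#'   the vessel mask is empty.
#' @export
vessel_distance_map <- function(vessels) {
  stopifnot(inherits(vessels, "region_mask"))
  if (!any(vessels$mask)) {
    warning("empty vessel mask: distance map is Inf everywhere")
    return(matrix(Inf, nrow(vessels$mask), ncol(vessels$mask)))
  }
  distance_transform(vessels$mask, vessels$pixel_size_um)
}

#' Sample tumor-cell positions on a regular grid
#'
#' Approximates individual tumor cells by sampling equally spaced pixels
#' (default pitch 20 um, a typical tumor-cell diameter) within the tumor
#' ROI; each sample records its GFP intensity and distance to the nearest
#' vessel.
#'
#' @param tumor a [region_mask].
#' @param gfp numeric matrix of GFP intensities.
#' @param dmap distance map in um (from [vessel_distance_map()]).
#' @param spacing_um grid pitch in um (default 20).
#' @return data.frame with columns `x_px`, `y_px` (0-based), `gfp_intensity`,
#'   `distance_um`, `gfp_level` (NA until [classify_gfp_levels()]).
#' @export
sample_cells <- function(tumor, gfp, dmap, spacing_um = 20) {
  stopifnot(inherits(tumor, "region_mask"),
            all(dim(gfp) == dim(tumor$mask)),
            all(dim(dmap) == dim(tumor$mask)))
  pitch <- round(spacing_um / tumor$pixel_size_um)
  if (pitch < 1) stop("spacing_um is smaller than one pixel")
  nr <- nrow(tumor$mask); nc <- ncol(tumor$mask)
  rows <- seq(1L, nr, by = pitch)
  cols <- seq(1L, nc, by = pitch)
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  keep <- tumor$mask[cbind(rr, cc)]
  rr <- rr[keep]; cc <- cc[keep]
  data.frame(x_px = cc - 1L, y_px = rr - 1L,
             gfp_intensity = gfp[cbind(rr, cc)],
             distance_um = dmap[cbind(rr, cc)],
             gfp_level = rep(NA_character_, length(rr)),
             stringsAsFactors = FALSE)
}

#' Bivariate probability histogram of distance versus GFP intensity
#'
#' 2D histogram of cell samples over the given bin edges, normalized so all
#' bins sum to 1. Bins are half-open `[e_i, e_{i+1})` with the last bin
#' closed; samples outside the edges are dropped.
#'
#' @param cells data.frame from [sample_cells()].
#' @param distance_edges,intensity_edges increasing bin edge vectors.
#' @return matrix (distance bins x intensity bins) of probabilities.
#' @export
bivariate_histogram <- function(cells, distance_edges, intensity_edges) {
  if (nrow(cells) == 0) stop("no cell samples")
  bin_of <- function(x, e) {
    b <- findInterval(x, e, rightmost.closed = TRUE)
    b[b < 1 | b >= length(e)] <- NA
    b
  }
  bd <- bin_of(cells$distance_um, distance_edges)
  bi <- bin_of(cells$gfp_intensity, intensity_edges)
  ok <- !is.na(bd) & !is.na(bi)
  h <- matrix(0, length(distance_edges) - 1, length(intensity_edges) - 1)
  for (k in which(ok)) h[bd[k], bi[k]] <- h[bd[k], bi[k]] + 1
  if (sum(h) == 0) stop("all samples fall outside the bin edges")
  h / sum(h)
}

#' Classify cells into low / moderate / high GFP levels
#'
#' Half-open convention: low = `[0, low_cut)`, moderate =
#' `[low_cut, high_cut)`, high = `[high_cut, Inf)`.
#'
#' @param cells data.frame with a `gfp_intensity` column.
#' @param low_cut,high_cut intensity cuts, `low_cut <= high_cut`.
#' @return `cells` with `gfp_level` filled in.
#' @export
classify_gfp_levels <- function(cells, low_cut, high_cut) {
  if (low_cut > high_cut) stop("low_cut must be <= high_cut")
  lv <- ifelse(cells$gfp_intensity < low_cut, "low",
               ifelse(cells$gfp_intensity < high_cut, "moderate", "high"))
  cells$gfp_level <- lv
  cells
}
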