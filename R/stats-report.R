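#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; p from the t distribution with n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @return list of class `correlation_result`: `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: r undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.3g, n = %d\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' Welch's unpaired t test
#'
#' Two-sided unpaired t test with Welch's correction (Welch-Satterthwaite
#' degrees of freedom).
#'
#' @param g1,g2 numeric vectors, each n >= 2; at least one group with
#'   positive variance.
#' @return list: `t`, `df`, `p_value`, `mean1`, `mean2`.
#' @export
welch_t <- function(g1, g2) {
  if (length(g1) < 2 || length(g2) < 2) stop("each group needs n >= 2")
  if (sd(g1) == 0 && sd(g2) == 0)
    stop("both groups constant: t undefined")
  ht <- t.test(g1, g2, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean1 = mean(g1), mean2 = mean(g2))
}

#' Fit a single-exponential decay and recover the half-life
#'
#' Least-squares fit of `I(t) = baseline + amplitude * 2^(-t / halflife)`.
#' The half-life is profiled (for a fixed half-life the baseline and
#' amplitude solve a linear least-squares problem), scanned over a wide
#' grid, then polished by golden-section/parabolic minimization, which is
#' robust and recovers noiseless series to near machine precision.
#'
#' @param times_h sampling times in hours (>= 4 points).
#' @param intensities non-negative intensities.
#' @return list of class `decay_fit`: `halflife_h` (`NA` with flag
#'   `"non_decaying"` when the best amplitude is <= 0), `baseline`,
#'   `amplitude`, `rss`, `flags`.
#' @export
fit_halflife <- function(times_h, intensities) {
  stopifnot(length(times_h) == length(intensities))
  if (length(times_h) < 4) stop("need at least 4 time points")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  profile_fit <- function(h) {
    X <- cbind(1, 2^(-times_h / h))
    cf <- tryCatch(qr.coef(qr(X), intensities),
                   error = function(e) c(NA, NA))
    if (any(!is.finite(cf))) return(list(rss = Inf, cf = cf))
    list(rss = sum((intensities - X %*% cf)^2), cf = cf)
  }
  span <- diff(range(times_h))
  grid <- exp(seq(log(span / 200), log(span * 20), length.out = 60))
  rss <- vapply(grid, function(h) profile_fit(h)$rss, 0)
  i <- which.min(rss)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(lh) profile_fit(exp(lh))$rss,
                  interval = log(c(lo, hi)), tol = 1e-12)
  h <- exp(opt$minimum)
  pf <- profile_fit(h)
  flags <- character()
  amp_tol <- 1e-8 * max(max(intensities), 1)
  if (!is.finite(pf$cf[2]) || pf$cf[2] <= amp_tol) {
    flags <- "non_decaying"
    return(structure(list(halflife_h = NA_real_, baseline = mean(intensities),
                          amplitude = 0,
                          rss = sum((intensities - mean(intensities))^2),
                          flags = flags),
                     class = "decay_fit"))
  }
  structure(list(halflife_h = h, baseline = unname(pf$cf[1]),
                 amplitude = unname(pf$cf[2]), rss = pf$rss, flags = flags),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (length(x$flags) && "non_decaying" %in% x$flags)
    cat("<decay_fit> non-decaying series (half-life not applicable)\n")
  else
    cat(sprintf(
      "<decay_fit> half-life %.3f h, baseline %.3g, amplitude %.3g\n",
      x$halflife_h, x$baseline, x$amplitude))
  invisible(x)
}

#' Aggregate per-image tables into a study-level report
#'
#' Concatenates per-image cell samples, peritumoral ROI tables and
#' image-level metrics, then computes the headline correlations (vascular
#' density vs GFP-positive fraction across images; GFP vs distance across
#' cells; GFP vs SHG, alignment and relative orientation across
#' peritumoral ROIs), grouped Welch comparisons, and the bivariate
#' distance-intensity histogram.
#'
#' @param images list of per-image results; each element may hold
#'   `cells` (data.frame), `rois` (data.frame), and `metrics` (list with
#'   `gfp_positive_fraction`, `mean_gfp_intensity`, `vascular_density`).
#' @param distance_edges,intensity_edges bin edges for the bivariate
#'   histogram (defaults derived from the pooled data).
#' @param orientation_breaks grouping for fiber orientation relative to
#'   the tumor edge, default parallel (< 10 deg) / intermediate /
#'   perpendicular (> 80 deg).
#' @return list: `cells`, `rois`, `metrics` (data.frame), `correlations`
#'   (list of `correlation_result`), `group_tests` (list of Welch
#'   results), `bivariate` (probability matrix or NULL).
#' @export
aggregate_study <- function(images, distance_edges = NULL,
                            intensity_edges = NULL,
                            orientation_breaks = c(0, 10, 80, 90)) {
  if (length(images) == 0) stop("empty input set")
  pull <- function(field) {
    tabs <- Filter(Negate(is.null), lapply(images, `[[`, field))
    if (length(tabs)) do.call(rbind, tabs) else NULL
  }
  cells <- pull("cells")
  rois <- pull("rois")
  metrics <- do.call(rbind, lapply(images, function(im) {
    m <- im$metrics
    if (is.null(m)) return(NULL)
    data.frame(gfp_positive_fraction = m$gfp_positive_fraction %||% NA,
               mean_gfp_intensity = m$mean_gfp_intensity %||% NA,
               vascular_density = m$vascular_density %||% NA)
  }))
  correlations <- list()
  group_tests <- list()
  safe_cor <- function(x, y) tryCatch(pearson_cor(x, y),
                                      error = function(e) NULL)
  if (!is.null(metrics) && nrow(metrics) >= 3)
    correlations$density_vs_gfp_fraction <-
      safe_cor(metrics$vascular_density, metrics$gfp_positive_fraction)
  bivar <- NULL
  if (!is.null(cells) && nrow(cells) >= 3) {
    fin <- is.finite(cells$distance_um)
    correlations$gfp_vs_distance <-
      safe_cor(cells$gfp_intensity[fin], cells$distance_um[fin])
    if (is.null(distance_edges))
      distance_edges <- pretty(cells$distance_um[fin], 20)
    if (is.null(intensity_edges))
      intensity_edges <- pretty(cells$gfp_intensity, 20)
    bivar <- tryCatch(
      bivariate_histogram(cells[fin, ], distance_edges, intensity_edges),
      error = function(e) NULL)
  }
  if (!is.null(rois) && nrow(rois) >= 3) {
    ok <- !is.na(rois$mean_gfp)
    correlations$gfp_vs_shg <- safe_cor(rois$mean_gfp[ok],
                                        rois$mean_shg[ok])
    correlations$gfp_vs_alignment <-
      safe_cor(rois$mean_gfp[ok], rois$alignment_score[ok])
    ori_ok <- ok & !is.na(rois$relative_orientation_deg)
    correlations$gfp_vs_relative_orientation <-
      safe_cor(rois$mean_gfp[ori_ok],
               rois$relative_orientation_deg[ori_ok])
    med_shg <- stats::median(rois$mean_shg[ok])
    hi <- rois$mean_gfp[ok & rois$mean_shg > med_shg]
    lo <- rois$mean_gfp[ok & rois$mean_shg <= med_shg]
    if (length(hi) >= 2 && length(lo) >= 2)
      group_tests$gfp_by_shg <- tryCatch(welch_t(hi, lo),
                                         error = function(e) NULL)
    if (any(ori_ok)) {
      grp <- cut(rois$relative_orientation_deg[ori_ok],
                 orientation_breaks, include.lowest = TRUE,
                 labels = c("parallel", "intermediate", "perpendicular"))
      par_g <- rois$mean_gfp[ori_ok][grp == "parallel"]
      per_g <- rois$mean_gfp[ori_ok][grp == "perpendicular"]
      if (length(par_g) >= 2 && length(per_g) >= 2)
        group_tests$gfp_parallel_vs_perpendicular <-
          tryCatch(welch_t(par_g, per_g), error = function(e) NULL)
    }
  }
  list(cells = cells, rois = rois, metrics = metrics,
       correlations = correlations, group_tests = group_tests,
       bivariate = bivar)
}
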