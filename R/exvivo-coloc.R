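#' Coarse bicubic downsampling of a stain image
#'
#' Shrinks each axis by an integer factor with bicubic interpolation
#' (Keys kernel, stretched by the shrink factor for antialiasing, as image
#' resize routines conventionally do). Coarse downsampling absorbs small
#' serial-section registration errors before pixel-intensity
#' colocalization. Interpolation undershoot is clipped at 0.
#'
#' @param image numeric matrix.
#' @param factor integer linear shrink factor per axis (>= 1).
#' @return numeric matrix of dimensions `ceiling(dim(image) / factor)`.
#' @export
coarse_downsample <- function(image, factor = 100L) {
  stopifnot(is.matrix(image))
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(image)
  out_r <- ceiling(nrow(image) / factor)
  out_c <- ceiling(ncol(image) / factor)
  Wr <- resample_weights(nrow(image), out_r, factor)
  Wc <- resample_weights(ncol(image), out_c, factor)
  out <- Wr %*% image %*% t(Wc)
  out[out < 0] <- 0
  out
}

#' Pairwise Pearson colocalization matrix across stains
#'
#' Pixel-intensity colocalization: for each stain pair, the Pearson
#' correlation of intensities over shared tissue pixels. By default the
#' analysis is restricted to a tissue mask (union of per-stain Otsu
#' foregrounds) so empty glass does not inflate correlations.
#'
#' @param stains named list of numeric matrices, identical dimensions,
#'   registered (and typically downsampled first).
#' @param pairs optional list of 2-element character vectors; default all
#'   pairs.
#' @param tissue_mask logical matrix restricting the pixels used; `NULL`
#'   (default) builds the Otsu-union mask, `NA` uses all pixels.
#' @return list of class `coloc_result`: `r` (symmetric matrix, unit
#'   diagonal, `NA` where a stain is constant), `n_pixels_used`.
#' @export
coloc_matrix <- function(stains, pairs = NULL, tissue_mask = NULL) {
  stopifnot(is.list(stains), length(stains) >= 2,
            !is.null(names(stains)))
  dims <- vapply(stains, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("stain images must share dimensions")
  nm <- names(stains)
  if (is.null(tissue_mask)) {
    tissue_mask <- Reduce(`|`, lapply(stains, function(s)
      s > otsu_threshold(s)))
  } else if (length(tissue_mask) == 1 && is.na(tissue_mask)) {
    tissue_mask <- matrix(TRUE, dims[1, 1], dims[2, 1])
  }
  if (sum(tissue_mask) < 3) stop("tissue mask leaves fewer than 3 pixels")
  vals <- lapply(stains, function(s) s[tissue_mask])
  r <- diag(1, length(nm))
  dimnames(r) <- list(nm, nm)
  if (is.null(pairs))
    pairs <- utils::combn(nm, 2, simplify = FALSE)
  for (p in pairs) {
    x <- vals[[p[1]]]; y <- vals[[p[2]]]
    rij <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
    r[p[1], p[2]] <- r[p[2], p[1]] <- rij
  }
  structure(list(r = r, n_pixels_used = sum(tissue_mask)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d pixels\n", x$n_pixels_used))
  print(round(x$r, 3))
  invisible(x)
}

#' Positive-stain fraction within viable tumor
#'
#' Thresholds the stain at a percentile of intensities pooled across all
#' stained tissues (so one global threshold serves every tumor) and
#' reports the positive area within the viable (DsRed-positive) tumor
#' mask divided by the viable area.
#'
#' @param stain numeric matrix.
#' @param viable a [region_mask] of viable tumor (non-empty).
#' @param pooled_values intensities pooled across all tumors for this
#'   stain.
#' @param percentile pooled percentile defining positivity (default 90,
#'   i.e. the top 10th percentile is positive).
#' @return fraction in [0, 1].
#' @export
positive_stain_fraction <- function(stain, viable, pooled_values,
                                    percentile = 90) {
  stopifnot(inherits(viable, "region_mask"),
            all(dim(stain) == dim(viable$mask)))
  if (!any(viable$mask)) stop("viable mask is empty")
  thr <- quantile(pooled_values, percentile / 100, names = FALSE)
  mean(stain[viable$mask] >= thr)
}

#' Correlate in vivo reporter intensity with ex vivo stain fraction
#'
#' Per-tumor Pearson correlation between mean in vivo GFP intensity and
#' the ex vivo positive-stain fraction of a hypoxia marker. Tumors flagged
#' as having no positive staining (fraction 0) can be excluded, mirroring
#' the exclusion of non-hypoxic samples from colocalization analysis.
#'
#' @param in_vivo_mean_gfp numeric vector, one value per tumor.
#' @param ex_vivo_fraction numeric vector, same length.
#' @param exclude_zero_fraction drop tumors with fraction 0 (default
#'   FALSE).
#' @return a `correlation_result` (see [pearson_cor()]) with an
#'   `n_excluded` field.
#' @export
in_vivo_vs_ex_vivo <- function(in_vivo_mean_gfp, ex_vivo_fraction,
                               exclude_zero_fraction = FALSE) {
  stopifnot(length(in_vivo_mean_gfp) == length(ex_vivo_fraction))
  keep <- rep(TRUE, length(ex_vivo_fraction))
  if (exclude_zero_fraction) keep <- ex_vivo_fraction > 0
  if (sum(keep) < 3) stop("need at least 3 tumors")
  out <- pearson_cor(in_vivo_mean_gfp[keep], ex_vivo_fraction[keep])
  out$n_excluded <- sum(!keep)
  out
}
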