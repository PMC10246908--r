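#' Saturating-exponential hypoxia gradient
#'
#' Mean reporter intensity as a function of distance to the nearest vessel:
#' `I(d) = I_max * (1 - exp(-d / L_um))`. This emulates an oxygen diffusion
#' gradient: cells adjacent to vessels are oxygenated (reporter off) and the
#' hypoxic transcriptional response saturates at `I_max` far from any vessel.
#' `d = Inf` (vessel-free scene) maps to the plateau `I_max`.
#'
#' @param I_max plateau intensity (arbitrary units).
#' @param L_um rise length in um; distances beyond a few multiples of `L_um`
#'   are effectively at plateau.
#' @return function mapping distance (um) to mean intensity.
#' @export
gfp_gradient_satexp <- function(I_max = 100, L_um = 100) {
  stopifnot(I_max >= 0, L_um > 0)
  f <- function(d) I_max * (1 - exp(-d / L_um))
  attr(f, "kind") <- "satexp"
  f
}

#' Flat (distance-independent) reporter level
#' @param I constant intensity.
#' @return function mapping distance (um) to `I`.
#' @export
gfp_gradient_flat <- function(I = 50) {
  stopifnot(I >= 0)
  f <- function(d) rep(I, length(d))
  attr(f, "kind") <- "flat"
  f
}

#' Axial von Mises orientation sampler
#'
#' Samples fiber orientations in `[0, 180)` degrees from an axial von Mises
#' distribution: angles are doubled onto the circle, drawn from
#' `VM(2 * mean, kappa)` (Best-Fisher rejection sampler), and halved.
#' `kappa = 0` gives the uniform distribution; `kappa = Inf` the point mass
#' at `mean_deg`.
#'
#' @param n number of draws.
#' @param mean_deg mean orientation in degrees, `[0, 180)`.
#' @param kappa concentration (of the doubled-angle distribution), >= 0.
#' @return numeric vector of orientations in degrees.
#' @export
rvonmises_axial <- function(n, mean_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  mu <- 2 * mean_deg * pi / 180
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(mean_deg %% 180, n))
  if (kappa == 0) return(runif(n, 0, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      theta <- (sign(runif(1) - 0.5) * acos(f) + mu) %% (2 * pi)
      out[i] <- theta / 2 * 180 / pi
    }
  }
  out %% 180
}

#' Scene generation parameters
#'
#' Bundles every knob of the synthetic intravital scene. Defaults emulate a
#' reduced 5x field of view (512 x 512 px at 1.186 um/px, i.e. the 2429-um
#' field sampled at a quarter of its native 2048-px grid) around a single
#' tumor focus.
#'
#' @param image_size_px integer pair (rows, cols).
#' @param pixel_size_um physical pixel size, um/px.
#' @param n_vessels number of vessel random-walk tubes (>= 0).
#' @param vessel_radius_um vessel half-width in um.
#' @param tumor_radius_um mean tumor blob radius in um.
#' @param gfp_gradient function of distance-to-vessel (um), e.g.
#'   [gfp_gradient_satexp()]; must accept `Inf`.
#' @param fiber_kappa axial von Mises concentration of fiber orientations.
#' @param fiber_mean_angle_deg mean fiber orientation, `[0, 180)`.
#' @param n_fibers number of collagen fiber segments in the peritumoral
#'   band (0 disables the SHG channel content).
#' @param fiber_length_um,fiber_width_um rendered segment geometry.
#' @param fiber_band_um width of the peritumoral band holding fibers.
#' @param fiber_density_coupling `"none"` or `"hypoxia"`: with
#'   `"hypoxia"`, fiber placement probability is proportional to the local
#'   distance-to-vessel gradient, so collagen densifies next to hypoxic
#'   tumor regions.
#' @param mixing_matrix an [unmix_matrix] (square, full rank) used to mix
#'   abundances into channels; default has mild DsRed/GFP/APC crosstalk and
#'   an uncoupled SHG channel.
#' @param gaussian_sigma,poisson_gain noise model: Poisson resampling of
#'   gain-scaled signal, then additive Gaussian read noise. Both default to
#'   0 (off) so analytic identities hold exactly.
#' @param intensities named vector of peak abundances for DsRed, APC and
#'   SHG (GFP peaks at the gradient plateau).
#' @param seed integer RNG seed; equal seeds give identical scenes.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(image_size_px = c(512L, 512L),
                         pixel_size_um = 1.186,
                         n_vessels = 5L,
                         vessel_radius_um = 8,
                         tumor_radius_um = 220,
                         gfp_gradient = gfp_gradient_satexp(100, 100),
                         fiber_kappa = 4,
                         fiber_mean_angle_deg = 30,
                         n_fibers = 400L,
                         fiber_length_um = 30,
                         fiber_width_um = 2,
                         fiber_band_um = 150,
                         fiber_density_coupling = c("none", "hypoxia"),
                         mixing_matrix = default_mixing_matrix(),
                         gaussian_sigma = 0,
                         poisson_gain = 0,
                         intensities = c(DsRed = 100, APC = 100, SHG = 80),
                         seed = 1L) {
  fiber_density_coupling <- match.arg(fiber_density_coupling)
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 16),
            pixel_size_um > 0, n_vessels >= 0, vessel_radius_um > 0,
            tumor_radius_um > 0, is.function(gfp_gradient),
            fiber_kappa >= 0, fiber_mean_angle_deg >= 0,
            fiber_mean_angle_deg < 180, n_fibers >= 0,
            gaussian_sigma >= 0, poisson_gain >= 0)
  stopifnot(inherits(mixing_matrix, "unmix_matrix"))
  structure(as.list(environment()), class = "scene_params")
}

#' Default spectral crosstalk matrix for the four-channel scene
#'
#' Rows (fluorophores) DsRed, GFP, APC, SHG over channels of the same
#' names; DsRed/GFP bleed into each other, APC is nearly clean, and SHG is
#' a separate nonlinear modality with no crosstalk. Rows sum to 1.
#' @return an [unmix_matrix].
#' @export
default_mixing_matrix <- function() {
  v <- rbind(DsRed = c(0.85, 0.10, 0.05, 0),
             GFP   = c(0.12, 0.85, 0.03, 0),
             APC   = c(0.05, 0.03, 0.92, 0),
             SHG   = c(0,    0,    0,    1))
  colnames(v) <- c("DsRed", "GFP", "APC", "SHG")
  unmix_matrix(v)
}

# Evaluate with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Random-walk vessel centerlines: list of segment endpoint vectors
# (r0, c0, r1, c1), 0-based pixel coordinates.
vessel_segments <- function(n_vessels, nr, nc, step_px = 6) {
  segs <- list()
  for (v in seq_len(n_vessels)) {
    side <- sample.int(4L, 1L)
    pos <- switch(side,
                  c(0, runif(1, 0, nc - 1)),
                  c(nr - 1, runif(1, 0, nc - 1)),
                  c(runif(1, 0, nr - 1), 0),
                  c(runif(1, 0, nr - 1), nc - 1))
    ang <- switch(side, pi / 2, -pi / 2, 0, pi)  # inward: (dr,dc)=(sin,cos)
    ang <- ang + runif(1, -0.5, 0.5)
    max_steps <- ceiling(3 * sqrt(nr^2 + nc^2) / step_px)
    for (s in seq_len(max_steps)) {
      nxt <- pos + step_px * c(sin(ang), cos(ang))
      segs[[length(segs) + 1L]] <- c(pos, nxt)
      pos <- nxt
      ang <- ang + rnorm(1, 0, 0.22)
      if (pos[1] < -step_px || pos[1] > nr - 1 + step_px ||
          pos[2] < -step_px || pos[2] > nc - 1 + step_px) break
    }
  }
  segs
}

#' Render an oriented fiber field
#'
#' Superposes anti-aliased straight segments with orientations drawn from
#' an axial von Mises distribution; the elementary texture behind the SHG
#' channel of [generate_scene()] and a direct fixture for orientation and
#' alignment tests.
#'
#' @param size_px patch side (square) in pixels.
#' @param n_fibers number of segments.
#' @param mean_angle_deg,kappa orientation distribution
#'   (see [rvonmises_axial()]).
#' @param length_px,width_px segment geometry in pixels.
#' @param centers optional n x 2 matrix of 0-based (row, col) centers;
#'   random uniform if `NULL`.
#' @return numeric `size_px` x `size_px` matrix.
#' @export
render_fiber_field <- function(size_px, n_fibers, mean_angle_deg, kappa,
                               length_px = 25, width_px = 2,
                               centers = NULL) {
  if (n_fibers == 0) return(matrix(0, size_px, size_px))
  if (is.null(centers))
    centers <- cbind(runif(n_fibers, 0, size_px - 1),
                     runif(n_fibers, 0, size_px - 1))
  th <- rvonmises_axial(n_fibers, mean_angle_deg, kappa) * pi / 180
  # orientation theta measured from +x (columns), CCW in (x, y = row) frame
  dr <- sin(th) * length_px / 2
  dc <- cos(th) * length_px / 2
  draw_segments_cpp(size_px, size_px,
                    centers[, 1] - dr, centers[, 2] - dc,
                    centers[, 1] + dr, centers[, 2] + dc,
                    width_px, rep(1, n_fibers))
}

#' Generate a synthetic intravital scene with ground truth
#'
#' Builds fluorophore abundance maps — a DsRed tumor blob, an HRE/GFP
#' reporter whose intensity follows `gfp_gradient` of the distance to the
#' nearest vessel, APC-labelled vessel tubes from random walks, and an SHG
#' collagen fiber band around the tumor — then mixes them through the
#' spectral crosstalk matrix (S = A x R) and applies the noise model.
#'
#' @param params a [scene_params] object.
#' @return list with `image` (a [spectral_image], channels DsRed, GFP, APC,
#'   SHG) and `truth` (list: `tumor_mask`, `vessel_mask` ([region_mask]),
#'   `distance_map_um` (Inf where no vessel exists), `fiber_angle_deg`,
#'   `abundances`, `params`).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  R <- params$mixing_matrix
  if (nrow(R$values) != ncol(R$values))
    stop("mixing_matrix must be square")
  if (abs(det(R$values)) < 1e-12)
    stop("mixing_matrix is singular")
  with_seed(params$seed, {
    nr <- params$image_size_px[1]; nc <- params$image_size_px[2]
    px <- params$pixel_size_um
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    row <- matrix(seq_len(nr), nr, nc)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    phi <- atan2(row - cr, col - cc)
    rad_px <- sqrt((row - cr)^2 + (col - cc)^2)
    p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
    rho_px <- params$tumor_radius_um / px *
      (1 + 0.12 * sin(3 * phi + p1) + 0.08 * sin(5 * phi + p2))
    tumor <- rad_px <= rho_px

    segs <- vessel_segments(params$n_vessels, nr, nc)
    if (length(segs)) {
      m <- do.call(rbind, segs)
      cov <- draw_segments_cpp(nr, nc, m[, 1], m[, 2], m[, 3], m[, 4],
                               2 * params$vessel_radius_um / px,
                               rep(1, nrow(m)))
      vessel <- pmin(cov, 1) >= 0.5
    } else {
      vessel <- matrix(FALSE, nr, nc)
    }
    dmap <- distance_transform(vessel, px)

    A <- list(
      DsRed = params$intensities[["DsRed"]] * tumor,
      GFP = matrix(params$gfp_gradient(as.numeric(dmap)), nr, nc) * tumor,
      APC = params$intensities[["APC"]] * vessel,
      SHG = matrix(0, nr, nc))

    if (params$n_fibers > 0) {
      d_out <- distance_transform(tumor, px)
      band <- d_out > 0 & d_out <= params$fiber_band_um
      idx <- which(band)
      if (length(idx)) {
        w <- NULL
        if (params$fiber_density_coupling == "hypoxia") {
          dv <- as.numeric(dmap[idx])
          dv[!is.finite(dv)] <- max(dv[is.finite(dv)], 1)
          w <- 0.05 + dv / max(dv)
        }
        pick <- sample(idx, params$n_fibers, replace = TRUE, prob = w)
        ctr <- cbind((pick - 1) %% nr, (pick - 1) %/% nr)  # 0-based (r, c)
        th <- rvonmises_axial(params$n_fibers,
                              params$fiber_mean_angle_deg,
                              params$fiber_kappa) * pi / 180
        hl <- params$fiber_length_um / px / 2
        fib <- draw_segments_cpp(nr, nc,
                                 ctr[, 1] - sin(th) * hl,
                                 ctr[, 2] - cos(th) * hl,
                                 ctr[, 1] + sin(th) * hl,
                                 ctr[, 2] + cos(th) * hl,
                                 params$fiber_width_um / px,
                                 rep(1, params$n_fibers))
        A$SHG <- params$intensities[["SHG"]] * pmin(fib, 1)
      }
    }

    img <- mix_abundances(A, R, px)
    if (params$poisson_gain > 0)
      img$channels <- lapply(img$channels, function(m) {
        matrix(rpois(length(m), pmax(m, 0) * params$poisson_gain) /
                 params$poisson_gain, nrow(m), ncol(m))
      })
    if (params$gaussian_sigma > 0)
      img$channels <- lapply(img$channels, function(m)
        m + matrix(rnorm(length(m), 0, params$gaussian_sigma),
                   nrow(m), ncol(m)))

    list(image = img,
         truth = list(
           tumor_mask = region_mask(tumor, px, "tumor_roi"),
           vessel_mask = region_mask(vessel, px, "vessel"),
           distance_map_um = dmap,
           fiber_angle_deg = params$fiber_mean_angle_deg,
           abundances = A,
           params = params))
  })
}

#' Generate registered serial-section stain images from a shared latent field
#'
#' Emulates serial 5-um sections of one tumor stained separately for GFP,
#' PIMO, CA9, CD31 and DsRed. A single smooth latent "hypoxia" field H in
#' [0, 1] drives every hypoxia stain through a logistic transform
#' `100 * plogis((H - mid) / slope)`; PIMO's default midpoint is higher
#' than GFP/CA9's, mirroring its stricter oxygen threshold (adducts form
#' below ~10 mmHg versus CA9 expression below ~20 mmHg), so GFP and CA9
#' track each other more closely than either tracks PIMO. Each stain is
#' rigidly shifted by at most `misregistration_um` and independently noised.
#'
#' @param seed integer RNG seed.
#' @param misregistration_um maximum rigid shift per stain (um).
#' @param size_px section side length in pixels.
#' @param pixel_size_um pixel size of the section scans.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param smooth_sigma_px correlation length of the latent field.
#' @param stain_params named list of `c(mid, slope)` logistic parameters
#'   per stain; `slope = Inf` makes a stain flat (latent-independent).
#' @return list: `stains` (named list of matrices), `latent` (H),
#'   `viable` ([region_mask]), `pixel_size_um`.
#' @export
generate_serial_sections <- function(seed, misregistration_um = 0,
                                     size_px = 256L, pixel_size_um = 3.25,
                                     noise_sd = 0,
                                     smooth_sigma_px = size_px / 10,
                                     stain_params = list(
                                       GFP  = c(mid = 0.50, slope = 0.08),
                                       CA9  = c(mid = 0.50, slope = 0.10),
                                       PIMO = c(mid = 0.65, slope = 0.08),
                                       CD31 = c(mid = 0.50, slope = -0.10),
                                       DsRed = c(mid = 0.05, slope = 0.30))) {
  stopifnot(misregistration_um >= 0, noise_sd >= 0)
  with_seed(seed, {
    n <- size_px
    H <- gaussian_blur_fft(matrix(rnorm(n * n), n, n), smooth_sigma_px)
    H <- (H - min(H)) / (max(H) - min(H))
    ctr <- (n + 1) / 2
    row <- matrix(seq_len(n), n, n)
    col <- matrix(seq_len(n), n, n, byrow = TRUE)
    viable <- sqrt((row - ctr)^2 + (col - ctr)^2) <= 0.42 * n
    max_shift <- floor(misregistration_um / pixel_size_um)
    stains <- lapply(stain_params, function(p) {
      slope <- p[["slope"]]
      val <- if (is.finite(slope))
        100 * stats::plogis((H - p[["mid"]]) / slope) else
        matrix(50, n, n)
      val <- val * viable
      if (max_shift > 0) {
        sh <- sample(seq(-max_shift, max_shift), 2, replace = TRUE)
        val <- shift_matrix(val, sh[1], sh[2])
      }
      if (noise_sd > 0)
        val <- val + matrix(rnorm(n * n, 0, noise_sd), n, n)
      val
    })
    list(stains = stains, latent = H,
         viable = region_mask(viable, pixel_size_um, "viable_tumor"),
         pixel_size_um = pixel_size_um)
  })
}

# Rigid integer shift, zero-padded.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

#' Generate an in vitro reporter decay time course
#'
#' Intensity follows `baseline + amplitude * 2^(-t / halflife_h)`, the
#' single-exponential decay used to model reporter fluorescence after
#' reoxygenation.
#'
#' @param halflife_h half-life in hours (> 0).
#' @param baseline,amplitude decay parameters (intensity units).
#' @param times_h sampling times in hours.
#' @param noise_sd additive Gaussian noise SD (0 = noiseless).
#' @param seed optional seed used when `noise_sd > 0`.
#' @return data.frame with columns `time_h`, `intensity`.
#' @export
generate_timecourse <- function(halflife_h, baseline = 0, amplitude = 10,
                                times_h = 0:12, noise_sd = 0, seed = NULL) {
  if (halflife_h <= 0) stop("halflife_h must be positive")
  mu <- baseline + amplitude * 2^(-times_h / halflife_h)
  if (noise_sd > 0) {
    mu <- if (!is.null(seed))
      with_seed(seed, mu + rnorm(length(mu), 0, noise_sd)) else
      mu + rnorm(length(mu), 0, noise_sd)
  }
  data.frame(time_h = times_h, intensity = mu)
}
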