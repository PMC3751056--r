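#' Parameters of a synthetic IVOCT phantom frame
#'
#' Describes one synthetic Cartesian frame emulating the features of
#' display-format TD-OCT coronary cross-sections: a dark lumen bounded by
#' a bright tissue ring with exponential depth attenuation and
#' multiplicative speckle, angular gain variation (the contrast loss of an
#' off-center catheter), a catheter-ring annulus of known radius, a thin
#' alignment-mark line crossing the frame, intraluminal noise blobs
#' (blood/thrombus), and angular branch-shadow sectors in which the tissue
#' return is suppressed.
#'
#' The lumen boundary radius is
#' `rho(theta) = R0 * (1 + ecc cos(theta - ecc_angle) +
#'   perturb_amp sin(perturb_freq theta + perturb_phase))`
#' and must stay positive and leave the tissue ring inside the field of
#' view.
#'
#' @param side_px Image side in pixels (default 400).
#' @param fov_mm Field-of-view side in mm (default 6).
#' @param lumen_radius_mm Mean lumen radius `R0` in mm.
#' @param eccentricity Relative amplitude of the `cos` boundary term.
#' @param ecc_angle_rad Orientation of the eccentricity.
#' @param perturb_amp,perturb_freq,perturb_phase Relative amplitude,
#'   integer lobe count and phase of the boundary perturbation.
#' @param wall_thickness_mm Visible tissue ring thickness in mm.
#' @param tissue_intensity Peak tissue reflectivity in `[0, 1]`.
#' @param gain_min Angular gain at the far side (1 = uniform contrast;
#'   0.2 = strong loss).
#' @param gain_angle_rad Angle of maximum gain.
#' @param speckle_contrast Standard deviation of the unit-mean
#'   multiplicative gamma speckle (0 = noise-free).
#' @param attenuation_per_mm Exponential depth attenuation rate.
#' @param catheter_ring_radius_px,catheter_intensity Radius and intensity
#'   of the catheter-ring annulus.
#' @param alignment_mark,alignment_angle_rad,alignment_intensity Thin
#'   full-width alignment line toggle, orientation and intensity.
#' @param branch_sectors List of `c(theta_start_deg, theta_width_deg)`
#'   shadow sectors (widths < 180).
#' @param blob_count,blob_size_px,blob_intensity Number, Gaussian sigma
#'   and peak intensity of intraluminal noise blobs.
#' @param seed RNG seed; fixes the frame exactly.
#' @return A list of class `"phantom_params"`.
#' @export
phantom_params <- function(side_px = 400L, fov_mm = 6,
                           lumen_radius_mm = 1.2,
                           eccentricity = 0, ecc_angle_rad = 0,
                           perturb_amp = 0, perturb_freq = 3L,
                           perturb_phase = 0,
                           wall_thickness_mm = 0.8,
                           tissue_intensity = 0.8,
                           gain_min = 1, gain_angle_rad = 0,
                           speckle_contrast = 0,
                           attenuation_per_mm = 2.5,
                           catheter_ring_radius_px = 16,
                           catheter_intensity = 0.95,
                           alignment_mark = TRUE,
                           alignment_angle_rad = pi / 3,
                           alignment_intensity = 0.6,
                           branch_sectors = list(),
                           blob_count = 0L, blob_size_px = 4,
                           blob_intensity = 0.5,
                           seed = 1L) {
  p <- as.list(environment())
  max_rho <- lumen_radius_mm * (1 + abs(eccentricity) + abs(perturb_amp))
  min_rho <- lumen_radius_mm * (1 - abs(eccentricity) - abs(perturb_amp))
  if (min_rho <= 0) stop("boundary modulation collapses the lumen")
  if (max_rho + wall_thickness_mm > fov_mm / 2)
    stop("lumen plus tissue ring does not fit inside the field of view")
  for (bs in branch_sectors)
    if (length(bs) != 2 || bs[2] <= 0 || bs[2] >= 180)
      stop("branch sectors must be c(start_deg, width_deg) with width in (0, 180)")
  if (speckle_contrast < 0) stop("'speckle_contrast' must be >= 0")
  class(p) <- "phantom_params"
  p
}

#' Generate one synthetic IVOCT frame with its gold-standard mask
#'
#' Deterministic given `params$seed` (the caller's RNG state is left
#' untouched). The gold mask is the exact rasterization of the analytic
#' lumen region; the image composes background, attenuated and speckled
#' tissue ring with angular gain, branch-shadow suppression, catheter
#' ring, alignment mark and intraluminal blobs. Metadata records, for each
#' branch sector, the affected column range of the standard 630-column
#' polar grid.
#'
#' @param params A [phantom_params()].
#' @param n_theta Polar grid width used for the branch-column metadata.
#' @return A list with `image` (numeric matrix in `[0, 1]`), `gold`
#'   (logical matrix), `meta` (list: `branch_cols`, `px_mm`, `center`),
#'   and `params`.
#' @export
generate_phantom <- function(params = phantom_params(), n_theta = 630L) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  side <- p$side_px
  px_mm <- p$fov_mm / side
  cc <- (side + 1) / 2
  xs <- seq_len(side) - cc
  x <- outer(rep(1, side), xs)        # column offset
  y <- outer(xs, rep(1, side))        # row offset
  r_mm <- sqrt(x^2 + y^2) * px_mm
  th <- atan2(-y, x) %% (2 * pi)      # same convention as cartesian_to_polar
  rho <- p$lumen_radius_mm *
    (1 + p$eccentricity * cos(th - p$ecc_angle_rad) +
       p$perturb_amp * sin(p$perturb_freq * th + p$perturb_phase))
  gold <- r_mm <= rho
  img <- .with_seed(p$seed, {
    depth <- r_mm - rho
    tissue <- depth > 0 & depth <= p$wall_thickness_mm
    gain <- p$gain_min + (1 - p$gain_min) * (1 + cos(th - p$gain_angle_rad)) / 2
    im <- matrix(0, side, side)
    im[tissue] <- p$tissue_intensity * gain[tissue] *
      exp(-p$attenuation_per_mm * depth[tissue])
    if (p$speckle_contrast > 0) {
      k <- 1 / p$speckle_contrast^2
      im[tissue] <- im[tissue] * rgamma(sum(tissue), shape = k, rate = k)
    }
    # branch-shadow sectors: no tissue return beyond the lumen border
    for (bs in p$branch_sectors) {
      a0 <- (bs[1] %% 360) * pi / 180
      wdt <- bs[2] * pi / 180
      insec <- ((th - a0) %% (2 * pi)) <= wdt
      im[insec & r_mm > rho] <- 0
    }
    # intraluminal blobs (blood / thrombus)
    if (p$blob_count > 0) {
      # blobs sit in the mid-to-outer lumen (thrombus is wall-adherent,
      # blood clumps drift with flow) and clear of the catheter body
      rb_lo_mm <- (p$catheter_ring_radius_px + 3 * p$blob_size_px) * px_mm
      for (b in seq_len(p$blob_count)) {
        tb <- runif(1, 0, 2 * pi)
        rho_b <- p$lumen_radius_mm *
          (1 + p$eccentricity * cos(tb - p$ecc_angle_rad) +
             p$perturb_amp * sin(p$perturb_freq * tb + p$perturb_phase))
        rb_mm <- max(rb_lo_mm, runif(1, 0.45, 0.8) * rho_b)
        bx <- rb_mm / px_mm * cos(tb)
        by <- -rb_mm / px_mm * sin(tb)
        d2 <- (x - bx)^2 + (y - by)^2
        bump <- p$blob_intensity * exp(-d2 / (2 * p$blob_size_px^2))
        im <- pmax(im, bump * (r_mm < rho))   # blobs live inside the lumen
      }
    }
    # catheter-ring annulus (hardware artifact, drawn on top)
    r_px <- r_mm / px_mm
    ring <- abs(r_px - p$catheter_ring_radius_px) <= 1
    im[ring] <- p$catheter_intensity
    if (isTRUE(p$alignment_mark)) {
      a <- p$alignment_angle_rad
      dline <- abs(x * sin(a) - (-y) * cos(a))
      im[dline <= 0.75] <- pmax(im[dline <= 0.75], p$alignment_intensity)
    }
    pmin(pmax(im, 0), 1)
  })
  branch_cols <- lapply(p$branch_sectors, function(bs) {
    a0 <- (bs[1] %% 360) * pi / 180
    wdt <- bs[2] * pi / 180
    thj <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
    which(((thj - a0) %% (2 * pi)) <= wdt)
  })
  list(image = img, gold = gold,
       meta = list(branch_cols = branch_cols, px_mm = px_mm,
                   center = c(cc, cc)),
       params = p)
}

#' Generate a reproducible suite of phantom cases
#'
#' Draws `n` phantom parameter sets from `seed` at one of two difficulty
#' levels. `"easy"` frames have moderate speckle, a mild angular gain
#' gradient, mild eccentricity and boundary perturbation, and no branches
#' or blobs. `"hard"` frames add a strong gain gradient (down to about
#' 0.2 at the far side), one or two branch-shadow sectors, stronger
#' boundary perturbation, and intraluminal blobs.
#'
#' @param n Number of cases (>= 1).
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed Suite seed; fixes every case.
#' @return A list of `n` phantom cases as returned by [generate_phantom()].
#' @export
generate_suite <- function(n, difficulty = c("easy", "hard"), seed = 1L) {
  difficulty <- match.arg(difficulty)
  stopifnot(n >= 1)
  draws <- .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      hard <- difficulty == "hard"
      nb <- if (hard) sample(1:2, 1) else 0L
      sectors <- if (nb > 0) {
        starts <- runif(nb, 0, 360)
        if (nb == 2) starts[2] <- (starts[1] + 180 + runif(1, -60, 60)) %% 360
        lapply(seq_len(nb), function(s) c(starts[s], runif(1, 15, 40)))
      } else list()
      phantom_params(
        lumen_radius_mm = runif(1, 0.9, 1.5),
        eccentricity = if (hard) runif(1, 0.05, 0.15) else runif(1, 0, 0.10),
        ecc_angle_rad = runif(1, 0, 2 * pi),
        perturb_amp = if (hard) runif(1, 0.03, 0.08) else runif(1, 0, 0.03),
        perturb_freq = sample(2:5, 1),
        perturb_phase = runif(1, 0, 2 * pi),
        wall_thickness_mm = runif(1, 0.6, 1.0),
        tissue_intensity = runif(1, 0.6, 0.9),
        gain_min = if (hard) runif(1, 0.2, 0.3) else runif(1, 0.6, 1.0),
        gain_angle_rad = runif(1, 0, 2 * pi),
        speckle_contrast = if (hard) 0.5 else 0.4,
        attenuation_per_mm = runif(1, 2, 4),
        alignment_angle_rad = runif(1, 0, pi),
        branch_sectors = sectors,
        blob_count = if (hard) sample(2:5, 1) else 0L,
        blob_size_px = runif(1, 3, 6),
        blob_intensity = runif(1, 0.3, 0.6),
        seed = sample.int(.Machine$integer.max - 1L, 1)
      )
    })
  })
  lapply(draws, generate_phantom)
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
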