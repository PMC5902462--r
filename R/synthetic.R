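# Synthetic-data generators with analytic ground truth. These emulate the
# inputs of the tension-culture experiments: silhouettes of dissected midguts
# (curved tubes with hemispherical tips), before/after growth cohorts
# following a stress-dependent response law, peristalsis movies with
# propagating constrictions, and linear cantilever calibration tables.

#' Specification of a synthetic tube phantom
#'
#' Describes an axisymmetric curved tube: a disk of locally varying radius
#' swept along a planar midline of arclength `length_mm`. The swept disk
#' produces hemispherical end caps that protrude half a diameter beyond each
#' midline endpoint, as a rounded biological tube tip would. Ground truth
#' (length, diameter, volume) is defined on the midline span, i.e. between the
#' two cap centers.
#'
#' @param midline_kind `"straight"`, `"sinusoid"` or `"spline"` (seeded smooth
#'   random curve).
#' @param length_mm midline arclength (mm); must be >= 3 diameters.
#' @param base_diameter_mm tube diameter at the proximal end (mm).
#' @param taper fractional tip-to-tip diameter change in `[-0.5, 0.5]`;
#'   the distal diameter is `base_diameter_mm * (1 + taper)`.
#' @param bend_amplitude_mm amplitude of midline bending (mm).
#' @param bend_wavelength_mm wavelength of midline bending (mm).
#' @param scale_mm_per_px rasterization scale.
#' @param noise_sd_px boundary jitter: SD (in px) of a smooth random
#'   perturbation of the local radius.
#' @param rotation_deg rigid rotation of the phantom in the image plane.
#' @param seed integer; all randomness of the generator flows from it.
#' @return object of class `tube_phantom_spec`.
#' @export
tube_phantom_spec <- function(midline_kind = c("straight", "sinusoid", "spline"),
                              length_mm = 10, base_diameter_mm = 0.4,
                              taper = 0, bend_amplitude_mm = 0,
                              bend_wavelength_mm = 5,
                              scale_mm_per_px = 0.02, noise_sd_px = 0,
                              rotation_deg = 0, seed = 1L) {
  midline_kind <- match.arg(midline_kind)
  stopifnot(length_mm > 0, base_diameter_mm > 0,
            taper >= -0.5, taper <= 0.5,
            bend_amplitude_mm >= 0, bend_wavelength_mm > 0,
            scale_mm_per_px > 0, noise_sd_px >= 0)
  if (length_mm / base_diameter_mm < 3) {
    stop("not tubular: length_mm / base_diameter_mm must be >= 3")
  }
  structure(list(midline_kind = midline_kind, length_mm = length_mm,
                 base_diameter_mm = base_diameter_mm, taper = taper,
                 bend_amplitude_mm = bend_amplitude_mm,
                 bend_wavelength_mm = bend_wavelength_mm,
                 scale_mm_per_px = scale_mm_per_px, noise_sd_px = noise_sd_px,
                 rotation_deg = rotation_deg, seed = as.integer(seed)),
            class = "tube_phantom_spec")
}

# Continuous midline of a phantom, sampled at fine uniform arclength steps.
# Returns data.frame(s, x, y) with s in [0, length_mm].
.phantom_midline_fine <- function(spec, step) {
  L <- spec$length_mm
  A <- spec$bend_amplitude_mm
  lam <- spec$bend_wavelength_mm
  shape <- switch(spec$midline_kind,
    straight = function(u) cbind(u, 0 * u),
    sinusoid = function(u) cbind(u, A * sin(2 * pi * u / lam)),
    spline = {
      coefs <- with_seed(spec$seed + 1L, stats::runif(3, -1, 1))
      function(u) {
        cbind(u, A * (coefs[1] * sin(2 * pi * u / lam) +
                      coefs[2] * 0.6 * sin(4 * pi * u / lam + coefs[3] * pi)))
      }
    })
  # arclength-reparameterize: march in u until cumulative arclength reaches L
  du <- step / 4
  u <- seq(0, 2 * L + 4 * A + du, by = du)
  xy <- shape(u)
  s <- gm_arclength(xy)
  if (max(s) < L) stop("internal: midline parameter range too short")
  si <- seq(0, L, by = step)
  if (si[length(si)] < L) si <- c(si, L)
  out <- cbind(stats::approx(s, xy[, 1], xout = si)$y,
               stats::approx(s, xy[, 2], xout = si)$y)
  if (spec$rotation_deg != 0) {
    a <- spec$rotation_deg * pi / 180
    out <- out %*% t(matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2))
  }
  data.frame(s = si, x = out[, 1], y = out[, 2])
}

# Local radius profile r(s), including smooth boundary jitter when requested.
.phantom_radius <- function(spec, s) {
  L <- spec$length_mm
  r <- (spec$base_diameter_mm / 2) * (1 + spec$taper * s / L)
  if (spec$noise_sd_px > 0) {
    sd_mm <- spec$noise_sd_px * spec$scale_mm_per_px
    corr_len <- spec$base_diameter_mm / 2
    ds <- s[2] - s[1]
    half <- max(1L, ceiling(3 * corr_len / ds))
    kern <- stats::dnorm(seq(-half, half) * ds, sd = corr_len)
    kern <- kern / sum(kern)
    white <- with_seed(spec$seed + 2L, stats::rnorm(length(s) + 2L * half))
    sm <- stats::filter(white, kern, sides = 2)
    sm <- sm[(half + 1L):(half + length(s))]
    sm <- sm / stats::sd(sm)
    r <- pmax(r + sd_mm * sm, 0.25 * spec$base_diameter_mm / 2)
  }
  r
}

#' Generate a rasterized tube phantom with analytic ground truth
#'
#' Sweeps a disk of radius `r(s)` along the phantom midline and rasterizes the
#' union on a pixel grid (pixel centers at integer coordinates, 0-based;
#' `x = col * scale`, `y = row * scale`). The returned truth holds the midline
#' length, arclength-weighted mean diameter and the solid-of-revolution volume
#' `V = integral pi r(s)^2 ds`, all computed by quadrature of the generator's
#' own continuous profile at a step 10x finer than a pixel.
#'
#' @param spec a [tube_phantom_spec()].
#' @return list with `image` (grayscale matrix, 0 background / 255 foreground),
#'   `mask` (logical matrix), `truth` (a [tube_morphometry()]), `midline` (the
#'   ground-truth [midline()] in image mm coordinates) and `spec`.
#' @export
generate_tube_image <- function(spec) {
  stopifnot(inherits(spec, "tube_phantom_spec"))
  sc <- spec$scale_mm_per_px
  fine <- .phantom_midline_fine(spec, step = sc / 10)
  r <- .phantom_radius(spec, fine$s)

  # self-overlap guard: radius of curvature must exceed the tube diameter
  dxds <- c(NA, diff(fine$x)) / c(NA, diff(fine$s))
  dyds <- c(NA, diff(fine$y)) / c(NA, diff(fine$s))
  ds <- fine$s[2] - fine$s[1]
  ddx <- c(NA, diff(dxds)) / ds
  ddy <- c(NA, diff(dyds)) / ds
  kappa <- abs(dxds * ddy - dyds * ddx) / (dxds^2 + dyds^2)^1.5
  kmax <- max(kappa, na.rm = TRUE)
  if (kmax > 0 && 1 / kmax <= spec$base_diameter_mm) {
    stop(sprintf(paste0("phantom self-overlaps: minimum bend radius of curvature ",
                        "%.3f mm does not exceed the tube diameter %.3f mm"),
                 1 / kmax, spec$base_diameter_mm))
  }

  truth_len <- spec$length_mm
  truth_vol <- trapz(fine$s, pi * r^2)
  truth_d <- trapz(fine$s, 2 * r) / truth_len

  # sub-pixel dither of the origin: avoids the degenerate case where the
  # midline and radius are exact multiples of the pixel size (a real
  # photograph never aligns the organ to the pixel grid), which would place
  # contour pixel centers exactly on the tube surface and bias the raster.
  margin <- max(r) + max(4 * spec$noise_sd_px, 3) * sc
  x0 <- min(fine$x) - margin - 0.3819660 * sc
  y0 <- min(fine$y) - margin - 0.2360680 * sc
  xs <- fine$x - x0
  ys <- fine$y - y0
  nc <- ceiling((max(xs) + margin) / sc) + 1L
  nr <- ceiling((max(ys) + margin) / sc) + 1L
  mask <- matrix(FALSE, nr, nc)

  # stamp disks along the midline at half-pixel steps
  idx <- seq(1L, nrow(fine), by = 5L)  # fine step sc/10 -> stamping step sc/2
  colx <- (seq_len(nc) - 1L) * sc
  rowy <- (seq_len(nr) - 1L) * sc
  for (i in idx) {
    ri <- r[i]
    c0 <- max(1L, floor((xs[i] - ri) / sc) + 1L)
    c1 <- min(nc, ceiling((xs[i] + ri) / sc) + 1L)
    r0 <- max(1L, floor((ys[i] - ri) / sc) + 1L)
    r1 <- min(nr, ceiling((ys[i] + ri) / sc) + 1L)
    dx2 <- (colx[c0:c1] - xs[i])^2
    dy2 <- (rowy[r0:r1] - ys[i])^2
    hit <- outer(dy2, dx2, "+") <= ri^2
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | hit
  }

  coarse <- seq(1L, nrow(fine), by = 10L)
  truth_profile <- data.frame(s_mm = fine$s[coarse], diameter_mm = 2 * r[coarse])
  truth <- tube_morphometry(truth_len, truth_d, truth_vol,
                            diameter_profile = truth_profile)
  ml <- midline(fine$s[coarse], xs[coarse], ys[coarse], r[coarse])
  list(image = 255 * mask, mask = mask, truth = truth, midline = ml, spec = spec)
}

#' Specification of a synthetic growth cohort
#'
#' The stress-response law is piecewise linear in applied stress, in percent:
#' length and volume changes follow configurable lines, and the diameter change
#' is derived from the axisymmetric identity
#' `(1 + dV/V) = (1 + dl/l) * (1 + dd/d)^2` before per-channel Gaussian noise
#' is added independently. Defaults anchor the printed control behaviour
#' (-18% length, +2% volume at 0 Pa) and the +200% length / +180% volume
#' response at 150 Pa.
#'
#' @param n_specimens number of guts to simulate.
#' @param mass_mg_choices hanging masses cycled over specimens (0 = control).
#' @param diameter_mm_mean,diameter_mm_sd initial-diameter distribution.
#' @param length_mm_mean,length_mm_sd initial-length distribution.
#' @param response_law list with `length` and `volume` numeric vectors
#'   `c(intercept_pct, slope_pct_per_Pa)`.
#' @param noise_sd named percent SDs for channels `length`, `volume`, `diameter`.
#' @param dry_density named densities (mg/mm^3): `rho_E8`, `rho_ctl`,
#'   `rho_tension`.
#' @param cell_density named densities (cells/mm^3): `n_E8`, `n_cultured`.
#' @param duration_h culture duration (h).
#' @param seed integer seed.
#' @return object of class `growth_cohort_spec`.
#' @export
growth_cohort_spec <- function(n_specimens = 30L,
                               mass_mg_choices = c(0, 1, 1.5),
                               diameter_mm_mean = 0.35, diameter_mm_sd = 0.05,
                               length_mm_mean = 11, length_mm_sd = 1.5,
                               response_law = list(length = c(-18, 218 / 150),
                                                   volume = c(2, 178 / 150)),
                               noise_sd = c(length = 6, volume = 7, diameter = 7),
                               dry_density = c(rho_E8 = 0.100, rho_ctl = 0.104,
                                               rho_tension = 0.081),
                               cell_density = c(n_E8 = 4.15e5, n_cultured = 6.60e5),
                               duration_h = 48, seed = 1L) {
  stopifnot(n_specimens >= 1, all(mass_mg_choices >= 0),
            diameter_mm_mean > 0, diameter_mm_sd >= 0,
            all(noise_sd >= 0), all(dry_density > 0), all(cell_density > 0),
            duration_h > 0)
  structure(list(n_specimens = as.integer(n_specimens),
                 mass_mg_choices = mass_mg_choices,
                 diameter_mm_mean = diameter_mm_mean,
                 diameter_mm_sd = diameter_mm_sd,
                 length_mm_mean = length_mm_mean, length_mm_sd = length_mm_sd,
                 response_law = response_law, noise_sd = noise_sd,
                 dry_density = dry_density, cell_density = cell_density,
                 duration_h = duration_h, seed = as.integer(seed)),
            class = "growth_cohort_spec")
}

#' Generate a before/after growth cohort with known response law
#'
#' Each specimen draws an initial diameter and length, computes its applied
#' stress from the hanging mass via [buoyant_force()] and [applied_stress()],
#' draws percent changes from the response law plus Gaussian noise, and emits
#' before/after morphometry together with a final dry mass
#' (`m_f = rho_group * V_f`) and final cell count (`N_f = n_cultured * V_f`).
#'
#' @param spec a [growth_cohort_spec()].
#' @return data.frame with columns `specimen_id`, `group`, `mass_mg`,
#'   `stress_Pa`, `d0_mm`, `L0_mm`, `V0_mm3`, `L1_mm`, `V1_mm3`, `d1_mm`,
#'   `m_f_mg`, `N_f`, `duration_h`; the generating spec is attached as
#'   attribute `"spec"`.
#' @export
generate_growth_cohort <- function(spec) {
  stopifnot(inherits(spec, "growth_cohort_spec"))
  n <- spec$n_specimens
  masses <- spec$mass_mg_choices[((seq_len(n) - 1L) %% length(spec$mass_mg_choices)) + 1L]
  law <- spec$response_law
  with_seed(spec$seed, {
    d0 <- numeric(n); L0 <- numeric(n)
    dl <- numeric(n); dv <- numeric(n); dd <- numeric(n); sig <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:25) {
        d0i <- stats::rnorm(1, spec$diameter_mm_mean, spec$diameter_mm_sd)
        L0i <- stats::rnorm(1, spec$length_mm_mean, spec$length_mm_sd)
        if (d0i < 0.05 || L0i < 3 * d0i) next
        s <- applied_stress(buoyant_force(masses[i]), d0i)
        el <- law$length[1] + law$length[2] * s
        ev <- law$volume[1] + law$volume[2] * s
        ed <- (sqrt((1 + ev / 100) / (1 + el / 100)) - 1) * 100
        dli <- el + stats::rnorm(1, 0, spec$noise_sd["length"])
        dvi <- ev + stats::rnorm(1, 0, spec$noise_sd["volume"])
        ddi <- ed + stats::rnorm(1, 0, spec$noise_sd["diameter"])
        if (dli <= -95 || dvi <= -95 || ddi <= -95) next
        d0[i] <- d0i; L0[i] <- L0i; sig[i] <- s
        dl[i] <- dli; dv[i] <- dvi; dd[i] <- ddi
        ok <- TRUE
        break
      }
      if (!ok) stop("could not draw a physical specimen after bounded retries")
    }
    V0 <- pi * d0^2 / 4 * L0
    V1 <- V0 * (1 + dv / 100)
    grp <- ifelse(masses == 0, "control", "tension")
    rho <- ifelse(grp == "control", spec$dry_density["rho_ctl"],
                  spec$dry_density["rho_tension"])
    out <- data.frame(
      specimen_id = sprintf("S%03d", seq_len(n)),
      group = grp, mass_mg = masses, stress_Pa = sig,
      d0_mm = d0, L0_mm = L0, V0_mm3 = V0,
      L1_mm = L0 * (1 + dl / 100), V1_mm3 = V1, d1_mm = d0 * (1 + dd / 100),
      m_f_mg = as.numeric(rho) * V1,
      N_f = as.numeric(spec$cell_density["n_cultured"]) * V1,
      duration_h = spec$duration_h)
    attr(out, "spec") <- spec
    out
  })
}

#' Specification of a synthetic peristalsis movie
#'
#' A straight tube imaged over time, with Gaussian-profile constrictions
#' nucleating at the left end at the stated frequency and translating
#' rightward at the stated speed.
#'
#' @param frames number of frames.
#' @param frame_interval_s time between frames (s). The paper's recordings ran
#'   at 0.5 Hz, i.e. 2 s.
#' @param tube_length_mm,tube_diameter_mm,scale_mm_per_px tube geometry.
#' @param wave_frequency_mHz nucleation frequency (mHz); 0 for a static movie.
#' @param wave_speed_mm_s propagation speed (mm/s).
#' @param constriction_depth fractional diameter reduction at wave center,
#'   in (0, 1).
#' @param constriction_width_mm Gaussian sigma of the constriction (mm).
#' @param intensity_noise_sd grey-level SD of additive frame noise.
#' @param seed integer seed.
#' @return object of class `peristalsis_movie_spec`.
#' @export
peristalsis_movie_spec <- function(frames = 600L, frame_interval_s = 2,
                                   tube_length_mm = 6, tube_diameter_mm = 0.4,
                                   scale_mm_per_px = 0.02,
                                   wave_frequency_mHz = 15,
                                   wave_speed_mm_s = 0.1,
                                   constriction_depth = 0.5,
                                   constriction_width_mm = 0.5,
                                   intensity_noise_sd = 0, seed = 1L) {
  stopifnot(frames >= 2, frame_interval_s > 0, tube_length_mm > 0,
            tube_diameter_mm > 0, scale_mm_per_px > 0,
            wave_frequency_mHz >= 0, wave_speed_mm_s > 0,
            constriction_depth > 0, constriction_depth < 1,
            constriction_width_mm > 0, intensity_noise_sd >= 0)
  if (wave_frequency_mHz >= 500 / frame_interval_s) {
    stop(sprintf(paste0("Nyquist violation: wave frequency %.1f mHz is not below ",
                        "the sampling limit 500/frame_interval = %.1f mHz"),
                 wave_frequency_mHz, 500 / frame_interval_s))
  }
  if (wave_frequency_mHz > 0 &&
      frames * frame_interval_s < 2 * 1000 / wave_frequency_mHz) {
    stop("movie too short: duration must cover at least two wave periods")
  }
  structure(list(frames = as.integer(frames), frame_interval_s = frame_interval_s,
                 tube_length_mm = tube_length_mm,
                 tube_diameter_mm = tube_diameter_mm,
                 scale_mm_per_px = scale_mm_per_px,
                 wave_frequency_mHz = wave_frequency_mHz,
                 wave_speed_mm_s = wave_speed_mm_s,
                 constriction_depth = constriction_depth,
                 constriction_width_mm = constriction_width_mm,
                 intensity_noise_sd = intensity_noise_sd,
                 seed = as.integer(seed)),
            class = "peristalsis_movie_spec")
}

#' Generate a peristalsis movie with known wave statistics
#'
#' @param spec a [peristalsis_movie_spec()].
#' @return list with `stack` (numeric array rows x cols x frames), `truth`
#'   (a [wave_stats_record()]), `scale_mm_per_px`, `dt_s` and `spec`.
#' @export
generate_peristalsis_movie <- function(spec) {
  stopifnot(inherits(spec, "peristalsis_movie_spec"))
  sc <- spec$scale_mm_per_px
  r0 <- spec$tube_diameter_mm / 2
  L <- spec$tube_length_mm
  nx <- as.integer(ceiling(L / sc)) + 1L
  ny <- as.integer(2 * ceiling((r0 + 4 * sc) / sc)) + 1L
  yc <- (ny - 1) / 2 * sc
  xv <- (seq_len(nx) - 1L) * sc
  yv <- (seq_len(ny) - 1L) * sc
  f_Hz <- spec$wave_frequency_mHz / 1000
  v <- spec$wave_speed_mm_s
  w <- spec$constriction_width_mm
  duration <- (spec$frames - 1L) * spec$frame_interval_s
  stack <- array(0, dim = c(ny, nx, spec$frames))
  noise <- spec$intensity_noise_sd
  with_seed(spec$seed, {
    for (j in seq_len(spec$frames)) {
      t <- (j - 1L) * spec$frame_interval_s
      depth_prof <- rep(0, nx)
      if (f_Hz > 0) {
        # waves k = 0, 1, ... nucleate at x = 0 at times k / f
        kmax <- floor(t * f_Hz)
        for (k in 0:kmax) {
          cen <- v * (t - k / f_Hz)
          if (cen > L + 3 * w) next
          depth_prof <- depth_prof +
            spec$constriction_depth * exp(-(xv - cen)^2 / (2 * w^2))
        }
      }
      rprof <- r0 * pmax(1 - depth_prof, 0.05)
      # anti-aliased edge (1 px linear ramp): hard binary edges quantize the
      # apparent tube width to whole pixels, which imprints spurious
      # subharmonics of the nucleation frequency onto the kymograph
      signed <- outer(rep(1, ny), rprof) - abs(outer(yv - yc, rep(1, nx)))
      frame <- 255 * pmin(pmax(signed / sc + 0.5, 0), 1)
      if (noise > 0) frame <- frame + matrix(stats::rnorm(ny * nx, 0, noise), ny, nx)
      stack[, , j] <- frame
    }
  })
  nw <- if (f_Hz > 0) as.integer(floor(f_Hz * duration)) else 0L
  truth <- wave_stats_record(spec$wave_frequency_mHz,
                             if (f_Hz > 0) v else 0, nw,
                             direction = if (f_Hz > 0) "forward" else "mixed",
                             detection_floor_mHz = 2000 / duration)
  list(stack = stack, truth = truth, scale_mm_per_px = sc,
       dt_s = spec$frame_interval_s, spec = spec)
}

#' Generate cantilever calibration data (mass vs deflection)
#'
#' Emulates the fiber-sensitivity protocol: weights of increasing known mass
#' are hung from the fiber and the angular deflection recorded; the
#' deflection-force characteristic is linear with slope equal to the fiber
#' sensitivity in degrees per Newton.
#'
#' @param sensitivity_deg_per_N true fiber sensitivity.
#' @param masses_mg nondecreasing nonnegative masses (mg); the protocol used 4.
#' @param noise_sd_deg Gaussian SD of the deflection reading (degrees).
#' @param seed integer seed.
#' @param g gravitational acceleration (m/s^2).
#' @return data.frame with columns `mass_mg`, `force_N`, `deflection_deg`.
#' @export
generate_calibration_data <- function(sensitivity_deg_per_N, masses_mg,
                                      noise_sd_deg = 0, seed = 1L, g = 9.81) {
  stopifnot(sensitivity_deg_per_N > 0, all(masses_mg >= 0),
            !is.unsorted(masses_mg), noise_sd_deg >= 0)
  force_N <- masses_mg * 1e-6 * g
  defl <- sensitivity_deg_per_N * force_N
  if (noise_sd_deg > 0) {
    defl <- defl + with_seed(seed, stats::rnorm(length(masses_mg), 0, noise_sd_deg))
  }
  data.frame(mass_mg = masses_mg, force_N = force_N, deflection_deg = defl)
}
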