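# S3 containers shared across modules. All lengths are mm, volumes mm^3,
# stresses Pa, forces uN, masses mg unless a suffix says otherwise.

#' Tube morphometry of one gut at one time point
#'
#' @param length_mm midline length (cap-center to cap-center for capped tubes).
#' @param mean_diameter_mm arclength-weighted mean of the diameter profile.
#' @param volume_mm3 solid-of-revolution volume, `V = integral pi r(s)^2 ds`.
#' @param diameter_profile optional data.frame with columns `s_mm`,
#'   `diameter_mm`.
#' @param flags optional character vector of quality flags (e.g. `"high_residual"`).
#' @return object of class `tube_morphometry`.
#' @export
tube_morphometry <- function(length_mm, mean_diameter_mm, volume_mm3,
                             diameter_profile = NULL, flags = character()) {
  stopifnot(is.numeric(length_mm), length_mm > 0,
            is.numeric(mean_diameter_mm), mean_diameter_mm > 0,
            is.numeric(volume_mm3), volume_mm3 > 0)
  structure(list(length_mm = as.numeric(length_mm),
                 mean_diameter_mm = as.numeric(mean_diameter_mm),
                 volume_mm3 = as.numeric(volume_mm3),
                 diameter_profile = diameter_profile,
                 flags = flags),
            class = "tube_morphometry")
}

#' @export
print.tube_morphometry <- function(x, ...) {
  cat(sprintf("Tube morphometry: length %.3f mm, mean diameter %.3f mm, volume %.4f mm^3\n",
              x$length_mm, x$mean_diameter_mm, x$volume_mm3))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Arclength-parameterized tube midline
#'
#' Ordered samples of the medial axis with the local inscribed radius.
#'
#' @param s arclength (mm), strictly increasing from 0.
#' @param x,y coordinates (mm).
#' @param r local radius (mm); must be > 0 at interior samples.
#' @return a `midline` object (data.frame with columns `s`, `x`, `y`, `r`).
#' @export
midline <- function(s, x, y, r) {
  stopifnot(length(s) >= 2, all(diff(s) > 0), abs(s[1]) < 1e-9)
  n <- length(s)
  if (n > 2 && any(r[2:(n - 1)] <= 0)) {
    stop("midline has non-positive radius at an interior sample")
  }
  structure(data.frame(s = s, x = x, y = y, r = r),
            class = c("midline", "data.frame"))
}

#' Contraction-wave statistics of a motility recording
#'
#' @param frequency_mHz dominant contraction frequency (mHz).
#' @param speed_mm_s propagation speed magnitude (mm/s).
#' @param n_waves integer count, `floor(frequency * duration)`.
#' @param direction `"forward"`, `"backward"`, or `"mixed"`.
#' @param detection_floor_mHz minimum detectable frequency (2 / duration).
#' @return object of class `wave_stats`.
#' @export
wave_stats_record <- function(frequency_mHz, speed_mm_s, n_waves,
                              direction = c("forward", "backward", "mixed"),
                              detection_floor_mHz = NA_real_) {
  direction <- match.arg(direction)
  stopifnot(frequency_mHz >= 0, speed_mm_s >= 0, n_waves >= 0)
  structure(list(frequency_mHz = frequency_mHz, speed_mm_s = speed_mm_s,
                 n_waves = as.integer(n_waves), direction = direction,
                 detection_floor_mHz = detection_floor_mHz),
            class = "wave_stats")
}

#' @export
print.wave_stats <- function(x, ...) {
  cat(sprintf("Wave stats: f = %.2f mHz, v = %.4f mm/s, n = %d (%s)\n",
              x$frequency_mHz, x$speed_mm_s, x$n_waves, x$direction))
  invisible(x)
}

#' Space-time kymograph (motiligram)
#'
#' @param matrix_ intensity matrix, rows = positions along the ROI line,
#'   columns = frames.
#' @param dx_mm spatial step between rows (mm).
#' @param dt_s frame interval (s).
#' @return object of class `kymograph`.
#' @export
kymograph <- function(matrix_, dx_mm, dt_s) {
  stopifnot(is.matrix(matrix_), nrow(matrix_) >= 2, ncol(matrix_) >= 2,
            dx_mm > 0, dt_s > 0)
  structure(list(matrix = matrix_, dx_mm = dx_mm, dt_s = dt_s),
            class = "kymograph")
}

#' Linear deflection-force characteristic of a glass-fiber cantilever
#'
#' @param sensitivity_deg_per_N fitted slope (degrees per Newton).
#' @param intercept_deg fitted intercept (degrees).
#' @param r_squared coefficient of determination of the fit.
#' @param points data.frame with columns `force_N`, `deflection_deg`.
#' @param slope_se standard error of the slope.
#' @return object of class `cantilever_calibration`.
#' @export
cantilever_calibration <- function(sensitivity_deg_per_N, intercept_deg,
                                   r_squared, points, slope_se = NA_real_) {
  stopifnot(sensitivity_deg_per_N > 0, nrow(points) >= 2,
            length(unique(points$force_N)) >= 2)
  structure(list(sensitivity_deg_per_N = sensitivity_deg_per_N,
                 intercept_deg = intercept_deg, r_squared = r_squared,
                 points = points, slope_se = slope_se),
            class = "cantilever_calibration")
}

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All generator randomness flows through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal integration.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
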