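# Kymograph (motiligram) construction from time-lapse movies and extraction
# of contraction-wave frequency and propagation speed. Propagating
# constrictions appear as sloped stripes: stripe count per unit time is the
# frequency, stripe slope the speed.

#' Build a kymograph from a movie along a line ROI
#'
#' For each frame, intensity is sampled by bilinear interpolation at 1-px
#' steps along the line and averaged across `width_px` perpendicular offsets.
#' Rows are positions along the line, columns are frames.
#'
#' @param stack numeric array `rows x cols x frames`.
#' @param roi_line numeric `c(x0, y0, x1, y1)` in pixel coordinates (0-based,
#'   x = column, y = row).
#' @param width_px averaging width perpendicular to the line (>= 1).
#' @param scale_mm_per_px spatial scale.
#' @param dt_s frame interval (s).
#' @return a [kymograph()].
#' @export
build_kymograph <- function(stack, roi_line, width_px = 1,
                            scale_mm_per_px, dt_s) {
  stopifnot(length(dim(stack)) == 3, length(roi_line) == 4,
            scale_mm_per_px > 0, dt_s > 0)
  if (width_px < 1) stop("width_px must be >= 1")
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nf <- dim(stack)[3]
  p0 <- roi_line[1:2]; p1 <- roi_line[3:4]
  len <- sqrt(sum((p1 - p0)^2))
  if (len < 1) stop("ROI line is degenerate")
  npos <- as.integer(floor(len)) + 1L
  tpar <- seq(0, 1, length.out = npos)
  ux <- (p1[1] - p0[1]) / len; uy <- (p1[2] - p0[2]) / len
  nx <- -uy; ny <- ux
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = max(1L, as.integer(width_px)))
  xs <- outer(p0[1] + tpar * (p1[1] - p0[1]), offs * nx, "+")
  ys <- outer(p0[2] + tpar * (p1[2] - p0[2]), offs * ny, "+")
  if (min(xs) < 0 || max(xs) > nc - 1 || min(ys) < 0 || max(ys) > nr - 1) {
    stop("ROI line (with width) exits the frame")
  }
  # bilinear interpolation weights, shared across frames
  cx <- pmin(floor(xs), nc - 2); cy <- pmin(floor(ys), nr - 2)
  fx <- xs - cx; fy <- ys - cy
  i00 <- (cy + 1) + cx * nr          # [row, col] -> linear index (1-based)
  i10 <- i00 + 1L
  i01 <- i00 + nr
  i11 <- i01 + 1L
  w00 <- (1 - fx) * (1 - fy); w10 <- (1 - fx) * fy
  w01 <- fx * (1 - fy); w11 <- fx * fy
  K <- matrix(0, npos, nf)
  for (f in seq_len(nf)) {
    fr <- stack[, , f]
    vals <- w00 * fr[i00] + w10 * fr[i10] + w01 * fr[i01] + w11 * fr[i11]
    K[, f] <- rowMeans(matrix(vals, npos))
  }
  kymograph(K, dx_mm = scale_mm_per_px, dt_s = dt_s)
}

#' Extract contraction-wave statistics from a kymograph
#'
#' Frequency comes from the dominant peak of the Hann-windowed temporal power
#' spectrum averaged over positions (after subtracting each position's
#' temporal mean); the peak location is refined by parabolic interpolation of
#' log-power. Speed comes from a shear search: the kymograph rows are shifted
#' in time by `x / v` for candidate speeds `v` and the variance of the
#' row-averaged profile is maximized (stripes align at the true speed), with
#' a coarse log-spaced grid followed by a fine local grid. Negative candidate
#' speeds capture backward propagation.
#'
#' Result flags: direction is `"mixed"` when a secondary spectral peak reaches
#' at least `mixed_ratio` of the primary peak's power; a constant kymograph
#' returns frequency 0 and is not an error. Frequencies below the detection
#' floor of two full periods per recording are reported as 0.
#'
#' @param kymo a [kymograph()].
#' @param speed_range_mm_s c(min, max) magnitude of candidate speeds.
#' @param n_speed_grid coarse grid size per direction.
#' @param mixed_ratio secondary/primary spectral power ratio flagging "mixed".
#' @return a [wave_stats_record()].
#' @export
wave_stats <- function(kymo, speed_range_mm_s = c(0.01, 1), n_speed_grid = 48L,
                       mixed_ratio = 0.8) {
  stopifnot(inherits(kymo, "kymograph"))
  K <- kymo$matrix
  npos <- nrow(K); nf <- ncol(K)
  duration <- (nf - 1) * kymo$dt_s
  floor_mHz <- 2000 / duration
  D <- K - rowMeans(K)  # detrend: per-position temporal mean
  if (max(abs(D)) < 1e-9 * (max(abs(K)) + 1e-300) || stats::sd(D) == 0) {
    return(wave_stats_record(0, 0, 0L, "mixed", floor_mHz))
  }

  # --- frequency: position-averaged temporal power spectrum
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, nf - 1) / (nf - 1))
  Dw <- sweep(D, 2, hann, "*")
  P <- abs(stats::mvfft(t(Dw)))^2          # rows = frequency bins
  pw <- rowMeans(P)[seq_len(floor(nf / 2))]
  freqs_mHz <- (seq_along(pw) - 1) / (nf * kymo$dt_s) * 1000
  valid <- freqs_mHz >= floor_mHz
  if (!any(valid)) return(wave_stats_record(0, 0, 0L, "mixed", floor_mHz))
  kpk <- which(valid)[which.max(pw[valid])]
  if (pw[kpk] <= 0) return(wave_stats_record(0, 0, 0L, "mixed", floor_mHz))
  bin_mHz <- 1000 / (nf * kymo$dt_s)

  # subharmonic folding: a non-sinusoidal wave train is a comb at multiples of
  # the true frequency and its dominant tooth may be a harmonic. If an
  # integer submultiple of the dominant peak carries a substantial local peak,
  # take the largest such divisor as the fundamental.
  local_peak <- function(f_target) {
    ks <- which(abs(freqs_mHz - f_target) <= 1.5 * bin_mHz & valid)
    if (!length(ks)) return(NULL)
    ks[which.max(pw[ks])]
  }
  kfund <- kpk
  for (m in 5:2) {
    fc <- freqs_mHz[kpk] / m
    if (fc < floor_mHz) next
    kc <- local_peak(fc)
    if (is.null(kc) || pw[kc] < 0.25 * pw[kpk]) next
    # require the full comb: every multiple of fc up to the dominant peak
    comb_ok <- all(vapply(seq_len(m), function(j) {
      kj <- local_peak(j * fc)
      !is.null(kj) && pw[kj] >= 0.15 * pw[kpk]
    }, logical(1)))
    if (comb_ok) {
      kfund <- kc
      break
    }
  }

  # parabolic refinement on log power
  f_mHz <- freqs_mHz[kfund]
  if (kfund > 1 && kfund < length(pw) && pw[kfund - 1] > 0 && pw[kfund + 1] > 0) {
    la <- log(pw[kfund - 1]); lb <- log(pw[kfund]); lc <- log(pw[kfund + 1])
    den <- la - 2 * lb + lc
    if (den < 0) {
      delta <- 0.5 * (la - lc) / den
      f_mHz <- f_mHz + delta * bin_mHz
    }
  }

  # secondary peak check: local maxima that are neither the fundamental nor
  # (within tolerance) one of its harmonics
  is_peak <- valid & c(FALSE, diff(pw) > 0) & c(rev(diff(rev(pw))) > 0, FALSE)
  harm_ratio <- freqs_mHz / max(f_mHz, bin_mHz)
  near_harm <- abs(harm_ratio - round(harm_ratio)) * f_mHz <= 2.5 * bin_mHz
  others <- which(is_peak & !near_harm &
                    abs(freqs_mHz - f_mHz) > 2.5 * bin_mHz)
  mixed <- length(others) > 0 && max(pw[others]) >= mixed_ratio * pw[kfund]

  # --- speed: shear search (rows subsampled for cost; stripes are smooth)
  rows_use <- seq(1L, npos, by = max(1L, npos %/% 128L))
  x_mm <- (seq_len(npos) - 1) * kymo$dx_mm
  tf <- seq_len(nf)
  score <- function(v_mm_s) {
    shift_frames <- x_mm / v_mm_s / kymo$dt_s
    acc <- numeric(nf); wt <- numeric(nf)
    for (i in rows_use) {
      # a wave at speed v reaches position x at time t_k + x/v, so advancing
      # row i by x_i / v aligns the stripes across rows
      y <- stats::approx(tf - shift_frames[i], D[i, ], xout = tf)$y
      ok <- !is.na(y)
      acc[ok] <- acc[ok] + y[ok]; wt[ok] <- wt[ok] + 1
    }
    use <- wt >= length(rows_use) / 2
    if (sum(use) < 8) return(0)
    stats::var(acc[use] / wt[use])
  }
  vgrid <- exp(seq(log(speed_range_mm_s[1]), log(speed_range_mm_s[2]),
                   length.out = n_speed_grid))
  cand <- c(vgrid, -vgrid)
  sc <- vapply(cand, score, numeric(1))
  best <- which.max(sc)
  v0 <- cand[best]
  fine <- v0 * seq(0.8, 1.25, length.out = 41)
  scf <- vapply(fine, score, numeric(1))
  v_hat <- fine[which.max(scf)]

  n_waves <- as.integer(floor(f_mHz / 1000 * duration))
  direction <- if (mixed) "mixed" else if (v_hat >= 0) "forward" else "backward"
  wave_stats_record(f_mHz, abs(v_hat), n_waves, direction, floor_mHz)
}
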