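# Cohort statistics: box-plot style group summaries, the two-tailed
# Mann-Whitney U test (exact by enumeration for small untied samples, normal
# approximation with tie and continuity corrections otherwise), and
# stress-response trend fitting over growth cohorts.

#' Summarize a group of measurements
#'
#' Median, quartiles (linear-interpolation convention, matching the usual
#' box-plot quantiles), mean and sample SD.
#'
#' @param values numeric vector (n >= 1).
#' @return list with `n`, `median`, `q25`, `q75`, `mean`, `sd`.
#' @export
summarize_group <- function(values) {
  stopifnot(length(values) >= 1, is.numeric(values))
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(values), median = q[2], q25 = q[1], q75 = q[3],
       mean = mean(values), sd = if (length(values) > 1) stats::sd(values) else 0)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact p-value by complete enumeration of rank assignments when
#' `n_a + n_b <= exact_max` and the pooled data have no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#' U is the number of (a, b) pairs with `a > b` (+ half the ties).
#'
#' @param a,b numeric vectors (each n >= 1).
#' @param exact_max largest pooled size for exact enumeration.
#' @return list with `U`, `p`, `method` (`"exact"` or `"normal"`), and
#'   `significant` at the 0.05 threshold.
#' @export
mann_whitney <- function(a, b, exact_max = 14L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  Ra <- sum(rk[seq_len(na)])
  U <- Ra - na * (na + 1) / 2  # pairs with a > b (ties count 1/2)
  ties <- any(duplicated(pooled))
  if (!ties && na + nb <= exact_max) {
    # enumerate all C(na+nb, na) assignments of ranks to group a
    combs <- utils::combn(na + nb, na)
    Us <- colSums(matrix(seq_len(na + nb)[combs], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    n <- na + nb
    sig2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method, significant = p < 0.05)
}

#' Fit the stress-response trend of a growth cohort
#'
#' Ordinary least squares of percent change versus applied stress (Pa);
#' controls enter at 0 Pa. Channels: `length` uses `L1/L0 - 1`, `volume`
#' `V1/V0 - 1`, `diameter` `d1/d0 - 1`, in percent.
#'
#' @param records data.frame in the layout of [generate_growth_cohort()]
#'   (columns `stress_Pa`, `L0_mm`, `L1_mm`, `V0_mm3`, `V1_mm3`, `d0_mm`,
#'   `d1_mm`).
#' @param channel `"length"`, `"volume"` or `"diameter"`.
#' @return list with `channel`, `slope` (% per Pa), `intercept` (% at 0 Pa),
#'   `residual_sd`, `n`.
#' @export
fit_stress_trend <- function(records, channel = c("length", "volume", "diameter")) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(records))
  if (nrow(records) < 3) stop("need at least 3 records")
  if (length(unique(records$stress_Pa)) < 2) stop("all stresses equal: trend unidentifiable")
  pct <- switch(channel,
    length = 100 * (records$L1_mm / records$L0_mm - 1),
    volume = 100 * (records$V1_mm3 / records$V0_mm3 - 1),
    diameter = 100 * (records$d1_mm / records$d0_mm - 1))
  fit <- stats::lm(pct ~ records$stress_Pa)
  co <- stats::coef(fit)
  list(channel = channel, slope = unname(co[2]), intercept = unname(co[1]),
       residual_sd = stats::sd(stats::residuals(fit)), n = nrow(records))
}

#' Derived biomechanical quantities for a growth cohort
#'
#' Adds relative changes, dry-mass change, cell-number change and (for tensed,
#' elongating specimens) the effective viscosity to a cohort table.
#'
#' @param records cohort data.frame (layout of [generate_growth_cohort()]).
#' @param rho_ref_mg_mm3 reference dry density of native tissue.
#' @param n_ref_cells_mm3 reference cell density of native tissue.
#' @return the input data.frame with extra columns `dl_rel`, `dv_rel`,
#'   `dd_rel`, `dm_rel`, `dn_rel`, `eta_Pa_s`.
#' @export
augment_growth_records <- function(records, rho_ref_mg_mm3 = 0.100,
                                   n_ref_cells_mm3 = 4.15e5) {
  stopifnot(is.data.frame(records))
  out <- records
  out$dl_rel <- relative_change(records$L0_mm, records$L1_mm)
  out$dv_rel <- relative_change(records$V0_mm3, records$V1_mm3)
  out$dd_rel <- relative_change(records$d0_mm, records$d1_mm)
  out$dm_rel <- if ("m_f_mg" %in% names(records)) {
    dry_mass_change(records$m_f_mg, records$V0_mm3, rho_ref_mg_mm3)
  } else NA_real_
  out$dn_rel <- if ("N_f" %in% names(records)) {
    cell_number_change(records$N_f, records$V0_mm3, n_ref_cells_mm3)
  } else NA_real_
  eta <- rep(NA_real_, nrow(records))
  ok <- out$dl_rel > 0 & records$stress_Pa > 0
  if (any(ok)) {
    eta[ok] <- effective_viscosity(records$stress_Pa[ok],
                                   records$duration_h[ok], out$dl_rel[ok])
  }
  out$eta_Pa_s <- eta
  out
}
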