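# Shared fixtures, built in code at test time.

# A quick mid-resolution phantom (about 0.3 s to generate and measure).
quick_phantom <- function(kind = "sinusoid", seed = 1L, ...) {
  args <- utils::modifyList(
    list(midline_kind = kind, length_mm = 8, base_diameter_mm = 0.4,
         bend_amplitude_mm = if (kind == "straight") 0 else 0.5,
         bend_wavelength_mm = 5, scale_mm_per_px = 0.025, seed = seed),
    list(...))
  generate_tube_image(do.call(tube_phantom_spec, args))
}

# Random phantom spec drawn from the acceptance-style family (sinusoidal
# midlines, bend amplitude up to 2 diameters, taper up to 30%,
# scale <= diameter / 20).
random_phantom_spec <- function(seed) {
  set.seed(seed)
  d <- runif(1, 0.3, 0.5)
  tube_phantom_spec(
    midline_kind = "sinusoid",
    length_mm = runif(1, 8, 12),
    base_diameter_mm = d,
    taper = runif(1, -0.3, 0.3),
    bend_amplitude_mm = runif(1, 0, 2) * d,
    bend_wavelength_mm = runif(1, 5, 8),
    scale_mm_per_px = min(0.02, d / 20),
    noise_sd_px = runif(1, 0, 0.5),
    seed = seed)
}

# Synthetic disk image (for degenerate-shape tests).
disk_image <- function(radius_px = 60, pad = 12) {
  n <- 2 * (radius_px + pad)
  cc <- (n - 1) / 2 + 0.27
  rr <- matrix(0:(n - 1), n, n)
  255 * ((rr - cc)^2 + (t(rr) - cc)^2 <= radius_px^2)
}
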