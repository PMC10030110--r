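#' Specification for a synthetic terrain class
#'
#' Terrain classes mirror the three experimental tracks: `flat`, and two
#' undulating classes with increasing unevenness, `uneven1` (amplitude
#' 18 +/- 6 mm, wavelength 102 +/- 45 mm) and `uneven2` (28 +/- 11 mm,
#' 108 +/- 52 mm). Amplitude is the peak-to-valley height difference and
#' wavelength the peak-to-peak longitudinal separation, both as measured by
#' [measure_amplitude_wavelength()].
#'
#' @param class one of `"flat"`, `"uneven1"`, `"uneven2"`
#' @param amplitude,amplitude_sd target amplitude mean and SD (m)
#' @param wavelength,wavelength_sd target wavelength mean and SD (m)
#' @param length,width field extents (m); defaults are the 21.6 m straight
#'   section of a 0.6 m wide track
#' @param resolution grid spacing (m)
#' @param seed integer seed
#' @return an object of class `terrain_spec`
#' @export
terrain_spec <- function(class = c("uneven1", "uneven2", "flat"),
                         amplitude = NULL, amplitude_sd = NULL,
                         wavelength = NULL, wavelength_sd = NULL,
                         length = 21.6, width = 0.6,
                         resolution = 0.005, seed = 1L) {
  class <- match.arg(class)
  defaults <- switch(class,
    flat = list(a = 0, asd = 0, w = NaN, wsd = 0),
    uneven1 = list(a = 0.018, asd = 0.006, w = 0.102, wsd = 0.045),
    uneven2 = list(a = 0.028, asd = 0.011, w = 0.108, wsd = 0.052)
  )
  spec <- structure(
    list(
      class = class,
      amplitude = amplitude %||% defaults$a,
      amplitude_sd = amplitude_sd %||% defaults$asd,
      wavelength = wavelength %||% defaults$w,
      wavelength_sd = wavelength_sd %||% defaults$wsd,
      length = length, width = width,
      resolution = resolution, seed = as.integer(seed)
    ),
    class = "terrain_spec"
  )
  if (spec$class == "flat" && spec$amplitude != 0) {
    stop("a flat terrain spec must have zero amplitude")
  }
  if (spec$amplitude < 0 || spec$wavelength <= 0 && spec$class != "flat") {
    stop("amplitude targets must be >= 0 and wavelength targets > 0")
  }
  spec
}

# annular Gaussian band-pass of a white-noise spectrum
band_pass_field <- function(zf, ky, kx, k0, sig_k) {
  kk <- sqrt(outer(ky^2, kx^2, "+"))
  w <- exp(-((kk - k0)^2) / (2 * sig_k^2))
  out <- Re(stats::fft(zf * w, inverse = TRUE)) / length(zf)
  out - mean(out)
}

#' Generate a calibrated synthetic terrain field
#'
#' Synthesizes a band-pass-filtered 2D Gaussian random field and iteratively
#' tunes the pass band centre until the wavelength measured by
#' [measure_amplitude_wavelength()] matches the spec target, then rescales
#' heights so the measured amplitude matches exactly. The same white-noise
#' realization is refiltered at every iteration, so the result is a pure
#' function of `(spec, seed)`.
#'
#' @param spec a [terrain_spec()]
#' @param tol_amplitude amplitude calibration tolerance (m); default 2 mm
#' @param tol_wavelength wavelength calibration tolerance (m); default 10 mm
#' @param max_iter maximum band-tuning iterations
#' @param squash_frac soft bound on heights as a fraction of the target
#'   amplitude: Gaussian tails are squashed through
#'   `a * tanh(h / a)` with `a = squash_frac * amplitude`, emulating the
#'   bounded height distribution of a physically built surface
#' @return a [terrain_field()] with an attached `calibration` attribute
#'   holding the achieved statistics
#' @export
generate_terrain <- function(spec, tol_amplitude = 0.002,
                             tol_wavelength = 0.010, max_iter = 12L,
                             squash_frac = 0.75) {
  ny <- round(spec$length / spec$resolution) + 1L
  nx <- round(spec$width / spec$resolution) + 1L
  if (spec$class == "flat" || spec$amplitude == 0) {
    fld <- terrain_field(matrix(0, ny, nx), spec$resolution)
    attr(fld, "calibration") <- list(converged = TRUE, iterations = 0L,
                                     seed = spec$seed)
    return(fld)
  }
  z <- with_seed(spec$seed, matrix(rnorm(ny * nx), ny, nx))
  zf <- stats::fft(z)
  # spatial frequencies in cycles/m along each axis
  freqs <- function(n, d) {
    k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1L, -1L)) / (n * d)
    k
  }
  ky <- freqs(ny, spec$resolution)
  kx <- freqs(nx, spec$resolution)
  k0 <- 1 / spec$wavelength
  rel_bw <- min(max(spec$wavelength_sd / spec$wavelength, 0.1), 0.6)
  stats_m <- NULL
  converged <- FALSE
  h <- NULL
  shape <- function(h_raw) {
    # scale to target amplitude, then soft-clip the Gaussian tails so the
    # height distribution is bounded like a hand-built undulating surface,
    # then rescale (linear) so the measured amplitude is exact
    m1 <- measure_amplitude_wavelength(terrain_field(h_raw, spec$resolution))
    if (!is.finite(m1$wavelength_mean)) {
      stop("terrain calibration failed: no extrema detected")
    }
    h1 <- h_raw * spec$amplitude / m1$amplitude_mean
    a_s <- squash_frac * spec$amplitude
    h2 <- a_s * tanh(h1 / a_s)
    m2 <- measure_amplitude_wavelength(terrain_field(h2, spec$resolution))
    list(h = h2 * spec$amplitude / m2$amplitude_mean, stats = m2)
  }
  for (it in seq_len(max_iter)) {
    sh <- shape(band_pass_field(zf, ky, kx, k0, rel_bw * k0))
    h <- sh$h
    stats_m <- sh$stats
    if (abs(stats_m$wavelength_mean - spec$wavelength) <= tol_wavelength) {
      converged <- TRUE
      break
    }
    k0 <- k0 * stats_m$wavelength_mean / spec$wavelength
  }
  if (!converged) {
    stop(sprintf(
      paste0("terrain wavelength calibration did not converge: achieved ",
             "%.1f mm for a %.1f mm target"),
      1e3 * stats_m$wavelength_mean, 1e3 * spec$wavelength
    ))
  }
  fld <- terrain_field(h, spec$resolution)
  achieved <- measure_amplitude_wavelength(fld)
  if (abs(achieved$amplitude_mean - spec$amplitude) > tol_amplitude) {
    stop(sprintf(
      "terrain amplitude calibration failed: achieved %.1f mm for %.1f mm",
      1e3 * achieved$amplitude_mean, 1e3 * spec$amplitude
    ))
  }
  attr(fld, "calibration") <- list(
    converged = TRUE, iterations = it, k0 = k0, rel_bandwidth = rel_bw,
    achieved = achieved, seed = spec$seed
  )
  fld
}
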