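#' Eye phantom specification
#'
#' Describes a synthetic ex vivo eye: a Kelvin-Voigt apex (stiffness k,
#' damping c) plus the optical geometry needed to render an M-scan — resting
#' anterior depth, central corneal thickness (CCT), speckle statistics and a
#' seed. Rendered interface positions are optical depths in micrometers in
#' air: the posterior interface appears `baseline_cct * group_index` below
#' the anterior one.
#'
#' @param kv A [kv_params()]; defaults roughly reproduce a porcine cornea at
#'   physiological intraocular pressure under a 120.8 mN puff (peak apex
#'   displacement near 0.8 mm).
#' @param baseline_cct Resting physical CCT in micrometers.
#' @param compression_fraction Relative CCT reduction at maximum deformation,
#'   in `[0, 1)`. Thickness shrinks linearly with instantaneous displacement.
#' @param anterior_depth Resting anterior interface depth below the image
#'   top, micrometers (in-air scale).
#' @param group_index Corneal group refractive index used to convert
#'   physical to optical thickness (default 1.376).
#' @param speckle_contrast Standard deviation of the unit-mean multiplicative
#'   speckle factor; 0 disables speckle, 1 is fully developed speckle.
#' @param background_level Mean background intensity (arbitrary units; the
#'   interface bands peak at 1).
#' @param band_sigma Gaussian half-width of a rendered interface band,
#'   micrometers (the effective axial point-spread of the instrument).
#' @param seed Integer seed making the rendered image reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kv = kv_params(k = 150, c = 0.12),
                         baseline_cct = 950, compression_fraction = 0.03,
                         anterior_depth = 800, group_index = 1.376,
                         speckle_contrast = 0.5, background_level = 0.03,
                         band_sigma = 16, seed = 1L) {
  if (!inherits(kv, "kv_params"))
    cp_stop("corneapuff_invalid_spec", "kv must be kv_params")
  check_scalar(baseline_cct, "baseline_cct", positive = TRUE)
  check_scalar(anterior_depth, "anterior_depth", nonneg = TRUE)
  check_scalar(group_index, "group_index", positive = TRUE)
  check_scalar(speckle_contrast, "speckle_contrast", nonneg = TRUE)
  check_scalar(background_level, "background_level", nonneg = TRUE)
  check_scalar(band_sigma, "band_sigma", positive = TRUE)
  check_scalar(compression_fraction, "compression_fraction", nonneg = TRUE)
  if (compression_fraction >= 1)
    cp_stop("corneapuff_invalid_spec", "compression_fraction must be < 1")
  structure(list(kv = kv, baseline_cct = baseline_cct,
                 compression_fraction = compression_fraction,
                 anterior_depth = anterior_depth, group_index = group_index,
                 speckle_contrast = speckle_contrast,
                 background_level = background_level,
                 band_sigma = band_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Simulate the apex response of a phantom eye
#'
#' Thin wrapper delegating to [kv_response()] with the phantom's
#' Kelvin-Voigt parameters.
#'
#' @param force A [force_trace()].
#' @param phantom A [phantom_spec()].
#' @return A [displacement_trace()] (micrometers, inward positive).
#' @export
simulate_eye_response <- function(force, phantom) {
  if (!inherits(phantom, "phantom_spec"))
    cp_stop("corneapuff_invalid_spec", "phantom must be a phantom_spec")
  kv_response(force, phantom$kv)
}

#' OCT M-scan container
#'
#' A depth-by-time intensity image: each column is one A-scan, columns are
#' time-ordered at the A-scan rate, depth increases downward.
#'
#' @param intensity Numeric matrix, depth_px x n_ascan, finite, nonnegative.
#' @param axial_pitch Axial pixel pitch in micrometers-in-air per pixel.
#' @param ascan_rate A-scan (column) rate in Hz.
#' @param t0 Acquisition time of the first column, seconds.
#' @return An object of class `mscan`.
#' @export
mscan <- function(intensity, axial_pitch, ascan_rate, t0 = 0) {
  if (!is.matrix(intensity) || ncol(intensity) < 2L)
    cp_stop("corneapuff_invalid_spec", "intensity must be a matrix with >= 2 columns")
  if (!all(is.finite(intensity)) || any(intensity < 0))
    cp_stop("corneapuff_invalid_spec", "intensities must be finite and >= 0")
  check_scalar(axial_pitch, "axial_pitch", positive = TRUE)
  check_scalar(ascan_rate, "ascan_rate", positive = TRUE)
  structure(list(intensity = intensity, axial_pitch = axial_pitch,
                 ascan_rate = ascan_rate, t0 = t0),
            class = "mscan")
}

#' @export
print.mscan <- function(x, ...) {
  cat(sprintf("<mscan> %d px depth x %d A-scans, %.3g um/px, %.4g kHz\n",
              nrow(x$intensity), ncol(x$intensity), x$axial_pitch,
              x$ascan_rate / 1e3))
  invisible(x)
}

# Column times of an M-scan, seconds.
mscan_time <- function(m) m$t0 + (seq_len(ncol(m$intensity)) - 1L) / m$ascan_rate

#' Render a synthetic M-scan from a displacement trace
#'
#' Draws, for every A-scan column, two bright Gaussian interface bands: the
#' anterior surface at `anterior_depth + x(t)` and the posterior surface one
#' optical thickness below it. The optical thickness shrinks linearly with
#' the instantaneous relative displacement `x(t)/max(x)`, reaching
#' `(1 - compression_fraction)` of its resting value at peak deformation.
#' Unit-mean multiplicative speckle (a shifted exponential with standard
#' deviation `speckle_contrast`) and additive Gaussian background noise are
#' then applied. Rendering is a pure function of `(x, phantom, geometry)`:
#' the same seed yields a bitwise-identical image.
#'
#' @param x A [displacement_trace()] (micrometers, inward positive).
#' @param phantom A [phantom_spec()].
#' @param axial_pitch Axial pixel pitch, micrometers-in-air per pixel.
#' @param depth_px Number of depth pixels.
#' @return An [mscan()].
#' @export
render_mscan <- function(x, phantom, axial_pitch = 8, depth_px = 448) {
  if (!inherits(x, "displacement_trace"))
    cp_stop("corneapuff_invalid_trace", "x must be a displacement_trace")
  if (!inherits(phantom, "phantom_spec"))
    cp_stop("corneapuff_invalid_spec", "phantom must be a phantom_spec")
  check_scalar(axial_pitch, "axial_pitch", positive = TRUE)
  n <- length(x$x)
  opt_thick0 <- phantom$baseline_cct * phantom$group_index
  xmax <- max(x$x)
  rel <- if (xmax > 0) pmax(x$x, 0) / xmax else rep(0, n)
  thick <- opt_thick0 * (1 - phantom$compression_fraction * rel)
  ant_um <- phantom$anterior_depth + x$x
  post_um <- ant_um + thick
  ant_px <- ant_um / axial_pitch
  post_px <- post_um / axial_pitch
  margin <- 3 * phantom$band_sigma / axial_pitch
  bad <- which(ant_px < margin | post_px > depth_px - 1 - margin)
  if (length(bad) > 0L)
    cp_stop("corneapuff_out_of_range",
            "surfaces leave the depth range at A-scan %d (anterior %.1f px, posterior %.1f px, depth %d px)",
            bad[1], ant_px[bad[1]], post_px[bad[1]], depth_px)
  rows <- seq_len(depth_px) - 1L           # 0-based pixel centers
  s2 <- 2 * (phantom$band_sigma / axial_pitch)^2
  clean <- phantom$background_level +
    exp(-(outer(rows, ant_px, "-"))^2 / s2) +
    exp(-(outer(rows, post_px, "-"))^2 / s2)
  img <- with_seed(phantom$seed, {
    sc <- phantom$speckle_contrast
    out <- clean
    if (sc > 0) {
      mult <- 1 + sc * (stats::rexp(length(clean)) - 1)
      out <- out * pmax(mult, 0)
    }
    if (phantom$background_level > 0) {
      out <- out + stats::rnorm(length(clean),
                                sd = 0.25 * phantom$background_level)
    }
    pmax(out, 0)
  })
  mscan(matrix(img, nrow = depth_px), axial_pitch = axial_pitch,
        ascan_rate = 1 / mean(diff(x$time)), t0 = x$time[1])
}
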