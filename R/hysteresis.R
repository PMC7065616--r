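#' Build a force-displacement hysteresis curve
#'
#' Pairs the apex displacement trace `x(t)` with the force trace `F(t)` into
#' the time-ordered dynamic hysteresis curve `F(x)`. The force is linearly
#' resampled onto the displacement timestamps (identity pairing when the
#' clocks coincide); samples outside the overlap of the two clocks are
#' dropped. The loop is split at the maximum displacement (first occurrence
#' on ties): the loading phase is samples `1..split_index`, the unloading
#' phase `split_index..n`.
#'
#' @param x A [displacement_trace()] (micrometers).
#' @param f A [force_trace()] (newtons).
#' @return An object of class `hysteresis_curve` with fields `x` (um), `F`
#'   (N), `time` (s), `split_index` and `mad` (um).
#' @export
build_hysteresis <- function(x, f) {
  if (!inherits(x, "displacement_trace"))
    cp_stop("corneapuff_invalid_trace", "x must be a displacement_trace")
  if (!inherits(f, "force_trace"))
    cp_stop("corneapuff_invalid_trace", "f must be a force_trace")
  keep <- x$time >= min(f$time) & x$time <= max(f$time)
  if (!any(keep))
    cp_stop("corneapuff_alignment",
            "displacement and force traces have no overlapping time support")
  t <- x$time[keep]
  xv <- x$x[keep]
  fv <- stats::approx(f$time, f$force, xout = t)$y
  mad <- max(xv)
  if (mad <= 0)
    cp_stop("corneapuff_no_deformation", "maximum displacement is not positive")
  split <- which.max(xv)
  structure(list(x = xv, F = fv, time = t, split_index = split, mad = mad),
            class = "hysteresis_curve")
}

#' @export
print.hysteresis_curve <- function(x, ...) {
  cat(sprintf("<hysteresis_curve> %d samples, MAD %.1f um, peak force %.4g N\n",
              length(x$x), x$mad, max(x$F)))
  invisible(x)
}

loading_idx <- function(h) seq_len(h$split_index)
unloading_idx <- function(h) h$split_index:length(h$x)

#' Loading-phase energy
#'
#' Trapezoidal integral of force over displacement along the loading phase,
#' in joules (displacement converted from micrometers to meters). This is
#' the mechanical energy delivered to the cornea up to maximum deformation
#' and the denominator of the hysteresis ratio.
#'
#' @param h A [build_hysteresis()] curve.
#' @return Energy in joules.
#' @export
loading_energy <- function(h) {
  i <- loading_idx(h)
  trapz(h$x[i] * 1e-6, h$F[i])
}

#' Hysteresis area (dissipated energy)
#'
#' The energy enclosed by the force-displacement loop, computed as the
#' time-parameterized line integral of F dx around the closed loop
#' (trapezoidal shoelace rule, closing the loop from the last sample back to
#' the first). For loops whose loading and unloading phases are each
#' monotone in x this equals the difference of the loading and unloading
#' phase integrals; the time parameterization additionally handles
#' non-monotone segments and post-recovery ringing without re-sorting.
#'
#' @param h A [build_hysteresis()] curve with at least 4 samples.
#' @return Dissipated energy in joules.
#' @export
hysteresis_area <- function(h) {
  n <- length(h$x)
  if (n < 4L)
    cp_stop("corneapuff_insufficient_data",
            "need at least 4 samples for a loop area (got %d)", n)
  xm <- h$x * 1e-6
  nxt <- c(2:n, 1L)
  sum((h$F[nxt] + h$F) * (xm[nxt] - xm)) / 2
}

#' Hysteresis ratio
#'
#' The percentage of the loading-phase energy dissipated over one
#' deformation-recovery cycle: `HR = 100 * HA / loading_energy`.
#'
#' @param h A [build_hysteresis()] curve.
#' @return Hysteresis ratio in percent.
#' @export
hysteresis_ratio <- function(h) {
  e <- loading_energy(h)
  if (e <= 0)
    cp_stop("corneapuff_undefined_ratio", "loading energy is not positive")
  100 * hysteresis_area(h) / e
}

# First-crossing of the 10%-of-MAD point on the loading phase, with linear
# interpolation to exactly 0.1 * MAD. Returns list(x, F) at the point.
mad10_point <- function(h) {
  i <- loading_idx(h)
  xl <- h$x[i]; fl <- h$F[i]
  target <- 0.1 * h$mad
  j <- which(xl >= target)[1]
  if (is.na(j))
    cp_stop("corneapuff_slope_undefined", "loading never reaches 10%% of MAD")
  if (j == 1L || xl[j] == target) return(list(x = xl[j], F = fl[j]))
  w <- (target - xl[j - 1L]) / (xl[j] - xl[j - 1L])
  list(x = target, F = fl[j - 1L] + w * (fl[j] - fl[j - 1L]))
}

#' Secant slope of the loading curve
#'
#' Slope of the line joining the 10%-of-MAD point (first crossing on the
#' loading phase, linearly interpolated to exactly 0.1 MAD) and the maximum
#' displacement point, in N/m.
#'
#' @param h A [build_hysteresis()] curve.
#' @return Slope in N/m.
#' @export
secant_slope <- function(h) {
  p10 <- mad10_point(h)
  f_mad <- h$F[h$split_index]
  dx <- (h$mad - p10$x) * 1e-6
  if (dx <= 0)
    cp_stop("corneapuff_slope_undefined", "degenerate secant span")
  (f_mad - p10$F) / dx
}

# Least-squares slope of F vs x (um -> m) over loading samples with x in
# [lo, hi] (closed interval), requiring >= 3 samples.
window_slope <- function(h, lo, hi) {
  i <- loading_idx(h)
  sel <- i[h$x[i] >= lo & h$x[i] <= hi]
  if (length(sel) < 3L)
    cp_stop("corneapuff_insufficient_window",
            "loading window [%.1f, %.1f] um contains %d samples (need >= 3)",
            lo, hi, length(sel))
  xm <- h$x[sel] * 1e-6
  stats::cov(xm, h$F[sel]) / stats::var(xm)
}

#' Low-strain slope of the loading curve
#'
#' Least-squares slope of force versus displacement over the first
#' `window_um` (default 120) micrometers of the loading curve starting at
#' the 10%-of-MAD point — the compliant, extracellular-matrix-dominated
#' regime of the J-shaped loading curve.
#'
#' @param h A [build_hysteresis()] curve.
#' @param window_um Fit window length in micrometers.
#' @return Slope in N/m.
#' @export
low_strain_slope <- function(h, window_um = 120) {
  p10 <- mad10_point(h)
  if (p10$x + window_um > h$mad)
    cp_stop("corneapuff_insufficient_window",
            "low-strain window [%.1f, %.1f] um exceeds MAD = %.1f um",
            p10$x, p10$x + window_um, h$mad)
  window_slope(h, p10$x, p10$x + window_um)
}

#' High-strain slope of the loading curve
#'
#' Least-squares slope of force versus displacement over the last
#' `window_um` (default 120) micrometers of the loading curve, up to the
#' maximum displacement — the stiffer, collagen-stretching regime.
#'
#' @inheritParams low_strain_slope
#' @return Slope in N/m.
#' @export
high_strain_slope <- function(h, window_um = 120) {
  i <- loading_idx(h)
  if (h$mad - min(h$x[i]) < window_um)
    cp_stop("corneapuff_insufficient_window",
            "loading span %.1f um is shorter than the %.0f um window",
            h$mad - min(h$x[i]), window_um)
  window_slope(h, h$mad - window_um, h$mad)
}

#' Compute the full hysteresis descriptor set
#'
#' Builds the hysteresis curve from a displacement and a force trace and
#' evaluates every descriptor of one air-puff stimulation: MAD, HA, HR,
#' S_sec, S_low, S_high, loading energy, and — when a CCT triplet is
#' supplied — the thickness descriptors. A descriptor whose preconditions
#' fail (e.g. a loading phase shorter than a slope window, or missing
#' posterior segmentation) is reported as NA with the reason recorded in
#' `flags`, never silently dropped.
#'
#' @param x A [displacement_trace()].
#' @param f A [force_trace()].
#' @param cct Optional [cct_at_instants()] triplet.
#' @return An object of class `hysteresis_metrics`: fields `mad` (um), `ha`
#'   (J), `hr` (%), `s_sec`, `s_low`, `s_high` (N/m), `loading_energy` (J),
#'   `cct_bef`, `cct_max`, `cct_aft` (um), plus a named list `flags` of
#'   failure reasons.
#' @export
compute_all_metrics <- function(x, f, cct = NULL) {
  flags <- list()
  grab <- function(name, expr) {
    tryCatch(expr, corneapuff_error = function(e) {
      flags[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  h <- build_hysteresis(x, f)
  out <- list(
    mad = h$mad,
    ha = grab("ha", hysteresis_area(h)),
    hr = grab("hr", hysteresis_ratio(h)),
    s_sec = grab("s_sec", secant_slope(h)),
    s_low = grab("s_low", low_strain_slope(h)),
    s_high = grab("s_high", high_strain_slope(h)),
    loading_energy = grab("loading_energy", loading_energy(h))
  )
  if (is.null(cct)) {
    flags$cct <- "no CCT triplet supplied"
    out$cct_bef <- out$cct_max <- out$cct_aft <- NA_real_
  } else {
    out$cct_bef <- cct$cct_bef
    out$cct_max <- cct$cct_max
    out$cct_aft <- cct$cct_aft
  }
  out$flags <- flags
  structure(out, class = "hysteresis_metrics")
}

#' @export
print.hysteresis_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<hysteresis_metrics>\n",
    "  MAD    %8.1f um     HA  %10.4g J    HR  %6.2f %%\n",
    "  S_sec  %8.2f N/m    S_low %8.2f N/m  S_high %8.2f N/m\n",
    "  CCT    %6.1f / %6.1f / %6.1f um (bef/max/aft)\n"),
    x$mad, x$ha, x$hr, x$s_sec, x$s_low, x$s_high,
    x$cct_bef, x$cct_max, x$cct_aft))
  if (length(x$flags))
    cat("  flags:", paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.hysteresis_metrics <- function(x, ...) {
  data.frame(mad_um = x$mad, ha_j = x$ha, hr_pct = x$hr,
             s_sec_n_per_m = x$s_sec, s_low_n_per_m = x$s_low,
             s_high_n_per_m = x$s_high, loading_energy_j = x$loading_energy,
             cct_bef_um = x$cct_bef, cct_max_um = x$cct_max,
             cct_aft_um = x$cct_aft)
}

#' Export a hysteresis loop as CSV
#'
#' Writes the loop as a two-column CSV (`x_um`, `F_N`) for external plotting.
#'
#' @param h A [build_hysteresis()] curve.
#' @param path Output path.
#' @export
write_hysteresis_csv <- function(h, path) {
  utils::write.csv(data.frame(x_um = h$x, F_N = h$F), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a hysteresis loop
#'
#' Loading phase in blue, unloading in red, on force (mN) versus
#' displacement (mm) axes.
#'
#' @param x A `hysteresis_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hysteresis_curve <- function(x, ...) {
  li <- loading_idx(x); ui <- unloading_idx(x)
  graphics::plot(x$x[li] / 1e3, 1e3 * x$F[li], type = "l", col = "blue",
                 xlab = "apex displacement (mm)", ylab = "force (mN)",
                 xlim = range(x$x) / 1e3, ylim = 1e3 * range(x$F), ...)
  graphics::lines(x$x[ui] / 1e3, 1e3 * x$F[ui], col = "red")
  graphics::legend("topleft", c("loading", "unloading"), lty = 1,
                   col = c("blue", "red"), bty = "n")
  invisible(x)
}
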