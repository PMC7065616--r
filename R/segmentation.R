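#' Segment corneal surfaces in an M-scan
#'
#' Per A-scan column, the anterior surface is the first intensity peak
#' (scanning from the image top) whose height exceeds the column background
#' by `min_prominence` of the column's dynamic range; the posterior surface
#' is the next such peak at least `min_separation_um` deeper. Columns are
#' smoothed axially with a boxcar of `smooth_px` pixels before peak finding,
#' peak positions are refined to subpixel precision by parabolic
#' interpolation of the peak sample and its two neighbors, and the resulting
#' surface traces are median-filtered over time with a window of
#' `median_width` columns. Columns where either surface is not detected are
#' flagged invalid — never silently interpolated in the returned object.
#'
#' The detector uses only intensity ratios within each column, so it is
#' invariant to a global rescaling of the image.
#'
#' @param m An [mscan()].
#' @param params List of tuning parameters: `smooth_px` (axial boxcar width,
#'   pixels), `min_prominence` (fraction of column dynamic range a peak must
#'   rise above background, in (0, 1)), `median_width` (odd temporal median
#'   window, columns), `min_separation_um` (minimum optical anterior-posterior
#'   separation, micrometers).
#' @return An object of class `surface_pair`: `anterior` and `posterior`
#'   subpixel optical depths in micrometers (NA where invalid), a logical
#'   `valid` mask, and the pitch/clock metadata carried through.
#' @export
segment_surfaces <- function(m, params = list()) {
  if (!inherits(m, "mscan"))
    cp_stop("corneapuff_invalid_spec", "m must be an mscan")
  p <- utils::modifyList(
    list(smooth_px = 5L, min_prominence = 0.25, median_width = 9L,
         min_separation_um = 300),
    params
  )
  if (p$smooth_px < 1 || p$min_prominence <= 0 || p$median_width < 1)
    cp_stop("corneapuff_invalid_spec", "segmentation parameters must be positive")
  img <- m$intensity
  d <- nrow(img)
  n <- ncol(img)
  min_sep_px <- p$min_separation_um / m$axial_pitch
  # axial boxcar smoothing, column-wise
  w <- max(1L, as.integer(p$smooth_px))
  if (w > 1L) {
    sm <- apply(img, 2L, function(col)
      stats::filter(col, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- 0
  } else sm <- img
  ant <- rep(NA_real_, n)
  post <- rep(NA_real_, n)
  any_peak <- FALSE
  for (j in seq_len(n)) {
    col <- sm[, j]
    bg <- stats::median(col)
    rng <- max(col) - bg
    if (rng <= 0) next
    thr <- bg + p$min_prominence * rng
    is_pk <- c(FALSE, col[2:(d - 1)] >= col[1:(d - 2)] &
                       col[2:(d - 1)] > col[3:d], FALSE) & col > thr
    pk <- which(is_pk)
    if (length(pk) == 0L) next
    any_peak <- TRUE
    a <- pk[1]
    ant[j] <- refine_peak(col, a)
    deeper <- pk[pk >= a + min_sep_px]
    if (length(deeper) > 0L) post[j] <- refine_peak(col, deeper[1])
  }
  if (!any_peak)
    cp_stop("corneapuff_no_surface", "no interface peaks found in any A-scan")
  valid <- !is.na(ant) & !is.na(post)
  if (mean(!valid) > 0.2)
    cp_stop("corneapuff_segmentation_failure",
            "%.0f%% of A-scans have no surface detection", 100 * mean(!valid))
  # temporal median filter on an interpolation-completed series; invalid
  # columns stay NA in the output
  k <- as.integer(p$median_width)
  if (k %% 2L == 0L) k <- k + 1L
  smooth_trace <- function(v) {
    filled <- v
    if (anyNA(v))
      filled <- stats::approx(which(!is.na(v)), v[!is.na(v)], xout = seq_len(n),
                              rule = 2)$y
    out <- if (k > 1L && n > k) stats::runmed(filled, k, endrule = "median")
           else filled
    out[!valid] <- NA_real_
    out
  }
  ant_f <- smooth_trace(ant)
  post_f <- smooth_trace(post)
  structure(list(anterior = ant_f * m$axial_pitch,
                 posterior = post_f * m$axial_pitch,
                 valid = valid, axial_pitch = m$axial_pitch,
                 ascan_rate = m$ascan_rate, t0 = m$t0),
            class = "surface_pair")
}

# Parabolic 3-point subpixel refinement around row index i (1-based);
# returns a 0-based continuous row coordinate.
refine_peak <- function(col, i) {
  d <- length(col)
  if (i <= 1L || i >= d) return(i - 1)
  y0 <- col[i - 1L]; y1 <- col[i]; y2 <- col[i + 1L]
  den <- y0 - 2 * y1 + y2
  delta <- if (den < 0) 0.5 * (y0 - y2) / den else 0
  if (!is.finite(delta) || abs(delta) > 1) delta <- 0
  (i - 1) + delta
}

#' @export
print.surface_pair <- function(x, ...) {
  cat(sprintf("<surface_pair> %d A-scans, %d valid (%.1f%%)\n",
              length(x$anterior), sum(x$valid),
              100 * mean(x$valid)))
  invisible(x)
}

#' Apex displacement from segmented surfaces
#'
#' Converts the anterior surface trace to inward-positive apex displacement:
#' `x(t) = anterior(t) - mean(anterior over the baseline window)`. Invalid
#' columns are linearly interpolated in the output trace only (and flagged
#' via the trace's `interpolated` field); the raw [segment_surfaces()] output
#' keeps its NAs for audit.
#'
#' @param s A `surface_pair`.
#' @param m The [mscan()] the surfaces came from (provides the clock).
#' @param baseline_window Integer indices of pre-stimulus columns; must
#'   contain at least 10 valid samples.
#' @return A [displacement_trace()] in micrometers.
#' @export
displacement_from_surfaces <- function(s, m, baseline_window) {
  if (!inherits(s, "surface_pair"))
    cp_stop("corneapuff_invalid_spec", "s must be a surface_pair")
  n <- length(s$anterior)
  if (length(baseline_window) == 0L || any(baseline_window < 1) ||
      any(baseline_window > n))
    cp_stop("corneapuff_invalid_window", "baseline window empty or out of range")
  bw_valid <- intersect(baseline_window, which(s$valid))
  if (length(bw_valid) < 10L)
    cp_stop("corneapuff_invalid_window",
            "baseline window has %d valid samples (need >= 10)", length(bw_valid))
  ant <- s$anterior
  interpolated <- !s$valid
  if (anyNA(ant))
    ant <- stats::approx(which(!is.na(ant)), ant[!is.na(ant)],
                         xout = seq_len(n), rule = 2)$y
  x <- ant - mean(ant[bw_valid])
  displacement_trace(mscan_time(m), x, baseline_window = baseline_window,
                     interpolated = interpolated)
}

#' Central corneal thickness triplet
#'
#' Physical CCT at the three instants of the deformation-recovery cycle:
#' before the puff (`cct_bef`, mean over the baseline window), at maximum
#' apex displacement (`cct_max`, median over the argmax column +/- 2), and
#' after recovery (`cct_aft`, mean over the trailing run of samples where
#' `|x| < 5%` of the maximum apex displacement). Optical thickness
#' (posterior - anterior) is converted to physical via `group_index`.
#'
#' @param s A `surface_pair`.
#' @param x The matching [displacement_trace()] (same column index).
#' @param group_index Corneal group refractive index (default 1.376).
#' @return An object of class `cct_triplet` with fields `cct_bef`,
#'   `cct_max`, `cct_aft` (micrometers, physical) and `group_index`.
#' @export
cct_at_instants <- function(s, x, group_index = 1.376) {
  if (!inherits(s, "surface_pair"))
    cp_stop("corneapuff_invalid_spec", "s must be a surface_pair")
  n <- length(s$anterior)
  if (length(x$x) != n)
    cp_stop("corneapuff_invalid_trace",
            "trace and surfaces must share the column index")
  phys <- (s$posterior - s$anterior) / group_index
  bw <- x$baseline_window
  if (is.null(bw))
    cp_stop("corneapuff_invalid_window", "trace has no baseline window")
  cct_bef <- mean(phys[bw], na.rm = TRUE)
  imax <- which.max(x$x)
  mad <- x$x[imax]
  near <- max(1L, imax - 2L):min(n, imax + 2L)
  cct_max <- stats::median(phys[near], na.rm = TRUE)
  rec <- which(seq_len(n) > imax & abs(x$x) < 0.05 * mad & s$valid)
  if (length(rec) == 0L)
    cp_stop("corneapuff_no_recovery",
            "no post-peak samples recover to |x| < 5%% of MAD")
  runs <- split(rec, cumsum(c(TRUE, diff(rec) != 1L)))
  tail_run <- runs[[length(runs)]]
  cct_aft <- mean(phys[tail_run], na.rm = TRUE)
  structure(list(cct_bef = cct_bef, cct_max = cct_max, cct_aft = cct_aft,
                 group_index = group_index),
            class = "cct_triplet")
}

#' @export
print.cct_triplet <- function(x, ...) {
  cat(sprintf("<cct_triplet> bef %.1f / max %.1f / aft %.1f um (n = %.3f)\n",
              x$cct_bef, x$cct_max, x$cct_aft, x$group_index))
  invisible(x)
}
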