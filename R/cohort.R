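#' Synthetic cohort specification
#'
#' Describes a cohort of phantom eyes for one of the two study designs:
#'
#' * `"inflation"`: a cyclic intraocular-pressure (IOP) test — every eye is
#'   measured at each IOP level in ascending order and then back down in
#'   descending order (the top level is not duplicated). Stiffness follows
#'   the affine IOP proxy `k = k_of_iop[1] + k_of_iop[2] * IOP`, which must
#'   be strictly increasing in IOP.
#' * `"cxl"`: a corneal cross-linking progression — each eye is measured at
#'   every stage (`EPI_OFF`, `RS`, `RS_UV`) under each IOP level, with
#'   per-stage damping (`c_of_stage`) and resting thickness (`cct_of_stage`).
#'
#' Per-eye stiffness is jittered by a seeded log-normal factor (`eye_cv`,
#' default 5% coefficient of variation) held constant across conditions, so
#' paired designs stay paired.
#'
#' @param design `"inflation"` or `"cxl"`.
#' @param iop_levels IOP levels in mm Hg, each within `[5, 35]`.
#' @param k_of_iop Numeric `c(intercept, slope)` of the affine IOP-to-
#'   stiffness map (N/m per mm Hg); slope must be > 0.
#' @param c_damp Damping in N s/m for the inflation design.
#' @param c_of_stage Named damping (N s/m) per CXL stage.
#' @param cct_of_stage Named resting physical CCT (um) per CXL stage.
#' @param baseline_cct Resting physical CCT (um) for the inflation design.
#' @param eyes_per_condition Number of eyes (>= 1).
#' @param repetitions Consecutive measurements per eye and condition.
#' @param pulse A [pulse_spec()]; the default places a 4 ms pre-stimulus
#'   baseline ahead of a raised-cosine puff peaking at 120.8 mN.
#' @param speckle_contrast Speckle level of the rendered M-scans.
#' @param axial_pitch,depth_px M-scan rendering geometry.
#' @param eye_cv Coefficient of variation of the per-eye stiffness factor.
#' @param seed Cohort seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(design = c("inflation", "cxl"),
                        iop_levels = if (design == "cxl") c(15, 25) else seq(5, 35, by = 5),
                        k_of_iop = c(100, 3),
                        c_damp = 0.12,
                        c_of_stage = c(EPI_OFF = 0.10, RS = 0.14, RS_UV = 0.18),
                        cct_of_stage = c(EPI_OFF = 900, RS = 770, RS_UV = 576),
                        baseline_cct = 950,
                        eyes_per_condition = 1L, repetitions = 1L,
                        pulse = pulse_spec(delay = 0.004),
                        speckle_contrast = 0.5,
                        axial_pitch = 8, depth_px = 448,
                        eye_cv = 0.05, seed = 1L) {
  design <- match.arg(design)
  if (any(iop_levels < 5 | iop_levels > 35))
    cp_stop("corneapuff_invalid_spec", "iop_levels must lie within [5, 35] mm Hg")
  if (length(k_of_iop) != 2L || k_of_iop[2] <= 0)
    cp_stop("corneapuff_invalid_spec",
            "k_of_iop must be c(intercept, slope) with slope > 0")
  if (min(k_of_iop[1] + k_of_iop[2] * iop_levels) <= 0)
    cp_stop("corneapuff_invalid_spec", "k_of_iop must be positive on iop_levels")
  if (eyes_per_condition < 1L)
    cp_stop("corneapuff_invalid_spec", "eyes_per_condition must be >= 1")
  if (repetitions < 1L)
    cp_stop("corneapuff_invalid_spec", "repetitions must be >= 1")
  if (design == "cxl") {
    stages <- c("EPI_OFF", "RS", "RS_UV")
    if (!all(stages %in% names(c_of_stage)) ||
        !all(stages %in% names(cct_of_stage)))
      cp_stop("corneapuff_invalid_spec",
              "c_of_stage and cct_of_stage must name EPI_OFF, RS, RS_UV")
  }
  structure(list(design = design, iop_levels = iop_levels,
                 k_of_iop = k_of_iop, c_damp = c_damp,
                 c_of_stage = c_of_stage, cct_of_stage = cct_of_stage,
                 baseline_cct = baseline_cct,
                 eyes_per_condition = as.integer(eyes_per_condition),
                 repetitions = as.integer(repetitions), pulse = pulse,
                 speckle_contrast = speckle_contrast,
                 axial_pitch = axial_pitch, depth_px = depth_px,
                 eye_cv = eye_cv, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Condition table for a cohort: one row per measurement condition.
cohort_conditions <- function(spec) {
  if (spec$design == "inflation") {
    asc <- spec$iop_levels
    desc <- rev(asc)[-1]                   # top level not duplicated
    data.frame(
      phase = c(rep("ascending", length(asc)), rep("descending", length(desc))),
      iop_mmHg = c(asc, desc), stage = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    g <- expand.grid(stage = c("EPI_OFF", "RS", "RS_UV"),
                     iop_mmHg = spec$iop_levels, stringsAsFactors = FALSE)
    data.frame(phase = NA_character_, iop_mmHg = g$iop_mmHg, stage = g$stage,
               stringsAsFactors = FALSE)
  }
}

#' Generate a synthetic measurement cohort
#'
#' Produces one record per eye, condition and repetition. Each record holds
#' the rendered M-scan (unless `render = FALSE`), the synchronized
#' pressure-sensor trace (kPa, derived from the true force through the
#' default calibration), and a ground-truth block: the Kelvin-Voigt
#' parameters, the true force and displacement traces, the true maximum apex
#' displacement, and the true CCT triplet. Ground truth is generated before
#' rendering and persisted verbatim, so recovery tests never re-derive it
#' from images. The whole cohort is a pure function of its spec (seed
#' included).
#'
#' @param spec A [cohort_spec()].
#' @param render Render M-scans (set `FALSE` for trace-level studies; the
#'   ground-truth block is unaffected).
#' @return A list of class `cohort`: `spec`, `conditions` (data.frame), and
#'   `records` (list; each has `eye_id`, `phase`, `iop_mmHg`, `stage`,
#'   `repetition`, `seed`, `mscan`, `pressure`, `truth`).
#' @export
generate_cohort <- function(spec, render = TRUE) {
  if (!inherits(spec, "cohort_spec"))
    cp_stop("corneapuff_invalid_spec", "spec must be a cohort_spec")
  conds <- cohort_conditions(spec)
  force <- generate_force_pulse(spec$pulse)
  cal <- default_calibration()
  pressure <- data.frame(time_s = force$time, value = force$force / cal$slope)
  eye_factor <- with_seed(spec$seed,
    exp(stats::rnorm(spec$eyes_per_condition, 0, spec$eye_cv)))
  records <- list()
  counter <- 0L
  for (eye in seq_len(spec$eyes_per_condition)) {
    for (ci in seq_len(nrow(conds))) {
      for (rep_i in seq_len(spec$repetitions)) {
        counter <- counter + 1L
        rec_seed <- derive_seed(spec$seed, counter)
        iop <- conds$iop_mmHg[ci]
        k <- (spec$k_of_iop[1] + spec$k_of_iop[2] * iop) * eye_factor[eye]
        if (spec$design == "cxl") {
          stage <- conds$stage[ci]
          cc <- spec$c_of_stage[[stage]]
          cct <- spec$cct_of_stage[[stage]]
        } else {
          stage <- NA_character_
          cc <- spec$c_damp
          cct <- spec$baseline_cct
        }
        ph <- phantom_spec(kv = kv_params(k, cc), baseline_cct = cct,
                           speckle_contrast = spec$speckle_contrast,
                           seed = rec_seed)
        x <- simulate_eye_response(force, ph)
        truth <- list(
          k = k, c = cc, mad = max(x$x),
          cct_bef = cct,
          cct_max = cct * (1 - ph$compression_fraction),
          cct_aft = cct,
          compression_fraction = ph$compression_fraction,
          group_index = ph$group_index,
          anterior_depth = ph$anterior_depth,
          x = x, force = force
        )
        m <- if (render)
          render_mscan(x, ph, axial_pitch = spec$axial_pitch,
                       depth_px = spec$depth_px)
        else NULL
        records[[counter]] <- list(
          eye_id = eye, phase = conds$phase[ci], iop_mmHg = iop,
          stage = stage, repetition = rep_i, seed = rec_seed,
          mscan = m, pressure = pressure, truth = truth
        )
      }
    }
  }
  structure(list(spec = spec, conditions = conds, records = records),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> design %s: %d records (%d conditions x %d eyes x %d reps)\n",
              x$spec$design, length(x$records), nrow(x$conditions),
              x$spec$eyes_per_condition, x$spec$repetitions))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One directory per record containing the M-scan TIFF + JSON sidecar (when
#' rendered), the pressure trace CSV, and the ground-truth record as JSON
#' (traces included, so downstream recovery checks can run file-based).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    rd <- file.path(dir, sprintf("record_%04d", i))
    dir.create(rd, showWarnings = FALSE)
    if (!is.null(rec$mscan)) write_mscan(rec$mscan, file.path(rd, "mscan.tiff"))
    write_trace_csv(rec$pressure, file.path(rd, "pressure.csv"))
    truth <- rec$truth
    truth$x <- as.data.frame(truth$x)
    truth$force <- as.data.frame(truth$force)
    meta <- rec[c("eye_id", "phase", "iop_mmHg", "stage", "repetition", "seed")]
    jsonlite::write_json(c(meta, truth), file.path(rd, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}
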