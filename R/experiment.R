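# Orchestration of the two synthetic study designs and the study statistics.

# Full single-record pipeline: segment -> displacement -> CCT -> calibrate ->
# metrics. With use_truth = TRUE the ground-truth traces bypass rendering and
# segmentation (truth CCTs are reported directly).
process_record <- function(record, calibration, seg_params = list(),
                           use_truth = FALSE) {
  force <- pressure_to_force(record$pressure, calibration)
  delay <- NULL
  if (use_truth || is.null(record$mscan)) {
    x <- record$truth$x
    cct <- structure(list(cct_bef = record$truth$cct_bef,
                          cct_max = record$truth$cct_max,
                          cct_aft = record$truth$cct_aft,
                          group_index = record$truth$group_index),
                     class = "cct_triplet")
  } else {
    m <- record$mscan
    s <- segment_surfaces(m, seg_params)
    # baseline = columns acquired before the force departs from zero
    onset <- which(force$force > 1e-6 * max(force$force))[1]
    bw <- seq_len(max(10L, onset - 1L))
    x <- displacement_from_surfaces(s, m, baseline_window = bw)
    cct <- cct_at_instants(s, x, group_index = record$truth$group_index)
  }
  compute_all_metrics(x, force, cct)
}

metric_units <- c(
  mad_um = "um", ha_j = "J", hr_pct = "%", s_sec_n_per_m = "N/m",
  s_low_n_per_m = "N/m", s_high_n_per_m = "N/m", loading_energy_j = "J",
  cct_bef_um = "um", cct_max_um = "um", cct_aft_um = "um",
  mad_over_cct = "1"
)

# Long-format rows for one processed record.
record_rows <- function(record, metrics) {
  df <- as.data.frame(metrics)
  df$mad_over_cct <- df$mad_um / df$cct_bef_um
  vals <- unlist(df[1, ])
  data.frame(
    eye_id = record$eye_id,
    condition = if (is.na(record$stage)) record$iop_mmHg else record$stage,
    iop_mmHg = record$iop_mmHg, phase = record$phase, stage = record$stage,
    repetition = record$repetition,
    metric_name = names(vals), value = as.numeric(vals),
    units = unname(metric_units[names(vals)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

run_experiment <- function(cohort, calibration, seg_params, use_truth) {
  rows <- vector("list", length(cohort$records))
  failures <- list()
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    res <- tryCatch(process_record(rec, calibration, seg_params, use_truth),
                    corneapuff_error = function(e) e)
    if (inherits(res, "condition")) {
      failures[[length(failures) + 1L]] <- data.frame(
        record = i, eye_id = rec$eye_id, iop_mmHg = rec$iop_mmHg,
        stage = rec$stage, phase = rec$phase, repetition = rec$repetition,
        reason = conditionMessage(res), stringsAsFactors = FALSE
      )
    } else {
      rows[[i]] <- record_rows(rec, res)
    }
  }
  results <- do.call(rbind, rows)
  failures <- if (length(failures)) do.call(rbind, failures) else NULL
  list(results = results, failures = failures)
}

# mean/SD/n per (condition, phase, metric)
summarize_results <- function(results) {
  key <- paste(results$condition, results$phase, results$metric_name,
               sep = "\r")
  parts <- split(results, key)
  out <- do.call(rbind, lapply(parts, function(d) data.frame(
    condition = d$condition[1], phase = d$phase[1],
    metric_name = d$metric_name[1], units = d$units[1],
    mean = mean(d$value, na.rm = TRUE), sd = stats::sd(d$value, na.rm = TRUE),
    n = sum(!is.na(d$value)), stringsAsFactors = FALSE
  )))
  rownames(out) <- NULL
  out[order(out$metric_name, out$phase, out$condition), ]
}

#' Run the cyclic IOP inflation experiment on a synthetic cohort
#'
#' Simulates, renders, segments, calibrates and extracts the hysteresis
#' descriptors for every eye at each IOP level of an ascending-then-
#' descending inflation cycle, then summarizes each metric per level and
#' reports its Pearson correlation with IOP. Per-record failures are logged,
#' not fatal.
#'
#' @param spec An inflation-design [cohort_spec()].
#' @param calibration A `calibration_model` (default [default_calibration()]).
#' @param seg_params Parameters passed to [segment_surfaces()].
#' @param use_truth If TRUE, compute metrics from the ground-truth traces
#'   instead of rendered M-scans (fast; exercises no segmentation).
#' @return An object of class `experiment_result`: `results` (long-format
#'   data.frame: eye_id, condition, iop_mmHg, phase, stage, repetition,
#'   metric_name, value, units), `summary`, `correlations` (Pearson R of
#'   each metric vs IOP), `failures`, and `provenance` (design + seed).
#' @export
run_inflation_experiment <- function(spec, calibration = default_calibration(),
                                     seg_params = list(), use_truth = FALSE) {
  if (spec$design != "inflation")
    cp_stop("corneapuff_invalid_spec", "spec must have design = 'inflation'")
  cohort <- generate_cohort(spec, render = !use_truth)
  ex <- run_experiment(cohort, calibration, seg_params, use_truth)
  cors <- vapply(split(ex$results, ex$results$metric_name), function(d) {
    if (stats::sd(d$value, na.rm = TRUE) == 0 || sum(!is.na(d$value)) < 3)
      return(NA_real_)
    ok <- !is.na(d$value)
    pearson_r(d$iop_mmHg[ok], d$value[ok])
  }, numeric(1))
  structure(list(results = ex$results, summary = summarize_results(ex$results),
                 correlations = cors, failures = ex$failures,
                 provenance = list(design = "inflation", seed = spec$seed)),
            class = "experiment_result")
}

#' Run the corneal cross-linking (CXL) experiment on a synthetic cohort
#'
#' Measures every eye at the three CXL stages (EPI_OFF, RS, RS_UV) under each
#' IOP level, extracts the descriptor set including the CCT-corrected MAD
#' (`mad_over_cct = MAD / CCT_bef`), and runs two-sample t tests between
#' consecutive stages for each metric and IOP level. Eye identity is kept in
#' the long table so paired re-analysis remains possible.
#'
#' @param spec A cxl-design [cohort_spec()].
#' @inheritParams run_inflation_experiment
#' @return An `experiment_result` with an additional `stage_tests`
#'   data.frame (metric, iop_mmHg, comparison, t, df, p).
#' @export
run_cxl_experiment <- function(spec, calibration = default_calibration(),
                               seg_params = list(), use_truth = FALSE) {
  if (spec$design != "cxl")
    cp_stop("corneapuff_invalid_spec", "spec must have design = 'cxl'")
  cohort <- generate_cohort(spec, render = !use_truth)
  ex <- run_experiment(cohort, calibration, seg_params, use_truth)
  res <- ex$results
  comparisons <- list(c("EPI_OFF", "RS"), c("RS", "RS_UV"),
                      c("EPI_OFF", "RS_UV"))
  tests <- list()
  for (mn in unique(res$metric_name)) {
    for (iop in unique(res$iop_mmHg)) {
      for (cmp in comparisons) {
        a <- res$value[res$metric_name == mn & res$iop_mmHg == iop &
                         res$stage == cmp[1]]
        b <- res$value[res$metric_name == mn & res$iop_mmHg == iop &
                         res$stage == cmp[2]]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L) next
        tt <- tryCatch(two_sample_ttest(a, b),
                       corneapuff_error = function(e) NULL)
        if (is.null(tt)) next
        tests[[length(tests) + 1L]] <- data.frame(
          metric_name = mn, iop_mmHg = iop,
          comparison = paste(cmp, collapse = " vs "),
          t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(results = res, summary = summarize_results(res),
                 stage_tests = if (length(tests)) do.call(rbind, tests) else NULL,
                 failures = ex$failures,
                 provenance = list(design = "cxl", seed = spec$seed)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s design, %d metric rows, %d failures\n",
              x$provenance$design, nrow(x$results),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  invisible(x)
}

#' Write experiment result tables as CSV
#'
#' Emits `results.csv` (long format) and `summary.csv` (mean/SD/n per
#' condition and metric) into `dir`; byte-identical across runs with the
#' same spec and seed.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if missing).
#' @export
write_experiment_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$results, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Pooled two-sample Student's t test
#'
#' Classical equal-variance two-sample t statistic with two-sided p value,
#' the test used for between-condition comparisons throughout the analysis
#' (significance at alpha = 0.05).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return A list with `t`, `df` and `p`.
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p = 0.0213
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    cp_stop("corneapuff_invalid_spec", "each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
  tt <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                 error = function(e)
                   cp_stop("corneapuff_undefined_statistic",
                           "pooled variance is zero"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Pearson correlation coefficient
#'
#' Sample Pearson R with the precondition checks used across the pipeline:
#' equal lengths of at least 3 and nonzero variance in both variables.
#'
#' @param a,b Numeric vectors.
#' @return Pearson R in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    cp_stop("corneapuff_invalid_spec", "need equal lengths >= 3")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    cp_stop("corneapuff_undefined_correlation",
            "zero variance; correlation undefined")
  stats::cor(a, b)
}
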