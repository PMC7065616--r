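test_that("cohort conditions follow the ascending/descending cycle without duplicating the top level", {
  spec <- cohort_spec("inflation", eyes_per_condition = 1, repetitions = 1)
  cohort <- generate_cohort(spec, render = FALSE)
  expect_length(cohort$records, 13L)   # 7 ascending + 6 descending
  iops <- vapply(cohort$records, `[[`, numeric(1), "iop_mmHg")
  expect_equal(iops, c(seq(5, 35, 5), seq(30, 5, -5)))
  # CXL arm size: 3 stages x 2 IOPs per eye; 13 eyes x 5 reps = 390 records
  small <- generate_cohort(cohort_spec("cxl", eyes_per_condition = 2,
                                       repetitions = 1), render = FALSE)
  expect_length(small$records, 12L)
  expect_identical(nrow(small$conditions) * 13L * 5L, 390L)
})

test_that("seeded cohorts are reproducible and truth MAD decreases with stiffness", {
  spec <- cohort_spec("inflation", eyes_per_condition = 2, repetitions = 1,
                      seed = 9)
  c1 <- generate_cohort(spec, render = FALSE)
  c2 <- generate_cohort(spec, render = FALSE)
  mads1 <- vapply(c1$records, function(r) r$truth$mad, numeric(1))
  mads2 <- vapply(c2$records, function(r) r$truth$mad, numeric(1))
  expect_identical(mads1, mads2)
  # within one eye, ascending k (IOP) implies strictly decreasing true MAD
  asc1 <- vapply(c1$records, function(r)
    r$eye_id == 1 && identical(r$phase, "ascending"), logical(1))
  expect_true(all(diff(mads1[asc1]) < 0))
})

test_that("inflation experiment reproduces the IOP trends on noiseless phantoms", {
  spec <- cohort_spec("inflation", eyes_per_condition = 2, repetitions = 1,
                      speckle_contrast = 0, eye_cv = 0.02, seed = 3)
  res <- run_inflation_experiment(spec)
  expect_null(res$failures)
  expect_lt(res$correlations[["mad_um"]], -0.95)   # MAD falls with IOP
  expect_gt(res$correlations[["s_sec_n_per_m"]], 0.95)  # stiffer with IOP
  # HA and MAD are driven by the same response: nearly perfect coupling
  wide <- res$results
  ha <- wide$value[wide$metric_name == "ha_j"]
  mad <- wide$value[wide$metric_name == "mad_um"]
  expect_gt(pearson_r(ha, mad), 0.99)
  # memoryless phantom: ascending and descending level means coincide
  sm <- res$summary
  m_asc <- sm[sm$metric_name == "mad_um" & sm$phase == "ascending", ]
  m_desc <- sm[sm$metric_name == "mad_um" & sm$phase == "descending", ]
  shared <- intersect(m_asc$condition, m_desc$condition)
  a <- m_asc$mean[match(shared, m_asc$condition)]
  d <- m_desc$mean[match(shared, m_desc$condition)]
  expect_equal(a, d, tolerance = 0.01)
})

test_that("pipeline metrics from rendered M-scans track ground-truth metrics", {
  spec <- cohort_spec("inflation", iop_levels = c(10, 25),
                      eyes_per_condition = 1, repetitions = 1, seed = 5)
  res_img <- run_inflation_experiment(spec)                 # default speckle
  res_truth <- run_inflation_experiment(spec, use_truth = TRUE)
  for (metric in c("mad_um", "ha_j")) {
    vi <- res_img$results$value[res_img$results$metric_name == metric]
    vt <- res_truth$results$value[res_truth$results$metric_name == metric]
    tol <- if (metric == "mad_um") 0.01 else 0.03
    expect_equal(vi, vt, tolerance = tol)
  }
})

test_that("CXL experiment recovers the programmed thickness reduction and ratio behavior", {
  spec <- cohort_spec("cxl", eyes_per_condition = 3, repetitions = 2,
                      speckle_contrast = 0, eye_cv = 0.02, seed = 13)
  res <- run_cxl_experiment(spec)
  expect_null(res$failures)
  sm <- res$summary
  cct <- function(stage) mean(sm$mean[sm$metric_name == "cct_bef_um" &
                                        sm$condition == stage])
  reduction <- 100 * (1 - cct("RS_UV") / cct("EPI_OFF"))
  expect_equal(reduction, 36, tolerance = 0.01)   # 900 -> 576 um programmed
  # CCT-corrected MAD rises when CCT drops faster than MAD
  ratio <- function(stage) mean(sm$mean[sm$metric_name == "mad_over_cct" &
                                          sm$condition == stage])
  expect_gt(ratio("RS_UV"), ratio("EPI_OFF"))
  expect_true(!is.null(res$stage_tests))
  expect_true(all(res$stage_tests$p >= 0 & res$stage_tests$p <= 1))
})

test_that("experiment CSVs are byte-identical across reruns of the same seed", {
  spec <- cohort_spec("inflation", iop_levels = c(10, 20, 30),
                      eyes_per_condition = 1, repetitions = 1, seed = 17)
  d1 <- file.path(withr::local_tempdir(), "run1")
  d2 <- file.path(withr::local_tempdir(), "run2")
  write_experiment_csv(run_inflation_experiment(spec, use_truth = TRUE), d1)
  write_experiment_csv(run_inflation_experiment(spec, use_truth = TRUE), d2)
  for (fn in c("results.csv", "summary.csv")) {
    b1 <- readBin(file.path(d1, fn), "raw", file.size(file.path(d1, fn)))
    b2 <- readBin(file.path(d2, fn), "raw", file.size(file.path(d2, fn)))
    expect_identical(b1, b2)
  }
})

test_that("cohorts round-trip to disk with ground truth alongside", {
  spec <- cohort_spec("inflation", iop_levels = c(15, 25),
                      eyes_per_condition = 1, repetitions = 1, seed = 23)
  cohort <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  recs <- list.files(dir, pattern = "^record_")
  expect_length(recs, 3L)   # 2 ascending + 1 descending
  truth <- jsonlite::read_json(file.path(dir, recs[1], "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$mad, cohort$records[[1]]$truth$mad)
  expect_true(file.exists(file.path(dir, recs[1], "mscan.tiff")))
  p <- read_trace_csv(file.path(dir, recs[1], "pressure.csv"))
  expect_equal(max(p$value), 18.18, tolerance = 1e-3)
})

test_that("pooled t test and Pearson R match hand-computed references", {
  tt <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0213, tolerance = 1e-3)
  expect_identical(two_sample_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_error(two_sample_ttest(1, c(2, 3)), class = "corneapuff_invalid_spec")
  expect_error(two_sample_ttest(c(2, 2), c(3, 3)),
               class = "corneapuff_undefined_statistic")

  a <- c(1, 2, 3)
  expect_equal(pearson_r(a, 2 * a + 1), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(pearson_r(a, c(1, 2, 4)), 0.9820, tolerance = 1e-4)
  expect_error(pearson_r(a, c(5, 5, 5)),
               class = "corneapuff_undefined_correlation")
  expect_error(pearson_r(c(1, 2), c(3, 4)), class = "corneapuff_invalid_spec")
})
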