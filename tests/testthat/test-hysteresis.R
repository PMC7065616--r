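test_that("identical clocks pair without interpolation and split at the argmax", {
  n <- 1600
  t <- (0:(n - 1)) / 5e4
  xx <- c(seq(0, 1000, length.out = 800), seq(1000, 0, length.out = 800))
  ff <- 1e-4 * xx
  h <- build_hysteresis(displacement_trace(t, xx), force_trace(t, ff))
  expect_equal(h$F, ff)
  expect_identical(h$split_index, 800L)
  expect_equal(h$mad, 1000)
})

test_that("force at twice the displacement rate resamples by exact linear interpolation", {
  tx <- seq(0, 0.01, by = 2e-4)
  tf <- seq(-0.001, 0.011, by = 1e-4)
  ff <- 3 + 2 * tf                      # piecewise-linear (in fact linear)
  xx <- c(seq(0, 1, length.out = 25), seq(1, 0.1, length.out = 26))
  h <- build_hysteresis(displacement_trace(tx, xx), force_trace(tf, ff))
  expect_equal(h$F, 3 + 2 * tx, tolerance = 1e-12)
  # non-overlapping clocks
  expect_error(
    build_hysteresis(displacement_trace(tx + 10, xx), force_trace(tf, ff)),
    class = "corneapuff_alignment"
  )
})

test_that("the worked analytic loop yields HA = 2e-5 J and HR = 33.33%", {
  h <- analytic_loop(10000)
  expect_equal(loading_energy(h), 6e-5, tolerance = 1e-6)
  expect_equal(hysteresis_area(h), 2e-5, tolerance = 1e-4)
  expect_equal(hysteresis_ratio(h), 100 / 3, tolerance = 1e-4)
})

test_that("a reversible loop dissipates nothing and zero unloading force dissipates everything", {
  n <- 400
  xx <- c(seq(0, 500, length.out = n), seq(500, 0, length.out = n)[-1])
  ff <- 2e-4 * xx
  t <- seq_along(xx) * 1e-4
  h <- build_hysteresis(displacement_trace(t, xx), force_trace(t, ff))
  expect_equal(hysteresis_area(h), 0, tolerance = 1e-15)
  expect_equal(hysteresis_ratio(h), 0, tolerance = 1e-10)
  ff2 <- ff
  ff2[n:length(ff2)] <- 0
  h2 <- build_hysteresis(displacement_trace(t, xx), force_trace(t, ff2))
  expect_equal(hysteresis_ratio(h2), 100, tolerance = 1e-9)
})

test_that("shoelace area equals the phase-integral difference on monotone loops", {
  withr::with_seed(7, {
    for (i in 1:200) {
      h <- random_monotone_loop()
      a <- hysteresis_area(h)
      b <- eq1_area(h)
      expect_equal(a, b, tolerance = 1e-9)
    }
  })
})

test_that("Kelvin-Voigt loops dissipate per the sinusoidal closed form", {
  k <- 120; cc <- 0.15; w <- 2 * pi * 50; F0 <- 0.1
  t <- seq(0, 0.4, by = 1 / 50000)
  f <- force_trace(t, F0 * sin(w * t))
  x <- kv_response(f, kv_params(k, cc))
  late <- t >= 0.38 - 1e-12              # exactly one late cycle
  hx <- displacement_trace(t[late] - t[late][1], x$x[late] - min(x$x[late]) + 1)
  hf <- force_trace(t[late] - t[late][1], f$force[late])
  h <- build_hysteresis(hx, hf)
  X <- F0 / sqrt(k^2 + (cc * w)^2)
  expect_equal(hysteresis_area(h), pi * cc * w * X^2, tolerance = 0.01)
})

test_that("secant slope handles linear, quadratic and constant loading", {
  n <- 2001
  xx <- c(seq(0, 1000, length.out = n), seq(1000, 0, length.out = n)[-1])
  t <- seq_along(xx) * 1e-5
  lin <- build_hysteresis(displacement_trace(t, xx),
                          force_trace(t, 100 * xx * 1e-6))
  expect_equal(secant_slope(lin), 100, tolerance = 1e-9)
  a <- 5e4  # F = a x^2 with x in meters
  quad <- build_hysteresis(displacement_trace(t, xx),
                           force_trace(t, a * (xx * 1e-6)^2))
  expect_equal(secant_slope(quad), 1.1 * a * 1000e-6, tolerance = 1e-4)
  const <- build_hysteresis(displacement_trace(t, xx),
                            force_trace(t, rep(0.05, length(xx))))
  expect_equal(secant_slope(const), 0, tolerance = 1e-12)
})

test_that("window slopes recover the bilinear segments and order on a J-curve", {
  h <- bilinear_loop(s1 = 44, s2 = 82, mad = 1000, x_break = 500)
  expect_equal(low_strain_slope(h), 44, tolerance = 1e-6)
  expect_equal(high_strain_slope(h), 82, tolerance = 1e-6)
  expect_equal(secant_slope(h),
               (44 * 500 + 82 * 500 - 44 * 100) * 1e-6 / (900e-6),
               tolerance = 1e-6)
  # exponential J-curve: convexity orders the slopes
  n <- 2001
  xx <- c(seq(0, 1000, length.out = n), seq(1000, 0, length.out = n)[-1])
  t <- seq_along(xx) * 1e-5
  fj <- 0.01 * (exp(3e3 * xx * 1e-6) - 1)
  hj <- build_hysteresis(displacement_trace(t, xx), force_trace(t, fj))
  expect_gt(high_strain_slope(hj), low_strain_slope(hj))
  expect_gt(secant_slope(hj), low_strain_slope(hj))
  expect_lt(secant_slope(hj), high_strain_slope(hj))
})

test_that("slope windows that exceed the loading span raise classed errors", {
  n <- 301
  xx <- c(seq(0, 130, length.out = n), seq(130, 0, length.out = n)[-1])
  t <- seq_along(xx) * 1e-5
  h <- build_hysteresis(displacement_trace(t, xx),
                        force_trace(t, 100 * xx * 1e-6))
  # x10 = 13 um, window [13, 133] exceeds MAD = 130 um
  expect_error(low_strain_slope(h), class = "corneapuff_insufficient_window")
  # loading span 130 um >= 120 um: the high-strain window still fits
  expect_equal(high_strain_slope(h), 100, tolerance = 1e-9)
  xx2 <- c(seq(0, 100, length.out = n), seq(100, 0, length.out = n)[-1])
  h2 <- build_hysteresis(displacement_trace(t, xx2),
                         force_trace(t, 100 * xx2 * 1e-6))
  expect_error(high_strain_slope(h2), class = "corneapuff_insufficient_window")
  expect_error(hysteresis_area(build_hysteresis(
    displacement_trace(c(0, 1e-3, 2e-3), c(0, 5, 1)),
    force_trace(c(0, 1e-3, 2e-3), c(0, 0.1, 0)))),
    class = "corneapuff_insufficient_data")
})

test_that("area scales linearly with displacement (unit-coherence metamorphic)", {
  withr::with_seed(99, {
    h <- random_monotone_loop()
    h2 <- h
    h2$x <- h$x * 1000
    h2$mad <- h$mad * 1000
    expect_equal(hysteresis_area(h2), 1000 * hysteresis_area(h),
                 tolerance = 1e-12)
    # HR is scale-free in x
    expect_equal(hysteresis_ratio(h2), hysteresis_ratio(h), tolerance = 1e-9)
  })
})

test_that("compute_all_metrics populates, flags and reproduces deterministically", {
  rec <- make_phantom_record(seed = 41)
  s <- segment_surfaces(rec$mscan)
  x <- displacement_from_surfaces(s, rec$mscan, baseline_window = rec$baseline)
  cct <- cct_at_instants(s, x)
  m1 <- compute_all_metrics(x, rec$force, cct)
  for (fld in c("mad", "ha", "hr", "s_sec", "s_low", "s_high",
                "cct_bef", "cct_max", "cct_aft"))
    expect_true(is.finite(m1[[fld]]), info = fld)
  expect_equal(m1$hr, 100 * m1$ha / m1$loading_energy, tolerance = 1e-9)
  expect_true(m1$hr >= 0 && m1$hr <= 100)
  # without a CCT triplet the thickness fields are flagged, the rest valid
  m2 <- compute_all_metrics(x, rec$force)
  expect_true(is.na(m2$cct_bef))
  expect_true("cct" %in% names(m2$flags))
  expect_equal(m2$ha, m1$ha)
  # deterministic: same seeded record twice
  rec2 <- make_phantom_record(seed = 41)
  s2 <- segment_surfaces(rec2$mscan)
  x2 <- displacement_from_surfaces(s2, rec2$mscan, baseline_window = rec2$baseline)
  m3 <- compute_all_metrics(x2, rec2$force, cct_at_instants(s2, x2))
  expect_identical(as.data.frame(m1), as.data.frame(m3))
})

test_that("loop CSV export writes the documented two-column schema", {
  h <- analytic_loop(200)
  path <- file.path(withr::local_tempdir(), "loop.csv")
  write_hysteresis_csv(h, path)
  df <- utils::read.csv(path)
  expect_named(df, c("x_um", "F_N"))
  expect_equal(nrow(df), length(h$x))
})
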