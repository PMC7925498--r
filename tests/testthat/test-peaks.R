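test_that("CSV traces read and validate", {
  tr <- dplyr::bind_rows(
    gaussian_trace(id = "a"),
    gaussian_trace(apex = 18, id = "b"),
    gaussian_trace(apex = 22, id = "c")
  )
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tr, tmp)
  got <- read_traces(tmp)
  expect_s3_class(got, "sq_traces")
  expect_equal(dplyr::n_distinct(got$transition_id), 3)
  expect_equal(got$intensity, tr$intensity)

  # empty file errors
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_traces(empty), "empty")

  # non-monotone time errors
  bad <- tr
  bad$time_min[2] <- bad$time_min[1]
  readr::write_csv(bad, tmp)
  expect_error(read_traces(tmp), "non-monotone")
})

test_that("a single Gaussian is detected at its apex", {
  tr <- gaussian_trace(apex = 20.5, sigma = 0.1, area = 1e5 * 0.1 * sqrt(2 * pi))
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$apex_rt_min - 20.5), 0.02)
  expect_gt(pk$snr, 3)
})

test_that("flat traces yield no peaks", {
  t <- seq(0, 10, by = 0.01)
  flat <- tibble::tibble(transition_id = "z", time_min = t,
                         intensity = rep(0, length(t)))
  expect_equal(nrow(detect_peaks(flat)), 0)
})

test_that("two separated Gaussians are both detected", {
  tr <- tibble::tibble(
    transition_id = "ab",
    time_min = seq(10, 30, by = 0.01),
    intensity = 1e5 * stats::dnorm(seq(10, 30, by = 0.01), 18, 0.1) +
      5e4 * stats::dnorm(seq(10, 30, by = 0.01), 20, 0.1)
  )
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(round(pk$apex_rt_min, 1)), c(18, 20))
})

test_that("trapezoidal integration matches closed forms", {
  # Gaussian: area A*sigma*sqrt(2*pi) within 1%
  A <- 1e5
  sigma <- 0.1
  tr <- gaussian_trace(apex = 20, sigma = sigma, area = A * sigma * sqrt(2 * pi))
  got <- integrate_peak(tr, 19, 21, baseline = FALSE)
  expect_lt(abs(got - A * sigma * sqrt(2 * pi)) / (A * sigma * sqrt(2 * pi)),
            0.01)
  # zero trace integrates to zero
  z <- tibble::tibble(time_min = seq(0, 5, 0.01),
                      intensity = rep(0, 501))
  expect_equal(integrate_peak(z, 1, 4), 0)
  # rectangle: h * w exactly (trapezoid on a constant)
  t <- seq(0, 10, by = 0.01)
  rect <- tibble::tibble(
    time_min = t,
    intensity = ifelse(t >= 4 & t <= 6, 1000, 0)
  )
  expect_equal(integrate_peak(rect, 4, 6, baseline = FALSE), 1000 * 2)
  # bounds outside the span error
  expect_error(integrate_peak(z, -1, 4), "span")
})

test_that("area is translation-invariant and scales linearly", {
  base <- gaussian_trace(apex = 18, sigma = 0.12, area = 4e4)
  shifted <- base
  shifted$time_min <- shifted$time_min + 3
  a0 <- integrate_peak(base, 17, 19)
  expect_equal(integrate_peak(shifted, 20, 22), a0, tolerance = 1e-10)
  scaled <- base
  scaled$intensity <- scaled$intensity * 7
  expect_equal(integrate_peak(scaled, 17, 19), 7 * a0, tolerance = 1e-10)
})

test_that("peaks assign to panel analytes by retention-time window", {
  p <- sq_reference_panel()
  tr <- gaussian_trace(apex = 20.5, id = "792 (ISD):quantifier",
                       from = 16, to = 25)
  pk <- detect_peaks(tr)
  asn <- assign_peaks(pk, p, rt_tolerance_min = 0.5)
  expect_true(asn$assigned[1])
  expect_equal(asn$analyte[1], "792 (ISD)")
  expect_equal(asn$role[1], "quantifier")

  # peak far from the panel retention time stays unassigned
  far <- gaussian_trace(apex = 24.8, id = "792 (ISD):quantifier",
                        from = 20, to = 30)
  asn2 <- assign_peaks(detect_peaks(far), p, rt_tolerance_min = 0.5)
  expect_false(any(asn2$assigned))
  expect_equal(asn2$flag[1], "outside_window")

  # screening-only analyte (no panel Rt) is skipped with a flag
  scr <- gaussian_trace(apex = 15, id = "867:quantifier", from = 10, to = 20)
  asn3 <- assign_peaks(detect_peaks(scr), p)
  expect_false(any(asn3$assigned))
  expect_equal(asn3$flag[1], "no_panel_rt")

  # two peaks in the window: larger area wins, flagged
  two <- tibble::tibble(
    transition_id = "792 (ISD):quantifier",
    time_min = seq(18, 23, by = 0.01),
    intensity = 1e5 * stats::dnorm(seq(18, 23, by = 0.01), 20.3, 0.05) +
      5e4 * stats::dnorm(seq(18, 23, by = 0.01), 20.7, 0.05)
  )
  asn4 <- assign_peaks(detect_peaks(two), p)
  expect_equal(sum(asn4$assigned), 1)
  expect_equal(asn4$flag[asn4$assigned], "multiple_peaks_in_window")
  expect_equal(asn4$apex_rt_min[asn4$assigned], 20.3, tolerance = 0.03)
})

test_that("SRM channel ids resolve through the panel", {
  p <- sq_reference_panel()
  got <- sqmrm:::resolve_channel("SRM SIC Q1=815.4 Q3=80.9", p)
  expect_equal(got$analyte, "815")
  expect_equal(got$role, "quantifier")
})
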