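panel_subset <- function(analytes) {
  p <- sq_reference_panel()
  sqmrm:::new_sq_panel(p[p$analyte %in% analytes, ])
}

test_that("simulated runs are reproducible for a fixed seed", {
  p <- panel_subset(c("792 (ISD)", "815"))
  a <- simulate_run(p, c("815" = 5), area_noise_cv = 0.05,
                    baseline_noise_sd = 20, seed = 123)
  b <- simulate_run(p, c("815" = 5), area_noise_cv = 0.05,
                    baseline_noise_sd = 20, seed = 123)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- simulate_run(p, c("815" = 5), area_noise_cv = 0.05,
                    baseline_noise_sd = 20, seed = 124)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("zero-noise areas match the configured ground truth within 1%", {
  p <- panel_subset(c("792 (ISD)", "815", "817", "555"))
  conc <- c("815" = 5, "817" = 2, "555" = 8)
  tr <- simulate_run(p, conc, seed = 1)
  truth <- attr(tr, "truth")
  pk <- detect_peaks(tr)
  asn <- assign_peaks(pk, p)
  asn <- asn[asn$assigned, ]
  expect_equal(nrow(asn), nrow(truth[truth$area_counts > 0, ]))
  merged <- dplyr::inner_join(asn, truth, by = c("analyte", "role"))
  expect_true(all(
    abs(merged$area_counts.x - merged$area_counts.y) /
      merged$area_counts.y < 0.01
  ))
})

test_that("zero concentration gives no peak on the analyte's channels", {
  p <- panel_subset(c("792 (ISD)", "815", "817"))
  tr <- simulate_run(p, c("815" = 5), seed = 1)
  ch817 <- tr[tr$transition_id == "817:quantifier", ]
  expect_equal(max(ch817$intensity), 0)
})

test_that("analytes without retention time are skipped with a warning", {
  p <- panel_subset(c("792 (ISD)", "867"))
  expect_warning(tr <- simulate_run(p, c("867" = 5), seed = 1), "867")
  expect_false(any(grepl("^867", unique(tr$transition_id))))
})

test_that("simulated traces round-trip through CSV and mzML readers", {
  p <- panel_subset(c("792 (ISD)", "815"))
  tr <- simulate_run(p, c("815" = 5), baseline_noise_sd = 10, seed = 42)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_traces(tr, csv)
  back <- read_traces(csv)
  expect_equal(dplyr::n_distinct(back$transition_id), 6)
  expect_equal(back$intensity, tr$intensity, tolerance = 1e-12)

  skip_if_not_installed("mzR")
  skip_if_not_installed("xml2")
  mzml <- withr::local_tempfile(fileext = ".mzML")
  write_traces(tr, mzml, format = "mzml", panel = p)
  back2 <- read_traces(mzml)
  expect_equal(dplyr::n_distinct(back2$transition_id),
               dplyr::n_distinct(tr$transition_id))
  # channels resolve back to the same analytes/roles
  res <- sqmrm:::resolve_channel(unique(back2$transition_id), p)
  expect_setequal(paste(res$analyte, res$role),
                  paste(c("792 (ISD)", "815"),
                        rep(c("quantifier", "qualifier1", "qualifier2"),
                            each = 2)))
  # intensities survive the binary encoding
  isd <- back2[grepl("Q1=792", back2$transition_id) &
                 grepl("Q3=96", back2$transition_id), ]
  orig <- tr[tr$transition_id == "792 (ISD):quantifier", ]
  expect_equal(isd$intensity, orig$intensity, tolerance = 1e-12)
  expect_equal(isd$time_min, orig$time_min, tolerance = 1e-9)
})

test_that("simulated calibration reproduces the reference design", {
  lv <- simulate_calibration(seed = 1)
  expect_equal(nrow(lv), 10)
  expect_equal(lv$conc, as.numeric(1:10))
  cal <- fit_calibration(lv)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$slope, 0.33, tolerance = 1e-9)
  expect_error(simulate_calibration(n_levels = 2), "3 levels")
  expect_error(simulate_calibration(c_min = 10, c_max = 1), "below")
})

test_that("validation-study noise produces the configured precision", {
  # noiseless: CV exactly 0
  v0 <- simulate_validation_study(qc_levels = 5, n_days = 1, noise_cv = 0,
                                  seed = 1)
  expect_equal(cv_percent(v0$response), 0)

  # day effect dominates: inter-day CV exceeds intra-day CV
  vd <- simulate_validation_study(qc_levels = 5, replicates_per_day = 5,
                                  n_days = 3, noise_cv = 0.005,
                                  day_effect_cv = 0.1, seed = 2)
  rep_v <- validate_method(vd)
  expect_gt(rep_v$inter_day_cv, rep_v$intra_day_cv)

  expect_error(simulate_validation_study(replicates_per_day = 1), "2 replicates")
})

test_that("mean intra-day CV is calibrated to the noise level", {
  # 200 seeded repetitions at 5% multiplicative noise: the mean sample-CV
  # estimate (n = 5) sits between 4% and 6%
  cvs <- vapply(1:200, function(s) {
    v <- simulate_validation_study(qc_levels = 5, replicates_per_day = 5,
                                   n_days = 1, noise_cv = 0.05, seed = s)
    cv_percent(v$response)
  }, numeric(1))
  expect_gt(mean(cvs), 4)
  expect_lt(mean(cvs), 6)
})

test_that("full round trip recovers concentrations within 5% above LOQ", {
  p <- panel_subset(c("792 (ISD)", "815", "817", "555", "791"))
  truth_conc <- c("815" = 6, "817" = 3, "555" = 9, "791" = 2)

  # calibration runs at the 10 reference levels, 1% area noise
  run_response <- function(conc_815, seed) {
    tr <- simulate_run(p, c("815" = conc_815), area_noise_cv = 0.01,
                       seed = seed)
    resp <- quantifier_responses(assign_peaks(detect_peaks(tr), p), p)
    resp$areas$area[resp$areas$analyte == "815"] / resp$isd_area
  }
  lv <- tibble::tibble(
    conc = as.numeric(1:10),
    response = vapply(1:10, function(i) run_response(i, 100 + i), numeric(1))
  )
  cal <- fit_calibration(lv)

  # sample run at known concentrations, quantified on that curve
  tr <- simulate_run(p, truth_conc, area_noise_cv = 0.01, seed = 77)
  resp <- quantifier_responses(assign_peaks(detect_peaks(tr), p), p)
  q <- quantify(resp$areas, cal, isd_area = resp$isd_area)
  q <- q[q$conc_ug_ml >= cal$loq_ug_ml, ]
  expect_gt(nrow(q), 0)
  rel_err <- abs(q$conc_ug_ml - truth_conc[q$analyte]) / truth_conc[q$analyte]
  expect_true(all(rel_err < 0.05))
})
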