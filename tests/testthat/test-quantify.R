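test_that("recovery follows the spike formula and is affine-invariant", {
  expect_equal(recovery(15, 5, 10), 100)
  expect_equal(recovery(13.3, 5, 10), 83)
  expect_equal(recovery(5, 5, 10), 0)
  expect_error(recovery(5, 5, 0), "positive")
  # affine invariance under common rescaling
  for (k in c(0.1, 2, 17)) {
    expect_equal(recovery(13.3 * k, 5 * k, 10 * k), recovery(13.3, 5, 10),
                 tolerance = 1e-12)
  }
})

test_that("CV uses the sample SD and is scale-invariant", {
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  expect_equal(cv_percent(rep(1, 6)), 0)
  expect_error(cv_percent(5), "2 replicates")
  set.seed(1)
  x <- rlnorm(20)
  for (k in c(0.5, 3, 1e4)) {
    expect_equal(cv_percent(k * x), cv_percent(x), tolerance = 1e-10)
  }
})

test_that("inverse calibration reproduces nominal concentrations", {
  lv <- tibble::tibble(conc = 1:10, response = 0.33 * (1:10) + 0.02)
  cal <- fit_calibration(lv)
  q <- quantify(
    tibble::tibble(analyte = paste0("a", 1:10), response = lv$response),
    cal
  )
  expect_equal(q$conc_ug_ml, as.numeric(1:10), tolerance = 1e-9)
  # single point: response at 5 ug/mL back-calculates to 5
  q5 <- quantify(
    tibble::tibble(analyte = "815", response = cal$slope * 5 + cal$intercept),
    cal
  )
  expect_equal(q5$conc_ug_ml, 5, tolerance = 1e-12)
})

test_that("dry-weight content applies volume, dilution and mass", {
  cal <- fit_calibration(
    tibble::tibble(conc = 1:10, response = 0.33 * (1:10))
  )
  q <- quantify(
    tibble::tibble(analyte = "815", response = 0.33 * 5),
    cal,
    dilution_factor = 10, extract_volume_ml = 1, sample_mass_g = 0.5
  )
  # 5 ug/mL * 1 mL * 10 / 0.5 g = 100 ug/g = 0.1 mg/g
  expect_equal(q$content_mg_g, 0.1, tolerance = 1e-12)
  expect_equal(q$share_percent, 100)
  expect_error(quantify(q, cal, sample_mass_g = 0), "positive")
})

test_that("responses below the curve floor at zero with flags", {
  lv <- simulate_calibration(noise_cv = 0.05, seed = 5)
  cal <- fit_calibration(lv)
  q <- quantify(
    tibble::tibble(analyte = c("lo", "hi"),
                   response = c(cal$intercept - 0.01, cal$slope * 8)),
    cal
  )
  expect_equal(q$conc_ug_ml[1], 0)
  expect_equal(q$flag[1], "<LOD")
  expect_equal(q$flag[2], "")
  expect_true(is.na(q$share_percent[1]))
})

test_that("composition shares normalise to 100", {
  sh <- composition_shares(c(A = 2, B = 1, C = 1))
  expect_equal(sh$share_percent, c(50, 25, 25))
  expect_equal(sum(sh$share_percent), 100)
  eq <- composition_shares(c(a = 3, b = 3, c = 3, d = 3))
  expect_equal(eq$share_percent, rep(25, 4))
  expect_error(composition_shares(c(A = 0, B = 0)), "zero")
  # arbitrary positive contents renormalise to a 100% total
  set.seed(2)
  v <- stats::runif(9, 0.1, 60)
  names(v) <- paste0("s", 1:9)
  expect_equal(sum(composition_shares(v)$share_percent), 100,
               tolerance = 1e-9)
})

test_that("quantification shares sum to 100 over quantifiable analytes", {
  cal <- fit_calibration(
    tibble::tibble(conc = 1:10, response = 0.33 * (1:10))
  )
  q <- quantify(
    tibble::tibble(analyte = c("a", "b", "c"),
                   response = 0.33 * c(2, 3, 5)),
    cal
  )
  expect_equal(sum(q$share_percent), 100, tolerance = 0.01)
  expect_equal(attr(q, "total_content_mg_g") * 1000,
               sum(q$conc_ug_ml), tolerance = 1e-9)
})

test_that("validation statistics flag imprecise levels", {
  qc <- tibble::tibble(
    qc_level = rep(5, 6), day = rep(1, 6), replicate = 1:6,
    response = rep(1.65, 6)
  )
  v <- validate_method(qc)
  expect_equal(v$intra_day_cv, 0)
  expect_true(v$pass)

  qc2 <- tibble::tibble(
    qc_level = rep(5, 3), day = rep(1, 3), replicate = 1:3,
    response = c(1, 2, 3)
  )
  v2 <- validate_method(qc2)
  expect_equal(v2$intra_day_cv, 50)
  expect_false(v2$pass)

  # CV just above the threshold fails, just below passes
  mk <- function(cv) {
    m <- 1
    s <- cv / 100 * m
    # two replicates with mean m and sample SD s
    tibble::tibble(qc_level = 5, day = 1, replicate = 1:2,
                   response = c(m - s / sqrt(2), m + s / sqrt(2)))
  }
  expect_false(validate_method(mk(16))$pass)
  expect_true(validate_method(mk(14))$pass)

  # single replicate errors
  expect_error(
    validate_method(tibble::tibble(qc_level = 5, day = 1, replicate = 1,
                                   response = 1)),
    ">= 2 replicates"
  )
})

test_that("accuracy is back-calculated against nominal", {
  cal <- fit_calibration(
    tibble::tibble(conc = 1:10, response = 0.33 * (1:10))
  )
  qc <- tibble::tibble(
    qc_level = rep(4, 4), day = rep(1:2, each = 2), replicate = rep(1:2, 2),
    response = 0.33 * 4 * c(1.02, 0.98, 1.02, 0.98)
  )
  v <- validate_method(qc, cal)
  expect_equal(v$accuracy_percent, 100, tolerance = 1e-9)
  expect_equal(v$n_days, 2)
  expect_false(is.na(v$inter_day_cv))
})
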