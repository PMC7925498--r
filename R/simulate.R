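# Seeded simulator of MRM runs, calibration series, and QC validation
# studies with ground truth, emulating the study design the toolkit
# quantifies: Gaussian peaks at panel retention times, areas proportional
# to concentration, multiplicative (lognormal) area noise, additive
# baseline noise, and an internal standard at constant concentration.

# mean-one lognormal multiplier with exact coefficient of variation `cv`
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog)) / exp(sdlog^2 / 2)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate an MRM run over a transition panel
#'
#' One trace per transition of every analyte with a panel retention time
#' (screening-only analytes are skipped with a warning): a Gaussian peak at
#' the panel retention time (plus optional jitter), with quantifier area =
#' `response_factor` × concentration, qualifier areas at fixed fractions of
#' the quantifier, multiplicative lognormal area noise, and additive
#' baseline noise (clamped at zero). The internal standard is simulated at
#' `isd_conc`. The ground truth (per-transition noiseless areas and
#' retention times) is attached as attribute `"truth"`.
#'
#' @param panel an `sq_panel` tibble.
#' @param true_conc named numeric vector, analyte → concentration (µg/mL).
#'   Analytes absent from the vector get concentration 0 (no peak).
#' @param isd_conc internal-standard concentration, µg/mL (default 5).
#' @param response_factor area counts per (µg/mL); scalar or named per
#'   analyte. Default 2e4 (ISD at 5 µg/mL integrates to 1e5 counts).
#' @param qualifier_ratios areas of qualifier1/qualifier2 relative to the
#'   quantifier (default 0.4 and 0.2).
#' @param peak_sigma_min Gaussian peak width (SD) in minutes (default 0.15).
#' @param rt_jitter_sd_min SD of per-analyte retention-time jitter.
#' @param area_noise_cv coefficient of variation of multiplicative area
#'   noise.
#' @param baseline_noise_sd SD of additive baseline noise in counts.
#' @param sampling_interval_min sampling interval (default 0.01 min).
#' @param run_length_min run length (default 52 min, the full LC program:
#'   gradient, 34-min hold, and re-equilibration).
#' @param seed integer seed; the RNG state is restored afterwards.
#' @return An `sq_traces` tibble with attribute `"truth"`.
#' @examples
#' panel <- sq_reference_panel()
#' tr <- simulate_run(panel, c("815" = 5), seed = 1)
#' @export
simulate_run <- function(panel, true_conc = numeric(), isd_conc = 5,
                         response_factor = 2e4,
                         qualifier_ratios = c(qualifier1 = 0.4,
                                              qualifier2 = 0.2),
                         peak_sigma_min = 0.15, rt_jitter_sd_min = 0,
                         area_noise_cv = 0, baseline_noise_sd = 0,
                         sampling_interval_min = 0.01, run_length_min = 52,
                         seed = NULL) {
  stopifnot(sampling_interval_min > 0, peak_sigma_min > 0,
            rt_jitter_sd_min >= 0, area_noise_cv >= 0, baseline_noise_sd >= 0)
  rts <- panel$rt_min[!is.na(panel$rt_min)]
  if (length(rts) && (max(rts) + 4 * peak_sigma_min) > run_length_min) {
    stop("run_length_min does not cover all panel retention times",
         call. = FALSE)
  }
  with_seed(seed, {
    analytes <- dplyr::distinct(
      tibble::as_tibble(panel)[c("analyte", "class", "rt_min")]
    )
    no_rt <- analytes$analyte[is.na(analytes$rt_min)]
    if (length(no_rt)) {
      warning("skipping analytes without retention time: ",
              paste(no_rt, collapse = ", "), call. = FALSE)
      analytes <- analytes[!is.na(analytes$rt_min), ]
    }
    grid <- seq(0, run_length_min, by = sampling_interval_min)
    ratios <- c(quantifier = 1, qualifier_ratios)
    rf <- function(a) {
      if (length(response_factor) == 1L && is.null(names(response_factor))) {
        response_factor
      } else {
        unname(response_factor[a])
      }
    }
    conc_of <- function(a, cls) {
      if (cls == "ISD") isd_conc
      else if (a %in% names(true_conc)) unname(true_conc[a])
      else 0
    }
    truth <- list()
    traces <- purrr::map_dfr(seq_len(nrow(analytes)), function(i) {
      a <- analytes$analyte[i]
      conc <- conc_of(a, analytes$class[i])
      rt <- analytes$rt_min[i] + stats::rnorm(1, 0, rt_jitter_sd_min)
      purrr::map_dfr(names(ratios), function(role) {
        area <- rf(a) * conc * ratios[[role]]
        noisy_area <- area * lognormal_noise(1, area_noise_cv)
        y <- if (noisy_area > 0) {
          noisy_area * stats::dnorm(grid, rt, peak_sigma_min)
        } else {
          rep(0, length(grid))
        }
        if (baseline_noise_sd > 0) {
          y <- y + stats::rnorm(length(grid), 0, baseline_noise_sd)
        }
        truth[[length(truth) + 1L]] <<- tibble::tibble(
          analyte = a, role = role, conc_ug_ml = conc, rt_min = rt,
          area_counts = noisy_area
        )
        tibble::tibble(
          transition_id = paste0(a, ":", role),
          time_min = grid,
          intensity = pmax(y, 0)
        )
      })
    })
    out <- new_sq_traces(traces)
    attr(out, "truth") <- dplyr::bind_rows(truth)
    out
  })
}

#' Simulate an internal-standard calibration series
#'
#' Equidistant concentration levels between `c_min` and `c_max` (the
#' reference design: 10 points, 1–10 µg/mL, ISD constant at 5 µg/mL).
#' Analyte areas are `response_factor × conc × isd_area`, ISD areas are
#' constant, each perturbed by mean-one lognormal noise of the given CV,
#' so the fitted response-vs-concentration slope estimates
#' `response_factor`.
#'
#' @param n_levels number of levels (≥ 3; default 10).
#' @param c_min,c_max concentration range, µg/mL (default 1–10).
#' @param isd_conc ISD concentration, µg/mL (default 5; recorded in truth).
#' @param response_factor true response per (µg/mL) (default 0.33).
#' @param noise_cv multiplicative noise CV on each area.
#' @param isd_area mean ISD area in counts (default 1e5).
#' @param seed integer seed.
#' @return Tibble of levels: `conc`, `analyte_area`, `isd_area`,
#'   `response`; attribute `"truth"` holds the generating parameters.
#' @examples
#' simulate_calibration(noise_cv = 0, seed = 1)
#' @export
simulate_calibration <- function(n_levels = 10, c_min = 1, c_max = 10,
                                 isd_conc = 5, response_factor = 0.33,
                                 noise_cv = 0, isd_area = 1e5, seed = NULL) {
  if (n_levels < 3) stop("calibration needs at least 3 levels", call. = FALSE)
  if (c_min >= c_max) stop("c_min must be below c_max", call. = FALSE)
  with_seed(seed, {
    conc <- seq(c_min, c_max, length.out = n_levels)
    isd <- isd_area * lognormal_noise(n_levels, noise_cv)
    analyte <- response_factor * conc * isd_area *
      lognormal_noise(n_levels, noise_cv)
    out <- tibble::tibble(
      conc = conc,
      analyte_area = analyte,
      isd_area = isd,
      response = analyte / isd
    )
    attr(out, "truth") <- list(
      response_factor = response_factor, isd_conc = isd_conc,
      noise_cv = noise_cv
    )
    out
  })
}

#' Simulate a QC validation study
#'
#' Replicate QC responses per level, day, and replicate with a
#' multiplicative day effect (lognormal, CV `day_effect_cv`) shared by all
#' replicates of a day and independent within-day noise (CV `noise_cv`),
#' the design used for intra-/inter-day precision assessment.
#'
#' @param qc_levels QC nominal concentrations, µg/mL (default 2, 4, 6, 8).
#' @param replicates_per_day replicates per level per day (≥ 2; default 5).
#' @param n_days number of days (default 3).
#' @param noise_cv within-day multiplicative noise CV (default 0.05).
#' @param day_effect_cv between-day multiplicative effect CV (default 0).
#' @param response_factor true response per (µg/mL) (default 0.33).
#' @param seed integer seed.
#' @return Tibble of QC runs: `qc_level`, `day`, `replicate`, `response`,
#'   `true_response`.
#' @examples
#' simulate_validation_study(qc_levels = 5, n_days = 1, seed = 1)
#' @export
simulate_validation_study <- function(qc_levels = c(2, 4, 6, 8),
                                      replicates_per_day = 5, n_days = 3,
                                      noise_cv = 0.05, day_effect_cv = 0,
                                      response_factor = 0.33, seed = NULL) {
  if (replicates_per_day < 2) {
    stop("need at least 2 replicates per day", call. = FALSE)
  }
  with_seed(seed, {
    design <- tidyr::expand_grid(
      qc_level = qc_levels,
      day = seq_len(n_days),
      replicate = seq_len(replicates_per_day)
    )
    day_eff <- tidyr::expand_grid(qc_level = qc_levels, day = seq_len(n_days))
    day_eff$effect <- lognormal_noise(nrow(day_eff), day_effect_cv)
    design <- dplyr::left_join(design, day_eff, by = c("qc_level", "day"))
    design$true_response <- response_factor * design$qc_level
    design$response <- design$true_response * design$effect *
      lognormal_noise(nrow(design), noise_cv)
    design$effect <- NULL
    design
  })
}
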