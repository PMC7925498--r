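# Concentration back-calculation, dry-weight content, composition shares,
# recovery, and FDA-style method-validation statistics.

#' Spike recovery rate
#'
#' RE = (c_sample − c_endogenous) · 100 / c_spiked, the fraction of a known
#' spike recovered from a matrix after sample preparation. Affine under
#' common rescaling of all three concentrations.
#'
#' @param c_sample measured concentration of the spiked sample.
#' @param c_endogen endogenous (unspiked) concentration.
#' @param c_spiked nominal spiked concentration (> 0). All three share a
#'   unit.
#' @return Recovery in percent (vectorised).
#' @examples
#' recovery(13.3, 5, 10)  # 83 %
#' @export
recovery <- function(c_sample, c_endogen, c_spiked) {
  if (any(c_spiked <= 0)) {
    stop("c_spiked must be positive", call. = FALSE)
  }
  (c_sample - c_endogen) * 100 / c_spiked
}

#' Coefficient of variation
#'
#' Sample standard deviation (n−1 denominator) divided by the mean, in
#' percent. Scale-invariant: `cv(k * x) == cv(x)` for `k > 0`.
#'
#' @param x numeric vector (≥ 2 values).
#' @return CV in percent.
#' @examples
#' cv_percent(c(1, 2, 3))  # 50
#' @export
cv_percent <- function(x) {
  if (length(x) < 2L) {
    stop("CV needs at least 2 replicates", call. = FALSE)
  }
  stats::sd(x) / mean(x) * 100
}

#' Back-calculate concentrations and dry-weight contents
#'
#' Inverse calibration of ISD-normalised responses: concentration =
#' (response − intercept) / slope, floored at zero. Content per dry weight
#' is concentration × extract volume × dilution factor / sample mass.
#' Composition shares are computed over the analytes at or above the LOQ.
#'
#' @param areas tibble with `analyte` and `area` (quantifier peak areas),
#'   or `analyte` and `response` (already ISD-normalised).
#' @param curve an `sq_calibration` object. Analytes without their own
#'   authentic standard are quantified on this surrogate curve.
#' @param isd_area internal-standard quantifier area (required with
#'   `area` input).
#' @param dilution_factor fold dilution of the extract before injection.
#' @param extract_volume_ml extract volume in mL.
#' @param sample_mass_g dry sample mass in g (> 0).
#' @return An `sq_quant` tibble: `analyte`, `response`, `conc_ug_ml`,
#'   `content_mg_g`, `share_percent` (NA below LOQ), `flag`
#'   (`""`, `"<LOQ"`, `"<LOD"`), plus attributes `total_content_mg_g`
#'   (total over analytes ≥ LOQ) and `calibration` (`"surrogate"`).
#' @examples
#' lv <- tibble::tibble(conc = 1:10, response = 0.33 * (1:10))
#' cal <- fit_calibration(lv)
#' quantify(tibble::tibble(analyte = "815", response = 0.33 * 5), cal)
#' @export
quantify <- function(areas, curve, isd_area = NULL, dilution_factor = 1,
                     extract_volume_ml = 1, sample_mass_g = 1) {
  stopifnot(inherits(curve, "sq_calibration"))
  if (sample_mass_g <= 0) stop("sample_mass_g must be positive", call. = FALSE)
  areas <- tibble::as_tibble(areas)
  if (!"response" %in% names(areas)) {
    if (is.null(isd_area) || isd_area <= 0) {
      stop("area input requires a positive isd_area", call. = FALSE)
    }
    areas$response <- areas$area / isd_area
  }
  conc <- (areas$response - curve$intercept) / curve$slope
  flag <- rep("", nrow(areas))
  flag[conc < curve$loq_ug_ml] <- "<LOQ"
  flag[conc < curve$lod_ug_ml] <- "<LOD"
  conc <- pmax(conc, 0)
  # ug/mL * mL * dilution / g = ug/g; report mg/g
  content <- conc * extract_volume_ml * dilution_factor / sample_mass_g / 1000
  quantifiable <- flag == ""
  total <- sum(content[quantifiable])
  share <- rep(NA_real_, nrow(areas))
  if (total > 0) share[quantifiable] <- content[quantifiable] / total * 100
  out <- tibble::tibble(
    analyte = areas$analyte,
    response = areas$response,
    conc_ug_ml = conc,
    content_mg_g = content,
    share_percent = share,
    flag = flag
  )
  attr(out, "total_content_mg_g") <- total
  attr(out, "calibration") <- "surrogate"
  class(out) <- c("sq_quant", class(out))
  out
}

#' Composition shares of total sulfolipid content
#'
#' Each analyte's content as a percentage of the summed content; shares
#' sum to 100.
#'
#' @param contents named numeric vector (analyte → content) or tibble with
#'   `analyte` and `content` columns.
#' @return Tibble with `analyte`, `content`, `share_percent`.
#' @examples
#' composition_shares(c(A = 2, B = 1, C = 1))
#' @export
composition_shares <- function(contents) {
  if (is.data.frame(contents)) {
    analyte <- contents$analyte
    content <- contents$content
  } else {
    analyte <- names(contents)
    content <- unname(contents)
  }
  if (any(content < 0)) stop("contents must be non-negative", call. = FALSE)
  total <- sum(content)
  if (total <= 0) stop("total content is zero", call. = FALSE)
  tibble::tibble(
    analyte = analyte,
    content = content,
    share_percent = content / total * 100
  )
}

#' Method-validation statistics
#'
#' Per QC level: intra-day precision (mean over days of the within-day
#' replicate CV), inter-day precision (CV pooled over all replicates of
#' all days), and, when a calibration curve is supplied, accuracy as mean
#' back-calculated concentration over nominal in percent. A level passes
#' when both CVs are below the threshold (FDA bioanalytical guidance:
#' 15%).
#'
#' @param qc tibble of QC runs: `qc_level` (nominal concentration, µg/mL),
#'   `day`, `replicate`, `response`.
#' @param curve optional `sq_calibration` for accuracy.
#' @param cv_threshold precision acceptance bound in percent (default 15).
#' @return An `sq_validation` tibble: one row per QC level with
#'   `qc_level`, `n_days`, `n_total`, `intra_day_cv`, `inter_day_cv`,
#'   `accuracy_percent`, `pass`.
#' @export
validate_method <- function(qc, curve = NULL, cv_threshold = 15) {
  qc <- tibble::as_tibble(qc)
  stopifnot(all(c("qc_level", "day", "replicate", "response") %in% names(qc)))
  per_day <- qc |>
    dplyr::group_by(.data$qc_level, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      cv = {
        if (dplyr::n() < 2L) {
          stop("intra-day CV needs >= 2 replicates per day", call. = FALSE)
        }
        cv_percent(.data$response)
      },
      .groups = "drop"
    )
  out <- qc |>
    dplyr::group_by(.data$qc_level) |>
    dplyr::summarise(
      n_days = dplyr::n_distinct(.data$day),
      n_total = dplyr::n(),
      inter_day_cv = if (dplyr::n_distinct(.data$day) >= 2L) {
        cv_percent(.data$response)
      } else {
        NA_real_
      },
      accuracy_percent = if (!is.null(curve)) {
        mean((.data$response - curve$intercept) / curve$slope) /
          .data$qc_level[1] * 100
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(per_day, .data$qc_level),
                       intra_day_cv = mean(.data$cv), .groups = "drop"),
      by = "qc_level"
    ) |>
    dplyr::mutate(
      pass = .data$intra_day_cv < cv_threshold &
        (is.na(.data$inter_day_cv) | .data$inter_day_cv < cv_threshold)
    ) |>
    dplyr::select(
      "qc_level", "n_days", "n_total", "intra_day_cv", "inter_day_cv",
      "accuracy_percent", "pass"
    )
  attr(out, "cv_threshold") <- cv_threshold
  class(out) <- c("sq_validation", class(out))
  out
}
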