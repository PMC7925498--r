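# Peak detection, trapezoidal integration, and retention-time assignment
# on MRM traces.
#
# The pipeline per channel: moving-average smoothing, rolling-minimum
# baseline, local-maximum search above a signal-to-noise threshold,
# boundary placement at the nearest valley or 1% of apex height, and
# trapezoidal integration of the baseline-subtracted signal. Deterministic
# for fixed input.

# centred moving average; width 1 = off
smooth_ma <- function(y, width) {
  if (width <= 1L) return(y)
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  out <- as.numeric(stats::filter(y, rep(1 / width, width), sides = 2))
  out[is.na(out)] <- y[is.na(out)]  # edges keep raw values
  out
}

# rolling-minimum baseline over a time window (minutes)
rolling_min_baseline <- function(y, time_min, window_min) {
  n <- length(y)
  dt <- stats::median(diff(time_min))
  k <- max(1L, as.integer(round(window_min / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= n) return(rep(min(y), n))
  zoo::rollapply(y, k, min, partial = TRUE, align = "center")
}

# robust noise scale of the baseline-corrected signal
noise_mad <- function(signal) {
  stats::mad(signal, center = stats::median(signal))
}

#' Detect chromatographic peaks
#'
#' Local maxima of the smoothed, baseline-subtracted signal above a
#' signal-to-noise threshold. The noise scale is the median absolute
#' deviation of the baseline-corrected trace (so a noise-free peak has
#' effectively infinite SNR); boundaries extend to the nearest valley or
#' to where the signal falls below 1% of the apex height.
#'
#' @param traces an `sq_traces` tibble (any number of channels) or a data
#'   frame with `time_min` and `intensity` for a single channel.
#' @param min_snr minimum apex signal-to-noise ratio (default 3).
#' @param min_width_min minimum peak width in minutes (default 0.02).
#' @param smooth_width moving-average width in points (default 5; 1 = off).
#' @param baseline_window_min rolling-minimum window in minutes (default 2).
#' @return Tibble with columns `transition_id`, `apex_rt_min`,
#'   `left_rt_min`, `right_rt_min`, `height_counts`, `area_counts`, `snr`.
#' @export
detect_peaks <- function(traces, min_snr = 3, min_width_min = 0.02,
                         smooth_width = 5, baseline_window_min = 2) {
  if (!"transition_id" %in% names(traces)) {
    traces <- tibble::tibble(
      transition_id = "trace", time_min = traces$time_min,
      intensity = traces$intensity
    )
  }
  traces |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$transition_id) |>
    dplyr::group_modify(~ detect_peaks_one(
      .x$time_min, .x$intensity, min_snr, min_width_min,
      smooth_width, baseline_window_min
    )) |>
    dplyr::ungroup()
}

detect_peaks_one <- function(time_min, intensity, min_snr, min_width_min,
                             smooth_width, baseline_window_min) {
  empty <- tibble::tibble(
    apex_rt_min = numeric(), left_rt_min = numeric(),
    right_rt_min = numeric(), height_counts = numeric(),
    area_counts = numeric(), snr = numeric()
  )
  n <- length(time_min)
  if (n < 5L) stop("trace needs at least 5 points", call. = FALSE)
  y <- smooth_ma(intensity, smooth_width)
  base <- rolling_min_baseline(y, time_min, baseline_window_min)
  sig <- y - base
  noise <- noise_mad(sig)
  if (max(sig) <= 0) return(empty)
  # interior local maxima (plateaus resolved to their first point)
  is_max <- sig >= dplyr::lag(sig, default = -Inf) &
    sig > dplyr::lead(sig, default = -Inf) & sig > 0
  apexes <- which(is_max)
  snr <- sig[apexes] / max(noise, .Machine$double.xmin)
  apexes <- apexes[snr >= min_snr]
  if (length(apexes) == 0L) return(empty)
  peaks <- purrr::map_dfr(apexes, function(a) {
    floor_level <- 0.01 * sig[a]
    l <- a
    while (l > 1L && sig[l - 1L] <= sig[l] && sig[l - 1L] > floor_level) {
      l <- l - 1L
    }
    r <- a
    while (r < n && sig[r + 1L] <= sig[r] && sig[r + 1L] > floor_level) {
      r <- r + 1L
    }
    # include the floor-crossing point unless the walk stopped at a valley
    if (l > 1L && sig[l - 1L] <= sig[l]) l <- l - 1L
    if (r < n && sig[r + 1L] <= sig[r]) r <- r + 1L
    tibble::tibble(
      apex_rt_min = time_min[a],
      left_rt_min = time_min[l],
      right_rt_min = time_min[r],
      height_counts = sig[a],
      area_counts = trapezoid(time_min[l:r], sig[l:r]),
      snr = sig[a] / max(noise, .Machine$double.xmin)
    )
  })
  # a shared boundary means the maxima belong to one structure: keep both
  # only if separated by a genuine valley
  peaks[peaks$right_rt_min - peaks$left_rt_min >= min_width_min, ]
}

trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Integrate a trace between retention-time bounds
#'
#' Trapezoidal integral of the baseline-subtracted intensity over
#' `[left, right]`. The baseline is the same rolling minimum used by
#' [detect_peaks()]; set `baseline_window_min = Inf` to subtract the
#' global minimum, or `baseline = FALSE` to integrate the raw signal.
#'
#' @param trace single-channel data frame with `time_min`, `intensity`.
#' @param left,right integration bounds in minutes (within the trace span).
#' @param baseline subtract the rolling-minimum baseline first?
#' @param baseline_window_min rolling-minimum window in minutes.
#' @return Area in counts·min.
#' @export
integrate_peak <- function(trace, left, right, baseline = TRUE,
                           baseline_window_min = 2) {
  stopifnot(left < right)
  t <- trace$time_min
  y <- trace$intensity
  if (left < min(t) || right > max(t)) {
    stop("integration bounds outside trace span", call. = FALSE)
  }
  if (baseline) {
    y <- y - rolling_min_baseline(y, t, baseline_window_min)
  }
  keep <- t >= left & t <= right
  trapezoid(t[keep], y[keep])
}

#' Assign detected peaks to panel analytes
#'
#' A peak is assigned to its channel's analyte when the apex lies within
#' `rt_tolerance_min` of the panel retention time. Channels whose analyte
#' has no panel retention time (screening-only entries) are skipped and
#' flagged; when several peaks fall in one window the largest area wins
#' and the assignment is flagged.
#'
#' @param peaks peak tibble from [detect_peaks()] (with `transition_id`).
#' @param panel an `sq_panel` tibble.
#' @param rt_tolerance_min retention-time tolerance in minutes (default 0.5).
#' @return Tibble with `analyte`, `role`, `apex_rt_min`, `area_counts`,
#'   `height_counts`, `snr`, `assigned` (logical), `flag`
#'   (`""`, `"no_panel_rt"`, `"multiple_peaks_in_window"`, or
#'   `"outside_window"`).
#' @export
assign_peaks <- function(peaks, panel, rt_tolerance_min = 0.5) {
  stopifnot(rt_tolerance_min > 0)
  chan <- resolve_channel(unique(peaks$transition_id), panel)
  out <- purrr::map_dfr(seq_len(nrow(chan)), function(i) {
    pk <- peaks[peaks$transition_id == chan$transition_id[i], ]
    if (nrow(pk) == 0L) return(NULL)
    analyte <- chan$analyte[i]
    role <- chan$role[i]
    base <- tibble::tibble(
      analyte = analyte, role = role,
      apex_rt_min = pk$apex_rt_min, area_counts = pk$area_counts,
      height_counts = pk$height_counts, snr = pk$snr,
      assigned = FALSE, flag = ""
    )
    if (is.na(analyte)) {
      base$analyte <- chan$transition_id[i]
      base$flag <- "unresolved_channel"
      return(base)
    }
    rt <- panel$rt_min[panel$analyte == analyte][1]
    if (is.na(rt)) {
      base$flag <- "no_panel_rt"
      return(base)
    }
    inside <- abs(base$apex_rt_min - rt) <= rt_tolerance_min
    base$flag[!inside] <- "outside_window"
    if (sum(inside) > 1L) {
      win <- which(inside)
      best <- win[which.max(base$area_counts[win])]
      base$assigned[best] <- TRUE
      base$flag[best] <- "multiple_peaks_in_window"
    } else if (sum(inside) == 1L) {
      base$assigned[inside] <- TRUE
    }
    base
  })
  out
}

#' Extract quantifier responses from assigned peaks
#'
#' Convenience step between [assign_peaks()] and [quantify()]: keeps the
#' assigned quantifier peak per analyte and normalises areas to the
#' internal-standard quantifier area.
#'
#' @param assigned output of [assign_peaks()].
#' @param panel an `sq_panel` tibble (identifies the ISD analyte).
#' @return List with `areas` (tibble `analyte`, `area`) for the sulfolipid
#'   analytes and `isd_area` (scalar).
#' @export
quantifier_responses <- function(assigned, panel) {
  q <- assigned[assigned$role == "quantifier" & assigned$assigned, ]
  isd_name <- unique(panel$analyte[panel$class == "ISD"])
  isd_area <- q$area_counts[q$analyte %in% isd_name]
  if (length(isd_area) != 1L) {
    stop("expected exactly one assigned ISD quantifier peak, found ",
         length(isd_area), call. = FALSE)
  }
  list(
    areas = tibble::tibble(
      analyte = q$analyte[!q$analyte %in% isd_name],
      area = q$area_counts[!q$analyte %in% isd_name]
    ),
    isd_area = isd_area
  )
}
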