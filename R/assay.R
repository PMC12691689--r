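#' Initial-rate slope of an A340 trace
#'
#' Ordinary least-squares slope of absorbance against time over an initial
#' window. With `window = "auto"` the longest initial window (prefix of the
#' trace, minimum 3 points) whose linear fit reaches `r2_min` is used, so that
#' curvature from substrate depletion or NADH exhaustion is excluded while as
#' many clean points as possible enter the regression. If no prefix reaches
#' `r2_min`, the minimal 3-point window is used and its (poor) r-squared is
#' reported. A constant trace fits a flat line perfectly (slope 0,
#' r-squared 1).
#'
#' @param time_min Strictly increasing times, minutes.
#' @param a340 Absorbance readings, same length as `time_min`.
#' @param window `"auto"`, `"all"`, or an integer vector of length 2 giving an
#'   index range.
#' @param r2_min Fit-quality threshold for the automatic window (default 0.99).
#' @return One-row tibble: `slope_a340_min`, `r_squared`, `window_start`,
#'   `window_end`, `n_points`.
#' @examples
#' t <- 0:10
#' fit_initial_slope(t, 1 - 0.0388 * t)
#' @export
fit_initial_slope <- function(time_min, a340, window = "auto", r2_min = 0.99) {
  if (length(time_min) != length(a340)) {
    abort_invalid("time_min and a340 must have the same length.")
  }
  if (length(time_min) < 3L) {
    abort_insufficient("At least 3 points are required for slope fitting.")
  }
  if (any(diff(time_min) <= 0)) {
    abort_invalid("time_min must be strictly increasing.")
  }
  n <- length(time_min)

  ols <- function(idx) {
    t <- time_min[idx]; y <- a340[idx]
    tc <- t - mean(t); yc <- y - mean(y)
    sst <- sum(yc^2)
    slope <- sum(tc * yc) / sum(tc^2)
    sse <- sum((yc - slope * tc)^2)
    r2 <- if (sst < 1e-20) 1 else 1 - sse / sst
    list(slope = slope, r2 = r2)
  }

  if (identical(window, "auto")) {
    win <- c(1L, 3L)
    fit <- ols(1:3)
    for (k in n:3) {            # longest prefix first
      f <- ols(1:k)
      if (f$r2 >= r2_min) {
        win <- c(1L, k)
        fit <- f
        break
      }
    }
  } else if (identical(window, "all")) {
    win <- c(1L, n)
    fit <- ols(1:n)
  } else if (is.numeric(window) && length(window) == 2L) {
    win <- as.integer(window)
    if (win[1] < 1L || win[2] > n || diff(win) < 2L) {
      abort_insufficient("The window must lie inside the trace and span >= 3 points.")
    }
    fit <- ols(win[1]:win[2])
  } else {
    abort_invalid('window must be "auto", "all", or an index range of length 2.')
  }

  tibble(
    slope_a340_min = fit$slope,
    r_squared = fit$r2,
    window_start = win[1],
    window_end = win[2],
    n_points = win[2] - win[1] + 1L
  )
}

#' Remove the minus-myokinase background slope
#'
#' The coupled assay converts AMP released by alarmone synthesis into NADH
#' oxidation; a matched reaction omitting myokinase reports NADH consumption
#' by ADP-producing side activities only. Subtracting the background slope
#' isolates the synthesis signal. A positive net slope (absorbance rising
#' after correction) means no synthesis signal and raises a warning.
#'
#' @param slope_full Slope (A340/min) of the complete coupled reaction.
#' @param slope_minus_myokinase Slope (A340/min) of the matched background
#'   reaction.
#' @return Net slope (A340/min), vectorised.
#' @examples
#' subtract_background(-0.0488, -0.0100)
#' @export
subtract_background <- function(slope_full, slope_minus_myokinase) {
  net <- slope_full - slope_minus_myokinase
  if (any(net > 0)) {
    warn("Net slope is positive after background subtraction: no synthesis signal.")
  }
  net
}

#' Convert a net A340 slope to a synthesis velocity
#'
#' NADH oxidation tracks product formation through the extinction coefficient
#' `epsilon_per_mM` (A340 per mM product; default 3.88, an opaque calibration
#' constant of the coupled assay). Synthesis consumes NADH, so valid signals
#' have negative net slopes; any positive net slope maps to velocity 0 rather
#' than a negative rate. The dilution factor of the enzyme sample rescales
#' the in-well velocity back to sample activity.
#'
#' @param net_slope Background-corrected slope, A340/min (vectorised).
#' @param epsilon_per_mM Extinction coefficient, A340 per mM product, > 0.
#' @param dilution_factor Sample dilution factor, >= 1.
#' @return Velocity in uM/min, floored at 0.
#' @examples
#' slope_to_velocity(-0.0388)            # 10 uM/min
#' slope_to_velocity(-0.0388, dilution_factor = 100)
#' @export
slope_to_velocity <- function(net_slope, epsilon_per_mM = 3.88,
                              dilution_factor = 1) {
  if (!is.numeric(epsilon_per_mM) || any(epsilon_per_mM <= 0)) {
    abort_invalid("epsilon_per_mM must be positive.")
  }
  if (any(dilution_factor < 1)) {
    abort_invalid("dilution_factor must be >= 1.")
  }
  pmax(0, -net_slope) / epsilon_per_mM * 1000 * dilution_factor
}

#' Reduce a table of coupled-assay traces to synthesis velocities
#'
#' Takes long-format plate-reader data (one row per reading), fits an
#' initial-rate slope per well, pairs each complete reaction with the
#' minus-myokinase background well declared under the same `condition_id`,
#' subtracts the background, and converts the net slope to a velocity in
#' uM/min. Pairing is by explicit condition declaration, never by plate
#' position. A condition without a background well is reduced uncorrected and
#' flagged.
#'
#' @param traces Data frame with columns `well_id`, `time_min`, `a340`,
#'   `has_myokinase` (logical or 0/1), `dilution_factor`, `condition_id`.
#' @param window,r2_min Passed to [fit_initial_slope()].
#' @param epsilon_per_mM Passed to [slope_to_velocity()].
#' @return A tibble with one row per complete-reaction well: slopes, fit
#'   quality, net slope, `velocity_uM_min`, and flags `background_corrected`
#'   and `no_signal`.
#' @export
reduce_traces <- function(traces, window = "auto", epsilon_per_mM = 3.88,
                          r2_min = 0.99) {
  required <- c("well_id", "time_min", "a340", "has_myokinase",
                "dilution_factor", "condition_id")
  miss <- setdiff(required, names(traces))
  if (length(miss)) {
    abort_invalid(paste0("traces is missing columns: ",
                         paste(miss, collapse = ", "), "."))
  }
  traces <- as_tibble(traces) |>
    mutate(has_myokinase = as.logical(.data$has_myokinase))

  per_well <- traces |>
    arrange(.data$well_id, .data$time_min) |>
    group_by(.data$condition_id, .data$well_id,
             .data$has_myokinase, .data$dilution_factor) |>
    tidyr::nest() |>
    ungroup() |>
    mutate(fit = purrr::map(.data$data, function(d) {
      fit_initial_slope(d$time_min, d$a340, window = window, r2_min = r2_min)
    })) |>
    select(-"data") |>
    tidyr::unnest("fit")

  bg <- per_well |>
    filter(!.data$has_myokinase) |>
    select("condition_id", well_id_background = "well_id",
           slope_background = "slope_a340_min",
           r2_background = "r_squared")
  if (anyDuplicated(bg$condition_id)) {
    abort_design("More than one minus-myokinase well declared for a condition; pairing is ambiguous.")
  }

  full <- per_well |> filter(.data$has_myokinase)
  if (nrow(full) == 0L) {
    abort_design("No complete (myokinase-containing) wells found in the trace table.")
  }

  out <- full |>
    left_join(bg, by = "condition_id") |>
    mutate(
      background_corrected = !is.na(.data$slope_background),
      net_slope = .data$slope_a340_min -
        dplyr::coalesce(.data$slope_background, 0),
      no_signal = .data$net_slope > 0,
      velocity_uM_min = slope_to_velocity(
        .data$net_slope, epsilon_per_mM = epsilon_per_mM,
        dilution_factor = .data$dilution_factor
      )
    ) |>
    select("condition_id", "well_id", "well_id_background",
           slope_full = "slope_a340_min", r2_full = "r_squared",
           "window_start", "window_end", "n_points",
           "slope_background", "net_slope", "velocity_uM_min",
           "dilution_factor", "background_corrected", "no_signal")
  out
}

#' Plot coupled-assay traces
#'
#' Absorbance against time, one line per well, complete and minus-myokinase
#' reactions distinguished by linetype, faceted by condition.
#'
#' @param traces Long-format trace table as in [reduce_traces()].
#' @return A ggplot object.
#' @export
plot_traces <- function(traces) {
  ggplot2::ggplot(
    dplyr::mutate(traces, has_myokinase = as.logical(.data$has_myokinase)),
    ggplot2::aes(x = .data$time_min, y = .data$a340,
                 group = .data$well_id,
                 colour = .data$well_id,
                 linetype = .data$has_myokinase)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition_id) +
    ggplot2::labs(x = "time (min)", y = expression(A[340]),
                  linetype = "+ myokinase", colour = "well") +
    ggplot2::theme_bw()
}
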