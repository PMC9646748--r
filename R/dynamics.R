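#' Parameters of the population-dynamics series
#'
#' @param window_h sliding-window width for event rates, hours (6 h).
#' @param grid_interval_min spacing of the output time grid, minutes.
#' @param duration_h end of the time grid, hours (96 h).
#' @param rate_units `"per_window"` applies the windowed-rate formula
#'   literally (events per 6-h window per living cell); `"per_hour"`
#'   additionally divides by the window width, giving the per-hour rates
#'   quoted for the real cohorts (~0.03/h).
#' @return Object of class `dynamics_params`.
#' @export
dynamics_params <- function(window_h = 6, grid_interval_min = 30,
                            duration_h = 96,
                            rate_units = c("per_window", "per_hour")) {
  rate_units <- match.arg(rate_units)
  check(window_h > 0 && duration_h > 0 && grid_interval_min > 0,
        "window, duration and grid interval must be positive")
  structure(list(window_h = window_h,
                 grid_interval_min = grid_interval_min,
                 duration_h = duration_h,
                 rate_units = rate_units),
            class = "dynamics_params")
}

# Count initial single cells in a fate table.
n_initial_singles <- function(records) {
  sum(records$initial_state == "SingleCell")
}

outcome_of_event <- function(event_type) {
  check(event_type %in% c("division", "death", "Divided", "Died"),
        "event_type must be 'division' or 'death'")
  if (event_type %in% c("division", "Divided")) "Divided" else "Died"
}

#' Cumulative event percentage at a time point
#'
#' `100 * N_events(<= t) / N_initial_singles`: the percentage of the
#' initial single cells that have divided (or died) by time `t`.
#'
#' @param records fate-record data frame (from [track_well()] /
#'   [track_cohort()], or ground truth in the same layout).
#' @param event_type `"division"` or `"death"`.
#' @param t_h evaluation time, hours.
#' @return Percentage in [0, 100].
#' @export
cumulative_event_percentage <- function(records, event_type, t_h) {
  n0 <- n_initial_singles(records)
  check(n0 > 0, "no initial single cells: percentage undefined")
  out <- outcome_of_event(event_type)
  ev <- records$outcome == out & !is.na(records$event_time_min) &
    records$event_time_min <= t_h * 60
  100 * sum(ev) / n0
}

#' Sliding-window event rate at a time point
#'
#' Events falling in the half-open window `(t - window, t]`, divided by
#' the number of single cells still alive and undivided at `t` (end of
#' window).  With `rate_units = "per_hour"` the result is additionally
#' divided by the window width.  When no living single cell remains the
#' rate is undefined and returned as `NA` (never coerced to zero).
#'
#' @inheritParams cumulative_event_percentage
#' @param params a [dynamics_params()].
#' @return Rate (per window or per hour), or `NA_real_`.
#' @export
sliding_event_rate <- function(records, event_type, t_h,
                               params = dynamics_params()) {
  check(t_h >= params$window_h, "t must be at least one window width")
  out <- outcome_of_event(event_type)
  t_min <- t_h * 60
  w_min <- params$window_h * 60
  ev_t <- records$outcome == out & !is.na(records$event_time_min)
  in_window <- sum(ev_t & records$event_time_min > t_min - w_min &
                     records$event_time_min <= t_min)
  gone <- records$outcome %in% c("Divided", "Died") &
    !is.na(records$event_time_min) & records$event_time_min <= t_min
  living <- n_initial_singles(records) - sum(gone)
  if (living <= 0) return(NA_real_)
  rate <- in_window / living
  if (params$rate_units == "per_hour") rate <- rate / params$window_h
  rate
}

#' Full population-dynamics series of a tracked cohort
#'
#' Evaluates, on a regular time grid, the cumulative division and death
#' percentages and the sliding-window division and death rates, together
#' with the underlying counts.  At every grid point the conservation
#' `divided + died + living = initial singles` holds.
#'
#' @param records fate-record data frame; must contain at least one
#'   tracked single cell.
#' @param params a [dynamics_params()].
#' @return A data frame of class `dynamics_series` with columns `time_h`,
#'   `n_divided`, `n_died`, `n_living`, `pct_divided`, `pct_died`,
#'   `rate_division`, `rate_death` (rates `NA` before one full window),
#'   and attributes `n_single_cells` and `params`.
#' @export
compute_dynamics_series <- function(records, params = dynamics_params()) {
  check(nrow(records) > 0, "empty fate table")
  n0 <- n_initial_singles(records)
  check(n0 > 0, "no initial single cells")
  grid_h <- seq(0, params$duration_h, by = params$grid_interval_min / 60)
  n_div <- vapply(grid_h, function(t)
    sum(records$outcome == "Divided" & !is.na(records$event_time_min) &
          records$event_time_min <= t * 60), numeric(1))
  n_die <- vapply(grid_h, function(t)
    sum(records$outcome == "Died" & !is.na(records$event_time_min) &
          records$event_time_min <= t * 60), numeric(1))
  n_liv <- n0 - n_div - n_die
  rate_at <- function(t, type) {
    if (t < params$window_h) return(NA_real_)
    sliding_event_rate(records, type, t, params)
  }
  series <- data.frame(
    time_h = grid_h,
    n_divided = n_div, n_died = n_die, n_living = n_liv,
    pct_divided = 100 * n_div / n0,
    pct_died = 100 * n_die / n0,
    rate_division = vapply(grid_h, rate_at, numeric(1), type = "division"),
    rate_death = vapply(grid_h, rate_at, numeric(1), type = "death"))
  structure(series, n_single_cells = n0, params = params,
            class = c("dynamics_series", "data.frame"))
}
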