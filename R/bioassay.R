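# CDC bottle bioassay: validation of cumulative mortality series, Abbott's
# control correction, diagnostic dose/time determination from a susceptible
# strain, and resistance classification of field populations.

DEFAULT_TIME_GRID <- seq(0L, 120L, by = 15L)

#' Construct one bottle's mortality series
#'
#' @param bottle_id Bottle identifier.
#' @param location Collection location.
#' @param dose Insecticide dose in ug/ml (0 for the acetone control).
#' @param n_insects Insects per bottle (default 25).
#' @param times Observation times in minutes, strictly increasing (default
#'   0-120 by 15).
#' @param cumulative_dead Cumulative dead counts, one per time point.
#' @return A validated `mortality_series`.
#' @export
mortality_series <- function(bottle_id, location, dose, n_insects = 25L,
                             times = DEFAULT_TIME_GRID, cumulative_dead) {
  s <- structure(list(bottle_id = as.character(bottle_id),
                      location = as.character(location),
                      dose = as.numeric(dose),
                      n_insects = as.integer(n_insects),
                      times = as.integer(times),
                      cumulative_dead = as.integer(cumulative_dead)),
                 class = "mortality_series")
  validate_series(s)
}

#' Validate a mortality series
#'
#' Enforces the series invariants: a strictly increasing time grid, one
#' cumulative count per time point, counts within `[0, n_insects]`, and
#' non-decreasing cumulative deaths. Violations raise an error naming the
#' bottle and the offending time point(s).
#'
#' @param series A `mortality_series`.
#' @return The series, invisibly usable downstream.
#' @export
validate_series <- function(series) {
  who <- paste0("bottle '", series$bottle_id, "'")
  t <- series$times
  d <- series$cumulative_dead
  if (length(t) < 2L || any(diff(t) <= 0L)) {
    stop(who, ": time grid must be strictly increasing", call. = FALSE)
  }
  if (length(d) != length(t)) {
    stop(who, ": need one cumulative count per time point", call. = FALSE)
  }
  if (any(is.na(d)) || any(d < 0L)) {
    stop(who, ": dead counts must be non-negative", call. = FALSE)
  }
  over <- which(d > series$n_insects)
  if (length(over)) {
    stop(who, ": dead count exceeds n_insects at t = ",
         paste(t[over], collapse = ", "), " min", call. = FALSE)
  }
  dec <- which(diff(d) < 0L)
  if (length(dec)) {
    stop(who, ": cumulative deaths decrease at t = ",
         paste(t[dec + 1L], collapse = ", "), " min", call. = FALSE)
  }
  series
}

#' Construct an assay run (treated bottles plus control)
#'
#' @param location Location label.
#' @param treated List of `mortality_series`, all at the same positive dose.
#' @param control One `mortality_series` at dose 0.
#' @param date Free-text test date.
#' @return An `assay_run`.
#' @export
assay_run <- function(location, treated, control, date = NA_character_) {
  if (!length(treated)) stop("need at least one treated bottle", call. = FALSE)
  lapply(treated, validate_series)
  doses <- unique(vapply(treated, `[[`, numeric(1L), "dose"))
  if (length(doses) != 1L || doses <= 0) {
    stop("all treated bottles must share one positive dose", call. = FALSE)
  }
  if (is.null(control)) stop("control bottle is required", call. = FALSE)
  validate_series(control)
  if (control$dose != 0) stop("control bottle must have dose 0", call. = FALSE)
  grids <- unique(lapply(c(treated, list(control)), `[[`, "times"))
  if (length(grids) != 1L) {
    stop("all bottles in a run must share one time grid", call. = FALSE)
  }
  structure(list(location = location, date = date, dose = doses,
                 treated = treated, control = control),
            class = "assay_run")
}

#' Abbott's correction for control mortality
#'
#' `(treated - control) / (1 - control)`, clamped to `[0, 1]`; the identity
#' when control mortality is zero. Runs whose control mortality exceeds 10%
#' are conventionally invalid — use [classify_run()] for that rule.
#'
#' @param treated_mortality,control_mortality Proportions in `[0, 1]`,
#'   `control_mortality < 1`.
#' @return Corrected mortality proportion.
#' @examples
#' abbott_correct(0.9, 0.05)  # 0.8947
#' @export
abbott_correct <- function(treated_mortality, control_mortality) {
  if (any(treated_mortality < 0 | treated_mortality > 1) ||
      any(control_mortality < 0 | control_mortality > 1)) {
    stop("mortalities must be proportions in [0, 1]", call. = FALSE)
  }
  if (any(control_mortality >= 1)) {
    stop("control mortality of 100% invalidates the run", call. = FALSE)
  }
  pmin(1, pmax(0, (treated_mortality - control_mortality) /
                 (1 - control_mortality)))
}

pooled_mortality <- function(series_list, time) {
  dead <- vapply(series_list, function(s) {
    i <- match(time, s$times)
    if (is.na(i)) stop("time ", time, " min is not on the observation grid",
                       call. = FALSE)
    s$cumulative_dead[i]
  }, integer(1L))
  sum(dead) / sum(vapply(series_list, `[[`, integer(1L), "n_insects"))
}

MAX_CONTROL_MORTALITY <- 0.10

#' Diagnostic dose and time from a susceptible-strain dose ladder
#'
#' The diagnostic dose is the smallest dose at which *every* treated bottle
#' reaches 100% Abbott-corrected mortality within the observation window;
#' the diagnostic time is the earliest grid time at which that dose reaches
#' 100% in all bottles. Survivors of the diagnostic dose at the diagnostic
#' time then indicate resistance in field material.
#'
#' @param panel List of [assay_run()] objects over >= 2 doses, all from a
#'   susceptible reference strain.
#' @return A list `list(dose =, time =)` (class `diagnostic_params`).
#' @export
diagnostic_from_susceptible <- function(panel) {
  doses <- vapply(panel, `[[`, numeric(1L), "dose")
  if (length(unique(doses)) < 2L) {
    stop("need runs at >= 2 doses to determine a diagnostic", call. = FALSE)
  }
  for (run in panel[order(doses)]) {
    grid <- run$treated[[1L]]$times
    ctrl_prop <- function(time) pooled_mortality(list(run$control), time)
    full_at <- vapply(grid, function(tm) {
      all(vapply(run$treated, function(s) {
        abbott_correct(pooled_mortality(list(s), tm), ctrl_prop(tm)) >= 1
      }, logical(1L)))
    }, logical(1L))
    if (any(full_at)) {
      return(structure(list(dose = run$dose, time = grid[which(full_at)[1L]]),
                       class = "diagnostic_params"))
    }
  }
  stop("no dose in the ladder achieves 100% kill in all bottles; ",
       "extend the ladder to higher doses", call. = FALSE)
}

#' Classify one assay run against diagnostic parameters
#'
#' Pools the treated bottles (sum of dead over sum exposed), applies
#' Abbott's correction with the run's control, and compares the corrected
#' mortality at the diagnostic time with `threshold`: at or above is
#' susceptible, below is resistant. Runs whose control mortality at the
#' diagnostic time exceeds 10% are invalid. Also reports the earliest grid
#' time with 100% pooled corrected mortality, or `NA` if never reached.
#'
#' @param run An [assay_run()] at the diagnostic dose.
#' @param params A `diagnostic_params` list (`dose`, `time`).
#' @param threshold Susceptibility threshold as a percentage (default 100,
#'   the rule implied by a diagnostic dose; CDC-style 90 or 97 bands can be
#'   supplied instead).
#' @return A `resistance_call`: `location`, `status` (`"susceptible"`,
#'   `"resistant"` or `"invalid"`), `mortality_at_diagnostic` (corrected,
#'   percent), `time_to_full_mortality` (min or `NA`),
#'   `control_mortality` (percent).
#' @export
classify_run <- function(run, params, threshold = 100) {
  if (!isTRUE(all.equal(run$dose, params$dose))) {
    stop("run dose (", run$dose, ") differs from diagnostic dose (",
         params$dose, ")", call. = FALSE)
  }
  grid <- run$treated[[1L]]$times
  if (!params$time %in% grid) {
    stop("diagnostic time ", params$time, " min is not on the grid",
         call. = FALSE)
  }
  ctrl <- pooled_mortality(list(run$control), params$time)
  if (ctrl > MAX_CONTROL_MORTALITY) {
    return(structure(list(location = run$location, status = "invalid",
                          mortality_at_diagnostic = NA_real_,
                          time_to_full_mortality = NA_integer_,
                          control_mortality = ctrl * 100),
                     class = "resistance_call"))
  }
  corrected <- vapply(grid, function(tm) {
    abbott_correct(pooled_mortality(run$treated, tm),
                   pooled_mortality(list(run$control), tm))
  }, numeric(1L))
  at_diag <- corrected[match(params$time, grid)] * 100
  full <- which(corrected >= 1)
  structure(list(
    location = run$location,
    status = if (at_diag >= threshold) "susceptible" else "resistant",
    mortality_at_diagnostic = at_diag,
    time_to_full_mortality = if (length(full)) grid[full[1L]] else NA_integer_,
    control_mortality = ctrl * 100),
    class = "resistance_call")
}

#' Resistance prevalence across locations
#'
#' `resistant / (resistant + susceptible) * 100`, rounded half-up to one
#' decimal; invalid runs are excluded and reported via a message.
#'
#' @param calls List of `resistance_call` objects (or a data.frame with a
#'   `status` column).
#' @return Prevalence percentage (one decimal).
#' @export
prevalence <- function(calls) {
  status <- if (is.data.frame(calls)) calls$status
            else vapply(calls, `[[`, character(1L), "status")
  invalid <- sum(status == "invalid")
  if (invalid > 0L) {
    message(invalid, " invalid run(s) excluded from prevalence")
  }
  status <- status[status != "invalid"]
  if (!length(status)) stop("all runs are invalid", call. = FALSE)
  round_half_up(sum(status == "resistant") / length(status) * 100, 1L)
}

mortality_cols <- function(df) {
  cols <- grep("^dead_[0-9]+$", names(df), value = TRUE)
  if (!length(cols)) {
    stop("mortality CSV needs dead_<minutes> columns (e.g. dead_0 ... ",
         "dead_120)", call. = FALSE)
  }
  cols[order(as.integer(sub("^dead_", "", cols)))]
}

#' Read bottle mortality series from CSV
#'
#' Expects columns `location`, `date`, `bottle_id`, `dose_ug_ml`,
#' `n_insects`, then one `dead_<minutes>` column per time point
#' (`dead_0` ... `dead_120`). Each location becomes one [assay_run()] with
#' its dose-0 row(s) as control.
#'
#' @param path CSV path ('#' comment lines allowed).
#' @return Named list of [assay_run()] objects, one per location.
#' @export
read_mortality_csv <- function(path) {
  df <- read_table_csv(path, "mortality CSV")
  stop_if_missing_cols(df, c("location", "bottle_id", "dose_ug_ml",
                             "n_insects"), "mortality CSV")
  cols <- mortality_cols(df)
  times <- as.integer(sub("^dead_", "", cols))
  runs <- lapply(split(df, df$location), function(loc) {
    series <- lapply(seq_len(nrow(loc)), function(i) {
      mortality_series(loc$bottle_id[i], loc$location[i],
                       loc$dose_ug_ml[i], loc$n_insects[i], times,
                       as.integer(loc[i, cols]))
    })
    is_ctrl <- vapply(series, function(s) s$dose == 0, logical(1L))
    if (!any(is_ctrl)) {
      stop("location '", loc$location[1L], "': no control (dose 0) bottle",
           call. = FALSE)
    }
    if (sum(is_ctrl) > 1L) {
      stop("location '", loc$location[1L], "': more than one control bottle",
           call. = FALSE)
    }
    assay_run(loc$location[1L], series[!is_ctrl], series[is_ctrl][[1L]],
              date = as.character(loc$date[1L] %||% NA))
  })
  runs[unique(df$location)]
}

#' Classify every location of a mortality table
#'
#' @param runs A list of [assay_run()] objects, or a path/data source
#'   accepted by [read_mortality_csv()].
#' @param dose,time Diagnostic parameters (ug/ml, minutes).
#' @param threshold Susceptibility threshold percentage (default 100).
#' @return A data.frame of resistance calls with columns `location`,
#'   `date`, `dose_ug_ml`, `status`, `mortality_at_diagnostic`,
#'   `time_to_full_mortality`, `control_mortality`.
#' @export
classify_mortality_table <- function(runs, dose, time, threshold = 100) {
  if (is.character(runs)) runs <- read_mortality_csv(runs)
  params <- structure(list(dose = dose, time = time),
                      class = "diagnostic_params")
  rows <- lapply(runs, function(run) {
    cl <- classify_run(run, params, threshold = threshold)
    data.frame(location = cl$location, date = run$date,
               dose_ug_ml = run$dose, status = cl$status,
               mortality_at_diagnostic = cl$mortality_at_diagnostic,
               time_to_full_mortality = cl$time_to_full_mortality,
               control_mortality = cl$control_mortality,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
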