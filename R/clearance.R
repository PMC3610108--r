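# Clearance-period estimation on the backward time scale.
#
# For every burn-diagnosis episode after a person's first, the backward
# time is the gap from the previous episode's end to this episode's start.
# The population hazard of these gaps stays elevated while readmissions for
# the same injury dominate and settles to a roughly constant level once new
# incident injuries take over; the clearance period is where the smoothed
# hazard enters its long-run plateau.
#
# Estimator: Nelson-Aalen increments of the gap distribution (gaps from a
# person's last qualifying episode to the end of follow-up enter as
# right-censored), smoothed with an Epanechnikov kernel and reflected at 0
# to correct the boundary (a Ramlau-Hansen-type kernel hazard estimator).

#' Backward recurrence times between qualifying episodes
#'
#' For each person, consecutive-pair gaps between qualifying episodes:
#' `start(next) - end(previous)`, in years. Persons with a single episode
#' contribute no gap. When `window_end` is given, the time from each
#' person's last episode end to `window_end` enters as a right-censored
#' observation, which keeps the hazard estimate unbiased at long backward
#' times despite the finite follow-up.
#'
#' @param episodes data frame with `person_id`, `start_date`, `end_date`
#'   (e.g. [episode_summary()] filtered to burn-diagnosis mechanisms),
#'   chronological within person. Non-chronological input errors.
#' @param window_end last observed date; `NULL` disables censored tails.
#' @param horizon observation-window length in years; durations are capped
#'   here. Defaults to the observed span.
#' @return object of class `backward_times`: list with `durations`
#'   (event gaps, years), `censored` (censored gaps, years), `horizon`.
#' @export
backward_times <- function(episodes, window_end = NULL, horizon = NULL) {
  stopifnot(all(c("person_id", "start_date", "end_date") %in% names(episodes)))
  if (nrow(episodes) == 0L) {
    return(structure(list(durations = numeric(0), censored = numeric(0),
                          horizon = horizon %||% NA_real_),
                     class = "backward_times"))
  }
  o <- order(episodes$person_id, method = "radix")  # stable: keeps within-person order
  e <- episodes[o, , drop = FALSE]
  start <- as.numeric(.as_date(e$start_date))
  end <- as.numeric(.as_date(e$end_date))
  pid <- e$person_id
  first <- .group_first(pid)
  if (any(diff(start)[!first[-1L]] < 0)) {
    stop("episodes must be chronological within person")
  }
  prev_end <- c(NA_real_, end[-length(end)])
  gaps <- (start - prev_end)[!first] / DAYS_PER_YEAR
  if (any(gaps <= 0)) {
    stop("non-positive backward time: episodes overlap; re-chain records first")
  }
  cens <- numeric(0)
  if (!is.null(window_end)) {
    last <- c(first[-1L], TRUE)
    cens <- (as.numeric(.as_date(window_end)) - end[last]) / DAYS_PER_YEAR
    cens <- cens[cens > 0]
  }
  if (is.null(horizon)) {
    horizon <- max(gaps, cens, 0)
  }
  structure(list(durations = pmin(gaps, horizon), censored = pmin(cens, horizon),
                 horizon = horizon),
            class = "backward_times")
}

#' @export
print.backward_times <- function(x, ...) {
  cat(sprintf("<backward_times: %d gaps, %d censored, horizon %.2f y>\n",
              length(x$durations), length(x$censored), x$horizon))
  invisible(x)
}

.epanechnikov <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)

#' Kernel-smoothed hazard of backward times
#'
#' Nelson-Aalen increments `d_i / Y(t_i)` at the event gaps (risk set
#' `Y(t)` counts event and censored gaps still at risk), smoothed with an
#' Epanechnikov kernel of the given bandwidth. The kernel is reflected at
#' zero so the estimate is not biased downwards near the origin. The grid
#' runs from 0 to `grid_max`, by default the 95th percentile of all
#' observed times — beyond that the shrinking risk set makes the raw
#' increments too unstable to smooth usefully.
#'
#' @param sample a [backward_times()] object.
#' @param bandwidth kernel bandwidth in years (> 0).
#' @param grid_step grid spacing in years.
#' @param grid_max upper end of the grid; `NULL` for the default above.
#' @return list with `grid`, `hazard` (non-negative, per year) and `se`,
#'   the pointwise standard error of the smoothed hazard (kernel-squared
#'   sum of the Nelson-Aalen increment variances `d_i / Y(t_i)^2`).
#' @export
smoothed_hazard <- function(sample, bandwidth = 0.5, grid_step = 0.05,
                            grid_max = NULL) {
  stopifnot(inherits(sample, "backward_times"))
  if (length(sample$durations) == 0L) stop("no backward times to smooth")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (grid_step <= 0) stop("grid_step must be positive")
  times <- c(sample$durations, sample$censored)
  status <- rep(c(1L, 0L), c(length(sample$durations), length(sample$censored)))
  if (is.null(grid_max)) {
    grid_max <- min(sample$horizon, stats::quantile(times, 0.95, names = FALSE))
  }
  grid <- seq(0, grid_max, by = grid_step)
  # Nelson-Aalen increments at distinct event times
  ev <- sort(unique(times[status == 1L]))
  d <- vapply(ev, function(t) sum(times == t & status == 1L), numeric(1))
  at_risk <- vapply(ev, function(t) sum(times >= t), numeric(1))
  dLambda <- d / at_risk
  # kernel smoothing with reflection at 0
  K <- outer(grid, ev, function(g, t) {
    .epanechnikov((g - t) / bandwidth) + .epanechnikov((g + t) / bandwidth)
  }) / bandwidth
  hazard <- as.numeric(K %*% dLambda)
  se <- sqrt(as.numeric((K^2) %*% (dLambda / at_risk)))
  list(grid = grid, hazard = pmax(hazard, 0), se = se)
}

#' Clearance period from a smoothed hazard curve
#'
#' Operationalises "the hazard becomes nearly constant": the long-run level
#' is the mean hazard over the final `ref_fraction` of the grid, and the
#' clearance period is the smallest grid time from which the hazard stays
#' within `band` (relative) of that level for the remainder of the grid.
#' When pointwise standard errors are supplied the band is widened by
#' `z_se` standard errors at each grid point, so that sampling noise in a
#' genuinely flat region does not break the plateau; without `se` the band
#' is purely relative. When the hazard never settles into the band, the
#' grid maximum is returned with `stabilised = FALSE`.
#'
#' @param grid,hazard output of [smoothed_hazard()].
#' @param band relative tolerance around the long-run level (default 0.25).
#' @param ref_fraction trailing fraction of the grid defining the long-run
#'   level (default 1/3).
#' @param se optional pointwise standard errors of `hazard`.
#' @param z_se number of standard errors added to the band width.
#' @return list with `clearance_period` (years), `reference_level`,
#'   `stabilised` (logical).
#' @export
estimate_clearance <- function(grid, hazard, band = 0.25, ref_fraction = 1/3,
                               se = NULL, z_se = 2) {
  stopifnot(length(grid) == length(hazard), length(grid) > 1)
  ref_start <- grid[length(grid)] - ref_fraction * (grid[length(grid)] - grid[1])
  ref <- mean(hazard[grid >= ref_start])
  tol <- band * ref
  if (!is.null(se)) {
    stopifnot(length(se) == length(hazard))
    tol <- tol + z_se * se
  }
  in_band <- abs(hazard - ref) <= tol
  # TRUE where every later grid point (inclusive) is in band
  tail_ok <- rev(cumprod(rev(in_band))) > 0
  if (!any(tail_ok)) {
    warning("hazard never stabilises within the band; returning grid maximum")
    return(list(clearance_period = grid[length(grid)], reference_level = ref,
                stabilised = FALSE))
  }
  list(clearance_period = grid[which(tail_ok)[1]], reference_level = ref,
       stabilised = TRUE)
}

#' Share of readmissions captured by a clearance period
#'
#' Among event gaps no longer than `min(horizon, 10)` years, the proportion
#' that are at most `clearance_period` — i.e. the share of within-horizon
#' readmissions a clearance rule of that length would catch.
#'
#' @param sample a [backward_times()] object.
#' @param clearance_period non-negative time in years.
#' @return proportion in `[0, 1]`; `NA` (with a warning) when no gap falls
#'   within the horizon.
#' @export
capture_fraction <- function(sample, clearance_period) {
  stopifnot(inherits(sample, "backward_times"), clearance_period >= 0)
  lim <- min(sample$horizon, 10)
  d <- sample$durations[sample$durations <= lim]
  if (!length(d)) {
    warning("no backward times within the horizon; capture fraction undefined")
    return(NA_real_)
  }
  mean(d <= clearance_period)
}

#' Flag incident episodes
#'
#' `FIRST_ONLY` marks only each person's first qualifying episode as a new
#' incident injury (the conservative bound). `CLEARANCE` marks an episode
#' incident when no earlier qualifying episode of the same person ended
#' within `clearance_period` years before its start.
#'
#' @param episodes data frame with `person_id`, `start_date`, `end_date`,
#'   chronological within person.
#' @param mode `"FIRST_ONLY"` or `"CLEARANCE"`.
#' @param clearance_period required in CLEARANCE mode; years.
#' @return logical vector along `episodes` rows (in their input order).
#' @export
incident_episodes <- function(episodes, mode = c("FIRST_ONLY", "CLEARANCE"),
                              clearance_period = NULL) {
  mode <- match.arg(mode)
  if (mode == "CLEARANCE" && is.null(clearance_period)) {
    stop("CLEARANCE mode requires a clearance_period")
  }
  n <- nrow(episodes)
  if (n == 0L) return(logical(0))
  o <- order(episodes$person_id, method = "radix")
  start <- as.numeric(.as_date(episodes$start_date))[o]
  end <- as.numeric(.as_date(episodes$end_date))[o]
  pid <- episodes$person_id[o]
  first <- .group_first(pid)
  if (any(diff(start)[!first[-1L]] < 0)) {
    stop("episodes must be chronological within person")
  }
  if (mode == "FIRST_ONLY") {
    flag <- first
  } else {
    prev_max_end <- c(-Inf, .cummax_by(end, pid)[-n])
    gap_years <- (start - prev_max_end) / DAYS_PER_YEAR
    flag <- first | gap_years > clearance_period
  }
  out <- logical(n)
  out[o] <- flag
  out
}

#' Fit the clearance model to backward recurrence times
#'
#' Convenience wrapper tying the pieces together: smooths the hazard,
#' applies the plateau rule and evaluates the capture fraction at the
#' estimated clearance period.
#'
#' @inheritParams smoothed_hazard
#' @inheritParams estimate_clearance
#' @return object of class `clearance_fit` with components `grid`,
#'   `hazard`, `clearance_period`, `reference_level`, `stabilised`,
#'   `capture_fraction`, `sample`, and the smoothing parameters.
#' @export
clearance_fit <- function(sample, bandwidth = 0.5, grid_step = 0.05,
                          grid_max = NULL, band = 0.25, ref_fraction = 1/3,
                          z_se = 2) {
  sm <- smoothed_hazard(sample, bandwidth, grid_step, grid_max)
  est <- estimate_clearance(sm$grid, sm$hazard, band, ref_fraction,
                            se = sm$se, z_se = z_se)
  structure(list(
    grid = sm$grid, hazard = sm$hazard, se = sm$se,
    clearance_period = est$clearance_period,
    reference_level = est$reference_level,
    stabilised = est$stabilised,
    capture_fraction = capture_fraction(sample, est$clearance_period),
    sample = sample,
    bandwidth = bandwidth, grid_step = grid_step, band = band,
    ref_fraction = ref_fraction
  ), class = "clearance_fit")
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat("Backward-time clearance fit\n")
  cat(sprintf("  gaps: %d events, %d censored (horizon %.1f y)\n",
              length(x$sample$durations), length(x$sample$censored),
              x$sample$horizon))
  cat(sprintf("  clearance period: %.2f y%s\n", x$clearance_period,
              if (x$stabilised) "" else " (hazard did not stabilise)"))
  cat(sprintf("  capture fraction at clearance: %.1f%%\n",
              100 * x$capture_fraction))
  invisible(x)
}

#' @export
summary.clearance_fit <- function(object, ...) {
  out <- list(
    n_events = length(object$sample$durations),
    n_censored = length(object$sample$censored),
    horizon = object$sample$horizon,
    bandwidth = object$bandwidth,
    grid_step = object$grid_step,
    band = object$band,
    clearance_period = object$clearance_period,
    reference_level = object$reference_level,
    stabilised = object$stabilised,
    capture_fraction = object$capture_fraction,
    capture_at_2y = capture_fraction(object$sample, 2)
  )
  class(out) <- "summary.clearance_fit"
  out
}

#' @export
print.summary.clearance_fit <- function(x, ...) {
  cat("Clearance-period estimate from backward recurrence times\n")
  cat(sprintf("  sample: %d readmission gaps, %d censored tails, horizon %.1f y\n",
              x$n_events, x$n_censored, x$horizon))
  cat(sprintf("  smoothing: Epanechnikov bandwidth %.2f y, grid step %.2f y\n",
              x$bandwidth, x$grid_step))
  cat(sprintf("  plateau band: +/-%.0f%% of long-run hazard %.3f /y\n",
              100 * x$band, x$reference_level))
  cat(sprintf("  clearance period: %.2f y (%s)\n", x$clearance_period,
              if (x$stabilised) "stabilised" else "NOT stabilised"))
  cat(sprintf("  capture fraction: %.1f%% at clearance, %.1f%% at 2 y\n",
              100 * x$capture_fraction, 100 * x$capture_at_2y))
  invisible(x)
}

#' Plot a fitted backward-time hazard
#'
#' Hazard curve with the plateau band and the estimated clearance period.
#'
#' @param x a `clearance_fit`.
#' @param ... passed to [plot()].
#' @export
plot.clearance_fit <- function(x, ...) {
  plot(x$grid, x$hazard, type = "l", lwd = 2,
       xlab = "Backward time since previous episode (years)",
       ylab = "Smoothed hazard (per year)", ...)
  graphics::abline(h = x$reference_level * c(1 - x$band, 1, 1 + x$band),
                   lty = c(3, 2, 3), col = "grey40")
  graphics::abline(v = x$clearance_period, col = "firebrick", lwd = 2)
  graphics::mtext(sprintf("clearance = %.2f y", x$clearance_period),
                  side = 3, adj = 1, cex = 0.8)
  invisible(x)
}
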