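eps_df <- function(person, starts, ends) {
  data.frame(person_id = person, start_date = as.Date(starts),
             end_date = as.Date(ends))
}

test_that("backward times are consecutive-pair gaps in years", {
  e <- eps_df("A", c("2000-01-01", "2001-01-01"), c("2000-01-01", "2001-02-01"))
  bt <- backward_times(e)
  expect_length(bt$durations, 1L)
  expect_equal(bt$durations, 366 / 365.25, tolerance = 1e-6)
  # single episode: nothing; three episodes: two gaps
  expect_length(backward_times(e[1, ])$durations, 0L)
  e3 <- eps_df("A", c("2000-01-01", "2001-01-01", "2005-06-01"),
               c("2000-02-01", "2001-02-01", "2005-07-01"))
  expect_length(backward_times(e3)$durations, 2L)
  # censored tail appended when a window end is given
  bt2 <- backward_times(e3, window_end = "2009-12-31")
  expect_length(bt2$censored, 1L)
  bad <- eps_df("A", c("2001-01-01", "2000-01-01"), c("2001-02-01", "2000-02-01"))
  expect_error(backward_times(bad), "chronological")
})

test_that("the smoothed hazard of exponential gaps is flat at the rate", {
  set.seed(21)
  lambda <- 0.8
  horizon <- 8
  raw <- rexp(4000, lambda)
  sample <- structure(list(durations = raw[raw <= horizon],
                           censored = rep(horizon, sum(raw > horizon)),
                           horizon = horizon),
                      class = "backward_times")
  sm <- smoothed_hazard(sample, bandwidth = 0.5, grid_step = 0.05)
  interior <- sm$grid >= 0.5 & sm$grid <= max(sm$grid) - 0.5
  expect_true(all(abs(sm$hazard[interior] - lambda) / lambda < 0.10))
  # degenerate concentration: a tiny bandwidth spikes at the atom
  atom <- structure(list(durations = rep(2, 50), censored = numeric(0),
                         horizon = 5),
                    class = "backward_times")
  sp <- smoothed_hazard(atom, bandwidth = 0.1, grid_step = 0.05, grid_max = 4)
  expect_equal(sp$grid[which.max(sp$hazard)], 2, tolerance = 0.1)
  expect_true(all(sp$hazard[sp$grid < 1.5 | sp$grid > 2.5] == 0))
  expect_error(smoothed_hazard(atom, bandwidth = 0), "bandwidth")
})

test_that("integrated smoothed hazard matches the survival package Nelson-Aalen", {
  skip_if_not_installed("survival")
  set.seed(22)
  raw <- rexp(800, 0.5)
  cens <- pmin(raw, 6)
  status <- as.integer(raw <= 6)
  sample <- structure(list(durations = cens[status == 1],
                           censored = cens[status == 0], horizon = 6),
                      class = "backward_times")
  sm <- smoothed_hazard(sample, bandwidth = 0.05, grid_step = 0.01,
                        grid_max = 5)
  integral <- sum(sm$hazard) * 0.01
  sf <- survival::survfit(survival::Surv(cens, status) ~ 1, ctype = 1)
  na_at_5 <- max(sf$cumhaz[sf$time <= 5])
  expect_equal(integral, na_at_5, tolerance = 0.02)
})

test_that("the plateau rule finds the changepoint and degrades gracefully", {
  grid <- seq(0, 10, by = 0.05)
  # flat hazard: clearance at the origin
  flat <- estimate_clearance(grid, rep(0.1, length(grid)))
  expect_equal(flat$clearance_period, 0)
  expect_true(flat$stabilised)
  # monotone decay to an asymptote: band entry point is analytic
  hazard <- 0.1 * (1 + 2 * exp(-grid))
  est <- estimate_clearance(grid, hazard)
  ref <- mean(hazard[grid >= 10 - 10 / 3])
  t_star_analytic <- -log((0.25 * ref) / 0.2)  # 0.2 exp(-t) = band half-width
  expect_lt(abs(est$clearance_period - t_star_analytic), 0.1)
  expect_true(est$stabilised)
  # a hazard that never settles returns the grid maximum with a warning
  expect_warning(
    wild <- estimate_clearance(grid, 0.1 + grid, band = 0.01),
    "never stabilises")
  expect_equal(wild$clearance_period, 10)
  expect_false(wild$stabilised)
})

test_that("clearance recovery on a simulated piecewise-hazard register", {
  cfg <- register_config(n_persons = 2000, seed = 2024)
  sim <- generate_register(cfg)
  a <- assign_episodes(sim$records)
  m <- classify_episodes(a)
  eps <- episode_summary(a)
  eps$mechanism <- m$mechanism[match(eps$episode_id, m$episode_id)]
  burn <- eps[eps$mechanism %in% c("FIRE", "BURN"), ]
  wend <- max(a$discharge_date)
  horizon <- as.numeric(wend - min(a$admission_date)) / 365.25
  bt <- backward_times(burn, window_end = wend, horizon = horizon)
  fit <- clearance_fit(bt)
  tau <- cfg$readmission[["tau"]]
  expect_lt(abs(fit$clearance_period - tau), fit$bandwidth + 2 * fit$grid_step)
  expect_true(fit$stabilised)
  tc <- truth_check(sim, a, m, clearance = fit)
  expect_lt(abs(tc$clearance_error), 0.7)
})

test_that("capture fraction is the empirical CDF at the clearance point", {
  s <- structure(list(durations = c(0.5, 1.5, 3.0), censored = numeric(0),
                      horizon = 10),
                 class = "backward_times")
  expect_equal(capture_fraction(s, 2), 2 / 3)
  expect_equal(capture_fraction(s, 0), 0)
  expect_equal(capture_fraction(s, 10), 1)
  # non-decreasing in the clearance period, equal to the ECDF
  set.seed(23)
  d <- rexp(200, 0.5)
  s2 <- structure(list(durations = d, censored = numeric(0), horizon = 20),
                  class = "backward_times")
  grid <- seq(0, 10, by = 0.5)
  cf <- vapply(grid, function(cp) capture_fraction(s2, cp), numeric(1))
  expect_true(all(diff(cf) >= 0))
  expect_equal(cf, stats::ecdf(d[d <= 10])(grid))
  empty <- structure(list(durations = numeric(0), censored = numeric(0),
                          horizon = 10), class = "backward_times")
  expect_warning(expect_true(is.na(capture_fraction(empty, 2))), "undefined")
})

test_that("incident flags follow the first-only and clearance definitions", {
  # person with backward gaps of 0.5 y and 5 y around three episodes
  e <- eps_df("A",
              c("2000-01-01", "2000-08-01", "2005-09-01"),
              c("2000-02-01", "2000-09-01", "2005-10-01"))
  expect_equal(incident_episodes(e, "CLEARANCE", clearance_period = 2),
               c(TRUE, FALSE, TRUE))
  expect_equal(incident_episodes(e, "FIRST_ONLY"), c(TRUE, FALSE, FALSE))
  expect_equal(incident_episodes(e[1, ], "FIRST_ONLY"), TRUE)
  expect_equal(incident_episodes(e[1, ], "CLEARANCE", clearance_period = 2), TRUE)
  expect_error(incident_episodes(e, "CLEARANCE"), "clearance_period")
  # clearance counts dominate first-only counts for any clearance period
  set.seed(24)
  many <- do.call(rbind, lapply(1:50, function(i) {
    n <- sample(1:5, 1)
    starts <- as.Date("2000-01-01") + cumsum(sample(30:2000, n, replace = TRUE))
    eps_df(sprintf("P%02d", i), starts, starts + 10)
  }))
  for (cp in c(0.5, 2, 5)) {
    expect_gte(sum(incident_episodes(many, "CLEARANCE", clearance_period = cp)),
               sum(incident_episodes(many, "FIRST_ONLY")))
  }
})
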