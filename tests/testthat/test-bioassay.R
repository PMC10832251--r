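# Bottle bioassay: series validation, Abbott correction, diagnostic
# determination and resistance classification.

grid <- seq(0, 120, by = 15)

test_that("validate_series enforces the mortality invariants", {
  ok <- mortality_series("b1", "x", 4.5, 25, grid,
                         c(0, 5, 10, 15, 20, 25, 25, 25, 25))
  expect_s3_class(ok, "mortality_series")
  expect_error(mortality_series("b1", "x", 4.5, 25, grid,
                                c(0, 5, 10, 15, 20, 26, 25, 25, 25)),
               "exceeds n_insects")
  expect_error(mortality_series("b1", "x", 4.5, 25, grid,
                                c(0, 10, 8, 15, 20, 25, 25, 25, 25)),
               "decrease")
  expect_error(mortality_series("b1", "x", 4.5, 25, c(0, 15, 15),
                                c(0, 1, 2)),
               "strictly increasing")
})

test_that("abbott_correct matches the closed form and clamps", {
  expect_equal(abbott_correct(1.0, 0.0), 1.0)
  expect_equal(abbott_correct(0.9, 0.05), 0.8947368421, tolerance = 1e-9)
  expect_equal(abbott_correct(0.02, 0.05), 0)  # clamped at zero
  expect_error(abbott_correct(0.9, 1), "100%")
  expect_error(abbott_correct(1.2, 0), "proportions")
})

test_that("diagnostic_from_susceptible finds dose and time on the ladder", {
  panel <- simulate_susceptible_panel()
  d <- diagnostic_from_susceptible(panel)
  expect_equal(d$dose, 4.5)
  expect_equal(d$time, 60)
  # if the lowest dose already kills everything at 15 min it wins
  fast <- lapply(c(1, 2), function(dose) {
    simulate_bioassay("susceptible", dose = dose,
                      curve = list(midpoint = 5, slope = 2, t100 = 15))
  })
  d2 <- diagnostic_from_susceptible(fast)
  expect_equal(d2$dose, 1)
  expect_equal(d2$time, 15)
  # a ladder that never reaches complete kill is an error
  weak <- lapply(c(1, 2), function(dose) {
    simulate_bioassay("susceptible", dose = dose,
                      curve = list(midpoint = 40, slope = 10, t100 = Inf,
                                   cap = 0.96))
  })
  expect_error(diagnostic_from_susceptible(weak), "higher")
})

test_that("classify_run reads mortality against the diagnostic", {
  params <- structure(list(dose = 4.5, time = 60),
                      class = "diagnostic_params")
  sus <- classify_run(simulate_bioassay("susceptible"), params)
  expect_equal(sus$status, "susceptible")
  expect_equal(sus$time_to_full_mortality, 60)
  res <- classify_run(simulate_bioassay("resistant"), params)
  expect_equal(res$status, "resistant")
  expect_equal(res$time_to_full_mortality, 90)
  # a population never reaching 100% is resistant with no full-kill time
  never <- classify_run(
    simulate_bioassay("resistant",
                      curve = list(midpoint = 60, slope = 20, t100 = Inf,
                                   cap = 0.9)), params)
  expect_equal(never$status, "resistant")
  expect_true(is.na(never$time_to_full_mortality))
  expect_error(classify_run(simulate_bioassay("susceptible", dose = 9),
                            params), "differs from diagnostic dose")
})

test_that("high control mortality invalidates a run", {
  params <- structure(list(dose = 4.5, time = 60),
                      class = "diagnostic_params")
  run <- simulate_bioassay("susceptible")
  run$control$cumulative_dead <- as.integer(round(25 * seq(0, 0.32,
                                                           length.out = 9)))
  cl <- classify_run(run, params)
  expect_equal(cl$status, "invalid")
  expect_message(p <- prevalence(list(cl,
                                      classify_run(
                                        simulate_bioassay("resistant"),
                                        params))),
                 "invalid")
  expect_equal(p, 100)
})

test_that("raising death counts never flips a call toward resistant", {
  params <- structure(list(dose = 4.5, time = 60),
                      class = "diagnostic_params")
  set.seed(5)
  for (i in 1:20) {
    run <- simulate_bioassay(sample(c("susceptible", "resistant"), 1),
                             stochastic = TRUE, seed = i)
    before <- classify_run(run, params)$status
    # bump one bottle's tail upward while keeping the series valid
    b <- sample(length(run$treated), 1)
    s <- run$treated[[b]]
    k <- sample(seq_along(s$times), 1)
    s$cumulative_dead[k:length(s$times)] <-
      pmin(s$n_insects, pmax(s$cumulative_dead[k:length(s$times)],
                             s$cumulative_dead[k] + 1L))
    run$treated[[b]] <- validate_series(s)
    after <- classify_run(run, params)$status
    expect_false(before == "susceptible" && after == "resistant")
  }
})

test_that("simulated resistant populations are recovered as resistant", {
  params <- structure(list(dose = 4.5, time = 60),
                      class = "diagnostic_params")
  hits <- vapply(1:200, function(i) {
    run <- simulate_bioassay("resistant", stochastic = TRUE, seed = 1000 + i)
    classify_run(run, params)$status == "resistant"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("prevalence summarises calls", {
  mk <- function(status) structure(list(status = status),
                                   class = "resistance_call")
  expect_equal(prevalence(list(mk("resistant"), mk("susceptible"),
                               mk("susceptible"))), 33.3)
  expect_equal(prevalence(list(mk("susceptible"), mk("susceptible"))), 0)
  expect_error(prevalence(list(mk("invalid"))), "all runs")
})

test_that("the packaged bioassay fixture reproduces the published screen", {
  calls <- classify_mortality_table(kdr_example("abudhabi2023_bioassay.csv"),
                                    dose = 4.5, time = 60)
  outcomes <- abudhabi_bioassay_outcomes()
  expect_equal(nrow(calls), 16)
  m <- match(outcomes$location, calls$location)
  expect_equal(calls$status[m], outcomes$status)
  expect_equal(calls$time_to_full_mortality[m], outcomes$time_to_full)
  expect_equal(prevalence(calls), 12.5)
})

test_that("mortality CSV reading catches schema problems", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("location,bottle_id,dose_ug_ml,n_insects,minute_0",
               "x,b,4.5,25,0"), bad)
  expect_error(read_mortality_csv(bad), "dead_")
  noctrl <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("location,date,bottle_id,dose_ug_ml,n_insects,dead_0,dead_15",
               "x,1 March,b,4.5,25,0,25"), noctrl)
  expect_error(read_mortality_csv(noctrl), "no control")
})
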