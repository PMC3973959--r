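test_that("event-time sampler inverts the scaled piecewise-exponential CDF", {
  h1 <- piecewise_hazard(numeric(0), 0.5)       # plain exponential, rate 0.5
  expect_equal(sample_event_time(h1, 1, exp(-1)), 2)     # t = 1/lambda
  expect_equal(sample_event_time(h1, 2, exp(-1)), 1)     # doubled hazard
  h <- piecewise_hazard()
  u <- c(0.1, 0.5, 0.9)
  t <- sample_event_time(h, 0.75, u)
  expect_equal(exp(-0.75 * cumulative_hazard(h, t)), u)
  expect_error(sample_event_time(h, 1, c(0.5, 1)), "strictly in")
  expect_error(sample_event_time(h, -1, 0.5), "positive")
})

test_that("sampled survival matches the closed form within Monte-Carlo error", {
  h <- piecewise_hazard()
  n <- 50000
  for (delta in c(0, 0.25)) {
    set.seed(2024 + round(100 * delta))
    t <- sample_event_time(h, 1 - delta, stats::runif(n))
    for (tt in 1:5) {
      p <- exp(-(1 - delta) * cumulative_hazard(h, tt))
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(t > tt) - p), 3 * se)
    }
  }
})

test_that("cohorts have exact 1:1 allocation, positive latent times, reproducible", {
  d <- small_design()
  co <- simulate_cohort(d, 0.25, seed = 42)
  expect_equal(nrow(co), 200)
  expect_equal(unname(table(co$arm))[1:2], c(100, 100), ignore_attr = TRUE)
  expect_true(all(co$latent_event > 0))
  expect_true(!is.unsorted(co$entry))
  expect_identical(co, simulate_cohort(d, 0.25, seed = 42))
  expect_false(identical(co, simulate_cohort(d, 0.25, seed = 43)))
  expect_error(simulate_cohort(d, 1.0), "\\[0, 1\\)")
})

test_that("arms are exchangeable at zero hazard reduction", {
  d <- small_design()
  co <- simulate_cohort(nsabp_c08_design(), 0, seed = 7)
  ks <- suppressWarnings(stats::ks.test(co$latent_event[co$arm == "control"],
                                        co$latent_event[co$arm == "experimental"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a 25% reduction scales the experimental survival curve as S^0.75", {
  co <- simulate_cohort(nsabp_c08_design(), 0.25, seed = 11)
  for (tt in c(1, 2, 3, 4)) {
    s_ctrl <- exp(-cumulative_hazard(nsabp_c08_design()$control_hazard, tt))
    s_exp_emp <- mean(co$latent_event[co$arm == "experimental"] > tt)
    p <- s_ctrl^0.75
    expect_lt(abs(s_exp_emp - p), 3 * sqrt(p * (1 - p) / 1316))
  }
})

test_that("snapshots censor exactly as an interim data lock would", {
  co <- five_patient_cohort()      # event calendar times 1.5, 1.6, 2.4, 3.1, 5.0
  expect_equal(nrow(snapshot_at(co, 0)), 0)
  s_late <- snapshot_at(co, 10)
  expect_equal(sum(s_late$event), 5)
  # at t = 2.0: all five enrolled, events for patients 1 and 2 only
  s <- snapshot_at(co, 2.0)
  expect_equal(nrow(s), 5)
  expect_equal(sum(s$event), 2)
  expect_equal(s$time, c(1.4, 1.4, 1.6, 1.4, 1.0))  # min(latent, 2 - entry)
  # at t = 0.5: only entries <= 0.5 appear
  expect_equal(nrow(snapshot_at(co, 0.5)), 3)
  # event counts non-decreasing in calendar time
  counts <- vapply(seq(0, 6, by = 0.25), function(t) sum(snapshot_at(co, t)$event), 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("calendar_time_of_nth_event matches the sort oracle and snapshots agree", {
  co <- five_patient_cohort()
  expect_equal(calendar_time_of_nth_event(co, 1), 1.5)
  oracle <- sort(co$entry + co$latent_event)
  times <- vapply(1:5, function(n) calendar_time_of_nth_event(co, n), 0)
  expect_equal(times, oracle)
  expect_true(all(diff(times) >= 0))
  for (n in 1:5)
    expect_equal(sum(snapshot_at(co, calendar_time_of_nth_event(co, n))$event), n)
  expect_error(calendar_time_of_nth_event(co, 6), "out of range")
})

test_that("cohort fixtures round-trip through the plain-text writer", {
  co <- simulate_cohort(small_design(), 0.1, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  back <- read_cohort(path, hazard_reduction = 0.1)
  expect_equal(back$arm, co$arm)
  expect_equal(back$entry, co$entry, tolerance = 1e-12)
  expect_equal(back$latent_event, co$latent_event, tolerance = 1e-12)
})
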