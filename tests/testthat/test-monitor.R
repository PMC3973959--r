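test_that("recorded analyses are consistent with independently recomputed tests", {
  d <- small_design()
  res <- run_trial(d, 0.15, seed = 314)
  co <- simulate_cohort(d, 0.15, seed = 314)   # same seed -> same cohort
  sched <- res$analyses
  for (i in seq_len(nrow(sched))) {
    snap <- snapshot_at(co, sched$time[i])
    expect_equal(sum(snap$event), sched$events[i])
    lr <- logrank_test(snap)
    expect_equal(lr$p_left, sched$p_left[i], tolerance = 1e-12)
    expect_equal(lr$p_right, sched$p_right[i], tolerance = 1e-12)
  }
  # the reported outcome is exactly what the boundary logic dictates
  k <- res$stopped_at
  if (res$outcome == "stop_superiority") {
    expect_lt(sched$p_left[nrow(sched)], d$interims[[k]]$efficacy_bound)
  } else if (res$outcome == "stop_futility") {
    expect_lt(sched$p_right[nrow(sched)], d$interims[[k]]$futility_bound)
  } else {
    expect_equal(k, length(d$interims) + 1L)
    expect_equal(res$outcome == "final_success",
                 sched$p_left[nrow(sched)] < d$final$significance)
  }
  # earlier analyses crossed nothing
  for (i in seq_len(nrow(sched) - 1)) {
    kk <- sched$analysis[i]
    expect_gte(sched$p_left[i], d$interims[[kk]]$efficacy_bound)
    expect_gte(sched$p_right[i], d$interims[[kk]]$futility_bound)
  }
})

test_that("a no-stopping design always reaches the final analysis", {
  d <- small_design(fut = c(0, 0), eff = c(0, 0))
  for (s in 1:20) {
    res <- run_trial(d, 0.2, seed = s)
    expect_true(res$outcome %in% c("final_success", "final_fail"))
    expect_equal(res$stopped_at, 3L)
  }
})

test_that("a certain-stop futility bound stops every replicate at interim 1", {
  d <- small_design(fut = c(1, 0.5), eff = c(0.001, 0.01))
  for (s in 1:20) {
    res <- run_trial(d, 0.2, seed = s)
    expect_equal(res$outcome, "stop_futility")
    expect_equal(res$stopped_at, 1L)
  }
})

test_that("outcome tables partition the replicates exactly", {
  d <- small_design()
  tab <- estimate_outcome_table(d, 0.2, n_reps = 400, seed = 8)
  with(tab$counts, expect_identical(sum(sup) + sum(fut) + final_success + final_fail,
                                    400L))
  expect_equal(sum(tab$sup) + sum(tab$fut) + tab$final_success + tab$final_fail, 1)
  expect_true(all(diff(tab$continue_past) <= 0))
  expect_true(all(tab$continue_past >= 0))
  expect_equal(tab$continue_past[length(tab$continue_past)],
               tab$final_success + tab$final_fail)
})

test_that("early superiority under the null is bounded by the summed efficacy levels", {
  d <- small_design(fut = c(0, 0), eff = c(0.01, 0.02))  # no futility stops
  tab <- estimate_outcome_table(d, 0, n_reps = 2000, seed = 21)
  bound <- 0.03
  se <- sqrt(bound * (1 - bound) / 2000)
  expect_lte(sum(tab$sup), bound + 3 * se)
})

test_that("sweeps reproduce single-effect tables and cache losslessly", {
  d <- small_design()
  sw <- sweep_effects(d, deltas = 0.25, n_reps = 150, seed = 4)
  single <- estimate_outcome_table(d, 0.25, 150, seed = 4)
  expect_equal(sw[["25%"]]$counts, single$counts)

  cache <- withr::local_tempdir()
  sw1 <- sweep_effects(d, deltas = c(0, 0.25), n_reps = 100, seed = 4,
                       cache_dir = cache)
  expect_length(list.files(cache), 2)
  sw2 <- sweep_effects(d, deltas = c(0, 0.25), n_reps = 100, seed = 4,
                       cache_dir = cache)   # from cache
  expect_equal(lapply(sw2, `[[`, "counts"), lapply(sw1, `[[`, "counts"))
})

test_that("outcome tables round-trip through both serialization formats", {
  d <- small_design()
  sw <- sweep_effects(d, deltas = c(0, 0.2), n_reps = 120, seed = 9)
  for (ext in c(".tsv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_outcome_tables(sw, path)
    back <- read_outcome_tables(path)
    expect_equal(names(back), names(sw))
    for (k in names(sw)) {
      expect_equal(back[[k]]$counts, sw[[k]]$counts)
      expect_equal(back[[k]]$sup, sw[[k]]$sup)
      expect_equal(back[[k]]$continue_past, sw[[k]]$continue_past)
    }
  }
})
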