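# two-effect fixture with exactly known probabilities, two interims + final
two_effect_sweep <- function() {
  fake_sweep(
    fake_table(0.0,  sup = c(0.00, 0.01), fut = c(0.30, 0.20), final_success = 0.09),
    fake_table(0.25, sup = c(0.05, 0.15), fut = c(0.02, 0.03), final_success = 0.55))
}

test_that("a point-mass prior reproduces that effect's outcome table", {
  sw <- two_effect_sweep()
  rep25 <- predictive_report(make_prior(1, support = 0.25), sw)
  expect_equal(rep25$suc, c(0.05, 0.15, 0.55))
  expect_equal(rep25$fut, c(0.02, 0.03, 0))
  # overall success equals that effect's power
  expect_equal(rep25$cum_suc[3], 0.75)
  expect_equal(eventual_outcome_summary(rep25, 0)[["success"]], 0.75)
})

test_that("unconditional columns are plain mixtures; 0.9/0.3 halves mix to 0.6", {
  sw <- fake_sweep(fake_table(0.1, sup = 0.0, fut = 0.0, final_success = 0.9),
                   fake_table(0.3, sup = 0.0, fut = 0.0, final_success = 0.3))
  r <- predictive_report(make_prior(c(1, 1), support = c(0.1, 0.3)), sw)
  expect_equal(eventual_outcome_summary(r, 0)[["success"]], 0.6)
})

test_that("report satisfies its internal identities column by column", {
  sw <- two_effect_sweep()
  r <- predictive_report(make_prior(c(2, 1), support = c(0, 0.25)), sw)
  # eventual triple sums to one at every analysis
  expect_equal(r$ev_suc_undec + r$ev_fut_undec + r$ev_fail_undec, rep(1, 3))
  # cumulative curves non-decreasing; futility structurally zero at the final
  expect_true(all(diff(r$cum_suc) >= 0))
  expect_true(all(diff(r$cum_fut) >= 0))
  expect_equal(r$fut[3], 0)
  # conditional x reach = unconditional, with reach the mixed continuation
  w <- c(2, 1) / 3
  c_mat <- rbind(c(1, sw[[1]]$continue_past), c(1, sw[[2]]$continue_past))
  reach <- as.vector(w %*% c_mat)
  expect_equal(r$suc_undec * reach, r$suc)
  expect_equal(r$fut_undec * reach, r$fut)
  # undecided at the final analysis is exactly eventual failure
  expect_equal(r$undec[3], sum(w * vapply(sw, `[[`, 0, "final_fail")))
})

test_that("conditionals are ratios of joint mixtures, not mixed conditionals", {
  sw <- two_effect_sweep()
  prior <- make_prior(c(1, 1), support = c(0, 0.25))
  r <- predictive_report(prior, sw)
  # wrong recipe: prior-weighted average of per-effect conditional success
  wrong <- mean(c(0.01 / sw[[1]]$continue_past[1], 0.15 / sw[[2]]$continue_past[1]))
  joint <- mean(c(0.01, 0.15)) / mean(c(sw[[1]]$continue_past[1],
                                        sw[[2]]$continue_past[1]))
  expect_equal(r$suc_undec[2], joint)
  expect_false(isTRUE(all.equal(r$suc_undec[2], wrong)))
})

test_that("the report is linear in the prior mixture, column by column", {
  sw <- two_effect_sweep()
  r1 <- predictive_report(make_prior(1, support = 0), sw)
  r2 <- predictive_report(make_prior(1, support = 0.25), sw)
  rmix <- predictive_report(make_prior(c(0.3, 0.7), support = c(0, 0.25)), sw)
  for (col in c("suc", "fut", "undec", "cum_suc", "cum_fut"))
    expect_equal(rmix[[col]], 0.3 * r1[[col]] + 0.7 * r2[[col]])
})

test_that("posterior route and conditional route agree (Bayes consistency)", {
  sw <- two_effect_sweep()
  prior <- make_prior(c(3, 5), support = c(0, 0.25))
  for (k in 1:2) {
    via_report <- eventual_outcome_summary(predictive_report(prior, sw), k)
    post <- posterior_given_continue(prior, sw, k)
    # mix each effect's conditional eventual triple with the posterior
    per_effect <- vapply(seq_along(sw), function(i) {
      t <- sw[[i]]; ck <- t$continue_past[k]
      c((sum(t$sup[-seq_len(k)]) + t$final_success) / ck,
        sum(t$fut[-seq_len(k)]) / ck,
        t$final_fail / ck)
    }, numeric(3))
    expect_equal(unname(via_report), as.vector(per_effect %*% post$prob),
                 tolerance = 1e-12)
  }
})

test_that("downstream results are invariant to the scale of the raw weights", {
  sw <- two_effect_sweep()
  r1 <- predictive_report(make_prior(c(2, 6), support = c(0, 0.25)), sw)
  r2 <- predictive_report(make_prior(c(1, 3), support = c(0, 0.25)), sw)
  for (col in setdiff(names(r1), "analysis"))
    expect_equal(r1[[col]], r2[[col]])
})

test_that("a missing table for a supported effect is a coverage error", {
  sw <- two_effect_sweep()
  expect_error(predictive_report(make_prior(c(1, 1), support = c(0, 0.10)), sw),
               "no outcome table")
})

test_that("the report writer emits the spreadsheet column headings", {
  sw <- two_effect_sweep()
  r <- predictive_report(make_prior(c(1, 1), support = c(0, 0.25)), sw)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(r, path)
  header <- readLines(path, n = 1)
  expect_equal(header, paste("analysis", "suc", "fut", "undec", "suc|undec",
                             "fut|undec", "eventual suc|undec",
                             "eventual fut|undec", "eventual fail|undec",
                             sep = "\t"))
  lines <- readLines(path)
  expect_length(lines, 4)                 # header + 2 interims + final
  expect_match(lines[4], "^final\t")
})
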