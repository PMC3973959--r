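# Shared fixtures: a fast miniature design, hand-built cohorts, fake outcome
# tables with exactly known probabilities, and a naive log-rank oracle.

# Miniature trial: 200 patients accrued in 5 months, high event rates, two
# interims, final at 60 events. One replicate runs in well under a
# millisecond, so property loops stay cheap.
small_design <- function(fut = c(0.10, 0.5), eff = c(0.001, 0.01),
                         final_sig = 0.025) {
  trial_design(
    accrual = accrual_model(start_rate = 40, end_rate = 40, ramp_months = 1,
                            total_n = 200),
    control_hazard = piecewise_hazard(1, c(0.30, 0.15)),
    interims = list(
      interim_spec(trigger_events = 20, futility_bound = fut[1],
                   efficacy_bound = eff[1]),
      interim_spec(trigger_time = 1.5, futility_bound = fut[2],
                   efficacy_bound = eff[2])),
    final = final_spec(trigger_events = 60, significance = final_sig))
}

# five patients with printed entry/latent times, for brute-force snapshot
# checks; event calendar times are 1.5, 1.6, 2.4, 3.1, 5.0
five_patient_cohort <- function() {
  structure(data.frame(
    arm = c("control", "experimental", "control", "experimental", "control"),
    entry = c(0.1, 0.2, 0.4, 0.6, 1.0),
    latent_event = c(1.4, 1.4, 2.0, 2.5, 4.0)),
    class = c("trial_cohort", "data.frame"), hazard_reduction = 0)
}

# outcome table with chosen probabilities (counts over n = 1000), K interims
fake_table <- function(delta, sup, fut, final_success, n = 1000) {
  stopifnot(sum(sup) + sum(fut) + final_success <= 1)
  ff <- round(n * (1 - sum(sup) - sum(fut) - final_success))
  gspred:::.outcome_table(delta, n, round(n * sup), round(n * fut),
                          round(n * final_success), ff)
}

fake_sweep <- function(...) {
  out <- list(...)
  names(out) <- vapply(out, function(t) sprintf("%g%%", 100 * t$delta), "")
  class(out) <- "outcome_sweep"
  out
}

# independent log-rank oracle: plain loop over distinct event times
naive_logrank_z <- function(time, event, arm) {
  ut <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (u in ut) {
    at <- time >= u
    n <- sum(at); n1 <- sum(at & arm == "control")
    d <- sum(event & time == u); d1 <- sum(event & time == u & arm == "control")
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E) / sqrt(V)
}
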