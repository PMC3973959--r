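#' Sample event times from a scaled piecewise-exponential distribution
#'
#' Inverse-CDF sampling: returns the time `t` solving
#' `exp(-hazard_ratio * H(t)) = u`, where `H` is the cumulative hazard of
#' `hazard`. Deterministic given `u`, so the same uniforms always map to the
#' same event times.
#'
#' @param hazard A [piecewise_hazard()].
#' @param hazard_ratio Positive multiplier on the hazard (1 for the control
#'   arm; `1 - delta` for an experimental arm with hazard reduction `delta`).
#' @param u Uniform(0,1) draws (vectorized), strictly inside the unit
#'   interval.
#' @return Event times in years, one per element of `u`.
#' @export
sample_event_time <- function(hazard, hazard_ratio = 1, u) {
  if (hazard_ratio <= 0) stop("`hazard_ratio` must be positive")
  u <- as.numeric(u)
  if (any(u <= 0) || any(u >= 1)) stop("`u` must lie strictly in (0, 1)")
  cumulative_hazard_inverse(hazard, -log(u) / hazard_ratio)
}

# internal flat cohort used in the simulation hot path:
# list(entry, latent, is_control) with entry sorted ascending
.simulate_cohort_raw <- function(design, hazard_reduction) {
  n <- design$accrual$total_n
  entry <- sort(accrual_time_of(design$accrual, stats::runif(n) * n)) / 12
  is_control <- rep_len(c(TRUE, FALSE), n)          # alternate by entry order
  hr <- ifelse(is_control, 1, 1 - hazard_reduction)
  latent <- cumulative_hazard_inverse(design$control_hazard,
                                      -log(stats::runif(n)) / hr)
  list(entry = entry, latent = latent, is_control = is_control)
}

#' Simulate one virtual trial cohort
#'
#' Generates `total_n` patients: entry times by inverting the cumulative
#' accrual curve at uniform draws, exact 1:1 allocation by alternating
#' assignment in entry order, and latent (uncensored) event times from the
#' control hazard scaled by `1 - hazard_reduction` in the experimental arm.
#'
#' @param design A validated `trial_design`.
#' @param hazard_reduction Treatment effect `delta` in `[0, 1)`; the
#'   experimental-arm hazard ratio is `1 - delta`.
#' @param seed Optional integer seed; when given the cohort is reproducible.
#' @return A data frame of class `trial_cohort` with columns `arm`
#'   (`"control"`/`"experimental"`), `entry` (calendar years) and
#'   `latent_event` (years from entry to the event).
#' @export
simulate_cohort <- function(design, hazard_reduction, seed = NULL) {
  if (hazard_reduction < 0 || hazard_reduction >= 1)
    stop("`hazard_reduction` must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  raw <- .simulate_cohort_raw(design, hazard_reduction)
  structure(data.frame(arm = ifelse(raw$is_control, "control", "experimental"),
                       entry = raw$entry, latent_event = raw$latent),
            class = c("trial_cohort", "data.frame"),
            hazard_reduction = hazard_reduction)
}

# censoring rule shared by snapshot_at() and the monitor hot path
.snapshot_raw <- function(entry, latent, is_control, time) {
  inc <- entry <= time
  list(time = pmin(latent[inc], time - entry[inc]),
       event = latent[inc] <= (time - entry[inc]),
       is_control = is_control[inc])
}

#' Censored view of a cohort at a calendar time
#'
#' Returns the data as a monitoring committee would see them at calendar time
#' `time`: only patients already enrolled appear, with follow-up administratively
#' censored at `time - entry`.
#'
#' @param cohort A `trial_cohort`.
#' @param time Calendar time in years, non-negative.
#' @return A data frame of class `trial_snapshot` with columns `time`
#'   (observed follow-up), `event` (logical) and `arm`; the analysis time is
#'   kept in `attr(, "analysis_time")`.
#' @export
snapshot_at <- function(cohort, time) {
  stopifnot(inherits(cohort, "trial_cohort"))
  if (time < 0) stop("negative calendar time")
  raw <- .snapshot_raw(cohort$entry, cohort$latent_event,
                       cohort$arm == "control", time)
  structure(data.frame(time = raw$time, event = raw$event,
                       arm = ifelse(raw$is_control, "control", "experimental")),
            class = c("trial_snapshot", "data.frame"),
            analysis_time = time)
}

#' Calendar time of the n-th disease event
#'
#' The n-th order statistic of `entry + latent_event`; a snapshot taken at
#' exactly this instant contains `n` events (event-time ties, which have
#' probability zero under the continuous model, are broken by patient index).
#'
#' @param cohort A `trial_cohort`.
#' @param n Event rank, `1 <= n <= nrow(cohort)`.
#' @return Calendar time in years.
#' @export
calendar_time_of_nth_event <- function(cohort, n) {
  stopifnot(inherits(cohort, "trial_cohort"))
  if (n < 1 || n > nrow(cohort)) stop("`n` out of range")
  sort(cohort$entry + cohort$latent_event, partial = n)[n]
}

#' Read or write a cohort as a plain-text table
#'
#' Tab-separated with columns `arm`, `entry`, `latent_event`; used for small
#' fixtures and worked examples.
#'
#' @param cohort A `trial_cohort`.
#' @param path File path.
#' @param hazard_reduction Effect size recorded on the object read back in.
#' @return `read_cohort()` returns a `trial_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, hazard_reduction = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("arm", "entry", "latent_event") %in% names(df)))
  structure(df[c("arm", "entry", "latent_event")],
            class = c("trial_cohort", "data.frame"),
            hazard_reduction = hazard_reduction)
}
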