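#' Piecewise-constant hazard function
#'
#' Defines a hazard that is constant on intervals between `breakpoints`.
#' The default reproduces the control-arm disease-free-survival hazard of the
#' NSABP C-08 adjuvant colon-cancer trial: 0.089 events per person-year during
#' the first three years after randomization, 0.039 thereafter.
#'
#' @param breakpoints Times (years, strictly increasing) at which the hazard
#'   changes. May be empty for a plain exponential.
#' @param rates Positive hazard rates (events per person-year); one more entry
#'   than `breakpoints`.
#' @return An object of class `piecewise_hazard`.
#' @examples
#' h <- piecewise_hazard()
#' cumulative_hazard(h, c(1, 3, 5))
#' @export
piecewise_hazard <- function(breakpoints = 3, rates = c(0.089, 0.039)) {
  breakpoints <- as.numeric(breakpoints)
  rates <- as.numeric(rates)
  if (length(rates) != length(breakpoints) + 1L)
    stop("`rates` must have exactly one more entry than `breakpoints`")
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all hazard rates must be positive and finite")
  if (length(breakpoints) && (any(breakpoints <= 0) || is.unsorted(breakpoints, strictly = TRUE)))
    stop("`breakpoints` must be positive and strictly increasing")
  structure(list(breakpoints = breakpoints, rates = rates),
            class = "piecewise_hazard")
}

#' Cumulative hazard of a piecewise-constant hazard
#'
#' @param hazard A [piecewise_hazard()].
#' @param t Times in years (vectorized), all non-negative.
#' @return Cumulative hazard H(t); continuous, piecewise linear, strictly
#'   increasing, with H(0) = 0.
#' @export
cumulative_hazard <- function(hazard, t) {
  stopifnot(inherits(hazard, "piecewise_hazard"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("negative time in `cumulative_hazard`")
  starts <- c(0, hazard$breakpoints)           # left edge of each segment
  Hb <- c(0, cumsum(hazard$rates[-length(hazard$rates)] * diff(starts))[seq_along(hazard$breakpoints)])
  if (!length(hazard$breakpoints)) Hb <- 0
  seg <- findInterval(t, starts)               # >= 1 since t >= 0
  Hb[seg] + hazard$rates[seg] * (t - starts[seg])
}

#' Inverse cumulative hazard
#'
#' Solves H(t) = `target` for t; used by the event-time sampler.
#'
#' @param hazard A [piecewise_hazard()].
#' @param target Non-negative cumulative-hazard values (vectorized).
#' @return Times t with `cumulative_hazard(hazard, t) == target`.
#' @export
cumulative_hazard_inverse <- function(hazard, target) {
  stopifnot(inherits(hazard, "piecewise_hazard"))
  target <- as.numeric(target)
  if (any(target < 0)) stop("negative cumulative hazard in inverse")
  starts <- c(0, hazard$breakpoints)
  Hb <- c(0, cumsum(hazard$rates[-length(hazard$rates)] * diff(starts))[seq_along(hazard$breakpoints)])
  if (!length(hazard$breakpoints)) Hb <- 0
  seg <- findInterval(target, Hb)
  seg[seg < 1L] <- 1L
  starts[seg] + (target - Hb[seg]) / hazard$rates[seg]
}

#' Ramped patient-accrual model
#'
#' Monthly accrual rate rises linearly from `start_rate` to `end_rate` over
#' `ramp_months`, stays at `end_rate` afterwards, and stops once `total_n`
#' patients are enrolled. Defaults are the NSABP C-08 projections: 63 to 105
#' patients per month over two years, 2,632 patients in total (complete within
#' 30 months).
#'
#' @param start_rate Patients/month at month 0.
#' @param end_rate Patients/month at the end of the ramp.
#' @param ramp_months Ramp duration in months.
#' @param total_n Total number of patients.
#' @return An object of class `accrual_model`.
#' @export
accrual_model <- function(start_rate = 63, end_rate = 105, ramp_months = 24,
                          total_n = 2632) {
  if (start_rate <= 0 || end_rate <= 0 || ramp_months <= 0 || total_n < 1)
    stop("accrual parameters must be positive")
  structure(list(start_rate = start_rate, end_rate = end_rate,
                 ramp_months = ramp_months, total_n = as.integer(total_n)),
            class = "accrual_model")
}

# cumulative accrual before the total_n cap, t in months
.accrual_raw <- function(a, t) {
  slope <- (a$end_rate - a$start_rate) / a$ramp_months
  ifelse(t <= a$ramp_months,
         a$start_rate * t + slope * t^2 / 2,
         a$start_rate * a$ramp_months + slope * a$ramp_months^2 / 2 +
           a$end_rate * (t - a$ramp_months))
}

#' Expected cumulative accrual
#'
#' @param accrual An [accrual_model()].
#' @param t Calendar time in months (vectorized), non-negative.
#' @return Expected number of patients enrolled by month `t`, capped at
#'   `total_n`.
#' @export
expected_accrual <- function(accrual, t) {
  stopifnot(inherits(accrual, "accrual_model"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("negative time in `expected_accrual`")
  pmin(.accrual_raw(accrual, t), accrual$total_n)
}

#' Time at which a given cumulative accrual is reached
#'
#' Inverts the cumulative accrual curve; `accrual_completion_months(a)` is
#' `accrual_time_of(a, a$total_n)`.
#'
#' @param accrual An [accrual_model()].
#' @param count Patient counts in `[0, total_n]` (vectorized).
#' @return Calendar time in months.
#' @export
accrual_time_of <- function(accrual, count) {
  stopifnot(inherits(accrual, "accrual_model"))
  count <- as.numeric(count)
  if (any(count < 0) || any(count > accrual$total_n))
    stop("`count` must lie in [0, total_n]")
  a <- accrual
  slope <- (a$end_rate - a$start_rate) / a$ramp_months
  Aramp <- .accrual_raw(a, a$ramp_months)
  inv_ramp <- if (slope == 0) count / a$start_rate
              else (-a$start_rate + sqrt(a$start_rate^2 + 2 * slope * count)) / slope
  ifelse(count <= Aramp, inv_ramp,
         a$ramp_months + (count - Aramp) / a$end_rate)
}

#' @rdname accrual_time_of
#' @export
accrual_completion_months <- function(accrual) accrual_time_of(accrual, accrual$total_n)

#' Interim-analysis specification
#'
#' Each interim is triggered either by a cumulative event count or by a
#' calendar time, and carries a one-sided futility bound (on the right-sided
#' p-value) and a one-sided efficacy bound (on the left-sided p-value).
#'
#' @param trigger_events Event count trigger (or `NULL`).
#' @param trigger_time Calendar-time trigger in years (or `NULL`). Exactly one
#'   of the two triggers must be given.
#' @param futility_bound Stop for futility when the right-sided p-value falls
#'   below this.
#' @param efficacy_bound Stop for superiority when the left-sided p-value
#'   falls below this.
#' @return An object of class `interim_spec`.
#' @export
interim_spec <- function(trigger_events = NULL, trigger_time = NULL,
                         futility_bound, efficacy_bound) {
  if (is.null(trigger_events) == is.null(trigger_time))
    stop("give exactly one of `trigger_events` or `trigger_time`")
  structure(list(trigger_events = if (!is.null(trigger_events)) as.integer(trigger_events),
                 trigger_time = trigger_time,
                 futility_bound = futility_bound,
                 efficacy_bound = efficacy_bound),
            class = "interim_spec")
}

#' Final-analysis specification
#'
#' @param trigger_events Event count at which the final analysis occurs.
#' @param significance One-sided significance level for final success.
#' @return An object of class `final_spec`.
#' @export
final_spec <- function(trigger_events = 592, significance = 0.0246) {
  structure(list(trigger_events = as.integer(trigger_events),
                 significance = significance),
            class = "final_spec")
}

#' Group-sequential trial design
#'
#' Bundles accrual, the control-arm hazard, the allocation ratio, the interim
#' schedule and the final analysis. The experimental arm's hazard is the
#' control hazard scaled by a constant hazard ratio `1 - delta`, where `delta`
#' is the hazard reduction supplied to the simulator.
#'
#' @param accrual An [accrual_model()].
#' @param control_hazard A [piecewise_hazard()].
#' @param interims List of [interim_spec()] objects, in schedule order.
#' @param final A [final_spec()].
#' @param allocation Length-2 positive weights (control, experimental). Only
#'   1:1 allocation is currently supported.
#' @return An object of class `trial_design`.
#' @seealso [nsabp_c08_design()] for the packaged default.
#' @export
trial_design <- function(accrual, control_hazard, interims, final,
                         allocation = c(1, 1)) {
  design <- structure(list(accrual = accrual, control_hazard = control_hazard,
                           interims = interims, final = final,
                           allocation = allocation),
                      class = "trial_design")
  bad <- validate_design(design)
  if (length(bad)) stop("invalid trial design:\n  - ", paste(bad, collapse = "\n  - "))
  design
}

#' The published NSABP C-08 monitoring plan
#'
#' Returns the trial design used throughout the package's examples: 2,632
#' patients, accrual ramping 63 to 105/month over 24 months, control hazard
#' 0.089/0.039 with a break at 3 years, interim 1 triggered at 148 events,
#' interims 2-6 at calendar years 2.5-4.5, asymmetric one-sided boundaries
#' (futility 0.05, 0.25, then 0.5; efficacy 0.00025, 0.0005, then 0.001), and
#' a final log-rank analysis at 592 events at one-sided level 0.0246.
#'
#' @return A `trial_design`.
#' @export
nsabp_c08_design <- function() {
  fut <- c(0.05, 0.25, 0.5, 0.5, 0.5, 0.5)
  eff <- c(0.00025, 0.0005, 0.001, 0.001, 0.001, 0.001)
  interims <- vector("list", 6L)
  interims[[1]] <- interim_spec(trigger_events = 148,
                                futility_bound = fut[1], efficacy_bound = eff[1])
  times <- c(NA, 2.5, 3.0, 3.5, 4.0, 4.5)
  for (k in 2:6)
    interims[[k]] <- interim_spec(trigger_time = times[k],
                                  futility_bound = fut[k], efficacy_bound = eff[k])
  trial_design(accrual = accrual_model(),
               control_hazard = piecewise_hazard(),
               interims = interims,
               final = final_spec())
}

#' Validate a trial design
#'
#' Checks every structural invariant and returns human-readable messages for
#' the violated ones. Never raises; an empty character vector means the design
#' is internally consistent.
#'
#' @param design A `trial_design` (possibly malformed).
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_design <- function(design) {
  bad <- character()
  note <- function(msg) bad[[length(bad) + 1L]] <<- msg
  if (!inherits(design$accrual, "accrual_model"))
    note("`accrual` is not an accrual_model")
  if (!inherits(design$control_hazard, "piecewise_hazard"))
    note("`control_hazard` is not a piecewise_hazard")
  if (!inherits(design$final, "final_spec"))
    note("`final` is not a final_spec")
  if (length(design$allocation) != 2 || any(design$allocation <= 0))
    note("`allocation` must be two positive weights")
  else if (design$allocation[1] != design$allocation[2])
    note("only 1:1 allocation is supported")
  ks <- seq_along(design$interims)
  ev_triggers <- integer()
  for (k in ks) {
    it <- design$interims[[k]]
    if (!inherits(it, "interim_spec")) { note(sprintf("interim %d is not an interim_spec", k)); next }
    if (!is.null(it$trigger_events)) ev_triggers <- c(ev_triggers, it$trigger_events)
    # a zero bound disables that kind of stop (comparisons are strict), so
    # efficacy < futility is only required when futility stopping is active
    if (it$efficacy_bound < 0 || it$futility_bound > 1 ||
        (it$futility_bound > 0 && it$efficacy_bound >= it$futility_bound))
      note(sprintf("interim %d: bounds must satisfy 0 <= efficacy < futility <= 1 (got %g, %g)",
                   k, it$efficacy_bound, it$futility_bound))
  }
  # triggers strictly ordered within each trigger family
  evs <- Filter(Negate(is.null), lapply(design$interims, `[[`, "trigger_events"))
  tts <- Filter(Negate(is.null), lapply(design$interims, `[[`, "trigger_time"))
  if (length(evs) > 1 && is.unsorted(unlist(evs), strictly = TRUE))
    note("interim event-count triggers must be strictly increasing")
  if (length(tts) > 1 && is.unsorted(unlist(tts), strictly = TRUE))
    note("interim calendar triggers must be strictly increasing")
  if (inherits(design$final, "final_spec")) {
    if (length(ev_triggers) && design$final$trigger_events < max(ev_triggers))
      note(sprintf("final analysis (%d events) is triggered before interim event trigger (%d): final before interim",
                   design$final$trigger_events, max(ev_triggers)))
    if (design$final$significance <= 0 || design$final$significance >= 1)
      note("final significance level must lie in (0, 1)")
    if (inherits(design$accrual, "accrual_model") &&
        design$final$trigger_events > design$accrual$total_n)
      note("final event trigger exceeds the number of patients")
  }
  bad
}

#' Remove futility stopping from a design
#'
#' Sets every interim futility bound to zero so that no simulated trial can
#' stop for futility; efficacy boundaries are kept. Used for type-I-error
#' cross-checks against the efficacy-only alpha-spending calculation.
#'
#' @param design A `trial_design`.
#' @return A `trial_design` with futility disabled.
#' @export
disable_futility <- function(design) {
  for (k in seq_along(design$interims)) design$interims[[k]]$futility_bound <- 0
  design
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Group-sequential trial design\n")
  cat(sprintf("  patients: %d (1:1), accrual %g->%g/month over %g months\n",
              x$accrual$total_n, x$accrual$start_rate, x$accrual$end_rate,
              x$accrual$ramp_months))
  cat(sprintf("  control hazard: rates %s; breaks at %s years\n",
              paste(x$control_hazard$rates, collapse = "/"),
              paste(x$control_hazard$breakpoints, collapse = ", ")))
  for (k in seq_along(x$interims)) {
    it <- x$interims[[k]]
    trg <- if (!is.null(it$trigger_events)) sprintf("%d events", it$trigger_events)
           else sprintf("%.1f years", it$trigger_time)
    cat(sprintf("  interim %d at %s: futility p_right < %g, efficacy p_left < %g\n",
                k, trg, it$futility_bound, it$efficacy_bound))
  }
  cat(sprintf("  final at %d events, one-sided level %g\n",
              x$final$trigger_events, x$final$significance))
  invisible(x)
}

#' Read or write a trial design as a YAML config
#'
#' The config keys mirror the constructor arguments; `design_to_config()`
#' followed by `design_from_config()` round-trips exactly. The packaged file
#' `system.file("extdata", "nsabp_c08_design.yaml", package = "gspred")`
#' reproduces the published monitoring plan.
#'
#' @param path File path.
#' @param design A `trial_design`.
#' @return `design_from_config()` returns a validated `trial_design`;
#'   `design_to_config()` returns `path` invisibly.
#' @export
design_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  interims <- lapply(cfg$interims, function(it)
    interim_spec(trigger_events = it$trigger_events,
                 trigger_time = it$trigger_time,
                 futility_bound = it$futility_bound,
                 efficacy_bound = it$efficacy_bound))
  trial_design(
    accrual = do.call(accrual_model, cfg$accrual),
    control_hazard = piecewise_hazard(unlist(cfg$control_hazard$breakpoints),
                                      unlist(cfg$control_hazard$rates)),
    interims = interims,
    final = do.call(final_spec, cfg$final),
    allocation = if (is.null(cfg$allocation)) c(1, 1) else unlist(cfg$allocation))
}

#' @rdname design_from_config
#' @export
design_to_config <- function(design, path) {
  cfg <- list(
    accrual = design$accrual[c("start_rate", "end_rate", "ramp_months", "total_n")],
    control_hazard = list(breakpoints = design$control_hazard$breakpoints,
                          rates = design$control_hazard$rates),
    interims = lapply(design$interims, function(it)
      Filter(Negate(is.null), it[c("trigger_events", "trigger_time",
                                   "futility_bound", "efficacy_bound")])),
    final = design$final[c("trigger_events", "significance")],
    allocation = design$allocation)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
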