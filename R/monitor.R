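# Deterministic seed-splitting rule: each (delta, master-seed) pair names a
# stream, from which one 31-bit seed per replicate is drawn without
# replacement. Tables are therefore reproducible delta-by-delta and
# independent of evaluation order, and distinct master seeds produce
# unrelated replicate streams (a plain additive rule would make master
# seeds s and s+1 share almost all replicates).
.replicate_seeds <- function(master, delta, n) {
  set.seed((abs(master) + 1000003 * round(delta * 1000)) %% 2147483647)
  sample.int(2147483646, n)
}

# schedule unpacked once per sweep, not once per replicate
.prepare_schedule <- function(design) {
  K <- length(design$interims)
  list(K = K,
       ev_trigger = vapply(design$interims, function(it)
         if (is.null(it$trigger_events)) NA_integer_ else it$trigger_events, 0L),
       time_trigger = vapply(design$interims, function(it)
         if (is.null(it$trigger_time)) NA_real_ else it$trigger_time, 0),
       fut = vapply(design$interims, `[[`, 0, "futility_bound"),
       eff = vapply(design$interims, `[[`, 0, "efficacy_bound"),
       final_events = design$final$trigger_events,
       final_sig = design$final$significance)
}

# One pass through the analysis schedule. Returns a list with `outcome`
# ("stop_superiority", "stop_futility", "final_success", "final_fail"),
# `stopped_at` (analysis index; K+1 for the final), and, when record = TRUE,
# a per-analysis data frame of times, event counts and one-sided p-values.
# Interims whose realized time falls at or after the final trigger are
# skipped; an undefined log-rank statistic maps to "continue".
.run_trial_impl <- function(design, delta, sched, record = FALSE) {
  raw <- .simulate_cohort_raw(design, delta)
  entry <- raw$entry; latent <- raw$latent; is_control <- raw$is_control
  event_cal <- sort(entry + latent)
  t_final <- event_cal[sched$final_events]
  rec_time <- numeric(0); rec_events <- integer(0)
  rec_pl <- numeric(0); rec_pr <- numeric(0); rec_k <- integer(0)
  outcome <- NULL; stopped_at <- sched$K + 1L
  for (k in seq_len(sched$K)) {
    tk <- if (!is.na(sched$ev_trigger[k])) event_cal[sched$ev_trigger[k]]
          else sched$time_trigger[k]
    if (tk >= t_final) next                      # final supersedes this interim
    snap <- .snapshot_raw(entry, latent, is_control, tk)
    lr <- .logrank_core(snap$time, snap$event, snap$is_control)
    if (record) {
      rec_k <- c(rec_k, k); rec_time <- c(rec_time, tk)
      rec_events <- c(rec_events, sum(snap$event))
      rec_pl <- c(rec_pl, if (is.null(lr)) NA_real_ else lr$p_left)
      rec_pr <- c(rec_pr, if (is.null(lr)) NA_real_ else lr$p_right)
    }
    if (is.null(lr)) next                        # no test -> cannot stop
    if (lr$p_left < sched$eff[k]) { outcome <- "stop_superiority"; stopped_at <- k; break }
    if (lr$p_right < sched$fut[k]) { outcome <- "stop_futility"; stopped_at <- k; break }
  }
  if (is.null(outcome)) {
    snap <- .snapshot_raw(entry, latent, is_control, t_final)
    lr <- .logrank_core(snap$time, snap$event, snap$is_control)
    win <- !is.null(lr) && lr$p_left < sched$final_sig
    outcome <- if (win) "final_success" else "final_fail"
    if (record) {
      rec_k <- c(rec_k, sched$K + 1L); rec_time <- c(rec_time, t_final)
      rec_events <- c(rec_events, sum(snap$event))
      rec_pl <- c(rec_pl, if (is.null(lr)) NA_real_ else lr$p_left)
      rec_pr <- c(rec_pr, if (is.null(lr)) NA_real_ else lr$p_right)
    }
  }
  out <- list(outcome = outcome, stopped_at = stopped_at)
  if (record)
    out$analyses <- data.frame(analysis = rec_k, time = rec_time,
                               events = rec_events, p_left = rec_pl,
                               p_right = rec_pr)
  out
}

#' Run one simulated trial through its monitoring schedule
#'
#' Simulates a cohort and walks the analysis schedule in order. At each
#' interim the trial stops for superiority when `p_left` falls below the
#' efficacy bound, otherwise for futility when `p_right` falls below the
#' futility bound (superiority is checked first; with asymmetric bounds the
#' two can never be crossed simultaneously). At the final analysis (triggered
#' by the design's final event count) the trial succeeds when `p_left` is
#' below the final significance level, and fails otherwise. Interims whose
#' realized time falls after the final trigger are skipped, mirroring a trial
#' whose events accumulate faster than projected.
#'
#' @param design A validated `trial_design`.
#' @param hazard_reduction Treatment effect `delta` in `[0, 1)`.
#' @param seed Optional integer seed for a reproducible replicate.
#' @return An object of class `trial_result`: `outcome` (one of
#'   `"stop_superiority"`, `"stop_futility"`, `"final_success"`,
#'   `"final_fail"`), `stopped_at` (analysis index; `K + 1` means the final
#'   analysis of a schedule with `K` interims), and `analyses`, a data frame
#'   with one row per analysis actually performed (calendar time, event
#'   count, one-sided p-values).
#' @export
run_trial <- function(design, hazard_reduction, seed = NULL) {
  if (hazard_reduction < 0 || hazard_reduction >= 1)
    stop("`hazard_reduction` must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  res <- .run_trial_impl(design, hazard_reduction, .prepare_schedule(design),
                         record = TRUE)
  res$hazard_reduction <- hazard_reduction
  class(res) <- "trial_result"
  res
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Simulated trial (hazard reduction %.0f%%): %s at analysis %d\n",
              100 * x$hazard_reduction, x$outcome, x$stopped_at))
  print(x$analyses, row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo outcome table for one treatment effect
#'
#' Runs `n_reps` independent replicates of [run_trial()] and tabulates, for
#' each analysis, the probability of stopping for superiority, stopping for
#' futility, and continuing, plus the final success and failure
#' probabilities. The counts partition the replicates, so the probabilities
#' sum to one exactly. Each replicate uses its own derived seed, so tables
#' are reproducible independently of evaluation order.
#'
#' @param design A validated `trial_design`.
#' @param hazard_reduction Treatment effect `delta` in `[0, 1)`.
#' @param n_reps Number of replicates (the original analysis used 70,000 per
#'   effect; a few thousand give percent-level Monte-Carlo error).
#' @param seed Master integer seed.
#' @return An object of class `outcome_table`: `delta`, `n_reps`, vectors
#'   `sup`, `fut`, `continue_past` (length `K`), scalars `final_success`,
#'   `final_fail`, the raw `counts`, and Monte-Carlo standard errors `se`.
#' @export
estimate_outcome_table <- function(design, hazard_reduction, n_reps,
                                   seed = 1L) {
  stopifnot(n_reps >= 1)
  sched <- .prepare_schedule(design)
  K <- sched$K
  sup_n <- integer(K); fut_n <- integer(K); fs_n <- 0L; ff_n <- 0L
  rep_seeds <- .replicate_seeds(seed, hazard_reduction, n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    res <- .run_trial_impl(design, hazard_reduction, sched)
    switch(res$outcome,
           stop_superiority = sup_n[res$stopped_at] <- sup_n[res$stopped_at] + 1L,
           stop_futility = fut_n[res$stopped_at] <- fut_n[res$stopped_at] + 1L,
           final_success = fs_n <- fs_n + 1L,
           final_fail = ff_n <- ff_n + 1L)
  }
  .outcome_table(hazard_reduction, n_reps, sup_n, fut_n, fs_n, ff_n, seed)
}

.outcome_table <- function(delta, n_reps, sup_n, fut_n, fs_n, ff_n, seed = NA) {
  sup <- sup_n / n_reps; fut <- fut_n / n_reps
  fs <- fs_n / n_reps; ff <- ff_n / n_reps
  cont <- 1 - cumsum(sup + fut)
  se <- function(p) sqrt(p * (1 - p) / n_reps)
  structure(list(delta = delta, n_reps = as.integer(n_reps),
                 sup = sup, fut = fut, continue_past = cont,
                 final_success = fs, final_fail = ff,
                 counts = list(sup = as.integer(sup_n), fut = as.integer(fut_n),
                               final_success = as.integer(fs_n),
                               final_fail = as.integer(ff_n)),
                 se = list(sup = se(sup), fut = se(fut),
                           final_success = se(fs), final_fail = se(ff)),
                 seed = seed),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat(sprintf("Outcome table: hazard reduction %.0f%%, %d replicates\n",
              100 * x$delta, x$n_reps))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  p <- sum(x$sup) + x$final_success
  cat(sprintf("P(statistical success) = %.4f (MC SE %.4f)\n",
              p, sqrt(max(0, p * (1 - p)) / x$n_reps)))
  invisible(x)
}

#' @export
as.data.frame.outcome_table <- function(x, ...) {
  K <- length(x$sup)
  data.frame(delta = x$delta,
             analysis = c(as.character(seq_len(K)), "final"),
             p_superiority = c(x$sup, x$final_success),
             p_futility = c(x$fut, 0),
             p_continue = c(x$continue_past, x$final_fail),
             n_reps = x$n_reps)
}

#' Sweep outcome tables across a grid of treatment effects
#'
#' One [estimate_outcome_table()] per hazard reduction, with independent
#' derived seed streams so that any single table can be re-estimated on its
#' own. When `cache_dir` is given, each table is stored as JSON keyed by a
#' fingerprint of (design, delta, n_reps, seed) and reused on the next call:
#' the expensive step is the sweep, re-mixing with new priors is cheap.
#'
#' @param design A validated `trial_design`.
#' @param deltas Hazard reductions in `[0, 1)`; default is the practical grid
#'   0 to 40% in 5% steps.
#' @param n_reps Replicates per effect.
#' @param seed Master integer seed.
#' @param cache_dir Optional directory for cached tables.
#' @param verbose Print progress.
#' @return A named list of `outcome_table`s (class `outcome_sweep`), one per
#'   delta, names formatted as percentages.
#' @export
sweep_effects <- function(design, deltas = (0:8) / 20, n_reps,
                          seed = 1L, cache_dir = NULL, verbose = FALSE) {
  stopifnot(length(deltas) >= 1, all(deltas >= 0 & deltas < 1))
  fp <- .design_fingerprint(design)
  out <- vector("list", length(deltas))
  names(out) <- .delta_key(deltas)
  for (i in seq_along(deltas)) {
    d <- deltas[i]
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("gspred_%s_d%04d_n%d_s%d.json",
                                   fp, round(d * 1000), n_reps, seed))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      out[[i]] <- .outcome_table_from_list(jsonlite::read_json(cache_file,
                                                               simplifyVector = TRUE))
    } else {
      out[[i]] <- estimate_outcome_table(design, d, n_reps, seed)
      if (!is.null(cache_file)) {
        dir.create(dirname(cache_file), showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(.outcome_table_as_list(out[[i]]), cache_file,
                             auto_unbox = TRUE, digits = NA)
      }
    }
    if (verbose)
      message(sprintf("delta = %.2f: P(success) = %.4f", d,
                      sum(out[[i]]$sup) + out[[i]]$final_success))
  }
  class(out) <- "outcome_sweep"
  out
}

.delta_key <- function(delta) sprintf("%g%%", 100 * delta)

# small rolling hash over the serialized design, for cache keys only
.design_fingerprint <- function(design) {
  b <- as.integer(serialize(design, NULL, version = 2))
  h <- 17
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

.outcome_table_as_list <- function(x)
  list(delta = x$delta, n_reps = x$n_reps, counts = x$counts, seed = x$seed)

.outcome_table_from_list <- function(l)
  .outcome_table(l$delta, l$n_reps, l$counts$sup, l$counts$fut,
                 l$counts$final_success, l$counts$final_fail, l$seed)

#' Serialize outcome tables
#'
#' `write_outcome_tables()` writes either a delimited table (one row per
#' (delta, analysis); the final row's `p_superiority`/`p_continue` columns
#' hold the final success and failure probabilities) or a compact JSON form
#' holding the raw replicate counts. Both round-trip losslessly through
#' `read_outcome_tables()`; the JSON form is the one the cache uses.
#'
#' @param tables An `outcome_sweep` (or list of `outcome_table`s).
#' @param path Output path; format chosen by extension (`.json` or anything
#'   else for tab-delimited text).
#' @return `read_outcome_tables()` returns an `outcome_sweep`;
#'   `write_outcome_tables()` returns `path` invisibly.
#' @export
write_outcome_tables <- function(tables, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lapply(unclass(tables), .outcome_table_as_list), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    df <- do.call(rbind, lapply(tables, function(x) {
      d <- as.data.frame(x)
      d$count_superiority <- c(x$counts$sup, x$counts$final_success)
      d$count_futility <- c(x$counts$fut, 0L)
      d$count_continue <- c(x$n_reps - cumsum(x$counts$sup + x$counts$fut),
                            x$counts$final_fail)
      d$seed <- x$seed
      d
    }))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_outcome_tables
#' @export
read_outcome_tables <- function(path) {
  if (grepl("\\.json$", path)) {
    l <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- lapply(l, .outcome_table_from_list)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    out <- lapply(split(df, df$delta), function(d) {
      d <- d[order(match(d$analysis, c(as.character(seq_len(nrow(d) - 1)), "final"))), ]
      K <- nrow(d) - 1L
      .outcome_table(d$delta[1], d$n_reps[1],
                     d$count_superiority[seq_len(K)], d$count_futility[seq_len(K)],
                     d$count_superiority[K + 1L], d$count_continue[K + 1L],
                     d$seed[1])
    })
    out <- out[order(as.numeric(names(out)))]
  }
  names(out) <- .delta_key(vapply(out, `[[`, 0, "delta"))
  class(out) <- "outcome_sweep"
  out
}
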