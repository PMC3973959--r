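#' Predictive-probability report for a monitored trial
#'
#' Mixes per-effect outcome tables over a discrete prior to produce, for each
#' analysis (interims 1..K and the final), the predictive probabilities a
#' public observer can state before the trial starts: `suc`/`fut` (success or
#' futility declared at that analysis), `undec` (no decision: the trial
#' continues, or at the final analysis ends without statistical
#' significance), the same conditioned on "no decision at any previous
#' analysis" (`suc|undec`, `fut|undec`), and the eventual-outcome
#' probabilities given continuation through the previous analysis
#' (`eventual suc|undec`, `eventual fut|undec`, `eventual fail|undec`, which
#' sum to one).
#'
#' Every conditional column is a ratio of prior-weighted joint probabilities
#' (numerator: outcome and continued through k-1; denominator: continued
#' through k-1). Mixing per-effect conditional probabilities directly would
#' be wrong - conditioning re-weights the effects to their posterior - and
#' that distinction is the heart of the method.
#'
#' @param prior A `discrete_prior`.
#' @param tables An `outcome_sweep` covering the prior's support, all with
#'   the same analysis schedule.
#' @return An object of class `predictive_report`: a data frame with one row
#'   per analysis (the last labeled `"final"`) and columns `suc`, `fut`,
#'   `undec`, `cum_suc`, `cum_fut`, `suc_undec`, `fut_undec`,
#'   `ev_suc_undec`, `ev_fut_undec`, `ev_fail_undec`.
#' @export
predictive_report <- function(prior, tables) {
  stopifnot(inherits(prior, "discrete_prior"))
  tabs <- lapply(prior$support, function(d) .table_for(tables, d))
  K <- length(tabs[[1]]$sup)
  if (!all(vapply(tabs, function(t) length(t$sup), 0L) == K))
    stop("outcome tables disagree on the number of interim analyses")
  w <- prior$prob
  S <- t(vapply(tabs, function(t) c(t$sup, t$final_success), numeric(K + 1)))
  F <- t(vapply(tabs, function(t) c(t$fut, 0), numeric(K + 1)))
  FAIL <- vapply(tabs, `[[`, 0, "final_fail")
  C <- t(vapply(tabs, function(t) c(1, t$continue_past), numeric(K + 1)))
  # C[, j] = P(continue past analysis j-1 | delta); C[, K+1] = P(reach final)

  suc <- as.vector(w %*% S)
  fut <- as.vector(w %*% F)
  undec <- c(as.vector(w %*% C[, -1, drop = FALSE])[seq_len(K)], sum(w * FAIL))
  reach <- as.vector(w %*% C)                       # mixture P(continued through k-1)
  ev_suc_joint <- t(apply(S[, (K + 1):1, drop = FALSE], 1, cumsum))[, (K + 1):1, drop = FALSE]
  ev_fut_joint <- t(apply(F[, (K + 1):1, drop = FALSE], 1, cumsum))[, (K + 1):1, drop = FALSE]
  df <- data.frame(
    analysis = c(as.character(seq_len(K)), "final"),
    suc = suc, fut = fut, undec = undec,
    cum_suc = cumsum(suc), cum_fut = cumsum(fut),
    suc_undec = suc / reach, fut_undec = fut / reach,
    ev_suc_undec = as.vector(w %*% ev_suc_joint) / reach,
    ev_fut_undec = as.vector(w %*% ev_fut_joint) / reach,
    ev_fail_undec = sum(w * FAIL) / reach)
  structure(df, class = c("predictive_report", "data.frame"),
            prior = prior, n_interims = K)
}

#' Eventual-outcome summary after k continuation announcements
#'
#' The predictive probabilities of the trial's three terminal outcomes -
#' eventual statistical success, stopping early for futility, and continuing
#' to completion without statistical significance - conditional on the trial
#' having continued through interim `k`. `k = 0` gives the pre-trial
#' (prior-predictive) summary. The three probabilities sum to one.
#'
#' @param report A `predictive_report`.
#' @param k Number of interims known to have continued
#'   (`0 <= k <=` number of interims).
#' @return Named numeric vector `c(success, futility, fail)`.
#' @export
eventual_outcome_summary <- function(report, k = 0) {
  K <- attr(report, "n_interims")
  stopifnot(inherits(report, "predictive_report"), k >= 0, k <= K)
  row <- k + 1L
  c(success = report$ev_suc_undec[row],
    futility = report$ev_fut_undec[row],
    fail = report$ev_fail_undec[row])
}

#' @export
print.predictive_report <- function(x, ...) {
  prior <- attr(x, "prior")
  cat("Predictive report",
      if (!is.null(prior$name)) sprintf("(prior: %s)", prior$name), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  s <- eventual_outcome_summary(x, 0)
  cat(sprintf("Overall: success %.1f%%, futility %.1f%%, undecided %.1f%%\n",
              100 * s[1], 100 * s[2], 100 * s[3]))
  invisible(x)
}

#' Write a predictive report as a delimited table
#'
#' Emits the spreadsheet-style column headings (`suc`, `fut`, `undec`,
#' `suc|undec`, `fut|undec`, `eventual suc|undec`, `eventual fut|undec`,
#' `eventual fail|undec`), one row per analysis with the last row labeled
#' `"final"`.
#'
#' @param report A `predictive_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- data.frame(report$analysis, report$suc, report$fut, report$undec,
                   report$suc_undec, report$fut_undec, report$ev_suc_undec,
                   report$ev_fut_undec, report$ev_fail_undec)
  names(df) <- c("analysis", "suc", "fut", "undec", "suc|undec", "fut|undec",
                 "eventual suc|undec", "eventual fut|undec",
                 "eventual fail|undec")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
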