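# Core two-sample log-rank arithmetic on flat vectors; the simulation hot
# path calls this directly. Distinct event times are grouped and the
# multi-event hypergeometric variance term is used, so tied times are handled
# exactly as in the standard definition. Returns NULL when the statistic is
# undefined (no events, or variance zero because risk sets are single-arm).
.logrank_core <- function(time, event, is_control) {
  ord <- order(time, method = "radix")
  t <- time[ord]; d <- event[ord]; g <- is_control[ord]
  n <- length(t)
  te <- t[d]
  if (!length(te)) return(NULL)
  ut <- unique(te)                                # sorted: te is sorted
  # at risk just before each distinct event time u: #(t >= u)
  nrisk <- n - findInterval(ut, t, left.open = TRUE)
  tc <- t[g]
  nrisk1 <- length(tc) - findInterval(ut, tc, left.open = TRUE)
  idx <- findInterval(te, ut)
  dj <- tabulate(idx, nbins = length(ut))
  tec <- t[d & g]
  d1j <- if (length(tec)) tabulate(findInterval(tec, ut), nbins = length(ut))
         else numeric(length(ut))
  frac <- nrisk1 / nrisk
  O1 <- sum(d1j)
  E1 <- sum(dj * frac)
  vterm <- dj * frac * (1 - frac) * (nrisk - dj) / pmax(nrisk - 1, 1)
  vterm[nrisk <= 1] <- 0
  V <- sum(vterm)
  if (V <= 0) return(NULL)
  z <- (O1 - E1) / sqrt(V)
  list(z = z,
       p_left = stats::pnorm(z, lower.tail = FALSE),
       p_right = stats::pnorm(z),
       observed = c(control = O1, experimental = sum(dj) - O1),
       expected = c(control = E1, experimental = sum(dj) - E1),
       variance = V)
}

#' Two-sample log-rank test with one-sided p-values
#'
#' Standard (unweighted) log-rank statistic over the distinct event times of a
#' snapshot, standardized with the hypergeometric variance. The sign
#' convention matches sequential-monitoring practice for a superiority trial:
#' `z > 0` when the control arm has experienced more events than expected,
#' i.e. when the trend favors the experimental arm. The left-sided p-value
#' `p_left = 1 - pnorm(z)` is small when the experimental arm looks superior
#' (it is compared against efficacy boundaries); the right-sided p-value
#' `p_right = pnorm(z)` is small when it looks inferior (futility boundaries).
#' The two always sum to one.
#'
#' @param snapshot A `trial_snapshot` (see [snapshot_at()]), or any data frame
#'   with columns `time`, `event` and `arm`.
#' @return An object of class `logrank_result`: a list with `z`, `p_left`,
#'   `p_right`, per-arm `observed` and `expected` event counts, and the
#'   hypergeometric `variance`.
#' @examples
#' snap <- data.frame(time = 1:6, event = TRUE,
#'                    arm = rep(c("control", "experimental"), each = 3))
#' logrank_test(snap)
#' @export
logrank_test <- function(snapshot) {
  stopifnot(all(c("time", "event", "arm") %in% names(snapshot)))
  res <- .logrank_core(as.numeric(snapshot$time),
                       as.logical(snapshot$event),
                       snapshot$arm == "control")
  if (is.null(res))
    stop("log-rank statistic undefined: no events, or all events in risk sets ",
         "with a single arm represented")
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: z = %.4f, p_left = %.5g, p_right = %.5g\n",
              x$z, x$p_left, x$p_right))
  cat(sprintf("  control: observed %g, expected %.2f; variance %.2f\n",
              x$observed["control"], x$expected["control"], x$variance))
  invisible(x)
}
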