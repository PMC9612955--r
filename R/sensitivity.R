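#' Nonparametric sensitivity statistic A
#'
#' Computes the nonparametric signal-detection sensitivity index A from hit
#' and false-alarm rates.  A lies in \[0, 1\]: 1 is perfect discrimination,
#' 0.5 is chance, 0 means every response is incorrect.  Unlike d', A remains
#' defined when rates sit at or near 0 or 1, which is why it is the standard
#' per-trial performance score for short n-back streams.
#'
#' The statistic uses the three-case piecewise form
#' \deqn{A = \frac{3}{4} + \frac{H-F}{4} - \begin{cases}
#'   F(1-H) & F \le 0.5 \le H \\
#'   F/(4H) & F \le H < 0.5 \\
#'   (1-H)/(4(1-F)) & 0.5 < F \le H
#' \end{cases}}
#' extended below the chance diagonal by the symmetry
#' \eqn{A(H, F) = 1 - A(F, H)}.  On the diagonal (including the corners
#' \eqn{H=F=0} and \eqn{H=F=1}, where the case formulas are 0/0) A is defined
#' as 0.5, so the symmetry identity and monotonicity hold everywhere; for
#' \eqn{F = 0 < H} the term \eqn{F/(4H)} is taken as 0.
#'
#' @param h hit rate(s) in \[0, 1\].
#' @param f false-alarm rate(s) in \[0, 1\]; recycled against `h`.
#' @return numeric vector of A values in \[0, 1\].
#' @examples
#' a_sensitivity(1, 0)     # perfect observer: 1
#' a_sensitivity(0.7, 0.7) # chance: 0.5
#' a_sensitivity(0.8, 0.2) # 0.86
#' @export
a_sensitivity <- function(h, f) {
  if (!is.numeric(h) || !is.numeric(f))
    stop("`h` and `f` must be numeric")
  n <- max(length(h), length(f))
  h <- rep_len(h, n); f <- rep_len(f, n)
  if (anyNA(h) || anyNA(f) || any(h < 0 | h > 1) || any(f < 0 | f > 1))
    stop("hit and false-alarm rates must lie in [0, 1]")
  upper <- function(hh, ff) {
    # A on or above the chance diagonal (ff <= hh)
    out <- numeric(length(hh))
    d <- (hh - ff) / 4
    c1 <- ff <= 0.5 & hh >= 0.5
    c2 <- hh < 0.5               # implies ff <= hh < 0.5
    c3 <- ff > 0.5               # implies 0.5 < ff <= hh
    out[c1] <- 0.75 + d[c1] - ff[c1] * (1 - hh[c1])
    out[c2] <- 0.75 + d[c2] - ifelse(ff[c2] == 0, 0, ff[c2] / (4 * hh[c2]))
    out[c3] <- 0.75 + d[c3] - (1 - hh[c3]) / (4 * (1 - ff[c3]))
    out
  }
  a <- numeric(n)
  diag_ <- h == f
  up <- !diag_ & h > f
  lo <- !diag_ & h < f
  a[diag_] <- 0.5
  a[up] <- upper(h[up], f[up])
  a[lo] <- 1 - upper(f[lo], h[lo])
  a
}

#' Score a response stream into hit/false-alarm rates and A
#'
#' Classifies each scoreable stimulus of a response stream as a hit, miss,
#' false alarm, or correct rejection and returns counts, rates, and the A
#' sensitivity statistic.  For the 2-back task a "same" response to a 2-back
#' match is a hit and a "same" response to a non-match is a false alarm; the
#' first two letters of a stream have no 2-back referent and are excluded.
#' For the left--right arrow control task the left arrow is (by convention)
#' the signal category: a "left" response to a left arrow is a hit and a
#' "left" response to a right arrow is a false alarm.  A is invariant to
#' swapping the signal assignment.  Omitted responses carry no signal
#' response, so they score as misses on targets and correct rejections on
#' non-targets.
#'
#' @param stream a data frame with logical columns `target` (is the stimulus
#'   in the signal category; `NA` marks unscoreable stimuli) and `response`
#'   (did the observer give the signal response; `NA` is an omission), e.g.
#'   from [simulate_nback_stream()].
#' @param task `"2back"` or `"LR"`; recorded in the result (the scoring rule
#'   is shared, only the signal convention differs).
#' @return an object of class `trial_score`: a list with `n_targets`,
#'   `n_nontargets`, `hits`, `false_alarms`, `H`, `F`, `A`, `degenerate`,
#'   and `task`.
#' @export
score_stream <- function(stream, task = c("2back", "LR")) {
  task <- match.arg(task)
  if (!is.data.frame(stream) || nrow(stream) == 0)
    stop("`stream` must be a non-empty data frame")
  if (!all(c("target", "response") %in% names(stream)))
    stop("`stream` needs columns `target` and `response`")
  s <- stream[!is.na(stream$target), , drop = FALSE]
  said_signal <- !is.na(s$response) & s$response
  n_t <- sum(s$target)
  n_n <- sum(!s$target)
  hits <- sum(s$target & said_signal)
  fas <- sum(!s$target & said_signal)
  degenerate <- n_t < 1L || n_n < 1L
  H <- if (n_t > 0) hits / n_t else NA_real_
  F <- if (n_n > 0) fas / n_n else NA_real_
  A <- if (degenerate) NA_real_ else a_sensitivity(H, F)
  structure(list(n_targets = n_t, n_nontargets = n_n, hits = hits,
                 false_alarms = fas, H = H, F = F, A = A,
                 degenerate = degenerate, task = task),
            class = "trial_score")
}

#' @export
as.data.frame.trial_score <- function(x, ...) {
  data.frame(hits = x$hits, fas = x$false_alarms, n_targets = x$n_targets,
             n_nontargets = x$n_nontargets, A = x$A)
}

#' @export
print.trial_score <- function(x, ...) {
  cat(sprintf("%s stream: %d targets, %d non-targets\n", x$task,
              x$n_targets, x$n_nontargets))
  cat(sprintf("  H = %.3f (%d hits), F = %.3f (%d false alarms)\n",
              x$H, x$hits, x$F, x$false_alarms))
  if (x$degenerate) cat("  degenerate stream: A undefined\n")
  else cat(sprintf("  A = %.3f\n", x$A))
  invisible(x)
}
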