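#' Fit a thermal temperature-response curve and invert it
#'
#' Fits separate monotone response curves to the warmth-rated (nonpainful)
#' and pain-rated stimulations of a method-of-constant-stimuli session and
#' inverts them to find the participant's working temperatures: the low
#' temperature rated 80/100 on the warmth scale and the high temperature
#' rated 60/100 on the pain scale.  Each branch is an ordinary
#' least-squares line of rating on temperature; if a branch's slope is not
#' positive the fit falls back to isotonic regression and inverts the step
#' function by interpolation.  Both inverted temperatures are clipped to
#' the stimulated range of 40--49 degrees C.
#'
#' @param ratings data frame with one row per stimulation and columns
#'   `temperature` (degrees C), `painful` (logical), and `rating` (0--100;
#'   warmth rating when not painful, pain-intensity rating when painful).
#' @param warmth_target,pain_target the rating levels to invert at.
#' @return an object of class `thermal_calibration`: a list with
#'   `low_temp`, `high_temp`, per-branch coefficients and method, and the
#'   number of stimulations used.
#' @export
fit_thermal_curve <- function(ratings, warmth_target = 80, pain_target = 60) {
  req <- c("temperature", "painful", "rating")
  miss <- setdiff(req, names(ratings))
  if (length(miss)) stop("`ratings` is missing column(s): ",
                         paste(miss, collapse = ", "))
  painful <- as.logical(ratings$painful)
  if (!any(painful))
    stop("thermal calibration failed: no stimulation was rated painful, ",
         "so the pain branch cannot be fitted")
  warm <- ratings[!painful, , drop = FALSE]
  pain <- ratings[painful, , drop = FALSE]
  if (length(unique(warm$temperature)) < 2L)
    stop("need warmth ratings at >= 2 distinct temperatures")
  if (length(unique(pain$temperature)) < 2L)
    stop("need pain ratings at >= 2 distinct temperatures")

  invert_branch <- function(d, target, label) {
    cf <- coef(stats::lm(rating ~ temperature, data = d))
    if (is.na(cf[2]) || cf[2] == 0)
      stop("thermal calibration failed: the ", label,
           " rating curve is flat, inversion undefined")
    if (cf[2] > 0) {
      list(temp = (target - cf[1]) / cf[2], coef = cf, method = "ols")
    } else {
      # non-increasing line: fall back to a monotone step fit
      iso <- isoreg(d$temperature, d$rating)
      xs <- sort(unique(d$temperature))
      ys <- vapply(xs, function(x) max(iso$yf[iso$x == x]), numeric(1))
      if (diff(range(ys)) == 0)
        stop("thermal calibration failed: the ", label,
             " rating curve is flat, inversion undefined")
      tmp <- approx(ys, xs, xout = target, ties = "ordered", rule = 2)$y
      list(temp = tmp, coef = cf, method = "isotonic")
    }
  }
  wfit <- invert_branch(warm, warmth_target, "warmth")
  pfit <- invert_branch(pain, pain_target, "pain")
  low <- min(max(wfit$temp, 40), 49)
  high <- min(max(pfit$temp, 40), 49)
  if (low >= high)
    warning("calibrated low temperature is not below the high temperature",
            call. = FALSE)
  structure(list(low_temp = low, high_temp = high,
                 low_temp_raw = wfit$temp, high_temp_raw = pfit$temp,
                 warmth_coef = wfit$coef, pain_coef = pfit$coef,
                 warmth_method = wfit$method, pain_method = pfit$method,
                 n_stimulations = nrow(ratings)),
            class = "thermal_calibration")
}

#' @export
print.thermal_calibration <- function(x, ...) {
  cat(sprintf("thermal calibration (%d stimulations)\n", x$n_stimulations))
  cat(sprintf("  low (warmth 80):  %.2f C  [%s fit]\n", x$low_temp,
              x$warmth_method))
  cat(sprintf("  high (pain 60):   %.2f C  [%s fit]\n", x$high_temp,
              x$pain_method))
  invisible(x)
}

#' Adaptive staircase calibration of the interstimulus interval
#'
#' Runs the 15-trial 2-back staircase that titrates the interstimulus
#' interval (ISI) toward a target sensitivity band.  After each trial the
#' stream is scored with [score_stream()]: if A exceeds the band the ISI is
#' divided by the current step factor (the task speeds up), if A falls
#' below the band the ISI is multiplied by it, otherwise it is held.  Steps
#' are multiplicative starting at x1.5, and the factor's distance from 1
#' halves after every direction reversal, so the procedure settles within
#' the trial budget.  The ISI is clamped to the presentable range of 19 to
#' 2583 ms throughout.
#'
#' @param observer a function of `isi` returning a response stream (see
#'   [simulate_nback_stream()]); its expected A should be monotone
#'   non-increasing as the ISI shrinks.
#' @param n_trials maximum staircase trials.
#' @param band target A band, `c(lower, upper)`.
#' @param isi_start starting ISI in ms.
#' @param step_factor initial multiplicative step.
#' @param seed optional integer seed (governs the observer's streams when
#'   the observer uses the session RNG).
#' @return an object of class `isi_calibration`: list with `final_isi`, a
#'   `trajectory` data frame `(trial, isi, A)`, and `monotone_warning`.
#' @export
run_isi_staircase <- function(observer, n_trials = 15L,
                              band = c(0.75, 0.85), isi_start = 1250,
                              step_factor = 1.5, seed = NULL) {
  stopifnot(is.function(observer), n_trials >= 1L, length(band) == 2L,
            band[1] < band[2])
  with_seed(seed, {
    isi <- min(max(isi_start, 19), 2583)
    fac <- step_factor
    last_dir <- 0L
    traj <- data.frame(trial = integer(), isi = numeric(), A = numeric())
    for (k in seq_len(n_trials)) {
      sc <- score_stream(observer(isi), task = "2back")
      A <- sc$A
      if (is.na(A)) A <- 0.5 # degenerate stream: treat as chance
      traj <- rbind(traj, data.frame(trial = k, isi = isi, A = A))
      dir <- if (A > band[2]) -1L else if (A < band[1]) 1L else 0L
      if (dir != 0L) {
        if (last_dir != 0L && dir != last_dir) fac <- 1 + (fac - 1) / 2
        isi <- if (dir < 0L) isi / fac else isi * fac
        isi <- min(max(isi, 19), 2583)
        last_dir <- dir
      }
    }
    mono_warn <- FALSE
    if (length(unique(traj$isi)) >= 5L) {
      rho <- suppressWarnings(stats::cor(traj$isi, traj$A,
                                         method = "spearman"))
      mono_warn <- is.finite(rho) && rho < -0.5
      if (mono_warn)
        warning("observed A decreased with longer ISIs: ",
                "observer looks non-monotone", call. = FALSE)
    }
    structure(list(final_isi = isi, trajectory = traj,
                   monotone_warning = mono_warn),
              class = "isi_calibration")
  })
}

#' @export
print.isi_calibration <- function(x, ...) {
  cat(sprintf("ISI staircase: %d trials, final ISI = %.0f ms\n",
              nrow(x$trajectory), x$final_isi))
  cat(sprintf("  A range over trials: %.2f - %.2f\n",
              min(x$trajectory$A), max(x$trajectory$A)))
  invisible(x)
}

#' Calibrate the pain-for-money reward amount
#'
#' Fits a maximum-likelihood logistic regression of accept/reject decisions
#' on the offered dollar amount and inverts it at the 95% acceptance level:
#' `amount_95 = (logit(0.95) - intercept) / slope`, clamped to the allowed
#' offer range of $0.50 to $3.00.  Complete separation (including the
#' all-accept and all-reject tables) falls back to the midpoint between the
#' highest rejected and lowest accepted offers, with a warning; a
#' non-positive fitted slope clamps the amount to $3.00 with a warning.
#'
#' @param choices data frame with columns `offer` (dollars, in \[0, 3\])
#'   and `accept` (logical).
#' @return an object of class `money_calibration`: list with `intercept`,
#'   `slope`, `amount_95` (clamped), `amount_95_raw` (unclamped), `method`
#'   (`"mle"`, `"separation"` or `"nonpositive_slope"`), and `n_choices`.
#' @export
fit_money_acceptance <- function(choices) {
  miss <- setdiff(c("offer", "accept"), names(choices))
  if (length(miss)) stop("`choices` is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(choices$offer < 0 | choices$offer > 3))
    stop("offers must lie in [0, 3] dollars")
  acc <- as.logical(choices$accept)
  off <- choices$offer
  n <- length(acc)
  target <- qlogis(0.95)

  separation <- function() {
    hi_rej <- if (any(!acc)) max(off[!acc]) else -Inf
    lo_acc <- if (any(acc)) min(off[acc]) else Inf
    raw <- if (!any(acc)) Inf else if (!any(!acc)) -Inf
    else (hi_rej + lo_acc) / 2
    warning("complete separation in pain-for-money choices; ",
            "using the midpoint-between-extremes rule", call. = FALSE)
    structure(list(intercept = NA_real_, slope = NA_real_,
                   amount_95 = min(max(raw, 0.5), 3.0), amount_95_raw = raw,
                   method = "separation", n_choices = n),
              class = "money_calibration")
  }
  if (all(acc) || all(!acc)) return(separation())
  # separation with both classes present: every rejection below every accept
  if (max(off[!acc]) < min(off[acc])) {
    fit_try <- suppressWarnings(glm(acc ~ off, family = binomial()))
    if (!fit_try$converged || max(abs(coef(fit_try))) > 50)
      return(separation())
    fit <- fit_try
  } else {
    fit <- suppressWarnings(glm(acc ~ off, family = binomial()))
  }
  b <- coef(fit)
  if (is.na(b[2]) || b[2] <= 0) {
    warning("non-positive money-acceptance slope; clamping amount to $3.00",
            call. = FALSE)
    return(structure(list(intercept = unname(b[1]), slope = unname(b[2]),
                          amount_95 = 3.0, amount_95_raw = NA_real_,
                          method = "nonpositive_slope", n_choices = n),
                     class = "money_calibration"))
  }
  raw <- unname((target - b[1]) / b[2])
  structure(list(intercept = unname(b[1]), slope = unname(b[2]),
                 amount_95 = min(max(raw, 0.5), 3.0), amount_95_raw = raw,
                 method = "mle", n_choices = n),
            class = "money_calibration")
}

#' @export
print.money_calibration <- function(x, ...) {
  cat(sprintf("money calibration (%d choices, %s)\n", x$n_choices, x$method))
  if (x$method == "mle")
    cat(sprintf("  logit P(accept) = %.3f + %.3f * offer\n",
                x$intercept, x$slope))
  cat(sprintf("  amount accepted 95%% of the time: $%.2f\n", x$amount_95))
  invisible(x)
}
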