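#' Generative configuration for a synthetic cohort
#'
#' Bundles everything needed to forward-simulate a motivated-distraction
#' experiment: cohort size, the fixed effects of the trial-level mediation
#' model run forward, the random-effect covariance across participants, the
#' residual noise, and the distributions of the participant-level
#' calibration parameters (thermal thresholds, cognitive speed, monetary
#' sensitivity).
#'
#' The forward model generates, per trial (task indicator \eqn{X}, reward
#' indicator \eqn{W}, trial number \eqn{t}):
#' \deqn{M = \alpha_M + u_{0Mj} + (a + a_W W + u_{aj}) X + r_M W +
#'   \gamma_{1M} t + \gamma_{2M} \log t + e_M}
#' \deqn{Y = \alpha_Y + u_{0Yj} + (b + b_W W + u_{bj}) M +
#'   (c' + c'_W W + u_{c'j}) X + r_Y W + \gamma_{1Y} t +
#'   \gamma_{2Y} \log t + e_Y}
#' with performance `M` clipped to \[0, 1\] and the rating emitted as
#' \eqn{100\,\mathrm{clip}(Y, 0, 1)}.  Random effects
#' \eqn{(u_{aj}, u_{bj}, u_{c'j}, u_{0Mj}, u_{0Yj})} are drawn from a
#' zero-mean multivariate normal with covariance `Psi`.
#'
#' Defaults reproduce the study conditions: 57 participants, 64 trials in a
#' balanced 2 (task) x 2 (reward) x 2 (temperature) factorial, fixed effects
#' at the fitted values of the published mediation model, a small positive
#' log-trial coefficient (rapid early pain sensitization), and a trial-rating
#' reaction-time distribution in which about 1.1% of trials are fast guesses
#' below the 150 ms validity cutoff.
#'
#' @param n_participants number of participants.
#' @param n_trials trials per participant; must be divisible by 8 so the
#'   2x2x2 cells balance.
#' @param fixed named list of fixed effects: `alpha_M`, `a`, `rew_M`, `a_w`,
#'   `g1_M`, `g2_M`, `alpha_Y`, `b`, `rew_Y`, `b_w`, `cprime`, `cprime_w`,
#'   `g1_Y`, `g2_Y`.  Unnamed entries keep their defaults.
#' @param Psi 5x5 symmetric positive semi-definite covariance of the random
#'   effects, ordered `(a, b, cprime, int_M, int_Y)`.
#' @param sigma_M,sigma_Y residual SDs of performance and of the 0--1 rating.
#' @param painful_prob_high probability that a high-temperature trial is
#'   classified "painful" (the realized proportion is not reported for the
#'   study; 1 keeps the generative model identical to the analysis model).
#' @param painful_prob_low probability a low-temperature trial is classified
#'   "painful".
#' @param fast_rt_rate fraction of rating reaction times drawn as fast
#'   guesses (50--149 ms).
#' @param rt_meanlog,rt_sdlog log-normal parameters of ordinary rating
#'   reaction times, in log-ms.
#' @param temp_low_mean,temp_low_sd,temp_high_mean,temp_high_sd distribution
#'   of per-participant calibrated temperatures, degrees C.
#' @param isi_meanlog,isi_sdlog log-normal parameters of the participant's
#'   true (calibrated) interstimulus interval, log-ms.
#' @param money_int_mean,money_int_sd,money_slope_mean,money_slope_sd
#'   distribution of the logistic pain-for-money choice parameters
#'   (intercept; slope per dollar, truncated positive).
#' @return an object of class `cohort_config` (a validated named list).
#' @seealso [simulate_participants()], [simulate_trials()]
#' @export
cohort_config <- function(n_participants = 57L,
                          n_trials = 64L,
                          fixed = list(),
                          Psi = NULL,
                          sigma_M = 0.08,
                          sigma_Y = 0.18,
                          painful_prob_high = 1,
                          painful_prob_low = 0,
                          fast_rt_rate = 0.011,
                          rt_meanlog = log(1100), rt_sdlog = 0.35,
                          temp_low_mean = 45.3, temp_low_sd = 1.9,
                          temp_high_mean = 48.4, temp_high_sd = 0.6,
                          isi_meanlog = 6.689, isi_sdlog = 0.4286,
                          money_int_mean = -2, money_int_sd = 1,
                          money_slope_mean = 2.5, money_slope_sd = 0.8) {
  fx <- list(alpha_M = 0.96, a = -0.13, rew_M = 0.00, a_w = 0.04,
             g1_M = 0, g2_M = 0.01,
             alpha_Y = 0.64, b = -0.16, rew_Y = -0.13, b_w = 0.09,
             cprime = -0.04, cprime_w = -0.04, g1_Y = 0, g2_Y = 0.03)
  if (length(fixed)) {
    bad <- setdiff(names(fixed), names(fx))
    if (length(bad)) stop("unknown fixed effect(s): ",
                          paste(bad, collapse = ", "))
    fx[names(fixed)] <- fixed
  }
  if (is.null(Psi)) {
    sds <- c(a = 0.08, b = 0.12, cprime = 0.03, int_M = 0.04, int_Y = 0.10)
    Psi <- diag(sds^2)
    dimnames(Psi) <- list(names(sds), names(sds))
    Psi["a", "b"] <- Psi["b", "a"] <- 0.005
  }
  Psi <- as.matrix(Psi)
  if (!isTRUE(all.equal(dim(Psi), c(5L, 5L))))
    stop("`Psi` must be a 5x5 matrix over (a, b, cprime, int_M, int_Y)")
  if (max(abs(Psi - t(Psi))) > 1e-10) stop("`Psi` must be symmetric")
  if (min(eigen(Psi, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("`Psi` must be positive semi-definite")
  if (is.null(dimnames(Psi)))
    dimnames(Psi) <- rep(list(c("a", "b", "cprime", "int_M", "int_Y")), 2)
  stopifnot(sigma_M >= 0, sigma_Y >= 0, n_participants >= 1)
  if (n_trials %% 8L != 0L)
    stop("`n_trials` must be divisible by 8 for a balanced 2x2x2 factorial")
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials), fixed = fx, Psi = Psi,
                 sigma_M = sigma_M, sigma_Y = sigma_Y,
                 painful_prob_high = painful_prob_high,
                 painful_prob_low = painful_prob_low,
                 fast_rt_rate = fast_rt_rate,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 temp_low_mean = temp_low_mean, temp_low_sd = temp_low_sd,
                 temp_high_mean = temp_high_mean, temp_high_sd = temp_high_sd,
                 isi_meanlog = isi_meanlog, isi_sdlog = isi_sdlog,
                 money_int_mean = money_int_mean, money_int_sd = money_int_sd,
                 money_slope_mean = money_slope_mean,
                 money_slope_sd = money_slope_sd),
            class = "cohort_config")
}

#' Read or write a cohort configuration as YAML
#'
#' @param path file path.
#' @param config a [cohort_config()] object.
#' @return `read_cohort_config` returns a `cohort_config`;
#'   `write_cohort_config` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$Psi)) x$Psi <- matrix(unlist(x$Psi), 5, 5)
  do.call(cohort_config, x)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$Psi <- apply(unname(x$Psi), 2, as.numeric, simplify = FALSE)
  yaml::write_yaml(x, path, precision = 12L)
  invisible(path)
}

#' Simulate participant profiles
#'
#' Draws one profile per participant: the five correlated random mediation
#' effects (a, b, c-prime slopes and the two intercept deviations), the
#' participant's true low/high temperatures, their true interstimulus
#' interval, and their pain-for-money logistic parameters.  The reward
#' amount defaults to the amount the money model implies they would accept
#' 95% of the time, clamped to the allowed \[0.50, 3.00\] dollar range.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return a data frame of class `participant_profiles`, one row per
#'   participant.
#' @export
simulate_participants <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    J <- config$n_participants
    u <- MASS::mvrnorm(J, mu = rep(0, 5), Sigma = config$Psi)
    if (J == 1L) u <- matrix(u, nrow = 1)
    colnames(u) <- c("u_a", "u_b", "u_cprime", "u_int_m", "u_int_y")
    low <- pmin(pmax(rnorm(J, config$temp_low_mean, config$temp_low_sd),
                     40), 48.5)
    high <- pmin(pmax(rnorm(J, config$temp_high_mean, config$temp_high_sd),
                      40.5), 49)
    swap <- low >= high
    if (any(swap)) { # calibrated low must sit below high
      lo2 <- pmin(low[swap], high[swap]) - 0.5
      high[swap] <- pmax(low[swap], high[swap])
      low[swap] <- pmax(lo2, 40)
    }
    isi <- pmin(pmax(rlnorm(J, config$isi_meanlog, config$isi_sdlog),
                     19), 2583)
    m_int <- rnorm(J, config$money_int_mean, config$money_int_sd)
    m_slope <- pmax(rnorm(J, config$money_slope_mean, config$money_slope_sd),
                    0.3)
    amount <- pmin(pmax((qlogis(0.95) - m_int) / m_slope, 0.5), 3.0)
    out <- data.frame(participant_id = seq_len(J), u,
                      low_temp = low, high_temp = high, true_isi = isi,
                      money_logit_intercept = m_int,
                      money_logit_slope = m_slope,
                      reward_amount = amount)
    class(out) <- c("participant_profiles", "data.frame")
    out
  })
}

# balanced 2x2x2 cell schedule in a pseudo-random order with no more than
# `max_run` consecutive trials at the same temperature level
condition_schedule <- function(n_trials, max_run = 3L) {
  cells <- expand.grid(task = c("LR", "2back"), reward = 0:1,
                       temperature = c("low", "high"),
                       stringsAsFactors = FALSE)
  sched <- cells[rep(seq_len(8L), each = n_trials / 8L), ]
  repeat {
    ord <- sample.int(nrow(sched))
    if (max(rle(sched$temperature[ord])$lengths) <= max_run) break
  }
  sched <- sched[ord, ]
  rownames(sched) <- NULL
  sched
}

#' Simulate the full trial table of a cohort
#'
#' Runs the generative mediation model forward for every participant over a
#' balanced, pseudo-randomly ordered 2 (task) x 2 (reward) x 2 (temperature)
#' factorial.  Output columns follow the long trial-table layout:
#' `participant_id`, `trial`, `task`, `reward`, `temperature`,
#' `performance`, `pain_binary`, `rating`, `rating_rt_ms`, plus
#' `reward_amount_shown`.
#'
#' @param profiles from [simulate_participants()].
#' @param config the matching [cohort_config()].
#' @param seed optional integer seed.
#' @return a data frame with `config$n_trials` rows per participant.
#' @export
simulate_trials <- function(profiles, config = cohort_config(), seed = NULL) {
  stopifnot(inherits(profiles, "data.frame"),
            inherits(config, "cohort_config"))
  fx <- config$fixed
  with_seed(seed, {
    out <- vector("list", nrow(profiles))
    for (i in seq_len(nrow(profiles))) {
      pr <- profiles[i, ]
      nt <- config$n_trials
      sched <- condition_schedule(nt)
      t_ <- seq_len(nt)
      x <- as.numeric(sched$task == "2back")
      w <- sched$reward
      eM <- rnorm(nt, 0, config$sigma_M)
      eY <- rnorm(nt, 0, config$sigma_Y)
      M <- fx$alpha_M + pr$u_int_m + (fx$a + fx$a_w * w + pr$u_a) * x +
        fx$rew_M * w + fx$g1_M * t_ + fx$g2_M * log(t_) + eM
      M <- pmin(pmax(M, 0), 1)
      Y <- fx$alpha_Y + pr$u_int_y + (fx$b + fx$b_w * w + pr$u_b) * M +
        (fx$cprime + fx$cprime_w * w + pr$u_cprime) * x +
        fx$rew_Y * w + fx$g1_Y * t_ + fx$g2_Y * log(t_) + eY
      rating <- 100 * pmin(pmax(Y, 0), 1)
      p_pain <- ifelse(sched$temperature == "high",
                       config$painful_prob_high, config$painful_prob_low)
      painful <- rbinom(nt, 1L, p_pain) == 1L
      fast <- runif(nt) < config$fast_rt_rate
      rt <- ifelse(fast, runif(nt, 50, 149),
                   rlnorm(nt, config$rt_meanlog, config$rt_sdlog))
      out[[i]] <- data.frame(
        participant_id = pr$participant_id, trial = t_,
        task = sched$task, reward = w, temperature = sched$temperature,
        performance = M,
        pain_binary = ifelse(painful, "painful", "not painful"),
        rating = rating, rating_rt_ms = rt,
        reward_amount_shown = w * pr$reward_amount)
    }
    do.call(rbind, out)
  })
}

#' Simulate one 2-back response stream
#'
#' Builds the stimulus timeline of a single 20-second 2-back trial (250 ms
#' fixation + 500 ms letter + `isi` ms blank per stimulus, so
#' `floor(duration / (750 + isi))` letters) and simulates an equal-variance
#' Gaussian observer: on target stimuli the "same" response is emitted with
#' probability \eqn{\Phi(d'/2)}, on non-targets with \eqn{\Phi(-d'/2)}.
#' The first two letters have no 2-back referent and are marked
#' unscoreable.  `d = Inf` yields an error-free observer, `d = 0` a
#' guessing one.
#'
#' @param isi interstimulus interval in ms, in \[19, 2583\].
#' @param duration_s stream duration in seconds.
#' @param observer the observer's sensitivity d-prime: a single number or a
#'   function of `isi` (monotone non-decreasing in `isi` for a plausible
#'   observer).
#' @param target_rate probability that a scoreable stimulus is a 2-back
#'   match.
#' @param seed optional integer seed.
#' @return a data frame of class `response_stream` with columns `onset_ms`,
#'   `target`, `response`; the ISI is stored in `attr(, "isi")`.
#' @export
simulate_nback_stream <- function(isi, duration_s = 20, observer = 2,
                                  target_rate = 1 / 3, seed = NULL) {
  if (!is.numeric(isi) || isi < 19 || isi > 2583)
    stop("`isi` must lie in [19, 2583] ms")
  d <- if (is.function(observer)) observer(isi) else observer
  stopifnot(is.numeric(d), length(d) == 1L, !is.na(d))
  n <- floor(duration_s * 1000 / (750 + isi))
  if (n < 1L) stop("stream too short: no stimuli fit in the duration")
  with_seed(seed, {
    target <- runif(n) < target_rate
    if (n >= 1L) target[seq_len(min(2L, n))] <- NA
    pH <- pnorm(d / 2); pF <- pnorm(-d / 2)
    p <- ifelse(is.na(target), pF, ifelse(target, pH, pF))
    response <- runif(n) < p
    out <- data.frame(onset_ms = (seq_len(n) - 1L) * (750 + isi),
                      target = target, response = response)
    attr(out, "isi") <- isi
    class(out) <- c("response_stream", "data.frame")
    out
  })
}

#' Simulate a pain-for-money choice table
#'
#' One Bernoulli accept/reject decision per monetary offer, with
#' \eqn{P(\mathrm{accept}) = \mathrm{logit}^{-1}(\beta_0 + \beta_1
#' \cdot \mathrm{offer})}.  An infinite slope gives the step-function limit
#' (accept exactly when the linear predictor is positive).
#'
#' @param intercept,slope logistic parameters (slope per dollar).
#' @param offers offer amounts in dollars, each in \[0, 3\]; the default is
#'   the study's 26 evenly spaced offers from $0 to $3.
#' @param seed optional integer seed.
#' @return a data frame with columns `offer`, `p_accept`, `accept`.
#' @export
simulate_choices <- function(intercept, slope,
                             offers = seq(0, 3, length.out = 26),
                             seed = NULL) {
  if (any(offers < 0 | offers > 3)) stop("offers must lie in [0, 3] dollars")
  eta <- intercept + slope * offers
  eta[slope == Inf & offers == 0] <- intercept
  p <- plogis(eta)
  with_seed(seed, {
    data.frame(offer = offers, p_accept = p,
               accept = runif(length(offers)) < p)
  })
}
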