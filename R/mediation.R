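#' Stack mediator and outcome rows for the 1-1-1 mediation model
#'
#' Rewrites each analysed trial as two rows of a single response vector:
#' a mediator row (selector `sm = 1`, response `z =` performance) and an
#' outcome row (`sy = 1`, `z =` the 0--1 pain rating).  Every predictor is
#' interacted with its selector, so one linear mixed model estimates both
#' regression equations at once while sharing a random-effect covariance
#' across them — the construction that lets the indirect effect include the
#' covariance between the random a and b slopes.
#'
#' Trials with a missing performance score or rating are dropped (and
#' counted in `attr(, "n_dropped")`).
#'
#' @param table a [preprocess_trials()] table restricted to the
#'   high-temperature (pain) analysis set; columns `participant_id`,
#'   `trial`, `task`, `reward`, `performance`, `rating01`, `t`, `log_t`.
#' @return a data frame of class `stacked_design` with 2 rows per trial:
#'   identifiers (`participant_id`, `trial`, `outcome`), the response `z`,
#'   and predictors `sm`, `sy`, `sm_x`, `sm_w`, `sm_xw`, `sm_t`, `sm_logt`,
#'   `sy_m`, `sy_w`, `sy_mw`, `sy_x`, `sy_xw`, `sy_t`, `sy_logt`.
#' @export
stack_mediation <- function(table) {
  req <- c("participant_id", "trial", "task", "reward", "performance",
           "rating01", "t", "log_t")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("table is missing column(s): ", paste(miss, collapse = ", "))
  ok <- !is.na(table$performance) & !is.na(table$rating01)
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(n_drop, " trial(s) dropped for missing mediator or rating")
  d <- table[ok, , drop = FALSE]
  x <- as.numeric(d$task == "2back")
  w <- as.numeric(d$reward)
  zero <- numeric(nrow(d))
  mrow <- data.frame(participant_id = d$participant_id, trial = d$trial,
                     outcome = "M", z = d$performance,
                     sm = 1, sy = 0, sm_x = x, sm_w = w, sm_xw = x * w,
                     sm_t = d$t, sm_logt = d$log_t,
                     sy_m = zero, sy_w = zero, sy_mw = zero, sy_x = zero,
                     sy_xw = zero, sy_t = zero, sy_logt = zero)
  yrow <- data.frame(participant_id = d$participant_id, trial = d$trial,
                     outcome = "Y", z = d$rating01,
                     sm = 0, sy = 1, sm_x = zero, sm_w = zero, sm_xw = zero,
                     sm_t = zero, sm_logt = zero,
                     sy_m = d$performance, sy_w = w, sy_mw = d$performance * w,
                     sy_x = x, sy_xw = x * w, sy_t = d$t, sy_logt = d$log_t)
  out <- rbind(mrow, yrow)
  out <- out[order(out$participant_id, out$trial, out$outcome), ]
  rownames(out) <- NULL
  attr(out, "n_trials") <- nrow(d)
  attr(out, "n_dropped") <- n_drop
  class(out) <- c("stacked_design", "data.frame")
  out
}

#' Recover the trial table from a stacked design
#'
#' Inverse of [stack_mediation()]: pairs each trial's mediator and outcome
#' rows back into one row per trial.
#'
#' @param stacked a `stacked_design`.
#' @return data frame with columns `participant_id`, `trial`, `x`, `w`,
#'   `t`, `log_t`, `performance`, `rating01`.
#' @export
unstack_mediation <- function(stacked) {
  m <- stacked[stacked$outcome == "M", ]
  y <- stacked[stacked$outcome == "Y", ]
  key <- paste(m$participant_id, m$trial)
  y <- y[match(key, paste(y$participant_id, y$trial)), ]
  data.frame(participant_id = m$participant_id, trial = m$trial,
             x = m$sm_x, w = m$sm_w, t = m$sm_t, log_t = m$sm_logt,
             performance = m$z, rating01 = y$z)
}

# report-name maps between stacked design columns and path names
.fixed_cols <- c(int_M = "sm", a = "sm_x", rewM = "sm_w", a_W = "sm_xw",
                 g1M = "sm_t", g2M = "sm_logt",
                 int_Y = "sy", b = "sy_m", rewY = "sy_w", b_W = "sy_mw",
                 cprime = "sy_x", cprime_W = "sy_xw",
                 g1Y = "sy_t", g2Y = "sy_logt")
.random_cols <- c(int_M = "sm", int_Y = "sy", a = "sm_x", b = "sy_m",
                  cprime = "sy_x")

#' Fit the multilevel moderated mediation model
#'
#' The core engine.  Fits, by restricted maximum likelihood, the stacked
#' 1-1-1 mediation model with reward moderation:
#' \deqn{M_{ij} = \alpha_M + (a + a_W W + u_{aj}) X + r_M W + \gamma_{1M} t
#'   + \gamma_{2M} \log t + e_{Mij}}
#' \deqn{Y_{ij} = \alpha_Y + (b + b_W W + u_{bj}) M + (c' + c'_W W +
#'   u_{c'j}) X + r_Y W + \gamma_{1Y} t + \gamma_{2Y} \log t + e_{Yij}}
#' with an unstructured covariance \eqn{\Psi} over the active random
#' effects and independent residuals with one variance per outcome type.
#' The residual scale and fixed effects are profiled out of the REML
#' objective; the covariance is parameterised by its log-Cholesky factor
#' and optimised by quasi-Newton iteration with jittered restarts.
#' Coefficient degrees of freedom are reported as (stacked rows - fixed
#' effects), an intentionally rough large-sample convention — inference on
#' the indirect quantities should come from [bootstrap_mediation()].
#'
#' @param data either a clean trial table (it is restricted to the
#'   high-temperature rows automatically when a `temperature` column is
#'   present) or a ready [stack_mediation()] design.
#' @param random which paths get random effects: the `"default"` preset
#'   `{int_M, int_Y, a, b, cprime}`, the `"paper"` preset `{a, b, cprime}`
#'   (random effects on the three paths only), or any character subset of
#'   those five names.
#' @param psi `"unstructured"` (default) or `"diagonal"` (random-effect
#'   covariances forced to zero).
#' @param start optional covariance-parameter starting values (a previous
#'   fit's `$theta`), used to warm-start bootstrap refits.
#' @param rel_tol REML convergence tolerance.
#' @return an object of class `mediation_fit`; see [summary.mediation_fit()].
#'   Key elements: `coefficients` (named by path: `int_M`, `a`, `rewM`,
#'   `a_W`, `g1M`, `g2M`, `int_Y`, `b`, `rewY`, `b_W`, `cprime`,
#'   `cprime_W`, `g1Y`, `g2Y`), `se`, `tstat`, `df`, `p`, `Psi`,
#'   `sigma2_M`, `sigma2_Y`, `loglik`, `converged`.
#' @seealso [indirect_effects()], [bootstrap_mediation()],
#'   [fit_total_effect()]
#' @export
fit_mediation <- function(data, random = "default",
                          psi = c("unstructured", "diagonal"),
                          start = NULL, rel_tol = 1e-10) {
  psi <- match.arg(psi)
  if (!inherits(data, "stacked_design")) {
    if ("temperature" %in% names(data))
      data <- select_analysis_set(data, "pain")
    data <- stack_mediation(data)
  }
  if (length(random) == 1L && random %in% c("default", "paper"))
    random <- switch(random, default = c("int_M", "int_Y", "a", "b", "cprime"),
                     paper = c("a", "b", "cprime"))
  bad <- setdiff(random, names(.random_cols))
  if (length(bad) || length(random) == 0L)
    stop("`random` must be a non-empty subset of: ",
         paste(names(.random_cols), collapse = ", "))
  J <- length(unique(data$participant_id))
  if (J < 10L) stop("need at least 10 participants for the mediation model")
  if (any(data$z[data$outcome == "Y"] < 0 | data$z[data$outcome == "Y"] > 1))
    stop("outcome rows must carry ratings rescaled to [0, 1]")

  X <- as.matrix(data[, unname(.fixed_cols)])
  colnames(X) <- names(.fixed_cols)
  Z <- as.matrix(data[, unname(.random_cols[random])])
  colnames(Z) <- random
  wclass <- as.integer(data$outcome == "Y")
  fit <- stacked_reml(data$z, X, Z, data$participant_id, wclass = wclass,
                      start = start, rel_tol = rel_tol,
                      diagonal = (psi == "diagonal"))
  if (!fit$converged)
    warning("mediation model did not converge; see $optim_info",
            call. = FALSE)
  df <- nrow(data) - ncol(X)
  se <- sqrt(diag(fit$vcov))
  tstat <- fit$beta / se
  structure(list(coefficients = fit$beta, se = se, tstat = tstat, df = df,
                 p = 2 * pt(-abs(tstat), df), vcov = fit$vcov,
                 Psi = fit$Psi, sigma2_M = fit$sigma2_M,
                 sigma2_Y = fit$sigma2_Y, loglik = fit$loglik,
                 theta = fit$theta, ranef = fit$ranef,
                 fitted = fit$fitted,
                 fitted_conditional = fit$fitted_conditional,
                 converged = fit$converged, boundary = fit$boundary,
                 grad_norm = fit$grad_norm, optim_info = fit$optim_info,
                 random_set = random, psi = psi,
                 n_participants = J, n_trials = attr(data, "n_trials"),
                 n_rows = nrow(data), stacked = data, stats = fit$stats,
                 call = match.call()),
            class = "mediation_fit")
}

#' Covariance-inclusive indirect effects
#'
#' Computes the indirect effect of the mediation model including the
#' covariance between the random a and b slopes:
#' \eqn{ab = \hat a \hat b + \hat\sigma_{ab}}, the conditional indirect
#' effects at the two reward levels
#' \eqn{IE(w) = (\hat a + \hat a_W w)(\hat b + \hat b_W w) +
#' \hat\sigma_{ab}} for \eqn{w \in \{0, 1\}}, and their difference.  When
#' a and b are not both in the random set, \eqn{\sigma_{ab} = 0} and the
#' indirect effect reduces to the fixed-effect product.
#'
#' @param fit a [fit_mediation()] object.
#' @return named numeric vector of class `indirect_effects`:
#'   `ab`, `ie_w0`, `ie_w1`, `ie_diff` (= `ie_w1 - ie_w0`).
#' @export
indirect_effects <- function(fit) {
  stopifnot(inherits(fit, "mediation_fit"))
  if (!fit$converged)
    warning("indirect effects from a non-converged fit", call. = FALSE)
  out <- indirect_core(fit$coefficients, fit$Psi, fit$random_set)
  class(out) <- c("indirect_effects", class(out))
  out
}

# shared arithmetic for indirect quantities from named fixed effects and the
# random-effect covariance
indirect_core <- function(cf, Psi, random_set) {
  s_ab <- if (all(c("a", "b") %in% random_set)) Psi["a", "b"] else 0
  b_w <- if ("b_W" %in% names(cf)) cf[["b_W"]] else 0
  ie <- function(w) (cf[["a"]] + cf[["a_W"]] * w) * (cf[["b"]] + b_w * w) +
    s_ab
  out <- c(ab = cf[["a"]] * cf[["b"]] + s_ab, ie_w0 = ie(0), ie_w1 = ie(1))
  out["ie_diff"] <- out[["ie_w1"]] - out[["ie_w0"]]
  out
}

#' @export
print.indirect_effects <- function(x, digits = 4, ...) {
  cat("indirect effects (product of fixed effects + random a-b covariance)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Participant-level bootstrap for the mediation model
#'
#' Resamples participants with replacement (every resampled participant's
#' trials enter once per draw, under a fresh participant index so repeated
#' draws stay distinct clusters), refits the mediation model on each
#' replicate warm-started from the full-sample estimates, and returns
#' percentile confidence intervals for all fixed effects and the indirect
#' quantities.  Non-convergent replicates are dropped and counted; more
#' than 10% failures is an error.
#'
#' @param data clean trial table or stacked design (as [fit_mediation()]).
#' @param B number of bootstrap replicates (>= 100).
#' @param seed optional integer seed; fixes the resampling stream.
#' @param random,psi passed to [fit_mediation()].
#' @param level confidence level for the percentile intervals.
#' @param rel_tol REML tolerance for the replicate fits.
#' @return an object of class `mediation_boot`: list with `t0` (full-sample
#'   estimates), `draws` (replicates x quantities), `ci` (2-column matrix
#'   of percentile bounds), `n_fail`, `B`, `level`, `seed`.
#' @export
bootstrap_mediation <- function(data, B = 1000L, seed = NULL,
                                random = "default",
                                psi = c("unstructured", "diagonal"),
                                level = 0.95, rel_tol = 1e-8) {
  psi <- match.arg(psi)
  if (B < 100L) stop("`B` must be at least 100")
  if (!inherits(data, "stacked_design")) {
    if ("temperature" %in% names(data))
      data <- select_analysis_set(data, "pain")
    data <- stack_mediation(data)
  }
  full <- fit_mediation(data, random = random, psi = psi)
  t0 <- c(full$coefficients, indirect_effects(full))
  J <- full$n_participants
  q <- length(full$random_set)

  draws <- matrix(NA_real_, B, length(t0),
                  dimnames = list(NULL, names(t0)))
  n_fail <- 0L
  last_err <- NULL
  with_seed(seed, {
    for (bb in seq_len(B)) {
      # resample participants; each draw enters the refit as its own
      # cluster (the sufficient statistics of a participant are reused,
      # which is equivalent to re-indexing their rows)
      take <- sample.int(J, J, replace = TRUE)
      res <- tryCatch({
        opt <- suppressWarnings(
          reml_optimize(full$stats, take, q, TRUE, start = full$theta,
                        rel_tol = rel_tol, n_restarts = 2L,
                        diagonal = (psi == "diagonal")))
        if (!opt$converged) stop("replicate did not converge")
        est <- reml_estimates(opt$op$par, full$stats, take, TRUE)
        cf <- drop(est$beta)
        names(cf) <- names(full$coefficients)
        Psi <- est$Psi
        dimnames(Psi) <- dimnames(full$Psi)
        c(cf, indirect_core(cf, Psi, full$random_set))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        last_err <- conditionMessage(res)
      } else draws[bb, ] <- res
    }
  })
  if (n_fail == B)
    stop("all bootstrap replicates failed; last error: ", last_err)
  if (n_fail > 0.10 * B)
    stop(sprintf("%d of %d bootstrap replicates failed to converge (> 10%%)",
                 n_fail, B))
  keep <- draws[stats::complete.cases(draws), , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- t(apply(keep, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- paste0(c(alpha, 1 - alpha) * 100, "%")
  structure(list(t0 = t0, draws = keep, ci = ci, n_fail = n_fail, B = B,
                 level = level, seed = seed, random_set = full$random_set),
            class = "mediation_boot")
}

#' @export
print.mediation_boot <- function(x, digits = 4, ...) {
  cat(sprintf("participant-level bootstrap: %d replicates (%d failed)\n",
              x$B, x$n_fail))
  tab <- cbind(estimate = x$t0, x$ci)
  print(round(tab, digits))
  invisible(x)
}

#' Total effect of task demands on pain
#'
#' Fits the separate total-effect model (no performance predictor): the
#' 0--1 pain rating on task demands, reward, their interaction, and the
#' trial-number covariates, with a random intercept and a random task
#' slope per participant.  The task coefficient is the total effect `c`;
#' the interaction is its reward moderation `c_rew`.
#'
#' @param data clean trial table; restricted to the high-temperature rows
#'   automatically when a `temperature` column is present.
#' @param rel_tol REML convergence tolerance.
#' @return an object of class `total_effect_fit` with `coefficients`
#'   (`int`, `c`, `rew`, `c_rew`, `g1`, `g2`), `se`, `tstat`, `df`, `p`,
#'   `Psi`, `sigma2`, `loglik`, `converged`.
#' @export
fit_total_effect <- function(data, rel_tol = 1e-10) {
  if ("temperature" %in% names(data))
    data <- select_analysis_set(data, "pain")
  req <- c("participant_id", "task", "reward", "rating01", "t", "log_t")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("table is missing column(s): ", paste(miss, collapse = ", "))
  x <- as.numeric(data$task == "2back")
  w <- as.numeric(data$reward)
  X <- cbind(int = 1, c = x, rew = w, c_rew = x * w, g1 = data$t,
             g2 = data$log_t)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("total-effect design is rank deficient; inestimable column(s): ",
         paste(dropped, collapse = ", "))
  }
  Z <- cbind(int = 1, c = x)
  fit <- stacked_reml(data$rating01, X, Z, data$participant_id,
                      rel_tol = rel_tol)
  if (!fit$converged)
    warning("total-effect model did not converge", call. = FALSE)
  df <- nrow(X) - ncol(X)
  se <- sqrt(diag(fit$vcov))
  tstat <- fit$beta / se
  structure(list(coefficients = fit$beta, se = se, tstat = tstat, df = df,
                 p = 2 * pt(-abs(tstat), df), vcov = fit$vcov,
                 Psi = fit$Psi, sigma2 = fit$sigma2_M, loglik = fit$loglik,
                 converged = fit$converged, n_rows = nrow(X),
                 n_participants = length(unique(data$participant_id)),
                 call = match.call()),
            class = "total_effect_fit")
}

#' @export
print.total_effect_fit <- function(x, digits = 4, ...) {
  cat("total-effect mixed model (pain rating ~ task * reward + trial covariates)\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, t = x$tstat, p = x$p)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.total_effect_fit <- function(object, ...) object$coefficients

# ---- mediation_fit methods ----

#' @export
print.mediation_fit <- function(x, digits = 4, ...) {
  cat(sprintf("multilevel mediation fit: %d participants, %d trials (%d stacked rows)\n",
              x$n_participants, x$n_trials, x$n_rows))
  cat(sprintf("random effects: {%s}%s; converged: %s\n",
              paste(x$random_set, collapse = ", "),
              if (x$psi == "diagonal") " (diagonal)" else "",
              x$converged))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summarise a mediation fit
#'
#' @param object a [fit_mediation()] object.
#' @param ... unused.
#' @return an object of class `summary.mediation_fit` holding the
#'   coefficient table, the random-effect covariance, residual variances,
#'   and the indirect effects.
#' @export
summary.mediation_fit <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, se = object$se,
               t = object$tstat, df = object$df, p = object$p)
  structure(list(coefficients = tab, Psi = object$Psi,
                 sigma2_M = object$sigma2_M, sigma2_Y = object$sigma2_Y,
                 indirect = indirect_effects(object),
                 loglik = object$loglik, converged = object$converged,
                 n_participants = object$n_participants,
                 n_trials = object$n_trials, random_set = object$random_set),
            class = "summary.mediation_fit")
}

#' @export
print.summary.mediation_fit <- function(x, digits = 4, ...) {
  cat("Multilevel moderated mediation (stacked REML)\n")
  cat(sprintf("  %d participants, %d trials; random {%s}; converged: %s\n\n",
              x$n_participants, x$n_trials,
              paste(x$random_set, collapse = ", "), x$converged))
  cat("Fixed effects:\n")
  tab <- x$coefficients
  tab[, "p"] <- signif(tab[, "p"], 3)
  print(round(tab, digits))
  cat("\nRandom-effect covariance (Psi):\n")
  print(round(x$Psi, 6))
  cat(sprintf("\nResidual variances: sigma2_M = %.6f, sigma2_Y = %.6f\n",
              x$sigma2_M, x$sigma2_Y))
  cat("\n")
  print(x$indirect, digits = digits)
  invisible(x)
}

#' @export
coef.mediation_fit <- function(object, ...) object$coefficients

#' @export
vcov.mediation_fit <- function(object, ...) object$vcov

#' @export
logLik.mediation_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              length(object$theta) + 1, class = "logLik")
}

#' @export
fitted.mediation_fit <- function(object, level = c("conditional", "marginal"),
                                 ...) {
  level <- match.arg(level)
  if (level == "marginal") object$fitted else object$fitted_conditional
}

#' @export
residuals.mediation_fit <- function(object,
                                    level = c("conditional", "marginal"),
                                    ...) {
  object$stacked$z - fitted(object, level = match.arg(level))
}

#' Predict from a mediation fit
#'
#' @param object a [fit_mediation()] object.
#' @param newdata optional `stacked_design` (or clean trial table, which is
#'   stacked); defaults to the fitting data.
#' @param level `"marginal"` (fixed effects only) or `"conditional"`
#'   (adds the participant's estimated random effects; unseen participants
#'   fall back to the marginal prediction).
#' @param ... unused.
#' @return numeric vector of predicted responses, one per stacked row.
#' @export
predict.mediation_fit <- function(object, newdata = NULL,
                                  level = c("marginal", "conditional"),
                                  ...) {
  level <- match.arg(level)
  if (is.null(newdata)) return(fitted(object, level = level))
  if (!inherits(newdata, "stacked_design")) {
    if ("temperature" %in% names(newdata))
      newdata <- select_analysis_set(newdata, "pain")
    newdata <- stack_mediation(newdata)
  }
  X <- as.matrix(newdata[, unname(.fixed_cols)])
  eta <- drop(X %*% object$coefficients)
  if (level == "conditional") {
    Z <- as.matrix(newdata[, unname(.random_cols[object$random_set])])
    hit <- match(as.character(newdata$participant_id),
                 rownames(object$ranef))
    u <- object$ranef[hit, , drop = FALSE]
    u[is.na(hit), ] <- 0
    eta <- eta + rowSums(Z * u)
  }
  eta
}

#' Simulate new stacked responses from a fitted mediation model
#'
#' Draws fresh random effects per participant from the estimated
#' covariance and fresh residuals from the estimated per-outcome
#' variances, keeping the design (conditions, trial numbers, mediator
#' values on outcome rows) fixed — a parametric bootstrap generator.
#'
#' @param object a [fit_mediation()] object.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with `nsim` columns, one simulated stacked response
#'   per column.
#' @export
simulate.mediation_fit <- function(object, nsim = 1, seed = NULL, ...) {
  st <- object$stacked
  X <- as.matrix(st[, unname(.fixed_cols)])
  Z <- as.matrix(st[, unname(.random_cols[object$random_set])])
  ids <- unique(st$participant_id)
  eta <- drop(X %*% object$coefficients)
  sdres <- ifelse(st$outcome == "Y", sqrt(object$sigma2_Y),
                  sqrt(object$sigma2_M))
  with_seed(seed, {
    out <- replicate(nsim, {
      u <- MASS::mvrnorm(length(ids), mu = rep(0, ncol(Z)),
                         Sigma = object$Psi)
      if (length(ids) == 1L) u <- matrix(u, nrow = 1)
      eta + rowSums(Z * u[match(st$participant_id, ids), , drop = FALSE]) +
        rnorm(nrow(st), 0, sdres)
    })
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}

#' Coefficient table in the published two-block layout
#'
#' Arranges the fixed effects of a mediation fit as two outcome blocks
#' (performance equation, then ratings equation) followed by the indirect
#' effect and the difference of conditional indirect effects, with
#' bootstrap percentile confidence limits when a bootstrap is supplied.
#'
#' @param fit a [fit_mediation()] object.
#' @param boot optional [bootstrap_mediation()] result.
#' @return a data frame with columns `block`, `predictor`, `estimate`,
#'   `lower`, `upper`, `df`, `t`, `p`.
#' @export
mediation_table <- function(fit, boot = NULL) {
  labs <- c(int_M = "(Intercept)", a = "Task demands", rewM = "Reward",
            a_W = "Task demands x reward", g1M = "Trial number",
            g2M = "log(trial number)",
            int_Y = "(Intercept)", b = "Performance", rewY = "Reward",
            b_W = "Performance x reward", cprime = "Task demands",
            cprime_W = "Task demands x reward", g1Y = "Trial number",
            g2Y = "log(trial number)")
  blocks <- rep(c("Outcome: performance", "Outcome: ratings"), c(6L, 8L))
  nm <- names(labs)
  tab <- data.frame(block = blocks, predictor = unname(labs),
                    estimate = unname(fit$coefficients[nm]),
                    lower = NA_real_, upper = NA_real_,
                    df = fit$df, t = unname(fit$tstat[nm]),
                    p = unname(fit$p[nm]))
  ie <- indirect_effects(fit)
  tab <- rbind(tab, data.frame(
    block = "Indirect", predictor = c("Indirect effect",
                                      "Difference of indirect effects"),
    estimate = c(ie[["ab"]], ie[["ie_diff"]]),
    lower = NA_real_, upper = NA_real_, df = NA, t = NA, p = NA))
  if (!is.null(boot)) {
    key <- c(nm, "ab", "ie_diff")
    tab$lower <- boot$ci[key, 1]
    tab$upper <- boot$ci[key, 2]
  }
  tab
}

#' Path-diagram text summary
#'
#' One-screen account of the fitted mediation paths, the analogue of a
#' path diagram: a, a x reward, b, c-prime, the random a-b covariance, the
#' indirect effect and its reward moderation.
#'
#' @param fit a [fit_mediation()] object.
#' @param total optional [fit_total_effect()] object to report c and
#'   c_rew alongside.
#' @return character vector of lines, invisibly; printed as a side effect.
#' @export
path_summary <- function(fit, total = NULL) {
  cf <- fit$coefficients
  ie <- indirect_effects(fit)
  s_ab <- if (all(c("a", "b") %in% fit$random_set)) fit$Psi["a", "b"] else 0
  lines <- c(
    "mediation path summary (task demands -> performance -> pain rating)",
    sprintf("  a      (task -> performance)          = %+0.4f", cf[["a"]]),
    sprintf("  a*rew  (reward moderation of a)       = %+0.4f", cf[["a_W"]]),
    sprintf("  b      (performance -> rating)        = %+0.4f", cf[["b"]]),
    sprintf("  c'     (direct task -> rating)        = %+0.4f", cf[["cprime"]]),
    sprintf("  c'*rew (reward moderation of c')      = %+0.4f", cf[["cprime_W"]]),
    sprintf("  cov(a_j, b_j)                         = %+0.5f", s_ab),
    sprintf("  ab     (indirect, incl. covariance)   = %+0.4f", ie[["ab"]]),
    sprintf("  IE(reward) - IE(no reward)            = %+0.4f", ie[["ie_diff"]]))
  if (!is.null(total))
    lines <- c(lines,
               sprintf("  c      (total effect)                 = %+0.4f",
                       total$coefficients[["c"]]),
               sprintf("  c*rew  (reward moderation of c)       = %+0.4f",
                       total$coefficients[["c_rew"]]))
  cat(lines, sep = "\n")
  invisible(lines)
}
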