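#' Restricted maximum likelihood for a grouped mixed model
#'
#' Internal fitting engine shared by [fit_mediation()] and
#' [fit_total_effect()].  Fits
#' \deqn{y = X\beta + Z_j u_j + e, \quad u_j \sim N(0, \Psi),}
#' with one set of random-effect columns per grouping unit and, optionally,
#' two residual-variance classes (one per stacked outcome type).  The
#' residual scale and the fixed effects are profiled out; the remaining
#' parameters (log-Cholesky factor of \eqn{\Psi/\sigma^2} and the log
#' variance ratio) are optimised by quasi-Newton iteration with jittered
#' restarts on failure.  The objective is evaluated from per-group
#' sufficient statistics, which also lets participant-level bootstrap
#' replicates refit without re-assembling rows.
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (no implicit intercept).
#' @param Z random-effect design matrix (columns named).
#' @param group grouping factor (participant).
#' @param wclass integer 0/1 residual-variance class per row, or `NULL` for a
#'   single residual variance.
#' @param start optional starting value for the covariance parameters (a
#'   previous fit's `theta`), used to warm-start bootstrap refits.
#' @param rel_tol relative convergence tolerance for the REML objective.
#' @param n_restarts number of jittered restarts attempted on failure.
#' @param diagonal force the random-effect covariance diagonal.
#' @param blups also compute conditional modes and fitted values.
#' @param grad_check compute a central-difference gradient diagnostic at the
#'   optimum.
#' @return a list with elements `beta`, `vcov`, `sigma2_M`, `sigma2_Y`,
#'   `Psi`, `theta`, `loglik`, `ranef`, `fitted`, `fitted_conditional`,
#'   `converged`, `boundary`, `grad_norm`, `optim_info`, `stats`.
#' @keywords internal
#' @noRd
stacked_reml <- function(y, X, Z, group, wclass = NULL, start = NULL,
                         rel_tol = 1e-10, n_restarts = 3L,
                         diagonal = FALSE, blups = TRUE, grad_check = TRUE) {
  group <- as.factor(group)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(Z) == n, length(group) == n)
  p <- ncol(X)
  q <- ncol(Z)
  has_delta <- !is.null(wclass)
  if (!has_delta) wclass <- integer(n)

  ord <- order(group)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; Z <- Z[ord, , drop = FALSE]
  wclass <- as.integer(wclass[ord]); group <- group[ord]
  runs <- rle(as.integer(group))
  gend <- cumsum(runs$lengths)
  gstart <- c(1L, head(gend, -1L) + 1L)
  XY <- cbind(X, y)
  stats <- reml_group_stats(XY, Z, gstart - 1L, gend - 1L, wclass)
  J <- length(gstart)
  n_theta <- q + q * (q - 1L) / 2L + as.integer(has_delta)

  if (is.null(start)) {
    # moment-based start: modest relative random-effect SDs, zero
    # correlations, residual ratio from a per-class OLS residual split
    r <- stats::lm.fit(X, y)$residuals
    start <- numeric(n_theta)
    start[seq_len(q)] <- log(0.5)
    if (has_delta) {
      v0 <- stats::var(r[wclass == 0L]); v1 <- stats::var(r[wclass == 1L])
      start[n_theta] <- log(max(v1, 1e-12) / max(v0, 1e-12))
    }
  }
  stopifnot(length(start) == n_theta)

  opt <- reml_optimize(stats, seq_len(J), q, has_delta, start,
                       rel_tol = rel_tol, n_restarts = n_restarts,
                       diagonal = diagonal)
  op <- opt$op

  gn <- NA_real_
  if (grad_check && opt$converged) {
    h <- 1e-5
    g <- vapply(seq_len(n_theta), function(i) {
      ei <- numeric(n_theta); ei[i] <- h
      (opt$obj(op$par + ei) - opt$obj(op$par - ei)) / (2 * h)
    }, numeric(1))
    gn <- sqrt(sum(g^2))
  }

  est <- reml_estimates(op$par, stats, seq_len(J), has_delta)
  beta <- drop(est$beta); names(beta) <- colnames(X)
  vc <- est$vcov; dimnames(vc) <- list(colnames(X), colnames(X))
  Psi <- est$Psi; dimnames(Psi) <- list(colnames(Z), colnames(Z))
  boundary <- any(op$par[seq_len(q)] < -6)
  if (boundary && opt$converged)
    warning("variance-component estimate at or near the zero boundary",
            call. = FALSE)

  fitted_m <- fitted_c <- ranef <- NULL
  if (blups) {
    bl <- reml_blups(op$par, est$beta, XY, Z, gstart - 1L, gend - 1L,
                     wclass, has_delta)
    ranef <- bl$ranef
    dimnames(ranef) <- list(levels(group), colnames(Z))
    inv <- order(ord)
    fitted_m <- drop(bl$fitted_marginal)[inv]
    fitted_c <- drop(bl$fitted_conditional)[inv]
  }

  list(beta = beta, vcov = vc,
       sigma2_M = est$sigma2, sigma2_Y = est$sigma2 * est$delta,
       Psi = Psi, theta = op$par, loglik = est$loglik,
       ranef = ranef, fitted = fitted_m, fitted_conditional = fitted_c,
       converged = opt$converged, boundary = boundary, grad_norm = gn,
       optim_info = list(objective = op$objective,
                         iterations = op$iterations,
                         convergence = op$convergence,
                         message = op$message),
       stats = stats, has_delta = has_delta, q = q, p = p)
}

# optimise the REML objective over the covariance parameters for the groups
# listed in `take` (with repeats allowed, for bootstrap resamples)
reml_optimize <- function(stats, take, q, has_delta, start,
                          rel_tol = 1e-10, n_restarts = 3L,
                          diagonal = FALSE) {
  n_theta <- length(start)
  lower <- rep(-20, n_theta); upper <- rep(20, n_theta)
  lower[seq_len(q)] <- -10; upper[seq_len(q)] <- 6
  if (diagonal && q > 1L) {
    off <- seq(q + 1L, q + q * (q - 1L) / 2L)
    lower[off] <- upper[off] <- 0
    start[off] <- 0
  }
  take <- as.integer(take)
  obj <- function(th) reml_objective(th, stats, take, has_delta)

  run1 <- function(th0)
    stats::nlminb(th0, obj, lower = lower, upper = upper,
                  control = list(rel.tol = rel_tol, iter.max = 500L,
                                 eval.max = 2000L))

  # PORT reports "false/singular convergence" when the surface is flat or
  # badly scaled near a variance boundary; treat the point as converged only
  # if re-polishing from it cannot improve the deviance any further
  attempt <- function(th0) {
    cand <- run1(th0)
    tries <- 0L
    while (cand$convergence != 0 && is.finite(cand$objective) &&
           cand$objective < 1e9 && tries < 3L) {
      pol <- run1(cand$par)
      if (pol$objective < cand$objective - 1e-2) {
        cand <- pol
        tries <- tries + 1L
      } else {
        if (pol$objective < cand$objective) cand <- pol
        cand$stationary <- TRUE
        break
      }
    }
    cand$ok <- is.finite(cand$objective) && cand$objective < 1e9 &&
      (cand$convergence == 0 || isTRUE(cand$stationary))
    cand
  }

  op <- NULL
  for (k in 0:n_restarts) {
    th0 <- if (k == 0L) start else
      pmin(pmax(start + stats::rnorm(n_theta, 0, 0.5), lower), upper)
    cand <- attempt(th0)
    if (is.null(op) || (cand$ok && cand$objective < op$objective)) op <- cand
    if (cand$ok) break
  }
  list(op = op, converged = op$ok, obj = obj)
}
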