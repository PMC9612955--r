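# Independent oracles and fixture builders used across the suite.

# Holm step-down by brute-force enumeration: for the i-th smallest p, the
# adjusted value is the running maximum of (m - j + 1) * p_(j) over j <= i,
# capped at 1.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(run, 1)
  }
  adj
}

# paired t statistic of a difference score
paired_t <- function(d) mean(d) / (sd(d) / sqrt(length(d)))

# build a cell_means object directly from a participants x 4 matrix
# (columns ordered lo.lo, hi.lo, lo.hi, hi.hi over factors f1, f2)
cells_from_matrix <- function(m, f1 = "task", f2 = "reward",
                              l1 = c("a1", "a2"), l2 = c("b1", "b2")) {
  cells <- expand.grid(stats::setNames(list(l1, l2), c(f1, f2)),
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  colnames(m) <- paste(cells[[f1]], cells[[f2]], sep = ":")
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  structure(m, factors = stats::setNames(list(l1, l2), c(f1, f2)),
            cells = cells, value = "y",
            class = c("cell_means", "matrix", "array"))
}

# simulate a cohort and return its clean high-temperature analysis set;
# intercepts default away from the [0,1] clipping bounds
gen_pain_set <- function(J, n_trials, fixed = list(), Psi = NULL,
                         sigma_M = 0.08, sigma_Y = 0.15, seed = 1) {
  fx <- modifyList(list(alpha_M = 0.8, alpha_Y = 0.5, rew_Y = 0), fixed)
  cc <- cohort_config(n_participants = J, n_trials = n_trials, fixed = fx,
                      Psi = Psi, sigma_M = sigma_M, sigma_Y = sigma_Y,
                      fast_rt_rate = 0)
  pr <- simulate_participants(cc, seed = seed)
  tr <- simulate_trials(pr, cc, seed = seed + 1)
  select_analysis_set(preprocess_trials(tr), "pain")
}

# 5x5 random-effect covariance with the given nonzero entries
psi_matrix <- function(sd = c(a = 0, b = 0, cprime = 0, int_M = 0,
                              int_Y = 0), cov_ab = 0) {
  nm <- c("a", "b", "cprime", "int_M", "int_Y")
  s <- stats::setNames(numeric(5), nm)
  s[names(sd)] <- sd
  P <- diag(s^2)
  dimnames(P) <- list(nm, nm)
  P["a", "b"] <- P["b", "a"] <- cov_ab
  P
}

# deterministic response stream with the requested hit/false-alarm pattern
stream_fixture <- function(targets, responses) {
  data.frame(onset_ms = seq_along(targets), target = targets,
             response = responses)
}
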