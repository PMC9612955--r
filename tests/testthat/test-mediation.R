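test_that("stacking doubles rows with the right sparsity and round-trips", {
  pain <- gen_pain_set(J = 12, n_trials = 32, seed = 51)
  st <- stack_mediation(pain)
  expect_equal(nrow(st), 2 * nrow(pain))
  expect_equal(attr(st, "n_trials"), nrow(pain))
  m <- st[st$outcome == "M", ]; y <- st[st$outcome == "Y", ]
  # every predictor is zero on the other outcome's rows
  expect_true(all(m[, c("sy_m", "sy_w", "sy_mw", "sy_x", "sy_xw", "sy_t",
                        "sy_logt")] == 0))
  expect_true(all(y[, c("sm_x", "sm_w", "sm_xw", "sm_t", "sm_logt")] == 0))
  expect_true(all(m$sm == 1 & m$sy == 0 & y$sy == 1 & y$sm == 0))
  # round trip
  back <- unstack_mediation(st)
  expect_equal(back$performance, pain$performance)
  expect_equal(back$rating01, pain$rating01)
  expect_equal(back$x, as.numeric(pain$task == "2back"))
  expect_equal(back$w, as.numeric(pain$reward))
  # an all-LR table gives identically zero task columns
  lr <- pain[pain$task == "LR", ]
  st_lr <- stack_mediation(lr)
  expect_true(all(st_lr$sm_x == 0 & st_lr$sy_x == 0))
})

test_that("with zero random-effect variance the fit matches per-equation OLS", {
  pain <- gen_pain_set(J = 20, n_trials = 32, Psi = psi_matrix(), seed = 52)
  fit <- suppressWarnings(fit_mediation(pain, random = "paper"))
  x <- as.numeric(pain$task == "2back"); w <- as.numeric(pain$reward)
  olsM <- lm(performance ~ x * w + t + log_t, data = cbind(pain, x = x,
                                                           w = w))
  olsY <- lm(rating01 ~ performance * w + x + x:w + t + log_t,
             data = cbind(pain, x = x, w = w))
  expect_equal(fit$coefficients[["a"]], coef(olsM)[["x"]], tolerance = 1e-4)
  expect_equal(fit$coefficients[["a_W"]], coef(olsM)[["x:w"]],
               tolerance = 1e-4)
  expect_equal(fit$coefficients[["b"]], coef(olsY)[["performance"]],
               tolerance = 1e-4)
  expect_equal(fit$coefficients[["cprime"]], coef(olsY)[["x"]],
               tolerance = 1e-4)
  expect_equal(fit$coefficients[["int_M"]], coef(olsM)[["(Intercept)"]],
               tolerance = 1e-4)
})

test_that("the stacked fit agrees with the nlme toolchain on shared data", {
  pain <- gen_pain_set(J = 25, n_trials = 32,
                       Psi = psi_matrix(sd = c(a = 0.07, b = 0.1,
                                               cprime = 0.05),
                                        cov_ab = 0.004),
                       seed = 53)
  st <- stack_mediation(pain)
  fit <- fit_mediation(st, random = "paper")
  d <- as.data.frame(st)
  d$idf <- factor(d$participant_id)
  d$cls <- as.integer(d$outcome == "Y")
  g <- nlme::lme(
    z ~ 0 + sm + sm_x + sm_w + sm_xw + sm_t + sm_logt + sy + sy_m + sy_w +
      sy_mw + sy_x + sy_xw + sy_t + sy_logt,
    random = list(idf = nlme::pdSymm(~ 0 + sm_x + sy_m + sy_x)),
    weights = nlme::varIdent(form = ~ 1 | cls), data = d, method = "REML",
    control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                               returnObject = TRUE))
  ref <- nlme::fixef(g)
  expect_equal(unname(fit$coefficients[c("int_M", "a", "rewM", "a_W")]),
               unname(ref[c("sm", "sm_x", "sm_w", "sm_xw")]),
               tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[c("int_Y", "b", "cprime")]),
               unname(ref[c("sy", "sy_m", "sy_x")]), tolerance = 1e-3)
  vc <- as.matrix(nlme::getVarCov(g))
  expect_equal(unname(fit$Psi["a", "b"]), vc[1, 2], tolerance = 5e-4)
  expect_equal(unname(diag(fit$Psi)), unname(diag(vc)), tolerance = 1e-3)
})

test_that("relabelling participants leaves the fit unchanged", {
  pain <- gen_pain_set(J = 15, n_trials = 16, seed = 54)
  f1 <- fit_mediation(pain, random = "paper")
  perm <- sample(unique(pain$participant_id))
  pain2 <- pain
  pain2$participant_id <- perm[match(pain$participant_id,
                                     unique(pain$participant_id))]
  f2 <- fit_mediation(pain2, random = "paper")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$Psi, f2$Psi, tolerance = 1e-6)
})

test_that("indirect-effect arithmetic follows the covariance-inclusive definition", {
  pain <- gen_pain_set(J = 12, n_trials = 16, seed = 55)
  fit <- fit_mediation(pain, random = "paper")
  ie <- indirect_effects(fit)
  cf <- fit$coefficients
  s_ab <- fit$Psi["a", "b"]
  expect_equal(ie[["ab"]], cf[["a"]] * cf[["b"]] + s_ab)
  expect_equal(ie[["ie_w0"]], ie[["ab"]])
  expect_equal(ie[["ie_w1"]],
               (cf[["a"]] + cf[["a_W"]]) * (cf[["b"]] + cf[["b_W"]]) + s_ab)
  expect_equal(ie[["ie_diff"]], ie[["ie_w1"]] - ie[["ie_w0"]])
  # published point estimates as a worked example of the arithmetic:
  # a = -0.13, b = -0.16, sigma_ab = 0 gives ab = 0.0208
  fake <- fit
  fake$coefficients[c("a", "b", "a_W", "b_W")] <- c(-0.13, -0.16, 0, 0)
  fake$Psi["a", "b"] <- fake$Psi["b", "a"] <- 0
  ie2 <- indirect_effects(fake)
  expect_equal(ie2[["ab"]], 0.0208)
  expect_equal(ie2[["ie_diff"]], 0)
  # pure-covariance case
  fake$coefficients[c("a", "b")] <- 0
  fake$Psi["a", "b"] <- fake$Psi["b", "a"] <- 0.05
  expect_equal(indirect_effects(fake)[["ab"]], 0.05)
  # without a joint random (a, b) pair the covariance term vanishes
  fit_b <- suppressWarnings(fit_mediation(pain, random = c("int_M", "int_Y")))
  ieb <- indirect_effects(fit_b)
  expect_equal(ieb[["ab"]],
               fit_b$coefficients[["a"]] * fit_b$coefficients[["b"]])
})

test_that("a diagonal Psi reduces ab to the plain product", {
  pain <- gen_pain_set(J = 15, n_trials = 16,
                       Psi = psi_matrix(sd = c(a = 0.08, b = 0.1,
                                               cprime = 0.04)),
                       seed = 56)
  fit <- fit_mediation(pain, random = "paper", psi = "diagonal")
  expect_equal(fit$Psi["a", "b"], 0)
  ie <- indirect_effects(fit)
  expect_equal(ie[["ab"]], fit$coefficients[["a"]] * fit$coefficients[["b"]])
})

test_that("the REML optimizer never degrades its starting objective", {
  pain <- gen_pain_set(J = 12, n_trials = 16, seed = 57)
  fit <- fit_mediation(pain, random = "paper")
  take <- seq_len(fit$n_participants)
  set.seed(58)
  for (i in 1:5) {
    th0 <- fit$theta + rnorm(length(fit$theta), 0, 1)
    opt <- medistract:::reml_optimize(fit$stats, take,
                                      q = 3, has_delta = TRUE, start = th0)
    expect_lte(opt$op$objective,
               medistract:::reml_objective(th0, fit$stats,
                                           as.integer(take), TRUE) + 1e-8)
    # and never beats the full fit's optimum by more than numerical slack
    expect_gte(opt$op$objective, fit$optim_info$objective - 1e-4)
  }
})

test_that("bootstrap intervals are reproducible, and degenerate noise shrinks them", {
  pain <- gen_pain_set(J = 12, n_trials = 16, seed = 59)
  b1 <- bootstrap_mediation(pain, B = 100, seed = 60, random = "paper")
  b2 <- bootstrap_mediation(pain, B = 100, seed = 60, random = "paper")
  expect_equal(b1$ci, b2$ci)
  expect_equal(b1$n_fail, 0)
  expect_error(bootstrap_mediation(pain, B = 50, seed = 1), "at least 100")
  # noise-free outcome equation: its intervals collapse toward points
  # (the mediator keeps ordinary noise so that b stays identified)
  tiny <- gen_pain_set(J = 12, n_trials = 16, Psi = psi_matrix(),
                       sigma_M = 0.08, sigma_Y = 1e-5, seed = 61)
  bt <- suppressWarnings(bootstrap_mediation(tiny, B = 100, seed = 62,
                                             random = "paper"))
  widths <- bt$ci[, 2] - bt$ci[, 1]
  expect_lt(max(widths[c("b", "cprime", "b_W", "cprime_W")]), 1e-3)
  expect_lt(widths[["ab"]], 0.02)
})

test_that("the total-effect model recovers nulls and rejects rank deficiency", {
  pain <- gen_pain_set(J = 25, n_trials = 32,
                       fixed = list(cprime = 0, cprime_w = 0, b = 0,
                                    b_w = 0),
                       Psi = psi_matrix(sd = c(int_Y = 0.05)), seed = 63)
  fit <- fit_total_effect(pain)
  expect_true(fit$converged)
  # no generating task effect on the rating in any pathway
  expect_lt(abs(fit$coefficients[["c"]]), 2 * fit$se[["c"]] + 0.02)
  lr_only <- pain[pain$task == "LR", ]
  expect_error(fit_total_effect(lr_only), "c")
})

test_that("mediation_fit methods expose coherent pieces", {
  pain <- gen_pain_set(J = 12, n_trials = 16, seed = 64)
  fit <- fit_mediation(pain, random = "paper")
  expect_s3_class(fit, "mediation_fit")
  expect_named(coef(fit), names(medistract:::.fixed_cols))
  expect_equal(dim(vcov(fit)), c(14L, 14L))
  expect_equal(length(residuals(fit)), fit$n_rows)
  expect_equal(fitted(fit) + residuals(fit), fit$stacked$z)
  expect_equal(predict(fit), fitted(fit, level = "marginal"))
  sims <- simulate(fit, nsim = 3, seed = 65)
  expect_equal(dim(sims), c(fit$n_rows, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 65))
  tab <- mediation_table(fit)
  expect_equal(nrow(tab), 16L)
  expect_output(print(summary(fit)), "Random-effect covariance")
  expect_output(path_summary(fit), "indirect")
  # ratings outside [0, 1] are refused
  bad <- pain; bad$rating01[1] <- 1.7
  expect_error(fit_mediation(bad, random = "paper"), "\\[0, 1\\]")
})
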