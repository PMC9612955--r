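test_that("participant profiles honour the covariance and cohort size", {
  # degenerate covariance: all random effects exactly zero
  cc0 <- cohort_config(n_participants = 8, Psi = psi_matrix())
  pr0 <- simulate_participants(cc0, seed = 1)
  expect_equal(unlist(pr0[, c("u_a", "u_b", "u_cprime", "u_int_m",
                              "u_int_y")]),
               rep(0, 40), ignore_attr = TRUE)
  # the study cohort: 57 profiles with ids 1..57
  pr <- simulate_participants(cohort_config(), seed = 2)
  expect_equal(pr$participant_id, 1:57)
  expect_true(all(pr$reward_amount >= 0.5 & pr$reward_amount <= 3))
  expect_true(all(pr$low_temp < pr$high_temp))
  # Monte-Carlo: sample cov of (a_j, b_j) approaches the requested 0.05
  ccMC <- cohort_config(n_participants = 10000,
                        Psi = psi_matrix(sd = c(a = 0.25, b = 0.25),
                                         cov_ab = 0.05))
  prMC <- simulate_participants(ccMC, seed = 3)
  expect_lt(abs(cov(prMC$u_a, prMC$u_b) - 0.05), 0.005)
})

test_that("invalid generative configs are rejected", {
  P <- psi_matrix(); P[1, 2] <- 0.5 # asymmetric
  expect_error(cohort_config(Psi = P), "symmetric")
  P2 <- psi_matrix(sd = c(a = 0.1)); P2[1, 2] <- P2[2, 1] <- 0.5 # not PSD
  expect_error(cohort_config(Psi = P2), "semi-definite")
  expect_error(cohort_config(n_trials = 60), "divisible by 8")
})

test_that("trial tables are balanced, bounded, and deterministic", {
  cc <- cohort_config(n_participants = 6, n_trials = 32)
  pr <- simulate_participants(cc, seed = 4)
  tr <- simulate_trials(pr, cc, seed = 5)
  expect_equal(nrow(tr), 6 * 32)
  counts <- table(tr$participant_id, tr$task, tr$reward, tr$temperature)
  expect_true(all(counts == 4)) # 32 / 8 per cell
  expect_true(all(tr$performance >= 0 & tr$performance <= 1))
  expect_true(all(tr$rating >= 0 & tr$rating <= 100))
  # temperature runs capped at 3 by the permuted-block scheme
  runs <- tapply(tr$temperature, tr$participant_id,
                 function(x) max(rle(x)$lengths))
  expect_true(all(runs <= 3))
  # low-temperature trials default to "not painful"
  expect_true(all(tr$pain_binary[tr$temperature == "low"] == "not painful"))
  # determinism: same profiles + config + seed give identical tables
  expect_identical(tr, simulate_trials(pr, cc, seed = 5))
})

test_that("the noise-free forward model is exact", {
  # all paths zero: every M equals alpha_M, every rating 100 * alpha_Y
  fx0 <- list(a = 0, rew_M = 0, a_w = 0, g1_M = 0, g2_M = 0, b = 0,
              rew_Y = 0, b_w = 0, cprime = 0, cprime_w = 0, g1_Y = 0,
              g2_Y = 0, alpha_M = 0.7, alpha_Y = 0.4)
  cc0 <- cohort_config(n_participants = 3, n_trials = 16, fixed = fx0,
                       Psi = psi_matrix(), sigma_M = 0, sigma_Y = 0)
  tr0 <- simulate_trials(simulate_participants(cc0, seed = 6), cc0, seed = 7)
  expect_equal(tr0$performance, rep(0.7, nrow(tr0)))
  expect_equal(tr0$rating, rep(40, nrow(tr0)))
  # a = -0.13 with everything else off: the task contrast is exact
  fx1 <- modifyList(fx0, list(a = -0.13, alpha_M = 0.96))
  cc1 <- cohort_config(n_participants = 3, n_trials = 16, fixed = fx1,
                       Psi = psi_matrix(), sigma_M = 0, sigma_Y = 0)
  tr1 <- simulate_trials(simulate_participants(cc1, seed = 6), cc1, seed = 7)
  expect_equal(mean(tr1$performance[tr1$task == "2back"]) -
                 mean(tr1$performance[tr1$task == "LR"]), -0.13)
})

test_that("n-back streams follow the timeline and the observer's sensitivity", {
  # 1250 ms ISI: floor(20000 / 2000) = 10 letters
  st <- simulate_nback_stream(1250, observer = 2, seed = 8)
  expect_equal(nrow(st), 10)
  expect_true(all(is.na(st$target[1:2])))
  expect_error(simulate_nback_stream(10), "\\[19, 2583\\]")
  # an error-free observer is always correct
  stInf <- simulate_nback_stream(500, observer = Inf, seed = 9)
  sc <- score_stream(stInf)
  expect_equal(sc$H, 1)
  expect_equal(sc$F, 0)
  # a guessing observer has matching hit and false-alarm rates on average
  hs <- fs <- numeric(300)
  for (i in seq_len(300)) {
    s <- score_stream(simulate_nback_stream(300, observer = 0,
                                            seed = 100 + i))
    hs[i] <- s$H; fs[i] <- s$F
  }
  expect_lt(abs(mean(hs, na.rm = TRUE) - mean(fs, na.rm = TRUE)), 0.03)
})

test_that("choice tables follow the logistic value function", {
  ch <- simulate_choices(-2, 2.5, seed = 10)
  expect_equal(nrow(ch), 26)
  expect_identical(ch, simulate_choices(-2, 2.5, seed = 10))
  expect_error(simulate_choices(0, 1, offers = c(1, 4)), "\\[0, 3\\]")
  # infinite slope: a step function in the offer
  st <- simulate_choices(-1, Inf, seed = 11)
  expect_true(all(st$accept[st$offer > 0]))
  expect_equal(st$p_accept[st$offer == 0], plogis(-1))
})
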