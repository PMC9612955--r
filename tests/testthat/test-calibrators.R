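test_that("thermal calibration inverts a noise-free linear observer exactly", {
  temps <- c(40, 44, 45, 46, 47, 48, 49)
  # warmth = 10 * (T - 37) below the pain threshold; pain intensity rises
  # from 30 at 47 C
  tab <- do.call(rbind, lapply(1:4, function(site) {
    painful <- temps >= 47
    data.frame(temperature = temps, painful = painful,
               rating = ifelse(painful, 30 + 15 * (temps - 47),
                               10 * (temps - 37)))
  }))
  cal <- fit_thermal_curve(tab)
  expect_equal(cal$n_stimulations, 28)
  expect_equal(cal$low_temp, 45.0, tolerance = 1e-6)
  expect_equal(cal$high_temp, 49.0, tolerance = 1e-6) # 60 = 30 + 15*(T-47)
  expect_lt(cal$low_temp, cal$high_temp)
})

test_that("thermal calibration fails loudly on degenerate input", {
  temps <- rep(c(40, 44, 45, 46, 47, 48, 49), 2)
  flat <- data.frame(temperature = temps, painful = temps >= 47, rating = 50)
  expect_error(fit_thermal_curve(flat), "flat")
  none_painful <- data.frame(temperature = temps, painful = FALSE,
                             rating = 10 * (temps - 37))
  expect_error(fit_thermal_curve(none_painful), "painful")
})

test_that("a non-increasing least-squares branch falls back to the monotone fit", {
  # warmth ratings whose OLS slope is negative but whose isotonic fit still
  # rises; the pain branch is a clean line
  tab <- rbind(
    data.frame(temperature = c(40, 44, 45), painful = FALSE,
               rating = c(80, 40, 90)),
    data.frame(temperature = 46:49, painful = TRUE,
               rating = 20 + 12 * (46:49 - 46)))
  cal <- fit_thermal_curve(tab)
  expect_equal(cal$warmth_method, "isotonic")
  expect_equal(cal$pain_method, "ols")
  expect_true(cal$low_temp >= 40 && cal$low_temp <= 49)
  expect_true(cal$low_temp < cal$high_temp)
})

test_that("the ISI staircase holds inside the band and brackets a threshold", {
  # observer always inside the band (H = 0.7, F = 0.3, A = 0.79):
  # the ISI never moves
  in_band <- function(isi) {
    tg <- c(NA, NA, rep(TRUE, 10), rep(FALSE, 10))
    rsp <- tg; rsp[is.na(rsp)] <- FALSE
    rsp[3:5] <- FALSE  # 3 misses  -> H = 0.7
    rsp[13:15] <- TRUE # 3 false alarms -> F = 0.3
    stream_fixture(tg, rsp)
  }
  st <- run_isi_staircase(in_band, seed = 1)
  expect_equal(length(unique(st$trajectory$isi)), 1L)
  expect_equal(st$final_isi, 1250)
  # deterministic threshold observer: perfect above 800 ms, chance below
  thresh <- function(isi) {
    tg <- c(NA, NA, rep(TRUE, 10), rep(FALSE, 10))
    rsp <- tg; rsp[is.na(rsp)] <- FALSE
    if (isi <= 800) { # H = F = 0.5 -> A = 0.5
      rsp[3:7] <- FALSE; rsp[13:17] <- TRUE
    }
    stream_fixture(tg, rsp)
  }
  st2 <- run_isi_staircase(thresh, seed = 2)
  expect_lte(nrow(st2$trajectory), 15)
  expect_gt(st2$final_isi, 800 / 1.25)
  expect_lt(st2$final_isi, 800 * 1.25)
})

test_that("staircase on a stochastic observer settles near the band", {
  observer <- function(isi) simulate_nback_stream(
    isi, observer = min(1.35 * (isi / 700)^0.4, 4.5))
  finals <- vapply(seq_len(100), function(i)
    run_isi_staircase(observer, seed = 1000 + i)$final_isi, numeric(1))
  expect_true(all(finals >= 19 & finals <= 2583))
  # replay 50 fresh trials at each run's final ISI and average A
  mean_A <- mean(vapply(seq_len(100), function(i) {
    as <- vapply(seq_len(50), function(k) {
      s <- score_stream(simulate_nback_stream(
        finals[i], observer = min(1.35 * (finals[i] / 700)^0.4, 4.5),
        seed = i * 1000 + k))
      if (is.na(s$A)) 0.5 else s$A
    }, numeric(1))
    mean(as)
  }, numeric(1)))
  expect_gte(mean_A, 0.70)
  expect_lte(mean_A, 0.90)
})

test_that("money calibration recovers a known logistic observer", {
  truth_int <- -qlogis(0.95); truth_slope <- qlogis(0.95) # amount_95 = 2.00
  offers <- rep(seq(0, 3, length.out = 26), 40)
  ch <- simulate_choices(truth_int, truth_slope, offers = offers, seed = 31)
  cal <- fit_money_acceptance(ch)
  expect_equal(cal$method, "mle")
  expect_equal(cal$amount_95, 2.00, tolerance = 0.15)
  # the defining identity: the fitted curve passes through 0.95 at the
  # unclamped calibrated amount
  expect_equal(plogis(cal$intercept + cal$slope * cal$amount_95_raw), 0.95,
               tolerance = 1e-8)
})

test_that("money calibration clamps and falls back as specified", {
  all_yes <- data.frame(offer = seq(0, 3, length.out = 26), accept = TRUE)
  expect_warning(cal <- fit_money_acceptance(all_yes), "separation")
  expect_equal(cal$amount_95, 0.50)
  all_no <- data.frame(offer = seq(0, 3, length.out = 26), accept = FALSE)
  expect_warning(cal2 <- fit_money_acceptance(all_no), "separation")
  expect_equal(cal2$amount_95, 3.00)
  # an eager observer accepted nearly everything: raw amount below $0.50
  # clamps up
  ch <- simulate_choices(3, 4, offers = rep(seq(0, 3, length.out = 26), 20),
                         seed = 32)
  cal3 <- suppressWarnings(fit_money_acceptance(ch))
  expect_gte(cal3$amount_95, 0.50)
  # money-averse pattern: acceptance decreasing in the offer
  dec <- data.frame(offer = seq(0, 3, length.out = 26),
                    accept = seq(0, 3, length.out = 26) < 1.5)
  expect_warning(cal4 <- fit_money_acceptance(dec), "slope|separation")
  expect_true(cal4$amount_95 %in% c(0.5, 3) || cal4$method != "mle")
})
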