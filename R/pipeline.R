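#' Configuration of a full pipeline run
#'
#' @param seed top-level integer seed; every stochastic stage derives its
#'   own named substream from it, so e.g. changing the bootstrap size never
#'   perturbs cohort generation.
#' @param cohort a [cohort_config()].
#' @param preset `"default"` (random intercepts plus the three path slopes,
#'   desk-scale bootstrap) or `"paper"` (random effects on the a, b and
#'   c-prime paths only, 10,000 bootstrap replicates).
#' @param bootstrap_B bootstrap replicates; overrides the preset when
#'   given. `0` skips the bootstrap (point estimates only, empty CI
#'   columns).
#' @param random_set overrides the preset's random-effect set.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, cohort = cohort_config(),
                       preset = c("default", "paper"),
                       bootstrap_B = NULL, random_set = NULL) {
  preset <- match.arg(preset)
  stopifnot(inherits(cohort, "cohort_config"))
  if (is.null(bootstrap_B))
    bootstrap_B <- if (preset == "paper") 10000L else 200L
  if (is.null(random_set))
    random_set <- if (preset == "paper") c("a", "b", "cprime")
  else c("int_M", "int_Y", "a", "b", "cprime")
  structure(list(seed = as.integer(seed), cohort = cohort, preset = preset,
                 bootstrap_B = as.integer(bootstrap_B),
                 random_set = random_set),
            class = "run_config")
}

# simulate one participant's 28-stimulation thermal session from their true
# thresholds: a warmth line through (low_temp, 80) and a pain-intensity
# line through (high_temp, 60), with rating noise
simulate_thermal_ratings <- function(low_temp, high_temp,
                                     warmth_slope = 9, pain_slope = 12,
                                     rating_sd = 4, n_sites = 4L,
                                     temps = c(40, 44, 45, 46, 47, 48, 49)) {
  tt <- rep(temps, n_sites)
  # keep at least two stimulated temperatures on each side of the pain
  # threshold so both branches of the curve are estimable
  pain_threshold <- min(max((low_temp + high_temp) / 2, 44.5), 47.5)
  painful <- tt >= pain_threshold
  rating <- ifelse(painful,
                   60 + pain_slope * (tt - high_temp),
                   80 + warmth_slope * (tt - low_temp)) +
    rnorm(length(tt), 0, rating_sd)
  data.frame(temperature = tt, painful = painful,
             rating = pmin(pmax(rating, 0), 100))
}

#' Run the whole analysis pipeline
#'
#' Orchestrates one reproducible end-to-end run on a synthetic cohort:
#' simulate participants, simulate and fit their three calibration sessions
#' (thermal curve, ISI staircase, pain-for-money choices), generate the
#' factorial trial table using each participant's calibrated reward amount,
#' filter and rescale trials, run the pain and performance repeated-measures
#' ANOVAs with planned contrasts and within-subject SEs, fit the total-effect
#' and mediation models, bootstrap the indirect effects, and (optionally)
#' write every table plus a run manifest under `out_dir`.  The same config
#' and seed always reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return an object of class `report_bundle` (list of all stage results),
#'   invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(c(name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- config$seed

  profiles <- stage("simulate", simulate_participants(
    config$cohort, seed = child_seed(seed, "participants")))

  calib <- stage("calibrate", with_seed(child_seed(seed, "calibrate"), {
    out <- vector("list", nrow(profiles))
    for (i in seq_len(nrow(profiles))) {
      pr <- profiles[i, ]
      th <- fit_thermal_curve(
        simulate_thermal_ratings(pr$low_temp, pr$high_temp))
      observer <- local({
        true_isi <- pr$true_isi
        function(isi) simulate_nback_stream(
          isi, observer = min(1.35 * (isi / true_isi)^0.4, 4.5))
      })
      st <- run_isi_staircase(observer)
      mc <- suppressWarnings(fit_money_acceptance(
        simulate_choices(pr$money_logit_intercept, pr$money_logit_slope)))
      out[[i]] <- data.frame(
        participant_id = pr$participant_id,
        low_temp = th$low_temp, high_temp = th$high_temp,
        final_isi = st$final_isi, amount_95 = mc$amount_95,
        money_method = mc$method)
    }
    do.call(rbind, out)
  }))

  profiles$reward_amount <- calib$amount_95
  trials <- stage("simulate", simulate_trials(
    profiles, config$cohort, seed = child_seed(seed, "trials")))
  clean <- stage("preprocess", preprocess_trials(trials))

  pain <- select_analysis_set(clean, "pain")
  perf <- select_analysis_set(clean, "performance")
  anova_res <- stage("anova", {
    pain_cells <- cell_means(pain, "pain0", c("task", "reward"))
    perf_cells <- cell_means(perf, "performance", c("temperature", "reward"))
    list(pain_cells = pain_cells,
         pain_anova = rm_anova_2x2(pain_cells),
         pain_contrasts = planned_contrasts(pain_cells),
         perf_cells = perf_cells,
         perf_anova = rm_anova_2x2(perf_cells),
         perf_contrasts = planned_contrasts(perf_cells))
  })

  med <- stage("mediation", {
    fit <- fit_mediation(pain, random = config$random_set)
    total <- fit_total_effect(pain)
    boot <- if (config$bootstrap_B > 0)
      bootstrap_mediation(pain, B = config$bootstrap_B,
                          seed = child_seed(seed, "bootstrap"),
                          random = config$random_set)
    list(fit = fit, total = total, boot = boot,
         indirect = indirect_effects(fit),
         table = mediation_table(fit, boot))
  })

  manifest <- list(
    package = "medistract",
    version = as.character(utils::packageVersion("medistract")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, preset = config$preset,
    bootstrap_B = config$bootstrap_B,
    random_set = config$random_set,
    n_participants = config$cohort$n_participants,
    n_trials = config$cohort$n_trials,
    config_hash = config_hash(config),
    filter_report = attr(clean, "filter_report"))

  bundle <- structure(list(config = config, profiles = profiles,
                           calibrations = calib, trials = trials,
                           clean = clean, anova = anova_res,
                           mediation = med, manifest = manifest),
                      class = "report_bundle")
  if (!is.null(out_dir)) {
    stage("report", write_report(bundle, out_dir))
    return(invisible(bundle))
  }
  bundle
}

# order-invariant FNV-style hash of a config's deparsed content, so the
# manifest can certify that two runs used identical settings
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "\n")
  h <- 216613626
  for (ch in utf8ToInt(txt)) h <- ((h * 16777619) + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  cohort_cols <- c("participant_id", "trial", "task", "reward",
                   "temperature", "performance", "pain_binary", "rating",
                   "rating_rt_ms")
  write.csv(bundle$trials[, cohort_cols], p("cohort.csv"), row.names = FALSE)
  write.csv(bundle$calibrations, p("calibrations.csv"), row.names = FALSE)
  jsonlite::write_json(attr(bundle$clean, "filter_report"),
                       p("filter_report.json"), auto_unbox = TRUE,
                       digits = NA)
  a <- bundle$anova
  write.csv(a$pain_anova, p("anova_pain.csv"), row.names = FALSE)
  write.csv(a$pain_contrasts, p("contrasts_pain.csv"), row.names = FALSE)
  write.csv(cell_summary(a$pain_cells), p("cellmeans_pain.csv"),
            row.names = FALSE)
  write.csv(a$perf_anova, p("anova_performance.csv"), row.names = FALSE)
  write.csv(a$perf_contrasts, p("contrasts_performance.csv"),
            row.names = FALSE)
  write.csv(cell_summary(a$perf_cells), p("cellmeans_performance.csv"),
            row.names = FALSE)
  m <- bundle$mediation
  write.csv(m$table, p("mediation_coefficients.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(Psi = m$fit$Psi, sigma2_M = m$fit$sigma2_M,
         sigma2_Y = m$fit$sigma2_Y, converged = m$fit$converged,
         loglik = m$fit$loglik, random_set = m$fit$random_set,
         bootstrap = list(B = bundle$config$bootstrap_B,
                          seed = child_seed(bundle$config$seed, "bootstrap"),
                          n_fail = if (!is.null(m$boot)) m$boot$n_fail)),
    p("mediation_fit.json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  writeLines(utils::capture.output(path_summary(m$fit, m$total)),
             p("path_summary.txt"))
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("motivated-distraction pipeline run\n")
  cat(sprintf("  seed %d, preset '%s', %d participants x %d trials\n",
              x$manifest$seed, x$manifest$preset,
              x$manifest$n_participants, x$manifest$n_trials))
  cat(sprintf("  trials removed by the 150 ms rule: %d (%.2f%% of all)\n",
              x$manifest$filter_report$n_removed,
              100 * x$manifest$filter_report$frac_removed_all))
  cat("\npain ANOVA:\n"); print(x$anova$pain_anova)
  cat("\n"); path_summary(x$mediation$fit, x$mediation$total)
  invisible(x)
}
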