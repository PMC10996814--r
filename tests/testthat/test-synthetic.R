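# The generator is validated against its own declared calibration
# targets and against independent statistical oracles (empirical
# survival vs. the closed-form discrete survival, GLM coefficient
# recovery), never against quantities tuned after the fact.

big <- generate_cohort(cohort_spec(n_patients = 4000, seed = 1))

test_that("generation is deterministic and independent of the global RNG", {
  g1 <- generate_cohort(cohort_spec(n_patients = 40, seed = 5))
  set.seed(987); stats::runif(13)   # perturb the global RNG state
  g2 <- generate_cohort(cohort_spec(n_patients = 40, seed = 5))
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$burden, g2$burden)
  expect_identical(g1$ground_truth$true_params, g2$ground_truth$true_params)
  g3 <- generate_cohort(cohort_spec(n_patients = 40, seed = 6))
  expect_false(identical(g1$cohort$age, g3$cohort$age))
})

test_that("large cohorts reproduce the published summary table", {
  s <- table1_summary(big$cohort)
  co <- big$cohort
  n <- nrow(co)
  # categorical proportions within 3 percentage points
  white <- s$pct[s$feature == "race" & s$level == "White"] / 100
  expect_lt(abs(white - 76 / 93), 0.03)
  male <- s$pct[s$feature == "sex" & s$level == "male"] / 100
  expect_lt(abs(male - 47 / 93), 0.03)
  smoker <- mean(co$ever_smoker)
  expect_lt(abs(smoker - 52 / 93), 0.03)
  # continuous medians near the published values, ranges inside the
  # published (truncation) bounds
  med <- function(f) s$median[s$feature == f & is.na(s$level)]
  expect_lt(abs(med("age") - 58.3), 2)
  expect_lt(abs(med("neutrophil_bsl") - 4.8), 0.5)
  expect_lt(abs(med("lymphocyte_bsl") - 1.16), 0.2)
  # the kill-rate median has a wide lower half (scale ~0.3), so its
  # sampling SD at n = 4000 is ~0.004; 0.02 is a ~5-sigma bound
  expect_lt(abs(med("mu") - 0.0090), 0.02)
  expect_true(all(co$age >= 20 & co$age <= 83))
  expect_true(all(co$mu >= -0.89 & co$mu <= 0.120))
  expect_true(all(co$Lambda >= -11.2 & co$Lambda <= 3.70))
  expect_true(all(co$kps %in% c(0.6, 0.7, 0.8, 0.9, 1.0)))
  expect_equal(stats::median(co$kps), 0.8)
})

test_that("mechanistic draws are sign-coupled and never blow up", {
  co <- big$cohort
  expect_true(all(co$mu * co$Lambda >= 0))
  b <- big$burden
  expect_true(all(is.finite(b$normalized_burden)))
  expect_true(all(b$normalized_burden > 0))
  # baseline burden is exactly 1; scans on the declared schedule
  expect_true(all(b$normalized_burden[b$time_days == 0] == 1))
  expect_equal(sort(unique(b$time_days)), c(0, 60, 120, 180))
  # alpha1 is the log-slope of the observed first-restaging burden
  first <- b[b$time_days == 60, ]
  first <- first[match(co$patient_id, first$patient_id), ]
  expect_equal(co$alpha1, log(first$normalized_burden) / 60,
               tolerance = 1e-12)
})

test_that("with null effects the empirical survival matches the baseline", {
  null_beta <- stats::setNames(numeric(0), character(0))
  g <- generate_cohort(cohort_spec(n_patients = 2500, seed = 3,
                                   feature_effects = null_beta,
                                   censoring_rate = 0))
  h0 <- 0.09
  edges <- g$ground_truth$bin_edges
  surv_true <- cumprod(rep(1 - h0, 20))
  for (j in c(3, 7, 12)) {
    emp <- mean(g$cohort$duration_days > edges[j + 1])
    expect_lt(abs(emp - surv_true[j]), 0.04)
  }
  # only administrative censoring: all censored durations equal horizon
  cens <- g$cohort$duration_days[g$cohort$event == 0]
  expect_true(all(cens == 730))
})

test_that("a positive log-hazard effect shortens survival", {
  g <- generate_cohort(cohort_spec(n_patients = 1500, seed = 4,
                                   feature_effects = c(neutrophil_bsl = 0.8),
                                   censoring_rate = 0))
  lp <- g$ground_truth$true_params$linear_predictor
  expect_lt(stats::cor(lp, g$cohort$duration_days, method = "spearman"),
            -0.2)
  expect_lt(stats::cor(g$cohort$neutrophil_bsl, g$cohort$duration_days,
                       method = "spearman"), -0.1)
})

test_that("independent censoring is uncorrelated with patient features", {
  null_beta <- stats::setNames(numeric(0), character(0))
  # censoring_rate is the probability of drawing an independent
  # censoring time; events can pre-empt it, so with h0 = 0.09 the
  # expected censored fraction is 0.5*mean(0.91^(1:20)) + 0.5*0.91^20
  # ~ 0.29
  g <- suppressWarnings(
    generate_cohort(cohort_spec(n_patients = 4000, seed = 8,
                                feature_effects = null_beta,
                                censoring_rate = 0.5)))
  cens <- as.numeric(g$cohort$event == 0)
  for (f in c("age", "neutrophil_bsl", "lymphocyte_bsl", "mu", "alpha1")) {
    expect_lt(abs(stats::cor(cens, g$cohort[[f]])), 0.05)
  }
  expect_true(g$ground_truth$achieved_censoring > 0.2 &&
                g$ground_truth$achieved_censoring < 0.45)
})

test_that("the discrete-hazard GLM recovers the generating coefficients", {
  rec <- fit_discrete_hazard_glm(big$cohort, big$ground_truth)
  expect_named(rec$beta_hat, names(rec$beta_true))
  expect_true(all(abs(rec$beta_hat - rec$beta_true) < 0.15))
  # baseline log-odds recovered by the bin intercepts
  bins <- stats::coef(rec$fit)[paste0("bin", 1:20)]
  expect_lt(abs(stats::median(bins) - stats::qlogis(0.09)), 0.15)
})

test_that("noiseless trajectories round-trip through the mechanistic fit", {
  # the trajectory identifies (a, b), not (mu, Lambda) individually
  # (saturated curves pin down only a/b), so the round-trip check is on
  # the fitted trajectory itself
  g <- generate_cohort(cohort_spec(n_patients = 40, seed = 9,
                                   noise_sigma = 0))
  tp <- g$ground_truth$true_params
  idx <- which(abs(tp$mu) > 0.02 & abs(tp$mu * tp$Lambda) > 1e-3)[1:5]
  for (i in idx) {
    b <- g$burden[g$burden$patient_id == tp$patient_id[i], ]
    series <- tumor_burden_series(tp$patient_id[i], b$time_days,
                                  b$normalized_burden)
    fit <- fit_mechanistic_params(series, alpha0 = tp$alpha0[i])
    expect_lt(attr(fit, "rss"), 1e-8)
    refit_traj <- solve_tumor_burden(fit, b$time_days)
    expect_equal(refit_traj, b$normalized_burden, tolerance = 1e-4)
  }
})

test_that("specification validation rejects malformed requests", {
  expect_error(cohort_spec(n_patients = 5), ">= 10")
  expect_error(cohort_spec(censoring_rate = 0.95), "censoring_rate")
  expect_error(cohort_spec(baseline_hazard = 1.2), "\\(0, 1\\)")
  expect_error(cohort_spec(feature_effects = c(nlr = 1)), "unknown")
  expect_error(table1_summary(big$cohort[0, ]), "empty")
})

test_that("cohort artifacts are written as plain text files", {
  dir <- file.path(tempdir(), "gen-out")
  g <- generate_cohort(cohort_spec(n_patients = 20, seed = 2))
  paths <- write_cohort(g, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["cohort"]])
  expect_equal(nrow(back), 20)
  expect_equal(back$patient_id, g$cohort$patient_id)
  gt <- jsonlite::read_json(paths[["ground_truth"]], simplifyVector = TRUE)
  expect_equal(unlist(gt$beta), g$ground_truth$beta, tolerance = 1e-12)
  expect_length(gt$bin_edges, 21)
  unlink(dir, recursive = TRUE)
})
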