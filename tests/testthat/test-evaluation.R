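test_that("Wald intervals reproduce the reported parameter CIs", {
  ci <- wald_ci(0.317, 0.015)
  expect_equal(round(ci$conf.low, 3), 0.288)
  expect_equal(round(ci$conf.high, 3), 0.346)
  ci2 <- wald_ci(2.187, 0.194)
  expect_equal(round(ci2$conf.low, 3), 1.807)
  # SE zero degenerates to the point estimate
  ci3 <- wald_ci(1.5, 0)
  expect_equal(ci3$conf.low, 1.5)
  expect_equal(ci3$conf.high, 1.5)
  expect_error(wald_ci(1, -0.1), ">= 0")
})

test_that("external metrics match their definitions", {
  m <- external_metrics(pred = c(3.79, 8.73), obs = c(4.26, 9.03))
  expect_equal(m$mpe, -0.385)
  expect_equal(m$mae, 0.385)
  expect_equal(m$mspe, 0.15545)
  expect_equal(external_metrics(pred = 1:5, obs = 1:5)$mpe, 0)
  expect_equal(external_metrics(pred = 1:5, obs = 1:5)$mspe, 0)
  single <- external_metrics(pred = 10, obs = 8)
  expect_equal(single$mpe, 2)
  expect_equal(single$mae, 2)
  expect_equal(single$mspe, 4)
  # data-frame-first form
  df <- tibble::tibble(p = c(1, 2), o = c(2, 1))
  expect_equal(external_metrics(df, p, o)$mae, 1)
  expect_error(external_metrics(pred = 1:3, obs = 1:2), "equal")
  expect_error(external_metrics(pred = numeric(), obs = numeric()),
               "equal")
})

test_that("metric inequalities hold on arbitrary inputs", {
  withr::local_seed(3)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    m <- external_metrics(pred = rnorm(n, 8, 4), obs = rnorm(n, 8, 4))
    expect_gte(m$mae, abs(m$mpe))
    expect_gte(m$mspe, m$mpe^2)
  }
})

test_that("case prediction error is percent relative to the observation", {
  expect_equal(round(case_prediction_error(3.79, 4.26), 1), 11.0)
  expect_equal(round(case_prediction_error(8.73, 9.03), 2), 3.32)
  expect_equal(case_prediction_error(5, 5), 0)
  expect_error(case_prediction_error(5, 0), "positive")
})

test_that("trough prediction is linear in dose and near steady state by dose 6", {
  cov <- list(bbw = 3.9, pna = 23)
  reg <- dosing_regimen(35, 8, 60)
  t6 <- predict_trough(vanco_final_model, cov, reg, at_dose_index = 6)
  expect_gt(t6, 2)
  expect_lt(t6, 7)
  # doubling every dose doubles the trough (linear kinetics, eta = 0)
  reg2 <- dplyr::mutate(reg, amt = amt * 2)
  expect_equal(predict_trough(vanco_final_model, cov, reg2, 6), 2 * t6,
               tolerance = 1e-10)
  # dose 6 is within 2% of the steady-state trough
  t60 <- predict_trough(vanco_final_model, cov, reg, at_dose_index = 60)
  expect_lt(abs(t60 - t6) / t60, 0.02)
  expect_error(predict_trough(vanco_final_model, cov, reg, 1), ">= 2")
})

test_that("prior observations pull the trough prediction via MAP", {
  cov <- list(bbw = 3.9, pna = 23)
  reg <- dosing_regimen(35, 8, 8)
  pop <- predict_trough(vanco_final_model, cov, reg, 6)
  # an observed trough well above the population prediction implies a
  # slower individual clearance, raising the individual prediction
  prior <- tibble::tibble(time = reg$time[5], dv = pop * 1.8)
  map_up <- predict_trough(vanco_final_model, cov, reg, 6,
                           prior_obs = prior)
  expect_gt(map_up, pop)
  prior_lo <- tibble::tibble(time = reg$time[5], dv = pop * 0.5)
  map_dn <- predict_trough(vanco_final_model, cov, reg, 6,
                           prior_obs = prior_lo)
  expect_lt(map_dn, pop)
})

test_that("bootstrap degenerates correctly and is seed-reproducible", {
  ev <- rich_cohort(n = 1, seed = 91, stdev0 = 1)
  m <- init_model()
  m$effects <- list()
  bt <- suppressWarnings(
    ppk_bootstrap(ev, m, n_reps = 3, seed = 7,
                  fix = c("tvV1", "tvV2", "tvQ", "omega_CL"))
  )
  # a single subject resampled is always the original dataset
  expect_equal(bt$converged, 3)
  expect_true(all(bt$summary$se < 1e-10 | is.na(bt$summary$se)))
  ev2 <- rich_cohort(n = 8, seed = 92, stdev0 = 1)
  b1 <- ppk_bootstrap(ev2, init_model(), n_reps = 4, seed = 11)
  b2 <- ppk_bootstrap(ev2, init_model(), n_reps = 4, seed = 11)
  expect_identical(b1$summary, b2$summary)
  b3 <- ppk_bootstrap(ev2, init_model(), n_reps = 4, seed = 12)
  expect_false(identical(b1$summary$median, b3$summary$median))
})

test_that("VPC percentiles collapse onto PRED without variability", {
  m <- vanco_final_model
  m$iiv <- c(CL = 0)
  m$residual$stdev0 <- 0
  # identical design across subjects and one sampling time per bin so
  # the degenerate (variability-free) bands are point masses at PRED
  reg <- dosing_regimen(45, 8, 6)
  times <- c(17, 26, 35, 39.5)
  ev <- purrr::map_dfr(1:5, function(i) {
    p <- list(V1 = 1.27, V2 = 2.422, CL = 0.42, Q = 1.161)
    dplyr::bind_rows(
      tibble::tibble(id = i, time = reg$time, evid = 1, amt = reg$amt,
                     dur = reg$dur, dv = NA_real_, bloq = FALSE),
      tibble::tibble(id = i, time = times, evid = 0, amt = NA_real_,
                     dur = NA_real_, dv = predict_conc(times, reg, p),
                     bloq = FALSE)
    ) |>
      dplyr::mutate(bbw = 3.22, pna = 29) |>
      dplyr::arrange(time, dplyr::desc(evid))
  })
  v <- suppressMessages(ppk_vpc(ev, m, n_sim = 5, bins = 4, seed = 1))
  expect_equal(v$bands$p5, v$bands$p50, tolerance = 1e-9)
  expect_equal(v$bands$p50, v$bands$p95, tolerance = 1e-9)
  # and the bands equal the population predictions, so coverage is 1
  expect_equal(v$coverage, 1)
  # percentile ordering is an invariant in general
  ev2 <- simulate_cohort(cohort_spec(n_subjects = 20), seed = 6)
  v2 <- suppressMessages(ppk_vpc(ev2, vanco_final_model, n_sim = 30,
                                 bins = 6, seed = 2))
  expect_true(all(v2$bands$p5 <= v2$bands$p50))
  expect_true(all(v2$bands$p50 <= v2$bands$p95))
  v2b <- suppressMessages(ppk_vpc(ev2, vanco_final_model, n_sim = 30,
                                  bins = 6, seed = 2))
  expect_identical(v2$bands, v2b$bands)
})

test_that("diagnostics table has one row per quantifiable observation", {
  ev <- simulate_cohort(cohort_spec(n_subjects = 25), seed = 16)
  fit <- suppressMessages(
    ppk_fit(ev, vanco_final_model,
            fix = c("tvV1", "tvV2", "tvCL", "tvQ", "dCLdbbw", "dCLdpna",
                    "omega_CL", "stdev0"), se = FALSE)
  )
  d <- diagnostics_table(fit)
  expect_equal(nrow(d), sum(ev$evid == 0 & !ev$bloq))
  expect_true(all(c("dv", "pred", "ipred", "cwres", "time") %in% names(d)))
  # observed-vs-individual-prediction regression slope near unity
  slope <- unname(stats::coef(stats::lm(d$dv ~ d$ipred))[2])
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("result objects plot without error", {
  ev <- rich_cohort(n = 6, seed = 17, stdev0 = 1)
  fit <- ppk_fit(ev, init_model(), fix = c("tvV2", "tvQ"), se = FALSE)
  expect_s3_class(autoplot(fit), "ggplot")
  v <- ppk_vpc(ev, vanco_final_model, n_sim = 10, bins = 3, seed = 3)
  expect_s3_class(autoplot(v), "ggplot")
})
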