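test_that("zero-IIV OFV reduces to the nonlinear least-squares deviance", {
  ev <- rich_cohort(n = 4, seed = 21, omega = 0, stdev0 = 1.5)
  m <- vanco_final_model
  m$iiv <- c(CL = 0)
  m$residual$stdev0 <- 1.5
  ofv <- ppk_ofv(ev, m)
  # closed-form Gaussian deviance at the typical-value prediction
  obs <- ev[ev$evid == 0, ]
  rss <- 0
  for (i in unique(ev$id)) {
    d <- ev[ev$id == i & ev$evid == 1, ]
    o <- ev[ev$id == i & ev$evid == 0, ]
    p <- list(V1 = 1.27, V2 = 2.422,
              CL = individual_param(m, "CL", as.list(o[1, ])), Q = 1.161)
    rss <- rss + sum((o$dv - predict_conc(o$time, d[, c("time", "amt", "dur")], p))^2)
  }
  n <- nrow(obs)
  expect_equal(ofv, n * log(2 * pi * 1.5^2) + rss / 1.5^2,
               tolerance = 1e-8)
})

test_that("FOCE matches exact Gauss-Hermite marginal likelihood", {
  # small omega: the linearization is near-exact
  ev <- rich_cohort(n = 6, seed = 22, omega = 0.02, stdev0 = 1)
  m <- vanco_final_model
  m$iiv <- c(CL = 0.02)
  m$residual$stdev0 <- 1
  # linearization error is O(omega^2); at omega = 0.02 it is < 0.01
  # OFV units on ~100
  expect_lt(abs(ppk_ofv(ev, m) - ofv_quadrature(ev, m)), 0.01)
  # realistic omega: still close, small approximation error allowed
  ev <- rich_cohort(n = 6, seed = 23, omega = 0.317, stdev0 = 1)
  m$iiv <- c(CL = 0.317)
  exact <- ofv_quadrature(ev, m)
  expect_lt(abs(ppk_ofv(ev, m) - exact), 0.5)
})

test_that("OFV is lower at the generating parameters than at perturbed ones", {
  hits <- 0
  for (s in 1:20) {
    ev <- simulate_cohort(cohort_spec(n_subjects = 316), seed = 100 + s)
    perturbed <- vanco_final_model
    perturbed$theta[["CL"]] <- 0.42 * 1.5
    o_true <- suppressMessages(ppk_ofv(ev, vanco_final_model))
    o_pert <- suppressMessages(ppk_ofv(ev, perturbed))
    if (o_true < o_pert) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("OFV is invariant to subject order and consistent time shifts", {
  ev <- simulate_cohort(cohort_spec(n_subjects = 20), seed = 31)
  o1 <- suppressMessages(ppk_ofv(ev, vanco_final_model))
  # reverse subject order
  ev_rev <- dplyr::arrange(ev, dplyr::desc(.data$id), .data$time,
                           dplyr::desc(.data$evid))
  expect_equal(suppressMessages(ppk_ofv(ev_rev, vanco_final_model)), o1,
               tolerance = 1e-10)
  # shift one subject's clock consistently (doses and observations)
  ev_shift <- dplyr::mutate(
    ev, time = .data$time + ifelse(.data$id == 3, 5, 0)
  )
  expect_equal(suppressMessages(ppk_ofv(ev_shift, vanco_final_model)), o1,
               tolerance = 1e-8)
})

test_that("empirical Bayes estimates behave across information regimes", {
  m <- vanco_final_model
  m$residual$stdev0 <- 1
  # rich single-subject data at known eta
  withr::local_seed(33)
  reg <- dosing_regimen(amt = 50, interval = 8, n = 4)
  tt <- c(1.5, 3, 5, 8, 11, 16, 20, 24, 27, 31)
  cl <- individual_param(m, "CL", list(bbw = 3.22, pna = 29), eta = 0.3)
  p <- list(V1 = 1.27, V2 = 2.422, CL = cl, Q = 1.161)
  dv <- predict_conc(tt, reg, p) + rnorm(length(tt))
  ev <- dplyr::bind_rows(
    tibble::tibble(id = 1L, time = reg$time, evid = 1, amt = reg$amt,
                   dur = reg$dur, dv = NA_real_, bloq = FALSE),
    tibble::tibble(id = 1L, time = tt, evid = 0, amt = NA_real_,
                   dur = NA_real_, dv = dv, bloq = FALSE)
  ) |>
    dplyr::mutate(bbw = 3.22, pna = 29) |>
    dplyr::arrange(time, dplyr::desc(evid))
  eb <- ppk_ebe(ev, m)
  expect_gt(eb$eta_CL, 0)
  expect_lt(eb$eta_CL, 0.6)
  # IPRED tracks the data to within the residual SD
  fit_det <- ppk_fit(ev, m, fix = c(
    "tvV1", "tvV2", "tvCL", "tvQ", "dCLdbbw", "dCLdpna", "omega_CL",
    "stdev0"
  ), se = FALSE)
  rmse <- sqrt(mean((augment(fit_det)$ipred - dv)^2))
  expect_lt(rmse, 1)
  # flat-prior limit: EBE converges to the least-squares eta
  m_flat <- m
  m_flat$iiv <- c(CL = 50)
  eb_flat <- ppk_ebe(ev, m_flat)
  ls_eta <- stats::optimize(function(e) {
    pp <- p
    pp$CL <- individual_param(m, "CL", list(bbw = 3.22, pna = 29), eta = e)
    sum((dv - predict_conc(tt, reg, pp))^2)
  }, c(-3, 3))$minimum
  expect_equal(eb_flat$eta_CL, ls_eta, tolerance = 1e-3)
  # no observations: prior mode zero
  doses_only <- ev[ev$evid == 1, ]
  eb0 <- ppk_ebe(doses_only, m)
  expect_equal(eb0$eta_CL, 0)
})

test_that("shrinkage is one at total shrinkage, zero at full spread, and
           increases as sampling thins", {
  expect_equal(eta_shrinkage(rep(0, 10), 0.3), 1)
  eta <- c(-0.3, 0.1, 0.25, -0.05, 0.4)
  expect_equal(eta_shrinkage(eta * (0.3 / sd(eta)), 0.3), 0,
               tolerance = 1e-12)
  # sparse sampling shows more shrinkage than rich sampling
  ev_rich <- rich_cohort(n = 30, seed = 41, stdev0 = 2.187)
  ev_sparse <- rich_cohort(n = 30, seed = 41, stdev0 = 2.187,
                           times = 15.5)
  m <- vanco_final_model
  sh_rich <- eta_shrinkage(ppk_ebe(ev_rich, m)$eta_CL, 0.317)
  sh_sparse <- eta_shrinkage(ppk_ebe(ev_sparse, m)$eta_CL, 0.317)
  expect_gt(sh_sparse, sh_rich)
})

test_that("conditional weighted residuals are calibrated and deterministic", {
  # no-IIV reduction: CWRES = (DV - PRED) / stdev0
  ev <- rich_cohort(n = 5, seed = 51, omega = 0, stdev0 = 2)
  m <- vanco_final_model
  m$iiv <- c(CL = 0)
  m$residual$stdev0 <- 2
  fit <- ppk_fit(ev, m, fix = c("tvV1", "tvV2", "tvCL", "tvQ",
                                "dCLdbbw", "dCLdpna", "omega_CL",
                                "stdev0"), se = FALSE)
  d <- augment(fit)
  expect_equal(d$cwres, (d$dv - d$pred) / 2, tolerance = 1e-8)
  expect_equal(d$pred, d$ipred, tolerance = 1e-8)
  # simulated from the evaluated model: approximately standard normal
  ev2 <- rich_cohort(n = 70, seed = 52, omega = 0.317, stdev0 = 2.187)
  fit2 <- ppk_fit(ev2, vanco_final_model,
                  fix = c("tvV1", "tvV2", "tvCL", "tvQ", "dCLdbbw",
                          "dCLdpna", "omega_CL", "stdev0"), se = FALSE)
  cw <- augment(fit2)$cwres
  expect_gte(length(cw), 400)
  expect_lt(abs(mean(cw)), 0.1)
  expect_gte(sd(cw), 0.85)
  expect_lte(sd(cw), 1.15)
  # bit-identical on repeat
  fit2b <- ppk_fit(ev2, vanco_final_model,
                   fix = c("tvV1", "tvV2", "tvCL", "tvQ", "dCLdbbw",
                           "dCLdpna", "omega_CL", "stdev0"), se = FALSE)
  expect_identical(cw, augment(fit2b)$cwres)
})

test_that("underidentified and degenerate datasets fail loudly", {
  one_obs <- tibble::tibble(
    id = 1L, time = c(0, 6), evid = c(1, 0), amt = c(40, NA),
    dur = c(1, NA), dv = c(NA, 8), bloq = FALSE, bbw = 3.2, pna = 20
  )
  expect_error(ppk_fit(one_obs, init_model()), "too small")
})

test_that("fitted omega collapses when the data carry no IIV", {
  ev <- rich_cohort(n = 25, seed = 61, omega = 0, stdev0 = 1)
  m <- init_model()
  m$theta <- c(V1 = 1.27, V2 = 2.422, CL = 0.42, Q = 1.161)
  fit <- ppk_fit(ev, m, fix = c("tvV1", "tvV2", "tvQ"), se = FALSE)
  expect_lte(tidy(fit)$estimate[tidy(fit)$term == "omega_CL"], 0.05)
})

test_that("adding a spurious covariate never worsens the optimized OFV", {
  ev <- simulate_cohort(cohort_spec(n_subjects = 50), seed = 71)
  withr::local_seed(72)
  ev <- ev |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(noise = round(exp(rnorm(1, 1, 0.3)), 3)) |>
    dplyr::ungroup()
  fit0 <- suppressMessages(ppk_fit(ev, init_model(), se = FALSE))
  m1 <- init_model()
  m1$effects <- c(m1$effects, list(
    cov_effect("CL", "noise", exponent = 0,
               ref = stats::median(ev$noise))
  ))
  fit1 <- suppressMessages(ppk_fit(ev, m1, se = FALSE))
  expect_lte(fit1$ofv, fit0$ofv + 0.1)
})

test_that("fit reports Wald intervals mirroring the estimate +/- 1.96 SE", {
  ev <- rich_cohort(n = 20, seed = 81, stdev0 = 1)
  m <- init_model()
  fit <- ppk_fit(ev, m, fix = c("tvV2", "tvQ"), se = TRUE)
  td <- tidy(fit)
  free <- td[!td$fixed, ]
  expect_true(all(is.finite(free$std.error)))
  expect_equal(free$conf.low, free$estimate - 1.96 * free$std.error)
  expect_equal(free$conf.high, free$estimate + 1.96 * free$std.error)
  g <- glance(fit)
  expect_true(g$convergence)
  expect_equal(g$n_obs, sum(ev$evid == 0))
})
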