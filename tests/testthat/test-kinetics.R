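test_that("disposition constants solve the characteristic quadratic", {
  sp <- structural_params(V1 = 1.27, V2 = 2.422, CL = 0.4487, Q = 1.161)
  # quadratic-root oracle from the micro constants
  k10 <- 0.4487 / 1.27
  k12 <- 1.161 / 1.27
  k21 <- 1.161 / 2.422
  roots <- sort(Re(polyroot(c(k10 * k21, -(k10 + k12 + k21), 1))),
                decreasing = TRUE)
  expect_equal(sp$alpha, roots[1], tolerance = 1e-10)
  expect_equal(sp$beta, roots[2], tolerance = 1e-10)
  expect_equal(round(sp$alpha, 3), 1.644)
  expect_equal(round(sp$beta, 3), 0.103)
})

test_that("disposition identities hold over random parameter sets", {
  withr::local_seed(4)
  for (i in 1:50) {
    V1 <- runif(1, 0.3, 5); V2 <- runif(1, 0.3, 8)
    CL <- runif(1, 0.05, 2); Q <- runif(1, 0.05, 3)
    sp <- structural_params(V1, V2, CL, Q)
    expect_gt(sp$alpha, sp$beta)
    expect_gt(sp$beta, 0)
    # Vieta: product and sum of the roots
    expect_equal(sp$alpha * sp$beta, (CL / V1) * (Q / V2),
                 tolerance = 1e-12)
    expect_equal(sp$alpha + sp$beta, sp$k10 + sp$k12 + sp$k21,
                 tolerance = 1e-12)
    # unit-bolus coefficients sum to 1/V1
    expect_equal(sp$A + sp$B, 1 / V1, tolerance = 1e-12)
  }
})

test_that("Q = 0 collapses to the one-compartment limit", {
  sp <- structural_params(V1 = 2, V2 = 3, CL = 0.5, Q = 0)
  expect_equal(sp$alpha, 0.25)
  expect_equal(sp$A, 0.5)
  # bolus-like (very short infusion): conc ~ (Dose/V1) exp(-k t)
  doses <- data.frame(time = 0, amt = 10, dur = 1e-5)
  tt <- c(1, 2, 5)
  expect_equal(
    predict_conc(tt, doses, list(V1 = 2, V2 = 0, CL = 0.5, Q = 0)),
    10 / 2 * exp(-0.25 * tt),
    tolerance = 1e-4
  )
})

test_that("concentration is a linear superposition of doses", {
  p <- list(V1 = 1.27, V2 = 2.422, CL = 0.42, Q = 1.161)
  reg <- dosing_regimen(amt = 48.3, interval = 8, n = 6)
  tt <- seq(0.5, 60, by = 2.5)
  total <- predict_conc(tt, reg, p)
  summed <- Reduce(`+`, lapply(seq_len(nrow(reg)), function(j) {
    predict_conc(tt, reg[j, ], p)
  }))
  expect_equal(total, summed, tolerance = 1e-10)
  # linearity in amounts
  reg2 <- dplyr::mutate(reg, amt = amt * 2)
  expect_equal(predict_conc(tt, reg2, p), 2 * total, tolerance = 1e-12)
  # no doses -> zero everywhere
  expect_equal(predict_conc(tt, reg[0, ], p), rep(0, length(tt)))
  expect_error(predict_conc(-1, reg, p), "non-negative")
})

test_that("profile rises during infusion and decays to zero afterwards", {
  p <- list(V1 = 1.27, V2 = 2.422, CL = 0.42, Q = 1.161)
  reg <- dosing_regimen(amt = 40, interval = 8, n = 1, dur = 2)
  during <- predict_conc(seq(0.1, 2, by = 0.1), reg, p)
  expect_true(all(diff(during) > 0))
  late <- predict_conc(c(50, 100, 300), reg, p)
  expect_true(all(diff(late) < 0))
  expect_lt(late[3], 1e-6)
})

test_that("closed form matches the two-compartment ODE solution", {
  skip_if_not_installed("deSolve")
  withr::local_seed(7)
  n_bad <- 0
  for (i in 1:100) {
    p <- list(V1 = runif(1, 0.5, 3), V2 = runif(1, 0.5, 6),
              CL = runif(1, 0.1, 1.5), Q = runif(1, 0.1, 2.5))
    nd <- sample(2:5, 1)
    doses <- data.frame(time = sort(runif(nd, 0, 30)),
                        amt = runif(nd, 10, 80),
                        dur = runif(nd, 0.5, 2.5))
    k10 <- p$CL / p$V1; k12 <- p$Q / p$V1; k21 <- p$Q / p$V2
    rate_fn <- function(t) {
      sum(ifelse(t >= doses$time & t < doses$time + doses$dur,
                 doses$amt / doses$dur, 0))
    }
    rhs <- function(t, A, parms) {
      list(c(rate_fn(t) - (k10 + k12) * A[1] + k21 * A[2],
             k12 * A[1] - k21 * A[2]))
    }
    tt <- sort(runif(6, 1, 45))
    out <- deSolve::ode(c(0, 0), c(0, tt), rhs, NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-11, hmax = 0.2)
    ode_conc <- out[-1, 2] / p$V1
    cf <- predict_conc(tt, doses, p)
    rel <- abs(cf - ode_conc) / pmax(abs(ode_conc), 1e-9)
    if (max(rel) > 1e-6) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("troughs accumulate geometrically toward steady state", {
  p <- list(V1 = 1.27, V2 = 2.422, CL = 0.42, Q = 1.161)
  tau <- 8
  troughs <- vapply(2:40, function(n) {
    reg <- dosing_regimen(amt = 40, interval = tau, n = n)
    predict_conc(reg$time[n], reg[seq_len(n - 1), ], p)
  }, 0)
  # monotone approach to the steady-state trough
  expect_true(all(diff(troughs) > 0))
  # geometric oracle: per-exponential accumulation factors
  sp <- structural_params(p$V1, p$V2, p$CL, p$Q)
  one <- function(lam, cf) { # single-dose trough contribution at t = tau
    r <- 40 / 1
    r * cf / lam * (1 - exp(-lam * 1)) * exp(-lam * (tau - 1))
  }
  ss_oracle <- one(sp$alpha, sp$A) / (1 - exp(-sp$alpha * tau)) +
    one(sp$beta, sp$B) / (1 - exp(-sp$beta * tau))
  expect_equal(troughs[length(troughs)], ss_oracle, tolerance = 1e-4)
})
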