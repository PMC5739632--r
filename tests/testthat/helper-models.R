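# shared fixtures, all generated in code

# neutral starting values for refitting the final-model structure
init_model <- function() {
  pop_model(
    theta = c(V1 = 2, V2 = 2, CL = 0.5, Q = 1),
    effects = list(
      cov_effect("CL", "bbw", exponent = 0, ref = 3.22),
      cov_effect("CL", "pna", exponent = 0, ref = 29)
    ),
    iiv = c(CL = 0.3),
    residual = residual_error("additive", stdev0 = 2)
  )
}

# base structural model (no covariates), used by stepwise tests
base_model <- function() {
  pop_model(
    theta = c(V1 = 2, V2 = 2, CL = 0.5, Q = 1),
    iiv = c(CL = 0.3),
    residual = residual_error("additive", stdev0 = 2)
  )
}

# a small rich-design cohort: every subject sampled densely so the
# engine tests separate IIV from residual noise cleanly
rich_cohort <- function(n = 12, seed = 1, omega = 0.317, stdev0 = 1,
                        times = c(1.5, 3, 6, 8, 12, 15.5)) {
  model <- vanco_final_model
  model$iiv <- c(CL = omega)
  model$residual$stdev0 <- stdev0
  withr::local_seed(seed)
  purrr::map_dfr(seq_len(n), function(i) {
    bbw <- runif(1, 2, 4.5)
    pna <- round(runif(1, 5, 60))
    reg <- dosing_regimen(amt = 15 * bbw, interval = 8, n = 3)
    cl <- individual_param(model, "CL", list(bbw = bbw, pna = pna),
                           eta = rnorm(1, 0, omega))
    p <- list(V1 = model$theta[["V1"]], V2 = model$theta[["V2"]],
              CL = cl, Q = model$theta[["Q"]])
    dv <- predict_conc(times, reg, p) + rnorm(length(times), 0, stdev0)
    dplyr::bind_rows(
      tibble::tibble(id = i, time = reg$time, evid = 1, amt = reg$amt,
                     dur = reg$dur, dv = NA_real_, bloq = FALSE),
      tibble::tibble(id = i, time = times, evid = 0, amt = NA_real_,
                     dur = NA_real_, dv = pmax(dv, 0.01), bloq = FALSE)
    ) |>
      dplyr::mutate(bbw = bbw, pna = pna) |>
      dplyr::arrange(time, dplyr::desc(evid))
  })
}

# exact marginal -2 log-likelihood by Gauss-Hermite quadrature over a
# single scalar eta on CL; independent oracle for the FOCE objective
ofv_quadrature <- function(data, model, n_nodes = 60) {
  i_seq <- 1:(n_nodes - 1)
  a <- sqrt(i_seq / 2)
  J <- matrix(0, n_nodes, n_nodes)
  J[cbind(i_seq, i_seq + 1)] <- a
  J[cbind(i_seq + 1, i_seq)] <- a
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- (e$vectors[1, ])^2 # normalized: sum = 1 after /sqrt(pi)*sqrt(pi)
  omega <- as.numeric(model$iiv[["CL"]])
  stdev0 <- model$residual$stdev0
  total <- 0
  for (i in unique(data$id)) {
    d <- data[data$id == i & data$evid == 1, ]
    o <- data[data$id == i & data$evid == 0 & !data$bloq, ]
    dur <- ifelse(is.na(d$dur), model$infusion_default, d$dur)
    cv <- as.list(data[data$id == i, ][1, ])
    lik <- 0
    for (k in seq_len(n_nodes)) {
      eta <- sqrt(2) * omega * nodes[k]
      p <- list(
        V1 = individual_param(model, "V1", cv),
        V2 = individual_param(model, "V2", cv),
        CL = individual_param(model, "CL", cv, eta = eta),
        Q = individual_param(model, "Q", cv)
      )
      f <- predict_conc(o$time, data.frame(time = d$time, amt = d$amt,
                                           dur = dur), p)
      lik <- lik + weights[k] * prod(stats::dnorm(o$dv, f, stdev0))
    }
    total <- total - 2 * log(lik)
  }
  total
}
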