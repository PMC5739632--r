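#' Wald 95% confidence interval
#'
#' `estimate +/- 1.96 * se`, the interval convention used for the
#' parameter tables of this package.
#'
#' @param estimate Point estimate(s).
#' @param se Standard error(s), >= 0.
#' @return Tibble with `conf.low`, `conf.high`.
#' @examples
#' wald_ci(0.317, 0.015) # (0.288, 0.346)
#' @export
wald_ci <- function(estimate, se) {
  if (any(se < 0, na.rm = TRUE)) stop("`se` must be >= 0", call. = FALSE)
  tibble::tibble(conf.low = estimate - 1.96 * se,
                 conf.high = estimate + 1.96 * se)
}

#' Non-parametric bootstrap of a PopPK fit
#'
#' Resamples subjects (the exchangeable unit of hierarchical TDM data)
#' with replacement, refits each resampled dataset starting from the
#' original estimates, and summarizes the converged replicates:
#' per-parameter median, SE (SD across replicates), the percentile 95%
#' CI and the Wald-form median +/- 1.96 SE CI. Deterministic given the
#' seed; non-converging replicates are excluded and counted.
#'
#' @param data Event table.
#' @param model A [pop_model()]; initial values for each refit
#'   (typically the original fit's `$model`).
#' @param n_reps Number of bootstrap datasets (the reference workflow
#'   uses 2000; scale down for quick checks).
#' @param seed Integer seed.
#' @param interaction Passed to [ppk_fit()].
#' @param ... Further arguments (e.g. `fix`) passed to [ppk_fit()].
#' @return Object of class `ppk_boot`: `replicates` (per-replicate
#'   estimates), `summary` tibble, counts `attempted` / `converged`.
#' @export
ppk_bootstrap <- function(data, model, n_reps = 2000, seed = 1,
                          interaction = TRUE, ...) {
  stopifnot(n_reps >= 1)
  data <- validate_events(data)
  ids <- unique(data$id)
  by_id <- split(data, data$id)
  withr::local_seed(seed)
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    take <- sample(as.character(ids), length(ids), replace = TRUE)
    boot <- purrr::imap_dfr(take, function(old, new) {
      d <- by_id[[old]]
      d$id <- new
      d
    })
    fit <- tryCatch(
      ppk_fit(boot, model, se = FALSE, interaction = interaction, ...),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$convergence) {
      return(tibble::tibble(replicate = r, converged = FALSE,
                            term = NA_character_, estimate = NA_real_))
    }
    dplyr::transmute(tidy(fit), replicate = r, converged = TRUE,
                     .data$term, .data$estimate)
  })
  good <- reps |> dplyr::filter(.data$converged)
  summary <- good |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      median = stats::median(.data$estimate),
      se = stats::sd(.data$estimate),
      pct.low = unname(quantile(.data$estimate, 0.025)),
      pct.high = unname(quantile(.data$estimate, 0.975)),
      .groups = "drop"
    ) |>
    dplyr::mutate(wald.low = .data$median - 1.96 * .data$se,
                  wald.high = .data$median + 1.96 * .data$se)
  structure(
    list(replicates = reps, summary = summary,
         attempted = n_reps,
         converged = length(unique(good$replicate)), seed = seed),
    class = "ppk_boot"
  )
}

#' @method tidy ppk_boot
#' @export
tidy.ppk_boot <- function(x, ...) {
  x$summary
}

#' @export
print.ppk_boot <- function(x, ...) {
  cat(sprintf("<ppk_boot> %d/%d replicates converged (seed %d)\n",
              x$converged, x$attempted, x$seed))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates the study design (each subject's doses, covariates and
#' sampling times) `n_sim` times from the model with fresh
#' inter-individual and residual variability, then summarizes the
#' simulated concentrations per time bin (5th/50th/95th percentiles)
#' against the observations. Bins are quantile-based on time after the
#' most recent dose. Also reports the fraction of observations inside
#' the simulated 5th-95th band (binwise interpolated).
#'
#' @param data Event table defining the design and the observations.
#' @param model Generating [pop_model()] (typically a fitted model).
#' @param n_sim Number of simulated replicates of the design (the
#'   reference workflow simulates 1000 patients).
#' @param bins Number of quantile bins (default 8).
#' @param seed Integer seed.
#' @return Object of class `ppk_vpc`: `bands` (per-bin percentiles),
#'   `observed` (points with bin and in-band flag), `coverage`.
#' @export
ppk_vpc <- function(data, model, n_sim = 1000, bins = 8, seed = 1) {
  stopifnot(n_sim >= 1, bins >= 1)
  data <- validate_events(data)
  prep <- .prep_subjects(data, model)
  tp <- .typical_matrix(model, prep$covs)
  iiv_names <- names(model$iiv)
  q <- length(iiv_names)
  withr::local_seed(seed)

  # time after most recent dose for the observed points
  tad <- function(s) {
    vapply(s$t, function(t) t - max(s$dt[s$dt <= t]), 0)
  }
  obs <- purrr::map2_dfr(seq_along(prep$ids), prep$subjects, function(i, s) {
    tibble::tibble(id = prep$ids[i], time = s$t, tad = tad(s), dv = s$y)
  })

  sims <- purrr::map_dfr(seq_len(n_sim), function(r) {
    purrr::map2_dfr(seq_along(prep$ids), prep$subjects, function(i, s) {
      eta <- setNames(rnorm(q) * as.numeric(model$iiv), iiv_names)
      p <- as.list(tp[i, ])
      names(p) <- c("V1", "V2", "CL", "Q")
      for (nm in iiv_names) p[[nm]] <- p[[nm]] * exp(eta[[nm]])
      cpred <- as.numeric(conc_cpp(s$t, s$dt, s$da, s$dd,
                                   p$V1, p$V2, p$CL, p$Q))
      eps <- if (model$residual$type == "combined") {
        matrix(rnorm(2 * length(s$t)), ncol = 2)
      } else {
        rnorm(length(s$t))
      }
      tibble::tibble(time = s$t, tad = tad(s),
                     sim = apply_residual(cpred, model$residual, eps))
    })
  })

  brk <- unique(quantile(obs$tad, probs = seq(0, 1, length.out = bins + 1)))
  if (length(brk) < 2) brk <- c(min(obs$tad) - 1e-9, max(obs$tad) + 1e-9)
  brk[1] <- -Inf
  brk[length(brk)] <- Inf
  cut_bin <- function(x) cut(x, breaks = brk, labels = FALSE)
  sims$bin <- cut_bin(sims$tad)
  obs$bin <- cut_bin(obs$tad)
  bands <- sims |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      tad_mid = stats::median(.data$tad),
      p5 = unname(quantile(.data$sim, 0.05)),
      p50 = unname(quantile(.data$sim, 0.50)),
      p95 = unname(quantile(.data$sim, 0.95)),
      .groups = "drop"
    )
  obs <- obs |>
    dplyr::left_join(bands, by = "bin") |>
    dplyr::mutate(in_band = .data$dv >= .data$p5 & .data$dv <= .data$p95)
  structure(
    list(bands = bands, observed = obs,
         coverage = mean(obs$in_band), n_sim = n_sim, seed = seed),
    class = "ppk_vpc"
  )
}

#' @method tidy ppk_vpc
#' @export
tidy.ppk_vpc <- function(x, ...) {
  x$bands
}

#' @export
print.ppk_vpc <- function(x, ...) {
  cat(sprintf(
    "<ppk_vpc> %d simulated replicates; %.1f%% of observations in the 5th-95th band\n",
    x$n_sim, 100 * x$coverage))
  print(x$bands)
  invisible(x)
}

#' @rdname ppk_vpc
#' @param object A `ppk_vpc`.
#' @param ... Unused.
#' @method autoplot ppk_vpc
#' @export
autoplot.ppk_vpc <- function(object, ...) {
  ggplot2::ggplot(object$bands, ggplot2::aes(x = .data$tad_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50), colour = "steelblue") +
    ggplot2::geom_point(
      data = object$observed,
      ggplot2::aes(x = .data$tad, y = .data$dv), alpha = 0.5
    ) +
    ggplot2::labs(x = "time after most recent dose (h)",
                  y = "concentration (ug/mL)")
}

#' External-validation prediction-error metrics
#'
#' Mean prediction error \eqn{MPE = \frac1n\sum(c_{pred}-c_{obs})},
#' mean absolute error \eqn{MAE = \frac1n\sum|c_{pred}-c_{obs}|} and
#' mean squared error \eqn{MSPE = \frac1n\sum(c_{obs}-c_{pred})^2},
#' each with the SD of its elementwise terms. `MAE >= |MPE|` and
#' `MSPE >= MPE^2` always hold.
#'
#' @param data Optional data frame holding the prediction and
#'   observation columns; if omitted, pass bare vectors.
#' @param pred,obs Columns (unquoted, when `data` is given) or numeric
#'   vectors of predicted and observed concentrations (ug/mL).
#' @return One-row tibble: `mpe`, `mae`, `mspe` with `sd_pe`, `sd_ae`,
#'   `sd_spe` and `n`.
#' @examples
#' external_metrics(pred = c(3.79, 8.73), obs = c(4.26, 9.03))
#' @export
external_metrics <- function(data = NULL, pred, obs) {
  if (!is.null(data)) {
    pred <- rlang::eval_tidy(rlang::enquo(pred), data)
    obs <- rlang::eval_tidy(rlang::enquo(obs), data)
  }
  if (length(pred) != length(obs) || length(pred) == 0) {
    stop("`pred` and `obs` must have equal, non-zero length",
         call. = FALSE)
  }
  pe <- pred - obs
  tibble::tibble(
    n = length(pe),
    mpe = mean(pe), sd_pe = stats::sd(pe),
    mae = mean(abs(pe)), sd_ae = stats::sd(abs(pe)),
    mspe = mean(pe^2), sd_spe = stats::sd(pe^2)
  )
}

#' Relative prediction error of a single case
#'
#' \eqn{100 \cdot |c_{pred} - c_{obs}| / c_{obs}}, the percent error
#' used to judge individual trough predictions.
#'
#' @param pred Predicted concentration (ug/mL).
#' @param obs Observed concentration (ug/mL), > 0.
#' @return Percent error.
#' @examples
#' case_prediction_error(3.79, 4.26) # 11.0
#' @export
case_prediction_error <- function(pred, obs) {
  if (any(obs <= 0)) stop("`obs` must be positive", call. = FALSE)
  100 * abs(pred - obs) / obs
}

#' Predict a (steady-state) trough concentration for a patient
#'
#' Evaluates the model concentration immediately before the indexed
#' dose of a regimen. Without prior observations this is the
#' population prediction (\eqn{\eta = 0}) given the patient's
#' covariates; with prior concentrations it is the MAP (empirical
#' Bayes) individual prediction conditioned on them.
#'
#' @param model A [pop_model()] with fixed estimates.
#' @param covariates Named list of the patient's covariates (e.g.
#'   `list(bbw = 3.9, pna = 23)`).
#' @param regimen Dose-event data frame (`time`, `amt`, `dur`), e.g.
#'   from [dosing_regimen()]; doses at and after the trough time are
#'   ignored.
#' @param at_dose_index Trough is taken immediately before this dose
#'   number (>= 2).
#' @param prior_obs Optional data frame of prior concentrations
#'   (`time`, `dv`) to condition on.
#' @return Predicted trough concentration (ug/mL).
#' @examples
#' predict_trough(vanco_final_model, list(bbw = 3.9, pna = 23),
#'                dosing_regimen(35, 8, 6), at_dose_index = 6)
#' @export
predict_trough <- function(model, covariates, regimen, at_dose_index,
                           prior_obs = NULL) {
  stopifnot(inherits(model, "pop_model"))
  if (at_dose_index < 2) {
    stop("`at_dose_index` must be >= 2 (trough before a later dose)",
         call. = FALSE)
  }
  regimen <- tibble::as_tibble(regimen)
  if (nrow(regimen) < at_dose_index) {
    stop("regimen has fewer than `at_dose_index` doses", call. = FALSE)
  }
  t_trough <- regimen$time[at_dose_index]
  prior_doses <- regimen[regimen$time < t_trough, ]
  eta <- setNames(rep(0, length(model$iiv)), names(model$iiv))
  if (!is.null(prior_obs) && nrow(prior_obs) > 0) {
    ev <- dplyr::bind_rows(
      tibble::tibble(id = 1L, time = prior_doses$time, evid = 1,
                     amt = prior_doses$amt,
                     dur = prior_doses$dur %||% model$infusion_default,
                     dv = NA_real_, bloq = FALSE),
      tibble::tibble(id = 1L, time = prior_obs$time, evid = 0,
                     amt = NA_real_, dur = NA_real_,
                     dv = prior_obs$dv, bloq = FALSE)
    ) |>
      dplyr::arrange(.data$time, dplyr::desc(.data$evid)) |>
      dplyr::bind_cols(tibble::as_tibble(covariates))
    eb <- ppk_ebe(ev, model)
    for (nm in names(model$iiv)) {
      eta[[nm]] <- eb[[paste0("eta_", nm)]][1]
    }
  }
  pars <- lapply(c("V1", "V2", "CL", "Q"), function(p) {
    if (!p %in% names(model$theta)) return(0)
    individual_param(model, p, covariates,
                     eta = if (p %in% names(eta)) eta[[p]] else 0)
  })
  names(pars) <- c("V1", "V2", "CL", "Q")
  predict_conc(t_trough, prior_doses, pars,
               infusion_default = model$infusion_default)
}
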