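
# ---- internal plumbing -----------------------------------------------------

# Column order of the typical-parameter matrix handed to the C++ engine.
.struct_cols <- c(V1 = 1L, V2 = 2L, CL = 3L, Q = 4L)

# Split an event table into the per-subject structure the C++ engine
# consumes. BQL observations are excluded from the likelihood (M1).
.prep_subjects <- function(data, model) {
  data <- validate_events(data)
  ids <- unique(data$id)
  cov_names <- unique(vapply(model$effects, function(e) e$covariate, ""))
  covs <- data |>
    dplyr::group_by(.data$id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  missing_cov <- setdiff(cov_names, names(covs))
  if (length(missing_cov)) {
    stop("covariate(s) required by the model are missing from the data: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  fid <- factor(data$id, levels = ids)
  is_dose <- data$evid == 1
  is_obs <- data$evid == 0 & !data$bloq
  dose_idx <- split(which(is_dose), fid[is_dose])
  obs_idx <- split(which(is_obs), fid[is_obs])
  subjects <- lapply(as.character(ids), function(key) {
    d <- dose_idx[[key]]
    o <- obs_idx[[key]]
    dur <- data$dur[d]
    dur[is.na(dur)] <- model$infusion_default
    list(dt = as.numeric(data$time[d]), da = as.numeric(data$amt[d]),
         dd = as.numeric(dur), t = as.numeric(data$time[o]),
         y = as.numeric(data$dv[o]))
  })
  n_obs <- vapply(subjects, function(s) length(s$t), integer(1))
  if (all(n_obs == 0)) {
    stop("no subject has a quantifiable observation", call. = FALSE)
  }
  if (any(n_obs == 0)) {
    # all-BQL subjects carry no likelihood information under M1
    message(sum(n_obs == 0),
            " subject(s) without quantifiable observations dropped")
    keep <- n_obs > 0
    subjects <- subjects[keep]
    ids <- ids[keep]
    n_obs <- n_obs[keep]
  }
  list(subjects = subjects, covs = covs[match(ids, covs$id), ],
       ids = ids, n_obs = n_obs)
}

# n_subjects x 4 matrix of individual typical parameters (eta = 0):
# typical values with all covariate effects applied.
.typical_matrix <- function(model, covs) {
  n <- nrow(covs)
  tp <- matrix(0, n, 4)
  for (p in names(model$theta)) {
    tp[, .struct_cols[[p]]] <- model$theta[[p]]
  }
  for (e in model$effects) {
    v <- covs[[e$covariate]]
    if (is.null(v) || anyNA(v)) {
      stop("covariate `", e$covariate, "` required by the model is missing",
           call. = FALSE)
    }
    j <- .struct_cols[[e$param]]
    if (e$type == "power") {
      if (any(v <= 0)) {
        stop("covariate `", e$covariate, "` must be positive", call. = FALSE)
      }
      tp[, j] <- tp[, j] * (v / e$ref)^e$exponent
    } else {
      tp[, j] <- tp[, j] * exp(e$exponent * v)
    }
  }
  tp
}

.eta_cols0 <- function(model) {
  as.integer(.struct_cols[names(model$iiv)] - 1L)
}

.res_code <- function(residual) {
  match(residual$type, c("additive", "proportional", "combined")) - 1L
}

.foce_eval <- function(model, prep, interaction = TRUE, detail = FALSE,
                       eta_start = NULL) {
  n <- length(prep$subjects)
  q <- length(model$iiv)
  if (is.null(eta_start)) {
    eta_start <- matrix(0, n, max(q, 1))
  }
  foce_eval_cpp(prep$subjects, .typical_matrix(model, prep$covs),
                if (q > 0) .eta_cols0(model) else integer(0),
                as.numeric(model$iiv), .res_code(model$residual),
                model$residual$stdev0, model$residual$cv,
                interaction, detail, eta_start)
}

# ---- parameter packing -----------------------------------------------------

# The estimation vector is transformed: log scale for positive
# parameters (typical values, omega, residual SDs), identity for
# covariate-effect exponents/coefficients.
.build_terms <- function(model) {
  terms <- tibble::tibble(
    term = paste0("tv", names(model$theta)),
    kind = "theta", param = names(model$theta),
    covariate = NA_character_, transform = "log",
    value = as.numeric(model$theta)
  )
  if (length(model$effects)) {
    terms <- dplyr::bind_rows(terms, tibble::tibble(
      term = vapply(model$effects,
                    function(e) paste0("d", e$param, "d", e$covariate), ""),
      kind = "effect",
      param = vapply(model$effects, function(e) e$param, ""),
      covariate = vapply(model$effects, function(e) e$covariate, ""),
      transform = "identity",
      value = vapply(model$effects, function(e) e$exponent, 0)
    ))
  }
  if (length(model$iiv)) {
    terms <- dplyr::bind_rows(terms, tibble::tibble(
      term = paste0("omega_", names(model$iiv)),
      kind = "omega", param = names(model$iiv),
      covariate = NA_character_, transform = "log",
      value = as.numeric(model$iiv)
    ))
  }
  r <- model$residual
  if (r$type %in% c("additive", "combined")) {
    terms <- dplyr::bind_rows(terms, tibble::tibble(
      term = "stdev0", kind = "sigma_add", param = NA_character_,
      covariate = NA_character_, transform = "log",
      value = r$stdev0
    ))
  }
  if (r$type %in% c("proportional", "combined")) {
    terms <- dplyr::bind_rows(terms, tibble::tibble(
      term = "cv", kind = "sigma_cv", param = NA_character_,
      covariate = NA_character_, transform = "log",
      value = r$cv
    ))
  }
  terms
}

# starting values for log-scale parameters are floored away from zero
# (a zero init would be -Inf on the optimization scale); fixed terms
# keep their exact value.
.pack <- function(values, transform) {
  ifelse(transform == "log", log(pmax(values, 1e-3)), values)
}

.unpack_model <- function(par, terms, model) {
  est <- terms$value
  est[!terms$fixed] <- ifelse(terms$transform[!terms$fixed] == "log",
                              exp(par), par)
  for (i in seq_len(nrow(terms))) {
    k <- terms$kind[i]
    if (k == "theta") {
      model$theta[[terms$param[i]]] <- est[i]
    } else if (k == "effect") {
      for (j in seq_along(model$effects)) {
        e <- model$effects[[j]]
        if (e$param == terms$param[i] && e$covariate == terms$covariate[i]) {
          model$effects[[j]]$exponent <- est[i]
        }
      }
    } else if (k == "omega") {
      model$iiv[[terms$param[i]]] <- est[i]
    } else if (k == "sigma_add") {
      model$residual$stdev0 <- est[i]
    } else if (k == "sigma_cv") {
      model$residual$cv <- est[i]
    }
  }
  model
}

# central finite-difference Hessian on the transformed scale
.fd_hessian <- function(fn, x, step = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- step
    fp <- fn(x + ei); fm <- fn(x - ei)
    H[i, i] <- (fp - 2 * f0 + fm) / step^2
    if (i < p) {
      for (j in seq(i + 1, p)) {
        ej <- rep(0, p); ej[j] <- step
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * step^2)
      }
    }
  }
  H
}

# ---- exported engine surface ----------------------------------------------

#' Objective function value (-2 log-likelihood) of a model on a dataset
#'
#' FOCE approximation of minus twice the marginal log-likelihood:
#' for each subject the conditional mode \eqn{\hat\eta} is found by
#' Newton iteration and the marginal integral is evaluated on the
#' first-order expansion around it (with interaction, the residual
#' variance is evaluated at the individual prediction). Deterministic
#' given data and parameters. Observations flagged below the LLOQ are
#' excluded (M1).
#'
#' @param data Event table (see [event-tables]).
#' @param model A [pop_model()] supplying all parameter values.
#' @param interaction Evaluate residual variance at the conditional
#'   (rather than population) prediction; default `TRUE`.
#' @return The OFV (scalar), including the \eqn{n \log 2\pi} constant.
#' @export
ppk_ofv <- function(data, model, interaction = TRUE) {
  prep <- .prep_subjects(data, model)
  res <- .foce_eval(model, prep, interaction = interaction)
  res$ofv
}

#' Fit a population pharmacokinetic model by FOCE
#'
#' Maximum-likelihood estimation of all parameters carried by `model`
#' (typical values, covariate-effect exponents, IIV standard
#' deviations, residual-error parameters) on an event table, using a
#' quasi-Newton outer optimization on transformed parameters (log for
#' positive parameters) around the FOCE objective of [ppk_ofv()].
#' Standard errors come from the inverse central-finite-difference
#' Hessian; empirical Bayes estimates, shrinkage and conditional
#' weighted residuals are computed at the optimum.
#'
#' @param data Event table (see [event-tables]).
#' @param model A [pop_model()] whose parameter values serve as
#'   initial estimates.
#' @param fix Character vector of term names (as in the fit's `tidy()`
#'   output, e.g. `"tvQ"`, `"omega_CL"`) held fixed at their initial
#'   values.
#' @param interaction FOCE with interaction (default `TRUE`).
#' @param se Compute standard errors from the numerical Hessian
#'   (default `TRUE`); on failure SEs are reported missing and the fit
#'   remains usable.
#' @param control List: `iter_max` (default 500) and `rel_tol`
#'   (relative OFV change, default 1e-6) for the outer optimizer.
#' @return An object of class `ppk_fit`; see [tidy.ppk_fit()],
#'   [glance.ppk_fit()], [augment.ppk_fit()].
#' @examples
#' \donttest{
#' ev <- simulate_cohort(cohort_spec(n_subjects = 40), seed = 7)
#' fit <- ppk_fit(ev, vanco_final_model)
#' tidy(fit)
#' }
#' @export
ppk_fit <- function(data, model, fix = character(), interaction = TRUE,
                    se = TRUE, control = list()) {
  ctrl <- utils::modifyList(list(iter_max = 500, rel_tol = 1e-6), control)
  prep <- .prep_subjects(data, model)
  terms <- .build_terms(model)
  bad_fix <- setdiff(fix, terms$term)
  if (length(bad_fix)) {
    stop("unknown term(s) in `fix`: ", paste(bad_fix, collapse = ", "),
         call. = FALSE)
  }
  terms$fixed <- terms$term %in% fix
  free <- !terms$fixed
  n_fixed_eff <- sum(terms$kind %in% c("theta", "effect") & free)
  if (sum(prep$n_obs) < sum(free) ||
      length(unique(unlist(lapply(prep$subjects, `[[`, "t")))) < n_fixed_eff) {
    stop("dataset is too small to identify the requested parameters (",
         sum(prep$n_obs), " observations for ", sum(free), " parameters)",
         call. = FALSE)
  }

  eta_cache <- new.env(parent = emptyenv())
  eta_cache$m <- matrix(0, length(prep$subjects), max(length(model$iiv), 1))
  n_eval <- 0L
  objective <- function(par) {
    n_eval <<- n_eval + 1L
    m <- .unpack_model(par, terms, model)
    res <- tryCatch(
      .foce_eval(m, prep, interaction = interaction, detail = FALSE,
                 eta_start = eta_cache$m),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    res$ofv
  }

  start <- .pack(terms$value[free], terms$transform[free])
  opt <- if (length(start) == 0) {
    # all parameters fixed: evaluation-only "fit" (EBE / diagnostics)
    list(par = numeric(0), convergence = 0L, iterations = 0L,
         message = "all parameters fixed")
  } else {
    stats::nlminb(start, objective,
                  control = list(iter.max = ctrl$iter_max,
                                 eval.max = 20 * ctrl$iter_max,
                                 rel.tol = ctrl$rel_tol))
  }
  fitted_model <- .unpack_model(opt$par, terms, model)
  detail <- .foce_eval(fitted_model, prep, interaction = interaction,
                       detail = TRUE)

  terms$estimate <- terms$value
  terms$estimate[free] <- ifelse(terms$transform[free] == "log",
                                 exp(opt$par), opt$par)
  terms$std.error <- NA_real_
  vcov_t <- NULL
  if (se && length(opt$par)) {
    H <- tryCatch(.fd_hessian(objective, opt$par, step = 1e-4),
                  error = function(e) NULL)
    vcov_t <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vcov_t) && all(is.finite(diag(vcov_t))) &&
        all(diag(vcov_t) >= 0)) {
      se_t <- sqrt(diag(vcov_t))
      terms$std.error[free] <- ifelse(terms$transform[free] == "log",
                                      terms$estimate[free] * se_t, se_t)
    } else {
      vcov_t <- NULL
      warning("Hessian could not be inverted; standard errors unavailable",
              call. = FALSE)
    }
  }

  q <- length(model$iiv)
  eta <- tibble::as_tibble(
    setNames(as.data.frame(detail$eta[, seq_len(max(q, 1)), drop = FALSE]),
             if (q > 0) paste0("eta_", names(model$iiv)) else "eta")
  )
  if (q == 0) eta <- eta[, 0]
  eta <- dplyr::bind_cols(tibble::tibble(id = prep$ids), eta)

  shrink <- if (q > 0) {
    setNames(vapply(seq_len(q), function(k) {
      eta_shrinkage(detail$eta[, k], fitted_model$iiv[[k]])
    }, 0), names(model$iiv))
  } else {
    numeric()
  }

  pred_tbl <- purrr::map2_dfr(seq_along(prep$ids), prep$subjects,
    function(i, s) {
      tibble::tibble(id = prep$ids[i], time = s$t, dv = s$y,
                     pred = as.numeric(detail$pred[[i]]),
                     ipred = as.numeric(detail$ipred[[i]]),
                     cwres = as.numeric(detail$cwres[[i]]))
    })

  structure(
    list(model = fitted_model, model_init = model, terms = terms,
         ofv = detail$ofv, eta = eta, shrinkage = shrink,
         pred = pred_tbl, convergence = opt$convergence == 0,
         message = opt$message, iterations = opt$iterations,
         n_eval = n_eval, vcov_trans = vcov_t,
         n_subjects = length(prep$ids), n_obs = sum(prep$n_obs),
         interaction = interaction, data = data),
    class = "ppk_fit"
  )
}

#' Empirical Bayes estimates of the random effects
#'
#' Conditional (MAP) modes \eqn{\hat\eta} of each subject's random
#' effects under a given model — the inner problem of FOCE, also used
#' for individualized trough prediction. A subject with no quantifiable
#' observations gets the prior mode 0.
#'
#' @param data Event table.
#' @param model A [pop_model()] with fixed parameter values.
#' @param interaction Residual variance at the conditional prediction.
#' @return Tibble with `id` and one `eta_<param>` column per random
#'   effect.
#' @export
ppk_ebe <- function(data, model, interaction = TRUE) {
  data <- validate_events(data)
  if (length(model$iiv) == 0) {
    return(tibble::tibble(id = unique(data$id)))
  }
  obs_ids <- unique(data$id[data$evid == 0 & !data$bloq])
  no_obs <- setdiff(unique(data$id), obs_ids)
  with_obs <- data[data$id %in% obs_ids, ]
  q <- length(model$iiv)
  out <- if (nrow(with_obs) > 0) {
    prep <- .prep_subjects(with_obs, model)
    detail <- .foce_eval(model, prep, interaction = interaction,
                         detail = TRUE)
    dplyr::bind_cols(
      tibble::tibble(id = prep$ids),
      tibble::as_tibble(setNames(
        as.data.frame(detail$eta[, seq_len(max(q, 1)), drop = FALSE]),
        paste0("eta_", names(model$iiv))
      ))
    )
  } else {
    NULL
  }
  if (length(no_obs)) {
    zero <- dplyr::bind_cols(
      tibble::tibble(id = no_obs),
      tibble::as_tibble(setNames(
        as.data.frame(matrix(0, length(no_obs), q)),
        paste0("eta_", names(model$iiv))
      ))
    )
    out <- dplyr::bind_rows(out, zero)
  }
  dplyr::arrange(out, match(.data$id, unique(data$id)))
}

#' Eta shrinkage
#'
#' \eqn{1 - SD(\hat\eta)/\omega} over subjects: near 1 when the data
#' carry little information on a random effect (all EBEs shrunk to the
#' prior mode), near 0 when the EBE spread matches the population
#' variability.
#'
#' @param eta_hat Vector of empirical Bayes estimates.
#' @param omega Population SD of the random effect.
#' @return Shrinkage fraction.
#' @export
eta_shrinkage <- function(eta_hat, omega) {
  if (omega <= 0) return(NA_real_)
  1 - stats::sd(eta_hat) / omega
}

# ---- methods ---------------------------------------------------------------

#' Tidy a PopPK fit
#'
#' @param x A `ppk_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` (Wald 95% intervals, estimate +/- 1.96 SE).
#' @method tidy ppk_fit
#' @export
tidy.ppk_fit <- function(x, ...) {
  x$terms |>
    dplyr::transmute(
      .data$term, .data$estimate, .data$std.error,
      conf.low = .data$estimate - 1.96 * .data$std.error,
      conf.high = .data$estimate + 1.96 * .data$std.error,
      fixed = .data$fixed
    )
}

#' Fit-level summary of a PopPK fit
#'
#' @param x A `ppk_fit`.
#' @param ... Unused.
#' @return One-row tibble: OFV, counts, convergence, iterations.
#' @method glance ppk_fit
#' @export
glance.ppk_fit <- function(x, ...) {
  tibble::tibble(ofv = x$ofv, n_subjects = x$n_subjects, n_obs = x$n_obs,
                 n_param = sum(!x$terms$fixed),
                 convergence = x$convergence, iterations = x$iterations)
}

#' Per-observation diagnostics of a PopPK fit
#'
#' One row per quantifiable observation: `dv`, the population
#' prediction `pred` (\eqn{\eta = 0}), the individual prediction
#' `ipred` (at \eqn{\hat\eta}), and the conditional weighted residual
#' `cwres` (whitened by the FOCE-linearized per-subject covariance;
#' approximately standard normal under a correct model).
#'
#' @param x A `ppk_fit`.
#' @param ... Unused.
#' @return Tibble `id`, `time`, `dv`, `pred`, `ipred`, `cwres`.
#' @method augment ppk_fit
#' @export
augment.ppk_fit <- function(x, ...) {
  x$pred
}

#' @rdname augment.ppk_fit
#' @param fit A `ppk_fit`.
#' @export
diagnostics_table <- function(fit) {
  stopifnot(inherits(fit, "ppk_fit"))
  augment(fit)
}

#' @export
print.ppk_fit <- function(x, ...) {
  cat("<ppk_fit> FOCE", if (x$interaction) "(interaction)", "\n")
  cat(sprintf("  OFV %.3f | %d subjects, %d observations | %s\n",
              x$ofv, x$n_subjects, x$n_obs,
              if (x$convergence) "converged" else "NOT converged"))
  print(tidy(x), n = nrow(x$terms))
  if (length(x$shrinkage)) {
    cat("  shrinkage:",
        paste(sprintf("%s=%.2f", names(x$shrinkage), x$shrinkage),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Diagnostic plots for a PopPK fit
#'
#' Four standard goodness-of-fit panels: DV vs PRED, DV vs IPRED,
#' CWRES vs time and CWRES vs PRED.
#'
#' @param object A `ppk_fit`.
#' @param ... Unused.
#' @return A ggplot object (faceted panels).
#' @method autoplot ppk_fit
#' @export
autoplot.ppk_fit <- function(object, ...) {
  d <- augment(object)
  long <- dplyr::bind_rows(
    dplyr::transmute(d, panel = "DV vs PRED", x = .data$pred, y = .data$dv),
    dplyr::transmute(d, panel = "DV vs IPRED", x = .data$ipred, y = .data$dv),
    dplyr::transmute(d, panel = "CWRES vs time", x = .data$time,
                     y = .data$cwres),
    dplyr::transmute(d, panel = "CWRES vs PRED", x = .data$pred,
                     y = .data$cwres)
  )
  ref <- tibble::tibble(
    panel = c("DV vs PRED", "DV vs IPRED", "CWRES vs time", "CWRES vs PRED"),
    slope = c(1, 1, 0, 0), intercept = 0
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(
      data = ref,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}
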