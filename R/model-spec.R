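#' Define a population pharmacokinetic model
#'
#' A `pop_model` bundles the structural model (one- or two-compartment
#' IV infusion with first-order elimination), typical parameter values,
#' covariate effects, inter-individual variability (IIV) and the
#' residual-error model. It is the single object every other function
#' in the package consumes: simulation, estimation, covariate selection
#' and trough prediction.
#'
#' Covariate effects use the conventional power (allometric) form for
#' continuous covariates, \eqn{P_i = P_{pop} (Cov/Cov_{ref})^{\theta}},
#' and the exponential form \eqn{P_i = P_{pop} e^{\theta \cdot Cov}} for
#' 0/1 categorical covariates. IIV is exponential,
#' \eqn{P_i = P_{pop} e^{\eta_i}} with \eqn{\eta_i \sim N(0, \omega^2)}.
#'
#' @param structure `"2cmt"` (default) or `"1cmt"`.
#' @param theta Named numeric vector of typical values. For `"2cmt"`:
#'   `V1` (L), `V2` (L), `CL` (L/h), `Q` (L/h); for `"1cmt"`: `V1`, `CL`.
#' @param effects List of covariate effects built with [cov_effect()].
#' @param iiv Named numeric vector of IIV standard deviations
#'   (\eqn{\omega}, SD scale) keyed by parameter name, e.g.
#'   `c(CL = 0.317)`.
#' @param residual Residual-error specification from [residual_error()].
#' @param infusion_default Default infusion duration in hours used when
#'   a dose record carries none (default 1 h, standard neonatal
#'   vancomycin practice).
#' @return An object of class `pop_model`.
#' @seealso [vanco_final_model], [individual_param()], [ppk_fit()]
#' @examples
#' m <- pop_model(
#'   theta = c(V1 = 1.27, V2 = 2.422, CL = 0.42, Q = 1.161),
#'   effects = list(
#'     cov_effect("CL", "bbw", exponent = 0.888, ref = 3.22),
#'     cov_effect("CL", "pna", exponent = 0.449, ref = 29)
#'   ),
#'   iiv = c(CL = 0.317),
#'   residual = residual_error("additive", stdev0 = 2.187)
#' )
#' individual_param(m, "CL", list(bbw = 3.22, pna = 29))
#' @export
pop_model <- function(structure = c("2cmt", "1cmt"), theta,
                      effects = list(), iiv = numeric(),
                      residual = residual_error("additive", stdev0 = 1),
                      infusion_default = 1) {
  structure <- match.arg(structure)
  need <- if (structure == "2cmt") c("V1", "V2", "CL", "Q") else c("V1", "CL")
  if (!all(need %in% names(theta))) {
    stop("`theta` must name typical values for: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  theta <- theta[need]
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("all typical values must be positive and finite", call. = FALSE)
  }
  if (length(effects) > 0 &&
      (!is.list(effects) || !all(vapply(effects, inherits, TRUE, "cov_effect")))) {
    stop("`effects` must be a list of cov_effect() objects", call. = FALSE)
  }
  bad <- setdiff(vapply(effects, function(e) e$param, ""), need)
  if (length(bad)) {
    stop("covariate effect on unknown parameter: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(iiv)) {
    if (is.null(names(iiv)) || !all(names(iiv) %in% need)) {
      stop("`iiv` must be named by structural parameters", call. = FALSE)
    }
    if (any(iiv < 0)) stop("omega values must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(residual, "residual_error"))
  if (infusion_default <= 0) {
    stop("`infusion_default` must be positive (hours)", call. = FALSE)
  }
  structure(
    list(structure = structure, theta = theta, effects = effects,
         iiv = iiv, residual = residual,
         infusion_default = infusion_default),
    class = "pop_model"
  )
}

#' Covariate effect on a structural parameter
#'
#' @param param Structural parameter name (`"CL"`, `"V1"`, `"V2"`, `"Q"`).
#' @param covariate Covariate column name in the event table (e.g.
#'   `"bbw"`, `"pna"`, `"panipenem"`).
#' @param exponent Power exponent (continuous) or log-scale coefficient
#'   (categorical).
#' @param ref Reference value for a continuous covariate, typically the
#'   cohort median; ignored for categorical effects.
#' @param type `"power"` for continuous covariates, `"categorical"` for
#'   0/1 dummies.
#' @return An object of class `cov_effect`.
#' @export
cov_effect <- function(param, covariate, exponent = 0, ref = NULL,
                       type = c("power", "categorical")) {
  type <- match.arg(type)
  if (type == "power") {
    if (is.null(ref) || !is.finite(ref) || ref <= 0) {
      stop("continuous covariate effects need a positive reference value",
           call. = FALSE)
    }
  } else {
    ref <- NA_real_
  }
  structure(
    list(param = param, covariate = covariate, exponent = exponent,
         ref = ref, type = type),
    class = "cov_effect"
  )
}

#' Residual-error model
#'
#' Maps a model prediction `c_pred` and a standard-normal draw to an
#' observed concentration: additive `c_pred + eps * stdev0`,
#' proportional `c_pred * (1 + eps * cv)`, or combined
#' `c_pred * (1 + eps1 * cv) + eps2 * stdev0` with independent draws.
#'
#' @param type One of `"additive"`, `"proportional"`, `"combined"`.
#' @param stdev0 Additive SD in ug/mL (additive and combined models).
#' @param cv Proportional SD (proportional and combined models).
#' @return An object of class `residual_error`.
#' @export
residual_error <- function(type = c("additive", "proportional", "combined"),
                           stdev0 = 0, cv = 0) {
  type <- match.arg(type)
  if (type %in% c("additive", "combined") && stdev0 < 0) {
    stop("`stdev0` must be >= 0", call. = FALSE)
  }
  if (type %in% c("proportional", "combined") && cv < 0) {
    stop("`cv` must be >= 0", call. = FALSE)
  }
  structure(list(type = type, stdev0 = stdev0, cv = cv),
            class = "residual_error")
}

#' Residual-error variance at a prediction
#'
#' The variance function used in the likelihood:
#' additive \eqn{\sigma_0^2}; proportional \eqn{(cv \cdot c)^2};
#' combined \eqn{(cv \cdot c)^2 + \sigma_0^2}.
#'
#' @param spec A [residual_error()] object.
#' @param c_pred Vector of predicted concentrations (ug/mL).
#' @return Variance vector, (ug/mL)^2.
#' @export
residual_var <- function(spec, c_pred) {
  stopifnot(inherits(spec, "residual_error"))
  switch(spec$type,
    additive = rep(spec$stdev0^2, length(c_pred)),
    proportional = (spec$cv * c_pred)^2,
    combined = (spec$cv * c_pred)^2 + spec$stdev0^2
  )
}

#' Apply a residual-error model to predictions
#'
#' Deterministic given the standard-normal draws, so simulation code can
#' control the RNG. Simulated concentrations are truncated at zero (an
#' additive error can otherwise produce negative concentrations); the
#' likelihood itself uses the untruncated Gaussian.
#'
#' @param c_pred Predicted concentrations (ug/mL).
#' @param spec A [residual_error()] object.
#' @param eps Standard-normal draws, same length as `c_pred` (combined
#'   model: a two-column matrix).
#' @param truncate Truncate negative results at 0 (default `TRUE`).
#' @return Simulated observed concentrations (ug/mL).
#' @export
apply_residual <- function(c_pred, spec, eps, truncate = TRUE) {
  stopifnot(inherits(spec, "residual_error"))
  out <- switch(spec$type,
    additive = c_pred + eps * spec$stdev0,
    proportional = c_pred * (1 + eps * spec$cv),
    combined = {
      eps <- as.matrix(eps)
      if (ncol(eps) != 2) {
        stop("combined residual error needs two epsilon columns",
             call. = FALSE)
      }
      c_pred * (1 + eps[, 1] * spec$cv) + eps[, 2] * spec$stdev0
    }
  )
  if (truncate) out <- pmax(out, 0)
  out
}

#' Individual parameter value under the covariate and IIV model
#'
#' Evaluates \eqn{P_i = P_{pop} \prod (Cov/Cov_{ref})^{\theta}
#' \prod e^{\theta \cdot Cov_{cat}} e^{\eta}} for one subject. With no
#' covariate effects on the parameter and `eta = 0` this returns the
#' typical value.
#'
#' @param model A [pop_model()].
#' @param param Structural parameter name.
#' @param covariates Named list or one-row data frame of covariate
#'   values; must contain every covariate the model's effects on
#'   `param` reference.
#' @param eta Random-effect value (log scale), default 0.
#' @return Parameter value in its natural units (L or L/h).
#' @examples
#' individual_param(vanco_final_model, "CL",
#'                  list(bbw = 3.9, pna = 23)) # 0.4487 L/h
#' @export
individual_param <- function(model, param, covariates = list(), eta = 0) {
  stopifnot(inherits(model, "pop_model"))
  if (!param %in% names(model$theta)) {
    stop("unknown parameter `", param, "`", call. = FALSE)
  }
  covariates <- as.list(covariates)
  p <- unname(model$theta[[param]])
  for (e in model$effects) {
    if (e$param != param) next
    if (!e$covariate %in% names(covariates) ||
        is.na(covariates[[e$covariate]])) {
      stop("covariate `", e$covariate, "` required by the model is missing",
           call. = FALSE)
    }
    v <- covariates[[e$covariate]]
    if (e$type == "power") {
      if (v <= 0) {
        stop("covariate `", e$covariate, "` must be positive", call. = FALSE)
      }
      p <- p * (v / e$ref)^e$exponent
    } else {
      p <- p * exp(e$exponent * v)
    }
  }
  p * exp(eta)
}

#' Weight-normalized parameter value
#'
#' Divides a clearance or volume by body weight, e.g. expressing the
#' typical clearance 0.42 L/h at the cohort's median weight 3.95 kg as
#' 0.106 L/h/kg.
#'
#' @param value Parameter value (L or L/h).
#' @param weight Body weight in kg, > 0.
#' @return Value per kg.
#' @export
weight_normalized <- function(value, weight) {
  if (any(weight <= 0)) stop("`weight` must be positive", call. = FALSE)
  value / weight
}

#' @export
print.pop_model <- function(x, ...) {
  cat("<pop_model> ", x$structure, " IV infusion\n", sep = "")
  cat("  typical values:",
      paste(sprintf("%s=%.4g", names(x$theta), x$theta), collapse = ", "),
      "\n")
  if (length(x$effects)) {
    for (e in x$effects) {
      if (e$type == "power") {
        cat(sprintf("  %s ~ (%s/%.4g)^%.4g\n", e$param, e$covariate,
                    e$ref, e$exponent))
      } else {
        cat(sprintf("  %s ~ exp(%.4g * %s)\n", e$param, e$exponent,
                    e$covariate))
      }
    }
  }
  if (length(x$iiv)) {
    cat("  IIV (omega, SD):",
        paste(sprintf("%s=%.4g", names(x$iiv), x$iiv), collapse = ", "),
        "\n")
  }
  r <- x$residual
  cat("  residual:", r$type,
      if (r$type != "proportional") sprintf("stdev0=%.4g", r$stdev0) else "",
      if (r$type != "additive") sprintf("cv=%.4g", r$cv) else "", "\n")
  invisible(x)
}

#' Published final vancomycin model for neonates and young infants
#'
#' Two-compartment model with `V1` 1.27 L, `V2` 2.422 L, `Q` 1.161 L/h
#' and clearance
#' \deqn{CL = 0.42 \cdot (BBW/3.22)^{0.888} \cdot (PNA/29)^{0.449}
#'       \cdot e^{\eta_{CL}}}
#' (L/h, birth body weight in kg, postnatal age in days), exponential
#' IIV on CL (\eqn{\omega_{CL}} = 0.317, SD scale) and an additive
#' residual error of 2.187 ug/mL. Serves as the default simulation
#' truth and the fixed model for trough prediction.
#'
#' @format A [pop_model()] object.
#' @export
vanco_final_model <- pop_model(
  structure = "2cmt",
  theta = c(V1 = 1.27, V2 = 2.422, CL = 0.42, Q = 1.161),
  effects = list(
    cov_effect("CL", "bbw", exponent = 0.888, ref = 3.22),
    cov_effect("CL", "pna", exponent = 0.449, ref = 29)
  ),
  iiv = c(CL = 0.317),
  residual = residual_error("additive", stdev0 = 2.187),
  infusion_default = 1
)

#' Read / write a model specification file
#'
#' Plain YAML key-value serialization of a [pop_model()] so model
#' definitions can be versioned and passed to the command-line tools.
#' The packaged final model ships as
#' `system.file("models", "vanco_final_model.yaml", package = "neovanc")`.
#'
#' @param path File path.
#' @return `read_model()` returns a [pop_model()]; `write_model()`
#'   returns `path` invisibly.
#' @export
read_model <- function(path) {
  spec <- yaml::read_yaml(path)
  effects <- lapply(spec$effects %||% list(), function(e) {
    cov_effect(e$param, e$covariate, exponent = e$exponent,
               ref = e$ref, type = e$type %||% "power")
  })
  pop_model(
    structure = spec$structure %||% "2cmt",
    theta = unlist(spec$theta),
    effects = effects,
    iiv = unlist(spec$iiv) %||% numeric(),
    residual = residual_error(spec$residual$type %||% "additive",
                              stdev0 = spec$residual$stdev0 %||% 0,
                              cv = spec$residual$cv %||% 0),
    infusion_default = spec$infusion_default %||% 1
  )
}

#' @param model A [pop_model()] to serialize.
#' @rdname read_model
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pop_model"))
  spec <- list(
    structure = model$structure,
    theta = as.list(model$theta),
    effects = lapply(model$effects, function(e) {
      out <- list(param = e$param, covariate = e$covariate,
                  exponent = e$exponent, type = e$type)
      if (e$type == "power") out$ref <- e$ref
      out
    }),
    iiv = as.list(model$iiv),
    residual = list(type = model$residual$type,
                    stdev0 = model$residual$stdev0,
                    cv = model$residual$cv),
    infusion_default = model$infusion_default
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}
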