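#' Candidate covariate set for stepwise selection
#'
#' Builds the candidate table for [stepwise_covariates()]: one row per
#' (parameter, covariate) relation. Continuous candidates use the power
#' form centered at the dataset median; 0/1 covariates use the
#' exponential categorical form.
#'
#' @param covariates Character vector of covariate column names.
#' @param param Parameter the candidates act on (default `"CL"`, the
#'   only parameter retaining IIV in the reference workflow).
#' @param data Event table; used to detect 0/1 covariates and compute
#'   medians.
#' @return Tibble with columns `param`, `covariate`, `type`, `ref`.
#' @export
candidate_set <- function(covariates, data, param = "CL") {
  subj <- data |>
    dplyr::group_by(.data$id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  miss <- setdiff(covariates, names(subj))
  if (length(miss)) {
    stop("candidate covariate(s) not in the data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(covariates, function(cv) {
    v <- subj[[cv]]
    categorical <- all(v %in% c(0, 1))
    tibble::tibble(
      param = param, covariate = cv,
      type = if (categorical) "categorical" else "power",
      ref = if (categorical) NA_real_ else stats::median(v)
    )
  })
}

.add_candidate <- function(model, cand) {
  model$effects <- c(model$effects, list(
    cov_effect(cand$param, cand$covariate, exponent = 0,
               ref = if (cand$type == "power") cand$ref else NULL,
               type = cand$type)
  ))
  model
}

.drop_effect <- function(model, param, covariate) {
  keep <- !vapply(model$effects, function(e) {
    e$param == param && e$covariate == covariate
  }, TRUE)
  model$effects <- model$effects[keep]
  model
}

.has_effect <- function(model, param, covariate) {
  any(vapply(model$effects, function(e) {
    e$param == param && e$covariate == covariate
  }, TRUE))
}

.safe_fit <- function(data, model, ...) {
  fit <- tryCatch(ppk_fit(data, model, se = FALSE, ...),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$convergence) return(NULL)
  fit
}

#' One forward-inclusion step
#'
#' Fits each candidate relation added singly to the current model and
#' returns the candidate with the largest OFV drop, provided the drop
#' exceeds `threshold` (default 6.635, the chi-square 1-df 1% critical
#' value). Non-converging candidates are skipped with a warning. Ties
#' on Delta-OFV break lexicographically on covariate name.
#'
#' @param data Event table.
#' @param model Current [pop_model()] (initial values for refits).
#' @param candidates Candidate tibble from [candidate_set()]; rows
#'   already in `model` are ignored.
#' @param threshold Required OFV reduction (default 6.635).
#' @param base_fit Optional pre-computed fit of `model` to avoid
#'   refitting.
#' @return List with `selected` (one-row tibble or `NULL`), the
#'   updated `model`, its `fit`, and `trace` rows (one per candidate
#'   tried).
#' @export
forward_step <- function(data, model, candidates, threshold = 6.635,
                         base_fit = NULL) {
  if (is.null(base_fit)) base_fit <- .safe_fit(data, model)
  if (is.null(base_fit)) {
    stop("base model did not converge; cannot run a forward step",
         call. = FALSE)
  }
  candidates <- candidates |>
    dplyr::filter(!purrr::map2_lgl(.data$param, .data$covariate,
                                   ~ .has_effect(model, .x, .y))) |>
    dplyr::arrange(.data$covariate)
  fits <- vector("list", nrow(candidates))
  rows <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    fit <- .safe_fit(data, .add_candidate(base_fit$model, cand))
    fits[[i]] <<- fit
    if (is.null(fit)) {
      warning("candidate ", cand$covariate, " on ", cand$param,
              " did not converge; skipped", call. = FALSE)
      return(tibble::tibble(param = cand$param, covariate = cand$covariate,
                            ofv = NA_real_, delta_ofv = NA_real_,
                            converged = FALSE))
    }
    tibble::tibble(param = cand$param, covariate = cand$covariate,
                   ofv = fit$ofv, delta_ofv = fit$ofv - base_fit$ofv,
                   converged = TRUE)
  })
  ok_idx <- which(rows$converged & !is.na(rows$delta_ofv))
  selected <- NULL
  new_model <- model
  new_fit <- base_fit
  if (length(ok_idx) > 0) {
    ord <- ok_idx[order(rows$delta_ofv[ok_idx], rows$covariate[ok_idx])]
    best_i <- ord[1]
    if (rows$delta_ofv[best_i] < -threshold) {
      selected <- rows[best_i, ]
      new_fit <- fits[[best_i]]
      new_model <- new_fit$model
    }
  }
  list(selected = selected, model = new_model, fit = new_fit,
       trace = rows, base_ofv = base_fit$ofv)
}

#' One backward-elimination step
#'
#' Removes each covariate effect singly from the full model; an effect
#' is retained only if its removal raises the OFV by more than
#' `threshold` (default 10.828, chi-square 1-df 0.1%). Among removable
#' effects the one with the smallest OFV increase is dropped.
#'
#' @param data Event table.
#' @param model Full [pop_model()].
#' @param threshold Required OFV increase for retention (default
#'   10.828).
#' @param full_fit Optional pre-computed fit of `model`.
#' @return List with `dropped` (one-row tibble or `NULL`), updated
#'   `model`, its `fit`, and `trace` rows.
#' @export
backward_step <- function(data, model, threshold = 10.828,
                          full_fit = NULL) {
  if (length(model$effects) == 0) {
    return(list(dropped = NULL, model = model, fit = full_fit,
                trace = tibble::tibble()))
  }
  if (is.null(full_fit)) full_fit <- .safe_fit(data, model)
  if (is.null(full_fit)) {
    stop("full model did not converge; cannot run a backward step",
         call. = FALSE)
  }
  eff <- purrr::map_dfr(full_fit$model$effects, function(e) {
    tibble::tibble(param = e$param, covariate = e$covariate)
  }) |>
    dplyr::arrange(.data$covariate)
  fits <- vector("list", nrow(eff))
  rows <- purrr::map_dfr(seq_len(nrow(eff)), function(i) {
    reduced <- .drop_effect(full_fit$model, eff$param[i], eff$covariate[i])
    fit <- .safe_fit(data, reduced)
    fits[[i]] <<- fit
    if (is.null(fit)) {
      warning("reduced model without ", eff$covariate[i],
              " did not converge; effect retained", call. = FALSE)
      return(tibble::tibble(param = eff$param[i],
                            covariate = eff$covariate[i],
                            ofv = NA_real_, delta_ofv = NA_real_,
                            converged = FALSE))
    }
    tibble::tibble(param = eff$param[i], covariate = eff$covariate[i],
                   ofv = fit$ofv, delta_ofv = fit$ofv - full_fit$ofv,
                   converged = TRUE)
  })
  ok_idx <- which(rows$converged & !is.na(rows$delta_ofv) &
                    rows$delta_ofv <= threshold)
  dropped <- NULL
  new_model <- full_fit$model
  new_fit <- full_fit
  if (length(ok_idx) > 0) {
    ord <- ok_idx[order(rows$delta_ofv[ok_idx], rows$covariate[ok_idx])]
    best_i <- ord[1]
    dropped <- rows[best_i, ]
    new_fit <- fits[[best_i]]
    new_model <- new_fit$model
  }
  list(dropped = dropped, model = new_model, fit = new_fit,
       trace = rows, full_ofv = full_fit$ofv)
}

#' Stepwise covariate selection on OFV thresholds
#'
#' Greedy forward inclusion (one relation per iteration, largest OFV
#' drop, accepted if it exceeds `forward_dofv`) to exhaustion, followed
#' by backward elimination (an effect survives only if its removal
#' raises the OFV by more than `backward_dofv`) to stability. Emits a
#' ledger of every model evaluated, mirroring the conventional
#' stepwise-table layout. Deterministic given the data.
#'
#' @param data Event table.
#' @param model Base [pop_model()] without the candidate effects.
#' @param candidates Candidate tibble from [candidate_set()].
#' @param forward_dofv Forward threshold (default 6.635, p < 0.01,
#'   chi-square with 1 df).
#' @param backward_dofv Backward threshold (default 10.828, p < 0.001).
#' @return Object of class `stepwise_trace`: `steps` ledger tibble,
#'   `final_model`, `final_fit`.
#' @export
stepwise_covariates <- function(data, model, candidates,
                                forward_dofv = 6.635,
                                backward_dofv = 10.828) {
  stopifnot(forward_dofv > 0, backward_dofv > 0)
  steps <- tibble::tibble()
  n_model <- 1L
  base_fit <- .safe_fit(data, model)
  if (is.null(base_fit)) {
    stop("base model did not converge", call. = FALSE)
  }
  steps <- dplyr::bind_rows(steps, tibble::tibble(
    model_no = n_model, stage = "forward", action = "base",
    parameter = NA_character_, covariate = NA_character_,
    ofv = base_fit$ofv, delta_ofv = NA_real_, decision = "start"
  ))
  cur_fit <- base_fit
  cur_model <- base_fit$model
  if (nrow(candidates) > 0) {
    repeat {
      fs <- forward_step(data, cur_model, candidates,
                         threshold = forward_dofv, base_fit = cur_fit)
      if (is.null(fs$selected)) break
      n_model <- n_model + 1L
      steps <- dplyr::bind_rows(steps, tibble::tibble(
        model_no = n_model, stage = "forward", action = "add",
        parameter = fs$selected$param, covariate = fs$selected$covariate,
        ofv = fs$selected$ofv, delta_ofv = fs$selected$delta_ofv,
        decision = "added"
      ))
      cur_model <- fs$model
      cur_fit <- fs$fit
      if (all(purrr::map2_lgl(candidates$param, candidates$covariate,
                              ~ .has_effect(cur_model, .x, .y)))) break
    }
  }
  repeat {
    if (length(cur_model$effects) == 0) break
    bs <- backward_step(data, cur_model, threshold = backward_dofv,
                        full_fit = cur_fit)
    tr <- bs$trace[bs$trace$converged, , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      is_dropped <- !is.null(bs$dropped) &&
        tr$param[i] == bs$dropped$param &&
        tr$covariate[i] == bs$dropped$covariate
      n_model <- n_model + 1L
      steps <- dplyr::bind_rows(steps, tibble::tibble(
        model_no = n_model, stage = "backward", action = "remove",
        parameter = tr$param[i], covariate = tr$covariate[i],
        ofv = tr$ofv[i], delta_ofv = tr$delta_ofv[i],
        decision = if (is_dropped) "eliminated" else "retained"
      ))
    }
    if (is.null(bs$dropped)) break
    cur_model <- bs$model
    cur_fit <- bs$fit
  }
  structure(
    list(steps = steps, final_model = cur_model, final_fit = cur_fit,
         forward_dofv = forward_dofv, backward_dofv = backward_dofv),
    class = "stepwise_trace"
  )
}

#' @method tidy stepwise_trace
#' @export
tidy.stepwise_trace <- function(x, ...) {
  x$steps
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("<stepwise_trace> forward >", x$forward_dofv,
      "| backward >", x$backward_dofv, "\n")
  print(x$steps, n = nrow(x$steps))
  cat("final model effects:",
      if (length(x$final_model$effects) == 0) "(none)" else
        paste(vapply(x$final_model$effects,
                     function(e) paste0(e$covariate, "->", e$param), ""),
              collapse = ", "), "\n")
  invisible(x)
}
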