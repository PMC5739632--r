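#' Structural parameters and derived disposition constants
#'
#' Collects the two-compartment parameters and derives the micro rate
#' constants `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`, the disposition
#' exponents `alpha` and `beta` (roots of
#' \eqn{x^2 - (k10+k12+k21)x + k10 k21}), and the unit-bolus central
#' macro coefficients `A = (alpha-k21)/(V1(alpha-beta))`,
#' `B = (k21-beta)/(V1(alpha-beta))`. `Q = 0` (or `V2 = 0`) is the
#' one-compartment limit: a single exponential `CL/V1` with
#' coefficient `1/V1`.
#'
#' @param V1,V2 Central and peripheral volumes (L).
#' @param CL Clearance (L/h).
#' @param Q Inter-compartmental clearance (L/h); 0 collapses to one
#'   compartment.
#' @return A one-row tibble with columns `V1`, `V2`, `CL`, `Q`, `k10`,
#'   `k12`, `k21`, `alpha`, `beta`, `A`, `B`.
#' @examples
#' structural_params(V1 = 1.27, V2 = 2.422, CL = 0.42, Q = 1.161)
#' @export
structural_params <- function(V1, V2 = 0, CL, Q = 0) {
  if (V1 <= 0 || CL <= 0 || V2 < 0 || Q < 0) {
    stop("V1 and CL must be positive; V2 and Q non-negative",
         call. = FALSE)
  }
  if (Q <= 0 || V2 <= 0) {
    k <- CL / V1
    return(tibble::tibble(V1 = V1, V2 = V2, CL = CL, Q = Q,
                          k10 = k, k12 = 0, k21 = 0,
                          alpha = k, beta = 0, A = 1 / V1, B = 0))
  }
  k10 <- CL / V1
  k12 <- Q / V1
  k21 <- Q / V2
  s <- k10 + k12 + k21
  root <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + root) / 2
  beta <- (s - root) / 2
  A <- (alpha - k21) / (V1 * (alpha - beta))
  B <- (k21 - beta) / (V1 * (alpha - beta))
  tibble::tibble(V1 = V1, V2 = V2, CL = CL, Q = Q,
                 k10 = k10, k12 = k12, k21 = k21,
                 alpha = alpha, beta = beta, A = A, B = B)
}

#' Concentration-time profile under superposed IV infusions
#'
#' Closed-form central-compartment concentration of the linear one- or
#' two-compartment model under any sequence of constant-rate infusions,
#' by superposition of the standard per-dose solution. Linear in dose
#' amounts; continuous in time; decays to zero after the last dose.
#'
#' @param times Vector of times (hours since first dose), >= 0.
#' @param doses Data frame of dose events with columns `time` (h),
#'   `amt` (mg) and optionally `dur` (infusion duration, h).
#' @param params One-row data frame or named list with `V1`, `V2`,
#'   `CL`, `Q` (as from [structural_params()], or individual values).
#' @param infusion_default Duration (h) used where `doses$dur` is
#'   missing.
#' @return Concentration vector in ug/mL (== mg/L).
#' @examples
#' reg <- dosing_regimen(amt = 48.3, interval = 8, n = 6)
#' predict_conc(seq(0, 48, by = 0.5), reg,
#'              list(V1 = 1.27, V2 = 2.422, CL = 0.42, Q = 1.161))
#' @export
predict_conc <- function(times, doses, params, infusion_default = 1) {
  if (any(times < 0)) stop("`times` must be non-negative", call. = FALSE)
  if (is.null(doses) || nrow(doses) == 0) {
    return(rep(0, length(times)))
  }
  if (!all(c("time", "amt") %in% names(doses))) {
    stop("`doses` needs columns `time` and `amt`", call. = FALSE)
  }
  dur <- if ("dur" %in% names(doses)) doses$dur else
    rep(infusion_default, nrow(doses))
  dur[is.na(dur)] <- infusion_default
  if (any(doses$amt <= 0) || any(dur <= 0) || any(doses$time < 0)) {
    stop("dose amounts and durations must be positive, times non-negative",
         call. = FALSE)
  }
  p <- as.list(params)
  as.numeric(conc_cpp(as.numeric(times), as.numeric(doses$time),
                      as.numeric(doses$amt), as.numeric(dur),
                      p$V1, p$V2 %||% 0, p$CL, p$Q %||% 0))
}

#' Build a regular multiple-dose regimen
#'
#' @param amt Dose amount (mg).
#' @param interval Dosing interval tau (h).
#' @param n Number of doses.
#' @param dur Infusion duration (h), default 1.
#' @param start Time of the first dose (h), default 0.
#' @return Tibble of dose events (`time`, `amt`, `dur`).
#' @export
dosing_regimen <- function(amt, interval, n, dur = 1, start = 0) {
  stopifnot(amt > 0, interval > 0, n >= 1, dur > 0, start >= 0)
  tibble::tibble(time = start + interval * (seq_len(n) - 1),
                 amt = amt, dur = dur)
}
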