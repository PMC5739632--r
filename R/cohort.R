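#' Cohort design specification for synthetic TDM data
#'
#' Describes the statistical structure of a neonatal vancomycin
#' therapeutic-drug-monitoring cohort: covariate marginals (medians and
#' ranges), the dosing policy (daily mg/kg split over 2-4 doses at
#' regular intervals), the sparse trough-biased sampling policy
#' (1-6 samples per subject), the generating population model, and the
#' assay's lower limit of quantification. [simulate_cohort()] turns a
#' spec into an event table.
#'
#' The default covariate table reproduces the study cohort this package
#' models: e.g. birth body weight median 3.22 kg (1.25-5.38), postnatal
#' age median 29 d (2-77), 102/316 preterm, panipenem in 168/316 and
#' furosemide in 74/316 subjects.
#'
#' @param n_subjects Number of subjects (default 316).
#' @param model Generating [pop_model()] (default [vanco_final_model]).
#' @param covariates Data frame with columns `name`, `median`, `min`,
#'   `max` overriding the default continuous-covariate marginals.
#' @param daily_dose_range mg/kg/day range, default `c(13.7, 73.5)`.
#' @param doses_per_day Allowed doses per day, default `2:4`.
#' @param days_range Treatment duration range in days, default `c(2, 7)`.
#' @param n_samples_prob Probabilities of 1..6 samples per subject;
#'   default heavily weighted to one sample (cohort mean ~1.33).
#' @param trough_frac Fraction of samples drawn within 1 h before a
#'   dose (default 0.7); the rest are uniform within a dosing interval.
#' @param preterm_prob,panipenem_prob,furosemide_prob,male_prob
#'   Categorical covariate frequencies.
#' @param growth_rate Relative daily weight gain linking current to
#'   birth weight, `bw = bbw * (1 + growth_rate * pna)`, jittered
#'   plus/minus 30 percent per subject (default 0.0077/day).
#' @param lloq Lower limit of quantification, ug/mL (default 1).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 316,
                        model = vanco_final_model,
                        covariates = NULL,
                        daily_dose_range = c(13.7, 73.5),
                        doses_per_day = 2:4,
                        days_range = c(2, 7),
                        n_samples_prob = c(0.78, 0.13, 0.05, 0.02, 0.01, 0.01),
                        trough_frac = 0.7,
                        preterm_prob = 102 / 316,
                        panipenem_prob = 168 / 316,
                        furosemide_prob = 74 / 316,
                        male_prob = 201 / 316,
                        growth_rate = 0.0077,
                        lloq = 1) {
  stopifnot(n_subjects >= 1, inherits(model, "pop_model"),
            trough_frac >= 0, trough_frac <= 1,
            all(doses_per_day %in% 2:4), length(n_samples_prob) == 6)
  defaults <- tibble::tibble(
    name = c("ga", "pna", "bbw", "ht", "scr", "bun", "alt", "alb"),
    median = c(37, 29, 3.22, 49, 28.6, 2.35, 25.7, 33.1),
    min = c(28, 2, 1.25, 35, 12, 0.48, 5.4, 13.5),
    max = c(41, 77, 5.38, 62.3, 151, 7.54, 130.9, 52.6)
  )
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    defaults <- dplyr::rows_update(defaults, covariates, by = "name")
  }
  if (any(defaults$median < defaults$min | defaults$median > defaults$max)) {
    stop("covariate median outside its (min, max) range", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, model = model, covariates = defaults,
         daily_dose_range = daily_dose_range, doses_per_day = doses_per_day,
         days_range = days_range, n_samples_prob = n_samples_prob,
         trough_frac = trough_frac, preterm_prob = preterm_prob,
         panipenem_prob = panipenem_prob, furosemide_prob = furosemide_prob,
         male_prob = male_prob, growth_rate = growth_rate, lloq = lloq),
    class = "cohort_spec"
  )
}

#' Read / write a cohort design as a YAML config file
#'
#' Serializes a [cohort_spec()] (including its generating model, in the
#' same representation as [write_model()]) so simulation designs can be
#' versioned and passed to the command line.
#'
#' @param path File path.
#' @return `read_cohort_spec()` returns a [cohort_spec()];
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  model_path <- tempfile(fileext = ".yaml")
  on.exit(unlink(model_path))
  yaml::write_yaml(x$model, model_path)
  cohort_spec(
    n_subjects = x$n_subjects,
    model = read_model(model_path),
    covariates = if (!is.null(x$covariates)) {
      dplyr::bind_rows(lapply(x$covariates, tibble::as_tibble))
    },
    daily_dose_range = unlist(x$daily_dose_range),
    doses_per_day = unlist(x$doses_per_day),
    days_range = unlist(x$days_range),
    n_samples_prob = unlist(x$n_samples_prob),
    trough_frac = x$trough_frac,
    preterm_prob = x$preterm_prob,
    panipenem_prob = x$panipenem_prob,
    furosemide_prob = x$furosemide_prob,
    male_prob = x$male_prob,
    growth_rate = x$growth_rate,
    lloq = x$lloq
  )
}

#' @param spec A [cohort_spec()] to serialize.
#' @rdname read_cohort_spec
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  model_path <- tempfile(fileext = ".yaml")
  on.exit(unlink(model_path))
  write_model(spec$model, model_path)
  x <- list(
    n_subjects = spec$n_subjects,
    model = yaml::read_yaml(model_path),
    covariates = lapply(seq_len(nrow(spec$covariates)), function(i) {
      as.list(spec$covariates[i, ])
    }),
    daily_dose_range = spec$daily_dose_range,
    doses_per_day = spec$doses_per_day,
    days_range = spec$days_range,
    n_samples_prob = spec$n_samples_prob,
    trough_frac = spec$trough_frac,
    preterm_prob = spec$preterm_prob,
    panipenem_prob = spec$panipenem_prob,
    furosemide_prob = spec$furosemide_prob,
    male_prob = spec$male_prob,
    growth_rate = spec$growth_rate,
    lloq = spec$lloq
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

# sample one element of x (safe for length-1 x, unlike sample())
sample1 <- function(x, prob = NULL) {
  x[sample.int(length(x), 1, prob = prob)]
}

# Truncated log-normal with a given median whose (min, max) holds ~99%
# of the untruncated mass on the tighter side; rejection-sampled so all
# draws respect the bounds.
rtrunc_lnorm <- function(n, med, lo, hi) {
  sigma <- min(log(med / lo), log(hi / med)) / qnorm(0.995)
  sigma <- max(sigma, 1e-6)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 10, log(med), sigma)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Draw subject-level covariates
#'
#' Continuous covariates are truncated log-normal, parameterized so the
#' median matches the spec and essentially all mass lies inside the
#' published range. Current weight is generated jointly with birth
#' weight and postnatal age (`bw = bbw * (1 + g * pna)` with jittered
#' growth rate); GA is drawn conditionally on the preterm flag so the
#' preterm fraction matches; renal/hepatic markers are independent of
#' the PK truth. Derived covariates (`pma`, `bsa`, `gfr`) are computed,
#' not drawn.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param n Number of subjects (default `spec$n_subjects`).
#' @return Tibble of one row per subject.
#' @export
sample_covariates <- function(spec, seed, n = spec$n_subjects) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(seed)
  cv <- spec$covariates
  draw <- function(nm) {
    r <- cv[cv$name == nm, ]
    rtrunc_lnorm(n, r$median, r$min, r$max)
  }
  preterm <- rbinom(n, 1, spec$preterm_prob)
  ga_row <- cv[cv$name == "ga", ]
  ga <- ifelse(preterm == 1,
               runif(n, ga_row$min, 36.9),
               37 + (ga_row$max - 37) * stats::rbeta(n, 2, 3))
  pna <- round(rtrunc_lnorm(n, cv$median[cv$name == "pna"],
                            cv$min[cv$name == "pna"],
                            cv$max[cv$name == "pna"]))
  pna <- pmax(pna, cv$min[cv$name == "pna"])
  bbw <- draw("bbw")
  growth <- spec$growth_rate * runif(n, 0.7, 1.3)
  bw <- pmin(bbw * (1 + growth * pna), 7.62)
  ht <- draw("ht")
  scr <- draw("scr")
  tibble::tibble(
    id = seq_len(n),
    sex = rbinom(n, 1, spec$male_prob),
    ga = round(ga, 1),
    pna = pna,
    pma = pma(round(ga, 1), pna),
    bbw = round(bbw, 2),
    bw = round(bw, 2),
    ht = round(ht, 1),
    bsa = round(bsa(round(bw, 2), round(ht, 1)), 4),
    scr = round(scr, 1),
    gfr = round(schwartz_gfr(round(ht, 1), round(scr, 1), preterm == 1), 1),
    bun = round(draw("bun"), 2),
    alt = round(draw("alt"), 1),
    alb = round(draw("alb"), 1),
    preterm = preterm,
    panipenem = rbinom(n, 1, spec$panipenem_prob),
    furosemide = rbinom(n, 1, spec$furosemide_prob)
  )
}

#' Draw a dosing regimen for one subject
#'
#' Daily dose per kg uniform on the spec's range, split evenly over 2-4
#' doses at regular intervals (tau 12, 8 or 6 h) for 2-7 days; amounts
#' rounded to 0.1 mg.
#'
#' @param cov One-row covariate tibble (needs `bw`).
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Tibble of dose events (`time`, `amt`, `dur`).
#' @export
sample_regimen <- function(cov, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(seed)
  mgkg <- runif(1, spec$daily_dose_range[1], spec$daily_dose_range[2])
  per_day <- sample1(spec$doses_per_day)
  days <- sample1(seq(spec$days_range[1], spec$days_range[2]))
  amt <- round(mgkg * cov$bw / per_day, 1)
  dosing_regimen(amt = amt, interval = 24 / per_day, n = per_day * days,
                 dur = spec$model$infusion_default)
}

#' Draw sparse TDM sampling times for one subject
#'
#' 1-6 samples per subject; a `trough_frac` share fall within 1 h
#' before a scheduled dose, the rest uniformly within a dosing
#' interval. All samples fall after the third dose has started.
#'
#' @param regimen Dose-event tibble from [sample_regimen()].
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Sorted numeric vector of sampling times (h).
#' @export
sample_observation_times <- function(regimen, spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(seed)
  k <- sample1(1:6, prob = spec$n_samples_prob)
  nd <- nrow(regimen)
  tau <- if (nd > 1) regimen$time[2] - regimen$time[1] else 8
  times <- vapply(seq_len(k), function(i) {
    if (runif(1) < spec$trough_frac) {
      j <- if (nd >= 4) sample1(4:nd) else nd
      regimen$time[j] - runif(1, 0, 1)
    } else {
      j <- if (nd >= 4) sample1(3:(nd - 1)) else max(nd - 1, 1)
      regimen$time[j] + runif(1, 0, tau)
    }
  }, numeric(1))
  sort(pmax(times, regimen$time[1] + 1e-3))
}

#' Simulate a complete synthetic cohort
#'
#' Draws covariates, regimens and sampling times, then simulates
#' concentrations from the generating model with per-subject
#' exponential IIV and per-observation residual error. Simulated
#' values below the LLOQ are flagged `bloq` (and negative additive
#' draws truncated at 0). Deterministic given the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Event table tibble (see [event-tables]) carrying all
#'   covariate columns.
#' @examples
#' ev <- simulate_cohort(cohort_spec(n_subjects = 5), seed = 1)
#' dplyr::count(ev, evid)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  covs <- sample_covariates(spec, seed = seed)
  model <- spec$model
  withr::local_seed(seed + 1L)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2 * spec$n_subjects)
  iiv_names <- names(model$iiv)
  rows <- purrr::map(seq_len(spec$n_subjects), function(i) {
    cv <- covs[i, ]
    reg <- sample_regimen(cv, spec, seed = sub_seeds[2 * i - 1])
    tt <- sample_observation_times(reg, spec, seed = sub_seeds[2 * i])
    eta <- setNames(rnorm(length(iiv_names)) * model$iiv, iiv_names)
    pars <- lapply(c("V1", "V2", "CL", "Q"), function(p) {
      if (!p %in% names(model$theta)) return(0)
      individual_param(model, p, as.list(cv),
                       eta = if (p %in% iiv_names) eta[[p]] else 0)
    })
    names(pars) <- c("V1", "V2", "CL", "Q")
    cpred <- predict_conc(tt, reg, pars,
                          infusion_default = model$infusion_default)
    eps <- if (model$residual$type == "combined") {
      matrix(rnorm(2 * length(tt)), ncol = 2)
    } else {
      rnorm(length(tt))
    }
    dv <- apply_residual(cpred, model$residual, eps, truncate = TRUE)
    dose_rows <- tibble::tibble(id = cv$id, time = reg$time, evid = 1,
                                amt = reg$amt, dur = reg$dur,
                                dv = NA_real_, bloq = FALSE)
    obs_rows <- tibble::tibble(id = cv$id, time = tt, evid = 0,
                               amt = NA_real_, dur = NA_real_,
                               dv = round(dv, 3), bloq = dv < spec$lloq)
    dplyr::bind_rows(dose_rows, obs_rows) |>
      dplyr::arrange(.data$time, dplyr::desc(.data$evid)) |>
      dplyr::left_join(covs[i, ], by = "id")
  })
  validate_events(dplyr::bind_rows(rows))
}
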