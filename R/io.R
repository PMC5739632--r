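#' Event-record tables
#'
#' The package exchanges dosing and observation data as NONMEM-style
#' event tables: one row per event, identified by `evid` (1 = dose,
#' 0 = observation). Dose rows carry `amt` (mg) and `dur` (infusion
#' duration, h); observation rows carry `dv` (ug/mL) and `bloq`
#' (below the assay's lower limit of quantification). Times are hours
#' since the subject's first dose. Covariate columns (e.g. `bbw`,
#' `pna`, `bw`, `scr`) ride along on every row and are constant within
#' subject.
#'
#' @name event-tables
NULL

.event_cols <- c("id", "time", "evid", "amt", "dur", "dv", "bloq")

#' Validate an event table
#'
#' Checks the structural invariants of an event table: required
#' columns, non-negative and within-subject non-decreasing times,
#' mutually exclusive dose/observation fields, positive dose amounts
#' and durations, and that every observation is preceded by at least
#' one dose. Errors carry row numbers and subject ids.
#'
#' @param data Event table (data frame).
#' @param lenient If `TRUE`, rows are re-sorted by time within subject
#'   instead of failing on ordering, with a warning.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_events <- function(data, lenient = FALSE) {
  data <- tibble::as_tibble(data)
  need <- c("id", "time", "evid")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("event table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"bloq" %in% names(data)) data$bloq <- FALSE
  if (!"dur" %in% names(data)) data$dur <- NA_real_
  if (!all(data$evid %in% c(0, 1))) {
    stop("`evid` must be 0 (observation) or 1 (dose)", call. = FALSE)
  }
  bad <- which(data$time < 0)
  if (length(bad)) {
    stop("negative event times at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  unsorted <- data |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$id) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$time < dplyr::lag(.data$time)) |>
    dplyr::ungroup()
  if (nrow(unsorted) > 0) {
    if (!lenient) {
      stop("times decrease within subject at rows: ",
           paste(utils::head(unsorted$.row, 5), collapse = ", "),
           call. = FALSE)
    }
    warning("re-sorting events by time within subject", call. = FALSE)
    data <- dplyr::arrange(data, .data$id, .data$time, dplyr::desc(.data$evid))
  }
  dose <- data$evid == 1
  bad <- which(dose & (is.na(data$amt) | data$amt <= 0))
  if (length(bad)) {
    stop("dose rows need a positive `amt`; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(dose & !is.na(data$dur) & data$dur <= 0)
  if (length(bad)) {
    stop("infusion durations must be positive; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!dose & is.na(data$dv))
  if (length(bad)) {
    stop("observation rows need `dv`; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  orphan <- data |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      has_obs = any(.data$evid == 0),
      ok = !any(.data$evid == 0) ||
        (any(.data$evid == 1) &&
           min(.data$time[.data$evid == 0]) >=
             min(.data$time[.data$evid == 1])),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$has_obs, !.data$ok)
  if (nrow(orphan) > 0) {
    stop("observation precedes any dose for subject(s): ",
         paste(utils::head(orphan$id, 5), collapse = ", "), call. = FALSE)
  }
  data
}

#' Read or write an event table CSV
#'
#' Plain UTF-8 comma-separated files with a header, `.` decimal marks
#' and the column conventions of [event-tables]. Reading validates the
#' table; `write_events()` then `read_events()` is an identity on
#' values.
#'
#' @param path CSV file path.
#' @param lenient Passed to [validate_events()].
#' @return `read_events()` returns a validated tibble; `write_events()`
#'   returns `path` invisibly.
#' @export
read_events <- function(path, lenient = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("bloq" %in% names(raw)) raw$bloq <- as.logical(raw$bloq)
  validate_events(tibble::as_tibble(raw), lenient = lenient)
}

#' @param data Event table to write.
#' @rdname read_events
#' @export
write_events <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a validated event table as JSON
#'
#' Row-oriented JSON export of a validated event table, for consumers
#' outside R. Requires the `jsonlite` package.
#'
#' @param data Event table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(data, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("JSON export requires the `jsonlite` package", call. = FALSE)
  }
  data <- validate_events(data)
  jsonlite::write_json(data, path, dataframe = "rows", na = "null",
                       digits = NA)
  invisible(path)
}

#' Body surface area of an infant
#'
#' \eqn{BSA = BW^{0.5378} \cdot HT^{0.3964} \cdot 0.024265} with weight
#' in kg and height in cm.
#'
#' @param weight Body weight (kg), > 0.
#' @param height Height (cm), > 0.
#' @return BSA in m^2.
#' @examples
#' bsa(3.95, 49) # 0.238 m^2
#' @export
bsa <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop("`weight` and `height` must be positive", call. = FALSE)
  }
  weight^0.5378 * height^0.3964 * 0.024265
}

#' Schwartz estimate of glomerular filtration rate
#'
#' \eqn{GFR = k \cdot HT / SCr_{mg/dL}} with `k` 0.45 for full-term and
#' 0.33 for preterm infants. Serum creatinine is taken in umol/L and
#' converted internally (1 mg/dL = 88.4 umol/L).
#'
#' @param height Height (cm).
#' @param scr Serum creatinine (umol/L), > 0.
#' @param preterm Logical (or 0/1) preterm flag.
#' @return GFR in mL/min/1.73 m^2.
#' @examples
#' schwartz_gfr(49, 28.6, preterm = FALSE) # ~68.2
#' @export
schwartz_gfr <- function(height, scr, preterm = FALSE) {
  if (any(scr <= 0)) stop("`scr` must be positive", call. = FALSE)
  k <- ifelse(as.logical(preterm), 0.33, 0.45)
  k * height / (scr / 88.4)
}

#' Postmenstrual age
#'
#' Standard definition: gestational age plus postnatal age,
#' `PMA = GA + PNA/7` in weeks.
#'
#' @param ga_weeks Gestational age (weeks).
#' @param pna_days Postnatal age (days).
#' @return PMA in weeks.
#' @export
pma <- function(ga_weeks, pna_days) {
  ga_weeks + pna_days / 7
}
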