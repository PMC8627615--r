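# Longitudinal panel I/O and model-artifact serialisation.

panel_columns <- function() {
  c("person_id", "wave", "year", "state",
    paste0("med_", mets_components()), "lifestyle")
}

#' Construct a validated panel dataset
#'
#' A panel holds one row per person per observed examination wave, in
#' long format. Waves a person misses are simply absent: transitions are
#' only ever counted between consecutively observed waves, so gaps act
#' as censoring.
#'
#' @param records data.frame with columns `person_id`, `wave`
#'   (integer, 0-based), `year`, `state` (canonical label),
#'   `med_dyslipidemia`, `med_hyperglycemia`, `med_hypertension`,
#'   `med_obesity` (logical medication-use flags) and `lifestyle`
#'   (logical, lifestyle-intervention participant).
#' @param wave_years optional integer vector giving the calendar year of
#'   each wave index present; defaults to the years observed in
#'   `records`.
#' @return An object of class `mets_panel`: list with `records`,
#'   `n_waves` and `wave_years`.
#' @export
as_panel <- function(records, wave_years = NULL) {
  req <- panel_columns()
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L)
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  records <- records[req]
  records$wave <- as.integer(records$wave)
  bad <- which(!(records$state %in% state_labels()))
  if (length(bad) > 0L)
    stop(sprintf("unknown state label %s in row %d",
                 dQuote(records$state[bad[1L]], q = FALSE), bad[1L]))
  if (anyDuplicated(records[c("person_id", "wave")]) > 0L)
    stop("duplicated (person_id, wave) observations")
  for (cl in c(paste0("med_", mets_components()), "lifestyle"))
    records[[cl]] <- as.logical(records[[cl]])
  if (nrow(records) > 0L) {
    records <- records[order(records$person_id, records$wave), , drop = FALSE]
    rownames(records) <- NULL
  }
  waves <- if (nrow(records) > 0L) sort(unique(records$wave)) else integer(0)
  if (is.null(wave_years)) {
    wave_years <- vapply(waves, function(w)
      as.integer(records$year[records$wave == w][1L]), integer(1))
  }
  structure(list(records = records,
                 n_waves = length(waves),
                 wave_years = as.integer(wave_years)),
            class = "mets_panel")
}

#' @export
print.mets_panel <- function(x, ...) {
  cat(sprintf("MetS panel: %d records, %d persons, %d wave(s)\n",
              nrow(x$records), length(unique(x$records$person_id)), x$n_waves))
  if (x$n_waves > 0)
    cat("wave years:", paste(x$wave_years, collapse = ", "), "\n")
  invisible(x)
}

#' Read a longitudinal panel from CSV
#'
#' Expects the long ("tidy") layout written by [write_panel()]: header
#' row naming `person_id, wave, year, state, med_dyslipidemia,
#' med_hyperglycemia, med_hypertension, med_obesity, lifestyle`. Rows
#' whose state is not one of the 12 canonical labels are rejected with
#' an error naming the offending row.
#'
#' @param path file path.
#' @return A [as_panel()] object.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_panel(df)
}

#' Write a panel to CSV
#'
#' @param panel a `mets_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mets_panel"))
  utils::write.csv(panel$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a transition-probability matrix object
#'
#' @param p 12x12 numeric matrix, rows and columns in canonical state
#'   order; each row must be a probability distribution.
#' @param period_label free-text description of the period(s) the
#'   matrix was estimated from.
#' @param absorbing_applied logical; `TRUE` if the MetS row has been
#'   replaced by the absorbing unit vector.
#' @return Matrix of class `mets_tp` with canonical dimnames and the
#'   two metadata attributes.
#' @export
new_tp <- function(p, period_label = "", absorbing_applied = FALSE) {
  p <- as.matrix(p)
  labs <- state_labels()
  if (!all(dim(p) == c(12L, 12L)))
    stop("transition matrix must be 12x12")
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("transition probabilities must lie in [0, 1]")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition-matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  dimnames(p) <- list(labs, labs)
  structure(p, class = c("mets_tp", "matrix", "array"),
            period_label = period_label,
            absorbing_applied = isTRUE(absorbing_applied))
}

#' Write a transition matrix to CSV
#'
#' Probabilities are written as decimals to six places, with state
#' labels on rows and columns; [read_matrix()] reproduces the matrix to
#' within 1e-6.
#'
#' @param tp a `mets_tp` (or plain 12x12 row-stochastic matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(tp, path) {
  if (!inherits(tp, "mets_tp")) tp <- new_tp(tp)
  if (any(tp < 0)) stop("refusing to write matrix with negative cells")
  out <- format(round(unclass(tp), 6L), nsmall = 6L, trim = TRUE,
                scientific = FALSE)
  df <- data.frame(state = rownames(tp), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write matrix to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a transition matrix from CSV
#'
#' @param path file written by [write_matrix()].
#' @return A `mets_tp` matrix. Rows are re-normalised to sum exactly to
#'   1 to absorb the 6-decimal serialisation rounding.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!identical(rownames(m), state_labels()) ||
      !identical(colnames(m), state_labels()))
    stop("matrix file does not use the canonical 12-state ordering")
  new_tp(m / rowSums(m))
}

#' Write a trajectory to tidy CSV
#'
#' One row per (period, state): columns `period` (1-based), `year` (the
#' calendar year at the end of the period), `state`, `occupancy`
#' (persons in the state at the end of the period) and `rate_to_mets`
#' (new-MetS transitions per person-year at risk, for the cohort that
#' started the horizon in `state`).
#'
#' @param traj a `mets_trajectory` from [predict_markov()] or
#'   [simulate_msd()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mets_trajectory"))
  h <- traj$horizon
  if (h$n_periods < 1L) stop("trajectory must span at least one period")
  labs <- state_labels()
  df <- data.frame(
    period = rep(seq_len(h$n_periods), each = 12L),
    year = rep(h$period_years, each = 12L),
    state = rep(labs, times = h$n_periods),
    occupancy = as.vector(t(traj$occupancy[-1L, , drop = FALSE])),
    rate_to_mets = as.vector(t(traj$rate_to_mets)),
    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17L, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write trajectory to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a tidy trajectory CSV
#'
#' @param path file written by [write_trajectory()].
#' @return data.frame with columns `period`, `year`, `state`,
#'   `occupancy`, `rate_to_mets`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a control/failure rate table to JSON
#'
#' Serialises both the fraction and percent form of the per-tier
#' control (CR) and failure (FR) rates.
#'
#' @param rates a `mets_rates` from [estimate_cr_fr()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "mets_rates"))
  obj <- list(
    tier = c("no_component", "1_component", "2_component", "mets"),
    cr = unname(rates$cr), fr = unname(rates$fr),
    cr_percent = unname(round(rates$cr * 100, 2L)),
    fr_percent = unname(round(rates$fr * 100, 2L)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
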