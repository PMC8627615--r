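# 12-state MetS state space: component-count tiers, flow taxonomy, horizon.

#' Metabolic syndrome components
#'
#' The four defining components of metabolic syndrome: abdominal
#' obesity, hypertension, dyslipidemia (high triglycerides with low HDL)
#' and hyperglycemia. Returned in alphabetical order, which fixes the
#' canonical labelling of all composite states.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' mets_components()
mets_components <- function() {
  c("dyslipidemia", "hyperglycemia", "hypertension", "obesity")
}

#' Enumerate the 12-state MetS state space
#'
#' A person occupies, at any examination wave, one of 12 states defined
#' by which metabolic syndrome components are present: no component
#' (tier 0), one of the 4 isolated components (tier 1), one of the
#' C(4,2) = 6 component pairs (tier 2), or metabolic syndrome itself
#' (three or four components, tier 3, a single merged state). The order
#' is canonical — tier first, then alphabetical label — so that
#' transition matrices are comparable across runs.
#'
#' @param absorbing_mets logical; mark the MetS state as absorbing
#'   (default `TRUE`, the convention used by the Markov engine).
#' @return A data.frame with one row per state and columns
#'   `label` (snake_case, composite components joined alphabetically by
#'   `"+"`), `tier` (integer 0--3; 3 is MetS), `components`
#'   (list-column of character vectors) and `absorbing` (logical, only
#'   ever `TRUE` for MetS).
#' @export
#' @examples
#' s <- mets_states()
#' table(s$tier)       # 1 / 4 / 6 / 1
#' s$label[c(1, 12)]   # "no_component", "mets"
mets_states <- function(absorbing_mets = TRUE) {
  comps <- mets_components()
  pair_idx <- utils::combn(4L, 2L)
  pair_labels <- apply(pair_idx, 2L, function(j) paste(comps[j], collapse = "+"))
  labels <- c("no_component", comps, sort(pair_labels), "mets")
  tiers <- c(0L, rep(1L, 4L), rep(2L, 6L), 3L)
  component_sets <- c(
    list(character(0)),
    as.list(comps),
    lapply(sort(pair_labels), function(l) strsplit(l, "+", fixed = TRUE)[[1L]]),
    list(NA_character_)  # MetS: three or four components, not enumerated
  )
  out <- data.frame(label = labels, tier = tiers,
                    absorbing = c(rep(FALSE, 11L), isTRUE(absorbing_mets)),
                    stringsAsFactors = FALSE)
  out$components <- component_sets
  out
}

#' Canonical state labels
#'
#' @return Character vector of the 12 canonical state labels, in
#'   canonical order (tier, then alphabetical).
#' @export
state_labels <- function() mets_states()$label

#' State tiers in canonical order
#'
#' @return Integer vector of length 12: the component count of each
#'   canonical state (3 stands for MetS).
#' @export
state_tiers <- function() mets_states()$tier

#' Lateral (within-tier) state pairs
#'
#' Lateral transitions swap one component pattern for another with the
#' same component count: every unordered pair of tier-1 states and every
#' unordered pair of tier-2 states. There are C(4,2) = 6 such pairs in
#' tier 1 and C(6,2) = 15 in tier 2, 21 in total (42 directed
#' transitions).
#'
#' @return A data.frame with columns `from`, `to` (labels, `from` <
#'   `to` alphabetically) and `tier`.
#' @export
#' @examples
#' nrow(lateral_pairs())  # 21
lateral_pairs <- function() {
  s <- mets_states()
  res <- lapply(c(1L, 2L), function(k) {
    lab <- s$label[s$tier == k]
    idx <- utils::combn(length(lab), 2L)
    data.frame(from = lab[idx[1L, ]], to = lab[idx[2L, ]], tier = k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify a directed transition by flow kind
#'
#' Transitions between states fall into four kinds used by the
#' stock-and-flow engine: forward progression to a higher tier
#' (`"TPO_F"`, modulated by the failure rate), backward recovery to a
#' lower tier (`"TPO_B"`, modulated by the control rate), staying in
#' state (`"TPI"`, control-rate modulated), and lateral within-tier
#' conversion (`"TPW"`, unmodulated). The classification is total: every
#' ordered pair of canonical states maps to exactly one kind.
#'
#' @param origin,dest canonical state labels (vectorised).
#' @return Character vector of flow kinds.
#' @export
#' @examples
#' classify_flow("no_component", "mets")       # "TPO_F"
#' classify_flow("obesity", "hypertension")    # "TPW"
classify_flow <- function(origin, dest) {
  labs <- state_labels()
  tiers <- state_tiers()
  i <- match(origin, labs)
  j <- match(dest, labs)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(origin[is.na(i)], dest[is.na(j)]))
    stop("unknown state label(s): ", paste(bad, collapse = ", "))
  }
  ifelse(i == j, "TPI",
         ifelse(tiers[j] > tiers[i], "TPO_F",
                ifelse(tiers[j] < tiers[i], "TPO_B", "TPW")))
}

#' Prediction horizon
#'
#' A horizon of consecutive fixed-length periods, half-open on the
#' right: `[start_year, start_year + step_years)` and so on. The default
#' projection window used throughout is 2015--2036 in triennial steps,
#' i.e. 7 periods.
#'
#' @param start_year,end_year calendar years bounding the window.
#' @param step_years period length in years (default 3).
#' @return An object of class `mets_horizon`: a list with
#'   `start_year`, `end_year`, `step_years`, `n_periods` and
#'   `period_years` (the year at the *end* of each period).
#' @export
#' @examples
#' horizon(2015, 2036)$n_periods  # 7
horizon <- function(start_year, end_year, step_years = 3L) {
  stopifnot(is.numeric(start_year), is.numeric(end_year),
            is.numeric(step_years), step_years >= 1)
  if (end_year <= start_year)
    stop("end_year must be after start_year")
  n <- as.integer(floor((end_year - start_year) / step_years))
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 step_years = as.integer(step_years),
                 n_periods = n,
                 period_years = as.integer(start_year + step_years * seq_len(n))),
            class = "mets_horizon")
}

#' @export
print.mets_horizon <- function(x, ...) {
  cat(sprintf("Prediction horizon: %d-%d, %d periods of %d year(s)\n",
              x$start_year, x$end_year, x$n_periods, x$step_years))
  invisible(x)
}

# Index of the MetS state in canonical order.
mets_index <- function() 12L
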