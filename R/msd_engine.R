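# System-dynamics engine: per-tier control/failure rates estimated from
# intervention strata, a CR/FR-modulated flow network over the Markov
# transition matrix, and forward-Euler stock-and-flow simulation (one
# step per triennial period).

tier_names <- function() c("no_component", "one_component", "two_component", "mets")

#' Construct a control/failure rate table
#'
#' One control rate (CR) and one failure rate (FR) per tier. FR is the
#' fraction of at-risk person-transitions that progress to a higher
#' tier during a period; CR = 1 - FR counts staying and regressing as
#' "controlled". For the MetS tier only the regression (recovery) rate
#' is defined, reported as its CR; its FR is `NA`.
#'
#' @param cr,fr numeric vectors of length 4 (tiers 0, 1, 2, MetS);
#'   `fr[4]` must be `NA`.
#' @param enforce_complement require `cr + fr = 1` per tier (default).
#'   Disable only for deliberately degenerate tables, e.g. the
#'   all-ones identity modulation under which the stock-and-flow
#'   simulation reduces exactly to the Markov matrix-power prediction.
#' @return list of class `mets_rates` with named `cr` and `fr`.
#' @export
new_rates <- function(cr, fr, enforce_complement = TRUE) {
  stopifnot(length(cr) == 4L, length(fr) == 4L)
  if (!is.na(fr[4L])) stop("the MetS tier has no failure rate; fr[4] must be NA")
  both <- !is.na(cr[1:3]) & !is.na(fr[1:3])
  if (enforce_complement && any(abs(cr[1:3][both] + fr[1:3][both] - 1) > 1e-9))
    stop("cr + fr must equal 1 for tiers 0-2")
  ok <- c(cr, fr)
  if (any(ok < -1e-12 | ok > 1 + 1e-12, na.rm = TRUE))
    stop("rates must lie in [0, 1]")
  cr <- stats::setNames(as.numeric(cr), tier_names())
  fr <- stats::setNames(as.numeric(fr), tier_names())
  structure(list(cr = cr, fr = fr), class = "mets_rates")
}

#' @export
print.mets_rates <- function(x, ...) {
  m <- rbind(CR = x$cr * 100, FR = x$fr * 100)
  cat("Control and failure rates (%):\n")
  print(round(m, 2L))
  invisible(x)
}

#' Estimate per-tier control and failure rates from a panel
#'
#' For every consecutive wave pair and every tier k in \{0, 1, 2\},
#' FR_k is the fraction of persons occupying tier k whose next-wave
#' tier is higher; CR_k = 1 - FR_k. Rates are computed separately per
#' intervention stratum — `"lifestyle"` (lifestyle-intervention
#' participants) and `"medicinal"` (persons with any medication flag at
#' the origin wave) — with two exclusions: MetS occupants enter no CR
#' calculation except the MetS tier's own regression rate, and
#' no-component persons are excluded from the medicinal stratum (no
#' medication is indicated for healthy individuals). Stratum values are
#' combined by unweighted mean, then averaged over wave pairs. The MetS
#' tier's CR is the fraction of MetS occupants regressing to a lower
#' tier.
#'
#' @param panel a `mets_panel` with at least 2 waves.
#' @param strata `c("lifestyle", "medicinal")` (default), either one
#'   alone, or `"all"` to use every person without stratification (for
#'   panels lacking intervention flags).
#' @param stratum_weights `"equal"` (default, unweighted mean of
#'   stratum rates) or `"persons"` (weight strata by their at-risk
#'   counts).
#' @return A `mets_rates` with attributes `by_stratum` (stratum x tier
#'   FR array, averaged over wave pairs) and `n_wave_pairs`.
#' @export
estimate_cr_fr <- function(panel, strata = c("lifestyle", "medicinal"),
                           stratum_weights = c("equal", "persons")) {
  stopifnot(inherits(panel, "mets_panel"))
  stratum_weights <- match.arg(stratum_weights)
  if (panel$n_waves < 2L)
    stop("control/failure rates need at least two waves")
  tr <- panel_transitions(panel)
  if (nrow(tr) == 0L)
    stop("panel contains no observed transitions")
  r <- panel$records
  key <- paste(r$person_id, r$wave)
  origin <- match(paste(tr$person_id, tr$wave_from), key)
  tiers <- state_tiers()
  from_tier <- tiers[tr$from]
  to_tier <- tiers[tr$to]
  med_any <- Reduce(`|`, lapply(paste0("med_", mets_components()),
                                function(cl) r[[cl]][origin]))
  in_stratum <- list(
    lifestyle = r$lifestyle[origin] %in% TRUE,
    medicinal = med_any %in% TRUE & from_tier > 0L,  # healthy: no medication
    all = rep(TRUE, nrow(tr)))
  unknown <- setdiff(strata, names(in_stratum))
  if (length(unknown) > 0L)
    stop("unknown stratum: ", paste(unknown, collapse = ", "))

  pairs <- sort(unique(tr$wave_from))
  # fr_arr[pair, stratum, tier]: progression fraction (MetS slot holds
  # the regression fraction, i.e. the MetS CR)
  fr_arr <- array(NA_real_, c(length(pairs), length(strata), 4L),
                  dimnames = list(pairs, strata, tier_names()))
  n_arr <- array(0, dim(fr_arr), dimnames = dimnames(fr_arr))
  for (pi in seq_along(pairs)) {
    in_pair <- tr$wave_from == pairs[pi]
    for (si in seq_along(strata)) {
      sel <- in_pair & in_stratum[[strata[si]]]
      for (k in 0:2) {
        at_risk <- sel & from_tier == k
        if (any(at_risk)) {
          fr_arr[pi, si, k + 1L] <- mean(to_tier[at_risk] > k)
          n_arr[pi, si, k + 1L] <- sum(at_risk)
        }
      }
      in_mets <- sel & from_tier == 3L
      if (any(in_mets)) {
        fr_arr[pi, si, 4L] <- mean(to_tier[in_mets] < 3L)
        n_arr[pi, si, 4L] <- sum(in_mets)
      }
    }
  }
  # combine strata, then wave pairs
  combine <- function(v, w) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    if (stratum_weights == "persons") sum(v[ok] * w[ok]) / sum(w[ok])
    else mean(v[ok])
  }
  per_pair <- matrix(NA_real_, length(pairs), 4L)
  for (pi in seq_along(pairs)) for (tk in 1:4)
    per_pair[pi, tk] <- combine(fr_arr[pi, , tk], n_arr[pi, , tk])
  final <- colMeans(per_pair, na.rm = TRUE)
  final[is.nan(final)] <- NA_real_
  fr <- c(final[1:3], NA_real_)
  cr <- c(1 - final[1:3], final[4L])  # MetS slot already holds regression rate
  out <- new_rates(cr = cr, fr = fr)
  attr(out, "by_stratum") <- apply(fr_arr, c(2L, 3L), mean, na.rm = TRUE)
  attr(out, "n_wave_pairs") <- length(pairs)
  out
}

#' Build the CR/FR-modulated flow network
#'
#' One flow per nonzero transition-matrix cell, classified by
#' [classify_flow()]: forward flows (`TPO_F`) are modulated by the
#' origin tier's failure rate, backward flows (`TPO_B`) and
#' stay-in-state (`TPI`) by its control rate, lateral flows (`TPW`) are
#' unmodulated. MetS is treated as non-absorbing here: its recovery
#' flows carry the MetS control (regression) rate.
#'
#' @param tp a `mets_tp` matrix (pass a non-absorbing estimate;
#'   an absorbing MetS row simply yields no MetS outflows).
#' @param rates a `mets_rates`.
#' @return list of class `mets_flow_network`: `flows` (data.frame:
#'   `origin`, `dest`, `kind`, `base_tp`, `modulation`,
#'   `modulation_value`, `effective`), `rates`, `tp`.
#' @export
build_flow_network <- function(tp, rates) {
  if (!inherits(tp, "mets_tp")) tp <- new_tp(tp)
  stopifnot(inherits(rates, "mets_rates"))
  labs <- state_labels()
  tiers <- state_tiers()
  nz <- which(unclass(tp) > 0, arr.ind = TRUE)
  kind <- classify_flow(labs[nz[, 1L]], labs[nz[, 2L]])
  modulation <- c(TPO_F = "FR", TPO_B = "CR", TPI = "CR", TPW = "none")[kind]
  tier_of <- tiers[nz[, 1L]] + 1L
  mval <- ifelse(modulation == "FR", rates$fr[tier_of],
                 ifelse(modulation == "CR", rates$cr[tier_of], 1))
  flows <- data.frame(
    origin = labs[nz[, 1L]], dest = labs[nz[, 2L]], kind = kind,
    base_tp = unclass(tp)[nz], modulation = unname(modulation),
    modulation_value = unname(mval),
    effective = unclass(tp)[nz] * unname(mval),
    stringsAsFactors = FALSE)
  used <- flows$kind != "TPI"
  if (anyNA(flows$modulation_value[used]))
    stop("rate table lacks a value needed by the flow network")
  per_origin <- tapply(flows$effective[used], flows$origin[used], sum)
  if (any(per_origin > 1 + 1e-9))
    stop("modulated outflow exceeds 1 for state(s): ",
         paste(names(per_origin)[per_origin > 1 + 1e-9], collapse = ", "))
  structure(list(flows = flows, rates = rates, tp = tp),
            class = "mets_flow_network")
}

#' Write a flow network as an edge-list CSV
#'
#' @param network a `mets_flow_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flows <- function(network, path) {
  stopifnot(inherits(network, "mets_flow_network"))
  utils::write.csv(network$flows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Effective per-period stock-update matrix implied by the residual-mass
# closure: off-diagonal cells are the modulated flow fractions, the
# diagonal keeps whatever mass is not sent anywhere.
effective_matrix <- function(network) {
  labs <- state_labels()
  e <- matrix(0, 12L, 12L, dimnames = list(labs, labs))
  f <- network$flows
  off <- f$origin != f$dest
  e[cbind(match(f$origin[off], labs), match(f$dest[off], labs))] <-
    f$effective[off]
  diag(e) <- 1 - rowSums(e)
  if (any(diag(e) < -1e-9))
    stop("flow network sends more than the available mass out of a state")
  diag(e) <- pmax(diag(e), 0)
  e
}

#' Simulate the stock-and-flow MSD model
#'
#' Forward-Euler integration with one step per period. During a period
#' every state sends `N_origin * TP * m` persons along each flow, where
#' `m` is the origin tier's failure rate for forward flows, its control
#' rate for backward flows, and 1 for lateral flows; mass not sent
#' anywhere stays put (the residual closure, which conserves the
#' population and reduces to the pure Markov update when all rates are
#' 1). Progression rates toward MetS are the per-origin new-MetS flow
#' per person-year at risk, as in [predict_markov()].
#'
#' @param network a `mets_flow_network`.
#' @param initial non-negative 12-vector of persons per state.
#' @param hz a [horizon()].
#' @param substeps Euler sub-steps per period (default 1; larger values
#'   approximate the continuous-time flows more finely).
#' @return A `mets_trajectory`.
#' @export
simulate_msd <- function(network, initial, hz, substeps = 1L) {
  stopifnot(inherits(network, "mets_flow_network"),
            inherits(hz, "mets_horizon"))
  initial <- as.numeric(initial)
  if (length(initial) != 12L || any(initial < 0) || anyNA(initial))
    stop("initial must be a non-negative 12-vector")
  substeps <- as.integer(substeps)
  stopifnot(substeps >= 1L)
  e <- effective_matrix(network)
  # sub-stepping scales every flow by 1/substeps within a period
  es <- e / substeps
  diag(es) <- 1 - (rowSums(e) - diag(e)) / substeps
  m <- mets_index()
  n <- hz$n_periods
  occupancy <- matrix(0, n + 1L, 12L)
  occupancy[1L, ] <- initial
  rate <- matrix(0, n, 12L)
  occ <- initial
  unit <- diag(12L)  # per-origin cohort tracker
  for (t in seq_len(n)) {
    new_mets <- numeric(12L)
    at_risk <- 1 - unit[, m]
    for (s in seq_len(substeps)) {
      new_mets <- new_mets + as.vector(unit[, -m, drop = FALSE] %*% es[-m, m])
      occ <- as.vector(occ %*% es)
      unit <- unit %*% es
    }
    if (any(occ < -1e-9)) stop("negative occupancy during MSD integration")
    occ <- pmax(occ, 0)
    occupancy[t + 1L, ] <- occ
    rate[t, ] <- rate_rows(new_mets, at_risk, hz$step_years)
  }
  new_trajectory(hz, occupancy, rate, engine = "msd")
}

#' Fit and run the MSD engine on a panel
#'
#' Composition of the whole MSD pipeline: estimate the averaged
#' transition matrix (non-absorbing, so that the observed MetS
#' regression feeds the recovery flow), estimate the control/failure
#' rates, build the flow network, and simulate forward from the
#' last-wave state occupancy.
#'
#' @param panel a `mets_panel` with at least 2 waves.
#' @param hz a [horizon()].
#' @param strata passed to [estimate_cr_fr()].
#' @param rates optional `mets_rates` overriding the estimate.
#' @param substeps passed to [simulate_msd()].
#' @return A `mets_trajectory`.
#' @export
predict_msd <- function(panel, hz, strata = c("lifestyle", "medicinal"),
                        rates = NULL, substeps = 1L) {
  tp <- estimate_avg_tp(panel, absorbing = FALSE)
  if (is.null(rates)) rates <- estimate_cr_fr(panel, strata = strata)
  network <- build_flow_network(tp, rates)
  last_wave <- max(panel$records$wave)
  initial <- as.numeric(table(factor(
    panel$records$state[panel$records$wave == last_wave],
    levels = state_labels())))
  simulate_msd(network, initial, hz, substeps = substeps)
}
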