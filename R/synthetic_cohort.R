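# Synthetic TLGS-like cohort generator with known ground truth.
#
# The generator exists so that estimation, simulation and validation can
# be exercised against a known truth: wave-0 states are drawn from a
# baseline prevalence vector, later states from a known transition
# matrix, with an optional person-level intervention effect (treated
# persons get their backward-transition probabilities inflated by a
# multiplier, row re-normalised).

#' Tier-structured default transition matrix
#'
#' A plausible generating matrix for the synthetic cohort: strong
#' forward pull from low tiers (the dominant moves out of
#' `no_component` are into isolated components), moderate lateral
#' mixing, modest recovery, and a MetS row that keeps 60% in place and
#' regresses the rest — matching the observed magnitudes of stay-in-MetS
#' (~0.6) and MetS regression (~0.4) in the TLGS cohort. Rows sum to 1
#' exactly by construction (the stay probability takes the remainder).
#'
#' @param absorbing_mets logical; if `TRUE` the MetS row is the
#'   absorbing unit vector instead of the regressing row.
#' @return A `mets_tp` matrix.
#' @export
default_true_tp <- function(absorbing_mets = FALSE) {
  s <- mets_states()
  labs <- s$label
  tiers <- s$tier
  p <- matrix(0, 12L, 12L, dimnames = list(labs, labs))
  comp_sets <- s$components

  # tier 0: forward-dominated
  p["no_component", tiers == 1L] <- 0.10
  p["no_component", tiers == 2L] <- 0.012
  p["no_component", "mets"] <- 0.028

  for (i in which(tiers == 1L)) {
    ci <- comp_sets[[i]]
    supersets <- which(tiers == 2L &
                         vapply(comp_sets, function(cs) ci %in% cs, logical(1)))
    p[i, "no_component"] <- 0.15
    p[i, tiers == 1L] <- 0.02        # lateral (diagonal overwritten below)
    p[i, supersets] <- 0.09
    p[i, "mets"] <- 0.07
  }
  for (i in which(tiers == 2L)) {
    ci <- comp_sets[[i]]
    subsets <- which(tiers == 1L & labs %in% ci)
    p[i, "no_component"] <- 0.01
    p[i, subsets] <- 0.06
    p[i, tiers == 2L] <- 0.022       # lateral
    p[i, "mets"] <- 0.36
  }
  if (absorbing_mets) {
    p["mets", ] <- 0
    p["mets", "mets"] <- 1
  } else {
    p["mets", "no_component"] <- 0.01
    p["mets", tiers == 1L] <- 0.03
    p["mets", tiers == 2L] <- 0.045
  }
  diag(p) <- 0
  diag(p) <- 1 - rowSums(p)
  new_tp(p, period_label = "synthetic truth",
         absorbing_applied = absorbing_mets)
}

#' Default synthetic-cohort configuration
#'
#' Defaults emulate the structure of the TLGS cohort: 12,882 persons
#' followed over five examination waves spanning 16 years
#' (approximately triennial), with baseline state prevalences taken
#' from the published baseline counts ([tlgs_state_counts()],
#' normalised), a tier-structured generating matrix
#' ([default_true_tp()]), per-component medication flags and a
#' lifestyle-intervention subgroup whose backward (recovery)
#' transition probabilities are inflated.
#'
#' @param n_people cohort size (default 12,882).
#' @param n_waves number of examination waves (default 5).
#' @param wave_years calendar year of each wave; default
#'   `1999, 2003, ...` (approximately-triennial TLGS-like spacing).
#' @param baseline_prevalence probability vector over the 12 canonical
#'   states (must sum to 1 within 1e-9).
#' @param true_tp generating `mets_tp` transition matrix.
#' @param med_assignment_prob probability that a present component
#'   carries a medication flag at a wave.
#' @param lifestyle_prob probability a person belongs to the
#'   lifestyle-intervention subgroup.
#' @param intervention_regress_multiplier multiplier (> 0) applied to
#'   backward-transition probabilities for lifestyle-intervention
#'   persons; rows re-normalised. 1 disables the effect.
#' @param seed integer RNG seed.
#' @return list of class `mets_cohort_config`.
#' @export
cohort_config <- function(n_people = 12882L,
                          n_waves = 5L,
                          wave_years = NULL,
                          baseline_prevalence = NULL,
                          true_tp = default_true_tp(),
                          med_assignment_prob = 0.3,
                          lifestyle_prob = 0.2,
                          intervention_regress_multiplier = 1.5,
                          seed = 1L) {
  if (is.null(baseline_prevalence)) {
    counts <- tlgs_state_counts()$baseline
    baseline_prevalence <- counts / sum(counts)
  }
  if (is.null(wave_years))
    wave_years <- 1999L + 4L * (seq_len(n_waves) - 1L)
  cfg <- structure(list(
    n_people = as.integer(n_people),
    n_waves = as.integer(n_waves),
    wave_years = as.integer(wave_years[seq_len(n_waves)]),
    baseline_prevalence = baseline_prevalence,
    true_tp = if (inherits(true_tp, "mets_tp")) true_tp else new_tp(true_tp),
    med_assignment_prob = med_assignment_prob,
    lifestyle_prob = lifestyle_prob,
    intervention_regress_multiplier = intervention_regress_multiplier,
    seed = as.integer(seed)), class = "mets_cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_people < 1L) stop("n_people must be positive")
  if (cfg$n_waves < 1L) stop("n_waves must be positive")
  if (length(cfg$wave_years) != cfg$n_waves || anyNA(cfg$wave_years))
    stop("wave_years must supply one calendar year per wave")
  bp <- cfg$baseline_prevalence
  if (length(bp) != 12L || any(bp < 0))
    stop("baseline_prevalence must be a non-negative 12-vector")
  if (abs(sum(bp) - 1) > 1e-9)
    stop("baseline_prevalence must sum to 1")
  if (!is.numeric(cfg$intervention_regress_multiplier) ||
      cfg$intervention_regress_multiplier <= 0)
    stop("intervention_regress_multiplier must be positive")
  for (pr in c(cfg$med_assignment_prob, cfg$lifestyle_prob))
    if (pr < 0 || pr > 1) stop("probabilities must lie in [0, 1]")
  invisible(cfg)
}

# Backward-inflated, row-renormalised matrix for treated persons.
treated_tp <- function(tp, multiplier) {
  tiers <- state_tiers()
  p <- unclass(tp)
  for (i in seq_len(12L)) {
    back <- tiers < tiers[i]
    p[i, back] <- p[i, back] * multiplier
  }
  p / rowSums(p)
}

# Population mixture matrix and the per-tier control/failure rates it
# implies, weighting states within a tier by baseline prevalence.
true_rates <- function(cfg) {
  pmix <- (1 - cfg$lifestyle_prob) * unclass(cfg$true_tp) +
    cfg$lifestyle_prob * treated_tp(cfg$true_tp, cfg$intervention_regress_multiplier)
  tiers <- state_tiers()
  w <- cfg$baseline_prevalence
  fr <- rep(NA_real_, 4L)
  cr <- rep(NA_real_, 4L)
  for (k in 0:2) {
    rows <- which(tiers == k)
    fwd <- pmix[rows, tiers > k, drop = FALSE]
    fr[k + 1L] <- sum(w[rows] * rowSums(fwd)) / sum(w[rows])
    cr[k + 1L] <- 1 - fr[k + 1L]
  }
  cr[4L] <- sum(pmix[mets_index(), tiers < 3L])  # MetS regression rate
  new_rates(cr = cr, fr = fr)
}

#' Generate a synthetic cohort panel with known ground truth
#'
#' Wave-0 states are drawn from the baseline prevalence; each later
#' state from the person's transition-matrix row (the backward-inflated
#' matrix for lifestyle-intervention persons). Medication flags are
#' drawn per present component at every wave (MetS occupants are
#' treated as carrying all four components). Random draws are ordered
#' person-major, then wave-major, so enlarging the cohort does not
#' perturb earlier persons' trajectories; identical seeds give
#' identical datasets.
#'
#' @param cfg a [cohort_config()].
#' @return list with elements `panel` (a `mets_panel`) and `truth`
#'   (list: `true_tp`, `treated_tp`, `mixture_tp`, `rates` — the
#'   per-tier control/failure rates implied by the mixture matrix and
#'   baseline prevalence weights).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_people = 50, seed = 7))
#' cohort$panel
generate_cohort <- function(cfg) {
  validate_cohort_config(cfg)
  labs <- state_labels()
  comps <- mets_components()
  s <- mets_states()
  # component membership per state; MetS counts as all four
  comp_in_state <- matrix(FALSE, 12L, 4L, dimnames = list(labs, comps))
  for (i in seq_len(11L)) comp_in_state[i, unlist(s$components[i])] <- TRUE
  comp_in_state[12L, ] <- TRUE

  base_cum <- t(apply(unclass(cfg$true_tp), 1L, cumsum))
  trt_cum <- t(apply(treated_tp(cfg$true_tp, cfg$intervention_regress_multiplier),
                     1L, cumsum))
  prev_cum <- cumsum(cfg$baseline_prevalence)

  n <- cfg$n_people * cfg$n_waves
  person <- integer(n); wave <- integer(n); state <- integer(n)
  meds <- matrix(FALSE, n, 4L); life <- logical(n)

  set.seed(cfg$seed)
  row <- 0L
  for (pid in seq_len(cfg$n_people)) {
    treated <- stats::runif(1L) < cfg$lifestyle_prob
    cum <- if (treated) trt_cum else base_cum
    st <- findInterval(stats::runif(1L), prev_cum) + 1L
    for (w in seq_len(cfg$n_waves) - 1L) {
      row <- row + 1L
      person[row] <- pid; wave[row] <- w; state[row] <- st; life[row] <- treated
      present <- comp_in_state[st, ]
      if (any(present))
        meds[row, present] <- stats::runif(sum(present)) < cfg$med_assignment_prob
      if (w < cfg$n_waves - 1L)
        st <- findInterval(stats::runif(1L), cum[st, ]) + 1L
    }
  }

  records <- data.frame(
    person_id = sprintf("p%06d", person),
    wave = wave,
    year = cfg$wave_years[wave + 1L],
    state = labs[state],
    stringsAsFactors = FALSE)
  for (j in seq_len(4L)) records[[paste0("med_", comps[j])]] <- meds[, j]
  records$lifestyle <- life

  list(panel = as_panel(records, wave_years = cfg$wave_years),
       truth = list(
         true_tp = cfg$true_tp,
         treated_tp = new_tp(treated_tp(cfg$true_tp,
                                        cfg$intervention_regress_multiplier),
                             period_label = "synthetic truth (treated)"),
         mixture_tp = new_tp(
           (1 - cfg$lifestyle_prob) * unclass(cfg$true_tp) +
             cfg$lifestyle_prob * treated_tp(cfg$true_tp,
                                             cfg$intervention_regress_multiplier),
           period_label = "synthetic truth (population mixture)"),
         rates = true_rates(cfg)))
}
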