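# Discrete-time Markov engine: count-based TP estimation per triennial
# wave pair, period averaging with absorbing MetS, matrix-power
# prediction, and person-resampling bootstrap SEs.

# Person-level transition list: one row per pair of consecutively
# observed waves (wave, wave+1). Gaps censor: a person seen at waves 0
# and 2 contributes no transition to either pair.
panel_transitions <- function(panel) {
  stopifnot(inherits(panel, "mets_panel"))
  r <- panel$records
  if (nrow(r) < 2L)
    return(data.frame(person_id = character(0), wave_from = integer(0),
                      from = integer(0), to = integer(0)))
  same_person <- r$person_id[-nrow(r)] == r$person_id[-1L]
  consecutive <- r$wave[-1L] - r$wave[-nrow(r)] == 1L
  i <- which(same_person & consecutive)
  st <- match(r$state, state_labels())
  data.frame(person_id = r$person_id[i], wave_from = r$wave[i],
             from = st[i], to = st[i + 1L], stringsAsFactors = FALSE)
}

#' Count observed transitions between two consecutive waves
#'
#' `counts[i, j]` is the number of persons observed in state `i` at
#' `wave_from` and state `j` at `wave_from + 1`. Persons missing either
#' wave are excluded (censoring between observed waves).
#'
#' @param panel a `mets_panel`.
#' @param wave_from 0-based index of the origin wave; both `wave_from`
#'   and `wave_from + 1` must occur in the panel.
#' @return 12x12 integer matrix of class `mets_counts` with attribute
#'   `period = c(wave_from, wave_from + 1)`.
#' @export
count_transitions <- function(panel, wave_from) {
  stopifnot(inherits(panel, "mets_panel"))
  wave_from <- as.integer(wave_from)
  waves <- sort(unique(panel$records$wave))
  if (!(wave_from %in% waves) || !((wave_from + 1L) %in% waves))
    stop("waves ", wave_from, " and ", wave_from + 1L,
         " must both be present in the panel")
  tr <- panel_transitions(panel)
  tr <- tr[tr$wave_from == wave_from, , drop = FALSE]
  labs <- state_labels()
  counts <- table(factor(tr$from, levels = 1:12),
                  factor(tr$to, levels = 1:12))
  counts <- matrix(as.integer(counts), 12L, 12L, dimnames = list(labs, labs))
  structure(counts, class = c("mets_counts", "matrix", "array"),
            period = c(wave_from, wave_from + 1L))
}

#' Estimate a transition-probability matrix from counts
#'
#' Row-normalises the transition counts: `p[i, j] = counts[i, j] /
#' rowsum(i)`. A state with no one at risk (all-zero row) gets the
#' identity row (stay with probability 1) so the matrix remains
#' row-stochastic.
#'
#' @param counts a `mets_counts` matrix from [count_transitions()].
#' @return A `mets_tp` matrix.
#' @export
estimate_tp <- function(counts) {
  m <- unclass(counts)
  stopifnot(all(dim(m) == c(12L, 12L)), all(m >= 0))
  rs <- rowSums(m)
  p <- matrix(0, 12L, 12L)
  for (i in seq_len(12L)) {
    if (rs[i] > 0) p[i, ] <- m[i, ] / rs[i] else p[i, i] <- 1
  }
  period <- attr(counts, "period")
  new_tp(p, period_label = if (!is.null(period))
    sprintf("wave %d-%d", period[1L], period[2L]) else "")
}

#' Average per-period transition matrices into a final matrix
#'
#' Elementwise arithmetic mean of the per-period matrices, rows
#' re-normalised to sum to 1. With `absorbing = TRUE` the MetS row is
#' then replaced by the absorbing unit vector: once in MetS, no
#' transition out — the Markov engine's convention for the final
#' matrix.
#'
#' @param matrices non-empty list of `mets_tp` matrices.
#' @param absorbing logical (default `TRUE`).
#' @return A `mets_tp` matrix.
#' @export
average_tp <- function(matrices, absorbing = TRUE) {
  if (length(matrices) == 0L) stop("need at least one matrix to average")
  m <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  m <- m / rowSums(m)
  if (absorbing) {
    m[mets_index(), ] <- 0
    m[mets_index(), mets_index()] <- 1
  }
  new_tp(m, period_label = sprintf("average of %d period(s)", length(matrices)),
         absorbing_applied = absorbing)
}

#' Estimate the averaged transition matrix from a panel
#'
#' Convenience composition: [count_transitions()] and [estimate_tp()]
#' for every consecutive wave pair in the panel, then [average_tp()].
#'
#' @param panel a `mets_panel` with at least 2 waves.
#' @param absorbing passed to [average_tp()].
#' @return A `mets_tp` matrix.
#' @export
estimate_avg_tp <- function(panel, absorbing = TRUE) {
  waves <- sort(unique(panel$records$wave))
  if (length(waves) < 2L)
    stop("panel must contain at least two waves to estimate transitions")
  pairs <- waves[-length(waves)][waves[-1L] - waves[-length(waves)] == 1L]
  if (length(pairs) == 0L)
    stop("panel has no pair of consecutive waves")
  mats <- lapply(pairs, function(w) estimate_tp(count_transitions(panel, w)))
  average_tp(mats, absorbing = absorbing)
}

#' n-step transition matrix
#'
#' Returns `P^n` by repeated squaring; `P^0` is the identity. The
#' `(i, j)` element of `P^n` is the probability of occupying state `j`
#' exactly `n` periods after starting in state `i`.
#'
#' @param tp a `mets_tp` (or row-stochastic 12x12 matrix).
#' @param n non-negative integer number of steps.
#' @return A `mets_tp` matrix.
#' @export
n_step <- function(tp, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("n must be a single non-negative integer")
  p <- unclass(if (inherits(tp, "mets_tp")) tp else new_tp(tp))
  result <- diag(12L)
  n <- as.integer(n)
  while (n > 0L) {
    if (n %% 2L == 1L) result <- result %*% p
    p <- p %*% p
    n <- n %/% 2L
  }
  result <- result / rowSums(result)  # absorb floating-point drift
  new_tp(result, period_label = attr(tp, "period_label"),
         absorbing_applied = isTRUE(attr(tp, "absorbing_applied")))
}

new_trajectory <- function(hz, occupancy, rate_to_mets, engine) {
  labs <- state_labels()
  dimnames(occupancy) <- list(c(hz$start_year, hz$period_years), labs)
  dimnames(rate_to_mets) <- list(hz$period_years, labs)
  structure(list(horizon = hz, occupancy = occupancy,
                 rate_to_mets = rate_to_mets, engine = engine),
            class = "mets_trajectory")
}

#' @export
print.mets_trajectory <- function(x, ...) {
  cat(sprintf("MetS trajectory (%s engine): %d period(s), %d-%d\n",
              x$engine, x$horizon$n_periods, x$horizon$start_year,
              x$horizon$end_year))
  cat(sprintf("final MetS occupancy: %.1f of %.1f persons\n",
              x$occupancy[nrow(x$occupancy), mets_index()],
              sum(x$occupancy[1L, ])))
  invisible(x)
}

# Per-origin progression rates toward MetS shared by both engines:
# rate[t, i] = new MetS entries during period t, for a cohort started in
# state i, divided by at-risk person-years (non-MetS occupancy at the
# start of the period times the period length). The MetS origin row is 0
# by convention.
rate_rows <- function(new_mets, at_risk, step_years) {
  rate <- ifelse(at_risk > 0, new_mets / (at_risk * step_years), 0)
  rate[mets_index()] <- 0
  rate
}

#' Predict occupancies and progression rates with the Markov engine
#'
#' Occupancy after `t` periods is `initial %*% P^t`. The per-origin
#' progression rate toward MetS in period `t` is the number of new MetS
#' entries during the period — for a cohort that started the horizon in
#' the origin state — per person-year at risk, person-years being the
#' cohort's non-MetS occupancy at the start of the period times the
#' period length. With an absorbing MetS these curves rise and then
#' flatten to a common quasi-stationary level.
#'
#' @param tp a `mets_tp` matrix.
#' @param initial non-negative 12-vector of persons per state at the
#'   start of the horizon.
#' @param hz a [horizon()].
#' @return A `mets_trajectory`: `occupancy` is `(n_periods + 1) x 12`
#'   (row 1 = initial), `rate_to_mets` is `n_periods x 12` per-origin
#'   rates in events per person-year.
#' @export
#' @examples
#' tp <- default_true_tp(absorbing_mets = TRUE)
#' tr <- predict_markov(tp, rep(1000, 12), horizon(2015, 2036, 3))
#' tr
predict_markov <- function(tp, initial, hz) {
  if (!inherits(tp, "mets_tp")) tp <- new_tp(tp)
  stopifnot(inherits(hz, "mets_horizon"))
  initial <- as.numeric(initial)
  if (length(initial) != 12L || any(initial < 0) || anyNA(initial))
    stop("initial must be a non-negative 12-vector")
  p <- unclass(tp)
  m <- mets_index()
  n <- hz$n_periods
  occupancy <- matrix(0, n + 1L, 12L)
  occupancy[1L, ] <- initial
  rate <- matrix(0, n, 12L)
  pt_prev <- diag(12L)  # P^(t-1), per-origin cohort distribution
  occ <- initial
  for (t in seq_len(n)) {
    occ <- as.vector(occ %*% p)
    occupancy[t + 1L, ] <- occ
    new_mets <- as.vector(pt_prev[, -m, drop = FALSE] %*% p[-m, m])
    at_risk <- 1 - pt_prev[, m]
    rate[t, ] <- rate_rows(new_mets, at_risk, hz$step_years)
    pt_prev <- pt_prev %*% p
  }
  new_trajectory(hz, occupancy, rate, engine = "markov")
}

#' Bootstrap standard errors for the averaged transition matrix
#'
#' Persons (not records) are resampled with replacement; the averaged
#' transition matrix is re-estimated for each replicate and the
#' elementwise standard deviation across replicates is reported, the
#' usual bootstrap SE for panel-estimated transition probabilities.
#'
#' @param panel a `mets_panel` with at least 2 persons and 2 waves.
#' @param n_iter number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @param absorbing passed to the averaged-matrix estimator.
#' @return list of class `mets_bootstrap`: `se` (12x12 matrix),
#'   `n_iterations`, `seed`.
#' @export
bootstrap_se <- function(panel, n_iter = 1000L, seed = 1L, absorbing = TRUE) {
  stopifnot(inherits(panel, "mets_panel"))
  if (n_iter < 2L) stop("n_iter must be at least 2")
  persons <- unique(panel$records$person_id)
  np <- length(persons)
  if (np < 2L) stop("bootstrap needs at least 2 persons")
  tr <- panel_transitions(panel)
  if (nrow(tr) == 0L) stop("panel contains no observed transitions")
  pairs <- sort(unique(tr$wave_from))
  k <- length(pairs)
  pidx <- match(tr$person_id, persons)
  cell <- (match(tr$wave_from, pairs) - 1L) * 144L +
    (tr$from - 1L) * 12L + tr$to  # flat index over (pair, from, to)
  m <- mets_index()

  set.seed(seed)
  reps <- matrix(0, n_iter, 144L)
  for (b in seq_len(n_iter)) {
    wt <- tabulate(sample.int(np, np, replace = TRUE), nbins = np)
    tot <- numeric(144L * k)
    agg <- rowsum(wt[pidx], cell)
    tot[as.integer(rownames(agg))] <- agg
    acc <- matrix(0, 12L, 12L)
    for (j in seq_len(k)) {
      cm <- matrix(tot[((j - 1L) * 144L + 1L):(j * 144L)], 12L, 12L,
                   byrow = TRUE)
      rs <- rowSums(cm)
      pm <- cm / ifelse(rs > 0, rs, 1)
      diag(pm)[rs == 0] <- 1
      acc <- acc + pm
    }
    acc <- acc / k
    acc <- acc / rowSums(acc)
    if (absorbing) {
      acc[m, ] <- 0
      acc[m, m] <- 1
    }
    reps[b, ] <- acc
  }
  se <- matrix(apply(reps, 2L, stats::sd), 12L, 12L,
               dimnames = list(state_labels(), state_labels()))
  structure(list(se = se, n_iterations = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "mets_bootstrap")
}
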