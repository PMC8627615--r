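# Hold-one-wave-out validation and the model-comparison protocol:
# mean difference, mean SE of paired differences, two-sample
# Kolmogorov-Smirnov, and R-squared from a simple linear regression of
# actual on predicted.

#' Hold out the last wave and predict it
#'
#' Fits the chosen engine on all waves but the last and predicts the
#' held-out wave: the comparison cohort is every person observed at
#' both the last fitted wave and the held-out wave, so predicted and
#' actual occupancies count the same people. Returns the predicted and
#' actual occupancy vectors together with the predicted one-step
#' transition matrix and the matrix actually observed over the held-out
#' transition.
#'
#' @param panel a `mets_panel` with at least 3 waves.
#' @param engine `"markov"` (averaged matrix, absorbing MetS by
#'   default) or `"msd"` (CR/FR-modulated flows, non-absorbing MetS).
#' @param absorbing absorbing-MetS flag for the Markov engine.
#' @param strata,rates passed to [estimate_cr_fr()] for the MSD engine.
#' @return list of class `mets_holdout`: `engine`,
#'   `predicted_occupancy`, `actual_occupancy` (12-vectors),
#'   `predicted_matrix`, `actual_matrix` (`mets_tp`), `holdout_wave`.
#' @export
holdout_predict <- function(panel, engine = c("markov", "msd"),
                            absorbing = TRUE,
                            strata = c("lifestyle", "medicinal"),
                            rates = NULL) {
  stopifnot(inherits(panel, "mets_panel"))
  engine <- match.arg(engine)
  waves <- sort(unique(panel$records$wave))
  if (length(waves) < 3L)
    stop("hold-out validation needs at least 3 waves")
  w_hold <- waves[length(waves)]
  w_last_fit <- waves[length(waves) - 1L]
  if (w_hold - w_last_fit != 1L)
    stop("the last two waves must be consecutive to validate a one-step prediction")
  fit_records <- panel$records[panel$records$wave < w_hold, , drop = FALSE]
  fit_panel <- as_panel(fit_records,
                        wave_years = panel$wave_years[seq_len(length(waves) - 1L)])

  # cohort observed at both the last fitted wave and the held-out wave
  r <- panel$records
  at_fit <- r[r$wave == w_last_fit, c("person_id", "state")]
  at_hold <- r[r$wave == w_hold, c("person_id", "state")]
  cohort <- intersect(at_fit$person_id, at_hold$person_id)
  if (length(cohort) == 0L) stop("no person observed at both final waves")
  labs <- state_labels()
  occ_of <- function(states) as.numeric(table(factor(states, levels = labs)))
  initial <- occ_of(at_fit$state[match(cohort, at_fit$person_id)])
  actual <- occ_of(at_hold$state[match(cohort, at_hold$person_id)])

  step <- if (length(panel$wave_years) >= 2L)
    max(1L, diff(panel$wave_years)[length(waves) - 1L]) else 3L
  one_period <- horizon(0L, step, step)
  if (engine == "markov") {
    tp <- estimate_avg_tp(fit_panel, absorbing = absorbing)
    predicted <- as.vector(initial %*% unclass(tp))
    pred_matrix <- tp
  } else {
    tp <- estimate_avg_tp(fit_panel, absorbing = FALSE)
    if (is.null(rates)) rates <- estimate_cr_fr(fit_panel, strata = strata)
    network <- build_flow_network(tp, rates)
    pred_matrix <- new_tp(effective_matrix(network),
                          period_label = "MSD effective one-step matrix")
    predicted <- simulate_msd(network, initial, one_period)$occupancy[2L, ]
  }
  actual_matrix <- estimate_tp(count_transitions(panel, w_last_fit))
  structure(list(engine = engine,
                 predicted_occupancy = stats::setNames(predicted, labs),
                 actual_occupancy = stats::setNames(actual, labs),
                 predicted_matrix = pred_matrix,
                 actual_matrix = actual_matrix,
                 holdout_wave = w_hold),
            class = "mets_holdout")
}

#' Mean of paired differences
#'
#' Arithmetic mean of `predicted - actual`; positive values indicate
#' overestimation.
#'
#' @param predicted,actual numeric vectors of equal length.
#' @return scalar.
#' @export
mean_difference <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(predicted) < 1L)
    stop("predicted and actual must have equal, positive length")
  mean(predicted - actual)
}

#' Standard error of paired differences
#'
#' `sd(predicted - actual) / sqrt(n)` with the usual n-1 denominator in
#' the standard deviation.
#'
#' @param predicted,actual numeric vectors of equal length >= 2.
#' @return scalar.
#' @export
mean_se <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  if (length(predicted) < 2L)
    stop("standard error needs at least 2 pairs")
  stats::sd(predicted - actual) / sqrt(length(predicted))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the empirical distributions of the predicted and actual
#' value sets with the asymptotic two-sample KS test. With the small
#' sample sizes typical here (12 occupancy values) the asymptotic
#' p-value is approximate.
#'
#' @param predicted,actual non-empty numeric vectors.
#' @return list with `statistic` (D) and `pvalue`.
#' @export
ks_two_sample <- function(predicted, actual) {
  if (length(predicted) < 1L || length(actual) < 1L)
    stop("both value sets must be non-empty")
  res <- suppressWarnings(stats::ks.test(predicted, actual, exact = FALSE))
  list(statistic = unname(res$statistic), pvalue = unname(res$p.value))
}

#' R-squared of actual regressed on predicted
#'
#' Coefficient of determination from the ordinary least-squares fit
#' `actual ~ predicted`.
#'
#' @param predicted,actual numeric vectors of equal length >= 3;
#'   `predicted` must not be constant.
#' @return scalar in \[0, 1\].
#' @export
r_squared <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(predicted) < 3L)
    stop("R-squared needs at least 3 pairs of equal length")
  if (stats::sd(predicted) == 0)
    stop("predicted values are constant; the regression fit is undefined")
  fit <- stats::lm(actual ~ predicted)
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}

validation_report <- function(holdout, basis = c("cells", "occupancy")) {
  basis <- match.arg(basis)
  if (basis == "cells") {
    pred_md <- as.vector(unclass(holdout$predicted_matrix))
    act_md <- as.vector(unclass(holdout$actual_matrix))
  } else {
    pred_md <- holdout$predicted_occupancy
    act_md <- holdout$actual_occupancy
  }
  ks <- ks_two_sample(holdout$predicted_occupancy, holdout$actual_occupancy)
  list(engine = holdout$engine,
       comparison_basis = basis,
       mean_difference = mean_difference(pred_md, act_md),
       mean_se = mean_se(pred_md, act_md),
       ks_statistic = ks$statistic,
       ks_pvalue = ks$pvalue,
       r_squared = r_squared(holdout$predicted_occupancy,
                             holdout$actual_occupancy))
}

#' Compare the Markov and MSD engines on a hold-out wave
#'
#' Runs [holdout_predict()] for both engines and scores four criteria:
#' smaller absolute mean difference, smaller mean SE (both over the 144
#' transition-matrix cells by default), larger KS p-value and larger
#' R-squared (both over the 12 occupancy values). The engine winning at
#' least three criteria is reported as the overall winner.
#'
#' @param panel a `mets_panel` with at least 3 waves.
#' @param basis `"cells"` (default) or `"occupancy"`: which paired
#'   values feed the mean difference and mean SE.
#' @param absorbing absorbing-MetS flag for the Markov engine.
#' @param strata passed to the MSD engine's rate estimator.
#' @return list of class `mets_comparison`: `markov` and `msd`
#'   validation reports, `winner` (named character vector per
#'   criterion), `overall`.
#' @export
compare_models <- function(panel, basis = c("cells", "occupancy"),
                           absorbing = TRUE,
                           strata = c("lifestyle", "medicinal")) {
  basis <- match.arg(basis)
  h_markov <- holdout_predict(panel, "markov", absorbing = absorbing)
  h_msd <- holdout_predict(panel, "msd", strata = strata)
  rep_markov <- validation_report(h_markov, basis)
  rep_msd <- validation_report(h_msd, basis)
  pick <- function(markov_val, msd_val, larger_wins) {
    if (abs(markov_val - msd_val) <=
        1e-9 * max(1, abs(markov_val), abs(msd_val))) return("tie")
    better_msd <- if (larger_wins) msd_val > markov_val else msd_val < markov_val
    if (better_msd) "msd" else "markov"
  }
  winner <- c(
    mean_difference = pick(abs(rep_markov$mean_difference),
                           abs(rep_msd$mean_difference), FALSE),
    mean_se = pick(rep_markov$mean_se, rep_msd$mean_se, FALSE),
    ks_pvalue = pick(rep_markov$ks_pvalue, rep_msd$ks_pvalue, TRUE),
    r_squared = pick(rep_markov$r_squared, rep_msd$r_squared, TRUE))
  tally <- table(factor(winner, levels = c("markov", "msd", "tie")))
  overall <- if (tally[["msd"]] > tally[["markov"]]) "msd"
  else if (tally[["markov"]] > tally[["msd"]]) "markov" else "tie"
  structure(list(markov = rep_markov, msd = rep_msd,
                 winner = winner, overall = overall),
            class = "mets_comparison")
}

#' @export
print.mets_comparison <- function(x, ...) {
  fmt <- function(r) sprintf(
    "  %-6s mean_diff=%+.5f mean_se=%.6f ks_p=%.3f R2=%.3f",
    r$engine, r$mean_difference, r$mean_se, r$ks_pvalue, r$r_squared)
  cat("Engine comparison (basis:", x$markov$comparison_basis, "for diff/SE)\n")
  cat(fmt(x$markov), "\n"); cat(fmt(x$msd), "\n")
  cat("criterion winners:",
      paste(names(x$winner), x$winner, sep = "=", collapse = ", "), "\n")
  cat("overall:", x$overall, "\n")
  invisible(x)
}

#' Write a pair of validation reports as JSON
#'
#' @param comparison a `mets_comparison`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "mets_comparison"))
  jsonlite::write_json(unclass(comparison), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
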