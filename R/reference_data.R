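# Published TLGS state-occupancy reference table and its arithmetic.

#' Published TLGS state counts by wave
#'
#' State occupancy counts of the Tehran Lipid and Glucose Study cohort
#' (n = 12,882) at baseline and four follow-up waves, as published,
#' together with the published percent-change column (final wave vs
#' baseline). Counts sum to 12,882 at every wave. These counts seed the
#' synthetic generator's default baseline prevalence.
#'
#' @return data.frame with columns `state` (canonical label),
#'   `baseline`, `f1`--`f4` (counts) and `published_change_pct`.
#' @export
#' @examples
#' sum(tlgs_state_counts()$baseline)  # 12882
tlgs_state_counts <- function() {
  path <- system.file("extdata", "tlgs_state_counts.csv", package = "msdmets",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(df$state, state_labels()))
  df
}

#' Percent change between two counts
#'
#' `100 * (final - baseline) / baseline`. The published cohort table
#' reports this truncated toward zero at one decimal (not rounded);
#' `digits` reproduces that convention.
#'
#' @param baseline,final numeric vectors of counts.
#' @param digits if non-`NULL`, truncate toward zero to this many
#'   decimals (the source table's convention); `NULL` returns the exact
#'   value.
#' @return numeric vector of percent changes.
#' @export
#' @examples
#' percent_change(1604, 1248, digits = 1)  # -22.1
percent_change <- function(baseline, final, digits = NULL) {
  stopifnot(length(baseline) == length(final), all(baseline > 0))
  pc <- 100 * (final - baseline) / baseline
  if (!is.null(digits)) pc <- trunc(pc * 10^digits) / 10^digits
  pc
}
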