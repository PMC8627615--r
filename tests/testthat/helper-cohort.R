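# Shared fixtures, built in code.

# Quick panel builder: `moves` is a list of per-person state-label
# vectors; waves are consecutive from `start_wave` per person unless a
# vector is named with explicit waves via attr "waves".
make_panel <- function(moves, lifestyle = FALSE, meds = FALSE,
                       wave_years = NULL) {
  lifestyle <- rep_len(lifestyle, length(moves))
  rows <- lapply(seq_along(moves), function(i) {
    states <- moves[[i]]
    waves <- attr(states, "waves")
    if (is.null(waves)) waves <- seq_along(states) - 1L
    df <- data.frame(person_id = sprintf("p%04d", i), wave = waves,
                     year = 2000L + 3L * waves, state = as.vector(states),
                     stringsAsFactors = FALSE)
    for (cl in paste0("med_", mets_components())) df[[cl]] <- meds
    df$lifestyle <- lifestyle[i]
    df
  })
  as_panel(do.call(rbind, rows), wave_years = wave_years)
}

with_waves <- function(states, waves) {
  attr(states, "waves") <- as.integer(waves)
  states
}

# One moderately sized default-config cohort shared across test files.
shared_cohort_env <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(shared_cohort_env$cohort))
    shared_cohort_env$cohort <-
      generate_cohort(cohort_config(n_people = 3000L, seed = 123L))
  shared_cohort_env$cohort
}

last_wave_occupancy <- function(panel) {
  w <- max(panel$records$wave)
  as.numeric(table(factor(panel$records$state[panel$records$wave == w],
                          levels = state_labels())))
}

# All-ones modulation: the degenerate rate table under which the MSD
# flows reduce exactly to the Markov update.
identity_rates <- function() {
  new_rates(cr = c(1, 1, 1, 1), fr = c(1, 1, 1, NA),
            enforce_complement = FALSE)
}

# A 12x12 row-stochastic matrix embedding a hand-specified sub-chain;
# unspecified states stay put.
toy_tp <- function(cells) {
  labs <- state_labels()
  p <- diag(12L)
  dimnames(p) <- list(labs, labs)
  for (cell in cells) {
    p[cell$from, cell$to] <- cell$p
    p[cell$from, cell$from] <- p[cell$from, cell$from] - cell$p
  }
  new_tp(p)
}
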