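test_that("transition counts match a hand tally and respect censoring", {
  panel <- make_panel(list(
    c("no_component", "obesity"),
    c("no_component", "obesity"),
    c("obesity", "mets"),
    c("mets", "mets"),
    with_waves(c("dyslipidemia", "mets"), c(0L, 2L))))  # gap: censored
  counts <- count_transitions(panel, 0L)
  expect_equal(counts["no_component", "obesity"], 2L)
  expect_equal(counts["obesity", "mets"], 1L)
  expect_equal(counts["mets", "mets"], 1L)
  expect_equal(sum(counts), 4L)  # the gapped person contributes nothing
  expect_equal(sum(counts["dyslipidemia", ]), 0L)
  expect_error(count_transitions(panel, 5L), "present in the panel")
})

test_that("estimate_tp row-normalises and substitutes identity rows", {
  panel <- make_panel(list(
    c("no_component", "no_component"), c("no_component", "no_component"),
    c("no_component", "mets"), c("no_component", "mets")))
  tp <- estimate_tp(count_transitions(panel, 0L))
  expect_equal(tp["no_component", "no_component"], 0.5)
  expect_equal(tp["no_component", "mets"], 0.5)
  # unobserved states get the stay-with-probability-1 row
  expect_equal(unname(tp["obesity", ]), c(rep(0, 4), 1, rep(0, 7)))
  expect_equal(unname(rowSums(unclass(tp))), rep(1, 12), tolerance = 1e-12)
})

test_that("average_tp is the row-renormalised mean and can absorb MetS", {
  set.seed(11)
  a <- matrix(stats::rexp(144), 12L); a <- a / rowSums(a)
  b <- matrix(stats::rexp(144), 12L); b <- b / rowSums(b)
  avg <- average_tp(list(new_tp(a), new_tp(b)), absorbing = FALSE)
  hand <- (a + b) / 2
  hand <- hand / rowSums(hand)
  expect_equal(unclass(avg), hand, ignore_attr = TRUE, tolerance = 1e-12)

  same <- average_tp(list(new_tp(a), new_tp(a), new_tp(a)), absorbing = FALSE)
  expect_equal(unclass(same), a, ignore_attr = TRUE, tolerance = 1e-12)

  absd <- average_tp(list(new_tp(a), new_tp(diag(12L))), absorbing = TRUE)
  expect_equal(unname(absd["mets", ]), c(rep(0, 11), 1))
  expect_true(attr(absd, "absorbing_applied"))
  expect_error(average_tp(list()), "at least one")
})

test_that("n_step computes matrix powers and preserves stochasticity", {
  expect_equal(unclass(n_step(new_tp(diag(12L)), 9L)), diag(12L),
               ignore_attr = TRUE)
  # 2-state sub-chain [[0.9, 0.1], [0, 1]] squared = [[0.81, 0.19], [0, 1]]
  tp <- toy_tp(list(list(from = "no_component", to = "mets", p = 0.1)))
  sq <- n_step(tp, 2L)
  expect_equal(sq["no_component", "no_component"], 0.81)
  expect_equal(sq["no_component", "mets"], 0.19)
  expect_equal(sq["mets", "mets"], 1)

  p5 <- n_step(default_true_tp(), 5L)
  expect_lt(max(abs(rowSums(unclass(p5)) - 1)), 1e-9)
  expect_equal(unclass(n_step(default_true_tp(), 0L)), diag(12L),
               ignore_attr = TRUE)
  expect_error(n_step(default_true_tp(), -1L), "non-negative")
})

test_that("Chapman-Kolmogorov holds: P^(a+b) = P^a P^b", {
  tp <- default_true_tp()
  for (ab in list(c(1L, 2L), c(2L, 3L), c(4L, 3L))) {
    lhs <- unclass(n_step(tp, ab[1L] + ab[2L]))
    rhs <- unclass(n_step(tp, ab[1L])) %*% unclass(n_step(tp, ab[2L]))
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("predict_markov: occupancy by matrix powers, rates per person-year", {
  hz <- horizon(2015, 2036, 3)
  ident <- new_tp(diag(12L))
  tr <- predict_markov(ident, rep(50, 12), hz)
  expect_equal(dim(tr$occupancy), c(8L, 12L))
  expect_true(all(tr$occupancy == 50))
  expect_true(all(tr$rate_to_mets == 0))

  # 0.3 per period into MetS: period-1 rate = 30 / (100 * 3) = 0.1 / p-y
  tp <- toy_tp(list(list(from = "no_component", to = "mets", p = 0.3)))
  tr <- predict_markov(tp, c(100, rep(0, 11)), hz)
  expect_equal(tr$rate_to_mets[1L, "no_component"], 0.1)
  expect_equal(tr$occupancy[2L, "mets"], 30)
  expect_equal(nrow(tr$rate_to_mets), 7L)
  expect_equal(unname(tr$rate_to_mets[, "mets"]), rep(0, 7L))

  expect_error(predict_markov(tp, c(-1, rep(1, 11)), hz), "non-negative")
})

test_that("absorbing-MetS occupancy is non-decreasing and mass is conserved", {
  tp <- default_true_tp(absorbing_mets = TRUE)
  init <- tlgs_state_counts()$baseline
  tr <- predict_markov(tp, init, horizon(2015, 2036, 3))
  expect_true(all(diff(tr$occupancy[, "mets"]) >= 0))
  expect_lt(max(abs(rowSums(tr$occupancy) - sum(init))), 1e-6)
})

test_that("per-origin progression-rate curves converge to a common level", {
  tp <- default_true_tp(absorbing_mets = TRUE)
  tr <- predict_markov(tp, rep(1000, 12), horizon(2015, 2036, 3))
  spread <- apply(tr$rate_to_mets[, -12L], 1L, function(x) diff(range(x)))
  expect_lt(spread[7L], spread[1L])
})

test_that("bootstrap SEs are reproducible, zero for identical persons, and shrink with n", {
  clones <- make_panel(rep(list(c("no_component", "obesity", "mets")), 6L))
  bs <- bootstrap_se(clones, n_iter = 50L, seed = 9L)
  expect_true(all(bs$se == 0))

  cohort <- shared_cohort()
  b1 <- bootstrap_se(cohort$panel, n_iter = 25L, seed = 5L)
  b2 <- bootstrap_se(cohort$panel, n_iter = 25L, seed = 5L)
  expect_identical(b1$se, b2$se)
  b3 <- bootstrap_se(cohort$panel, n_iter = 25L, seed = 6L)
  expect_false(identical(b1$se, b3$se))
  # absorbing MetS row carries no sampling variability
  expect_equal(unname(b1$se[12L, ]), rep(0, 12L))

  expect_error(bootstrap_se(cohort$panel, n_iter = 1L), "at least 2")
  single <- make_panel(list(c("no_component", "obesity")))
  expect_error(bootstrap_se(single, n_iter = 10L), "2 persons")
})
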