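test_that("control/failure rates from hand-built panels", {
  # every tier-1 person progresses
  all_fail <- make_panel(list(c("obesity", "mets"),
                              c("hypertension", "hypertension+obesity"),
                              c("dyslipidemia", "dyslipidemia+obesity")),
                         lifestyle = TRUE)
  r <- estimate_cr_fr(all_fail)
  expect_equal(unname(r$fr["one_component"]), 1)
  expect_equal(unname(r$cr["one_component"]), 0)

  # every tier-1 person stays: staying counts as controlled
  all_stay <- make_panel(list(c("obesity", "obesity"),
                              c("hypertension", "hypertension")),
                         lifestyle = TRUE)
  r <- estimate_cr_fr(all_stay)
  expect_equal(unname(r$fr["one_component"]), 0)
  expect_equal(unname(r$cr["one_component"]), 1)

  # regressing also counts as controlled, and cr + fr = 1
  mixed <- make_panel(list(c("obesity", "no_component"),
                           c("obesity", "obesity"),
                           c("obesity", "mets"),
                           c("obesity", "hypertension+obesity")),
                      lifestyle = TRUE)
  r <- estimate_cr_fr(mixed)
  expect_equal(unname(r$fr["one_component"]), 0.5)
  expect_equal(unname(r$cr["one_component"] + r$fr["one_component"]), 1)
})

test_that("a planted progression fraction is recovered exactly", {
  n <- 200L
  nfail <- 73L
  dest <- c(rep("obesity", nfail), rep("no_component", n - nfail))
  planted <- make_panel(lapply(dest, function(d) c("no_component", d)),
                        lifestyle = TRUE)
  r <- estimate_cr_fr(planted)
  expect_equal(unname(r$fr["no_component"]), nfail / n)
})

test_that("stratum exclusions follow the intervention rules", {
  # medicated no-component persons must not enter the medicinal stratum;
  # with no lifestyle participants the tier-0 rate comes from nowhere
  panel <- make_panel(list(c("no_component", "obesity"),
                           c("no_component", "no_component")),
                      lifestyle = FALSE, meds = TRUE)
  r <- estimate_cr_fr(panel)
  expect_true(is.na(r$fr["no_component"]))

  # the same persons under lifestyle intervention are counted
  panel2 <- make_panel(list(c("no_component", "obesity"),
                            c("no_component", "no_component")),
                       lifestyle = TRUE, meds = TRUE)
  expect_equal(unname(estimate_cr_fr(panel2)$fr["no_component"]), 0.5)

  # MetS occupants appear only through the MetS regression rate
  panel3 <- make_panel(list(c("mets", "hypertension+obesity"),
                            c("mets", "mets"),
                            c("obesity", "obesity")),
                       lifestyle = TRUE)
  r3 <- estimate_cr_fr(panel3)
  expect_equal(unname(r3$cr["mets"]), 0.5)
  expect_true(is.na(r3$fr["mets"]))
  expect_equal(unname(r3$cr["one_component"]), 1)
})

test_that("flow network classifies and modulates flows by kind", {
  ident_net <- build_flow_network(new_tp(diag(12L)), identity_rates())
  expect_true(all(ident_net$flows$kind == "TPI"))

  rates <- new_rates(cr = c(0.5, 0.6, 0.7, 0.4), fr = c(0.5, 0.4, 0.3, NA))
  tp <- toy_tp(list(list(from = "no_component", to = "obesity", p = 0.2),
                    list(from = "obesity", to = "hypertension", p = 0.1),
                    list(from = "mets", to = "obesity", p = 0.25)))
  net <- build_flow_network(tp, rates)
  f <- net$flows
  fwd <- f[f$origin == "no_component" & f$dest == "obesity", ]
  expect_equal(fwd$kind, "TPO_F")
  expect_equal(fwd$modulation, "FR")
  expect_equal(fwd$effective, 0.2 * 0.5)
  lat <- f[f$origin == "obesity" & f$dest == "hypertension", ]
  expect_equal(lat$kind, "TPW")
  expect_equal(lat$modulation, "none")
  expect_equal(lat$effective, 0.1)
  back <- f[f$origin == "mets" & f$dest == "obesity", ]
  expect_equal(back$kind, "TPO_B")
  expect_equal(back$modulation, "CR")
  expect_equal(back$effective, 0.25 * 0.4)
})

test_that("MSD simulation conserves mass, stays non-negative, tracks flows", {
  hz <- horizon(2015, 2036, 3)
  ident_net <- build_flow_network(new_tp(diag(12L)), identity_rates())
  tr <- simulate_msd(ident_net, rep(10, 12), hz)
  expect_true(all(tr$occupancy == 10))

  rates <- new_rates(cr = c(0.5, 0.6, 0.7, 0.4), fr = c(0.5, 0.4, 0.3, NA))
  tp <- toy_tp(list(list(from = "no_component", to = "obesity", p = 0.2)))
  net <- build_flow_network(tp, rates)
  tr <- simulate_msd(net, c(100, rep(0, 11)), hz)
  # effective forward fraction 0.2 * fr0 = 0.1; residual stays put
  expect_equal(tr$occupancy[2L, "obesity"], 10)
  expect_equal(tr$occupancy[2L, "no_component"], 90)

  co <- shared_cohort()
  tp_est <- estimate_avg_tp(co$panel, absorbing = FALSE)
  net <- build_flow_network(tp_est, estimate_cr_fr(co$panel))
  init <- last_wave_occupancy(co$panel)
  tr <- simulate_msd(net, init, hz)
  expect_lt(max(abs(rowSums(tr$occupancy) - sum(init))), 1e-6)
  expect_true(all(tr$occupancy >= 0))
})

test_that("with all rates at 1 the MSD simulation equals matrix powers", {
  tp <- default_true_tp()
  net <- build_flow_network(tp, identity_rates())
  hz <- horizon(2015, 2024, 3)
  init <- c(500, rep(20, 10), 100)
  msd <- simulate_msd(net, init, hz)
  mkv <- predict_markov(tp, init, hz)
  expect_lt(max(abs(msd$occupancy - mkv$occupancy)), 1e-9)
  expect_lt(max(abs(msd$rate_to_mets - mkv$rate_to_mets)), 1e-9)
})

test_that("sub-stepping refines but does not break conservation", {
  co <- shared_cohort()
  tp <- estimate_avg_tp(co$panel, absorbing = FALSE)
  net <- build_flow_network(tp, estimate_cr_fr(co$panel))
  init <- last_wave_occupancy(co$panel)
  hz <- horizon(2015, 2036, 3)
  t1 <- simulate_msd(net, init, hz, substeps = 1L)
  t4 <- simulate_msd(net, init, hz, substeps = 4L)
  expect_lt(max(abs(rowSums(t4$occupancy) - sum(init))), 1e-6)
  # finer stepping changes the path but not wildly
  expect_lt(max(abs(t4$occupancy - t1$occupancy)) / sum(init), 0.05)
})

test_that("lowering a failure rate never increases MetS occupancy", {
  co <- shared_cohort()
  tp <- estimate_avg_tp(co$panel, absorbing = FALSE)
  base_rates <- estimate_cr_fr(co$panel)
  init <- last_wave_occupancy(co$panel)
  hz <- horizon(2015, 2036, 3)
  base_traj <- simulate_msd(build_flow_network(tp, base_rates), init, hz)
  for (k in 1:3) {
    fr2 <- base_rates$fr
    cr2 <- base_rates$cr
    fr2[k] <- fr2[k] * 0.5
    cr2[k] <- 1 - fr2[k]
    damped <- simulate_msd(build_flow_network(tp, new_rates(cr2, fr2)),
                           init, hz)
    expect_true(all(damped$occupancy[, "mets"] <=
                      base_traj$occupancy[, "mets"] + 1e-9))
  }
})

test_that("predict_msd composes the pipeline and propagates data errors", {
  co <- shared_cohort()
  hz <- horizon(2015, 2036, 3)
  tr <- predict_msd(co$panel, hz)
  expect_equal(tr$engine, "msd")
  expect_equal(nrow(tr$rate_to_mets), 7L)
  expect_true(all(tr$rate_to_mets >= 0))
  expect_lt(max(abs(rowSums(tr$occupancy) - sum(last_wave_occupancy(co$panel)))),
            1e-6)

  # under genuinely forward-dominant dynamics (no regression from MetS)
  # the MetS stock can only grow
  fwd <- generate_cohort(cohort_config(
    n_people = 2000L, true_tp = default_true_tp(absorbing_mets = TRUE),
    seed = 41L))
  tr_fwd <- predict_msd(fwd$panel, hz)
  expect_true(all(diff(tr_fwd$occupancy[, "mets"]) >= -1e-9))

  single <- generate_cohort(cohort_config(n_people = 30L, n_waves = 1L,
                                          seed = 2L))
  expect_error(predict_msd(single$panel, hz), "two waves")
})

test_that("flow-network edge list export round-trips", {
  co <- shared_cohort()
  tp <- estimate_avg_tp(co$panel, absorbing = FALSE)
  net <- build_flow_network(tp, estimate_cr_fr(co$panel))
  path <- withr::local_tempfile(fileext = ".csv")
  write_flows(net, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(net$flows))
  expect_equal(back$effective, net$flows$effective, tolerance = 1e-12)
})
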