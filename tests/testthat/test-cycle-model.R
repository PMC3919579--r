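test_that("scheme construction follows the condition flags", {
  with_rf2 <- build_scheme(cycle_conditions(complex = "post", rf2 = TRUE))
  no_rf2 <- build_scheme(cycle_conditions(complex = "vacant", rf2 = FALSE))
  k_exch <- function(s) {
    r <- Filter(function(r) r$label == "GDP release on ribosome", s$reactions)
    r[[1]]$k
  }
  expect_equal(k_exch(with_rf2), 35)
  expect_equal(k_exch(no_rf2), 0.15)
  # no ribosomes: only free-RF3 nucleotide exchange remains
  free_only <- build_scheme(cycle_conditions(ribosome = 0, complex = "none"))
  expect_length(free_only$reactions, 4)
  expect_true(all(grepl("free RF3", vapply(free_only$reactions, `[[`,
                                           character(1), "label"))))
  # the scheme omitting RF3-GDP ribosome binding drops exactly that step
  omit <- build_scheme(cycle_conditions(complex = "post", rf2 = TRUE),
                       omit_rf3gdp_binding = TRUE)
  expect_length(omit$reactions, length(with_rf2$reactions) - 1)
  # invalid rate overrides are refused
  expect_error(build_scheme(cycle_conditions(), rates = c(bogus = 1)),
               "unknown rate")
  expect_error(build_scheme(cycle_conditions(), rates = c(k_hyd = -1)),
               "positive")
})

test_that("simulation conserves totals and hydrolysis is cumulative", {
  sch <- build_scheme(cycle_conditions(2, 2, GTP = 1000, complex = "pre",
                                       rf2 = TRUE, rf2_variant = "wt"))
  tr <- simulate_cycle(sch, seq(0, 120, by = 0.5))
  expect_true(all(attr(tr, "conservation") <= 1e-8))
  expect_true(all(diff(tr$Pi) >= -1e-12))
  # peptide release proceeds at the wild-type RF2 rate
  expect_rel_equal(tr$PeptidylTRNA[tr$time == 2] / 2, exp(-0.9 * 2), 1e-4)
  # zero RF3: no hydrolysis ever
  sch0 <- build_scheme(cycle_conditions(RF3 = 0, ribosome = 2, GTP = 100))
  tr0 <- simulate_cycle(sch0, seq(0, 60, by = 1))
  expect_true(all(tr0$Pi == 0))
})

test_that("pseudo-first-order dissociation matches the analytic exponential", {
  # suppress rebinding: the RF3-GDP pool then decays as exp(-koff t)
  sch <- build_scheme(cycle_conditions(RF3 = 1, ribosome = 0, GTP = 0,
                                       complex = "none"),
                      rates = c(kon_nt = 1e-12))
  tg <- seq(0, 40, by = 0.5)
  tr <- simulate_cycle(sch, tg)
  expect_lt(max(abs(tr$RF3_GDP - exp(-0.13 * tg))), 1e-6)
})

test_that("with hydrolysis disabled the ODE reaches the competition equilibrium", {
  # free RF3 equilibrating with GTP and GDP; no ribosomes, so no GTPase
  rt <- default_cycle_rates()
  sch <- build_scheme(cycle_conditions(RF3 = 1, ribosome = 0, GTP = 5,
                                       GDP = 5, complex = "none"))
  tr <- simulate_cycle(sch, c(0, 10^seq(0, 3, by = 0.5)))
  fin <- tr[nrow(tr), ]
  # the GDP delivered on RF3 counts toward the GDP total
  eq <- solve_competition_equilibrium(binding_system(
    P_total = 1, X_total = 5, I_total = 5 + 1,
    K_d = rt[["koff_gtp_free"]] / rt[["kon_nt"]],
    K_I = rt[["koff_gdp_free"]] / rt[["kon_nt"]]))
  expect_rel_equal(fin$RF3_GTP, eq$PX, 0.01)
  expect_rel_equal(fin$RF3_GDP, eq$PI, 0.01)
})

test_that("RF2 stimulates nucleotide turnover but not single-round hydrolysis", {
  # identical conditions give identical velocities
  tc0 <- turnover_comparison(list(
    a = cycle_conditions(2, 2, GTP = 5, complex = "post", rf2 = TRUE),
    b = cycle_conditions(2, 2, GTP = 5, complex = "post", rf2 = TRUE)))
  expect_equal(tc0$k_GTP[1], tc0$k_GTP[2], tolerance = 1e-10)
  # low-GTP, limited-turnover window: RF2 changes k_GTP less than 2-fold
  tc <- turnover_comparison(list(
    rf2 = cycle_conditions(2, 2, GTP = 5, complex = "post", rf2 = TRUE),
    no_rf2 = cycle_conditions(2, 2, GTP = 5, complex = "post", rf2 = FALSE)),
    t_init = 60, t_end = 60)
  ratio_single <- tc$k_GTP[tc$condition == "rf2"] /
    tc$k_GTP[tc$condition == "no_rf2"]
  expect_lt(max(ratio_single, 1 / ratio_single), 2)
  # pre- vs post-termination complexes hydrolyze at the same rate
  tc_state <- turnover_comparison(list(
    pre = cycle_conditions(2, 2, GTP = 5, complex = "pre", rf2 = TRUE,
                           rf2_variant = "GGA"),
    post = cycle_conditions(2, 2, GTP = 5, complex = "post", rf2 = TRUE)),
    t_init = 60, t_end = 60)
  expect_lt(max(tc_state$k_GTP) / min(tc_state$k_GTP), 2)
  # multi-turnover at saturating GTP: several-fold cumulative stimulation
  tc2 <- turnover_comparison(list(
    rf2 = cycle_conditions(2, 2, GTP = 1000, complex = "post", rf2 = TRUE),
    no_rf2 = cycle_conditions(2, 2, GTP = 1000, complex = "post",
                              rf2 = FALSE)),
    t_init = 60, t_end = 600)
  ratio_multi <- tc2$turnover[tc2$condition == "rf2"] /
    tc2$turnover[tc2$condition == "no_rf2"]
  expect_gt(ratio_multi, 3)
  expect_gt(ratio_multi, 2 * max(ratio_single, 1 / ratio_single))
  # saturating-GTP initial velocity sits in the measured 0.3-0.4 s-1 band
  sat <- turnover_comparison(list(
    s = cycle_conditions(2, 2, GTP = 1000, complex = "post", rf2 = TRUE)),
    t_init = 20, t_end = 60)
  expect_gt(sat$k_GTP, 0.3)
  expect_lt(sat$k_GTP, 0.4)
})

test_that("faster GDP release raises turnover, not the first hydrolysis round", {
  base <- cycle_conditions(2, 2, GTP = 1000, complex = "post", rf2 = FALSE,
                           rf3_loaded = "gtp")
  run <- function(k_exch) {
    sch <- build_scheme(base, rates = c(koff_gdp_rib = k_exch))
    simulate_cycle(sch, sort(unique(c(seq(0, 0.2, by = 0.01),
                                      exp(seq(log(0.2), log(600),
                                              length.out = 80))))))
  }
  slow <- run(0.15); fast <- run(1.5)
  v0 <- function(tr) {
    e <- tr$time > 0 & tr$time <= 0.2
    sum(tr$time[e] * tr$Pi[e]) / sum(tr$time[e]^2)
  }
  # instantaneous velocity from the GTP-loaded factor is exchange-blind
  expect_rel_equal(v0(fast), v0(slow), 0.01)
  # cumulative hydrolysis at long times is not
  expect_gt(fast$Pi[nrow(fast)], 1.2 * slow$Pi[nrow(slow)])
})
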