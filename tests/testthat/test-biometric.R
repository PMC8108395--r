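# Saturated and ACE-family fits for continuous twin data.

test_that("unconstrained saturated MLEs equal the sample moments", {
  d <- ae_cohort(60, 60, seed = 8)
  f <- fit_saturated(d, "none")
  for (z in c("MZ", "DZ")) {
    g <- d[d$zygosity == z, ]
    n <- nrow(g)
    expect_equal(f$zygosity[[z]]$means,
                 c(mean(g$t1_score), mean(g$t2_score)), tolerance = 1e-9)
    expect_equal(f$zygosity[[z]]$vars,
                 c(var(g$t1_score), var(g$t2_score)) * (n - 1) / n,
                 tolerance = 1e-9)
    expect_equal(f$zygosity[[z]]$cov,
                 cov(g$t1_score, g$t2_score) * (n - 1) / n,
                 tolerance = 1e-9)
  }
})

test_that("constraint levels nest and duplicated columns give r = 1", {
  d <- ae_cohort(80, 80, seed = 12)
  at <- assumption_tests(d)
  expect_true(all(diff(at$minus2LL) >= -1e-6))  # -2LL rises with constraints
  expect_true(all(at$p[-1] > 0 & at$p[-1] <= 1))
  # identical twin columns force a perfect MZ correlation
  d2 <- d; d2$t2_score[d2$zygosity == "MZ"] <- d2$t1_score[d2$zygosity == "MZ"]
  f <- fit_saturated(d2, "none")
  expect_equal(f$zygosity$MZ$cor, 1, tolerance = 1e-9)
})

test_that("twin correlations recover simulated values with sane CIs", {
  d <- ae_cohort(4000, 4000, a2 = 0.65, seed = 21)
  tc <- twin_correlations(d)
  expect_lt(abs(tc$r[tc$zygosity == "MZ"] - 0.65), 0.025)
  expect_lt(abs(tc$r[tc$zygosity == "DZ"] - 0.325), 0.025)
  expect_true(all(tc$lower < tc$r & tc$r < tc$upper))
  # pure-E data: both near zero
  d0 <- simulate_continuous(sim_config(2000, 2000, a2 = 0, c2 = 0, e2 = 1,
                                       seed = 22))
  tc0 <- twin_correlations(d0, ci = FALSE)
  expect_lt(max(abs(tc0$r)), 0.06)
})

test_that("AE fit at study size matches the generating heritability", {
  d <- ae_cohort(seed = 31)
  f <- fit_ace(d, "AE")
  expect_equal(f$estimates$a2, 0.65, tolerance = 0.06)
  expect_equal(f$estimates$a2 + f$estimates$e2, 1, tolerance = 1e-9)
  expect_true(f$converged)
  # CI width comparable to a cohort of this size (reported 0.61-0.68 scale)
  w <- f$ci["a2", "upper"] - f$ci["a2", "lower"]
  expect_gt(w, 0.03); expect_lt(w, 0.15)
})

test_that("ACE fit with c2 pinned to zero reproduces the AE likelihood", {
  d <- ae_cohort(200, 200, seed = 41)
  ace <- fit_ace(d, "ACE", ci = "none")
  ae <- fit_ace(d, "AE", ci = "none")
  # profile of the ACE model at c2 = 0 equals the AE deviance
  dd <- biometwin:::.prep_pairs(d, c("t1_score", "t2_score"))
  st <- biometwin:::.sat_starts(dd)
  prof_c0 <- biometwin:::.make_cont_profile("ACE", "c2", dd, st)(0)
  expect_equal(prof_c0, ae$minus2LL, tolerance = 1e-6)
  expect_lte(ace$minus2LL, ae$minus2LL + 1e-8)
})

test_that("E-model deviance equals independent univariate normals", {
  d <- ae_cohort(150, 150, seed = 51)
  fe <- fit_ace(d, "E", ci = "none")
  y <- c(d$t1_score, d$t2_score)
  m <- mean(y); v <- mean((y - m)^2)
  expect_equal(fe$minus2LL, -2 * sum(dnorm(y, m, sqrt(v), log = TRUE)),
               tolerance = 1e-6)
})

test_that("profile CI endpoints sit at the 3.84 deviance rise", {
  d <- ae_cohort(400, 350, seed = 61)
  f <- fit_ace(d, "AE")
  dd <- biometwin:::.prep_pairs(d, c("t1_score", "t2_score"))
  st <- biometwin:::.sat_starts(dd)
  prof <- biometwin:::.make_cont_profile("AE", "a2", dd, st)
  crit <- qchisq(0.95, 1)
  for (ep in f$ci["a2", ]) {
    expect_equal(prof(ep) - f$minus2LL, crit, tolerance = 1e-3)
  }
  expect_lt(f$ci["a2", "lower"], f$estimates$a2)
  expect_gt(f$ci["a2", "upper"], f$estimates$a2)
})

test_that("CE-generated data prefer CE over AE by BIC at large n", {
  d <- simulate_continuous(sim_config(3000, 3000, a2 = 0, c2 = 0.5,
                                      e2 = 0.5, seed = 71))
  ce <- fit_ace(d, "CE", ci = "none")
  ae <- fit_ace(d, "AE", ci = "none")
  expect_lt(ce$BIC, ae$BIC)
})

test_that("ADE expectations use quarter-weighted dominance in DZ pairs", {
  # ADE data: d2 shifts MZ correlation above twice the DZ correlation
  cfg <- sim_config(20000, 20000, a2 = 0.4, c2 = 0, e2 = 0.6, seed = 81)
  d <- simulate_continuous(cfg)
  f <- fit_ace(d, "ADE", ci = "none")
  # with AE-generated data the D component should collapse to ~0
  expect_lt(f$estimates$d2, 0.08)
  expect_lt(abs(f$estimates$a2 - 0.4), 0.08)
  # and the fitted expectations reproduce the sample twin correlations
  tc <- twin_correlations(d, ci = FALSE)
  expect_lt(abs((f$estimates$a2 + f$estimates$d2) -
                  tc$r[tc$zygosity == "MZ"]), 0.01)
  expect_lt(abs((0.5 * f$estimates$a2 + 0.25 * f$estimates$d2) -
                  tc$r[tc$zygosity == "DZ"]), 0.01)
})
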