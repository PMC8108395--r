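# Joint categorical-continuous bivariate model.

joint_cohort <- function(n = 600, rA = 0.52, rE = 0.52, prev = 0.15,
                         seed = 1) {
  simulate_bivariate(sim_config(n, n, a2 = 0.65, c2 = 0, e2 = 0.35,
                                trait2 = list(a2 = 0.67, c2 = 0, e2 = 0.33,
                                              prevalence = prev),
                                rA = rA, rC = 0, rE = rE, seed = seed))
}

test_that("cross-twin cross-trait correlations separate MZ from DZ", {
  d <- joint_cohort(6000, seed = 3)
  ct <- cross_twin_cross_trait(d)
  r_mz <- ct$r[ct$zygosity == "MZ"]; r_dz <- ct$r[ct$zygosity == "DZ"]
  expect_gt(r_mz, r_dz)
  expect_lt(abs(r_mz - 0.52 * sqrt(0.65 * 0.67)), 0.05)
  expect_lt(abs(r_dz - 0.5 * 0.52 * sqrt(0.65 * 0.67)), 0.05)
  # zero cross-trait correlations: both near zero
  d0 <- joint_cohort(4000, rA = 0, rE = 0, seed = 5)
  ct0 <- cross_twin_cross_trait(d0)
  expect_lt(max(abs(ct0$r)), 0.05)
})

test_that("dichotomized same trait approaches the within-trait correlation", {
  # trait 2 == trait 1 (same factors): cross-twin cross-trait correlation
  # in MZ pairs approaches the MZ within-trait correlation
  d <- simulate_bivariate(sim_config(8000, 0, a2 = 0.65, c2 = 0, e2 = 0.35,
                                     trait2 = list(a2 = 0.65, c2 = 0,
                                                   e2 = 0.35,
                                                   prevalence = 0.4),
                                     rA = 1, rC = 1, rE = 1, seed = 7))
  ct <- cross_twin_cross_trait(d[d$zygosity == "MZ", ])
  expect_equal(ct$r[1], 0.65, tolerance = 0.05)
})

test_that("joint fit recovers cross-trait correlations with working CIs", {
  d <- joint_cohort(700, seed = 11)
  f <- fit_joint(d, "AE")
  expect_equal(f$estimates$rA, 0.52, tolerance = 0.15)
  expect_equal(f$estimates$rE, 0.52, tolerance = 0.15)
  expect_true(f$ci$rA[1] < f$estimates$rA & f$estimates$rA < f$ci$rA[2])
  expect_true(f$converged)
  # identity: rPH decomposition holds exactly on the estimates
  e <- f$estimates
  expect_equal(e$rPH,
               implied_rph(e$rA,
                           c(e$continuous$a2, e$continuous$c2,
                             e$continuous$e2),
                           c(e$liability$a2, e$liability$c2,
                             e$liability$e2),
                           rE = e$rE, rC = e$rC),
               tolerance = 1e-6)
  expect_equal(e$bivariate_h2,
               e$rA * sqrt(e$continuous$a2 * e$liability$a2) / e$rPH,
               tolerance = 1e-6)
})

test_that("threshold at -Inf reduces the joint deviance to the continuous one", {
  d <- joint_cohort(300, seed = 13)
  dd <- biometwin:::.prep_pairs(d, c("t1_score", "t2_score",
                                     "t1_dx", "t2_dx"))
  all1 <- function(x) { x[[1]][] <- 1L; x[[2]][] <- 1L; x }
  th <- list(mu = 0.02, v = 1.1, p1 = c(0.6, 0, 0, 0.4), t2 = -Inf,
             p2 = c(0.5, 0, 0, 0.5), rA = 0.4, rC = 0, rE = 0.2)
  m2_joint <- biometwin:::.joint_m2ll(th, dd$mz[1:2], all1(dd$mz[3:4]),
                                      dd$dz[1:2], all1(dd$dz[3:4]))
  m2_cont <- biometwin:::.m2ll_cont_group(dd$mz, 0.02, 0.02, 1.1, 1.1, 0.6) +
    biometwin:::.m2ll_cont_group(dd$dz, 0.02, 0.02, 1.1, 1.1, 0.3)
  expect_equal(m2_joint, m2_cont, tolerance = 1e-8)
})

test_that("zero cross-trait correlations split the deviance into parts", {
  d <- joint_cohort(300, seed = 17)
  dd <- biometwin:::.prep_pairs(d, c("t1_score", "t2_score",
                                     "t1_dx", "t2_dx"))
  th <- list(mu = 0.02, v = 1.1, p1 = c(0.6, 0, 0, 0.4), t2 = 1.1,
             p2 = c(0.5, 0, 0, 0.5), rA = 0, rC = 0, rE = 0)
  m2_joint <- biometwin:::.joint_m2ll(th, dd$mz[1:2], dd$mz[3:4],
                                      dd$dz[1:2], dd$dz[3:4])
  m2_cont <- biometwin:::.m2ll_cont_group(dd$mz, 0.02, 0.02, 1.1, 1.1, 0.6) +
    biometwin:::.m2ll_cont_group(dd$dz, 0.02, 0.02, 1.1, 1.1, 0.3)
  m2_bin <- biometwin:::.m2ll_bin_group(biometwin:::.dx_counts(dd$mz[3:4]),
                                        1.1, 0.5) +
    biometwin:::.m2ll_bin_group(biometwin:::.dx_counts(dd$dz[3:4]), 1.1, 0.25)
  expect_equal(m2_joint, m2_cont + m2_bin, tolerance = 1e-4)
})

test_that("joint and fully-continuous bivariate rA agree on dichotomized data", {
  # large-n: fit the joint model, and compare rA with the value implied by
  # the observed continuous-continuous structure before dichotomization
  cfg <- sim_config(4000, 4000, a2 = 0.65, c2 = 0, e2 = 0.35,
                    trait2 = list(a2 = 0.67, c2 = 0, e2 = 0.33,
                                  prevalence = 0.25),
                    rA = 0.5, rC = 0, rE = 0.5, seed = 19)
  d <- simulate_bivariate(cfg, keep_liability = TRUE)
  f <- fit_joint(d, "AE", ci = "none")
  expect_equal(f$estimates$rA, 0.5, tolerance = 0.05)
  # oracle from the latent continuous trait: cross-twin cross-trait
  # covariance in MZ pairs = rA * a1 * a2
  ctct <- cov(d$t1_score[d$zygosity == "MZ"], d$t2_liab[d$zygosity == "MZ"])
  rA_lat <- ctct / sqrt(0.65 * 0.67)
  expect_equal(f$estimates$rA, rA_lat, tolerance = 0.05)
})

test_that("printed-estimate identities give the published-style shares", {
  expect_equal(round(100 * bivariate_heritability(0.26, 0.65, 0.63, 0.39)),
               43)
  expect_equal(round(100 * bivariate_heritability(0.52, 0.65, 0.67, 0.52)),
               66)
  expect_equal(implied_rph(0.52, c(0.65, 0, 0.35), c(0.67, 0, 0.33),
                           rE = 0.52),
               0.52, tolerance = 0.005)
})
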