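# Synthetic twin-cohort generator: structural sharing, convergence of
# sample moments to the configured ground truth, determinism.

test_that("fully genetic trait makes MZ twins identical", {
  d <- simulate_continuous(sim_config(50, 50, a2 = 1, c2 = 0, e2 = 0,
                                      seed = 3))
  mz <- d[d$zygosity == "MZ", ]
  dz <- d[d$zygosity == "DZ", ]
  expect_equal(mz$t1_score, mz$t2_score)
  expect_false(isTRUE(all.equal(dz$t1_score, dz$t2_score)))
})

test_that("pure-E trait leaves twins uncorrelated", {
  d <- simulate_continuous(sim_config(5000, 5000, a2 = 0, c2 = 0, e2 = 1,
                                      seed = 5))
  for (z in c("MZ", "DZ")) {
    g <- d[d$zygosity == z, ]
    expect_lt(abs(cor(g$t1_score, g$t2_score)), 0.04)
  }
})

test_that("sample twin correlations converge to a2 + c2 and a2/2 + c2", {
  cases <- list(c(a2 = 0.65, c2 = 0), c(a2 = 0.4, c2 = 0.3))
  for (cs in cases) {
    cfg <- sim_config(50000, 50000, a2 = cs[["a2"]], c2 = cs[["c2"]],
                      e2 = 1 - sum(cs), seed = 7)
    d <- simulate_continuous(cfg)
    man <- ground_truth(cfg)
    mz <- d[d$zygosity == "MZ", ]; dz <- d[d$zygosity == "DZ", ]
    expect_lt(abs(cor(mz$t1_score, mz$t2_score) - man$expected_r_mz), 0.01)
    expect_lt(abs(cor(dz$t1_score, dz$t2_score) - man$expected_r_dz), 0.01)
    expect_lte(man$expected_r_dz, man$expected_r_mz)
  }
})

test_that("same seed and config give bit-identical tables", {
  cfg <- sim_config(100, 100, a2 = 0.5, c2 = 0.2, e2 = 0.3,
                    prevalence = 0.1, seed = 99)
  expect_identical(simulate_continuous(cfg), simulate_continuous(cfg))
  expect_identical(simulate_binary(cfg), simulate_binary(cfg))
})

test_that("binary prevalence converges to 1 - Phi(threshold)", {
  cfg <- sim_config(50000, 50000, a2 = 0.65, c2 = 0, e2 = 0.35,
                    prevalence = 0.057, seed = 2)
  d <- simulate_binary(cfg)
  expect_lt(abs(mean(c(d$t1_dx, d$t2_dx)) - 0.057), 0.003)
  # degenerate threshold: no cases
  cfg_inf <- sim_config(100, 100, a2 = 0.65, c2 = 0, e2 = 0.35, seed = 2)
  cfg_inf$threshold_z <- Inf
  d0 <- simulate_binary(cfg_inf)
  expect_equal(sum(d0$t1_dx, d0$t2_dx), 0)
})

test_that("median-split pure-E trait has ~50% probandwise concordance", {
  cfg <- sim_config(30000, 30000, a2 = 0, c2 = 0, e2 = 1,
                    prevalence = 0.5, seed = 13)
  ct <- concordance_table(simulate_binary(cfg))
  expect_equal(ct$concordance, c(0.5, 0.5), tolerance = 0.02)
})

test_that("rare genetic trait is more concordant in MZ than DZ pairs", {
  cfg <- sim_config(3e5, 3e5, a2 = 0.65, c2 = 0, e2 = 0.35,
                    prevalence = 0.024, seed = 17)
  ct <- concordance_table(simulate_binary(cfg))
  expect_gt(ct$concordance[ct$zygosity == "MZ"],
            ct$concordance[ct$zygosity == "DZ"])
  # compare against the orthant-probability expectation
  t <- qnorm(1 - 0.024)
  conc_exp <- function(r) {
    p11 <- pbvn_upper(t, t, r); p1 <- pnorm(-t)
    2 * p11 / (2 * p11 + 2 * (p1 - p11))
  }
  expect_equal(ct$concordance[1], conc_exp(0.65), tolerance = 0.05)
  expect_equal(ct$concordance[2], conc_exp(0.325), tolerance = 0.05)
})

test_that("bivariate generator reproduces the implied cross-trait structure", {
  cfg <- sim_config(40000, 40000, a2 = 0.65, c2 = 0, e2 = 0.35,
                    trait2 = list(a2 = 0.67, c2 = 0, e2 = 0.33,
                                  prevalence = 0.3),
                    rA = 0.52, rC = 0, rE = 0.52, seed = 23)
  man <- ground_truth(cfg)
  expect_equal(man$expected_r_ph, 0.52, tolerance = 0.001)
  d <- simulate_bivariate(cfg, keep_liability = TRUE)
  expect_equal(cor(c(d$t1_score, d$t2_score), c(d$t1_liab, d$t2_liab)),
               man$expected_r_ph, tolerance = 0.01)
  # zero cross-correlations: independent traits
  cfg0 <- sim_config(20000, 0, a2 = 0.65, c2 = 0, e2 = 0.35,
                     trait2 = list(a2 = 0.67, prevalence = 0.3),
                     rA = 0, rC = 0, rE = 0, seed = 29)
  d0 <- simulate_bivariate(cfg0, keep_liability = TRUE)
  expect_lt(abs(cor(d0$t1_score, d0$t1_liab)), 0.02)
  # perfect correlations with identical components: identical liabilities
  cfg1 <- sim_config(500, 500, a2 = 0.65, c2 = 0, e2 = 0.35,
                     trait2 = list(a2 = 0.65, c2 = 0, e2 = 0.35,
                                   prevalence = 0.3),
                     rA = 1, rC = 1, rE = 1, seed = 31)
  d1 <- simulate_bivariate(cfg1, keep_liability = TRUE)
  expect_equal(d1$t1_liab, d1$t1_score, tolerance = 1e-12)
})

test_that("skew transform hits its moment targets and preserves ranks", {
  set.seed(11)
  z <- rnorm(1e6)
  y <- apply_skew_transform(z, mean = 2.66, sd = 0.90, skew = 0.57)
  expect_equal(mean(y), 2.66, tolerance = 0.02)
  expect_equal(sd(y), 0.90, tolerance = 0.02)
  m <- mean(y)
  expect_equal(mean((y - m)^3) / sd(y)^3, 0.57, tolerance = 0.05)
  expect_true(all(y > 1 & y < 6))
  expect_equal(cor(z, y, method = "spearman"), 1)
  # identity-like spec: symmetric target keeps the normal shape
  y0 <- apply_skew_transform(z[1:10000], mean = 0, sd = 1, skew = 0,
                             lower = -10, upper = 10)
  expect_equal(cor(z[1:10000], y0), 1, tolerance = 1e-5)
  # the log transform shrinks the skew magnitude (the analysis scale)
  sk_log <- mean((log(y) - mean(log(y)))^3) / sd(log(y))^3
  expect_lt(abs(sk_log), abs(0.57))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(10, 10, a2 = 0.5, c2 = 0.2, e2 = 0.2),
               "sum to 1")
  expect_error(sim_config(10, 10, a2 = -0.1, c2 = 0.5, e2 = 0.6),
               "non-negative")
  expect_error(sim_config(10, 10, a2 = 0.5, e2 = 0.5, prevalence = 1.2),
               "prevalence")
  expect_error(sim_config(10, 10, a2 = 0.5, e2 = 0.5, prevalence = 0.1,
                          threshold_z = 2), "not both")
  expect_error(simulate_binary(sim_config(10, 10, a2 = 0.5, e2 = 0.5)),
               "threshold")
})

test_that("pair tables round-trip through CSV with manifest", {
  cfg <- sim_config(20, 20, a2 = 0.5, c2 = 0, e2 = 0.5, seed = 1)
  d <- simulate_continuous(cfg)
  path <- file.path(tempdir(), "pairs.csv")
  write_pairs(d, path, cfg)
  d2 <- read_pairs(path)
  expect_equal(d2$t1_score, d$t1_score, tolerance = 1e-12)
  man <- jsonlite::read_json(sub("\\.csv$", ".manifest.json", path))
  expect_equal(man$expected_r_mz, 0.5, tolerance = 1e-12)
  unlink(c(path, sub("\\.csv$", ".manifest.json", path)))
})
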