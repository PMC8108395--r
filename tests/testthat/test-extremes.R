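# DeFries-Fulker extremes analysis.

test_that("proband selection takes the high tail with ties included", {
  expect_true(all(select_probands(1:100, 100)))
  m <- select_probands(1:100, 10)
  expect_equal(which(m), 91:100)
  # ties at the cut-off are all included
  x <- c(rep(1, 90), rep(9, 10))
  expect_equal(sum(select_probands(x, 5)), 10)
  expect_error(select_probands(1:10, 0), "percentile")
  # study-size cohort at the 5th percentile: about 0.05 * N individuals
  d <- ae_cohort(seed = 2)
  sc <- c(d$t1_score, d$t2_score)
  expect_equal(sum(select_probands(sc, 5)), round(0.05 * length(sc)),
               tolerance = 3)
})

test_that("selection is rank-based: monotone rescaling keeps probands", {
  set.seed(5)
  x <- rlnorm(500)
  expect_identical(select_probands(x, 10), select_probands(log(x), 10))
})

test_that("the DF transform fixes the population and proband means", {
  set.seed(7)
  x <- rnorm(1000, 5, 2)
  m <- select_probands(x, 10)
  z <- df_transform(x, m)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(mean(z[m]), 1, tolerance = 1e-9)
  # affine example: population mean 0, proband mean 2, score 1 -> 0.5
  x2 <- c(-2, 0, 1, 2, 2, 2, -3)  # mean 2/7... construct exactly:
  x2 <- c(-1, 1, 2, 2)  # pop mean 1; probands the 2s -> proband mean 2
  z2 <- (x2 - 1) / (2 - 1)
  expect_equal(df_transform(x2, x2 == 2), z2)
  expect_error(df_transform(rep(1, 5), rep(TRUE, 5)), "degenerate")
})

test_that("co-twin means order like twin correlations under genetic load", {
  d <- ae_cohort(5000, 5000, a2 = 0.65, seed = 19)
  res <- group_heritability(d, 5, method = "regression")
  expect_gt(res$cotwin_means["MZ"], res$cotwin_means["DZ"])
  expect_gt(res$cotwin_means["DZ"], 0)
})

test_that("group heritability matches the generating h2 and both methods agree", {
  d <- ae_cohort(5000, 5000, a2 = 0.65, seed = 23)
  res <- group_heritability(d, 10)
  expect_equal(res$estimates$regression$h2g, 0.65, tolerance = 0.08)
  expect_equal(res$estimates$model$h2g, 0.65, tolerance = 0.08)
  expect_lt(abs(res$estimates$regression$h2g - res$estimates$model$h2g),
            0.03)
  # pure-E data: h2g ~ 0 at any percentile
  d0 <- simulate_continuous(sim_config(4000, 4000, a2 = 0, c2 = 0, e2 = 1,
                                       seed = 29))
  for (p in c(5, 10)) {
    r0 <- group_heritability(d0, p, method = "regression")
    expect_lt(abs(r0$diagnostics$regression_raw_h2g), 0.1)
  }
})

test_that("a wide proband group degenerates to the full-sample estimate", {
  d <- ae_cohort(8000, 8000, a2 = 0.65, seed = 37)
  res <- group_heritability(d, 50, method = "regression")
  full <- fit_ace(d, "AE", ci = "none")
  expect_equal(res$estimates$regression$h2g, full$estimates$a2,
               tolerance = 0.05)
})

test_that("h2g is invariant to affine rescaling of raw scores", {
  d <- ae_cohort(600, 600, seed = 43)
  r1 <- group_heritability(d, 10, method = "regression")
  d2 <- d
  d2$t1_score <- 3 + 2 * d$t1_score
  d2$t2_score <- 3 + 2 * d$t2_score
  r2 <- group_heritability(d2, 10, method = "regression")
  expect_equal(r1$estimates$regression$h2g, r2$estimates$regression$h2g,
               tolerance = 1e-9)
})

test_that("double entry is symmetric in proband labeling", {
  d <- ae_cohort(600, 600, seed = 47)
  r1 <- group_heritability(d, 10, method = "regression")
  # swap the twins: same pairs, opposite labeling
  d2 <- d
  d2$t1_score <- d$t2_score; d2$t2_score <- d$t1_score
  r2 <- group_heritability(d2, 10, method = "regression")
  expect_equal(r1$estimates$regression$h2g, r2$estimates$regression$h2g,
               tolerance = 1e-9)
})

test_that("missing probands in a zygosity group raise an explicit error", {
  d <- ae_cohort(50, 50, seed = 53)
  # force all top scores into MZ pairs
  d$t1_score[d$zygosity == "DZ"] <- -abs(d$t1_score[d$zygosity == "DZ"]) - 10
  d$t2_score[d$zygosity == "DZ"] <- -abs(d$t2_score[d$zygosity == "DZ"]) - 10
  expect_error(group_heritability(d, 5), "zygosity")
})
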