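# Questionnaire scoring, case classification, cohort summary.

test_that("total score is the mean of answered items under the 75% rule", {
  expect_equal(score_edi2(rep(1, 7), rep(1, 7), rep(1, 9)), 1)
  expect_equal(score_edi2(rep(6, 7), rep(6, 7), rep(6, 9)), 6)
  # one missing item per subscale still meets the minimums
  dt <- c(NA, rep(2, 6)); bu <- c(rep(3, 6), NA); bd <- c(rep(4, 7), NA, NA)
  expect_equal(score_edi2(dt, bu, bd),
               mean(c(rep(2, 6), rep(3, 6), rep(4, 7))))
  # permutation within subscale does not matter
  expect_equal(score_edi2(sample(dt), sample(bu), sample(bd)),
               score_edi2(dt, bu, bd))
  # appending an answered item equal to the current mean keeps the mean
  s0 <- score_edi2(rep(2, 7), rep(2, 7), c(rep(2, 7), NA, NA))
  s1 <- score_edi2(rep(2, 7), rep(2, 7), c(rep(2, 8), NA))
  expect_equal(s0, s1)
})

test_that("subscale completion below 75% yields a missing score", {
  # 5 of 7 answered on Drive for Thinness (needs >= 6)
  expect_true(is.na(score_edi2(c(rep(2, 5), NA, NA), rep(2, 7), rep(2, 9))))
  # 6 of 9 answered on Body Dissatisfaction (needs >= 7)
  expect_true(is.na(score_edi2(rep(2, 7), rep(2, 7),
                               c(rep(2, 6), NA, NA, NA))))
})

test_that("invalid item responses and lengths are rejected", {
  expect_error(score_edi2(c(rep(2, 6), 7), rep(2, 7), rep(2, 9)),
               "outside 1..6")
  expect_error(score_edi2(rep(2, 6), rep(2, 7), rep(2, 9)), "7 items")
})

test_that("log transform is exact and guards its domain", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(exp(1)), 1)
  expect_equal(log_transform(2.66), 0.9783, tolerance = 1e-4)
  expect_error(log_transform(c(2, 0)), "positive")
})

test_that("classification applies AN precedence over other-ED sources", {
  expect_equal(as.character(classify_ed(npr_an = TRUE,
                                        self_purging = TRUE)$group), "AN")
  expect_equal(as.character(classify_ed(self_purging = TRUE)$group), "OED")
  expect_equal(as.character(classify_ed(parent_treat_bn = TRUE,
                                        parent_treat_an = TRUE)$group), "AN")
  none <- classify_ed(FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(as.character(none$group), "NONE")
  expect_false(none$any_ed)
  # missing flags act as FALSE
  expect_equal(as.character(classify_ed(npr_an = NA,
                                        self_purging = TRUE)$group), "OED")
})

test_that("adding a source flag never demotes a classification", {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  names(grid) <- c("npr_an", "npr_oed", "parent_treat_an",
                   "parent_treat_bn", "self_purging")
  rank <- function(g) match(as.character(g), c("NONE", "OED", "AN"))
  base <- rank(classify_ed(grid$npr_an, grid$npr_oed, grid$parent_treat_an,
                           grid$parent_treat_bn, grid$self_purging)$group)
  for (j in seq_len(5)) {
    g2 <- grid; g2[[j]] <- TRUE
    up <- rank(classify_ed(g2$npr_an, g2$npr_oed, g2$parent_treat_an,
                           g2$parent_treat_bn, g2$self_purging)$group)
    expect_true(all(up >= base))
  }
})

test_that("ICD-10 codes parse with or without dots, exclusions dropped", {
  p <- parse_icd_codes(c("F500", "F50.9"))
  expect_true(p$npr_an); expect_true(p$npr_oed); expect_false(p$npr_bn)
  p2 <- parse_icd_codes(c("F50.4", "F98.2"))
  expect_false(p2$npr_an); expect_false(p2$npr_oed)
  expect_equal(p2$n_excluded, 2)
  expect_true(parse_icd_codes("F502")$npr_bn)
})

test_that("cohort summary reproduces known margins and overlaps", {
  f <- ed_flags_fixture()
  s <- cohort_summary(f)
  g <- function(nm) s$groups$percent[s$groups$group == nm]
  expect_equal(g("any_ed"), 5.7)
  expect_equal(s$sources$percent[s$sources$source == "npr_any"], 3.1)
  expect_equal(s$sources$percent[s$sources$source == "self_purging"], 3.2)
  expect_equal(s$overlap$any_ed_with_npr, 55.0)
  expect_equal(s$overlap$parent_an_with_npr_an, 56.5)
  expect_equal(s$overlap$parent_bn_with_npr_bn, 12.5)
  # mutually exclusive groups account for everyone
  excl <- s$groups[s$groups$group %in% c("AN", "OED", "NONE"), ]
  expect_equal(sum(excl$count), s$n)
  expect_equal(sum(excl$percent), 100, tolerance = 0.2)
})

test_that("cohort summary guards degenerate input", {
  expect_error(cohort_summary(data.frame()), "non-empty")
  one <- data.frame(npr_an = FALSE, npr_oed = FALSE, parent_treat_an = FALSE,
                    parent_treat_bn = FALSE, self_purging = FALSE)
  s <- cohort_summary(one)
  expect_equal(s$groups$percent[s$groups$group == "any_ed"], 0)
})
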