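# Shared fixtures, built in code at test time.

# small AE cohort on the standard-normal scale
ae_cohort <- function(n_mz = 768, n_dz = 713, a2 = 0.65, seed = 1) {
  simulate_continuous(sim_config(n_mz, n_dz, a2 = a2, c2 = 0, e2 = 1 - a2,
                                 seed = seed))
}

# slow, independent oracle for P(X > h, Y > k): nested 1-D quadrature of
# the conditional-normal representation, written without pbvn_upper
quad_orthant <- function(h, k, rho) {
  if (rho == 0) return(pnorm(-h) * pnorm(-k))
  s <- sqrt(1 - rho^2)
  f <- function(x) dnorm(x) * pnorm((k - rho * x) / s, lower.tail = FALSE)
  integrate(f, if (is.finite(h)) h else -40, 40,
            rel.tol = 1e-13, abs.tol = 1e-14, subdivisions = 500L)$value
}

# individual-level source-flag table reproducing a registry-linked
# three-source ascertainment pattern with known printed margins:
# 2962 individuals, 169 any-ED (93 register, 46 parent-AN, 8 parent-BN,
# 96 purging), 26 parent-AN with register AN, 1 parent-BN with register BN
ed_flags_fixture <- function() {
  n <- 2962
  f <- data.frame(npr_an = rep(FALSE, n), npr_oed = FALSE, npr_bn = FALSE,
                  parent_treat_an = FALSE, parent_treat_bn = FALSE,
                  self_purging = FALSE)
  # register: 57 AN-coded, 36 other-ED-coded (8 of them BN-coded) = 93
  f$npr_an[1:57] <- TRUE
  f$npr_oed[58:93] <- TRUE
  f$npr_bn[58:65] <- TRUE
  # parent-reported AN treatment: 46 total, 26 overlapping register AN
  f$parent_treat_an[c(1:26, 94:113)] <- TRUE
  # parent-reported BN treatment: 8 total, 1 overlapping register BN,
  # 6 also treated for AN
  f$parent_treat_bn[c(58, 94:99, 114)] <- TRUE
  # self-reported purging: 96 total, filling any-ED up to 169:
  # 40 overlap earlier sources, 56 new
  f$self_purging[c(30:57, 58:65, 94:97, 114:169)] <- TRUE
  f
}
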