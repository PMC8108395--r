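# Univariate twin models for a continuous phenotype: saturated models with
# equality constraints (assumption testing), twin correlations, and the
# ACE family (ACE / ADE / AE / CE / E) by full maximum likelihood.

# -2 log-likelihood of bivariate-normal pair data under common structure
.m2ll_cont_group <- function(y, m1, m2, v1, v2, r) {
  if (nrow(y) == 0) return(0)
  -2 * sum(.ldbvn(y[[1]], y[[2]], m1, m2, v1, v2, r))
}

#' Saturated bivariate-normal model of twin-pair data
#'
#' Fits per-zygosity bivariate normal distributions to the twin pairs by
#' maximum likelihood, at one of three constraint levels used for
#' assumption testing: \code{"none"} (per-zygosity, per-twin-order means
#' and variances plus a covariance; closed-form MLEs equal the sample
#' moments with 1/n denominators), \code{"order"} (means and variances
#' equated across twin order within zygosity), and \code{"zygosity"}
#' (means and variances additionally equated across zygosity — the
#' constrained model twin correlations are read from).
#'
#' @param pairs Pair table with \code{zygosity}, \code{t1_score},
#'   \code{t2_score}; incomplete pairs are dropped (listwise).
#' @param constraints One of \code{"none"}, \code{"order"},
#'   \code{"zygosity"}.
#' @param score_cols Names of the two phenotype columns.
#' @return An object of class \code{sat_fit}: per-zygosity means,
#'   variances, covariance and correlation, \code{minus2LL}, \code{npar},
#'   pair counts.
#' @export
fit_saturated <- function(pairs, constraints = c("none", "order", "zygosity"),
                          score_cols = c("t1_score", "t2_score")) {
  constraints <- match.arg(constraints)
  d <- .prep_pairs(pairs, score_cols)
  if (d$n_mz < 2 || d$n_dz < 2)
    stop("need at least 2 complete pairs per zygosity")

  if (constraints == "none") {
    est <- lapply(list(MZ = d$mz, DZ = d$dz), function(y) {
      n <- nrow(y)
      m1 <- mean(y[[1]]); m2 <- mean(y[[2]])
      v1 <- mean((y[[1]] - m1)^2); v2 <- mean((y[[2]] - m2)^2)
      cv <- mean((y[[1]] - m1) * (y[[2]] - m2))
      list(means = c(m1, m2), vars = c(v1, v2), cov = cv,
           cor = cv / sqrt(v1 * v2))
    })
    m2ll <- .m2ll_cont_group(d$mz, est$MZ$means[1], est$MZ$means[2],
                             est$MZ$vars[1], est$MZ$vars[2], est$MZ$cor) +
            .m2ll_cont_group(d$dz, est$DZ$means[1], est$DZ$means[2],
                             est$DZ$vars[1], est$DZ$vars[2], est$DZ$cor)
    npar <- 10L
    converged <- TRUE
  } else if (constraints == "order") {
    # theta: mu_mz, lv_mz, z_mz, mu_dz, lv_dz, z_dz
    fn <- function(th) {
      .m2ll_cont_group(d$mz, th[1], th[1], exp(th[2]), exp(th[2]),
                       tanh(th[3])) +
      .m2ll_cont_group(d$dz, th[4], th[4], exp(th[5]), exp(th[5]),
                       tanh(th[6]))
    }
    st <- .sat_starts(d)
    r <- .ml_minimize(fn, list(c(st$mu_mz, st$lv_mz, st$z_mz,
                                 st$mu_dz, st$lv_dz, st$z_dz)))
    est <- list(
      MZ = list(means = rep(r$par[1], 2), vars = rep(exp(r$par[2]), 2),
                cov = exp(r$par[2]) * tanh(r$par[3]), cor = tanh(r$par[3])),
      DZ = list(means = rep(r$par[4], 2), vars = rep(exp(r$par[5]), 2),
                cov = exp(r$par[5]) * tanh(r$par[6]), cor = tanh(r$par[6])))
    m2ll <- r$value; npar <- 6L; converged <- r$converged
  } else {
    # theta: mu, lv, z_mz, z_dz
    fn <- function(th) {
      v <- exp(th[2])
      .m2ll_cont_group(d$mz, th[1], th[1], v, v, tanh(th[3])) +
      .m2ll_cont_group(d$dz, th[1], th[1], v, v, tanh(th[4]))
    }
    st <- .sat_starts(d)
    r <- .ml_minimize(fn, list(c(st$mu, st$lv, st$z_mz, st$z_dz)))
    v <- exp(r$par[2])
    est <- list(
      MZ = list(means = rep(r$par[1], 2), vars = rep(v, 2),
                cov = v * tanh(r$par[3]), cor = tanh(r$par[3])),
      DZ = list(means = rep(r$par[1], 2), vars = rep(v, 2),
                cov = v * tanh(r$par[4]), cor = tanh(r$par[4])))
    m2ll <- r$value; npar <- 4L; converged <- r$converged
  }

  structure(list(model = "SAT", constraints = constraints, zygosity = est,
                 minus2LL = m2ll, npar = npar,
                 AIC = .aic(m2ll, npar), BIC = .bic(m2ll, npar, d$n_pairs),
                 n_pairs = d$n_pairs, n_mz = d$n_mz, n_dz = d$n_dz,
                 converged = converged),
            class = c("sat_fit", "twin_fit"))
}

.sat_starts <- function(d) {
  all_y <- c(d$mz[[1]], d$mz[[2]], d$dz[[1]], d$dz[[2]])
  cl <- function(r) atanh(max(min(r, 0.99), -0.99))
  list(mu = mean(all_y), lv = log(stats::var(all_y)),
       mu_mz = mean(c(d$mz[[1]], d$mz[[2]])),
       lv_mz = log(stats::var(c(d$mz[[1]], d$mz[[2]]))),
       z_mz = cl(stats::cor(d$mz[[1]], d$mz[[2]])),
       mu_dz = mean(c(d$dz[[1]], d$dz[[2]])),
       lv_dz = log(stats::var(c(d$dz[[1]], d$dz[[2]]))),
       z_dz = cl(stats::cor(d$dz[[1]], d$dz[[2]])))
}

#' Assumption tests for the twin model
#'
#' Likelihood-ratio tests of the equality constraints the genetic models
#' impose: means/variances equal across twin order within zygosity, and
#' additionally across zygosity.
#'
#' @inheritParams fit_saturated
#' @return Data frame with one row per constraint level and the LRT of
#'   each level against the unconstrained saturated model.
#' @export
assumption_tests <- function(pairs, score_cols = c("t1_score", "t2_score")) {
  fits <- lapply(c("none", "order", "zygosity"), fit_saturated,
                 pairs = pairs, score_cols = score_cols)
  base <- fits[[1]]
  rows <- lapply(fits, function(f) {
    data.frame(constraints = f$constraints, minus2LL = f$minus2LL,
               npar = f$npar,
               delta_chisq = f$minus2LL - base$minus2LL,
               delta_df = base$npar - f$npar,
               p = if (f$npar < base$npar)
                 stats::pchisq(max(f$minus2LL - base$minus2LL, 0),
                               base$npar - f$npar, lower.tail = FALSE)
               else NA_real_)
  })
  do.call(rbind, rows)
}

#' Twin correlations from a constrained saturated model
#'
#' Maximum-likelihood within-pair correlations by zygosity, with means and
#' variances equated across twin order and zygosity, and profile-likelihood
#' 95% confidence intervals.
#'
#' @inheritParams fit_saturated
#' @param ci Compute profile-likelihood CIs?
#' @param level Confidence level.
#' @return Data frame with rows MZ and DZ: \code{r}, \code{lower},
#'   \code{upper}.
#' @export
twin_correlations <- function(pairs, score_cols = c("t1_score", "t2_score"),
                              ci = TRUE, level = 0.95) {
  d <- .prep_pairs(pairs, score_cols)
  fit <- fit_saturated(pairs, "zygosity", score_cols)
  r_mz <- fit$zygosity$MZ$cor; r_dz <- fit$zygosity$DZ$cor
  out <- data.frame(zygosity = c("MZ", "DZ"), r = c(r_mz, r_dz),
                    lower = NA_real_, upper = NA_real_)
  if (ci) {
    st <- .sat_starts(d)
    prof <- function(which_z) function(r0) {
      fn <- function(th) {
        v <- exp(th[2])
        r3 <- if (which_z == "MZ") r0 else tanh(th[3])
        r4 <- if (which_z == "DZ") r0 else tanh(th[3])
        .m2ll_cont_group(d$mz, th[1], th[1], v, v, r3) +
        .m2ll_cont_group(d$dz, th[1], th[1], v, v, r4)
      }
      z_other <- atanh(max(min(if (which_z == "MZ") r_dz else r_mz,
                               0.999), -0.999))
      .ml_minimize(fn, list(c(st$mu, st$lv, z_other)))$value
    }
    ci_mz <- .profile_ci(prof("MZ"), r_mz, fit$minus2LL, -1, 1, level)
    ci_dz <- .profile_ci(prof("DZ"), r_dz, fit$minus2LL, -1, 1, level)
    out$lower <- c(ci_mz[1], ci_dz[1])
    out$upper <- c(ci_mz[2], ci_dz[2])
  }
  attr(out, "minus2LL") <- fit$minus2LL
  out
}

#' Fit an ACE-family model to continuous twin data
#'
#' Full-ML fit of a variance-components model with expected within-pair
#' covariance \eqn{a^2 + c^2} (MZ) and \eqn{0.5 a^2 + c^2} (DZ) — for ADE,
#' \eqn{a^2 + d^2} and \eqn{0.5 a^2 + 0.25 d^2} — and the grand mean and
#' total variance equated across twins and zygosity.  Standardized
#' components are parameterized through squared-path ratios, so they are
#' non-negative and sum to one by construction; 95% confidence intervals
#' are profile-likelihood intervals on the standardized scale (respecting
#' the boundary at 0/1).
#'
#' @inheritParams fit_saturated
#' @param model One of \code{"ACE"}, \code{"ADE"}, \code{"AE"},
#'   \code{"CE"}, \code{"E"}.
#' @param ci \code{"profile"} or \code{"none"}.
#' @param level Confidence level for the profile CIs.
#' @param bic_n Sample-size convention for BIC: \code{"pairs"} (default)
#'   or \code{"individuals"}.
#' @return A \code{twin_fit} object: \code{estimates} (standardized
#'   \code{a2, c2, d2, e2}, plus \code{mu} and \code{total_var}),
#'   \code{paths} (unstandardized path coefficients), \code{ci},
#'   \code{minus2LL}, \code{npar}, \code{AIC}, \code{BIC},
#'   \code{converged}, \code{boundary} (components pinned at 0).
#' @export
fit_ace <- function(pairs, model = c("ACE", "ADE", "AE", "CE", "E"),
                    score_cols = c("t1_score", "t2_score"),
                    ci = c("profile", "none"), level = 0.95,
                    bic_n = c("pairs", "individuals")) {
  model <- match.arg(model)
  ci <- match.arg(ci)
  bic_n <- match.arg(bic_n)
  d <- .prep_pairs(pairs, score_cols)
  if (d$n_mz < 2 || d$n_dz < 2)
    stop("need at least 2 complete pairs per zygosity")

  k_free <- .n_prop_free(model)
  obj <- function(th) {
    v <- exp(th[2])
    p <- .props_map(model, th[seq_len(k_free) + 2])
    r <- .twin_r(p)
    .m2ll_cont_group(d$mz, th[1], th[1], v, v, r["mz"]) +
      .m2ll_cont_group(d$dz, th[1], th[1], v, v, r["dz"])
  }

  st <- .sat_starts(d)
  r_mz <- tanh(st$z_mz); r_dz <- tanh(st$z_dz)
  # moment-based and agnostic starting proportions
  p_mom <- if (model == "ADE") {
    # ADE moments: rMZ = a2 + d2, rDZ = a2/2 + d2/4
    c(a2 = min(max(4 * r_dz - r_mz, 0.02), 0.95), c2 = 0.01,
      d2 = min(max(2 * r_mz - 4 * r_dz, 0.02), 0.95))
  } else {
    c(a2 = min(max(2 * (r_mz - r_dz), 0.02), 0.95),
      c2 = min(max(2 * r_dz - r_mz, 0.02), 0.95), d2 = 0.02)
  }
  p_mom <- c(p_mom, e2 = max(1 - sum(p_mom[c("a2", "c2")]), 0.05))
  p_mom <- p_mom / sum(p_mom)
  starts <- list(
    c(st$mu, st$lv, .props_unmap(model, p_mom)),
    c(st$mu, st$lv, .props_unmap(model, c(1, 1, 1, 1) / 3)[seq_len(k_free)]),
    c(st$mu, st$lv, .props_unmap(model, c(0.6, 0.1, 0.1, 0.3))))
  starts <- lapply(starts, function(s) s[seq_len(2 + k_free)])
  fit <- .ml_minimize(obj, starts)

  mu <- fit$par[1]; v <- exp(fit$par[2])
  p <- .props_map(model, fit$par[seq_len(k_free) + 2])
  names(p) <- c("a2", "c2", "d2", "e2")
  paths <- sqrt(p * v)
  names(paths) <- c("a", "c", "d", "e")
  m2ll <- fit$value
  npar <- 2L + k_free
  n_bic <- if (bic_n == "pairs") d$n_pairs else 2L * d$n_pairs

  comp_free <- switch(model, ACE = c("a2", "c2", "e2"),
                      ADE = c("a2", "d2", "e2"),
                      AE = c("a2", "e2"), CE = c("c2", "e2"), E = "e2")
  ci_tab <- matrix(NA_real_, length(comp_free), 2,
                   dimnames = list(comp_free, c("lower", "upper")))
  if (ci == "profile" && model != "E") {
    for (comp in comp_free) {
      prof <- .make_cont_profile(model, comp, d, st)
      ci_tab[comp, ] <- .profile_ci(prof, p[comp], m2ll, 0, 1, level)
    }
  }

  structure(list(model = model, minus2LL = m2ll, npar = npar,
                 estimates = c(as.list(p), list(mu = mu, total_var = v)),
                 paths = paths, ci = ci_tab,
                 AIC = .aic(m2ll, npar), BIC = .bic(m2ll, npar, n_bic),
                 bic_n = bic_n,
                 n_pairs = d$n_pairs, n_mz = d$n_mz, n_dz = d$n_dz,
                 converged = fit$converged,
                 boundary = names(p)[p < 1e-6 &
                                       names(p) %in% comp_free]),
            class = c("ace_fit", "twin_fit"))
}

# profiled -2LL for one standardized component of a continuous model
.make_cont_profile <- function(model, comp, d, st) {
  force(model); force(comp); force(d); force(st)
  needs_u <- model %in% c("ACE", "ADE")
  function(t) {
    fn <- function(th) {
      v <- exp(th[2])
      u <- if (needs_u) th[3] else 0
      p <- .props_fixed(model, comp, t, u)
      r <- .twin_r(p)
      .m2ll_cont_group(d$mz, th[1], th[1], v, v, r["mz"]) +
        .m2ll_cont_group(d$dz, th[1], th[1], v, v, r["dz"])
    }
    starts <- if (needs_u)
      list(c(st$mu, st$lv, 0), c(st$mu, st$lv, -2), c(st$mu, st$lv, 2))
    else list(c(st$mu, st$lv))
    .ml_minimize(fn, starts)$value
  }
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%d MZ + %d DZ pairs)\n",
              x$model, x$n_mz, x$n_dz))
  cat(sprintf("  -2LL = %.3f  npar = %d  AIC = %.3f  BIC = %.3f\n",
              x$minus2LL, x$npar, x$AIC, x$BIC))
  if (!is.null(x$estimates$a2)) {
    p <- unlist(x$estimates[c("a2", "c2", "d2", "e2")])
    keep <- p > 1e-12 | names(p) %in% rownames(x$ci)
    for (nm in names(p)[keep]) {
      ciline <- if (!is.null(x$ci) && nm %in% rownames(x$ci) &&
                    is.finite(x$ci[nm, 1]))
        sprintf("  (95%% CI %.3f-%.3f)", x$ci[nm, 1], x$ci[nm, 2]) else ""
      cat(sprintf("  %s = %.3f%s\n", nm, p[nm], ciline))
    }
  }
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  if (length(x$boundary)) cat("  boundary components:",
                              paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}
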