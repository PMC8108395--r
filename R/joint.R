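# Joint categorical-continuous bivariate twin model: one continuous trait
# and one threshold-liability trait, in a correlated-factors
# parameterization (per-trait A/C/E proportions plus cross-trait factor
# correlations rA, rC, rE), yielding the genetic correlation, the
# non-shared environmental correlation, the phenotypic correlation
# rPH = rA a1 a2 + rC c1 c2 + rE e1 e2 and the bivariate heritability
# rA a1 a2 / rPH.
#
# Likelihood per pair: the two continuous scores are bivariate normal; the
# two binary outcomes are, conditionally on the scores, a dichotomized
# bivariate normal whose conditional mean and correlation follow from the
# 4-variate structure (y1, y2, l1, l2).  The 4-dimensional integral thus
# factorizes into a closed-form density times a 2-D orthant integral —
# deterministic quadrature throughout.

# per-zygosity structure matrices for a parameter list th:
#  th: mu, v (continuous trait variance), p1 = c(a2,c2,d2,e2) trait 1,
#  t2 (threshold), p2 trait 2 (liability, unit variance), rA, rC, rE
.joint_struct <- function(th, R) {
  p1 <- th$p1; p2 <- th$p2
  r1 <- R * p1[1] + p1[2]
  r2 <- R * p2[1] + p2[2]
  a1 <- sqrt(p1[1]); c1 <- sqrt(p1[2]); e1 <- sqrt(p1[4])
  a2 <- sqrt(p2[1]); c2 <- sqrt(p2[2]); e2 <- sqrt(p2[4])
  w <- th$rA * a1 * a2 + th$rC * c1 * c2 + th$rE * e1 * e2  # within twin
  x <- R * th$rA * a1 * a2 + th$rC * c1 * c2                # cross twin
  list(r1 = r1, r2 = r2, w = w, x = x)
}

# -2LL contribution of one zygosity group
.m2ll_joint_group <- function(y, dx, th, R) {
  y1 <- y[[1]]; y2 <- y[[2]]
  n <- length(y1)
  if (n == 0) return(0)
  d1 <- dx[[1]]; d2 <- dx[[2]]
  s <- .joint_struct(th, R)
  v <- th$v
  if (v <= 0) return(Inf)
  det_yy <- 1 - s$r1^2
  if (det_yy <= 0) return(Inf)
  # continuous part: bivariate normal with common mean/variance
  sv <- sqrt(v)
  z1 <- (y1 - th$mu) / sv
  z2 <- (y2 - th$mu) / sv
  q <- (z1 * z1 - 2 * s$r1 * z1 * z2 + z2 * z2) / det_yy
  ll_c <- n * (-log(2 * pi) - log(v) - 0.5 * log(det_yy)) - 0.5 * sum(q)
  # conditional distribution of (l1, l2) | (y1, y2)
  # Sigma_yy (std) = [[1, r1], [r1, 1]]; Sigma_ly = [[w, x], [x, w]]
  # B = Sigma_ly %*% solve(Sigma_yy): symmetric with entries b1, b2
  b1 <- (s$w - s$x * s$r1) / det_yy
  b2 <- (s$x - s$w * s$r1) / det_yy
  cv11 <- 1 - (b1 * s$w + b2 * s$x)
  cv12 <- s$r2 - (b1 * s$x + b2 * s$w)
  if (cv11 <= 1e-10 || abs(cv12) >= cv11) return(Inf)
  sc <- sqrt(cv11)
  rc <- cv12 / cv11
  h1 <- (th$t2 - (b1 * z1 + b2 * z2)) / sc
  h2 <- (th$t2 - (b2 * z1 + b1 * z2)) / sc
  p11 <- pbvn_upper(h1, h2, rc)
  u1 <- pnorm(h1, lower.tail = FALSE)
  u2 <- pnorm(h2, lower.tail = FALSE)
  p <- d1 * d2 * p11 + d1 * (1 - d2) * (u1 - p11) +
    (1 - d1) * d2 * (u2 - p11) + (1 - d1) * (1 - d2) * (1 - u1 - u2 + p11)
  ll_b <- sum(log(pmax(p, 1e-300)))
  -2 * (ll_c + ll_b)
}

# full-data -2LL from a natural-scale parameter list
.joint_m2ll <- function(th, dmz, dxmz, ddz, dxdz) {
  .m2ll_joint_group(dmz, dxmz, th, 1) + .m2ll_joint_group(ddz, dxdz, th, 0.5)
}

# free-parameter vector <-> natural parameter list, per model family.
# layout: mu, lv, [prop1 free], t2, [prop2 free], zA?, zC?, zE
.joint_par_layout <- function(model) {
  k <- .n_prop_free(model)
  has <- switch(model, ACE = c(A = TRUE, C = TRUE, E = TRUE),
                AE = c(A = TRUE, C = FALSE, E = TRUE),
                CE = c(A = FALSE, C = TRUE, E = TRUE),
                E = c(A = FALSE, C = FALSE, E = TRUE))
  list(k = k, has = has, npar = 3L + 2L * k + sum(has))
}

.joint_unpack <- function(par, model) {
  lay <- .joint_par_layout(model)
  k <- lay$k
  i <- 0
  nxt <- function(n) { v <- par[i + seq_len(n)]; i <<- i + n; v }
  mu <- nxt(1); lv <- nxt(1)
  p1 <- .props_map(model, nxt(k))
  t2 <- nxt(1)
  p2 <- .props_map(model, nxt(k))
  rA <- if (lay$has["A"]) tanh(nxt(1)) else 0
  rC <- if (lay$has["C"]) tanh(nxt(1)) else 0
  rE <- if (lay$has["E"]) tanh(nxt(1)) else 0
  list(mu = mu, v = exp(lv), p1 = p1, t2 = t2, p2 = p2,
       rA = rA, rC = rC, rE = rE)
}

#' Cross-twin cross-trait correlations (continuous x liability)
#'
#' Polyserial-type ML correlation between one twin's continuous score and
#' the co-twin's liability to the binary trait, pooled over the two
#' orderings, per zygosity.  The continuous score is standardized with its
#' sample moments; the threshold and the correlation are estimated by ML.
#'
#' @param pairs Pair table with continuous and binary per-twin columns.
#' @param score_cols,dx_cols Column names.
#' @param ci Compute profile-likelihood CIs?
#' @param level Confidence level.
#' @return Data frame per zygosity: \code{r}, \code{threshold},
#'   \code{lower}, \code{upper}, \code{inestimable}.
#' @export
cross_twin_cross_trait <- function(pairs,
                                   score_cols = c("t1_score", "t2_score"),
                                   dx_cols = c("t1_dx", "t2_dx"),
                                   ci = FALSE, level = 0.95) {
  d <- .prep_pairs(pairs, c(score_cols, dx_cols))
  one <- function(y, zyg) {
    # pool (score of twin i, dx of twin j), i != j
    z <- c(y[[1]], y[[2]])
    z <- (z - mean(z)) / stats::sd(z)
    dx <- c(y[[4]], y[[3]])
    if (sum(dx) == 0)
      return(data.frame(zygosity = zyg, r = NA, threshold = NA,
                        lower = NA, upper = NA, inestimable = TRUE))
    nll <- function(th) {
      t0 <- th[1]; r <- tanh(th[2])
      # P(dx = 1 | z) = Phi((r z - t0)/sqrt(1-r^2))
      q <- (r * z - t0) / sqrt(1 - r^2)
      pr <- pnorm(q)
      pr <- pmin(pmax(ifelse(dx == 1, pr, 1 - pr), 1e-300), 1)
      -2 * sum(log(pr))
    }
    t_start <- qnorm(mean(dx), lower.tail = FALSE)
    fit <- .ml_minimize(nll, list(c(t_start, 0), c(t_start, 0.7),
                                  c(t_start, -0.7)))
    lo <- hi <- NA_real_
    if (ci) {
      prof <- function(r0) {
        z0 <- atanh(max(min(r0, 1 - 1e-12), -1 + 1e-12))
        .ml_minimize(function(t0) nll(c(t0, z0)), list(fit$par[1]))$value
      }
      cis <- .profile_ci(prof, tanh(fit$par[2]), fit$value, -1, 1, level)
      lo <- cis[1]; hi <- cis[2]
    }
    data.frame(zygosity = zyg, r = tanh(fit$par[2]), threshold = fit$par[1],
               lower = lo, upper = hi, inestimable = FALSE)
  }
  out <- rbind(one(d$mz, "MZ"), one(d$dz, "DZ"))
  rownames(out) <- NULL
  out
}

#' Fit a joint categorical-continuous bivariate twin model
#'
#' Maximum-likelihood fit of the correlated-factors model described above
#' to pairs measured on a continuous trait and a binary
#' (liability-threshold) trait.  The liability threshold is estimated
#' freely, equated across twins and zygosity.  Profile-likelihood CIs are
#' computed for the cross-trait correlations (\code{rA}, \code{rE}) and,
#' optionally, the per-trait heritabilities.
#'
#' @param pairs Pair table with \code{zygosity}, the two score columns and
#'   the two binary columns.
#' @param model \code{"ACE"}, \code{"AE"}, \code{"CE"} or \code{"E"},
#'   applied to both traits.
#' @param score_cols,dx_cols Column names.
#' @param ci \code{"profile"} or \code{"none"}.
#' @param ci_components Also profile the per-trait \code{a2}
#'   heritabilities (slower)?
#' @param level Confidence level.
#' @param bic_n BIC sample-size convention.
#' @return A \code{joint_fit} object: per-trait standardized components,
#'   threshold, \code{rA}, \code{rC}, \code{rE} with CIs, \code{rPH},
#'   \code{bivariate_h2} (share of rPH due to A), model-implied cross-twin
#'   cross-trait correlations by zygosity, \code{minus2LL}, AIC/BIC,
#'   convergence and boundary flags.
#' @export
fit_joint <- function(pairs, model = c("ACE", "AE", "CE", "E"),
                      score_cols = c("t1_score", "t2_score"),
                      dx_cols = c("t1_dx", "t2_dx"),
                      ci = c("profile", "none"), ci_components = FALSE,
                      level = 0.95, bic_n = c("pairs", "individuals")) {
  model <- match.arg(model)
  ci <- match.arg(ci)
  bic_n <- match.arg(bic_n)
  d <- .prep_pairs(pairs, c(score_cols, dx_cols))
  dmz <- d$mz[1:2]; dxmz <- d$mz[3:4]
  ddz <- d$dz[1:2]; dxdz <- d$dz[3:4]
  if (sum(dxmz[[1]], dxmz[[2]]) == 0 || sum(dxdz[[1]], dxdz[[2]]) == 0)
    stop("need affected individuals in both zygosity groups")

  lay <- .joint_par_layout(model)
  obj <- function(par) {
    th <- .joint_unpack(par, model)
    .joint_m2ll(th, dmz, dxmz, ddz, dxdz)
  }

  # starts from univariate fits and margins
  all_y <- c(dmz[[1]], dmz[[2]], ddz[[1]], ddz[[2]])
  mu0 <- mean(all_y); lv0 <- log(stats::var(all_y))
  prev <- mean(c(dxmz[[1]], dxmz[[2]], dxdz[[1]], dxdz[[2]]))
  t20 <- qnorm(prev, lower.tail = FALSE)
  k <- lay$k
  p_def <- switch(model, ACE = c(0.5, 0.1, 0, 0.4), AE = c(0.6, 0, 0, 0.4),
                  CE = c(0, 0.5, 0, 0.5), E = c(0, 0, 0, 1))
  base <- c(mu0, lv0, .props_unmap(model, p_def), t20,
            .props_unmap(model, p_def))
  mk <- function(rz) c(base, rz[seq_len(sum(lay$has))])
  starts <- list(mk(c(0.4, 0.2, 0.4)), mk(c(0, 0, 0)))
  fit <- .ml_minimize(obj, starts, nm_maxit = 800)
  th <- .joint_unpack(fit$par, model)

  names(th$p1) <- names(th$p2) <- c("a2", "c2", "d2", "e2")
  a1 <- sqrt(th$p1[["a2"]]); c1 <- sqrt(th$p1[["c2"]]); e1 <- sqrt(th$p1[["e2"]])
  a2p <- sqrt(th$p2[["a2"]]); c2p <- sqrt(th$p2[["c2"]]); e2p <- sqrt(th$p2[["e2"]])
  rPH <- th$rA * a1 * a2p + th$rC * c1 * c2p + th$rE * e1 * e2p
  biv_h2 <- if (abs(rPH) > 1e-12) th$rA * a1 * a2p / rPH else NA_real_
  s_mz <- .joint_struct(th, 1); s_dz <- .joint_struct(th, 0.5)

  m2ll <- fit$value
  npar <- lay$npar
  n_bic <- if (bic_n == "pairs") d$n_pairs else 2L * d$n_pairs

  # profile CIs on the cross-trait correlations
  ci_list <- list()
  if (ci == "profile") {
    r_names <- c("rA", "rC", "rE")[lay$has]
    # index of each correlation's free parameter in `par`
    idx0 <- 3L + 2L * k
    for (j in seq_along(r_names)) {
      nm <- r_names[j]
      ix <- idx0 + j
      # start each nuisance re-optimization from the solution at the
      # closest r0 already profiled (the profile path is continuous)
      cache_r <- th[[nm]]; cache_par <- list(fit$par[-ix])
      prof <- function(r0) {
        fn <- function(sub) {
          par <- numeric(lay$npar)
          par[-ix] <- sub
          par[ix] <- atanh(max(min(r0, 1 - 1e-9), -1 + 1e-9))
          obj(par)
        }
        r <- .ml_refine(fn, cache_par[[which.min(abs(cache_r - r0))]])
        if (r$value >= 1e11) r <- .ml_refine(fn, fit$par[-ix])
        if (r$value < 1e11) {
          cache_r <<- c(cache_r, r0)
          cache_par[[length(cache_par) + 1L]] <<- r$par
        }
        r$value
      }
      ci_list[[nm]] <- .profile_ci(prof, th[[nm]], m2ll, -1, 1, level,
                                   tol = 5e-4)
    }
    if (ci_components && k > 0) {
      for (tr in 1:2) {
        # profile a2 of trait `tr` by fixing it and re-optimizing the rest
        prof <- function(t) {
          fn <- function(sub) {
            # sub: all free params except trait tr's proportion block,
            # plus a split parameter when the model has 3 components
            par_fix <- .joint_fix_a2(sub, model, tr, t, lay)
            .joint_m2ll(par_fix, dmz, dxmz, ddz, dxdz)
          }
          .ml_refine(fn, .joint_sub_start(fit$par, model, tr, lay))$value
        }
        mle <- if (tr == 1) th$p1[["a2"]] else th$p2[["a2"]]
        ci_list[[paste0("h2_trait", tr)]] <-
          .profile_ci(prof, mle, m2ll, 0, 1, level)
      }
    }
  }

  structure(list(
    model = model, minus2LL = m2ll, npar = npar,
    estimates = list(
      continuous = c(as.list(th$p1[c("a2", "c2", "e2")]),
                     list(mu = th$mu, total_var = th$v)),
      liability = c(as.list(th$p2[c("a2", "c2", "e2")]),
                    list(threshold = th$t2)),
      rA = th$rA, rC = th$rC, rE = th$rE,
      rPH = rPH, bivariate_h2 = biv_h2),
    cross_twin_cross_trait = c(MZ = s_mz$x, DZ = s_dz$x),
    within_twin_cross_trait = s_mz$w,
    ci = ci_list,
    AIC = .aic(m2ll, npar), BIC = .bic(m2ll, npar, n_bic), bic_n = bic_n,
    n_pairs = d$n_pairs, n_mz = d$n_mz, n_dz = d$n_dz,
    converged = fit$converged,
    boundary = c(if (abs(th$rA) > 1 - 1e-4) "rA",
                 if (abs(th$rE) > 1 - 1e-4) "rE")),
    class = c("joint_fit", "twin_fit"))
}

# helpers for the component profile of fit_joint: rebuild the natural
# parameter list with trait `tr`'s a2 fixed at t
.joint_fix_a2 <- function(sub, model, tr, t, lay) {
  k <- lay$k
  i <- 0
  nxt <- function(n) { v <- sub[i + seq_len(n)]; i <<- i + n; v }
  mu <- nxt(1); lv <- nxt(1)
  free1 <- if (tr == 1) nxt(k - 1) else nxt(k)
  t2 <- nxt(1)
  free2 <- if (tr == 2) nxt(k - 1) else nxt(k)
  rz <- nxt(sum(lay$has))
  split_u <- if (k > 1) nxt(1) else numeric(0)
  fixed_props <- if (k > 1) .props_fixed(model, "a2", t, split_u)
                 else .props_fixed(model, "a2", t, 0)
  p1 <- if (tr == 1) fixed_props else .props_map(model, free1)
  p2 <- if (tr == 2) fixed_props else .props_map(model, free2)
  ri <- 0
  geta <- function(flag) if (flag) { ri <<- ri + 1; tanh(rz[ri]) } else 0
  list(mu = mu, v = exp(lv), p1 = p1, t2 = t2, p2 = p2,
       rA = geta(lay$has["A"]), rC = geta(lay$has["C"]),
       rE = geta(lay$has["E"]))
}

.joint_sub_start <- function(par, model, tr, lay) {
  k <- lay$k
  # drop trait tr's proportion block, append a neutral split parameter
  i_props <- if (tr == 1) 2L + seq_len(k) else 3L + k + seq_len(k)
  sub <- par[-i_props]
  if (k > 1) sub <- c(sub, 0)
  sub
}

#' Share of a phenotypic correlation explained by genetic overlap
#'
#' The bivariate heritability \code{rA * sqrt(h2_1 * h2_2) / rPH}: the
#' proportion of the phenotypic correlation between two traits that is due
#' to the additive genetic factors they share.
#'
#' @param rA Genetic correlation.
#' @param h2_1,h2_2 Heritabilities of the two traits.
#' @param rPH Phenotypic correlation.
#' @return Proportion (can exceed 1 when environmental contributions have
#'   opposite sign).
#' @export
bivariate_heritability <- function(rA, h2_1, h2_2, rPH) {
  if (any(rPH == 0)) stop("rPH must be nonzero")
  rA * sqrt(h2_1 * h2_2) / rPH
}

#' Phenotypic correlation implied by a cross-trait decomposition
#'
#' \code{rPH = rA a1 a2 + rC c1 c2 + rE e1 e2} with \code{a_i} etc. the
#' square roots of the standardized components.
#'
#' @param rA,rC,rE Cross-trait factor correlations.
#' @param comp1,comp2 Numeric vectors \code{c(a2, c2, e2)} per trait.
#' @return Implied phenotypic correlation.
#' @export
implied_rph <- function(rA, comp1, comp2, rE, rC = 0) {
  rA * sqrt(comp1[[1]] * comp2[[1]]) +
    rC * sqrt(comp1[[2]] * comp2[[2]]) +
    rE * sqrt(comp1[[3]] * comp2[[3]])
}

#' @export
print.joint_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("Joint categorical-continuous %s model (%d MZ + %d DZ pairs)\n",
              x$model, x$n_mz, x$n_dz))
  cat(sprintf("  -2LL = %.3f  npar = %d  AIC = %.3f  BIC = %.3f\n",
              x$minus2LL, x$npar, x$AIC, x$BIC))
  cat(sprintf("  continuous trait: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              e$continuous$a2, e$continuous$c2, e$continuous$e2))
  cat(sprintf("  liability trait:  a2 = %.3f, c2 = %.3f, e2 = %.3f (threshold %.3f)\n",
              e$liability$a2, e$liability$c2, e$liability$e2,
              e$liability$threshold))
  fmt_ci <- function(nm) if (!is.null(x$ci[[nm]]))
    sprintf(" (95%% CI %.3f-%.3f)", x$ci[[nm]][1], x$ci[[nm]][2]) else ""
  cat(sprintf("  rA = %.3f%s  rE = %.3f%s\n", e$rA, fmt_ci("rA"),
              e$rE, fmt_ci("rE")))
  cat(sprintf("  rPH = %.3f  bivariate heritability = %.3f\n",
              e$rPH, e$bivariate_h2))
  invisible(x)
}
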