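# Shared maximum-likelihood machinery: data preparation, multi-start
# quasi-Newton optimization, and profile-likelihood confidence intervals.
#
# All twin models parameterize standardized variance proportions through
# squared-path ratios, e.g. for ACE with free reals (pa, pc):
#   a2 = pa^2 / s,  c2 = pc^2 / s,  e2 = 1 / s,   s = pa^2 + pc^2 + 1.
# Every proportion is non-negative by construction, they sum to one
# exactly, and e2 > 0 structurally (E absorbs measurement error, so a model
# with e2 = 0 is never entertained).  Profile likelihoods for a
# standardized component fix it at a trial value t and re-optimize the
# rest, splitting the remaining 1 - t between the other two components
# with a logistic parameter.

# listwise-complete pairs split by zygosity; cols are required columns
.prep_pairs <- function(pairs, cols) {
  stopifnot(is.data.frame(pairs))
  miss <- setdiff(c("zygosity", cols), names(pairs))
  if (length(miss))
    stop("pair table lacks columns: ", paste(miss, collapse = ", "))
  zyg <- toupper(as.character(pairs$zygosity))
  if (!all(zyg %in% c("MZ", "DZ")))
    stop("`zygosity` must be 'MZ' or 'DZ'")
  keep <- stats::complete.cases(pairs[cols])
  pairs <- pairs[keep, , drop = FALSE]
  zyg <- zyg[keep]
  list(mz = pairs[zyg == "MZ", cols, drop = FALSE],
       dz = pairs[zyg == "DZ", cols, drop = FALSE],
       n_mz = sum(zyg == "MZ"), n_dz = sum(zyg == "DZ"),
       n_pairs = nrow(pairs))
}

# minimize fn over several starts; BFGS polish after Nelder-Mead when the
# dimension warrants it.  Returns the best optim result + a convergence flag.
.ml_minimize <- function(fn, starts, reltol = 1e-12, nm_maxit = 2000) {
  fn_raw <- fn
  fn <- function(p) {
    v <- tryCatch(fn_raw(p), error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL
  for (s in starts) {
    s <- unname(s)
    r <- tryCatch({
      if (length(s) > 1) {
        r0 <- stats::optim(s, fn, method = "Nelder-Mead",
                           control = list(maxit = nm_maxit, reltol = reltol))
        stats::optim(r0$par, fn, method = "BFGS",
                     control = list(maxit = 500, reltol = reltol))
      } else {
        stats::optim(s, fn, method = "Brent",
                     lower = s - 50, upper = s + 50)
      }
    }, error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
  }
  if (is.null(best)) stop("optimization failed from every starting point")
  best$converged <- best$convergence == 0
  best
}

# quick warm-start refinement: BFGS only, for profile-likelihood loops
# where the start is already near the optimum
.ml_refine <- function(fn, start, maxit = 50) {
  fn_raw <- fn
  fn <- function(p) {
    v <- tryCatch(fn_raw(p), error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  r <- tryCatch(
    stats::optim(unname(start), fn, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(r) || r$value >= 1e11)
    r <- stats::optim(unname(start), fn, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-9))
  r
}

# map free reals to standardized proportions for a given model family;
# returns c(a2, c2, d2, e2).  Number of free reals per model:
# ACE/ADE -> 2, AE/CE -> 1, E -> 0.
.props_map <- function(model, free) {
  sq <- free^2
  switch(model,
    ACE = { s <- sum(sq) + 1; c(sq[1], sq[2], 0, 1) / s },
    ADE = { s <- sum(sq) + 1; c(sq[1], 0, sq[2], 1) / s },
    AE  = { s <- sq[1] + 1; c(sq[1], 0, 0, 1) / s },
    CE  = { s <- sq[1] + 1; c(0, sq[1], 0, 1) / s },
    E   = c(0, 0, 0, 1),
    stop("unknown model '", model, "'"))
}

.n_prop_free <- function(model)
  switch(model, ACE = 2L, ADE = 2L, AE = 1L, CE = 1L, E = 0L)

# free reals reproducing given proportions (inverse of .props_map)
.props_unmap <- function(model, p) {
  # p = c(a2, c2, d2, e2); guard against zero e2
  e2 <- max(p[4], 1e-6)
  switch(model,
    ACE = sqrt(pmax(p[1:2], 1e-8) / e2),
    ADE = sqrt(pmax(c(p[1], p[3]), 1e-8) / e2),
    AE  = sqrt(max(p[1], 1e-8) / e2),
    CE  = sqrt(max(p[2], 1e-8) / e2),
    E   = numeric(0))
}

# expected twin correlations from proportions c(a2, c2, d2, e2)
.twin_r <- function(p) c(mz = p[[1]] + p[[2]] + p[[3]],
                         dz = 0.5 * p[[1]] + p[[2]] + 0.25 * p[[3]])

# proportions with one component fixed at t, remaining split by plogis(u);
# `fixed` is "a2" (or "d2" for ADE); models with 2 components need no u
.props_fixed <- function(model, fixed, t, u) {
  t <- unname(t)
  s <- stats::plogis(u)
  switch(model,
    ACE = switch(fixed,
      a2 = c(t, (1 - t) * s, 0, (1 - t) * (1 - s)),
      c2 = c((1 - t) * s, t, 0, (1 - t) * (1 - s)),
      e2 = c((1 - t) * s, (1 - t) * (1 - s), 0, t)),
    ADE = switch(fixed,
      a2 = c(t, 0, (1 - t) * s, (1 - t) * (1 - s)),
      d2 = c((1 - t) * s, 0, t, (1 - t) * (1 - s)),
      e2 = c((1 - t) * s, 0, (1 - t) * (1 - s), t)),
    AE = switch(fixed, a2 = c(t, 0, 0, 1 - t), e2 = c(1 - t, 0, 0, t)),
    CE = switch(fixed, c2 = c(0, t, 0, 1 - t), e2 = c(0, 1 - t, 0, t)))
}

# profile-likelihood CI for a scalar in [lower, upper]:
# prof_m2ll(t) = -2LL minimized over nuisance parameters at fixed t
.profile_ci <- function(prof_m2ll, mle, m2ll_min, lower = 0, upper = 1,
                        level = 0.95, tol = 1e-6) {
  crit <- stats::qchisq(level, 1)
  g <- function(t) {
    v <- tryCatch(prof_m2ll(t), error = function(e) Inf)
    v - m2ll_min - crit
  }
  find <- function(a, b) {
    # root between a (away from MLE) and b (MLE side, g < 0); evaluate a
    # hair inside the interval to dodge singular boundaries (r = +/-1)
    a_eff <- a + 1e-7 * (b - a)
    ga <- g(a_eff)
    if (!is.finite(ga)) return(a)
    if (ga <= 0) return(a)  # bound lies inside the confidence region
    stats::uniroot(g, lower = min(a_eff, b), upper = max(a_eff, b),
                   tol = tol)$root
  }
  lo <- if (mle - lower < 1e-9) lower else find(lower, mle)
  hi <- if (upper - mle < 1e-9) upper else find(upper, mle)
  c(lower = lo, upper = hi)
}

.aic <- function(m2ll, k) m2ll + 2 * k
.bic <- function(m2ll, k, n) m2ll + k * log(n)

# skewness (moment estimator, as questionnaire descriptives report it)
.skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}
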