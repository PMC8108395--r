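# Liability-threshold models for binary twin data, tetrachoric twin
# correlations, and probandwise concordance.
#
# Binary outcomes are modeled as an unobserved standard-normal liability
# exceeding a threshold t; within-pair resemblance is a correlation on the
# liability scale, with ACE structure r_MZ = a2 + c2, r_DZ = 0.5 a2 + c2.
# The likelihood is multinomial over the per-zygosity 2x2 tables with cell
# probabilities from bivariate-normal orthant integrals (deterministic
# quadrature, see pbvn_upper), so fits are exactly reproducible.

#' Probandwise concordance rate
#'
#' \code{2C / (2C + D)} for \code{C} concordant-affected and \code{D}
#' discordant pairs: the probability that the co-twin of a proband is also
#' a proband (each concordant pair contributes two probands).
#'
#' @param concordant,discordant Non-negative pair counts.
#' @return Rate in \code{[0, 1]}.
#' @export
probandwise_concordance <- function(concordant, discordant) {
  if (any(concordant < 0) || any(discordant < 0))
    stop("counts must be non-negative")
  if (any(concordant + discordant == 0))
    stop("no affected pairs: concordance undefined")
  2 * concordant / (2 * concordant + discordant)
}

#' Per-zygosity concordance table for a binary twin trait
#'
#' @param pairs Pair table with \code{zygosity} and the two binary columns.
#' @param dx_cols Names of the per-twin 0/1 columns.
#' @return Data frame per zygosity: concordant-affected pairs,
#'   discordant pairs, concordant-unaffected pairs, number of probands
#'   (affected individuals), and the probandwise concordance rate
#'   (\code{NA} when no pair contains an affected twin).
#' @export
concordance_table <- function(pairs, dx_cols = c("t1_dx", "t2_dx")) {
  d <- .prep_pairs(pairs, dx_cols)
  row <- function(y, zyg) {
    x1 <- y[[1]]; x2 <- y[[2]]
    conc <- sum(x1 == 1 & x2 == 1)
    disc <- sum(x1 + x2 == 1)
    none <- sum(x1 == 0 & x2 == 0)
    data.frame(zygosity = zyg, concordant = conc, discordant = disc,
               unaffected = none, probands = sum(x1) + sum(x2),
               concordance = if (conc + disc > 0)
                 probandwise_concordance(conc, disc) else NA_real_)
  }
  rbind(row(d$mz, "MZ"), row(d$dz, "DZ"))
}

# per-zygosity 2x2 cell counts
.dx_counts <- function(y) {
  c(n11 = sum(y[[1]] == 1 & y[[2]] == 1),
    n10 = sum(y[[1]] == 1 & y[[2]] == 0),
    n01 = sum(y[[1]] == 0 & y[[2]] == 1),
    n00 = sum(y[[1]] == 0 & y[[2]] == 0))
}

# -2 log multinomial likelihood of one 2x2 table given (t, r)
.m2ll_bin_group <- function(cnt, t, r) {
  p <- pbvn_cells(t, t, r)
  p <- pmax(c(p$p11, p$p10, p$p01, p$p00), 1e-300)
  -2 * sum(cnt * log(p))
}

#' Tetrachoric twin correlations of a binary trait
#'
#' Per-zygosity saturated threshold model: one threshold per zygosity
#' (equated across twin order) and a free liability correlation, fitted by
#' maximum likelihood with profile-likelihood CIs.  A correlation pinned at
#' the \code{[-1, 1]} edge (e.g. a zygosity group with no concordant
#' affected pairs) is flagged as a boundary solution rather than silently
#' returned.
#'
#' @inheritParams concordance_table
#' @param ci Compute profile-likelihood CIs?
#' @param level Confidence level.
#' @return Data frame per zygosity: \code{threshold}, \code{r},
#'   \code{lower}, \code{upper}, \code{boundary}, \code{inestimable}.
#' @export
tetrachoric_correlations <- function(pairs, dx_cols = c("t1_dx", "t2_dx"),
                                     ci = TRUE, level = 0.95) {
  d <- .prep_pairs(pairs, dx_cols)
  one <- function(y, zyg) {
    cnt <- .dx_counts(y)
    n_aff <- 2 * cnt["n11"] + cnt["n10"] + cnt["n01"]
    if (n_aff == 0 || cnt["n00"] + cnt["n01"] + cnt["n10"] == 0)
      return(data.frame(zygosity = zyg, threshold = NA, r = NA,
                        lower = NA, upper = NA, boundary = FALSE,
                        inestimable = TRUE))
    fn <- function(th) .m2ll_bin_group(cnt, th[1], tanh(th[2]))
    t0 <- qnorm(n_aff / (2 * sum(cnt)), lower.tail = FALSE)
    fit <- .ml_minimize(fn, list(c(t0, 0.5), c(t0, -0.5), c(t0, 2)))
    r_hat <- tanh(fit$par[2])
    bound <- abs(r_hat) > 1 - 1e-4
    # the atanh scale flattens near |r| = 1; check the edges explicitly
    # (e.g. a group with affected twins but no concordant pair)
    for (edge in c(-1, 1)) {
      fe <- .ml_minimize(function(t) .m2ll_bin_group(cnt, t, edge),
                         list(fit$par[1]))
      if (fe$value <= fit$value + 1e-3 && abs(r_hat - edge) > 1e-4) {
        fit <- list(par = c(fe$par, atanh(edge * (1 - 1e-12))),
                    value = fe$value, converged = TRUE)
        r_hat <- edge
        bound <- TRUE
      }
    }
    lo <- hi <- NA_real_
    if (ci) {
      prof <- function(r0) {
        .ml_minimize(function(th) .m2ll_bin_group(cnt, th, r0),
                     list(fit$par[1]))$value
      }
      cis <- .profile_ci(prof, r_hat, fit$value, -1, 1, level)
      lo <- cis[1]; hi <- cis[2]
    }
    data.frame(zygosity = zyg, threshold = fit$par[1], r = r_hat,
               lower = lo, upper = hi, boundary = bound,
               inestimable = FALSE)
  }
  out <- rbind(one(d$mz, "MZ"), one(d$dz, "DZ"))
  rownames(out) <- NULL
  out
}

#' Fit an ACE-family liability-threshold model
#'
#' Maximum likelihood over the per-zygosity 2x2 contingency tables, with
#' cell probabilities given by bivariate-normal orthant integrals
#' \eqn{\Phi_2(t, t; r_{zyg})}, liability correlations
#' \eqn{r_{MZ} = a^2 + c^2}, \eqn{r_{DZ} = 0.5 a^2 + c^2}, and the
#' threshold equated across twin order and zygosity by default.
#'
#' @inheritParams concordance_table
#' @param model One of \code{"ACE"}, \code{"AE"}, \code{"CE"}, \code{"E"}.
#' @param equate_thresholds Single threshold across zygosity (default) or
#'   one per zygosity (assumption check).
#' @param ci \code{"profile"} or \code{"none"}.
#' @param level Confidence level.
#' @param bic_n BIC sample-size convention (\code{"pairs"} or
#'   \code{"individuals"}).
#' @return A \code{twin_fit} object with standardized liability components
#'   \code{a2, c2, e2}, \code{threshold}(s), profile CIs, \code{minus2LL},
#'   information criteria and boundary diagnostics.
#' @export
fit_liability <- function(pairs, model = c("ACE", "AE", "CE", "E"),
                          dx_cols = c("t1_dx", "t2_dx"),
                          equate_thresholds = TRUE,
                          ci = c("profile", "none"), level = 0.95,
                          bic_n = c("pairs", "individuals")) {
  model <- match.arg(model)
  ci <- match.arg(ci)
  bic_n <- match.arg(bic_n)
  d <- .prep_pairs(pairs, dx_cols)
  cnt_mz <- .dx_counts(d$mz); cnt_dz <- .dx_counts(d$dz)
  if (2 * cnt_mz["n11"] + cnt_mz["n10"] + cnt_mz["n01"] == 0 ||
      2 * cnt_dz["n11"] + cnt_dz["n10"] + cnt_dz["n01"] == 0)
    stop("need at least one affected individual per zygosity")

  k_free <- .n_prop_free(model)
  n_thr <- if (equate_thresholds) 1L else 2L
  obj <- function(th) {
    p <- .props_map(model, th[n_thr + seq_len(k_free)])
    r <- .twin_r(p)
    t_mz <- th[1]; t_dz <- th[n_thr]
    .m2ll_bin_group(cnt_mz, t_mz, r["mz"]) +
      .m2ll_bin_group(cnt_dz, t_dz, r["dz"])
  }
  prev <- (2 * (cnt_mz["n11"] + cnt_dz["n11"]) + cnt_mz["n10"] +
             cnt_mz["n01"] + cnt_dz["n10"] + cnt_dz["n01"]) /
    (2 * (sum(cnt_mz) + sum(cnt_dz)))
  t0 <- qnorm(prev, lower.tail = FALSE)
  mk <- function(pr) c(rep(t0, n_thr), .props_unmap(model, pr))
  starts <- list(mk(c(0.6, 0.1, 0, 0.3)), mk(c(1, 1, 0, 1) / 3),
                 mk(c(0.1, 0.6, 0, 0.3)))
  fit <- .ml_minimize(obj, starts)

  p <- .props_map(model, fit$par[n_thr + seq_len(k_free)])
  names(p) <- c("a2", "c2", "d2", "e2")
  thr <- fit$par[seq_len(n_thr)]
  names(thr) <- if (n_thr == 1) "threshold" else c("t_mz", "t_dz")
  m2ll <- fit$value
  npar <- n_thr + k_free
  n_bic <- if (bic_n == "pairs") d$n_pairs else 2L * d$n_pairs
  r_hat <- .twin_r(p)

  comp_free <- switch(model, ACE = c("a2", "c2", "e2"),
                      AE = c("a2", "e2"), CE = c("c2", "e2"), E = "e2")
  ci_tab <- matrix(NA_real_, length(comp_free), 2,
                   dimnames = list(comp_free, c("lower", "upper")))
  if (ci == "profile" && model != "E") {
    needs_u <- model == "ACE"
    for (comp in comp_free) {
      prof <- function(t) {
        fn <- function(th) {
          u <- if (needs_u) th[n_thr + 1] else 0
          pp <- .props_fixed(model, comp, t, u)
          r <- .twin_r(pp)
          .m2ll_bin_group(cnt_mz, th[1], r["mz"]) +
            .m2ll_bin_group(cnt_dz, th[n_thr], r["dz"])
        }
        sts <- if (needs_u) list(c(thr, 0), c(thr, -2), c(thr, 2))
        else list(unname(thr))
        .ml_minimize(fn, sts)$value
      }
      ci_tab[comp, ] <- .profile_ci(prof, unname(p[comp]), m2ll, 0, 1, level)
    }
  }

  structure(list(model = model, minus2LL = m2ll, npar = npar,
                 estimates = c(as.list(p),
                               list(threshold = unname(thr),
                                    r_mz = unname(r_hat["mz"]),
                                    r_dz = unname(r_hat["dz"]))),
                 thresholds = thr, ci = ci_tab,
                 AIC = .aic(m2ll, npar), BIC = .bic(m2ll, npar, n_bic),
                 bic_n = bic_n, counts = list(MZ = cnt_mz, DZ = cnt_dz),
                 n_pairs = d$n_pairs, n_mz = d$n_mz, n_dz = d$n_dz,
                 converged = fit$converged,
                 boundary = names(p)[p < 1e-6 & names(p) %in% comp_free]),
            class = c("liability_fit", "twin_fit"))
}

#' Saturated threshold model for binary twin data
#'
#' Per-zygosity threshold (equated across twin order) plus a free
#' tetrachoric correlation per zygosity; the baseline the ACE-family
#' liability models are compared against.
#'
#' @inheritParams fit_liability
#' @return A \code{twin_fit} object (\code{model = "SAT"}).
#' @export
fit_liability_saturated <- function(pairs, dx_cols = c("t1_dx", "t2_dx"),
                                    bic_n = c("pairs", "individuals")) {
  bic_n <- match.arg(bic_n)
  d <- .prep_pairs(pairs, dx_cols)
  tet <- tetrachoric_correlations(pairs, dx_cols, ci = FALSE)
  if (any(tet$inestimable))
    stop("tetrachoric correlation inestimable for zygosity ",
         paste(tet$zygosity[tet$inestimable], collapse = ", "))
  cnt_mz <- .dx_counts(d$mz); cnt_dz <- .dx_counts(d$dz)
  m2ll <- .m2ll_bin_group(cnt_mz, tet$threshold[1], tet$r[1]) +
    .m2ll_bin_group(cnt_dz, tet$threshold[2], tet$r[2])
  npar <- 4L
  n_bic <- if (bic_n == "pairs") d$n_pairs else 2L * d$n_pairs
  structure(list(model = "SAT", minus2LL = m2ll, npar = npar,
                 estimates = list(thresholds = tet$threshold,
                                  r_mz = tet$r[1], r_dz = tet$r[2]),
                 boundary = c("r_mz", "r_dz")[tet$boundary],
                 AIC = .aic(m2ll, npar), BIC = .bic(m2ll, npar, n_bic),
                 bic_n = bic_n,
                 n_pairs = d$n_pairs, n_mz = d$n_mz, n_dz = d$n_dz,
                 converged = TRUE),
            class = c("liability_sat_fit", "twin_fit"))
}

#' Dichotomize a continuous twin phenotype at a percentile cut-off
#'
#' Adds \code{t1_dx}/\code{t2_dx} columns flagging scores in the extreme
#' (high-scoring) \code{percentile}% tail of the pooled score
#' distribution, for liability-threshold analysis of percentile-defined
#' extreme groups.
#'
#' @param pairs Pair table with the continuous score columns.
#' @param percentile Tail size in percent, in (0, 100].
#' @param score_cols Names of the per-twin score columns.
#' @return The pair table with \code{t1_dx}, \code{t2_dx} added.
#' @export
dichotomize_at_percentile <- function(pairs, percentile,
                                      score_cols = c("t1_score", "t2_score")) {
  scores <- c(pairs[[score_cols[1]]], pairs[[score_cols[2]]])
  mask <- select_probands(scores, percentile)
  n <- nrow(pairs)
  pairs$t1_dx <- as.integer(mask[seq_len(n)])
  pairs$t2_dx <- as.integer(mask[n + seq_len(n)])
  pairs
}
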