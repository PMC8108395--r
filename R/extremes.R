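# DeFries-Fulker extremes analysis.
#
# Probands are individuals scoring in the extreme (high-severity) tail of
# the continuous phenotype.  Scores are transformed so the population mean
# is 0 and the proband mean is 1; the co-twin means of probands then read
# like twin correlations, and group heritability h2g measures how far the
# genetic influences on extreme-group membership also drive continuous
# variation.  Two implementations are provided and should agree closely:
# the classical double-entered regression C = B1 P + B2 R + A (R = 1 for
# MZ, 0.5 for DZ; after the transformation h2g = B2), and a model-fitting
# (ML) version in which the expected transformed co-twin mean is
# h2g * R + c2g.

#' Select probands by percentile cut-off
#'
#' Probands are the individuals whose score lies at or above the
#' \code{(100 - p)}th sample quantile, i.e. within the most severe
#' \code{p}% of the distribution (high scores = more disordered).  Ties at
#' the cut-off are all included.  Selection operates on ranks, so any
#' strictly monotone rescaling of the scores (log, z) selects the same
#' probands.
#'
#' @param scores Numeric vector of individual scores.
#' @param percentile Tail size in percent, in (0, 100].
#' @return Logical mask over \code{scores}.
#' @export
select_probands <- function(scores, percentile) {
  if (percentile <= 0 || percentile > 100)
    stop("`percentile` must be in (0, 100]")
  if (percentile == 100) return(rep(TRUE, length(scores)))
  cut <- stats::quantile(scores, 1 - percentile / 100, na.rm = TRUE,
                         names = FALSE)
  mask <- !is.na(scores) & scores >= cut
  if (!any(mask)) stop("empty proband set at percentile ", percentile)
  mask
}

#' DeFries-Fulker score transformation
#'
#' Affine map sending the population mean to 0 and the proband mean to 1:
#' \code{(x - mean_pop) / (mean_proband - mean_pop)}.  Order-preserving.
#'
#' @param scores Numeric vector.
#' @param probands Logical mask of probands.
#' @return Transformed scores.
#' @export
df_transform <- function(scores, probands) {
  m_pop <- mean(scores, na.rm = TRUE)
  m_pro <- mean(scores[probands], na.rm = TRUE)
  if (!is.finite(m_pro) || abs(m_pro - m_pop) < 1e-12)
    stop("degenerate proband selection: proband mean equals population mean")
  (scores - m_pop) / (m_pro - m_pop)
}

# double-entered proband/co-twin frame: one row per proband, concordant
# pairs entered twice (once per proband)
.double_entry <- function(pairs, mask1, mask2, z1, z2) {
  rel <- ifelse(toupper(pairs$zygosity) == "MZ", 1, 0.5)
  rbind(
    data.frame(pair_id = pairs$pair_id[mask1], P = z1[mask1],
               C = z2[mask1], R = rel[mask1],
               zygosity = pairs$zygosity[mask1]),
    data.frame(pair_id = pairs$pair_id[mask2], P = z2[mask2],
               C = z1[mask2], R = rel[mask2],
               zygosity = pairs$zygosity[mask2]))
}

#' DeFries-Fulker group heritability
#'
#' Selects probands at a percentile cut-off of the pooled score
#' distribution, applies the DF transformation, double-enters concordant
#' proband pairs and estimates group heritability by the requested
#' method(s):
#' \describe{
#'   \item{regression}{OLS fit of \code{C ~ P + R}; \code{h2g} is the
#'     coefficient on the coefficient-of-relationship \code{R}. Standard
#'     errors are cluster-robust on pair id (double entry reuses pairs).}
#'   \item{model}{ML fit of the transformed co-twin scores with expected
#'     mean \code{h2g * R + c2g} and a free variance per zygosity;
#'     \code{c2g} is a shared-environment group component (dropped when
#'     \code{group_c = FALSE}).  CI by likelihood profile; double-entered
#'     rows are treated as independent in the likelihood, so the profile
#'     CI is mildly anticonservative — the regression CI is the
#'     cluster-robust one.}
#' }
#'
#' @param pairs Pair table with \code{pair_id}, \code{zygosity} and the
#'   score columns.
#' @param percentile Proband tail size in percent.
#' @param method \code{"regression"}, \code{"model"} or \code{"both"}.
#' @param score_cols Names of the per-twin score columns.
#' @param group_c Estimate the shared group component \code{c2g} in the
#'   model-fitting method (default TRUE, mirroring an ACE-with-reduction
#'   strategy)?
#' @param level Confidence level.
#' @return An \code{extremes_result} list: percentile, proband counts,
#'   per-zygosity transformed co-twin means and probandwise concordance,
#'   and per-method \code{h2g} (clipped to [0, 1] for reporting; raw value
#'   in \code{diagnostics}) with CI.
#' @export
group_heritability <- function(pairs, percentile,
                               method = c("both", "regression", "model"),
                               score_cols = c("t1_score", "t2_score"),
                               group_c = TRUE, level = 0.95) {
  method <- match.arg(method)
  stopifnot(all(c("pair_id", "zygosity", score_cols) %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[score_cols]), , drop = FALSE]
  s1 <- pairs[[score_cols[1]]]; s2 <- pairs[[score_cols[2]]]
  scores <- c(s1, s2)
  mask <- select_probands(scores, percentile)
  z <- df_transform(scores, mask)
  n <- nrow(pairs)
  mask1 <- mask[seq_len(n)]; mask2 <- mask[n + seq_len(n)]
  z1 <- z[seq_len(n)]; z2 <- z[n + seq_len(n)]

  de <- .double_entry(pairs, mask1, mask2, z1, z2)
  mzp <- de$zygosity == "MZ"
  if (!any(mzp) || all(mzp))
    stop("need probands in both zygosity groups; percentile ", percentile,
         " has none in ", if (any(mzp)) "DZ" else "MZ")

  cotwin_means <- c(MZ = mean(de$C[mzp]), DZ = mean(de$C[!mzp]))
  conc <- concordance_table(
    data.frame(zygosity = pairs$zygosity,
               t1_dx = as.integer(mask1), t2_dx = as.integer(mask2)))

  alpha <- 1 - level
  zq <- qnorm(1 - alpha / 2)
  out <- list(percentile = percentile,
              n_probands = sum(mask),
              n_proband_pairs = c(MZ = sum(mzp), DZ = sum(!mzp)),
              cotwin_means = cotwin_means,
              concordance = conc,
              estimates = list(), diagnostics = list())

  if (method %in% c("both", "regression")) {
    fit <- stats::lm(C ~ P + R, data = de)
    vc <- sandwich::vcovCL(fit, cluster = de$pair_id)
    b <- stats::coef(fit)["R"]
    se <- sqrt(vc["R", "R"])
    out$estimates$regression <- list(
      h2g = min(max(b, 0), 1), se = se,
      ci = c(lower = min(max(b - zq * se, 0), 1),
             upper = min(max(b + zq * se, 0), 1)),
      B1 = unname(stats::coef(fit)["P"]), B2 = unname(b))
    out$diagnostics$regression_raw_h2g <- unname(b)
    out$diagnostics$regression_vcov <- vc
  }

  if (method %in% c("both", "model")) {
    # ML analogue of the DF regression equation: the co-twin score is
    # normal with mean b1 * P + h2g * R (+ c2g) and a free variance per
    # zygosity group
    nll <- function(th) {
      b1 <- th[1]; h2g <- th[2]; c2g <- if (group_c) th[3] else 0
      lv <- th[(2 + group_c) + 1:2]
      mu <- b1 * de$P + h2g * de$R + c2g
      -2 * sum(dnorm(de$C, mu, sqrt(exp(ifelse(mzp, lv[1], lv[2]))),
                     log = TRUE))
    }
    lv0 <- log(c(max(stats::var(de$C[mzp]), 1e-4),
                 max(stats::var(de$C[!mzp]), 1e-4)))
    h0 <- 2 * (cotwin_means["MZ"] - cotwin_means["DZ"])
    st <- if (group_c)
      c(0.3, h0, cotwin_means["DZ"] * 2 - cotwin_means["MZ"], lv0)
    else c(0.3, h0, lv0)
    fit <- .ml_minimize(nll, list(unname(st)))
    h2g_hat <- fit$par[2]
    prof <- function(t) {
      fn <- function(th) {
        b1 <- th[1]; c2g <- if (group_c) th[2] else 0
        lv <- th[(1 + group_c) + 1:2]
        mu <- b1 * de$P + t * de$R + c2g
        -2 * sum(dnorm(de$C, mu, sqrt(exp(ifelse(mzp, lv[1], lv[2]))),
                       log = TRUE))
      }
      .ml_minimize(fn, list(unname(fit$par[-2])))$value
    }
    cis <- .profile_ci(prof, h2g_hat, fit$value, -2, 2, level)
    out$estimates$model <- list(
      h2g = min(max(h2g_hat, 0), 1),
      b1 = fit$par[1],
      c2g = if (group_c) fit$par[3] else 0,
      ci = c(lower = min(max(cis[1], 0), 1),
             upper = min(max(cis[2], 0), 1)),
      minus2LL = fit$value,
      converged = fit$converged)
    out$diagnostics$model_raw_h2g <- h2g_hat
    out$diagnostics$model_raw_ci <- cis
  }
  class(out) <- "extremes_result"
  out
}

#' @export
print.extremes_result <- function(x, ...) {
  cat(sprintf("DF extremes analysis at the %gth percentile: %d probands\n",
              x$percentile, x$n_probands))
  cat(sprintf("  transformed co-twin means: MZ %.3f, DZ %.3f\n",
              x$cotwin_means["MZ"], x$cotwin_means["DZ"]))
  for (m in names(x$estimates)) {
    e <- x$estimates[[m]]
    cat(sprintf("  h2g (%s) = %.3f (95%% CI %.3f-%.3f)\n",
                m, e$h2g, e$ci["lower"], e$ci["upper"]))
  }
  invisible(x)
}

#' Extremes analyses across several percentile cut-offs
#'
#' @inheritParams group_heritability
#' @param percentiles Vector of tail sizes in percent.
#' @return Data frame with one row per percentile and method.
#' @export
extremes_table <- function(pairs, percentiles = c(1, 3, 5, 10),
                           method = "both",
                           score_cols = c("t1_score", "t2_score"),
                           group_c = TRUE) {
  rows <- lapply(percentiles, function(p) {
    res <- group_heritability(pairs, p, method, score_cols, group_c)
    do.call(rbind, lapply(names(res$estimates), function(m) {
      e <- res$estimates[[m]]
      data.frame(percentile = p, method = m,
                 n_probands = res$n_probands,
                 cotwin_mean_mz = res$cotwin_means["MZ"],
                 cotwin_mean_dz = res$cotwin_means["DZ"],
                 concordance_mz = res$concordance$concordance[1],
                 concordance_dz = res$concordance$concordance[2],
                 h2g = e$h2g, ci_lower = e$ci["lower"],
                 ci_upper = e$ci["upper"], row.names = NULL)
    }))
  })
  do.call(rbind, rows)
}
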