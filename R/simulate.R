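# Synthetic twin-cohort generator.
#
# Latent-factor simulation: each twin's phenotype (or liability) is built
# explicitly from additive-genetic (A), shared-environment (C) and
# non-shared-environment (E) standard-normal factors,
#   y = sqrt(a2) A + sqrt(c2) C + sqrt(e2) E,
# with A fully shared within MZ pairs and correlated 0.5 within DZ pairs
# (DZ: A_i = sqrt(.5) A_shared + sqrt(.5) A_unique), C shared within pair
# and E independent.  This makes MZ/DZ sharing structural rather than an
# entry in a covariance matrix, and extends directly to two correlated
# traits.  Expected twin correlations are rMZ = a2 + c2, rDZ = 0.5 a2 + c2.

#' Configuration for a simulated twin cohort
#'
#' Bundles and validates everything the generators need.  Univariate mode
#' needs \code{a2, c2, e2}; binary mode additionally a \code{prevalence} or
#' a \code{threshold_z} (mutually exclusive); bivariate mode a second
#' trait's components and the cross-trait factor correlations.
#'
#' @param n_mz,n_dz Number of MZ / DZ twin pairs.
#' @param a2,c2,e2 Standardized variance proportions of the (first) trait;
#'   must be non-negative and sum to 1.
#' @param prevalence Population proportion above the liability threshold,
#'   in (0, 1); translated to \code{threshold_z = qnorm(1 - prevalence)}.
#' @param threshold_z Liability threshold in standard-normal units.
#'   Supply at most one of \code{prevalence} / \code{threshold_z}.
#' @param trait2 Optional list \code{list(a2, c2, e2, prevalence)} (or
#'   \code{threshold_z}) describing a second, dichotomized trait.
#' @param rA,rC,rE Cross-trait correlations of the A, C and E factors, each
#'   in \code{[-1, 1]}; used only with \code{trait2}.
#' @param skew Optional list \code{list(mean, sd, skew)}: target moments of
#'   a bounded 1-6 questionnaire-type scale that the continuous phenotype
#'   is mapped onto (see \code{\link{apply_skew_transform}}). \code{NULL}
#'   leaves the phenotype on its standard-normal scale.
#' @param seed Integer master seed; every generator call is a pure function
#'   of (config, seed).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_mz, n_dz, a2, c2 = 0, e2 = 1 - a2 - c2,
                       prevalence = NULL, threshold_z = NULL,
                       trait2 = NULL, rA = 0, rC = 0, rE = 0,
                       skew = NULL, seed = 1L) {
  stopifnot(n_mz >= 0, n_dz >= 0)
  .check_props(a2, c2, e2)
  if (!is.null(prevalence) && !is.null(threshold_z))
    stop("supply either `prevalence` or `threshold_z`, not both")
  if (!is.null(prevalence)) {
    if (prevalence <= 0 || prevalence >= 1)
      stop("`prevalence` must be in (0, 1)")
    threshold_z <- qnorm(1 - prevalence)
  }
  if (!is.null(trait2)) {
    t2 <- trait2
    .check_props(t2$a2, t2$c2 %||% 0, t2$e2 %||% (1 - t2$a2 - (t2$c2 %||% 0)))
    if (!is.null(t2$prevalence)) {
      if (t2$prevalence <= 0 || t2$prevalence >= 1)
        stop("trait2 `prevalence` must be in (0, 1)")
      t2$threshold_z <- qnorm(1 - t2$prevalence)
    }
    t2$c2 <- t2$c2 %||% 0
    t2$e2 <- t2$e2 %||% (1 - t2$a2 - t2$c2)
    trait2 <- t2
    for (r in c(rA, rC, rE))
      if (abs(r) > 1) stop("cross-trait correlations must lie in [-1, 1]")
  }
  structure(list(
    n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
    a2 = a2, c2 = c2, e2 = e2,
    threshold_z = threshold_z,
    trait2 = trait2, rA = rA, rC = rC, rE = rE,
    skew = skew, seed = as.integer(seed)), class = "sim_config")
}

.check_props <- function(a2, c2, e2) {
  if (any(c(a2, c2, e2) < 0))
    stop("variance proportions must be non-negative")
  if (abs(a2 + c2 + e2 - 1) > 1e-9)
    stop("variance proportions must sum to 1 (got ",
         format(a2 + c2 + e2, digits = 12), ")")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected values implied by a simulation configuration
#'
#' Ground-truth manifest: echoes the configuration and adds the closed-form
#' expectations that parameter-recovery tests check against — expected twin
#' correlations \code{rMZ = a2 + c2}, \code{rDZ = 0.5 a2 + c2}, expected
#' prevalence \code{1 - pnorm(threshold_z)}, and (bivariate mode) the
#' implied phenotypic cross-trait correlation
#' \code{rPH = rA a1 a2 + rC c1 c2 + rE e1 e2}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A list; serializable to JSON with \code{write_manifest}.
#' @export
ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  man <- list(
    config = unclass(cfg),
    expected_r_mz = cfg$a2 + cfg$c2,
    expected_r_dz = 0.5 * cfg$a2 + cfg$c2)
  if (!is.null(cfg$threshold_z))
    man$expected_prevalence <- pnorm(cfg$threshold_z, lower.tail = FALSE)
  if (!is.null(cfg$trait2)) {
    t2 <- cfg$trait2
    man$expected_r_mz_trait2 <- t2$a2 + t2$c2
    man$expected_r_dz_trait2 <- 0.5 * t2$a2 + t2$c2
    if (!is.null(t2$threshold_z))
      man$expected_prevalence_trait2 <- pnorm(t2$threshold_z, lower.tail = FALSE)
    man$expected_r_ph <- cfg$rA * sqrt(cfg$a2 * t2$a2) +
      cfg$rC * sqrt(cfg$c2 * t2$c2) + cfg$rE * sqrt(cfg$e2 * t2$e2)
  }
  man
}

# draw the within-pair latent factors for one trait: list of two n-vectors
# per factor, with the required cross-twin correlation structure
.draw_ace <- function(n_mz, n_dz) {
  n <- n_mz + n_dz
  mz <- seq_len(n_mz)
  a_sh <- rnorm(n); a_u1 <- rnorm(n); a_u2 <- rnorm(n)
  A1 <- a_sh; A2 <- a_sh
  if (n_dz > 0) {
    dz <- (n_mz + 1):n
    A1[dz] <- sqrt(0.5) * a_sh[dz] + sqrt(0.5) * a_u1[dz]
    A2[dz] <- sqrt(0.5) * a_sh[dz] + sqrt(0.5) * a_u2[dz]
  }
  C <- rnorm(n)
  list(A1 = A1, A2 = A2, C1 = C, C2 = C, E1 = rnorm(n), E2 = rnorm(n))
}

.compose <- function(f, a2, c2, e2, twin) {
  if (twin == 1) sqrt(a2) * f$A1 + sqrt(c2) * f$C1 + sqrt(e2) * f$E1
  else           sqrt(a2) * f$A2 + sqrt(c2) * f$C2 + sqrt(e2) * f$E2
}

.pair_frame <- function(cfg) {
  n <- cfg$n_mz + cfg$n_dz
  data.frame(pair_id = seq_len(n),
             zygosity = rep(c("MZ", "DZ"), c(cfg$n_mz, cfg$n_dz)),
             stringsAsFactors = FALSE)
}

#' Simulate a continuous twin phenotype
#'
#' Latent A/C/E factors are drawn per pair with cross-twin correlation 1
#' (MZ) or 0.5 (DZ) for A, 1 for C and 0 for E; the phenotype is their
#' weighted sum with weights \code{sqrt(a2)}, \code{sqrt(c2)},
#' \code{sqrt(e2)}, so it has population mean 0 and variance 1.  If the
#' configuration carries a \code{skew} target the standard-normal phenotype
#' is then mapped onto a bounded right-skewed 1-6 scale.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A data frame with columns \code{pair_id}, \code{zygosity},
#'   \code{t1_score}, \code{t2_score}.
#' @export
simulate_continuous <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  f <- .draw_ace(cfg$n_mz, cfg$n_dz)
  out <- .pair_frame(cfg)
  out$t1_score <- .compose(f, cfg$a2, cfg$c2, cfg$e2, 1)
  out$t2_score <- .compose(f, cfg$a2, cfg$c2, cfg$e2, 2)
  if (!is.null(cfg$skew)) {
    s <- cfg$skew
    tr <- apply_skew_transform(c(out$t1_score, out$t2_score),
                               mean = s$mean, sd = s$sd, skew = s$skew)
    out$t1_score <- tr[seq_len(nrow(out))]
    out$t2_score <- tr[-seq_len(nrow(out))]
  }
  out
}

#' Simulate a binary (liability-threshold) twin trait
#'
#' The continuous liability is simulated as in
#' \code{\link{simulate_continuous}} (same seed gives the same liabilities)
#' and dichotomized at the configured threshold, so observed prevalence
#' converges to \code{1 - pnorm(threshold_z)}.
#'
#' @param cfg A \code{\link{sim_config}} with a threshold or prevalence.
#' @param keep_liability Keep the latent liability columns in the output?
#' @return A data frame with \code{t1_dx}, \code{t2_dx} (0/1) and
#'   optionally \code{t1_liab}, \code{t2_liab}.
#' @export
simulate_binary <- function(cfg, keep_liability = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$threshold_z))
    stop("binary simulation needs `prevalence` or `threshold_z`")
  cfg2 <- cfg; cfg2$skew <- NULL
  out <- simulate_continuous(cfg2)
  names(out)[names(out) == "t1_score"] <- "t1_liab"
  names(out)[names(out) == "t2_score"] <- "t2_liab"
  out$t1_dx <- as.integer(out$t1_liab > cfg$threshold_z)
  out$t2_dx <- as.integer(out$t2_liab > cfg$threshold_z)
  if (!keep_liability) out$t1_liab <- out$t2_liab <- NULL
  out
}

#' Simulate a continuous trait and a correlated dichotomized trait
#'
#' Two latent phenotypes per twin are built from cross-correlated A/C/E
#' factors: the trait-1 and trait-2 factors of the same kind correlate
#' \code{rA}, \code{rC}, \code{rE} within a twin, A factors additionally
#' correlate 1 (MZ) / 0.5 (DZ) across twins — so the cross-twin cross-trait
#' A correlation is \code{rA} (MZ) or \code{0.5 rA} (DZ) — and C factors are
#' fully shared within a pair.  Trait 1 stays continuous (optionally
#' skew-transformed); trait 2 is dichotomized at its threshold.  The implied
#' within-twin cross-trait correlation is
#' \code{rPH = rA a1 a2 + rC c1 c2 + rE e1 e2}.
#'
#' @param cfg A \code{\link{sim_config}} with \code{trait2} and cross-trait
#'   correlations.
#' @param keep_liability Keep trait 2's latent liability columns?
#' @return A data frame with \code{t1_score}, \code{t2_score} (trait 1 for
#'   twins 1 and 2) and \code{t1_dx}, \code{t2_dx} (trait 2).
#' @export
simulate_bivariate <- function(cfg, keep_liability = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$trait2)) stop("bivariate simulation needs `trait2`")
  t2 <- cfg$trait2
  if (is.null(t2$threshold_z))
    stop("trait2 needs `prevalence` or `threshold_z`")
  # implied 2x2 cross-trait factor correlation matrices must be PSD;
  # with a single correlation each, |r| <= 1 suffices, checked already.
  set.seed(cfg$seed)
  n_mz <- cfg$n_mz; n_dz <- cfg$n_dz
  fA <- .draw_corr_factors(n_mz, n_dz, cfg$rA, genetic = TRUE)
  fC <- .draw_corr_factors(n_mz, n_dz, cfg$rC, genetic = FALSE, shared = TRUE)
  fE <- .draw_corr_factors(n_mz, n_dz, cfg$rE, genetic = FALSE, shared = FALSE)
  out <- .pair_frame(cfg)
  y1 <- function(twin) sqrt(cfg$a2) * fA[[twin]][, 1] +
    sqrt(cfg$c2) * fC[[twin]][, 1] + sqrt(cfg$e2) * fE[[twin]][, 1]
  y2 <- function(twin) sqrt(t2$a2) * fA[[twin]][, 2] +
    sqrt(t2$c2) * fC[[twin]][, 2] + sqrt(t2$e2) * fE[[twin]][, 2]
  out$t1_score <- y1(1); out$t2_score <- y1(2)
  l1 <- y2(1); l2 <- y2(2)
  out$t1_dx <- as.integer(l1 > t2$threshold_z)
  out$t2_dx <- as.integer(l2 > t2$threshold_z)
  if (keep_liability) { out$t1_liab <- l1; out$t2_liab <- l2 }
  if (!is.null(cfg$skew)) {
    s <- cfg$skew
    tr <- apply_skew_transform(c(out$t1_score, out$t2_score),
                               mean = s$mean, sd = s$sd, skew = s$skew)
    out$t1_score <- tr[seq_len(nrow(out))]
    out$t2_score <- tr[-seq_len(nrow(out))]
  }
  out
}

# bivariate factor pairs (trait1, trait2) with within-twin correlation r;
# genetic=TRUE adds the 1 / 0.5 cross-twin structure, shared=TRUE makes the
# factor identical for both twins, otherwise independent across twins
.draw_corr_factors <- function(n_mz, n_dz, r, genetic, shared = FALSE) {
  n <- n_mz + n_dz
  corr2 <- function(m) {
    z1 <- m[, 1]
    cbind(z1, r * z1 + sqrt(1 - r^2) * m[, 2], deparse.level = 0)
  }
  if (genetic) {
    sh <- corr2(matrix(rnorm(2 * n), n))
    u1 <- corr2(matrix(rnorm(2 * n), n))
    u2 <- corr2(matrix(rnorm(2 * n), n))
    f1 <- sh; f2 <- sh
    if (n_dz > 0) {
      dz <- (n_mz + 1):n
      f1[dz, ] <- sqrt(0.5) * sh[dz, ] + sqrt(0.5) * u1[dz, ]
      f2[dz, ] <- sqrt(0.5) * sh[dz, ] + sqrt(0.5) * u2[dz, ]
    }
    list(f1, f2)
  } else if (shared) {
    sh <- corr2(matrix(rnorm(2 * n), n))
    list(sh, sh)
  } else {
    list(corr2(matrix(rnorm(2 * n), n)), corr2(matrix(rnorm(2 * n), n)))
  }
}

#' Map standard-normal values onto a bounded right-skewed 1-6 scale
#'
#' Strictly monotone transform emulating a questionnaire total score: a
#' shifted-lognormal map \eqn{u = \alpha + \beta e^{\delta z}} whose tails
#' are eased smoothly (C1, exponential easing) into the open interval
#' (1, 6).  The three parameters are calibrated once per moment target by
#' deterministic Gauss-Hermite quadrature so that the transformed standard
#' normal has the requested mean, standard deviation and skewness; rank
#' order is preserved exactly and \code{log()} of the output restores
#' approximate normality.
#'
#' @param z Numeric vector (nominally standard normal).
#' @param mean,sd,skew Target moments of the transformed scale.
#' @param lower,upper Bounds of the scale (defaults 1 and 6).
#' @return Numeric vector, same length as \code{z}, strictly increasing in
#'   \code{z}, contained in \code{(lower, upper)}.
#' @export
apply_skew_transform <- function(z, mean = 2.66, sd = 0.90, skew = 0.57,
                                 lower = 1, upper = 6) {
  if (sd <= 0) stop("target `sd` must be positive")
  par <- .skew_calibrate(mean, sd, skew, lower, upper)
  .skew_map(z, par, lower, upper)
}

# smooth clip: identity on [lower + h, upper - h], exponential easing
# outside; strictly increasing, C1, range (lower, upper)
.squash <- function(u, lower, upper, h = 0.25) {
  lo <- lower + h; hi <- upper - h
  out <- u
  bl <- u < lo
  out[bl] <- lower + h * exp((u[bl] - lo) / h)
  bu <- u > hi
  out[bu] <- upper - h * exp(-(u[bu] - hi) / h)
  out
}

.skew_map <- function(z, par, lower, upper) {
  u <- par[["alpha"]] + par[["beta"]] * exp(par[["delta"]] * z)
  .squash(u, lower, upper)
}

# Gauss-Hermite moments of the transform; cached per target
.skew_cache <- new.env(parent = emptyenv())

.skew_calibrate <- function(mean, sd, skew, lower, upper) {
  key <- paste(mean, sd, skew, lower, upper, sep = "|")
  if (!is.null(.skew_cache[[key]])) return(.skew_cache[[key]])
  if (abs(skew) < 0.02) {
    # delta -> 0 limit of the shifted-lognormal family is the affine map
    # u = mean + sd * z; represent it with a tiny curvature
    delta <- 1e-6
    beta <- sd / delta
    return(.skew_cache[[key]] <- c(alpha = mean - beta, beta = beta,
                                   delta = delta))
  }
  gh <- .gauss_hermite_prob(80)
  moments <- function(p) {
    y <- .skew_map(gh$x, p, lower, upper)
    if (any(!is.finite(y))) return(c(NA, NA, NA))
    m1 <- sum(gh$w * y)
    m2 <- sum(gh$w * (y - m1)^2)
    m3 <- sum(gh$w * (y - m1)^3)
    c(m1, sqrt(m2), m3 / m2^1.5)
  }
  target <- c(mean, sd, skew)
  obj <- function(q) {
    if (any(abs(q) > 50)) return(1e10)
    p <- c(alpha = q[1], beta = exp(q[2]), delta = exp(q[3]))
    m <- moments(p)
    if (any(!is.finite(m))) return(1e10)
    sum((m - target)^2)
  }
  # shifted-lognormal closed-form start (ignoring the easing)
  if (abs(skew) < 1e-8) {
    start_delta <- 1e-4
  } else {
    f <- function(d) {
      w <- exp(d^2)
      (w + 2) * sqrt(w - 1) - abs(skew)
    }
    start_delta <- uniroot(f, c(1e-6, 2))$root
  }
  w <- exp(start_delta^2)
  s_ln <- sqrt((w - 1) * w)
  beta0 <- sd / s_ln
  alpha0 <- mean - beta0 * sqrt(w)
  fit <- optim(c(alpha0, log(beta0), log(start_delta)), obj,
               method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-14))
  fit <- optim(fit$par, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  par <- c(alpha = fit$par[1], beta = exp(fit$par[2]),
           delta = exp(fit$par[3]))
  if (sqrt(fit$value) > 1e-6)
    warning("skew-transform calibration residual ",
            format(sqrt(fit$value), digits = 3),
            "; targets may be unreachable within the bounds")
  .skew_cache[[key]] <- par
  par
}

# probabilists' Gauss-Hermite rule: nodes/weights for E[f(Z)], Z ~ N(0,1)
.gauss_hermite_prob <- function(n) {
  # Golub-Welsch from the Jacobi matrix of (physicists') Hermite, rescaled
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values * sqrt(2)
  w <- e$vectors[1, ]^2
  list(x = x, w = w)
}

#' Write a simulated pair table and its ground-truth manifest
#'
#' @param pairs Pair-level data frame from a `simulate_*` function.
#' @param path Output path for the data (CSV; header documented in the
#'   column names: `pair_id, zygosity, t1_score, t2_score, t1_dx, t2_dx`).
#' @param cfg Optional \code{\link{sim_config}}; when given, the
#'   \code{\link{ground_truth}} manifest is written as JSON next to the
#'   data (same path, extension `.manifest.json`).
#' @return Invisibly, the data path.
#' @export
write_pairs <- function(pairs, path, cfg = NULL) {
  utils::write.csv(pairs, path, row.names = FALSE)
  if (!is.null(cfg)) {
    man_path <- sub("\\.[^.]+$", "", path)
    jsonlite::write_json(ground_truth(cfg),
                         paste0(man_path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a pair-level twin data file
#'
#' @param path CSV/TSV file with at least `pair_id`, `zygosity` and the
#'   per-twin phenotype columns.
#' @return A data frame.
#' @export
read_pairs <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}
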