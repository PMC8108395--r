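# Study pipeline: phenotype construction -> descriptives -> assumption
# tests -> univariate ACE family -> DF extremes -> liability-threshold
# models -> joint categorical-continuous models -> consolidated report.

#' Simulation settings emulating a female adolescent twin cohort
#'
#' Defaults mirror a registry-linked questionnaire study design: 768 MZ
#' and 713 DZ female same-sex pairs; a continuous disordered-eating score
#' with heritability 0.65 (AE structure) reported on a bounded 1-6 scale
#' with mean 2.66, s.d. 0.90 and skew 0.57; an anorexia-nervosa-like
#' diagnosis (prevalence 2.4%, liability h2 0.63, genetic correlation 0.26
#' and non-shared environmental correlation 0.60 with the score) and an
#' other-eating-disorder-like diagnosis (prevalence 3.3%, h2 0.67,
#' rA = rE = 0.52).
#'
#' @param seed Master seed.
#' @param n_mz,n_dz Pair counts.
#' @return List of three \code{\link{sim_config}} objects
#'   (\code{continuous}, \code{an}, \code{oed}) sharing the score trait.
#' @export
study_cohort_config <- function(seed = 1L, n_mz = 768L, n_dz = 713L) {
  skew <- list(mean = 2.66, sd = 0.90, skew = 0.57)
  list(
    continuous = sim_config(n_mz, n_dz, a2 = 0.65, c2 = 0, e2 = 0.35,
                            skew = skew, seed = seed),
    an = sim_config(n_mz, n_dz, a2 = 0.65, c2 = 0, e2 = 0.35,
                    trait2 = list(a2 = 0.63, c2 = 0, e2 = 0.37,
                                  prevalence = 0.024),
                    rA = 0.26, rE = 0.60, skew = skew, seed = seed),
    oed = sim_config(n_mz, n_dz, a2 = 0.65, c2 = 0, e2 = 0.35,
                     trait2 = list(a2 = 0.67, c2 = 0, e2 = 0.33,
                                   prevalence = 0.033),
                     rA = 0.52, rE = 0.52, skew = skew, seed = seed))
}

#' Simulate a full study cohort: score plus two diagnosis traits
#'
#' One continuous disordered-eating score per twin plus two binary
#' diagnosis indicators (AN-like and OED-like) whose liabilities correlate
#' with the score through shared A and E factors.  The two diagnoses are
#' generated conditionally independent given the score's factors, each at
#' its configured genetic/non-shared correlation with the score.
#'
#' @inheritParams study_cohort_config
#' @return Pair table with columns \code{pair_id}, \code{zygosity},
#'   \code{t1_score}, \code{t2_score}, \code{t1_an}, \code{t2_an},
#'   \code{t1_oed}, \code{t2_oed}.
#' @export
simulate_study_cohort <- function(seed = 1L, n_mz = 768L, n_dz = 713L) {
  cfgs <- study_cohort_config(seed, n_mz, n_dz)
  # same seed -> identical score columns across the two bivariate draws
  d_an <- simulate_bivariate(cfgs$an)
  d_oed <- simulate_bivariate(cfgs$oed)
  out <- d_an[c("pair_id", "zygosity", "t1_score", "t2_score")]
  out$t1_an <- d_an$t1_dx; out$t2_an <- d_an$t2_dx
  out$t1_oed <- d_oed$t1_dx; out$t2_oed <- d_oed$t2_dx
  out
}

#' Run the complete twin-study workflow
#'
#' Orchestrates every analysis stage on a pair-level data set: score
#' descriptives; saturated-model assumption tests and twin correlations on
#' the log-transformed, standardized score; the univariate ACE family with
#' best-model selection; DF extremes analyses and percentile-based
#' liability-threshold models; and, for each supplied binary trait,
#' cross-twin cross-trait correlations and the joint
#' categorical-continuous model family.  Deterministic: the report is a
#' pure function of the input data and settings.
#'
#' @param pairs Pair table with \code{pair_id}, \code{zygosity},
#'   \code{t1_score}, \code{t2_score} and, per binary trait \code{x},
#'   columns \code{t1_x}/\code{t2_x}.
#' @param binary_traits Character vector of binary trait suffixes (e.g.
#'   \code{c("an", "oed")}); empty to skip joint models.
#' @param percentiles Extreme-group cut-offs in percent.
#' @param liability_min_percentile Smallest percentile at which the
#'   liability-threshold model is fitted (tiny extreme groups make it
#'   unstable; the 1st percentile is skipped by default).
#' @param log_score Log-transform the score before modeling (scores must
#'   then be positive)?
#' @param models ACE-family labels to fit at each stage.
#' @param joint_models Model labels for the joint stage (fitting the full
#'   family of joint models is expensive; default ACE + AE + E).
#' @param rule Best-model selection policy (\code{"lrt"} or \code{"bic"}).
#' @param ci Profile CIs where supported (\code{"profile"}) or skip
#'   (\code{"none"}).
#' @param outdir Optional directory: tables are written as JSON/CSV.
#' @param verbose Log stage progress to stderr?
#' @return A \code{study_report} list with one element per stage.
#' @export
run_study <- function(pairs, binary_traits = character(),
                      percentiles = c(1, 3, 5, 10),
                      liability_min_percentile = 3,
                      log_score = TRUE,
                      models = c("ACE", "AE", "CE", "E"),
                      joint_models = c("ACE", "AE", "E"),
                      rule = "lrt", ci = "profile",
                      outdir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[run_study] ", ...)
  stopifnot(all(c("pair_id", "zygosity", "t1_score", "t2_score")
                %in% names(pairs)))
  if (any(percentiles <= 0 | percentiles >= 100))
    stop("percentiles must lie in (0, 100)")

  raw <- c(pairs$t1_score, pairs$t2_score)
  desc <- list(n_pairs = nrow(pairs),
               n_mz = sum(toupper(pairs$zygosity) == "MZ"),
               n_dz = sum(toupper(pairs$zygosity) == "DZ"),
               mean = mean(raw, na.rm = TRUE),
               sd = stats::sd(raw, na.rm = TRUE),
               skew = .skewness(raw),
               range = range(raw, na.rm = TRUE))
  say("descriptives: mean ", round(desc$mean, 2), ", sd ",
      round(desc$sd, 2), ", skew ", round(desc$skew, 2))

  # analysis scale: natural log, then z-standardized
  z <- if (log_score) log_transform(raw) else raw
  z <- (z - mean(z, na.rm = TRUE)) / stats::sd(z, na.rm = TRUE)
  ana <- pairs
  n <- nrow(pairs)
  ana$t1_score <- z[seq_len(n)]
  ana$t2_score <- z[n + seq_len(n)]

  say("saturated models and assumption tests")
  assumptions <- assumption_tests(ana)
  say("twin correlations")
  twin_cor <- twin_correlations(ana, ci = (ci == "profile"))

  say("univariate ACE family")
  uni <- ace_family(ana, models = models, ci = ci, rule = rule)

  say("DF extremes analyses")
  extremes <- extremes_table(ana, percentiles = percentiles)

  say("liability-threshold models at percentile cut-offs")
  liab_pcts <- percentiles[percentiles >= liability_min_percentile]
  liability <- lapply(liab_pcts, function(p) {
    db <- dichotomize_at_percentile(ana, p)
    fits <- c(list(SAT = fit_liability_saturated(db)),
              stats::setNames(lapply(intersect(models, c("ACE", "AE", "CE", "E")),
                                     function(m) fit_liability(db, m, ci = ci)),
                              intersect(models, c("ACE", "AE", "CE", "E"))))
    list(percentile = p,
         tetrachoric = tetrachoric_correlations(db, ci = (ci == "profile")),
         table = compare_models(fits, baseline = 1L, rule = rule),
         fits = fits)
  })
  names(liability) <- paste0("p", liab_pcts)

  joint <- list()
  for (tr in binary_traits) {
    dx_cols <- paste0(c("t1_", "t2_"), tr)
    say("joint categorical-continuous models: ", tr)
    ctct <- cross_twin_cross_trait(ana, dx_cols = dx_cols)
    fits <- stats::setNames(lapply(joint_models, function(m)
      fit_joint(ana, m, dx_cols = dx_cols,
                ci = if (m %in% c("ACE", "AE")) ci else "none")),
      joint_models)
    joint[[tr]] <- list(trait = tr,
                        cross_twin_cross_trait = ctct,
                        table = compare_models(fits, baseline = 1L,
                                               rule = rule),
                        fits = fits)
  }

  report <- structure(list(descriptives = desc, assumptions = assumptions,
                           twin_correlations = twin_cor,
                           univariate = uni, extremes = extremes,
                           liability = liability, joint = joint),
                      class = "study_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write a study report to disk
#'
#' Emits the machine-readable bundle: one JSON file with every stage plus
#' CSVs of the flat tables.
#'
#' @param report A \code{study_report}.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, \code{outdir}.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  strip <- function(x) {
    if (inherits(x, "twin_fit"))
      x <- x[setdiff(names(x), c("counts", "diagnostics"))]
    if (is.list(x)) lapply(x, strip) else x
  }
  jsonlite::write_json(strip(unclass(report)),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  utils::write.csv(report$extremes,
                   file.path(outdir, "extremes.csv"), row.names = FALSE)
  utils::write.csv(report$univariate$table,
                   file.path(outdir, "model_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(report$twin_correlations,
                   file.path(outdir, "twin_correlations.csv"),
                   row.names = FALSE)
  invisible(outdir)
}

#' @export
print.study_report <- function(x, ...) {
  d <- x$descriptives
  cat(sprintf("Twin study report: %d pairs (%d MZ, %d DZ)\n",
              d$n_pairs, d$n_mz, d$n_dz))
  cat(sprintf("  score: mean %.2f, sd %.2f, skew %.2f\n",
              d$mean, d$sd, d$skew))
  tc <- x$twin_correlations
  cat(sprintf("  twin correlations: rMZ %.3f, rDZ %.3f\n",
              tc$r[tc$zygosity == "MZ"], tc$r[tc$zygosity == "DZ"]))
  best <- attr(x$univariate$table, "best")
  bf <- x$univariate$fits[[best]]
  cat(sprintf("  best univariate model: %s (a2 = %.3f)\n",
              best, bf$estimates$a2 %||% NA))
  if (nrow(x$extremes))
    cat(sprintf("  h2g across percentiles: %s\n",
                paste(sprintf("%g%%: %.2f", x$extremes$percentile,
                              x$extremes$h2g)[x$extremes$method ==
                                                "regression"],
                      collapse = ", ")))
  for (tr in names(x$joint)) {
    best_j <- attr(x$joint[[tr]]$table, "best")
    fj <- x$joint[[tr]]$fits[[best_j]]
    cat(sprintf("  joint model (%s, %s): rA %.2f, rE %.2f, rPH %.2f, bivariate h2 %.2f\n",
                tr, best_j, fj$estimates$rA, fj$estimates$rE,
                fj$estimates$rPH, fj$estimates$bivariate_h2))
  }
  invisible(x)
}
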