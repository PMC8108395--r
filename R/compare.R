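# Model-selection machinery: likelihood-ratio tests against a parent
# model, AIC/BIC, and best-model designation.

#' Likelihood-ratio test between nested model fits
#'
#' \eqn{\Delta\chi^2 = (-2LL_{nested}) - (-2LL_{parent})} referred to a
#' chi-square with \code{df} equal to the difference in free parameters.
#' Variance components sit on the boundary of their space when dropped, so
#' the plain chi-square reference is conservative for such reductions; a
#' 50:50 mixture reference is available via \code{boundary_mix}.
#'
#' @param parent,nested Fit objects (anything with \code{minus2LL},
#'   \code{npar} and \code{model} entries); \code{nested} must have fewer
#'   or equal free parameters.
#' @param boundary_mix Use the 0.5*chisq(df) + 0.5*chisq(df-1) mixture
#'   reference (one component dropped at a boundary)?
#' @return One-row data frame: models, \code{delta_chisq},
#'   \code{delta_df}, \code{p}.
#' @export
lrt <- function(parent, nested, boundary_mix = FALSE) {
  if (nested$npar > parent$npar)
    stop("`nested` has more free parameters than `parent`; not nested")
  dchi <- nested$minus2LL - parent$minus2LL
  if (dchi < 0) {
    if (dchi < -1e-4)
      stop("nested model fits better than parent (delta -2LL = ",
           format(dchi), "); models are not nested or a fit failed")
    dchi <- 0
  }
  ddf <- parent$npar - nested$npar
  p <- if (ddf == 0) NA_real_
  else if (boundary_mix && ddf >= 1) {
    0.5 * stats::pchisq(dchi, ddf, lower.tail = FALSE) +
      0.5 * (if (ddf > 1) stats::pchisq(dchi, ddf - 1, lower.tail = FALSE)
             else as.numeric(dchi == 0))
  } else stats::pchisq(dchi, ddf, lower.tail = FALSE)
  data.frame(parent = parent$model, nested = nested$model,
             delta_chisq = dchi, delta_df = ddf, p = p)
}

#' Fit-comparison table for a family of models
#'
#' One row per fit: -2LL, free parameters, LRT against the designated
#' comparison model (the first fit by default, typically the saturated or
#' full model), AIC and BIC, plus a best-model flag from
#' \code{\link{select_best}}.
#'
#' @param fits Named or unnamed list of fit objects; the LRT baseline is
#'   \code{fits[[baseline]]}.
#' @param baseline Index or model label of the comparison model.
#' @param rule Selection rule passed to \code{\link{select_best}}.
#' @param alpha LRT deterioration level.
#' @return Data frame (one row per model).
#' @export
compare_models <- function(fits, baseline = 1L, rule = c("lrt", "bic"),
                           alpha = 0.05) {
  rule <- match.arg(rule)
  labels <- vapply(fits, function(f) f$model, character(1))
  if (is.character(baseline)) baseline <- match(baseline, labels)
  base <- fits[[baseline]]
  rows <- lapply(fits, function(f) {
    cmp <- if (f$npar <= base$npar && f$model != base$model)
      lrt(base, f) else data.frame(delta_chisq = NA_real_,
                                   delta_df = NA_integer_, p = NA_real_)
    data.frame(model = f$model, minus2LL = f$minus2LL, npar = f$npar,
               delta_chisq = cmp$delta_chisq, delta_df = cmp$delta_df,
               p = cmp$p, AIC = f$AIC, BIC = f$BIC)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- select_best(tab, rule = rule, alpha = alpha)
  tab$best <- tab$model == best
  attr(tab, "best") <- best
  attr(tab, "conflict") <- attr(best, "conflict")
  tab
}

#' Designate the best-fitting model
#'
#' Two policies: \code{"lrt"} favors the most reduced model (fewest free
#' parameters) whose likelihood-ratio test against the comparison model
#' does not indicate significant deterioration (p > alpha), breaking ties
#' by lowest BIC; \code{"bic"} simply takes the lowest BIC.  When the two
#' policies disagree the conflict is reported in the \code{"conflict"}
#' attribute, never silently resolved.
#'
#' @param table A comparison table as built by \code{\link{compare_models}}
#'   (columns \code{model}, \code{npar}, \code{p}, \code{BIC}).
#' @param rule \code{"lrt"} or \code{"bic"}.
#' @param alpha Deterioration level for the LRT rule.
#' @return The selected model label (with attribute \code{conflict} naming
#'   the other policy's choice when they differ).
#' @export
select_best <- function(table, rule = c("lrt", "bic"), alpha = 0.05) {
  rule <- match.arg(rule)
  if (nrow(table) == 1) return(table$model[1])
  by_bic <- table$model[which.min(table$BIC)]
  ok <- !is.na(table$p) & table$p > alpha
  by_lrt <- if (any(ok)) {
    cand <- table[ok, ]
    cand <- cand[cand$npar == min(cand$npar), ]
    cand$model[which.min(cand$BIC)]
  } else {
    # everything deteriorates: keep the fullest candidate model
    base <- table[is.na(table$p), ]
    if (nrow(base)) base$model[which.max(base$npar)]
    else table$model[which.max(table$npar)]
  }
  best <- if (rule == "lrt") by_lrt else by_bic
  if (by_lrt != by_bic)
    attr(best, "conflict") <- c(lrt = by_lrt, bic = by_bic)
  best
}

#' Fit the ACE family and compare fits
#'
#' Convenience wrapper: fits the saturated model and the requested
#' ACE-family reductions to continuous twin data and assembles the
#' comparison table.
#'
#' @inheritParams fit_ace
#' @param models Model labels to fit.
#' @param rule Selection rule.
#' @return List with \code{fits} (named list) and \code{table}.
#' @export
ace_family <- function(pairs, models = c("ACE", "AE", "CE", "E"),
                       score_cols = c("t1_score", "t2_score"),
                       ci = "profile", rule = "lrt",
                       bic_n = c("pairs", "individuals")) {
  bic_n <- match.arg(bic_n)
  sat <- fit_saturated(pairs, "none", score_cols)
  fits <- c(list(SAT = sat),
            stats::setNames(lapply(models, function(m)
              fit_ace(pairs, m, score_cols,
                      ci = if (identical(ci, "profile")) "profile" else "none",
                      bic_n = bic_n)), models))
  list(fits = fits, table = compare_models(fits, baseline = 1L, rule = rule))
}
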