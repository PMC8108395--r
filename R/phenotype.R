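# Phenotype construction: questionnaire total score with missingness rules,
# log transform, and three-source eating-disorder case classification.

.edi2_lengths <- c(drive_for_thinness = 7L, bulimia = 7L,
                   body_dissatisfaction = 9L)
.edi2_minimums <- c(drive_for_thinness = 6L, bulimia = 6L,
                    body_dissatisfaction = 7L)

#' Score a 23-item eating-disorder inventory
#'
#' The total score is the mean of all answered items across the Drive for
#' Thinness (7 items), Bulimia (7 items) and Body Dissatisfaction (9 items)
#' subscales, computed only when at least 75% of the items on *each*
#' subscale were answered (at least 6/7, 6/7 and 7/9 respectively);
#' otherwise the score is missing.  Item responses are integers on a
#' 1 ("never") to 6 ("always") scale.
#'
#' @param drive_for_thinness,bulimia,body_dissatisfaction Numeric vectors
#'   of length 7, 7 and 9 with values in 1..6 or \code{NA}.
#' @return A single numeric score in \code{[1, 6]}, or \code{NA} when a
#'   subscale misses its completion minimum.
#' @examples
#' score_edi2(rep(1, 7), rep(1, 7), rep(1, 9))  # 1
#' @export
score_edi2 <- function(drive_for_thinness, bulimia, body_dissatisfaction) {
  items <- list(drive_for_thinness = drive_for_thinness,
                bulimia = bulimia,
                body_dissatisfaction = body_dissatisfaction)
  for (nm in names(items)) {
    x <- items[[nm]]
    if (length(x) != .edi2_lengths[[nm]])
      stop(sprintf("`%s` must have %d items, got %d",
                   nm, .edi2_lengths[[nm]], length(x)))
    bad <- !is.na(x) & (x < 1 | x > 6 | x != floor(x))
    if (any(bad))
      stop(sprintf("`%s` has responses outside 1..6", nm))
  }
  answered <- vapply(items, function(x) sum(!is.na(x)), integer(1))
  if (any(answered < .edi2_minimums)) return(NA_real_)
  all_items <- unlist(items, use.names = FALSE)
  mean(all_items, na.rm = TRUE)
}

#' Natural-log transform of a positive score
#'
#' Applied to questionnaire totals (which live on a 1-6 scale, so are
#' always >= 1) before model fitting, to reduce right skew.
#'
#' @param score Numeric vector, all values > 0 (NA passed through).
#' @return \code{log(score)}.
#' @export
log_transform <- function(score) {
  if (any(score <= 0, na.rm = TRUE))
    stop("`score` must be positive for the log transform")
  log(score)
}

# ICD-10 code sets (dot optional); exclusions are dropped, not classified
.icd_an <- c("F50.0", "F50.1")
.icd_oed <- c("F50.2", "F50.3", "F50.9")
.icd_excluded <- c("F50.4", "F50.5", "F50.8", "F98.2", "F98.3")

.norm_icd <- function(code) {
  code <- toupper(trimws(code))
  sub("^([A-Z][0-9]{2})([0-9])$", "\\1.\\2", code)
}

#' Interpret ICD-10 eating-disorder codes
#'
#' Maps codes to the AN set (F50.0 anorexia nervosa, F50.1 atypical AN) or
#' the OED set (F50.2 bulimia nervosa, F50.3 atypical BN, F50.9 EDNOS);
#' codes may be written with or without the dot (\code{F500} == \code{F50.0}).
#' Exclusion codes (F50.4, F50.5, F50.8, F98.2, F98.3) are dropped and
#' counted, not classified.
#'
#' @param codes Character vector of ICD-10 codes (one individual).
#' @return List with logicals \code{npr_an}, \code{npr_oed}, \code{npr_bn}
#'   (F50.2/F50.3 specifically) and \code{n_excluded}.
#' @export
parse_icd_codes <- function(codes) {
  codes <- .norm_icd(codes[!is.na(codes)])
  list(npr_an = any(codes %in% .icd_an),
       npr_oed = any(codes %in% .icd_oed),
       npr_bn = any(codes %in% c("F50.2", "F50.3")),
       n_excluded = sum(codes %in% .icd_excluded))
}

#' Classify eating-disorder caseness from three ascertainment sources
#'
#' Case sources are a national patient register (ICD-coded AN vs other-ED
#' diagnoses), parent-reported treatment (for AN, for BN), and self-reported
#' regular purging.  An individual is classified \code{AN} if any AN source
#' flags (register AN/atypical-AN diagnosis or parent-reported AN
#' treatment), else \code{OED} if any other-ED source flags (register
#' BN/atypical-BN/EDNOS diagnosis, parent-reported BN treatment, or
#' self-reported purging), else \code{NONE}.  Individuals with both AN and
#' OED indicators land in \code{AN} (AN takes precedence).  Missing flags
#' are treated as \code{FALSE}: ascertainment sources are incomplete (e.g.
#' parent reports available for only part of a cohort) and an unobserved
#' source cannot assert caseness.
#'
#' @param npr_an,npr_oed,parent_treat_an,parent_treat_bn,self_purging
#'   Logical vectors (recycled to common length); \code{NA} allowed.
#' @return A data frame with columns \code{group} (factor
#'   \code{AN/OED/NONE}) and \code{any_ed} (logical).
#' @export
classify_ed <- function(npr_an = FALSE, npr_oed = FALSE,
                        parent_treat_an = FALSE, parent_treat_bn = FALSE,
                        self_purging = FALSE) {
  n <- max(length(npr_an), length(npr_oed), length(parent_treat_an),
           length(parent_treat_bn), length(self_purging))
  f <- function(x) { x <- rep_len(as.logical(x), n); x[is.na(x)] <- FALSE; x }
  an <- f(npr_an) | f(parent_treat_an)
  oed <- f(npr_oed) | f(parent_treat_bn) | f(self_purging)
  group <- factor(ifelse(an, "AN", ifelse(oed, "OED", "NONE")),
                  levels = c("AN", "OED", "NONE"))
  data.frame(group = group, any_ed = an | oed)
}

# percentages rounded one decimal, half-up (so 56.45 -> 56.5, not 56.4)
.pct <- function(num, den) {
  if (den == 0) return(NA_real_)
  floor(num / den * 1000 + 0.5) / 10
}

#' Case counts, prevalences and source overlap for a classified cohort
#'
#' @param flags Data frame with one row per individual and logical columns
#'   \code{npr_an}, \code{npr_oed}, \code{parent_treat_an},
#'   \code{parent_treat_bn}, \code{self_purging}; optionally \code{npr_bn}
#'   (register BN specifically, for the parent-BN overlap figure).
#' @return A list: \code{n}; \code{groups} (count and percent for AN, OED,
#'   NONE, any ED); \code{sources} (count/percent flagged per source, and
#'   per-source availability = share of non-missing entries); and
#'   \code{overlap} — the share of any-ED cases carrying a register
#'   diagnosis, of parent-AN-treated individuals with a register AN
#'   diagnosis, of parent-BN-treated with a register BN diagnosis, and of
#'   cases identified by more than one source.  Percentages are rounded to
#'   one decimal, half-up.
#' @export
cohort_summary <- function(flags) {
  if (!is.data.frame(flags) || nrow(flags) == 0)
    stop("`flags` must be a non-empty data frame of source indicators")
  need <- c("npr_an", "npr_oed", "parent_treat_an", "parent_treat_bn",
            "self_purging")
  miss <- setdiff(need, names(flags))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(flags)
  cls <- classify_ed(flags$npr_an, flags$npr_oed, flags$parent_treat_an,
                     flags$parent_treat_bn, flags$self_purging)
  tf <- function(x) { x <- as.logical(x); x[is.na(x)] <- FALSE; x }
  npr_any <- tf(flags$npr_an) | tf(flags$npr_oed)
  parent_any <- tf(flags$parent_treat_an) | tf(flags$parent_treat_bn)
  purge <- tf(flags$self_purging)
  n_sources <- npr_any + parent_any + purge

  grp_count <- c(table(cls$group), any_ed = sum(cls$any_ed))
  groups <- data.frame(
    group = names(grp_count),
    count = as.integer(grp_count),
    percent = vapply(grp_count, .pct, numeric(1), den = n),
    row.names = NULL)

  src <- data.frame(
    source = c("npr_any", "npr_an", "npr_oed", "parent_treat_an",
               "parent_treat_bn", "self_purging"),
    count = c(sum(npr_any), sum(tf(flags$npr_an)), sum(tf(flags$npr_oed)),
              sum(tf(flags$parent_treat_an)), sum(tf(flags$parent_treat_bn)),
              sum(purge)),
    availability = c(NA, vapply(flags[need], function(x)
      .pct(sum(!is.na(x)), n), numeric(1))[c(1, 2, 3, 4, 5)]))
  src$percent <- vapply(src$count, .pct, numeric(1), den = n)

  any_cases <- sum(cls$any_ed)
  overlap <- list(
    any_ed_with_npr = .pct(sum(cls$any_ed & npr_any), any_cases),
    parent_an_with_npr_an = .pct(sum(tf(flags$parent_treat_an) &
                                       tf(flags$npr_an)),
                                 sum(tf(flags$parent_treat_an))),
    multi_source = .pct(sum(cls$any_ed & n_sources > 1), any_cases))
  if (!is.null(flags$npr_bn))
    overlap$parent_bn_with_npr_bn <- .pct(
      sum(tf(flags$parent_treat_bn) & tf(flags$npr_bn)),
      sum(tf(flags$parent_treat_bn)))

  list(n = n, groups = groups, sources = src, overlap = overlap)
}
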