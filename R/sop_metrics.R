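#' Strength of preference from association times
#'
#' The per-individual strength of preference is
#' `SOP = (T_C - T_H) / (T_C + T_H)`, where `T_C` and `T_H` are the times
#' (seconds) the focal individual spent in the conspecific and
#' heterospecific association zones. It ranges from +1 (complete
#' conspecific preference) through 0 (no preference) to -1 (complete
#' heterospecific preference), and can be read as the proportional
#' reduction in gene flow relative to random mating (a value of 0.3 means
#' a 30% reduction). When both times are zero the statistic is undefined
#' and `NA` is returned; neutral-zone time does not enter.
#'
#' @param t_conspecific,t_heterospecific Non-negative association times in
#'   seconds (vectorized).
#' @return Numeric vector in `[-1, 1]`, `NA` where `T_C + T_H = 0`.
#' @examples
#' compute_sop(600, 300)  # 1/3
#' compute_sop(450, 0)    # complete conspecific preference
#' @export
compute_sop <- function(t_conspecific, t_heterospecific) {
  if (any(!is.finite(t_conspecific)) || any(!is.finite(t_heterospecific))) {
    abort_domain("Association times must be finite.")
  }
  if (any(t_conspecific < 0) || any(t_heterospecific < 0)) {
    abort_domain("Association times must be non-negative.")
  }
  total <- t_conspecific + t_heterospecific
  out <- ifelse(total > 0, (t_conspecific - t_heterospecific) / total, NA_real_)
  as.numeric(out)
}

#' Per-individual SOP records from a trial table
#'
#' Attaches the strength of preference to each trial's grouping labels.
#' Trials with zero total association time yield a missing SOP and a
#' warning; they are excluded from downstream summaries because a 0/0 has
#' no preference interpretation.
#'
#' @param trials Tibble of validated dichotomous trials.
#' @return Tibble with columns `focal_id`, `population`, `context`, `sex`,
#'   `sop`.
#' @export
sop_records <- function(trials) {
  out <- tibble::tibble(
    focal_id = trials$focal_id,
    population = trials$population,
    context = trials$context,
    sex = trials$sex,
    sop = compute_sop(trials$t_conspecific, trials$t_heterospecific))
  n_missing <- sum(is.na(out$sop))
  if (n_missing > 0) {
    warn(sprintf(
      "%d trial(s) had zero total association time; their SOP is missing and excluded from summaries.",
      n_missing))
  }
  out
}

#' Group-level SOP summaries with a test against zero preference
#'
#' For each group defined by `group_by`, reports the number of non-missing
#' records, the arithmetic mean SOP, its standard error (sample SD /
#' sqrt(n)), and a two-sided test of the null of no preference (mean SOP
#' = 0): either a one-sample t test or a Wilcoxon signed-rank test. Groups
#' with too few usable records are returned with missing statistics and
#' `degenerate = TRUE` rather than dropped.
#'
#' @param records Tibble from [sop_records()] (columns used: `sop` plus
#'   the grouping labels).
#' @param group_by Character vector of grouping columns, any subset of
#'   `population`, `context`, `sex`.
#' @param test `"t_one_sample"` (default) or `"wilcoxon_signed_rank"`.
#' @return Tibble with one row per group: grouping labels, `n`, `mean`,
#'   `se`, `test_name`, `statistic`, `df` (NA for the rank test),
#'   `p_value`, `degenerate`.
#' @export
group_sop_summary <- function(records,
                              group_by = c("population", "context", "sex"),
                              test = c("t_one_sample", "wilcoxon_signed_rank")) {
  test <- match.arg(test)
  missing_cols <- setdiff(group_by, names(records))
  if (length(missing_cols) > 0) {
    abort_domain(sprintf("Grouping column(s) not present: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::group_modify(function(d, key) {
      x <- d$sop[!is.na(d$sop)]
      n <- length(x)
      if (n == 0) {
        return(tibble::tibble(n = 0L, mean = NA_real_, se = NA_real_,
                              test_name = test, statistic = NA_real_,
                              df = NA_real_, p_value = NA_real_,
                              degenerate = TRUE))
      }
      m <- mean(x)
      se <- if (n > 1) sd(x) / sqrt(n) else NA_real_
      res <- if (test == "t_one_sample") {
        r <- one_sample_t(x, mu0 = 0)
        tibble::tibble(statistic = r$statistic, df = r$df,
                       p_value = r$p_value, degenerate = r$degenerate)
      } else {
        r <- wilcoxon_signed_rank(x, mu0 = 0)
        tibble::tibble(statistic = r$Z, df = NA_real_,
                       p_value = r$p_value, degenerate = r$degenerate)
      }
      tibble::tibble(n = n, mean = m, se = se, test_name = test,
                     statistic = res$statistic, df = res$df,
                     p_value = res$p_value, degenerate = res$degenerate)
    }) |>
    dplyr::ungroup()
}

#' Sample-size-weighted pooling of group means
#'
#' Pools per-group means into a combined mean weighted by group sizes;
#' identical to the mean of the concatenated raw samples. Used to combine
#' populations within a geographic context (e.g., the two sympatric
#' populations) when contrasting sympatry against allopatry.
#'
#' @param means Numeric vector of group means.
#' @param ns Integer vector of group sizes (same length, all >= 1).
#' @return The pooled mean.
#' @examples
#' pool_group_means(c(0.73, 0.31), c(18, 18))  # 0.52
#' @export
pool_group_means <- function(means, ns) {
  if (length(means) != length(ns)) {
    abort_domain("means and ns must have the same length.")
  }
  if (any(!is.finite(ns)) || any(ns < 1)) abort_domain("All ns must be >= 1.")
  sum(means * ns) / sum(ns)
}

#' Check size matching of paired stimulus fish
#'
#' Stimulus pairs in dichotomous trials are size-matched so that length,
#' rather than species identity, cannot drive association preferences.
#' This check runs a paired Wilcoxon signed-rank test on the conspecific
#' vs heterospecific standard lengths and reports the fraction of pairs
#' whose relative length difference (absolute difference over the pair
#' mean) is within 15%, the conventional matching criterion.
#'
#' @param con_lengths,het_lengths Paired standard lengths (mm), equal
#'   length vectors.
#' @param tolerance Relative-difference threshold (default 0.15).
#' @return List with `n`, `within_tolerance` (fraction of pairs), `Z`,
#'   `p_value`, `degenerate` (TRUE when all differences are zero).
#' @export
size_match_check <- function(con_lengths, het_lengths, tolerance = 0.15) {
  if (length(con_lengths) != length(het_lengths)) {
    abort_domain("con_lengths and het_lengths must have the same length.")
  }
  keep <- !is.na(con_lengths) & !is.na(het_lengths)
  con <- con_lengths[keep]
  het <- het_lengths[keep]
  rel <- abs(con - het) / ((con + het) / 2)
  frac <- mean(rel <= tolerance)
  w <- wilcoxon_signed_rank(con, paired_with = het)
  list(n = length(con), within_tolerance = frac,
       Z = w$Z, p_value = w$p_value, degenerate = w$degenerate)
}
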