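#' Stalker-style behavioral isolation index
#'
#' `I = (C - H) / (C + H)` where `C` and `H` are the mean numbers of
#' conspecific- and heterospecific-directed interactions across
#' replicates. `I = +1` indicates complete conspecific bias, `-1` complete
#' heterospecific bias, 0 no bias. Undefined (returned as `NA`) when both
#' means are zero; antisymmetric under swapping the arguments; invariant
#' to scaling both means by a common positive factor.
#'
#' @param conspecific_mean,heterospecific_mean Non-negative means
#'   (vectorized).
#' @return Numeric vector in `[-1, 1]`, `NA` where both means are zero.
#' @examples
#' isolation_index(44.3, 6.0)   # 0.76 at 2 dp
#' isolation_index(237.0, 0)    # 1
#' @export
isolation_index <- function(conspecific_mean, heterospecific_mean) {
  if (any(!is.finite(conspecific_mean)) || any(!is.finite(heterospecific_mean))) {
    abort_domain("Interaction means must be finite.")
  }
  if (any(conspecific_mean < 0) || any(heterospecific_mean < 0)) {
    abort_domain("Interaction means must be non-negative.")
  }
  total <- conspecific_mean + heterospecific_mean
  as.numeric(ifelse(total > 0,
                    (conspecific_mean - heterospecific_mean) / total,
                    NA_real_))
}

check_behavior_subset <- function(behaviors) {
  bad <- setdiff(behaviors, STREAM_BEHAVIORS)
  if (length(bad) > 0) {
    abort_domain(sprintf("Unknown behavior(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(behaviors) == 0) {
    abort_domain("The behavior subset must be non-empty.")
  }
  invisible(behaviors)
}

# Long counts -> one row per replicate x species x behavior with paired
# conspecific/heterospecific counts; cells absent from the input are
# zero-filled (a behavior that was never observed is a count of zero).
pair_counts <- function(counts) {
  counts |>
    dplyr::group_by(.data$population, .data$context, .data$species) |>
    tidyr::complete(replicate_id = unique(.data$replicate_id),
                    behavior = STREAM_BEHAVIORS,
                    target = .targets,
                    fill = list(count = 0L)) |>
    dplyr::ungroup() |>
    tidyr::pivot_wider(names_from = "target", values_from = "count",
                       values_fill = 0L)
}

#' Per-behavior isolation table
#'
#' For every population x species x behavior, computes the mean and sample
#' standard deviation (n - 1 denominator) across replicates of the
#' conspecific- and heterospecific-directed counts, and the isolation
#' index from the two means. Behaviors never observed for a population x
#' species yield a row with both means zero and a missing index rather
#' than an error. This is the per-behavior summary a study reports per
#' population and species.
#'
#' @param counts Validated stream-count tibble (see
#'   [read_stream_counts()]).
#' @return Tibble with `scope = "behavior"` and columns `population`,
#'   `context`, `species`, `behavior`, `n_replicates`,
#'   `conspecific_mean`, `conspecific_sd`, `heterospecific_mean`,
#'   `heterospecific_sd`, `i_index`.
#' @export
behavior_isolation_table <- function(counts) {
  if (nrow(counts) == 0) abort_domain("counts is empty.")
  pair_counts(counts) |>
    dplyr::group_by(.data$population, .data$context, .data$species,
                    .data$behavior) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      conspecific_mean = mean(.data$conspecific),
      conspecific_sd = sd(.data$conspecific),
      heterospecific_mean = mean(.data$heterospecific),
      heterospecific_sd = sd(.data$heterospecific),
      .groups = "drop") |>
    dplyr::mutate(
      scope = "behavior",
      behavior = factor(.data$behavior, levels = STREAM_BEHAVIORS),
      i_index = isolation_index(.data$conspecific_mean,
                                .data$heterospecific_mean)) |>
    dplyr::arrange(.data$population, .data$species, .data$behavior) |>
    dplyr::mutate(behavior = as.character(.data$behavior)) |>
    dplyr::relocate("scope")
}

#' Total isolation per replicate
#'
#' For each replicate x species, sums the conspecific-directed and
#' heterospecific-directed counts over a behavior subset (by default all
#' five classes) and applies the isolation index to the per-replicate
#' sums. These per-replicate totals are the response variable of the
#' heteroskedastic GLS model (see [fit_total_isolation_gls()]).
#'
#' @param counts Validated stream-count tibble.
#' @param behaviors Non-empty subset of [STREAM_BEHAVIORS].
#' @return Tibble with `scope = "replicate_total"` and columns
#'   `replicate_id`, `population`, `context`, `species`,
#'   `conspecific_total`, `heterospecific_total`, `i_index`.
#' @export
total_isolation_per_replicate <- function(counts, behaviors = STREAM_BEHAVIORS) {
  check_behavior_subset(behaviors)
  if (nrow(counts) == 0) abort_domain("counts is empty.")
  pair_counts(counts) |>
    dplyr::filter(.data$behavior %in% behaviors) |>
    dplyr::group_by(.data$replicate_id, .data$population, .data$context,
                    .data$species) |>
    dplyr::summarise(conspecific_total = sum(.data$conspecific),
                     heterospecific_total = sum(.data$heterospecific),
                     .groups = "drop") |>
    dplyr::mutate(scope = "replicate_total",
                  i_index = isolation_index(.data$conspecific_total,
                                            .data$heterospecific_total)) |>
    dplyr::arrange(.data$population, .data$species, .data$replicate_id) |>
    dplyr::relocate("scope")
}

#' Population-level total isolation
#'
#' Averages the per-replicate summed conspecific and heterospecific totals
#' across replicates for each population x species, then applies the
#' isolation index to the averaged totals. Note the order of operations:
#' the averages of the summed counts are indexed, not the per-replicate
#' indices averaged; with a single replicate the two coincide.
#'
#' @inheritParams total_isolation_per_replicate
#' @return Tibble with `scope = "population_total"` and columns
#'   `population`, `context`, `species`, `n_replicates`,
#'   `conspecific_mean`, `conspecific_sd`, `heterospecific_mean`,
#'   `heterospecific_sd`, `i_index`.
#' @export
population_total_isolation <- function(counts, behaviors = STREAM_BEHAVIORS) {
  total_isolation_per_replicate(counts, behaviors) |>
    dplyr::group_by(.data$population, .data$context, .data$species) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      conspecific_mean = mean(.data$conspecific_total),
      conspecific_sd = sd(.data$conspecific_total),
      heterospecific_mean = mean(.data$heterospecific_total),
      heterospecific_sd = sd(.data$heterospecific_total),
      .groups = "drop") |>
    dplyr::mutate(scope = "population_total",
                  i_index = isolation_index(.data$conspecific_mean,
                                            .data$heterospecific_mean)) |>
    dplyr::relocate("scope")
}

#' Behavior-exclusion sensitivity analysis
#'
#' Recomputes per-replicate total isolation with a subset of behaviors
#' removed (for example, dropping the male solicitation classes to ask
#' whether they alone carry a sympatry-allopatry difference) and pairs it
#' with the full-set totals for downstream refitting.
#'
#' @param counts Validated stream-count tibble.
#' @param drop Proper subset of [STREAM_BEHAVIORS] to exclude; may be
#'   empty, in which case `reduced` equals `full`.
#' @return Tibble of per-replicate totals with an `analysis` column,
#'   `"full"` or `"reduced"`.
#' @export
exclude_behaviors_sensitivity <- function(counts, drop) {
  bad <- setdiff(drop, STREAM_BEHAVIORS)
  if (length(bad) > 0) {
    abort_domain(sprintf("Unknown behavior(s) in drop: %s",
                         paste(bad, collapse = ", ")))
  }
  keep <- setdiff(STREAM_BEHAVIORS, drop)
  if (length(keep) == 0) {
    abort_domain("drop must be a proper subset of the five behaviors.")
  }
  full <- total_isolation_per_replicate(counts, STREAM_BEHAVIORS)
  reduced <- total_isolation_per_replicate(counts, keep)
  dplyr::bind_rows(full = full, reduced = reduced, .id = "analysis")
}
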