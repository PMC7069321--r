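#' Configuration for simulated dichotomous trials
#'
#' The generative model allocates each focal individual's trial time in
#' two beta-distributed stages. First an activity fraction `a` (the share
#' of the trial spent in either association zone) is drawn with mean
#' `activity_mean` and precision `activity_precision`; total association
#' time is `A = trial_duration * a`. Then a conspecific share `c` is drawn
#' with mean `(1 + beta) / 2` and precision `kappa`, and the times are
#' `t_conspecific = A * c`, `t_heterospecific = A * (1 - c)`. Because the
#' strength of preference is `2c - 1`, its expectation equals `beta`
#' exactly, making `beta` a clean recovery target, and the construction
#' guarantees the two times never exceed the trial duration.
#'
#' @param groups Data frame with columns `population`, `context`, `sex`,
#'   `n` (trials per group, >= 1) and `beta` (latent preference bias,
#'   strictly inside (-1, 1)).
#' @param kappa Precision of the conspecific-share beta distribution
#'   (> 0); larger values give less variable preferences.
#' @param activity_mean Expected activity fraction, in (0, 1).
#' @param activity_precision Precision of the activity fraction (> 0).
#' @param trial_duration Trial length in seconds (default 900, a 15-min
#'   observation period).
#' @param seed Integer seed; each group draws from its own deterministic
#'   substream so adding a group leaves other groups' trials unchanged.
#' @return A validated `dichotomous_sim_config` object.
#' @export
dichotomous_sim_config <- function(groups, kappa = 5, activity_mean = 0.75,
                                   activity_precision = 10,
                                   trial_duration = 900, seed = 1L) {
  groups <- tibble::as_tibble(groups)
  need <- c("population", "context", "sex", "n", "beta")
  missing <- setdiff(need, names(groups))
  if (length(missing) > 0) {
    abort_config(sprintf("groups is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (nrow(groups) == 0) abort_config("groups must contain at least one row.")
  if (any(!is.finite(groups$beta)) || any(abs(groups$beta) >= 1)) {
    abort_config("Every group beta must be finite and strictly inside (-1, 1).")
  }
  if (any(!is_whole(groups$n)) || any(groups$n < 1)) {
    abort_config("Every group n must be an integer >= 1.")
  }
  if (!(groups |> dplyr::distinct(.data$population, .data$context) |>
          dplyr::count(.data$population) |> dplyr::pull(.data$n) |>
          (\(k) all(k == 1))())) {
    abort_config("Each population must map to a single context.")
  }
  if (!is.finite(kappa) || kappa <= 0) abort_config("kappa must be > 0.")
  if (!is.finite(activity_mean) || activity_mean <= 0 || activity_mean >= 1) {
    abort_config("activity_mean must lie strictly inside (0, 1).")
  }
  if (!is.finite(activity_precision) || activity_precision <= 0) {
    abort_config("activity_precision must be > 0.")
  }
  if (!is.finite(trial_duration) || trial_duration <= 0) {
    abort_config("trial_duration must be > 0 seconds.")
  }
  structure(list(groups = groups, kappa = kappa,
                 activity_mean = activity_mean,
                 activity_precision = activity_precision,
                 trial_duration = trial_duration,
                 seed = as.integer(seed)),
            class = "dichotomous_sim_config")
}

#' Simulate dichotomous mate-choice trials
#'
#' Draws `n` trials per configured group under the two-stage beta
#' allocation model of [dichotomous_sim_config()]. Output satisfies every
#' dichotomous-trial invariant and is bit-identical for identical seeds.
#'
#' @param config A `dichotomous_sim_config`.
#' @return A tibble of trials in the [read_dichotomous()] layout.
#' @examples
#' cfg <- dichotomous_sim_config(
#'   groups = data.frame(population = "A", context = "sympatric",
#'                       sex = "female", n = 5, beta = 0.5),
#'   seed = 42)
#' simulate_dichotomous(cfg)
#' @export
simulate_dichotomous <- function(config) {
  if (!inherits(config, "dichotomous_sim_config")) {
    abort_config("config must be created by dichotomous_sim_config().")
  }
  a1 <- config$activity_mean * config$activity_precision
  a2 <- (1 - config$activity_mean) * config$activity_precision
  rows <- lapply(seq_len(nrow(config$groups)), function(i) {
    g <- config$groups[i, ]
    m <- (1 + g$beta) / 2
    sub <- derive_seed(config$seed, "dichotomous", g$population, g$context, g$sex)
    with_substream(sub, {
      activity <- rbeta(g$n, a1, a2)
      share <- rbeta(g$n, m * config$kappa, (1 - m) * config$kappa)
      total <- config$trial_duration * activity
      tag <- sprintf("%s_%s_%s_%03d", g$population, g$context, g$sex, seq_len(g$n))
      tibble::tibble(
        trial_id = paste0("trial_", tag),
        focal_id = paste0("fish_", tag),
        population = g$population, context = g$context, sex = g$sex,
        t_conspecific = total * share,
        t_heterospecific = total * (1 - share),
        trial_duration = config$trial_duration,
        conspecific_side = rep(c("left", "right"), length.out = g$n),
        stimulus_con_length = NA_real_,
        stimulus_het_length = NA_real_)
    })
  })
  trials <- dplyr::bind_rows(rows)
  validate_dichotomous(trials)
  trials
}

#' Configuration for simulated stream-trial behavior counts
#'
#' Counts for each replicate x species x behavior are split between
#' conspecific and heterospecific targets: the conspecific count has mean
#' `lambda * (1 + iota) / 2` and the heterospecific count mean
#' `lambda * (1 - iota) / 2`, so the per-behavior isolation index
#' converges to `iota` as `lambda` grows. With `dispersion = 0` counts
#' are Poisson; with `dispersion > 0` they are gamma-mixed Poisson
#' (negative binomial with variance `mu + dispersion * mu^2`), which
#' reproduces the strongly overdispersed counts typical of free-interaction
#' assays, where standard deviations can exceed means.
#'
#' @param populations Data frame with columns `population`, `context`.
#' @param behaviors Data frame with columns `behavior` (a subset of
#'   [STREAM_BEHAVIORS]), `lambda` (expected total count per replicate,
#'   >= 0) and `iota` (conspecific bias in `[-1, 1]`). An optional
#'   `species` column gives each species its own rates (e.g., a resident
#'   species keeping a strong conspecific bias while the focal species'
#'   bias varies); without it both species share the same rates.
#' @param n_replicates Replicate trials per population (default 3).
#' @param dispersion Overdispersion parameter >= 0; 0 means Poisson.
#' @param species_pair Character vector of the two interacting species
#'   labels; counts are generated for both.
#' @param seed Integer seed (per-population substreams).
#' @return A validated `stream_sim_config` object.
#' @export
stream_sim_config <- function(populations, behaviors, n_replicates = 3,
                              dispersion = 0.3,
                              species_pair = c("species_A", "species_B"),
                              seed = 1L) {
  populations <- tibble::as_tibble(populations)
  behaviors <- tibble::as_tibble(behaviors)
  if (!all(c("population", "context") %in% names(populations))) {
    abort_config("populations must have columns population, context.")
  }
  if (!all(c("behavior", "lambda", "iota") %in% names(behaviors))) {
    abort_config("behaviors must have columns behavior, lambda, iota.")
  }
  bad <- setdiff(behaviors$behavior, STREAM_BEHAVIORS)
  if (length(bad) > 0) {
    abort_config(sprintf("Unknown behavior(s) in config: %s", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(behaviors$lambda)) || any(behaviors$lambda < 0)) {
    abort_config("Every lambda must be finite and >= 0.")
  }
  if (any(!is.finite(behaviors$iota)) || any(abs(behaviors$iota) > 1)) {
    abort_config("Every iota must lie in [-1, 1].")
  }
  if (!is_whole(n_replicates) || n_replicates < 1) {
    abort_config("n_replicates must be an integer >= 1.")
  }
  if (!is.finite(dispersion) || dispersion < 0) {
    abort_config("dispersion must be >= 0.")
  }
  if (length(species_pair) != 2 || anyDuplicated(species_pair)) {
    abort_config("species_pair must be two distinct labels.")
  }
  if ("species" %in% names(behaviors) &&
      !all(behaviors$species %in% species_pair)) {
    abort_config("behaviors$species must only use labels from species_pair.")
  }
  structure(list(populations = populations, behaviors = behaviors,
                 n_replicates = as.integer(n_replicates),
                 dispersion = dispersion, species_pair = species_pair,
                 seed = as.integer(seed)),
            class = "stream_sim_config")
}

rcount <- function(n, mu, dispersion) {
  if (dispersion > 0) rnbinom(n, size = 1 / dispersion, mu = mu)
  else rpois(n, mu)
}

#' Simulate stream-trial behavior counts
#'
#' Draws conspecific- and heterospecific-directed counts for every
#' replicate x species x behavior cell under [stream_sim_config()]'s count
#' model. Identical seeds give bit-identical output.
#'
#' @param config A `stream_sim_config`.
#' @return A tibble of counts in the [read_stream_counts()] layout.
#' @export
simulate_stream <- function(config) {
  if (!inherits(config, "stream_sim_config")) {
    abort_config("config must be created by stream_sim_config().")
  }
  rows <- lapply(seq_len(nrow(config$populations)), function(i) {
    p <- config$populations[i, ]
    sub <- derive_seed(config$seed, "stream", p$population, p$context)
    with_substream(sub, {
      grid <- tidyr::expand_grid(
        replicate = seq_len(config$n_replicates),
        species = config$species_pair,
        behavior = unique(config$behaviors$behavior))
      by <- if ("species" %in% names(config$behaviors))
        c("behavior", "species") else "behavior"
      grid <- dplyr::inner_join(grid, config$behaviors, by = by)
      mu_con <- grid$lambda * (1 + grid$iota) / 2
      mu_het <- grid$lambda * (1 - grid$iota) / 2
      n <- nrow(grid)
      tibble::tibble(
        replicate_id = rep(sprintf("%s_rep%d", p$population, grid$replicate), 2),
        population = p$population, context = p$context,
        species = rep(grid$species, 2),
        behavior = rep(grid$behavior, 2),
        target = rep(.targets, each = n),
        count = as.integer(c(rcount(n, mu_con, config$dispersion),
                             rcount(n, mu_het, config$dispersion))))
    })
  })
  counts <- dplyr::bind_rows(rows)
  validate_stream_counts(counts)
  counts
}

#' Build a study-scale synthetic dataset
#'
#' Generates a complete dataset with the group structure of a two-species
#' darter reinforcement study: four focal-species populations (two
#' sympatric with the congener, two allopatric), both sexes with 18
#' dichotomous trials per population x sex cell (one male cell with 16),
#' and three free-interaction stream replicates per population for both
#' species. Group preference biases are set near the strength-of-preference
#' means such a study reports (sympatric females strongest, allopatric
#' females weakest), and stream count rates are on the scale of hundreds
#' of chases/solicitations per replicate with rare spawning, conspecific
#' bias being weaker for allopatric male solicitation behaviors.
#'
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return A `reinfiso_dataset`.
#' @export
make_paper_like_dataset <- function(seed = 1L) {
  pops <- tibble::tibble(
    population = c("EF", "LC", "MF", "FC"),
    context = c("sympatric", "sympatric", "allopatric", "allopatric"))
  betas <- tibble::tibble(
    population = rep(pops$population, each = 2),
    context = rep(pops$context, each = 2),
    sex = rep(c("female", "male"), 4),
    n = c(18L, 16L, 18L, 18L, 18L, 18L, 18L, 18L),
    beta = c(0.73, 0.30, 0.31, 0.48, 0.27, 0.11, 0.02, 0.20))
  dcfg <- dichotomous_sim_config(groups = betas, kappa = 5,
                                 activity_mean = 0.75,
                                 activity_precision = 10,
                                 trial_duration = 900, seed = seed)
  trials <- simulate_dichotomous(dcfg)

  # The congener is resident at every trial site, so its conspecific bias
  # stays strong regardless of the focal population's context; only the
  # focal species' male solicitation bias drops in allopatry.
  behavior_rates <- function(context) {
    focal_solicit_iota <- if (context == "sympatric") 0.90 else 0.45
    dplyr::bind_rows(
      tibble::tibble(
        species = "E. zonale", behavior = STREAM_BEHAVIORS,
        lambda = c(3, 40, 150, 80, 90),
        iota = c(0.95, focal_solicit_iota, focal_solicit_iota, 0.90, 0.75)),
      tibble::tibble(
        species = "E. barrenense", behavior = STREAM_BEHAVIORS,
        lambda = c(3, 40, 150, 120, 100),
        iota = c(0.95, 0.90, 0.90, 0.90, 0.75)))
  }
  stream <- lapply(split(pops, pops$context), function(px) {
    cfg <- stream_sim_config(
      populations = px,
      behaviors = behavior_rates(px$context[1]),
      n_replicates = 3, dispersion = 0.3,
      species_pair = c("E. zonale", "E. barrenense"),
      seed = seed)
    simulate_stream(cfg)
  })
  counts <- dplyr::bind_rows(stream) |>
    dplyr::arrange(.data$population, .data$replicate_id, .data$species,
                   .data$behavior, .data$target)
  reinfiso_dataset(
    trials, counts,
    metadata = list(source = "simulated", generator = "make_paper_like_dataset",
                    seed = seed,
                    package_version = as.character(utils::packageVersion("reinfiso"))))
}
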