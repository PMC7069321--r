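#' Read dichotomous mate-choice trials from CSV
#'
#' Reads a table with one row per focal individual from a dichotomous
#' (two-stimulus) association-time trial. Required columns are `trial_id`,
#' `focal_id`, `population`, `context`, `sex`, `t_conspecific_s`,
#' `t_heterospecific_s`, and `trial_duration_s`; `conspecific_side`,
#' `stimulus_con_length_mm`, and `stimulus_het_length_mm` are optional and
#' may be absent entirely or blank per row (blank means missing, never
#' zero). Association times are seconds spent in the conspecific and
#' heterospecific association zones; the neutral-zone time is not stored
#' (it is `trial_duration - t_conspecific - t_heterospecific`).
#'
#' Every row is validated: times must be finite, non-negative, and sum to
#' at most the trial duration; `context` must be `"sympatric"` or
#' `"allopatric"`; `sex` must be `"female"` or `"male"`; and a population
#' may appear under only one context. Any violation raises a typed error
#' and nothing is returned.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header row,
#'   `"."` decimal).
#' @return A tibble of validated trials, one row per focal individual, in
#'   file order, with columns `trial_id`, `focal_id`, `population`,
#'   `context`, `sex`, `t_conspecific`, `t_heterospecific`,
#'   `trial_duration`, `conspecific_side`, `stimulus_con_length`,
#'   `stimulus_het_length`.
#' @seealso [read_stream_counts()], [write_dataset()], [compute_sop()]
#' @export
read_dichotomous <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("trial_id", "focal_id", "population", "context", "sex",
                "t_conspecific_s", "t_heterospecific_s", "trial_duration_s")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_schema(sprintf("Dichotomous trial file is missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  trials <- tibble::tibble(
    trial_id = raw$trial_id,
    focal_id = raw$focal_id,
    population = raw$population,
    context = raw$context,
    sex = raw$sex,
    t_conspecific = suppressWarnings(as.numeric(raw$t_conspecific_s)),
    t_heterospecific = suppressWarnings(as.numeric(raw$t_heterospecific_s)),
    trial_duration = suppressWarnings(as.numeric(raw$trial_duration_s)),
    conspecific_side = if ("conspecific_side" %in% names(raw)) raw$conspecific_side else NA_character_,
    stimulus_con_length = if ("stimulus_con_length_mm" %in% names(raw))
      suppressWarnings(as.numeric(raw$stimulus_con_length_mm)) else NA_real_,
    stimulus_het_length = if ("stimulus_het_length_mm" %in% names(raw))
      suppressWarnings(as.numeric(raw$stimulus_het_length_mm)) else NA_real_
  )
  validate_dichotomous(trials)
  trials
}

#' Validate a table of dichotomous trials
#'
#' Applies the invariants of the dichotomous-trial data model: finite
#' non-negative association times whose sum does not exceed the trial
#' duration, known context and sex tokens, valid optional side labels, and
#' a single-valued population-to-context mapping. Errors carry the class
#' `reinfiso_schema_error`, `reinfiso_validation_error`, or
#' `reinfiso_consistency_error` and cite the offending `trial_id`s.
#'
#' @param trials A tibble shaped like the output of [read_dichotomous()].
#' @return The input, invisibly, if valid.
#' @export
validate_dichotomous <- function(trials) {
  tid <- function(idx) paste(trials$trial_id[idx], collapse = ", ")
  bad_ctx <- which(!(trials$context %in% .contexts))
  if (length(bad_ctx) > 0) {
    abort_validation(sprintf(
      "Unknown context token for trial(s) %s; valid tokens: %s.",
      tid(bad_ctx), paste(.contexts, collapse = ", ")))
  }
  bad_sex <- which(!(trials$sex %in% .sexes))
  if (length(bad_sex) > 0) {
    abort_validation(sprintf(
      "Unknown sex token for trial(s) %s; valid tokens: %s.",
      tid(bad_sex), paste(.sexes, collapse = ", ")))
  }
  times_ok <- is.finite(trials$t_conspecific) & is.finite(trials$t_heterospecific) &
    is.finite(trials$trial_duration)
  if (any(!times_ok)) {
    abort_validation(sprintf("Non-numeric or non-finite time for trial(s) %s.",
                             tid(which(!times_ok))))
  }
  neg <- which(trials$t_conspecific < 0 | trials$t_heterospecific < 0 |
                 trials$trial_duration <= 0)
  if (length(neg) > 0) {
    abort_validation(sprintf(
      "Negative association time or non-positive duration for trial(s) %s.", tid(neg)))
  }
  over <- which(trials$t_conspecific + trials$t_heterospecific >
                  trials$trial_duration + 1e-9)
  if (length(over) > 0) {
    abort_validation(sprintf(
      "Association times exceed trial duration for trial(s) %s (t_conspecific + t_heterospecific must be <= trial_duration).",
      tid(over)))
  }
  bad_side <- which(!is.na(trials$conspecific_side) &
                      !(trials$conspecific_side %in% c("left", "right")))
  if (length(bad_side) > 0) {
    abort_validation(sprintf(
      "Unknown conspecific_side token for trial(s) %s; valid tokens: left, right.",
      tid(bad_side)))
  }
  bad_len <- which((!is.na(trials$stimulus_con_length) & trials$stimulus_con_length <= 0) |
                     (!is.na(trials$stimulus_het_length) & trials$stimulus_het_length <= 0))
  if (length(bad_len) > 0) {
    abort_validation(sprintf("Non-positive stimulus length for trial(s) %s.", tid(bad_len)))
  }
  check_population_context(trials$population, trials$context, "dichotomous trials")
  invisible(trials)
}

#' Read stream-trial behavior counts from CSV
#'
#' Reads a long-format table of behavior counts from free-interaction
#' artificial-stream trials: one row per replicate x species x behavior x
#' target, where `behavior` is one of the five classes in
#' [STREAM_BEHAVIORS] and `target` records whether the behavior was
#' directed at a conspecific or a heterospecific. Required columns:
#' `replicate_id`, `population`, `context`, `species`, `behavior`,
#' `target`, `count`. Species is a free-text label so the pipeline serves
#' species pairs beyond any one study system.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated counts in file order.
#' @seealso [read_dichotomous()], [behavior_isolation_table()]
#' @export
read_stream_counts <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("replicate_id", "population", "context", "species",
                "behavior", "target", "count")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_schema(sprintf("Stream count file is missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  counts <- tibble::tibble(
    replicate_id = raw$replicate_id,
    population = raw$population,
    context = raw$context,
    species = raw$species,
    behavior = raw$behavior,
    target = raw$target,
    count = suppressWarnings(as.numeric(raw$count))
  )
  validate_stream_counts(counts)
  counts$count <- as.integer(round(counts$count))
  counts
}

#' Validate a table of stream behavior counts
#'
#' Checks the stream-count invariants: counts are non-negative integers,
#' behavior tokens come from the five-class vocabulary, targets are
#' conspecific/heterospecific, the (replicate, species, behavior, target)
#' key is unique, and the population-to-context mapping is single-valued.
#'
#' @param counts A tibble shaped like the output of [read_stream_counts()].
#' @return The input, invisibly, if valid.
#' @export
validate_stream_counts <- function(counts) {
  bad_beh <- unique(counts$behavior[!(counts$behavior %in% STREAM_BEHAVIORS)])
  if (length(bad_beh) > 0) {
    abort_schema(sprintf(
      "Unknown behavior token(s) %s; the five valid tokens are: %s.",
      paste(bad_beh, collapse = ", "), paste(STREAM_BEHAVIORS, collapse = ", ")))
  }
  bad_tgt <- unique(counts$target[!(counts$target %in% .targets)])
  if (length(bad_tgt) > 0) {
    abort_schema(sprintf("Unknown target token(s) %s; valid tokens: %s.",
                         paste(bad_tgt, collapse = ", "),
                         paste(.targets, collapse = ", ")))
  }
  bad_ctx <- unique(counts$context[!(counts$context %in% .contexts)])
  if (length(bad_ctx) > 0) {
    abort_validation(sprintf("Unknown context token(s) %s; valid tokens: %s.",
                             paste(bad_ctx, collapse = ", "),
                             paste(.contexts, collapse = ", ")))
  }
  ok <- is.finite(counts$count) & counts$count >= 0 & is_whole(counts$count)
  if (any(!ok)) {
    bad <- which(!ok)
    abort_validation(sprintf(
      "Count must be a non-negative integer; offending row(s): %s.",
      paste(utils::head(bad, 10), collapse = ", ")))
  }
  key <- paste(counts$replicate_id, counts$species, counts$behavior,
               counts$target, sep = "\x1f")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    parts <- strsplit(dup, "\x1f", fixed = TRUE)[[1]]
    abort_consistency(sprintf(
      "Duplicate (replicate, species, behavior, target) key: (%s).",
      paste(parts, collapse = ", ")))
  }
  check_population_context(counts$population, counts$context, "stream counts")
  invisible(counts)
}

#' Bundle trials and stream counts into a dataset
#'
#' A `reinfiso_dataset` holds the two trial tables plus free-form
#' provenance metadata (source, seed, generator version). Construction
#' validates both tables and additionally checks that the
#' population-to-context mapping is single-valued *across* the two
#' collections.
#'
#' @param trials Tibble of dichotomous trials (see [read_dichotomous()]);
#'   may be empty.
#' @param stream_counts Tibble of stream behavior counts (see
#'   [read_stream_counts()]); may be empty.
#' @param metadata Named list of provenance fields.
#' @return An object of class `reinfiso_dataset`.
#' @export
reinfiso_dataset <- function(trials = empty_trials(),
                             stream_counts = empty_stream_counts(),
                             metadata = list()) {
  if (nrow(trials) > 0) validate_dichotomous(trials)
  if (nrow(stream_counts) > 0) validate_stream_counts(stream_counts)
  check_population_context(
    c(trials$population, stream_counts$population),
    c(trials$context, stream_counts$context),
    "the combined dataset")
  structure(list(trials = trials, stream_counts = stream_counts,
                 metadata = metadata),
            class = "reinfiso_dataset")
}

#' @export
print.reinfiso_dataset <- function(x, ...) {
  cat("<reinfiso_dataset>\n")
  cat(sprintf("  dichotomous trials: %d rows (%d populations)\n",
              nrow(x$trials), length(unique(x$trials$population))))
  cat(sprintf("  stream counts:      %d rows (%d replicates)\n",
              nrow(x$stream_counts), length(unique(x$stream_counts$replicate_id))))
  if (length(x$metadata) > 0) {
    cat(sprintf("  metadata: %s\n",
                paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

empty_trials <- function() {
  tibble::tibble(trial_id = character(), focal_id = character(),
                 population = character(), context = character(),
                 sex = character(), t_conspecific = numeric(),
                 t_heterospecific = numeric(), trial_duration = numeric(),
                 conspecific_side = character(),
                 stimulus_con_length = numeric(),
                 stimulus_het_length = numeric())
}

empty_stream_counts <- function() {
  tibble::tibble(replicate_id = character(), population = character(),
                 context = character(), species = character(),
                 behavior = character(), target = character(),
                 count = integer())
}

#' Write a dataset to a directory of CSV files
#'
#' Writes `dichotomous_trials.csv` and `stream_counts.csv` (external
#' column names, with explicit units in the headers) plus a
#' `provenance.json` sidecar holding the metadata. The representation
#' round-trips: [read_dataset()] on the output directory reproduces the
#' dataset field-for-field, including missing optional values.
#'
#' @param dataset A `reinfiso_dataset`.
#' @param path Directory to write into; created if absent.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "reinfiso_dataset"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort_io(sprintf("Cannot create output directory: %s", path))
  tr <- dataset$trials
  ext_trials <- tibble::tibble(
    trial_id = tr$trial_id, focal_id = tr$focal_id,
    population = tr$population, context = tr$context, sex = tr$sex,
    t_conspecific_s = tr$t_conspecific,
    t_heterospecific_s = tr$t_heterospecific,
    trial_duration_s = tr$trial_duration,
    conspecific_side = tr$conspecific_side,
    stimulus_con_length_mm = tr$stimulus_con_length,
    stimulus_het_length_mm = tr$stimulus_het_length)
  files <- c(
    trials = file.path(path, "dichotomous_trials.csv"),
    stream_counts = file.path(path, "stream_counts.csv"),
    provenance = file.path(path, "provenance.json"))
  readr::write_csv(ext_trials, files[["trials"]], na = "", progress = FALSE)
  readr::write_csv(dataset$stream_counts, files[["stream_counts"]], na = "",
                   progress = FALSE)
  jsonlite::write_json(dataset$metadata, files[["provenance"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path Directory containing `dichotomous_trials.csv`,
#'   `stream_counts.csv`, and optionally `provenance.json`.
#' @return A `reinfiso_dataset`.
#' @export
read_dataset <- function(path) {
  if (!dir.exists(path)) abort_io(sprintf("Directory not found: %s", path))
  trials <- read_dichotomous(file.path(path, "dichotomous_trials.csv"))
  counts <- read_stream_counts(file.path(path, "stream_counts.csv"))
  prov <- file.path(path, "provenance.json")
  metadata <- if (file.exists(prov)) {
    jsonlite::read_json(prov, simplifyVector = TRUE)
  } else list()
  reinfiso_dataset(trials, counts, metadata)
}
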