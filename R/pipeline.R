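#' Configuration for an end-to-end pipeline run
#'
#' Exactly one data source per trial kind: either a directory of CSVs
#' written by [write_dataset()] (`input_dir`) or simulation from
#' [make_paper_like_dataset()] (`simulate = TRUE`, in which case `seed` is
#' mandatory). Analysis switches cover the choices a study makes: which
#' test accompanies group SOP summaries, the full model for backward
#' selection, which behaviors to drop in the sensitivity analysis, the
#' GLS variance grouping, and the species treated as resident (always
#' sympatric) when coding context for the stream data.
#'
#' @param input_dir Directory with `dichotomous_trials.csv` and
#'   `stream_counts.csv`, or `NULL` when simulating.
#' @param simulate Generate the dataset with [make_paper_like_dataset()].
#' @param seed Integer seed (required when `simulate = TRUE`).
#' @param sop_test Test for group SOP summaries (`"t_one_sample"` or
#'   `"wilcoxon_signed_rank"`).
#' @param full_terms Starting terms for backward selection.
#' @param alpha Retention threshold for backward selection.
#' @param drop_behaviors Behaviors removed in the sensitivity refit
#'   (default: the two male solicitation classes).
#' @param variance_by GLS variance grouping column.
#' @param resident_species Species label coded as sympatric throughout
#'   the stream analysis, or `NULL` to use the recorded contexts.
#' @param digits Display rounding for the rendered report (computation is
#'   always full precision).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = is.null(input_dir),
                            seed = NULL,
                            sop_test = "t_one_sample",
                            full_terms = c("context", "sex", "population",
                                           "population:sex"),
                            alpha = 0.05,
                            drop_behaviors = c("solicit_success", "solicit_fail"),
                            variance_by = "context",
                            resident_species = "E. barrenense",
                            digits = 2) {
  if (simulate && !is.null(input_dir)) {
    abort_config("Provide either input_dir or simulate = TRUE, not both.")
  }
  if (!simulate && is.null(input_dir)) {
    abort_config("Provide input_dir or set simulate = TRUE.")
  }
  if (simulate && is.null(seed)) {
    abort_config("seed is mandatory when simulating.")
  }
  structure(list(input_dir = input_dir, simulate = simulate,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 sop_test = sop_test, full_terms = full_terms, alpha = alpha,
                 drop_behaviors = drop_behaviors, variance_by = variance_by,
                 resident_species = resident_species, digits = digits),
            class = "pipeline_config")
}

#' Run the full reinforcement analysis pipeline
#'
#' Sequences the whole analysis chain on one dataset: per-individual SOP
#' and group summaries (per population x sex, and pooled per context x
#' sex), backward-selected nested linear model with Type III tests,
#' Bonferroni LS-means contrasts (context, and population x sex cells),
#' per-sex Mann-Whitney sympatry-allopatry comparisons with Cohen's d,
#' the per-behavior isolation table, per-replicate and population total
#' isolation, the heteroskedastic GLS for total isolation, and the
#' behavior-exclusion sensitivity refit. Deterministic given the inputs
#' and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, machine-readable CSV/JSON
#'   tables and a markdown report are written (atomically: on any error no
#'   partial outputs remain).
#' @return A `reinforcement_report` object (list of result tables plus a
#'   provenance block).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- if (config$simulate) {
    make_paper_like_dataset(config$seed)
  } else {
    read_dataset(config$input_dir)
  }
  records <- sop_records(dataset$trials)
  sop_by_cell <- group_sop_summary(records, c("population", "context", "sex"),
                                   test = config$sop_test)
  sop_by_context_sex <- group_sop_summary(records, c("context", "sex"),
                                          test = config$sop_test)
  sel <- backward_select(records, config$full_terms, alpha = config$alpha)
  lsm_context <- lsmeans_contrasts(sel$final_fit, "context")
  lsm_cells <- lsmeans_contrasts(sel$final_fit, c("population", "sex"))

  sex_tests <- lapply(c("female", "male"), function(sx) {
    sub <- records[records$sex == sx & !is.na(records$sop), ]
    sym <- sub$sop[sub$context == "sympatric"]
    alo <- sub$sop[sub$context == "allopatric"]
    mw <- mann_whitney(sym, alo)
    d <- cohens_d(sym, alo)
    tibble::tibble(sex = sx, n_sympatric = length(sym),
                   n_allopatric = length(alo),
                   mean_sympatric = mean(sym), mean_allopatric = mean(alo),
                   U = mw$U, Z = mw$Z, p_value = mw$p_value,
                   cohens_d = d$d)
  }) |> dplyr::bind_rows()

  behavior_table <- behavior_isolation_table(dataset$stream_counts)
  replicate_totals <- total_isolation_per_replicate(dataset$stream_counts)
  population_totals <- population_total_isolation(dataset$stream_counts)
  gls_full <- fit_total_isolation_gls(
    replicate_totals, fixed = "context", variance_by = config$variance_by,
    resident_species = config$resident_species)
  sensitivity <- exclude_behaviors_sensitivity(dataset$stream_counts,
                                               config$drop_behaviors)
  gls_reduced <- fit_total_isolation_gls(
    sensitivity[sensitivity$analysis == "reduced", ],
    fixed = "context", variance_by = config$variance_by,
    resident_species = config$resident_species)

  report <- structure(list(
    sop_by_cell = sop_by_cell,
    sop_by_context_sex = sop_by_context_sex,
    anova_table = sel$final_fit$table,
    anova_residual_df = sel$final_fit$residual_df,
    selection_trace = sel$trace,
    lsmeans_context = lsm_context,
    lsmeans_cells = lsm_cells,
    sex_context_tests = sex_tests,
    behavior_isolation = behavior_table,
    replicate_totals = replicate_totals,
    population_totals = population_totals,
    gls_full = gls_full,
    gls_reduced = gls_reduced,
    sensitivity = sensitivity,
    provenance = list(
      source = if (config$simulate) "simulated" else config$input_dir,
      seed = config$seed,
      metadata = dataset$metadata,
      sop_test = config$sop_test,
      full_terms = config$full_terms,
      alpha = config$alpha,
      drop_behaviors = config$drop_behaviors,
      variance_by = config$variance_by,
      resident_species = config$resident_species,
      n_trials = nrow(dataset$trials),
      n_stream_rows = nrow(dataset$stream_counts),
      package_version = as.character(utils::packageVersion("reinfiso")))),
    class = "reinforcement_report")
  if (!is.null(out_dir)) write_report(report, out_dir, digits = config$digits)
  report
}

#' @export
print.reinforcement_report <- function(x, ...) {
  cat("<reinforcement_report>\n\n")
  cat("SOP by context and sex:\n")
  print(as.data.frame(x$sop_by_context_sex), row.names = FALSE, digits = 3)
  cat("\nFinal SOP model:\n")
  tab <- x$anova_table
  tab$f_value <- round(tab$f_value, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(as.data.frame(tab), row.names = FALSE)
  cat(sprintf("Residual df: %d\n", x$anova_residual_df))
  cat("\nPer-sex sympatry-allopatry comparison (Mann-Whitney, Cohen's d):\n")
  print(as.data.frame(x$sex_context_tests), row.names = FALSE, digits = 3)
  cat("\nTotal-isolation GLS (context effect):\n")
  print(x$gls_full)
  invisible(x)
}

#' Render the per-behavior isolation table in the classic layout
#'
#' Formats behavior-scope isolation estimates as the familiar wide table:
#' one row per population x species, and for each behavior a
#' `mean +/- SD` pair of conspecific and heterospecific counts with the
#' isolation index. Undefined indices (behavior never observed) render as
#' an en dash.
#'
#' @param estimates Behavior-scope tibble from
#'   [behavior_isolation_table()].
#' @param behaviors Behaviors (columns) to include, in display order.
#' @param digits Decimal places for the index (means and SDs print one
#'   decimal).
#' @return A tibble of formatted character columns.
#' @export
render_table3_style <- function(estimates,
                                behaviors = c("chase_mf", "chase_mm",
                                              "solicit_fail"),
                                digits = 2) {
  est <- estimates[estimates$behavior %in% behaviors, ]
  fmt_pair <- function(m, s) {
    ifelse(is.na(s), fmt2(m, 1), paste0(fmt2(m, 1), " ± ", fmt2(s, 1)))
  }
  est |>
    dplyr::mutate(
      behavior = factor(.data$behavior, levels = behaviors),
      conspecific = fmt_pair(.data$conspecific_mean, .data$conspecific_sd),
      heterospecific = fmt_pair(.data$heterospecific_mean,
                                .data$heterospecific_sd),
      I = ifelse(is.na(.data$i_index), "–", fmt2(.data$i_index, digits))) |>
    dplyr::arrange(.data$behavior) |>
    dplyr::select("context", "population", "species", "behavior",
                  "conspecific", "heterospecific", "I") |>
    tidyr::pivot_wider(names_from = "behavior",
                       values_from = c("conspecific", "heterospecific", "I"),
                       names_vary = "slowest") |>
    dplyr::arrange(dplyr::desc(.data$context), .data$population, .data$species)
}

write_report <- function(report, out_dir, digits = 2) {
  staging <- tempfile("reinfiso_report_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  wcsv <- function(x, name) {
    readr::write_csv(x, file.path(staging, name), na = "", progress = FALSE)
  }
  wcsv(report$sop_by_cell, "sop_by_population_sex.csv")
  wcsv(report$sop_by_context_sex, "sop_by_context_sex.csv")
  wcsv(report$anova_table, "sop_anova.csv")
  wcsv(report$selection_trace, "sop_model_selection_trace.csv")
  wcsv(report$lsmeans_context$contrasts, "lsmeans_context_contrasts.csv")
  wcsv(report$lsmeans_cells$contrasts, "lsmeans_cell_contrasts.csv")
  wcsv(report$sex_context_tests, "sex_context_tests.csv")
  wcsv(report$behavior_isolation, "behavior_isolation.csv")
  wcsv(report$replicate_totals, "replicate_total_isolation.csv")
  wcsv(report$population_totals, "population_total_isolation.csv")
  wcsv(report$gls_full$coefficients, "gls_full_coefficients.csv")
  wcsv(report$gls_reduced$coefficients, "gls_reduced_coefficients.csv")
  jsonlite::write_json(report$provenance,
                       file.path(staging, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  md <- c(
    "# Reinforcement analysis report", "",
    sprintf("Source: %s; seed: %s", report$provenance$source,
            report$provenance$seed %||% "none"), "",
    "## SOP by context and sex", "",
    md_table(dplyr::mutate(report$sop_by_context_sex,
                           dplyr::across(dplyr::where(is.numeric),
                                         ~ round(.x, digits)))), "",
    "## Final linear model for SOP", "",
    md_table(dplyr::mutate(report$anova_table,
                           sum_sq = round(.data$sum_sq, 4),
                           f_value = round(.data$f_value, 3),
                           p_value = signif(.data$p_value, 3))), "",
    sprintf("Residual df: %d", report$anova_residual_df), "",
    "## Per-behavior isolation", "",
    md_table(render_table3_style(report$behavior_isolation, digits = digits)), "",
    "## Total isolation (population level)", "",
    md_table(dplyr::mutate(report$population_totals,
                           dplyr::across(dplyr::where(is.numeric),
                                         ~ round(.x, digits)))), "",
    "## Total-isolation GLS", "",
    "Full behavior set:", "",
    md_table(dplyr::mutate(report$gls_full$coefficients,
                           dplyr::across(dplyr::where(is.numeric),
                                         ~ signif(.x, 4)))), "",
    sprintf("Reduced set (dropping %s):",
            paste(report$provenance$drop_behaviors, collapse = ", ")), "",
    md_table(dplyr::mutate(report$gls_reduced$coefficients,
                           dplyr::across(dplyr::where(is.numeric),
                                         ~ signif(.x, 4)))), "")
  writeLines(md, file.path(staging, "report.md"))

  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok) abort_io(sprintf("Cannot create output directory: %s", out_dir))
  for (f in list.files(staging, full.names = TRUE)) {
    file.copy(f, file.path(out_dir, basename(f)), overwrite = TRUE)
  }
  invisible(out_dir)
}

md_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) as.character(col), character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  cells[is.na(cells)] <- ""
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
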