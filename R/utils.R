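# Typed condition helpers. Every malformed input surfaces as one of these;
# nothing downstream ever sees a partially validated table.

abort_schema <- function(msg) abort(msg, class = "reinfiso_schema_error")
abort_validation <- function(msg) abort(msg, class = "reinfiso_validation_error")
abort_consistency <- function(msg) abort(msg, class = "reinfiso_consistency_error")
abort_domain <- function(msg) abort(msg, class = "reinfiso_domain_error")
abort_config <- function(msg) abort(msg, class = "reinfiso_config_error")
abort_io <- function(msg) abort(msg, class = "reinfiso_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed from a global seed plus labels, so adding a
# simulated group never perturbs the draws of existing groups. Plain Horner
# hash over the decimal seed and the labels, kept below 2^31 - 1 (all
# intermediates are exact in double precision).
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "\x1f")
  h <- 0
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h + 1L)
}

# Run `code` under a local RNG substream, restoring the caller's RNG state.
with_substream <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Check that the population -> context map is single-valued.
check_population_context <- function(population, context, what = "dataset") {
  map <- unique(data.frame(population = as.character(population),
                           context = as.character(context)))
  dup <- unique(map$population[duplicated(map$population)])
  if (length(dup) > 0) {
    abort_consistency(sprintf(
      "In %s, population(s) %s appear under more than one context; the population-to-context mapping must be single-valued.",
      what, paste(dup, collapse = ", ")))
  }
  invisible(TRUE)
}

is_whole <- function(x) {
  is.finite(x) & abs(x - round(x)) < sqrt(.Machine$double.eps)
}

fmt2 <- function(x, digits = 2) {
  # round() is round-half-even, which is what the report layer wants
  formatC(round(x, digits), format = "f", digits = digits)
}
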