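# Design machinery for the strength-of-preference linear model.
#
# The design has three crossed/nested factors: geographic context
# (sympatric/allopatric), sex, and population, with population nested
# within context (a population exists in exactly one context, so there is
# no population main effect across contexts). All encodings use
# sum-to-zero contrasts so that Type III (marginal) sums of squares test
# the conventional hypotheses in unbalanced designs.
#
# Term vocabulary:
#   "context"        1 df (for two contexts)
#   "sex"            1 df
#   "population"     population-within-context contrasts (sum over
#                    contexts of (k_c - 1) df)
#   "context:sex"    product of the context and sex contrasts
#   "population:sex" the full population-by-sex interaction given the
#                    nesting: sex crossed with (context + population
#                    within context); 3 df for 4 populations in 2
#                    contexts. Contains context:sex, so the two terms are
#                    mutually exclusive in one model.

.sop_terms <- c("context", "sex", "population", "context:sex", "population:sex")

normalize_term <- function(term) {
  parts <- sort(strsplit(term, ":", fixed = TRUE)[[1]])
  if (identical(parts, c("context"))) return("context")
  if (identical(parts, c("sex"))) return("sex")
  if (identical(parts, c("population"))) return("population")
  if (identical(parts, c("context", "sex"))) return("context:sex")
  if (identical(parts, c("population", "sex"))) return("population:sex")
  abort_schema(sprintf(
    "Unknown model term '%s'; supported terms: %s.", term,
    paste(.sop_terms, collapse = ", ")))
}

# Factor closure used for marginality: population implies context because
# of the nesting.
term_factors <- function(term) {
  switch(term,
         "context" = "context",
         "sex" = "sex",
         "population" = c("context", "population"),
         "context:sex" = c("context", "sex"),
         "population:sex" = c("context", "population", "sex"))
}

term_contains <- function(outer, inner) {
  fo <- term_factors(outer)
  fi <- term_factors(inner)
  all(fi %in% fo) && length(fo) > length(fi)
}

design_schema <- function(records) {
  contexts <- sort(unique(records$context))
  sexes <- sort(unique(records$sex))
  pops_by_context <- lapply(stats::setNames(contexts, contexts), function(cx) {
    sort(unique(records$population[records$context == cx]))
  })
  list(contexts = contexts, sexes = sexes, pops_by_context = pops_by_context)
}

contrast_rows <- function(levels_vec, values) {
  k <- length(levels_vec)
  out <- matrix(0, length(values), max(k - 1, 0))
  if (k > 1) {
    cm <- stats::contr.sum(k)
    out[] <- cm[match(values, levels_vec), , drop = FALSE]
  }
  out
}

base_blocks <- function(schema, context, sex, population) {
  C <- contrast_rows(schema$contexts, context)
  if (ncol(C) > 0) colnames(C) <- paste0("context", seq_len(ncol(C)))
  S <- contrast_rows(schema$sexes, sex)
  if (ncol(S) > 0) colnames(S) <- paste0("sex", seq_len(ncol(S)))
  pcols <- list()
  for (cx in schema$contexts) {
    pops <- schema$pops_by_context[[cx]]
    if (length(pops) < 2) next
    block <- contrast_rows(pops, population)
    block[context != cx, ] <- 0
    colnames(block) <- paste0("pop(", cx, ")", seq_len(ncol(block)))
    pcols[[cx]] <- block
  }
  P <- if (length(pcols) > 0) do.call(cbind, pcols) else
    matrix(0, length(context), 0)
  list(C = C, S = S, P = P)
}

col_products <- function(A, B) {
  if (ncol(A) == 0 || ncol(B) == 0) return(matrix(0, nrow(A), 0))
  out <- do.call(cbind, lapply(seq_len(ncol(B)), function(j) A * B[, j]))
  colnames(out) <- as.vector(outer(colnames(A), colnames(B), paste, sep = ":"))
  out
}

term_matrix <- function(term, blocks) {
  switch(term,
         "context" = blocks$C,
         "sex" = blocks$S,
         "population" = blocks$P,
         "context:sex" = col_products(blocks$C, blocks$S),
         "population:sex" = col_products(cbind(blocks$C, blocks$P), blocks$S))
}

build_design <- function(schema, context, sex, population, terms) {
  blocks <- base_blocks(schema, context, sex, population)
  n <- length(context)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  assign <- rep("(Intercept)", 1)
  for (tm in terms) {
    M <- term_matrix(tm, blocks)
    if (ncol(M) == 0) {
      abort_schema(sprintf(
        "Term '%s' has no estimable contrasts (a referenced factor has fewer than 2 levels).",
        tm))
    }
    X <- cbind(X, M)
    assign <- c(assign, rep(tm, ncol(M)))
  }
  list(X = X, assign = assign)
}

rss_of <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit the strength-of-preference linear model
#'
#' Least-squares fit of per-individual SOP on geographic context, sex, and
#' population (nested within context), with term-wise F tests. Population
#' enters only through context-specific contrasts, matching the
#' hierarchical structure in which context is the larger spatial scale.
#' The default sum-of-squares type is III (marginal, with sum-to-zero
#' contrasts), appropriate for unbalanced cell counts; sequential Type I
#' is available.
#'
#' @param records Tibble with columns `sop`, `population`, `context`,
#'   `sex` (rows with missing SOP are dropped).
#' @param terms Character vector of model terms from the vocabulary
#'   `context`, `sex`, `population`, `context:sex`, `population:sex`
#'   (factor order within a term does not matter). `population:sex` is the
#'   full population-by-sex interaction given the nesting and contains
#'   `context:sex`; the two cannot appear together.
#' @param ss_type `"III"` (default) or `"I"`.
#' @return An object of class `sop_model` with an ANOVA `table` (term,
#'   df, sum_sq, f_value, p_value), `residual_df`, `residual_ss`,
#'   coefficient vector, and the design objects needed by
#'   [lsmeans_contrasts()].
#' @export
fit_sop_model <- function(records,
                          terms = c("context", "sex", "population",
                                    "population:sex"),
                          ss_type = c("III", "I")) {
  ss_type <- match.arg(ss_type)
  terms <- vapply(terms, normalize_term, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(terms)) abort_schema("Duplicate model terms.")
  if (all(c("context:sex", "population:sex") %in% terms)) {
    abort_schema(
      "Terms context:sex and population:sex are aliased (population:sex contains the context-by-sex contrasts); include only one.")
  }
  records <- records[!is.na(records$sop), , drop = FALSE]
  n <- nrow(records)
  if (n < 3) abort_domain("Too few non-missing SOP records to fit a model.")
  schema <- design_schema(records)
  for (tm in terms) {
    for (f in setdiff(term_factors(tm), "population")) {
      k <- length(if (f == "context") schema$contexts else schema$sexes)
      if (k < 2) {
        abort_schema(sprintf(
          "Term '%s' references factor '%s' with fewer than 2 levels.", tm, f))
      }
    }
  }
  d <- build_design(schema, records$context, records$sex,
                    records$population, terms)
  X <- d$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    aliased <- unique(d$assign[match(dropped, colnames(X))])
    abort_schema(sprintf("Design is rank-deficient; aliased term(s): %s.",
                         paste(aliased, collapse = ", ")))
  }
  y <- records$sop
  fit <- stats::lm.fit(X, y)
  rss_full <- sum(fit$residuals^2)
  df_res <- n - ncol(X)
  if (df_res < 1) abort_domain("No residual degrees of freedom.")
  sigma2 <- rss_full / df_res
  tss <- sum((y - mean(y))^2)
  degenerate <- tss < 1e-12
  rows <- lapply(seq_along(terms), function(i) {
    tm <- terms[i]
    df_t <- sum(d$assign == tm)
    if (ss_type == "III") {
      Xm <- X[, d$assign != tm, drop = FALSE]
      ss <- rss_of(Xm, y) - rss_full
    } else {
      prev <- c("(Intercept)", terms[seq_len(i - 1)])
      Xprev <- X[, d$assign %in% prev, drop = FALSE]
      Xwith <- X[, d$assign %in% c(prev, tm), drop = FALSE]
      ss <- rss_of(Xprev, y) - rss_of(Xwith, y)
    }
    ss <- max(ss, 0)
    if (degenerate) {
      f_val <- 0
      p <- 1
    } else {
      f_val <- (ss / df_t) / sigma2
      p <- pf(f_val, df_t, df_res, lower.tail = FALSE)
    }
    tibble::tibble(term = tm, df = df_t, sum_sq = ss, f_value = f_val,
                   p_value = p)
  })
  XtX_inv <- chol2inv(qr.R(qrX)[seq_len(qrX$rank), seq_len(qrX$rank)])
  # undo the QR pivot so XtX_inv rows/cols follow the column order of X
  piv <- qrX$pivot
  XtX_inv <- XtX_inv[order(piv), order(piv), drop = FALSE]
  structure(list(
    table = dplyr::bind_rows(rows),
    residual_df = df_res,
    residual_ss = rss_full,
    sigma2 = sigma2,
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    XtX_inv = XtX_inv,
    schema = schema,
    terms = terms,
    assign = d$assign,
    ss_type = ss_type,
    degenerate = degenerate,
    data = records), class = "sop_model")
}

#' @export
print.sop_model <- function(x, ...) {
  cat(sprintf("Linear model for SOP (Type %s tests), n = %d\n",
              x$ss_type, nrow(x$data)))
  tab <- x$table
  tab$f_value <- round(tab$f_value, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(as.data.frame(tab), row.names = FALSE)
  cat(sprintf("Residual df: %d\n", x$residual_df))
  invisible(x)
}

#' Backward term selection honoring marginality
#'
#' Starting from a full model, repeatedly refits and removes the single
#' eligible term with the largest p value above `alpha`, until every
#' remaining term is either significant or protected. A term is eligible
#' for removal only if no retained interaction contains it (for the
#' nested design, `population:sex` contains `population`, `sex`,
#' `context`, and `context:sex`; `population` contains `context`).
#'
#' @inheritParams fit_sop_model
#' @param full_terms Terms of the starting model.
#' @param alpha Retention threshold (default 0.05).
#' @return List with `final_terms`, `final_fit` (a `sop_model`), and
#'   `trace`, a tibble with one row per fitted model recording the term
#'   dropped at that step (`NA` for the final model) and its p value.
#' @export
backward_select <- function(records,
                            full_terms = c("context", "sex", "population",
                                           "population:sex"),
                            alpha = 0.05, ss_type = "III") {
  terms <- vapply(full_terms, normalize_term, character(1), USE.NAMES = FALSE)
  steps <- list()
  repeat {
    fit <- fit_sop_model(records, terms, ss_type = ss_type)
    eligible <- terms[vapply(terms, function(tm) {
      !any(vapply(setdiff(terms, tm), term_contains, logical(1), inner = tm))
    }, logical(1))]
    tab <- fit$table[fit$table$term %in% eligible, ]
    tab <- tab[tab$p_value > alpha, ]
    if (nrow(tab) == 0 || length(terms) == 1) {
      steps[[length(steps) + 1]] <- list(fit = fit, dropped = NA_character_,
                                         p_dropped = NA_real_)
      break
    }
    worst <- tab$term[which.max(tab$p_value)]
    steps[[length(steps) + 1]] <- list(fit = fit, dropped = worst,
                                       p_dropped = max(tab$p_value))
    terms <- setdiff(terms, worst)
  }
  trace <- tibble::tibble(
    step = seq_along(steps),
    n_terms = vapply(steps, function(s) length(s$fit$terms), integer(1)),
    dropped = vapply(steps, function(s) s$dropped, character(1)),
    p_dropped = vapply(steps, function(s) s$p_dropped, numeric(1)))
  list(final_terms = terms, final_fit = steps[[length(steps)]]$fit,
       trace = trace, fits = lapply(steps, function(s) s$fit))
}

# Design rows for every population x sex cell of the schema (context is
# implied by the population).
cell_grid <- function(fit) {
  schema <- fit$schema
  pops <- unlist(schema$pops_by_context, use.names = FALSE)
  ctxs <- rep(names(schema$pops_by_context),
              vapply(schema$pops_by_context, length, integer(1)))
  grid <- tidyr::expand_grid(
    cell = seq_along(pops) ,
    sex = schema$sexes)
  grid$population <- pops[grid$cell]
  grid$context <- ctxs[grid$cell]
  grid$cell <- NULL
  d <- build_design(schema, grid$context, grid$sex, grid$population, fit$terms)
  grid$row <- seq_len(nrow(grid))
  list(grid = grid, X = d$X)
}

#' Least-squares means and Bonferroni-adjusted pairwise contrasts
#'
#' Model-based (least-squares) means for the levels of a factor or factor
#' combination, computed by averaging the fitted cell means over the
#' levels of the other design factors with equal weights, together with
#' all pairwise contrasts within the requested grouping. Contrast t
#' statistics use the model residual degrees of freedom; p values are
#' Bonferroni-adjusted over the family of contrasts emitted by the call.
#'
#' For the nested design, a `context` LS-mean averages over the
#' population x sex cells belonging to that context, and a `population`
#' LS-mean averages over sex with context fixed at the population's own
#' context.
#'
#' @param fit A `sop_model` from [fit_sop_model()].
#' @param factors Character vector naming the grouping, a subset of
#'   `population`, `context`, `sex` (e.g. `c("population", "sex")` for
#'   cell-level comparisons).
#' @param adjust Multiplicity adjustment; only `"bonferroni"` (default)
#'   and `"none"`.
#' @return List with `lsmeans` (one row per group: labels, `lsmean`,
#'   `se`) and `contrasts` (one row per pair: `contrast`, `estimate`,
#'   `se`, `t_statistic`, `df`, `p_raw`, `p_adjusted`, `estimable`).
#' @export
lsmeans_contrasts <- function(fit, factors = "context",
                              adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit, "sop_model"))
  ok <- c("population", "context", "sex")
  if (!all(factors %in% ok)) {
    abort_schema(sprintf("factors must be a subset of: %s.",
                         paste(ok, collapse = ", ")))
  }
  cg <- cell_grid(fit)
  grid <- cg$grid
  # observed cell sizes, to flag groups built on empty cells
  obs <- dplyr::count(fit$data, .data$population, .data$sex)
  grid <- dplyr::left_join(grid, obs, by = c("population", "sex"))
  grid$n[is.na(grid$n)] <- 0L
  groups <- grid |>
    dplyr::distinct(dplyr::across(dplyr::all_of(factors))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(factors)))
  L <- matrix(0, nrow(groups), ncol(cg$X))
  estimable <- logical(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(grid))
    for (f in factors) sel <- sel & grid[[f]] == groups[[f]][i]
    L[i, ] <- colMeans(cg$X[sel, , drop = FALSE])
    estimable[i] <- all(grid$n[sel] > 0)
  }
  beta <- fit$coefficients
  lsm <- as.vector(L %*% beta)
  lsm_se <- sqrt(fit$sigma2 * rowSums((L %*% fit$XtX_inv) * L))
  label <- apply(groups, 1, paste, collapse = " ")
  lsmeans <- dplyr::bind_cols(
    groups, tibble::tibble(lsmean = lsm, se = lsm_se, estimable = estimable))
  pairs <- combn(nrow(groups), 2)
  m <- ncol(pairs)
  contrasts <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    est_ok <- estimable[i1] && estimable[i2]
    Ld <- L[i1, ] - L[i2, ]
    est <- sum(Ld * beta)
    se <- sqrt(fit$sigma2 * sum((Ld %*% fit$XtX_inv) * Ld))
    tstat <- est / se
    p <- 2 * pt(-abs(tstat), fit$residual_df)
    tibble::tibble(
      contrast = paste(label[i1], "-", label[i2]),
      estimate = if (est_ok) est else NA_real_,
      se = if (est_ok) se else NA_real_,
      t_statistic = if (est_ok) tstat else NA_real_,
      df = fit$residual_df,
      p_raw = if (est_ok) p else NA_real_,
      estimable = est_ok)
  }) |> dplyr::bind_rows()
  fam <- if (adjust == "bonferroni") sum(contrasts$estimable) else 1
  contrasts$p_adjusted <- pmin(1, contrasts$p_raw * fam)
  list(lsmeans = lsmeans, contrasts = contrasts, family_size = fam,
       adjust = adjust)
}
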