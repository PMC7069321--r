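# Shared fixture builders and independent oracles.

# Brute-force Type III sums of squares via explicit projection matrices
# (P = X (X'X)^-1 X'), independent of the package's lm.fit/RSS route.
proj_rss <- function(X, y) {
  P <- X %*% solve(crossprod(X)) %*% t(X)
  sum((y - P %*% y)^2)
}

oracle_anova <- function(records, terms, ss_type = "III") {
  schema <- reinfiso:::design_schema(records)
  d <- reinfiso:::build_design(schema, records$context, records$sex,
                               records$population, terms)
  y <- records$sop
  X <- d$X
  rss_full <- proj_rss(X, y)
  df_res <- nrow(X) - ncol(X)
  sigma2 <- rss_full / df_res
  rows <- lapply(seq_along(terms), function(i) {
    tm <- terms[i]
    if (ss_type == "III") {
      ss <- proj_rss(X[, d$assign != tm, drop = FALSE], y) - rss_full
    } else {
      prev <- c("(Intercept)", terms[seq_len(i - 1)])
      ss <- proj_rss(X[, d$assign %in% prev, drop = FALSE], y) -
        proj_rss(X[, d$assign %in% c(prev, tm), drop = FALSE], y)
    }
    df_t <- sum(d$assign == tm)
    data.frame(term = tm, df = df_t, sum_sq = ss,
               f_value = (ss / df_t) / sigma2)
  })
  list(table = do.call(rbind, rows), residual_df = df_res)
}

# Random small SOP fixture over the 4-population / 2-context / 2-sex design.
random_sop_fixture <- function(seed, n_per_cell = 2:3) {
  set.seed(seed)
  pops <- data.frame(population = c("P1", "P2", "P3", "P4"),
                     context = rep(c("sympatric", "allopatric"), each = 2))
  cells <- merge(pops, data.frame(sex = c("female", "male")))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    n <- sample(n_per_cell, 1)
    data.frame(population = cells$population[i], context = cells$context[i],
               sex = cells$sex[i], sop = rnorm(n))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# SOP records with prescribed cell means, for constructed-effect fixtures.
sop_fixture_with_means <- function(cell_means, n_per_cell, sd, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(cell_means)), function(i) {
    data.frame(population = cell_means$population[i],
               context = cell_means$context[i],
               sex = cell_means$sex[i],
               sop = rnorm(n_per_cell, cell_means$mu[i], sd))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# A tiny valid dataset exercising every column, including missing optionals.
tiny_dataset <- function() {
  trials <- tibble::tibble(
    trial_id = c("t1", "t2", "t3"),
    focal_id = c("f1", "f2", "f3"),
    population = c("A", "A", "B"),
    context = c("sympatric", "sympatric", "allopatric"),
    sex = c("female", "male", "female"),
    t_conspecific = c(600, 0, 450.5),
    t_heterospecific = c(200, 0, 449.5),
    trial_duration = c(900, 900, 900),
    conspecific_side = c("left", NA, "right"),
    stimulus_con_length = c(45.2, NA, 51),
    stimulus_het_length = c(44.0, NA, NA))
  counts <- tibble::tibble(
    replicate_id = rep("A_rep1", 4),
    population = "A", context = "sympatric",
    species = rep(c("sp1", "sp2"), each = 2),
    behavior = "chase_mf",
    target = rep(c("conspecific", "heterospecific"), 2),
    count = c(44L, 6L, 10L, 0L))
  reinfiso_dataset(trials, counts, metadata = list(source = "unit-test",
                                                   seed = 42))
}

# Long-format stream counts from a per-replicate (conspecific,
# heterospecific) count matrix for one population/species.
stream_counts_from_matrix <- function(con, het, behavior = "chase_mm",
                                      population = "A",
                                      context = "sympatric",
                                      species = "sp1") {
  n <- length(con)
  tibble::tibble(
    replicate_id = rep(sprintf("%s_rep%d", population, seq_len(n)), 2),
    population = population, context = context, species = species,
    behavior = behavior,
    target = rep(c("conspecific", "heterospecific"), each = n),
    count = as.integer(c(con, het)))
}
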