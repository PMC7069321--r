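test_that("a single two-level factor reproduces the classical F = t^2 identity", {
  set.seed(51)
  rec <- tibble::tibble(
    population = rep(c("A", "B"), each = 10),
    context = rep(c("sympatric", "allopatric"), each = 10),
    sex = "female",
    sop = rnorm(20, rep(c(0.5, 0.1), each = 10), 0.3))
  fit <- fit_sop_model(rec, terms = "context")
  tt <- t.test(sop ~ context, data = rec, var.equal = TRUE)
  expect_equal(fit$table$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$residual_df, 18)
})

test_that("Type III and Type I F tests match the projection-matrix oracle", {
  terms <- c("context", "sex", "population", "population:sex")
  for (seed in c(101, 102, 103, 104, 105)) {
    rec <- random_sop_fixture(seed)
    expect_lte(nrow(rec), 30)
    for (type in c("III", "I")) {
      fit <- fit_sop_model(rec, terms, ss_type = type)
      orc <- oracle_anova(rec, terms, ss_type = type)
      expect_equal(fit$table$df, orc$table$df)
      expect_equal(fit$table$sum_sq, orc$table$sum_sq, tolerance = 1e-8)
      expect_equal(fit$table$f_value, orc$table$f_value, tolerance = 1e-8)
      expect_equal(fit$residual_df, orc$residual_df)
    }
  }
})

test_that("Type III tests agree with car::Anova on a crossed design", {
  skip_if_not_installed("car")
  set.seed(52)
  rec <- random_sop_fixture(61, n_per_cell = 3:5)
  fit <- fit_sop_model(rec, terms = c("context", "sex", "context:sex"))
  lm_fit <- lm(sop ~ context * sex, data = rec,
               contrasts = list(context = "contr.sum", sex = "contr.sum"))
  ca <- car::Anova(lm_fit, type = 3)
  expect_equal(fit$table$f_value,
               ca[c("context", "sex", "context:sex"), "F value"],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("degenerate and misspecified designs are reported, not mangled", {
  rec <- random_sop_fixture(71)
  const <- rec
  const$sop <- 0.4
  fit <- fit_sop_model(const, c("context", "sex"))
  expect_true(all(fit$table$f_value == 0))
  expect_true(all(fit$table$p_value == 1))

  expect_error(fit_sop_model(rec, c("context", "context:sex", "population:sex")),
               "aliased", class = "reinfiso_schema_error")
  expect_error(fit_sop_model(rec, "altitude"), class = "reinfiso_schema_error")

  one_sex <- rec[rec$sex == "female", ]
  expect_error(fit_sop_model(one_sex, c("context", "sex")),
               class = "reinfiso_schema_error")
})

test_that("backward selection drops noise interactions before real main effects", {
  # strong context effect, no sex or interaction structure
  cells <- tidyr::expand_grid(population = c("P1", "P2", "P3", "P4"),
                              sex = c("female", "male"))
  cells$context <- rep(c("sympatric", "sympatric", "allopatric", "allopatric"),
                       each = 2)
  cells$mu <- ifelse(cells$context == "sympatric", 0.6, 0.1)
  rec <- sop_fixture_with_means(cells, n_per_cell = 18, sd = 0.25, seed = 53)
  sel <- backward_select(rec, c("context", "sex", "population",
                                "population:sex"))
  expect_true("context" %in% sel$final_terms)
  dropped <- sel$trace$dropped[!is.na(sel$trace$dropped)]
  expect_true("population:sex" %in% dropped)
  # the interaction leaves before any main effect it contains
  expect_lt(match("population:sex", dropped),
            min(c(match(c("sex", "population"), dropped), Inf), na.rm = TRUE))

  # all-significant full model: nothing is removed, trace has one step
  cells$mu <- c(0.9, 0.1, 0.5, 0.42, 0.1, 0.6, -0.3, 0.25)
  rec2 <- sop_fixture_with_means(cells, n_per_cell = 30, sd = 0.15, seed = 54)
  sel2 <- backward_select(rec2, c("context", "sex", "population",
                                  "population:sex"))
  expect_equal(nrow(sel2$trace), 1L)
  expect_setequal(sel2$final_terms,
                  c("context", "sex", "population", "population:sex"))

  # marginality: a significant interaction protects its weak main effects
  fit2 <- sel2$fits[[1]]
  expect_lt(fit2$table$p_value[fit2$table$term == "population:sex"], 0.05)
})

test_that("LS-means equal raw means when the design is balanced", {
  set.seed(55)
  rec <- tibble::tibble(
    population = rep(c("A", "B"), each = 12),
    context = rep(c("sympatric", "allopatric"), each = 12),
    sex = rep(c("female", "male"), 12),
    sop = rnorm(24, 0.3, 0.2))
  fit <- fit_sop_model(rec, "context")
  lc <- lsmeans_contrasts(fit, "context")
  raw <- tapply(rec$sop, rec$context, mean)
  expect_equal(lc$lsmeans$lsmean,
               as.vector(raw[lc$lsmeans$context]), tolerance = 1e-10)
  # two groups: a single contrast, so adjusted p equals raw p
  expect_equal(nrow(lc$contrasts), 1L)
  expect_equal(lc$contrasts$p_adjusted, lc$contrasts$p_raw)
})

test_that("cell contrasts match emmeans on the saturated model", {
  skip_if_not_installed("emmeans")
  rec <- random_sop_fixture(81, n_per_cell = 3:5)
  fit <- fit_sop_model(rec, c("context", "sex", "population",
                              "population:sex"))
  lc <- lsmeans_contrasts(fit, c("population", "sex"))

  lm_fit <- lm(sop ~ population * sex, data = rec)
  em <- emmeans::emmeans(lm_fit, ~ population:sex)
  emc <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "bonferroni"))
  expect_equal(sort(abs(lc$contrasts$t_statistic)), sort(abs(emc$t.ratio)),
               tolerance = 1e-8)
  expect_equal(sort(lc$contrasts$p_adjusted), sort(emc$p.value),
               tolerance = 1e-8)
  expect_equal(unique(lc$contrasts$df), unname(unique(emc$df)))

  ems <- as.data.frame(em)
  key_em <- paste(ems$population, ems$sex)
  key_mine <- paste(lc$lsmeans$population, lc$lsmeans$sex)
  expect_equal(lc$lsmeans$lsmean, ems$emmean[match(key_mine, key_em)],
               tolerance = 1e-10)
})

test_that("contrasts touching an empty design cell are flagged inestimable", {
  rec <- random_sop_fixture(91, n_per_cell = 3:4)
  rec <- rec[!(rec$population == "P1" & rec$sex == "male"), ]
  fit <- fit_sop_model(rec, c("context", "sex"))
  lc <- lsmeans_contrasts(fit, c("population", "sex"))
  bad <- grepl("P1 male", lc$contrasts$contrast)
  expect_true(all(!lc$contrasts$estimable[bad]))
  expect_true(all(is.na(lc$contrasts$p_raw[bad])))
  expect_true(all(lc$contrasts$estimable[!bad]))
})
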