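# Per-replicate isolation fixtures for the GLS: i_index plus grouping labels.
gls_fixture <- function(y_sym, y_alo, species = "sp1") {
  n <- length(y_sym) + length(y_alo)
  tibble::tibble(
    replicate_id = sprintf("rep%d", seq_len(n)),
    population = rep(c("S", "A"), c(length(y_sym), length(y_alo))),
    context = rep(c("sympatric", "allopatric"),
                  c(length(y_sym), length(y_alo))),
    species = species,
    i_index = c(y_sym, y_alo))
}

test_that("two-group GLS matches the closed-form Welch-style computation", {
  set.seed(61)
  y1 <- rnorm(12, 0.8, 0.05)
  y2 <- rnorm(6, 0.45, 0.25)
  fit <- fit_total_isolation_gls(gls_fixture(y1, y2))
  co <- fit$coefficients
  # treatment coding, reference level "allopatric"
  expect_equal(co$estimate[co$term == "(Intercept)"], mean(y2))
  expect_equal(co$estimate[co$term == "contextsympatric"],
               mean(y1) - mean(y2), tolerance = 1e-10)
  v1 <- mean((y1 - mean(y1))^2)   # ML group variances
  v2 <- mean((y2 - mean(y2))^2)
  expect_equal(co$se[co$term == "contextsympatric"],
               sqrt(v1 / 12 + v2 / 6), tolerance = 1e-8)
  expect_equal(unname(fit$variance_groups["sympatric"]), v1, tolerance = 1e-8)
  expect_equal(co$df[1], 16)
})

test_that("the homoskedastic limit coincides with ordinary least squares", {
  # additive cell means with an identical residual pattern in every cell:
  # the realized variance is exactly equal across the two variance groups,
  # so the weighted fit must collapse to OLS, here with a 3-coefficient
  # model where unequal weights would genuinely move the estimates
  e <- c(-0.2, 0, 0.2)
  mu <- c(0.8, 0.6, 0.5, 0.3)  # sym/sp1, sym/sp2, alo/sp1, alo/sp2
  d <- tibble::tibble(
    replicate_id = sprintf("rep%d", 1:12),
    population = rep(c("S", "A"), each = 6),
    context = rep(c("sympatric", "allopatric"), each = 6),
    species = rep(rep(c("sp1", "sp2"), each = 3), 2),
    i_index = rep(mu, each = 3) + rep(e, 4))
  fit <- fit_total_isolation_gls(d, fixed = c("context", "species"))
  ols <- lm(i_index ~ context + species, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(diff(range(fit$variance_groups))), 0, tolerance = 1e-12)
})

test_that("the iterated fit matches nlme::gls with varIdent (ML)", {
  skip_if_not_installed("nlme")
  set.seed(62)
  d <- gls_fixture(rnorm(12, 0.75, 0.08), rnorm(9, 0.4, 0.3),
                   species = rep(c("sp1", "sp2"), length.out = 21))
  fit <- fit_total_isolation_gls(d, fixed = c("context", "species"))
  ref <- nlme::gls(i_index ~ context + species, data = d,
                   weights = nlme::varIdent(form = ~ 1 | context),
                   method = "ML")
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)), tolerance = 1e-6)
  # nlme rescales the ML covariance by n/(n - p) when reporting SEs
  n <- nrow(d)
  p <- 3
  expect_equal(fit$coefficients$se * sqrt(n / (n - p)),
               unname(summary(ref)$tTable[, "Std.Error"]), tolerance = 1e-4)
})

test_that("resident-species recoding makes the congener sympatric everywhere", {
  set.seed(63)
  d <- gls_fixture(rnorm(9, 0.8, 0.1), rnorm(9, 0.5, 0.1),
                   species = rep(c("focal", "resident"), length.out = 18))
  fit <- fit_total_isolation_gls(d, resident_species = "resident")
  recoded <- fit$data
  expect_true(all(recoded$context[recoded$species == "resident"] == "sympatric"))
  expect_true(any(recoded$context[recoded$species == "focal"] == "allopatric"))
})

test_that("degenerate variance structures raise errors with diagnostics", {
  d <- gls_fixture(c(0.7, 0.8, 0.9), 0.4)
  expect_error(fit_total_isolation_gls(d), "fewer than 2",
               class = "reinfiso_domain_error")
  flat <- gls_fixture(rep(0.7, 4), c(0.3, 0.4, 0.5))
  expect_error(fit_total_isolation_gls(flat),
               class = "reinfiso_domain_error")
})

test_that("optional within-replicate correlation is estimated and bounded", {
  set.seed(64)
  n_rep <- 9
  shared <- rnorm(n_rep, 0, 0.15)
  d <- tibble::tibble(
    replicate_id = rep(sprintf("rep%d", 1:n_rep), each = 2),
    population = rep(rep(c("S", "A", "A"), each = 2), 3),
    context = rep(rep(c("sympatric", "allopatric", "allopatric"), each = 2), 3),
    species = rep(c("sp1", "sp2"), n_rep),
    i_index = 0.5 + rep(shared, each = 2) + rnorm(2 * n_rep, 0, 0.05))
  fit <- fit_total_isolation_gls(d, replicate_effect = TRUE)
  expect_gt(fit$rho, 0)
  expect_lte(abs(fit$rho), 0.9)
  expect_true(fit$converged)
})

test_that("the context test holds its nominal size under a heteroskedastic null", {
  set.seed(65)
  n_sims <- 1000
  rej <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    d <- gls_fixture(rnorm(18, 0.5, 0.05), rnorm(18, 0.5, 0.25))
    f <- fit_total_isolation_gls(d)
    p <- f$coefficients$p_value[f$coefficients$term == "contextsympatric"]
    rej[i] <- p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})
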