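grp <- function(pop, ctx, sex, n, beta) {
  data.frame(population = pop, context = ctx, sex = sex, n = n, beta = beta)
}

test_that("dichotomous simulation is seed-deterministic and substream-stable", {
  g2 <- rbind(grp("A", "sympatric", "female", 20, 0.4),
              grp("B", "allopatric", "male", 20, -0.2))
  cfg <- dichotomous_sim_config(g2, seed = 11)
  t1 <- simulate_dichotomous(cfg)
  t2 <- simulate_dichotomous(cfg)
  expect_identical(t1, t2)
  t3 <- simulate_dichotomous(dichotomous_sim_config(g2, seed = 12))
  expect_false(isTRUE(all.equal(t1$t_conspecific, t3$t_conspecific)))

  # adding a third group leaves the first two groups' draws untouched
  g3 <- rbind(g2, grp("C", "sympatric", "male", 5, 0.1))
  t4 <- simulate_dichotomous(dichotomous_sim_config(g3, seed = 11))
  expect_identical(t1, t4[t4$population %in% c("A", "B"), ])
})

test_that("simulated trials satisfy the trial invariants", {
  cfg <- dichotomous_sim_config(grp("A", "sympatric", "female", 200, 0.9),
                                seed = 3)
  tr <- simulate_dichotomous(cfg)
  expect_silent(validate_dichotomous(tr))
  expect_true(all(tr$t_conspecific >= 0 & tr$t_heterospecific >= 0))
  expect_true(all(tr$t_conspecific + tr$t_heterospecific <= tr$trial_duration))
})

test_that("mean SOP converges to the configured preference bias", {
  # symmetric share distribution: mean SOP near 0
  t0 <- simulate_dichotomous(
    dichotomous_sim_config(grp("A", "sympatric", "female", 10000, 0),
                           kappa = 5, seed = 5))
  expect_lt(abs(mean(compute_sop(t0$t_conspecific, t0$t_heterospecific))), 0.02)

  t5 <- simulate_dichotomous(
    dichotomous_sim_config(grp("A", "sympatric", "female", 1000, 0.5),
                           kappa = 20, seed = 6))
  expect_lt(abs(mean(compute_sop(t5$t_conspecific, t5$t_heterospecific)) - 0.5),
            0.03)
})

test_that("invalid simulation configs fail before any sampling", {
  expect_error(dichotomous_sim_config(grp("A", "sympatric", "female", 5, 1)),
               class = "reinfiso_config_error")
  expect_error(dichotomous_sim_config(grp("A", "sympatric", "female", 0, 0.2)),
               class = "reinfiso_config_error")
  expect_error(dichotomous_sim_config(grp("A", "sympatric", "female", 5, 0.2),
                                      activity_mean = 1.2),
               class = "reinfiso_config_error")
  expect_error(
    stream_sim_config(data.frame(population = "A", context = "sympatric"),
                      data.frame(behavior = "waggle", lambda = 5, iota = 0)),
    class = "reinfiso_config_error")
  expect_error(
    stream_sim_config(data.frame(population = "A", context = "sympatric"),
                      data.frame(behavior = "spawn", lambda = 5, iota = 2)),
    class = "reinfiso_config_error")
})

test_that("stream counts respect boundary and degenerate bias settings", {
  pops <- data.frame(population = "A", context = "sympatric")
  beh <- data.frame(behavior = c("chase_mm", "spawn"),
                    lambda = c(50, 0), iota = c(1, 0.5))
  cfg <- stream_sim_config(pops, beh, n_replicates = 10, dispersion = 0.5,
                           seed = 2)
  cts <- simulate_stream(cfg)
  expect_identical(simulate_stream(cfg), cts)
  het <- cts$count[cts$behavior == "chase_mm" & cts$target == "heterospecific"]
  expect_true(all(het == 0))                     # iota = 1: no heterospecific acts
  expect_true(all(cts$count[cts$behavior == "spawn"] == 0))  # lambda = 0
  tab <- behavior_isolation_table(cts)
  expect_equal(tab$i_index[tab$behavior == "chase_mm"], c(1, 1))
  expect_true(all(is.na(tab$i_index[tab$behavior == "spawn"])))
})

test_that("per-behavior isolation recovers the configured bias", {
  pops <- data.frame(population = "A", context = "sympatric")
  beh <- data.frame(behavior = c("chase_mm", "chase_mf"),
                    lambda = 200, iota = c(0.6, 0))
  cts <- simulate_stream(stream_sim_config(pops, beh, n_replicates = 100,
                                           dispersion = 0, seed = 9))
  tab <- behavior_isolation_table(cts)
  est <- tab$i_index[match(c("chase_mm", "chase_mf"), tab$behavior)]
  expect_lt(abs(est[1] - 0.6), 0.05)
  expect_lt(abs(est[2] - 0), 0.05)
})

test_that("per-species behavior rates give each species its own bias", {
  pops <- data.frame(population = "A", context = "allopatric")
  beh <- data.frame(species = c("sp1", "sp2"), behavior = "chase_mf",
                    lambda = 300, iota = c(0.2, 0.9))
  cts <- simulate_stream(stream_sim_config(pops, beh, n_replicates = 50,
                                           dispersion = 0,
                                           species_pair = c("sp1", "sp2"),
                                           seed = 4))
  tab <- behavior_isolation_table(cts)
  i1 <- tab$i_index[tab$species == "sp1" & tab$behavior == "chase_mf"]
  i2 <- tab$i_index[tab$species == "sp2" & tab$behavior == "chase_mf"]
  expect_lt(abs(i1 - 0.2), 0.1)
  expect_lt(abs(i2 - 0.9), 0.1)
})

test_that("the study-scale synthetic dataset is valid, reproducible, and on target", {
  ds <- make_paper_like_dataset(1)
  expect_s3_class(ds, "reinfiso_dataset")
  expect_silent(validate_dichotomous(ds$trials))
  expect_silent(validate_stream_counts(ds$stream_counts))
  ds2 <- make_paper_like_dataset(1)
  expect_identical(ds$trials, ds2$trials)
  expect_identical(ds$stream_counts, ds2$stream_counts)

  # group structure: 18 per population x sex cell, one male cell with 16
  sizes <- dplyr::count(ds$trials, population, sex)
  expect_setequal(sizes$n, c(18L, 16L))
  expect_equal(sum(sizes$n == 16L), 1L)
  expect_equal(nrow(ds$trials), 142L)

  # 3 stream replicates per population, both species, all five behaviors
  reps <- dplyr::distinct(ds$stream_counts, population, replicate_id) |>
    dplyr::count(population)
  expect_true(all(reps$n == 3))

  # estimated group means sit near the configured biases: each cell mean
  # within 3 standard errors of its estimand (a sound Monte-Carlo bound
  # given the share-distribution variance at n = 18)
  rec <- sop_records(ds$trials)
  summ <- group_sop_summary(rec, c("population", "sex"))
  betas <- c(EF.female = 0.73, EF.male = 0.30, LC.female = 0.31,
             LC.male = 0.48, MF.female = 0.27, MF.male = 0.11,
             FC.female = 0.02, FC.male = 0.20)
  key <- paste(summ$population, summ$sex, sep = ".")
  got <- setNames(summ$mean, key)
  se <- setNames(summ$se, key)
  expect_true(all(abs(got[names(betas)] - betas) < 3 * se[names(betas)]))
  # and the reinforcement pattern is present: pooled sympatric means exceed
  # pooled allopatric means for both sexes
  pooled <- group_sop_summary(rec, c("context", "sex"))
  for (sx in c("female", "male")) {
    ps <- pooled[pooled$sex == sx, ]
    expect_gt(ps$mean[ps$context == "sympatric"],
              ps$mean[ps$context == "allopatric"])
  }
})
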