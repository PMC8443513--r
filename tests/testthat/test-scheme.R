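test_that("cycle metrics report MGV, fixation classes and accuracy", {
  map <- toy_map(list(c(0, 50, 100), c(20, 80)))
  arch <- toy_arch(map, effect = c(.4, .3, .2, .1, .5),
                   favorable = c("A", "A", "B", "A", "B"))
  # 3 plants; locus1 fixed favorable (A), locus3 fixed favorable (B),
  # locus2 fixed unfavorable (B), loci 4-5 segregating
  codes <- rbind(c(1, -1, -1, 1, 0),
                 c(1, -1, -1, 0, 1),
                 c(1, -1, -1, -1, -1))
  pop <- toy_pop(map, codes)
  model <- toy_model(1, setNames(2 * signed_effects(arch), map$locus))
  met <- compute_metrics(pop, model, arch)
  expect_equal(met$mgv, max(genetic_values(pop, arch)))
  expect_equal(met$prop_fixed_fav, 2 / 5)
  expect_equal(met$prop_fixed_unfav, 1 / 5)
  expect_equal(met$prop_unfixed, 2 / 5)
  expect_equal(met$prop_fixed_fav + met$prop_fixed_unfav +
                 met$prop_unfixed, 1)
  expect_equal(met$accuracy, 1)          # PV = 2*GV + 1, affine
  # intercept-only model: zero-variance PV -> accuracy NA
  met0 <- compute_metrics(pop, toy_model(3, setNames(rep(0, 5), map$locus)),
                          arch)
  expect_true(is.na(met0$accuracy))
})

test_that("constructed fixation proportions match the definition", {
  map <- toy_map(list(seq(0, 145, by = 5)))          # 30 loci
  arch <- toy_arch(map, effect = rep(0.1, 30), favorable = "A")
  codes <- matrix(rep(c(rep(1, 12), rep(-1, 3), rep(0, 15)), each = 4),
                  nrow = 4)
  met <- compute_metrics(toy_pop(map, codes),
                         toy_model(0, signed_effects(arch)), arch)
  expect_equal(met$prop_fixed_fav, 0.4)
  expect_equal(met$prop_fixed_unfav, 0.1)
  expect_equal(met$prop_unfixed, 0.5)
})

test_that("the model refits at odd cycles and is reused at even cycles", {
  set.seed(61)
  map <- build_genome(5, 150, 10)
  pop <- make_initial_population(map, 40)
  arch <- scale_effects(sample_effects(map), pop)
  model <- NULL
  coefs <- list()
  for (cyc in 1:4) {
    step <- run_cycle(pop, model, "P5", arch, h2 = 1, cycle_index = cyc,
                      n_f2_total = 40, n_folds = 5)
    expect_equal(step$record$model_updated, cyc %% 2 == 1)
    coefs[[cyc]] <- step$model$coefficients
    pop <- step$population; model <- step$model
  }
  expect_identical(coefs[[2]], coefs[[1]])
  expect_identical(coefs[[4]], coefs[[3]])
})

test_that("fully fixed populations carry the last record forward", {
  set.seed(62)
  map <- toy_map(list(c(0, 70), c(30)))
  arch <- toy_arch(map, effect = c(.5, .3, .2), favorable = "A")
  # population already fixed at every locus after cycle-1 crossing of
  # identical inbreds: run a scheme from a 4-plant monomorphic population
  pop <- toy_pop(map, matrix(rep(c(1, 1, -1), each = 4), nrow = 4))
  res <- suppressWarnings(run_scheme(pop, arch, h2 = 1, strategy = "P1",
                                     n_cycles = 4, n_f2_total = 20,
                                     n_folds = 4))
  expect_equal(res$cycle, 0:4)
  later <- res[res$cycle >= 1, c("mgv", "prop_fixed_fav",
                                 "prop_fixed_unfav", "prop_unfixed")]
  expect_true(all(vapply(later, function(x) length(unique(x)) == 1,
                         logical(1))))
  expect_equal(res$prop_unfixed[res$cycle == 4], 0)
})

test_that("run_experiment bookkeeping, matched pairs and determinism", {
  res <- run_experiment(c("S1", "P1"), n_qtl = 8, h2 = 1,
                        n_replicates = 2, n_cycles = 2, n_pop = 30,
                        n_groups = 4, n_f1_sim = 2, n_f2_sim = 10, k = 4,
                        n_folds = 5, seed = 63)
  expect_equal(nrow(res), 2 * 2 * 3)          # 2 strategies x 2 reps x 0..2
  expect_setequal(unique(res$cycle), 0:2)
  # matched pairs: strategies share the replicate's initial population
  c0 <- res[res$cycle == 0, ]
  for (r in 1:2)
    expect_equal(c0$mgv[c0$strategy == "S1" & c0$replicate == r],
                 c0$mgv[c0$strategy == "P1" & c0$replicate == r])
  res2 <- run_experiment(c("S1", "P1"), n_qtl = 8, h2 = 1,
                         n_replicates = 2, n_cycles = 2, n_pop = 30,
                         n_groups = 4, n_f1_sim = 2, n_f2_sim = 10, k = 4,
                         n_folds = 5, seed = 63)
  expect_identical(res, res2)
})

test_that("selection erodes segregation: prop_unfixed falls over cycles", {
  res <- run_experiment(c("S1", "S10", "P10"), n_qtl = 10, h2 = 1,
                        n_replicates = 6, n_cycles = 3, n_pop = 50,
                        n_groups = 5, n_f1_sim = 2, n_f2_sim = 10, k = 4,
                        n_folds = 5, seed = 64)
  for (s in unique(res$strategy)) {
    u1 <- mean(res$prop_unfixed[res$strategy == s & res$cycle == 1])
    u3 <- mean(res$prop_unfixed[res$strategy == s & res$cycle == 3])
    expect_lte(u3, u1)
  }
  # single-cross bottleneck: S1 loses segregation faster than S10
  u_s1 <- mean(res$prop_unfixed[res$strategy == "S1" & res$cycle == 2])
  u_s10 <- mean(res$prop_unfixed[res$strategy == "S10" & res$cycle == 2])
  expect_lt(u_s1, u_s10)
})

test_that("noiseless training yields higher early selection accuracy", {
  set.seed(65)
  wins <- 0L
  for (i in 1:20) {
    map <- build_genome(10, 150, 20)
    pop <- make_initial_population(map, 100)
    arch <- scale_effects(sample_effects(map), pop)
    acc <- vapply(c(1.0, 0.3), function(h2) {
      ph <- phenotype_population(pop, arch, h2)
      fit <- fit_prediction_model(genotype_codes(pop), ph$phenotype,
                                  n_folds = 5)
      pv <- predict(fit, genotype_codes(pop))
      if (var(pv) == 0) return(0)
      cor(pv, ph$gv)
    }, numeric(1))
    wins <- wins + (acc[1] >= acc[2])
  }
  expect_gte(wins, 16)          # >= 80% of matched replicates
})

test_that("matched-pair t statistics follow the closed form", {
  out <- matched_pair_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(out$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p, 2 * pt(-out$t, 2), tolerance = 1e-12)

  same <- matched_pair_test(c(1, 2), c(1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  bf <- matched_pair_test(rnorm(10), rnorm(10), n_comparisons = 5)
  expect_equal(bf$p_adjusted, min(1, bf$p * 5))
  expect_equal(matched_pair_test(c(2, 3), c(1, 2))$p, 0)  # constant shift
  expect_error(matched_pair_test(1:3, 1:2), "equal length")
})

test_that("strategy comparison tables cover all pairs and cycles", {
  res <- run_experiment(c("P1", "P5", "P10"), n_qtl = 6, h2 = 1,
                        n_replicates = 3, n_cycles = 2, n_pop = 30,
                        n_groups = 3, n_folds = 5, seed = 66)
  cmp <- compare_strategies(res)
  expect_equal(nrow(cmp), 3 * 2)               # C(3,2) pairs x 2 cycles
  expect_true(all(cmp$p_bonferroni >= cmp$p - 1e-15))
  expect_true(all(cmp$p_bonferroni <= 1))
})
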