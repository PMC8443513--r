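test_that("cross enumeration yields all unordered distinct pairs", {
  expect_equal(nrow(enumerate_crosses(194)), 18721)
  expect_equal(nrow(enumerate_crosses(80)), 3160)
  e3 <- enumerate_crosses(c("a", "b", "c"))
  expect_equal(nrow(e3), 3)
  expect_true(all(e3$parent1 != e3$parent2))
  expect_error(enumerate_crosses(1))
})

test_that("simulated progeny counts and degenerate crosses behave", {
  map <- toy_map(list(c(0, 40), 70))
  model <- toy_model(10, setNames(c(1, 0.5, -0.25), map$locus))
  pa <- toy_pop(map, rep(1, 3), ids = "A")
  pb <- toy_pop(map, rep(-1, 3), ids = "B")
  set.seed(51)
  sim <- simulate_cross_progeny(pa, pb, model, n_f1 = 5, n_f2_per_f1 = 50)
  expect_length(sim$pv, 250)

  # identical fully homozygous parents: progeny clone the parent
  sim_aa <- simulate_cross_progeny(pa, pa, model, 4, 25,
                                   return_genotypes = TRUE)
  expect_true(all(sim_aa$pv == unname(predict(model,
                                              genotype_codes(pa)))))
  expect_equal(var(sim_aa$pv), 0)
  expect_true(all(sim_aa$genotypes == 1L))

  # homozygous non-identical parents: the F1 is unique
  f1s <- cross(pa, pb, 5)
  expect_true(all(genotype_codes(f1s) == 0L))
})

test_that("cross scores are top/bottom-k means of progeny PVs", {
  expect_equal(score_cross(c(1, 2, 3, 4), 2, "high")$score, 3.5)
  expect_equal(score_cross(c(1, 2, 3, 4), 2, "low")$score, 1.5)
  cc <- score_cross(rep(2.5, 10), 3, "high")
  expect_equal(cc$score, 2.5)
  expect_equal(cc$variance, 0)
  expect_error(score_cross(1:4, 5, "high"), "between 1")
})

test_that("simulated scores match an independent sampling oracle", {
  # two unlinked loci, homozygous opposite parents: F2 codes are iid with
  # P(+1)=1/4, P(0)=1/2, P(-1)=1/4 at each locus, independent across loci.
  map <- toy_map(list(20, 30))
  model <- toy_model(0, setNames(c(1, 0.5), map$locus))
  pa <- toy_pop(map, c(1, 1), ids = "A")
  pb <- toy_pop(map, c(-1, -1), ids = "B")
  n_prog <- 40; k <- 4; reps <- 400
  set.seed(52)
  sim_scores <- replicate(reps, {
    pv <- simulate_cross_progeny(pa, pb, model, 4, 10)$pv
    score_cross(pv, k, "high")$score
  })
  oracle_scores <- replicate(reps, {
    codes <- cbind(sample(c(1, 0, -1), n_prog, TRUE, c(.25, .5, .25)),
                   sample(c(1, 0, -1), n_prog, TRUE, c(.25, .5, .25)))
    mean(sort(codes %*% c(1, 0.5), decreasing = TRUE)[1:k])
  })
  se <- sqrt(var(sim_scores) / reps + var(oracle_scores) / reps)
  expect_lt(abs(mean(sim_scores) - mean(oracle_scores)), 4 * se)
})

test_that("rank_all_crosses enumerates, sorts and scores every pair", {
  set.seed(53)
  map <- build_genome(3, 150, 6)
  pop <- make_initial_population(map, 12)
  arch <- scale_effects(sample_effects(map), pop)
  model <- toy_model(0, signed_effects(arch))
  rk <- rank_all_crosses(pop, model, n_f1 = 2, n_f2_per_f1 = 20, k = 4)
  expect_equal(nrow(rk), 12 * 11 / 2)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$score) <= 0))          # high: descending
  expect_true(all(rk$n_simulated == 40))
  expect_true(all(rk$parent1 != rk$parent2))
  rk_low <- rank_all_crosses(pop, model, 2, 20, 4, direction = "low")
  expect_true(all(diff(rk_low$score) >= 0))
  tiny <- pop[1:3]
  expect_equal(nrow(rank_all_crosses(tiny, model, 2, 10, 2)), 3)
})

test_that("P strategies select by own PV in chain designs", {
  set.seed(54)
  map <- build_genome(4, 150, 8)
  pop <- make_initial_population(map, 30)
  arch <- scale_effects(sample_effects(map), pop)
  model <- toy_model(0, signed_effects(arch))
  pv <- predict(model, genotype_codes(pop))

  p1 <- plan_crosses_pv(pop, model, 1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$n_f1, 10)
  top2 <- pop$ids[order(-pv)][1:2]
  expect_setequal(c(p1$parent1, p1$parent2), top2)

  p10 <- plan_crosses_pv(pop, model, 10)
  expect_equal(nrow(p10), 10)
  expect_true(all(p10$n_f1 == 1))
  sel <- pop$ids[order(-pv)][1:10]
  expect_equal(p10$parent1, sel)
  expect_equal(p10$parent2, sel[c(2:10, 1)])     # chain wraps to plant 1

  p5 <- plan_crosses_pv(pop, model, 5)
  expect_equal(nrow(p5), 5)
  expect_true(all(p5$n_f1 == 2))

  expect_error(plan_crosses_pv(pop[1:4], model, 10), "too small")
  expect_error(plan_crosses_pv(pop, model, 3), "divide")
})

test_that("S strategies take the top-ranked simulated crosses", {
  set.seed(55)
  map <- build_genome(4, 150, 8)
  pop <- make_initial_population(map, 15)
  arch <- scale_effects(sample_effects(map), pop)
  model <- toy_model(0, signed_effects(arch))

  set.seed(56)
  s1 <- plan_crosses_simulated(pop, model, 1, n_f1 = 2, n_f2_per_f1 = 20,
                               k = 4)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$n_f1, 10)
  set.seed(56)
  rk <- rank_all_crosses(pop, model, 2, 20, 4)
  expect_equal(c(s1$parent1, s1$parent2), c(rk$parent1[1], rk$parent2[1]))

  s10 <- plan_crosses_simulated(pop, model, 10, 2, 20, 4)
  expect_equal(nrow(s10), 10)
  expect_true(all(s10$n_f1 == 1))

  expect_error(plan_crosses_simulated(pop[1:2], model, 5, 2, 20, 4),
               "fewer than 5")
  expect_s3_class(select_strategy(pop, model, "P5"), "crossing_plan")
  expect_error(select_strategy(pop, model, "X3"), "unknown strategy")
})

test_that("next_generation pools equal selfed families into one F2 population", {
  set.seed(57)
  map <- build_genome(4, 150, 8)
  pop <- make_initial_population(map, 15)
  arch <- scale_effects(sample_effects(map), pop)
  model <- toy_model(0, signed_effects(arch))
  plan <- plan_crosses_pv(pop, model, 10)
  f2 <- next_generation(plan, pop, 200)
  expect_equal(n_individuals(f2), 200)
  expect_equal(f2$generation, "F2")
  expect_error(next_generation(plan, pop, 205), "divisible")
  # S1: all 200 descend from one pair -> only that pair's alleles present
  plan1 <- plan_crosses_pv(pop, model, 1)
  f2_one <- next_generation(plan1, pop, 200)
  parents <- pop[c(plan1$parent1, plan1$parent2)]
  par_codes <- genotype_codes(parents)
  fixed_same <- apply(par_codes, 2, function(x)
    all(x == x[1]) && x[1] != 0)
  expect_true(all(genotype_codes(f2_one)[, fixed_same] ==
                    rep(par_codes[1, fixed_same], each = 200)))
})

test_that("rankings are deterministic under a fixed seed", {
  set.seed(58)
  map <- build_genome(3, 150, 6)
  pop <- make_initial_population(map, 10)
  arch <- scale_effects(sample_effects(map), pop)
  model <- toy_model(0, signed_effects(arch))
  p1 <- tempfile(); p2 <- tempfile()
  set.seed(99)
  write_ranking(rank_all_crosses(pop, model, 2, 10, 2), p1)
  set.seed(99)
  write_ranking(rank_all_crosses(pop, model, 2, 10, 2), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
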