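test_that("a fully homozygous parent transmits its haplotype unchanged", {
  map <- toy_map(list(c(0, 50, 100), c(25, 75)))
  homo_a <- toy_pop(map, codes = rep(1, 5))
  g <- sample_gametes(homo_a, 50)
  expect_true(all(g == 0L))
  homo_b <- toy_pop(map, codes = rep(-1, 5))
  expect_true(all(sample_gametes(homo_b, 50) == 1L))
})

test_that("gametes only ever carry alleles present in the parent", {
  set.seed(21)
  map <- build_genome(3, 150, 9)
  pop <- make_initial_population(map, 30)
  f2 <- self_cross(founder_f1(map), 1)      # heterozygous at many loci
  for (ind in list(get_individual(pop, 5), f2)) {
    g <- sample_gametes(ind, 200)
    ok <- g == as.vector(ind$hap1) | g == as.vector(ind$hap2)
    expect_true(all(ok))
  }
})

test_that("recombination follows the Haldane map function", {
  set.seed(22)
  n <- 1e5
  d <- c(1, 10, 50, 150)
  rf <- vapply(d, function(dd) {
    map <- toy_map(list(c(0, dd)))
    g <- sample_gametes(founder_f1(map), n)
    mean(g[1, ] != g[2, ])
  }, numeric(1))
  r_exp <- (1 - exp(-2 * d / 100)) / 2
  se <- sqrt(r_exp * (1 - r_exp) / n)
  expect_true(all(abs(rf - r_exp) < 3 * se))
  # monotone in distance and bounded by 1/2
  expect_true(!is.unsorted(rf))
  expect_true(all(rf < 0.5))
})

test_that("loci on different linkage groups assort independently", {
  set.seed(23)
  map <- toy_map(list(75, 75))
  g <- sample_gametes(founder_f1(map), 1e5)
  rf <- mean(g[1, ] != g[2, ])
  expect_lt(abs(rf - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("observed phase switches match summed interval recombination", {
  # 150 cM group sampled at 5 cM spacing: the expected number of observable
  # switches is the sum of the 30 per-interval Haldane fractions
  set.seed(24)
  map <- toy_map(list(seq(0, 150, by = 5)))
  g <- sample_gametes(founder_f1(map), 2e4)
  switches <- colSums(g[-1, , drop = FALSE] != g[-nrow(g), , drop = FALSE])
  expected <- 30 * (1 - exp(-2 * 5 / 100)) / 2
  se <- sd(switches) / sqrt(length(switches))
  expect_lt(abs(mean(switches) - expected), 3 * se)
})

test_that("selfing a heterozygote segregates 1:2:1", {
  set.seed(25)
  map <- toy_map(list(10))
  off <- self_cross(founder_f1(map), 3e4)
  counts <- table(factor(genotype_codes(off)[, 1], levels = c(-1, 0, 1)))
  gof <- chisq.test(as.vector(counts), p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)
})

test_that("crossing homozygous founder lines gives the expected genotypes", {
  map <- toy_map(list(c(0, 30), 60))
  line_a <- toy_pop(map, codes = rep(1, 3), ids = "A")
  line_b <- toy_pop(map, codes = rep(-1, 3), ids = "B")
  off_aa <- cross(line_a, line_a, 20)
  expect_true(all(genotype_codes(off_aa) == 1L))
  f1 <- cross(line_a, line_b, 20)
  expect_true(all(genotype_codes(f1) == 0L))
  expect_error(cross(line_a, toy_pop(toy_map(list(5)), codes = 1)),
               "different genetic maps")
})

test_that("single-seed descent halves heterozygosity per generation", {
  map <- toy_map(list(c(0, 40, 80, 120), c(0, 50, 100)))
  homo <- toy_pop(map, codes = matrix(1, 4, 7))
  expect_identical(ssd_advance(homo, 5)$hap1, homo$hap1)
  pop <- make_initial_population(map, 100)
  expect_identical(ssd_advance(pop, 0), pop)

  set.seed(26)
  big <- make_initial_population(map, 1e4)   # F8: seven meioses from F1
  expect_lt(abs(heterozygosity(big) - 2^-7), 0.003)
})

test_that("the initial population is n independent F8 descendants", {
  set.seed(27)
  map <- build_genome(4, 150, 8)
  expect_true(all(genotype_codes(founder_f1(map)) == 0L))
  pop <- make_initial_population(map, 200)
  expect_equal(n_individuals(pop), 200)
  expect_equal(pop$generation, "F8")
  expect_error(make_initial_population(map, 1), "n >= 2")
})
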