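# Parent-selection strategies: the in-silico progeny cross-ranking engine
# (S strategies) and own-prediction-value selection (P strategies).

#' Enumerate all candidate crosses
#'
#' All unordered pairs of distinct parents (no self-crosses), with
#' `parent1` before `parent2` in population order: `n` parents give
#' `n*(n-1)/2` candidates (194 give 18,721).
#'
#' @param parents either a parent count or a vector of parent ids.
#' @return Data frame with columns `parent1`, `parent2`.
#' @export
enumerate_crosses <- function(parents) {
  ids <- if (length(parents) == 1 && is.numeric(parents)) {
    seq_len(parents)
  } else {
    parents
  }
  n <- length(ids)
  if (n < 2) stop("need at least 2 parents to enumerate crosses")
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1, from = 2:n)
  data.frame(parent1 = ids[i], parent2 = ids[j],
             stringsAsFactors = FALSE)
}

# Restrict a population's haplotypes and recombination structure to the
# model's markers; exact because the meiotic phase process is Markov along
# each group (see map_recomb).
model_subset <- function(pop, model) {
  rec <- map_recomb(pop$map, model$markers)
  beta <- model$coefficients[match(rec$loci, model$markers)]
  list(h1 = pop$hap1[rec$idx, , drop = FALSE],
       h2 = pop$hap2[rec$idx, , drop = FALSE],
       first = rec$first, r = rec$r, beta = unname(beta),
       loci = rec$loci)
}

#' Simulate F2 progeny of one cross and their prediction values
#'
#' Draws `n_f1` F1 genotypes from the parent pair, selfs each `n_f2_per_f1`
#' times, and evaluates the prediction model on every simulated F2 (5 x 50 =
#' 250 progeny per cross by default, the in-silico progeny sample used when
#' ranking second-cycle crosses). Meiosis is simulated at the model's
#' markers only, which is statistically exact under the no-interference
#' crossover model.
#'
#' @param p1,p2 single-member `population`s on the same map.
#' @param model a `prediction_model` whose markers lie on that map.
#' @param n_f1 number of F1 genotypes to simulate per cross.
#' @param n_f2_per_f1 number of selfed F2 per F1.
#' @param return_genotypes if `TRUE`, also return the simulated F2 code
#'   matrix (progeny x markers).
#' @return List with `pv` (numeric, length `n_f1 * n_f2_per_f1`) and, if
#'   requested, `genotypes`.
#' @export
simulate_cross_progeny <- function(p1, p2, model, n_f1 = 5,
                                   n_f2_per_f1 = 50,
                                   return_genotypes = FALSE) {
  stopifnot(n_individuals(p1) == 1, n_individuals(p2) == 1,
            n_f1 >= 1, n_f2_per_f1 >= 1)
  if (!identical(as.data.frame(p1$map), as.data.frame(p2$map)))
    stop("parents are defined on different genetic maps")
  sub1 <- model_subset(p1, model)
  sub2 <- model_subset(p2, model)
  res <- cpp_cross_progeny(sub1$h1[, 1], sub1$h2[, 1],
                           sub2$h1[, 1], sub2$h2[, 1],
                           sub1$first, sub1$r, sub1$beta, model$intercept,
                           as.integer(n_f1), as.integer(n_f2_per_f1),
                           isTRUE(return_genotypes))
  if (return_genotypes) {
    g <- t(res$genotypes)
    colnames(g) <- sub1$loci
    list(pv = res$pv, genotypes = g)
  } else {
    list(pv = res$pv)
  }
}

#' Score a simulated progeny distribution
#'
#' The cross score is the mean prediction value of the `k` best simulated
#' progeny: the `k` largest PVs when selecting for high trait values, the
#' `k` smallest when selecting for low. The reported variance is the
#' variance of all progeny PVs.
#'
#' @param pv numeric vector of simulated progeny prediction values.
#' @param k number of top (or bottom) progeny to average (k <= length(pv)).
#' @param direction `"high"` or `"low"`.
#' @return List with `score` and `variance`.
#' @examples
#' score_cross(c(1, 2, 3, 4), k = 2, direction = "high") # score 3.5
#' @export
score_cross <- function(pv, k, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (k < 1 || k > length(pv))
    stop("k must be between 1 and the number of progeny")
  s <- sort(pv, decreasing = (direction == "high"))[seq_len(k)]
  list(score = mean(s),
       variance = if (length(pv) > 1) var(pv) else 0)
}

#' Rank every pairwise cross of a population by simulated progeny
#'
#' For each of the `n*(n-1)/2` unordered parent pairs, simulates
#' `n_f1 * n_f2_per_f1` F2 progeny, evaluates the prediction model on each,
#' and scores the cross by the mean PV of the top `k` progeny (bottom `k`
#' when `direction = "low"`). Candidates are returned sorted by score
#' (descending for `"high"`, ascending for `"low"`), ties broken by
#' ascending parent indices.
#'
#' @param pop a `population` (n >= 2).
#' @param model a `prediction_model` whose markers lie on the
#'   population's map.
#' @param n_f1 simulated F1 genotypes per candidate cross.
#' @param n_f2_per_f1 selfed F2 per simulated F1.
#' @param k progeny averaged into the score.
#' @param direction selection direction, `"high"` or `"low"`.
#' @return A `cross_ranking` data frame: `rank`, `parent1`, `parent2`
#'   (ids), `score`, `progeny_variance`, `n_simulated`.
#' @export
rank_all_crosses <- function(pop, model, n_f1 = 5, n_f2_per_f1 = 40,
                             k = 10, direction = c("high", "low")) {
  direction <- match.arg(direction)
  n <- n_individuals(pop)
  if (n < 2) stop("need at least 2 parents to rank crosses")
  if (k < 1 || k > n_f1 * n_f2_per_f1)
    stop("k must be between 1 and n_f1 * n_f2_per_f1")
  sub <- model_subset(pop, model)
  res <- cpp_rank_crosses(sub$h1, sub$h2, sub$first, sub$r, sub$beta,
                          model$intercept, as.integer(n_f1),
                          as.integer(n_f2_per_f1), as.integer(k),
                          direction == "high")
  ord <- order(if (direction == "high") -res[, 3] else res[, 3],
               res[, 1], res[, 2])
  out <- data.frame(rank = seq_len(nrow(res)),
                    parent1 = pop$ids[res[ord, 1]],
                    parent2 = pop$ids[res[ord, 2]],
                    score = res[ord, 3],
                    progeny_variance = res[ord, 4],
                    n_simulated = n_f1 * n_f2_per_f1,
                    stringsAsFactors = FALSE)
  structure(out, direction = direction,
            class = c("cross_ranking", "data.frame"))
}

new_crossing_plan <- function(parent1, parent2, n_f1, strategy, direction,
                              f1_budget) {
  if (sum(n_f1) != f1_budget)
    stop("crossing plan must allot exactly ", f1_budget, " F1 genotypes")
  structure(data.frame(parent1 = parent1, parent2 = parent2, n_f1 = n_f1,
                       stringsAsFactors = FALSE),
            strategy = strategy, direction = direction,
            class = c("crossing_plan", "data.frame"))
}

#' Plan crosses from the simulated-progeny ranking (S strategies)
#'
#' Ranks all pairwise crosses with [rank_all_crosses()] and keeps the top
#' `n_crosses`, splitting the F1 budget (10 per cycle) equally among them:
#' S1 = 1 cross x 10 F1, S5 = 5 crosses x 2 F1, S10 = 10 crosses x 1 F1.
#'
#' @inheritParams rank_all_crosses
#' @param n_crosses number of crosses to carry out (must divide
#'   `f1_budget`; 1, 5 or 10 in the benchmark).
#' @param f1_budget total F1 genotypes per cycle (default 10).
#' @return A `crossing_plan` (columns `parent1`, `parent2`, `n_f1`).
#' @export
plan_crosses_simulated <- function(pop, model, n_crosses, n_f1 = 5,
                                   n_f2_per_f1 = 40, k = 10,
                                   direction = c("high", "low"),
                                   f1_budget = 10) {
  direction <- match.arg(direction)
  if (f1_budget %% n_crosses != 0)
    stop("n_crosses must divide the F1 budget of ", f1_budget)
  n <- n_individuals(pop)
  if (n * (n - 1) / 2 < n_crosses)
    stop("population of ", n, " yields fewer than ", n_crosses,
         " candidate crosses")
  ranking <- rank_all_crosses(pop, model, n_f1, n_f2_per_f1, k, direction)
  top <- ranking[seq_len(n_crosses), ]
  new_crossing_plan(top$parent1, top$parent2,
                    rep(f1_budget / n_crosses, n_crosses),
                    sprintf("S%d", n_crosses), direction, f1_budget)
}

#' Plan crosses from individual prediction values (P strategies)
#'
#' Ranks plants by their own PV (ties broken by population index). With
#' `n_crosses = 1` the top two plants are crossed (P1); otherwise the top
#' `n_crosses` plants are chained in a single round-robin design,
#' plant1 x plant2, plant2 x plant3, ..., plantk x plant1 (P5, P10). The F1
#' budget (10) is split equally among the crosses.
#'
#' @param pop a `population`.
#' @param model a `prediction_model`.
#' @param n_crosses number of crosses (must divide `f1_budget`).
#' @param direction `"high"` or `"low"`.
#' @param f1_budget total F1 genotypes per cycle (default 10).
#' @return A `crossing_plan`.
#' @export
plan_crosses_pv <- function(pop, model, n_crosses,
                            direction = c("high", "low"), f1_budget = 10) {
  direction <- match.arg(direction)
  if (f1_budget %% n_crosses != 0)
    stop("n_crosses must divide the F1 budget of ", f1_budget)
  n <- n_individuals(pop)
  n_plants <- if (n_crosses == 1) 2 else n_crosses
  if (n < n_plants)
    stop("population of ", n, " is too small for ", n_plants,
         " selected plants")
  pv <- predict(model, genotype_codes(pop))
  ord <- order(if (direction == "high") -pv else pv, seq_len(n))
  sel <- pop$ids[ord[seq_len(n_plants)]]
  if (n_crosses == 1) {
    p1 <- sel[1]; p2 <- sel[2]
  } else {
    p1 <- sel
    p2 <- sel[c(2:n_plants, 1)]
  }
  new_crossing_plan(p1, p2, rep(f1_budget / n_crosses, n_crosses),
                    sprintf("P%d", n_crosses), direction, f1_budget)
}

#' Apply a named selection strategy
#'
#' Dispatches the benchmark strategy labels: `"S1"`, `"S5"`, `"S10"`
#' (simulated-progeny cross ranking) and `"P1"`, `"P5"`, `"P10"`
#' (own-PV selection).
#'
#' @param pop a `population`.
#' @param model a `prediction_model`.
#' @param strategy strategy label.
#' @param n_f1_sim,n_f2_sim simulated progeny layout per candidate cross
#'   (S strategies only).
#' @param k progeny averaged into the cross score (S strategies only).
#' @param direction `"high"` or `"low"`.
#' @param f1_budget total F1 genotypes per cycle (default 10).
#' @return A `crossing_plan`.
#' @export
select_strategy <- function(pop, model, strategy, n_f1_sim = 5,
                            n_f2_sim = 40, k = 10,
                            direction = c("high", "low"), f1_budget = 10) {
  direction <- match.arg(direction)
  if (!grepl("^[SP][0-9]+$", strategy))
    stop("unknown strategy label: ", strategy)
  n_crosses <- as.integer(sub("^[SP]", "", strategy))
  if (startsWith(strategy, "S")) {
    plan_crosses_simulated(pop, model, n_crosses, n_f1_sim, n_f2_sim, k,
                           direction, f1_budget)
  } else {
    plan_crosses_pv(pop, model, n_crosses, direction, f1_budget)
  }
}

#' Generate the next-cycle F2 population from a crossing plan
#'
#' For each planned cross, draws its allotted F1 genotypes; every F1 is
#' then selfed an equal number of times and all F2 are pooled into a single
#' population of `n_f2_total` (200 in the benchmark scheme: 10 F1 x 20 F2
#' each).
#'
#' @param plan a `crossing_plan`.
#' @param pop the parental `population` (ids referenced by the plan).
#' @param n_f2_total size of the pooled F2 population; must be divisible
#'   by the plan's total F1 count.
#' @return A `population` of `n_f2_total` F2 individuals.
#' @export
next_generation <- function(plan, pop, n_f2_total = 200) {
  total_f1 <- sum(plan$n_f1)
  if (n_f2_total %% total_f1 != 0)
    stop("n_f2_total (", n_f2_total, ") must be divisible by the total F1 ",
         "count (", total_f1, ")")
  i <- match(plan$parent1, pop$ids)
  j <- match(plan$parent2, pop$ids)
  if (anyNA(i) || anyNA(j))
    stop("crossing plan references parents absent from the population")
  rec <- map_recomb(pop$map)
  p1_idx <- rep(i, plan$n_f1)
  p2_idx <- rep(j, plan$n_f1)
  f1_h1 <- cpp_meiosis(pop$hap1, pop$hap2, p1_idx, rec$first, rec$r)
  f1_h2 <- cpp_meiosis(pop$hap1, pop$hap2, p2_idx, rec$first, rec$r)
  per_f1 <- n_f2_total %/% total_f1
  self_idx <- rep(seq_len(total_f1), each = per_f1)
  h1 <- cpp_meiosis(f1_h1, f1_h2, self_idx, rec$first, rec$r)
  h2 <- cpp_meiosis(f1_h1, f1_h2, self_idx, rec$first, rec$r)
  w <- max(3L, nchar(as.character(n_f2_total)))
  new_population(h1, h2, pop$map,
                 sprintf("F2_%0*d", w, seq_len(n_f2_total)), "F2")
}

#' Write a cross ranking to a tab-separated file
#'
#' Columns `rank  parent1  parent2  score  progeny_variance  n_simulated`;
#' output is byte-stable for a given ranking.
#'
#' @param ranking a `cross_ranking` from [rank_all_crosses()].
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  df$score <- format(df$score, digits = 17, trim = TRUE)
  df$progeny_variance <- format(df$progeny_variance, digits = 17,
                                trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
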