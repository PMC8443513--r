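# Multi-cycle recurrent selection scheme: cycle metrics, the five-cycle
# runner with odd-cycle model refits and fixation carry-forward, replicated
# experiments with matched pairs, and the comparison statistics.

#' Per-cycle evaluation metrics of a population
#'
#' Computes, for one population under the current prediction model and the
#' true trait architecture:
#' * `mgv` - the maximum genetic value among the plants;
#' * `prop_fixed_fav` / `prop_fixed_unfav` / `prop_unfixed` - fractions of
#'   QTLs at which every individual is homozygous for the favorable allele,
#'   homozygous for the unfavorable allele, or still segregating (the three
#'   always sum to 1);
#' * `accuracy` - Pearson correlation between prediction values and genetic
#'   values over individuals (`NA` when either has zero variance, e.g.
#'   under an intercept-only model).
#'
#' @param pop a `population`.
#' @param model a `prediction_model`.
#' @param arch the true `trait_arch`.
#' @return One-row data frame with the fields above.
#' @export
compute_metrics <- function(pop, model, arch) {
  codes <- genotype_codes(pop)
  gv <- genetic_values(pop, arch)
  pv <- predict(model, codes)
  fav_code <- ifelse(arch$favorable == "A", 1L, -1L)
  fixed_fav <- vapply(seq_len(ncol(codes)),
                      function(l) all(codes[, l] == fav_code[l]), logical(1))
  fixed_unfav <- vapply(seq_len(ncol(codes)),
                        function(l) all(codes[, l] == -fav_code[l]),
                        logical(1))
  acc <- if (var(pv) <= 0 || var(gv) <= 0) NA_real_ else cor(pv, gv)
  data.frame(mgv = max(gv),
             prop_fixed_fav = mean(fixed_fav),
             prop_fixed_unfav = mean(fixed_unfav),
             prop_unfixed = mean(!fixed_fav & !fixed_unfav),
             accuracy = acc)
}

#' Are all QTLs fixed in a population?
#'
#' `TRUE` when every locus is monomorphic homozygous, i.e. all individuals
#' share one fully inbred genotype and crossing can create no new variation.
#'
#' @param pop a `population`.
#' @return Logical scalar.
#' @export
all_qtl_fixed <- function(pop) {
  codes <- genotype_codes(pop)
  all(codes != 0L) &&
    all(apply(codes, 2, function(x) length(unique(x)) == 1L))
}

#' Run one selection cycle
#'
#' At odd-numbered cycles the prediction model is refitted on the current
#' population's genotype codes and freshly drawn phenotypes (so the very
#' first model is trained on the initial inbred population); at even cycles
#' the previous model is reused. The strategy's crossing plan is then
#' applied and a pooled F2 population of `n_f2_total` produced; the cycle
#' record holds the metrics of that new F2 population.
#'
#' @param pop current `population`.
#' @param model current `prediction_model`, or `NULL` before the first fit.
#' @param strategy strategy label (see [select_strategy()]).
#' @param arch true `trait_arch`.
#' @param h2 heritability used for phenotyping at model updates.
#' @param cycle_index 1-based cycle number.
#' @param n_f2_total F2 population size per cycle (default 200).
#' @param n_f1_sim,n_f2_sim,k simulated-progeny layout for S strategies.
#' @param direction `"high"` or `"low"`.
#' @param n_folds cross-validation folds for model refits.
#' @return List with `population` (the new F2), `model`, and `record`
#'   (one-row data frame: `cycle`, metrics, `model_updated`).
#' @export
run_cycle <- function(pop, model, strategy, arch, h2, cycle_index,
                      n_f2_total = 200, n_f1_sim = 5, n_f2_sim = 40,
                      k = 10, direction = "high", n_folds = 10) {
  updated <- FALSE
  if (cycle_index %% 2 == 1 || is.null(model)) {
    ph <- phenotype_population(pop, arch, h2)
    model <- fit_prediction_model(genotype_codes(pop), ph$phenotype,
                                  n_folds)
    updated <- TRUE
  }
  plan <- select_strategy(pop, model, strategy, n_f1_sim, n_f2_sim, k,
                          direction)
  new_pop <- next_generation(plan, pop, n_f2_total)
  record <- cbind(data.frame(cycle = cycle_index),
                  compute_metrics(new_pop, model, arch),
                  data.frame(model_updated = updated))
  list(population = new_pop, model = model, record = record)
}

#' Run a full recurrent-selection scheme
#'
#' Runs `n_cycles` selection cycles from an initial population, recording
#' the initial population as cycle 0 and each cycle's F2 population as
#' cycles 1..n. Once every QTL is fixed, later cycles carry the last
#' record forward unchanged (crossing identical fully inbred plants cannot
#' create variation), mirroring how fixed replicates are handled when
#' selection runs to a fixed horizon.
#'
#' @param pop0 initial `population`.
#' @param arch true `trait_arch` (scaled).
#' @param h2 heritability.
#' @param strategy strategy label.
#' @param n_cycles number of selection cycles (default 5).
#' @inheritParams run_cycle
#' @return Data frame of cycle records (rows: cycle 0..n_cycles).
#' @export
run_scheme <- function(pop0, arch, h2, strategy, n_cycles = 5,
                       n_f2_total = 200, n_f1_sim = 5, n_f2_sim = 40,
                       k = 10, direction = "high", n_folds = 10) {
  pop <- pop0
  model <- NULL
  records <- vector("list", n_cycles + 1)
  last <- NULL
  for (cyc in seq_len(n_cycles)) {
    if (!is.null(last) && all_qtl_fixed(pop)) {
      rec <- last
      rec$cycle <- cyc
      rec$model_updated <- FALSE
      records[[cyc + 1]] <- rec
      last <- rec
      next
    }
    step <- run_cycle(pop, model, strategy, arch, h2, cyc, n_f2_total,
                      n_f1_sim, n_f2_sim, k, direction, n_folds)
    if (cyc == 1) {
      records[[1]] <- cbind(data.frame(cycle = 0),
                            compute_metrics(pop, step$model, arch),
                            data.frame(model_updated = FALSE))
    }
    pop <- step$population
    model <- step$model
    records[[cyc + 1]] <- step$record
    last <- step$record
  }
  do.call(rbind, records)
}

#' Run the replicated strategy-comparison experiment
#'
#' For every condition (each combination of `n_qtl` and `h2`) and each of
#' `n_replicates` replicates, builds one genome, trait architecture and
#' initial 200-plant F8 population (with effects scaled to unit genetic
#' variance on it), then runs every strategy from that identical starting
#' population with its own downstream random stream. Populations that share
#' a replicate are therefore matched pairs: strategies differ only in their
#' selection decisions.
#'
#' @param strategies character vector of strategy labels.
#' @param n_qtl vector of QTL counts to simulate (conditions).
#' @param h2 vector of heritabilities (conditions).
#' @param n_replicates independent replications per condition.
#' @param n_cycles selection cycles per run.
#' @param n_pop initial (and per-cycle F2) population size.
#' @param n_groups,length_cM genome layout.
#' @param n_f1_sim,n_f2_sim,k simulated-progeny layout for S strategies.
#' @param direction `"high"` or `"low"`.
#' @param n_folds cross-validation folds.
#' @param seed optional integer seed; the whole experiment is reproducible
#'   from it.
#' @return Long-format data frame: `strategy`, `n_qtl`, `h2`, `replicate`,
#'   `cycle` (0..n_cycles), `mgv`, `prop_fixed_fav`, `prop_fixed_unfav`,
#'   `prop_unfixed`, `accuracy`, `model_updated`.
#' @examples
#' \donttest{
#' res <- run_experiment(c("S1", "P1"), n_qtl = 10, h2 = 1,
#'                       n_replicates = 2, n_cycles = 2, n_pop = 40,
#'                       n_f1_sim = 2, n_f2_sim = 10, k = 5, seed = 1)
#' }
#' @export
run_experiment <- function(strategies = c("S1", "S5", "S10",
                                          "P1", "P5", "P10"),
                           n_qtl = 30, h2 = 1, n_replicates = 50,
                           n_cycles = 5, n_pop = 200, n_groups = 20,
                           length_cM = 150, n_f1_sim = 5, n_f2_sim = 40,
                           k = 10, direction = "high", n_folds = 10,
                           seed = NULL) {
  stopifnot(length(strategies) >= 1, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  conds <- expand.grid(n_qtl = n_qtl, h2 = h2)
  n_strat <- length(strategies)
  # one base seed per (condition, replicate) plus one per strategy run,
  # drawn up front so set.seed() inside the loops cannot disturb the stream
  n_runs <- nrow(conds) * n_replicates
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             n_runs * (1L + n_strat)),
                  nrow = n_runs)
  out <- vector("list", n_runs * n_strat)
  slot <- 1L
  run <- 0L
  for (ci in seq_len(nrow(conds))) {
    for (rep_i in seq_len(n_replicates)) {
      run <- run + 1L
      set.seed(seeds[run, 1])
      map <- build_genome(n_groups, length_cM, conds$n_qtl[ci])
      arch <- sample_effects(map)
      pop0 <- make_initial_population(map, n_pop)
      arch <- scale_effects(arch, pop0)
      for (si in seq_len(n_strat)) {
        set.seed(seeds[run, 1L + si])
        rec <- run_scheme(pop0, arch, conds$h2[ci], strategies[si],
                          n_cycles, n_pop, n_f1_sim, n_f2_sim, k,
                          direction, n_folds)
        out[[slot]] <- cbind(data.frame(strategy = strategies[si],
                                        n_qtl = conds$n_qtl[ci],
                                        h2 = conds$h2[ci],
                                        replicate = rep_i,
                                        stringsAsFactors = FALSE),
                             rec)
        slot <- slot + 1L
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Matched-pair t-test with Bonferroni adjustment
#'
#' Paired two-sided t-test on per-replicate values of two strategies (e.g.
#' maximum genetic values at a fixed cycle, where the pairing comes from
#' strategies sharing identical initial populations within a replicate),
#' with the p-value Bonferroni-adjusted for `n_comparisons` tests. When all
#' pairwise differences are zero the test statistic is reported as 0 with
#' p = 1.
#'
#' @param a,b numeric vectors of equal length (>= 2), paired by position.
#' @param n_comparisons number of simultaneous comparisons for the
#'   Bonferroni correction (default 1).
#' @return One-row data frame: `t`, `df`, `p`, `p_adjusted`.
#' @examples
#' matched_pair_test(c(1, 2, 3), c(0, 0, 0))
#' @export
matched_pair_test <- function(a, b, n_comparisons = 1) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (all(d == 0)) {
    t_stat <- 0
    p <- 1
  } else if (sd(d) == 0) {
    t_stat <- sign(mean(d)) * Inf
    p <- 0
  } else {
    tt <- t.test(a, b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  data.frame(t = t_stat, df = length(d) - 1, p = p,
             p_adjusted = min(1, p * n_comparisons))
}

#' Pairwise strategy comparison table
#'
#' Runs [matched_pair_test()] on the MGVs of every strategy pair at every
#' cycle of an experiment result, Bonferroni-adjusting over all tests
#' performed.
#'
#' @param result data frame from [run_experiment()] (one condition).
#' @param cycles cycles to compare (defaults to all recorded cycles > 0).
#' @return Data frame `cycle`, `strategy_a`, `strategy_b`, `t`, `p`,
#'   `p_bonferroni`.
#' @export
compare_strategies <- function(result, cycles = NULL) {
  cycles <- cycles %||% setdiff(sort(unique(result$cycle)), 0)
  strategies <- unique(result$strategy)
  pairs <- enumerate_crosses(strategies)
  n_comp <- nrow(pairs) * length(cycles)
  rows <- list()
  for (cyc in cycles) {
    for (pi in seq_len(nrow(pairs))) {
      sa <- pairs$parent1[pi]
      sb <- pairs$parent2[pi]
      a <- result$mgv[result$strategy == sa & result$cycle == cyc]
      b <- result$mgv[result$strategy == sb & result$cycle == cyc]
      tt <- matched_pair_test(a, b, n_comp)
      rows[[length(rows) + 1L]] <-
        data.frame(cycle = cyc, strategy_a = sa, strategy_b = sb,
                   t = tt$t, p = tt$p, p_bonferroni = tt$p_adjusted,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write an experiment result table
#'
#' Long-format tab-separated results as produced by [run_experiment()].
#'
#' @param result data frame of cycle records.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_results <- function(result, path) {
  df <- result
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}
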