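# Diploid individuals and populations: two founder-labelled haplotypes per
# individual over the mapped loci, stored as L x n integer matrices
# (0 = founder allele A, 1 = founder allele B).

new_population <- function(hap1, hap2, map, ids,
                           generation = NA_character_) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  stopifnot(identical(dim(hap1), dim(hap2)),
            nrow(hap1) == nrow(map), ncol(hap1) == length(ids))
  if (!all(hap1 %in% c(0L, 1L)) || !all(hap2 %in% c(0L, 1L)))
    stop("haplotype values must be 0 (A) or 1 (B)")
  dimnames(hap1) <- dimnames(hap2) <- list(map$locus, ids)
  structure(list(hap1 = hap1, hap2 = hap2, ids = as.character(ids),
                 generation = generation, map = map),
            class = "population")
}

#' Number of individuals in a population
#' @param pop a `population`.
#' @return Integer count.
#' @export
n_individuals <- function(pop) ncol(pop$hap1)

#' Subset a population
#' @param x a `population`.
#' @param i individual indices (or ids).
#' @param ... ignored.
#' @return A `population` containing the selected individuals.
#' @export
`[.population` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  new_population(x$hap1[, i, drop = FALSE], x$hap2[, i, drop = FALSE],
                 x$map, x$ids[i], x$generation)
}

#' Extract one individual
#' @param pop a `population`.
#' @param i index or id of the individual.
#' @return A single-member `population`.
#' @export
get_individual <- function(pop, i) pop[i]

#' The all-heterozygous founder F1
#'
#' A single individual carrying one all-A and one all-B haplotype, so that
#' every mapped locus segregates in its selfed progeny. Starting point of
#' the biparental simulated populations.
#'
#' @param map a `genetic_map`.
#' @return A single-member `population` labelled "F1".
#' @export
founder_f1 <- function(map) {
  L <- nrow(map)
  new_population(matrix(0L, L, 1), matrix(1L, L, 1), map, "F1_founder", "F1")
}

#' Sample meiotic gametes from one individual
#'
#' Each gamete is drawn under the Haldane model: on every linkage group the
#' starting parental phase is chosen with probability 1/2 and the phase
#' switches between consecutive loci with the recombination fraction implied
#' by their map distance (no crossover interference).
#'
#' @param ind a single-member `population`.
#' @param n number of gametes.
#' @return An L x n integer matrix of founder-allele labels
#'   (0 = A, 1 = B), rownames = locus ids.
#' @export
sample_gametes <- function(ind, n = 1) {
  stopifnot(n_individuals(ind) == 1, n >= 1)
  rec <- map_recomb(ind$map)
  g <- cpp_meiosis(ind$hap1, ind$hap2, rep(1L, n), rec$first, rec$r)
  rownames(g) <- ind$map$locus
  g
}

#' @rdname sample_gametes
#' @return `sample_gamete` returns one named integer vector.
#' @export
sample_gamete <- function(ind) drop(sample_gametes(ind, 1))

#' Cross two individuals
#'
#' Offspring receive one gamete from each parent. Both parents must live on
#' the identical genetic map.
#'
#' @param p1,p2 single-member `population`s on the same map.
#' @param n_offspring number of offspring to generate.
#' @param ids optional offspring ids.
#' @return A `population` of `n_offspring` F1 individuals.
#' @export
cross <- function(p1, p2, n_offspring = 1, ids = NULL) {
  stopifnot(n_individuals(p1) == 1, n_individuals(p2) == 1)
  if (!identical(as.data.frame(p1$map), as.data.frame(p2$map)))
    stop("parents are defined on different genetic maps")
  rec <- map_recomb(p1$map)
  h1 <- cpp_meiosis(p1$hap1, p1$hap2, rep(1L, n_offspring), rec$first, rec$r)
  h2 <- cpp_meiosis(p2$hap1, p2$hap2, rep(1L, n_offspring), rec$first, rec$r)
  ids <- ids %||% sprintf("%sx%s_%03d", p1$ids, p2$ids,
                          seq_len(n_offspring))
  new_population(h1, h2, p1$map, ids, "F1")
}

#' Self-pollinate an individual
#'
#' Equivalent to crossing the individual with itself.
#'
#' @param p a single-member `population`.
#' @param n_offspring number of selfed offspring.
#' @param ids optional offspring ids.
#' @return A `population` of selfed offspring.
#' @export
self_cross <- function(p, n_offspring = 1, ids = NULL) {
  ids <- ids %||% sprintf("%s_self_%03d", p$ids, seq_len(n_offspring))
  cross(p, p, n_offspring, ids)
}

#' Advance a population by single-seed descent
#'
#' Each individual is replaced by one selfed offspring, repeated for
#' `n_generations` rounds; expected heterozygosity halves per round.
#'
#' @param pop a `population`.
#' @param n_generations number of selfing rounds (>= 0).
#' @return A `population` of the same size.
#' @export
ssd_advance <- function(pop, n_generations) {
  stopifnot(n_generations >= 0)
  if (n_generations == 0) return(pop)
  rec <- map_recomb(pop$map)
  s <- cpp_self_rounds(pop$hap1, pop$hap2, rec$first, rec$r,
                       as.integer(n_generations))
  new_population(s$hap1, s$hap2, pop$map, pop$ids, pop$generation)
}

#' Create the initial inbred population
#'
#' One fully heterozygous founder F1 is selfed to produce `n` independent F2
#' individuals, each of which is advanced by single-seed descent through six
#' further selfing generations to F8 (seven meioses from the F1 in total, so
#' the expected residual per-locus heterozygosity is 2^-7, about 0.78%).
#'
#' @param map a `genetic_map`.
#' @param n population size (>= 2); 200 by default.
#' @return A `population` of `n` F8 individuals.
#' @examples
#' set.seed(1)
#' pop <- make_initial_population(build_genome(5, 150, 10), n = 20)
#' @export
make_initial_population <- function(map, n = 200) {
  if (n < 2) stop("initial population needs n >= 2")
  f1 <- founder_f1(map)
  rec <- map_recomb(map)
  h1 <- cpp_meiosis(f1$hap1, f1$hap2, rep(1L, n), rec$first, rec$r)
  h2 <- cpp_meiosis(f1$hap1, f1$hap2, rep(1L, n), rec$first, rec$r)
  s <- cpp_self_rounds(h1, h2, rec$first, rec$r, 6L)
  w <- max(3L, nchar(as.character(n)))
  new_population(s$hap1, s$hap2, map, sprintf("F8_%0*d", w, seq_len(n)),
                 "F8")
}

#' Genotype codes of a population
#'
#' Founder-allele based coding: +1 for the AA homozygote, 0 for the
#' heterozygote, -1 for the BB homozygote, independent of which allele is
#' favorable.
#'
#' @param pop a `population`.
#' @param loci optional locus ids to restrict to (kept in map order).
#' @return An n x L integer matrix (individuals x loci).
#' @export
genotype_codes <- function(pop, loci = NULL) {
  codes <- t(1L - (pop$hap1 + pop$hap2))
  if (!is.null(loci)) {
    m <- match(loci, colnames(codes))
    if (anyNA(m))
      stop("unknown loci: ", paste(loci[is.na(m)], collapse = ", "))
    codes <- codes[, sort(m), drop = FALSE]
  }
  codes
}

#' Genetic values of a population
#'
#' Sum over loci of the true additive effect times the genotype code, with
#' the sign arranged so that the favorable homozygote contributes
#' `+effect` per locus.
#'
#' @param pop a `population`.
#' @param arch a `trait_arch` defined on the same loci.
#' @return Numeric vector named by individual id, trait units.
#' @export
genetic_values <- function(pop, arch) {
  if (!identical(arch$locus, pop$map$locus))
    stop("trait architecture loci do not match the population map")
  drop(genotype_codes(pop) %*% signed_effects(arch))
}

#' Mean fraction of heterozygous loci
#' @param pop a `population`.
#' @return Proportion of (individual, locus) pairs that are heterozygous.
#' @export
heterozygosity <- function(pop) mean(pop$hap1 != pop$hap2)

#' @exportS3Method base::print
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals x %d loci (generation %s)\n",
              n_individuals(x), nrow(x$map), x$generation))
  cat(sprintf("  heterozygosity %.4f; ids %s%s\n", heterozygosity(x),
              paste(utils::head(x$ids, 3), collapse = ", "),
              if (n_individuals(x) > 3) ", ..." else ""))
  invisible(x)
}
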