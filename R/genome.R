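# Genome construction: genetic map and additive QTL architecture.

new_genetic_map <- function(loci, group_len) {
  stopifnot(is.data.frame(loci),
            all(c("locus", "group", "pos") %in% names(loci)))
  if (any(group_len <= 0)) stop("all linkage-group lengths must be > 0")
  if (anyDuplicated(loci$locus)) stop("duplicate locus ids in map")
  if (any(loci$pos < 0)) stop("negative map position")
  len <- group_len[as.character(loci$group)]
  if (anyNA(len)) stop("locus assigned to unknown linkage group")
  if (any(loci$pos > len)) stop("locus position beyond its group length")
  ord <- order(loci$group, loci$pos)
  loci <- loci[ord, c("locus", "group", "pos")]
  rownames(loci) <- NULL
  structure(loci, group_len = group_len,
            class = c("genetic_map", "data.frame"))
}

#' Build a random QTL genome
#'
#' Places `n_qtl` loci on `n_groups` linkage groups of equal length. Each
#' locus is assigned a group uniformly at random and a continuous position
#' uniform on `[0, length_cM]`; loci are then ordered within group. The
#' default genome (20 groups of 150 cM) is the standard simulated plant
#' genome used for benchmarking selection schemes.
#'
#' @param n_groups number of linkage groups (chromosome pairs).
#' @param length_cM map length of every group, in centimorgans.
#' @param n_qtl number of loci to place.
#' @return A `genetic_map`: a data frame with columns `locus`, `group`,
#'   `pos` (cM), sorted by (group, position), carrying the per-group map
#'   lengths as attribute `group_len`.
#' @examples
#' set.seed(1)
#' map <- build_genome(20, 150, 30)
#' head(map)
#' @export
build_genome <- function(n_groups = 20, length_cM = 150, n_qtl = 30) {
  if (n_groups < 1 || n_qtl < 1 || length_cM <= 0)
    stop("n_groups and n_qtl must be >= 1 and length_cM > 0")
  group <- sample.int(n_groups, n_qtl, replace = TRUE)
  pos <- runif(n_qtl, 0, length_cM)
  ord <- order(group, pos)
  w <- max(3L, nchar(as.character(n_qtl)))
  loci <- data.frame(locus = sprintf("Q%0*d", w, seq_len(n_qtl)),
                     group = group[ord], pos = pos[ord],
                     stringsAsFactors = FALSE)
  new_genetic_map(loci, setNames(rep(length_cM, n_groups),
                                 as.character(seq_len(n_groups))))
}

#' Haldane map function
#'
#' Recombination fraction between two loci `d_cM` centimorgans apart under
#' the Haldane (no crossover interference) model:
#' \eqn{r = (1 - e^{-2d/100})/2}.
#'
#' @param d_cM map distance in centimorgans.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# Per-locus recombination structure used by the meiosis core: for each locus
# (optionally restricted to a subset, kept in map order) whether it starts a
# linkage group and the Haldane recombination fraction to the previous
# retained locus. Restriction is exact: the phase process is Markov along a
# group, so the marginal law at a locus subset only needs the inter-locus
# distances of the retained loci.
map_recomb <- function(map, loci = NULL) {
  df <- as.data.frame(map)
  idx <- seq_len(nrow(df))
  if (!is.null(loci)) {
    m <- match(loci, df$locus)
    if (anyNA(m))
      stop("loci not on the map: ", paste(loci[is.na(m)], collapse = ", "))
    idx <- sort(m)
    df <- df[idx, ]
  }
  first <- !duplicated(df$group)
  d <- c(0, diff(df$pos))
  d[first] <- 0
  r <- haldane_r(d)
  r[first] <- 0
  list(first = as.integer(first), r = r, idx = idx,
       loci = df$locus)
}

#' Sample additive QTL effects
#'
#' Draws one additive-effect magnitude per mapped locus from a gamma
#' distribution (defaults: shape 0.4, scale 1.66, the classical heavy-tailed
#' architecture with many small and few large effects) and assigns each
#' locus a favorable founder allele.
#'
#' @param map a `genetic_map`.
#' @param shape,scale gamma distribution parameters (both > 0).
#' @param sign_mode `"random"` assigns the favorable allele to founder A or
#'   B with probability 1/2 each (both founders contribute favorable
#'   alleles, as in a real biparental cross); `"all_positive"` makes founder
#'   A favorable everywhere (the symmetric textbook architecture).
#' @return A `trait_arch`: data frame with columns `locus`, `effect`
#'   (magnitude, trait units per favorable-allele dose) and `favorable`
#'   ("A"/"B"), with attribute `scaled = FALSE`.
#' @examples
#' set.seed(1)
#' arch <- sample_effects(build_genome(2, 100, 5))
#' @export
sample_effects <- function(map, shape = 0.4, scale = 1.66,
                           sign_mode = c("random", "all_positive")) {
  sign_mode <- match.arg(sign_mode)
  if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0")
  n <- nrow(map)
  eff <- rgamma(n, shape = shape, scale = scale)
  fav <- if (sign_mode == "random") {
    sample(c("A", "B"), n, replace = TRUE)
  } else {
    rep("A", n)
  }
  structure(data.frame(locus = map$locus, effect = eff, favorable = fav,
                       stringsAsFactors = FALSE),
            scaled = FALSE, class = c("trait_arch", "data.frame"))
}

#' Signed per-locus effects
#'
#' Effect of one dose of the founder-A allele at each locus: `+effect` where
#' founder A carries the favorable allele, `-effect` otherwise. Genotype
#' codes are founder-based (+1 = AA), so the genetic value of an individual
#' is `codes %*% signed_effects(arch)`.
#'
#' @param arch a `trait_arch`.
#' @return Numeric vector named by locus.
#' @export
signed_effects <- function(arch) {
  setNames(ifelse(arch$favorable == "A", 1, -1) * arch$effect, arch$locus)
}

#' Scale effects so a reference population has unit genetic variance
#'
#' Multiplies every effect by the single constant `1/sd(GV)` computed on a
#' reference population, so that the variance of genetic values in that
#' population becomes exactly 1. Scaling the architecture against the
#' initial population pins the simulation's trait scale (and hence the
#' environmental variance implied by a heritability) to the starting
#' genetic variance.
#'
#' @param arch a `trait_arch` (unscaled).
#' @param reference_pop a `population` with at least 2 members and nonzero
#'   genetic variance under `arch`.
#' @return The rescaled `trait_arch`, with attribute `scaled = TRUE`.
#' @export
scale_effects <- function(arch, reference_pop) {
  if (n_individuals(reference_pop) < 2)
    stop("reference population must contain at least 2 individuals")
  gv <- genetic_values(reference_pop, arch)
  v <- var(gv)
  if (!is.finite(v) || v <= .Machine$double.eps)
    stop("degenerate reference population: zero genetic variance")
  arch$effect <- arch$effect / sqrt(v)
  attr(arch, "scaled") <- TRUE
  arch
}

#' Largest attainable genetic value
#'
#' The genetic value of an individual homozygous favorable at every locus,
#' `sum(|effect|)`; an upper bound for every simulated individual.
#'
#' @param arch a `trait_arch`.
#' @return Single number, trait units.
#' @export
max_genetic_value <- function(arch) sum(abs(arch$effect))

#' @exportS3Method base::print
print.genetic_map <- function(x, ...) {
  len <- attr(x, "group_len")
  cat(sprintf("genetic_map: %d loci on %d linkage groups (%s cM)\n",
              nrow(x), length(len),
              paste(unique(unname(len)), collapse = "/")))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more loci\n", nrow(x) - 6L))
  invisible(x)
}

#' @exportS3Method base::print
print.trait_arch <- function(x, ...) {
  cat(sprintf("trait_arch: %d loci, max GV %.4g, %s\n", nrow(x),
              max_genetic_value(x),
              if (isTRUE(attr(x, "scaled"))) "scaled to unit reference variance"
              else "unscaled"))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more loci\n", nrow(x) - 6L))
  invisible(x)
}
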