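# Synthetic empirical-mode fixture: a biparental RIL panel with the shape
# of a typical selfing-crop breeding panel (194 F8 lines genotyped at 513
# mapped SNPs, 29 of which enter the marker-effect model).

#' Generate a synthetic RIL-panel fixture for empirical-mode runs
#'
#' Simulates a biparental recombinant-inbred-line panel by selfing a fully
#' heterozygous F1 and advancing each F2 by single-seed descent to F8 over
#' a marker map of `n_markers` SNPs, then assigns gamma-distributed
#' additive effects to a random subset of `n_effect_markers` markers,
#' scales them to unit genetic variance on the panel, phenotypes the panel
#' at heritability `h2` around a baseline trait value (on a percent scale,
#' like seed protein content), and fits the L1-penalized model on the
#' effect markers. All empirical-mode inputs are written as tab-separated
#' text, so cross ranking can run with no external data.
#'
#' @param dir output directory (created if needed).
#' @param n_lines number of RILs.
#' @param n_markers total mapped markers.
#' @param n_effect_markers markers carrying effects / entering the model.
#' @param n_groups,length_cM marker-map layout.
#' @param h2 heritability of the simulated panel phenotypes.
#' @param baseline intercept added to all trait values (percent scale).
#' @param seed optional integer seed; fixed seed gives byte-identical
#'   files.
#' @return Invisibly, a list with the written `paths` (map, genotypes,
#'   model, phenotypes) and the underlying objects (`map`, `population`,
#'   `arch`, `model`, `phenotypes`).
#' @examples
#' fx <- generate_fixture(tempfile("fx"), n_lines = 6, n_markers = 8,
#'                        n_effect_markers = 3, n_groups = 2, seed = 1)
#' @export
generate_fixture <- function(dir, n_lines = 194, n_markers = 513,
                             n_effect_markers = 29, n_groups = 20,
                             length_cM = 150, h2 = 0.6, baseline = 43,
                             seed = NULL) {
  if (n_effect_markers > n_markers)
    stop("n_effect_markers cannot exceed n_markers")
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  map <- build_genome(n_groups, length_cM, n_markers)
  map$locus <- sprintf("M%0*d", max(3L, nchar(as.character(n_markers))),
                       seq_len(n_markers))
  rownames(map) <- NULL
  pop <- make_initial_population(map, n_lines)
  pop$ids <- sprintf("RIL%0*d", max(3L, nchar(as.character(n_lines))),
                     seq_len(n_lines))
  colnames(pop$hap1) <- colnames(pop$hap2) <- pop$ids

  effect_loci <- sort(sample.int(n_markers, n_effect_markers))
  arch <- sample_effects(map)
  arch$effect[-effect_loci] <- 0
  arch <- scale_effects(arch, pop)

  gv <- genetic_values(pop, arch)
  pheno <- sim_phenotypes(setNames(baseline + gv, pop$ids), h2)

  eff_ids <- map$locus[effect_loci]
  model <- if (n_effect_markers >= 2 && n_lines >= 10) {
    fit_prediction_model(genotype_codes(pop, eff_ids), pheno$phenotype)
  } else {
    new_prediction_model(mean(pheno$phenotype),
                         setNames(signed_effects(arch)[effect_loci],
                                  eff_ids),
                         NA_real_, n_lines)
  }

  paths <- list(map = file.path(dir, "map.tsv"),
                genotypes = file.path(dir, "genotypes.tsv"),
                model = file.path(dir, "model.tsv"),
                phenotypes = file.path(dir, "phenotypes.tsv"))
  write_map(map, paths$map)
  write_genotypes(genotype_codes(pop), paths$genotypes)
  write_model(model, paths$model)
  write_phenotypes(pheno, paths$phenotypes)
  invisible(list(paths = paths, map = map, population = pop, arch = arch,
                 model = model, phenotypes = pheno))
}

#' Assemble a population from a genotype table and map
#'
#' Reconstructs a fully inbred (RIL) population from genotype codes: codes
#' +1 / -1 become the corresponding homozygote; heterozygous codes (0) get
#' one A and one B haplotype. For inbred panels this is lossless. Genotype
#' codes carry no phase, and phase across linked loci matters in meiosis,
#' so panels with substantial heterozygosity should be loaded with the
#' haplotype reader ([read_population()]) instead; a warning is issued
#' above 1% heterozygous cells.
#'
#' @param codes n x m code matrix (individuals x markers).
#' @param map a `genetic_map` covering the markers.
#' @param generation generation label.
#' @return A `population`.
#' @export
population_from_codes <- function(codes, map, generation = "RIL") {
  m <- match(map$locus, colnames(codes))
  if (anyNA(m))
    stop("genotype table is missing mapped markers: ",
         paste(map$locus[is.na(m)], collapse = ", "))
  codes <- codes[, m, drop = FALSE]
  het <- mean(codes == 0)
  if (het > 0.01)
    warning(sprintf(paste0("%.1f%% heterozygous genotypes: phase across ",
                           "linked loci is assigned arbitrarily; prefer ",
                           "read_population() for haplotype data"),
                    100 * het))
  h1 <- t(ifelse(codes == 1, 0L, ifelse(codes == -1, 1L, 0L)))
  h2 <- t(ifelse(codes == 1, 0L, 1L))
  new_population(h1, h2, map, rownames(codes) %||%
                   as.character(seq_len(nrow(codes))), generation)
}
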