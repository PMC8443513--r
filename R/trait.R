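# Phenotypes: genetic value plus independent normal environmental noise
# whose variance is set by the heritability.

#' Simulate phenotypes for given genetic values
#'
#' Environmental deviations are drawn independently from
#' `Normal(0, sigma2_e)` with `sigma2_e = sigma2_g * (1 - h2) / h2`, i.e.
#' the noise variance implied by a narrow-sense heritability `h2` at a
#' reference genetic variance `sigma2_g` (1 after effect scaling). At
#' `h2 = 1` the phenotype equals the genetic value exactly. The reference
#' genetic variance, not the current population's, sets the noise level, so
#' the measurement-error scale stays constant while genetic variance erodes
#' over selection cycles.
#'
#' @param gv numeric vector of genetic values (names taken as ids).
#' @param h2 heritability, in (0, 1].
#' @param sigma2_g reference genetic variance (default 1).
#' @return Data frame with columns `id`, `gv`, `env`, `phenotype`
#'   (`phenotype = gv + env`).
#' @examples
#' set.seed(1)
#' sim_phenotypes(c(a = 0.2, b = -0.5), h2 = 0.6)
#' @export
sim_phenotypes <- function(gv, h2, sigma2_g = 1) {
  if (!is.numeric(h2) || length(h2) != 1 || h2 <= 0 || h2 > 1)
    stop("h2 must be a single value in (0, 1]")
  s2e <- sigma2_g * (1 - h2) / h2
  env <- if (s2e == 0) rep(0, length(gv)) else rnorm(length(gv), 0, sqrt(s2e))
  data.frame(id = names(gv) %||% as.character(seq_along(gv)),
             gv = as.numeric(gv), env = env,
             phenotype = as.numeric(gv) + env,
             stringsAsFactors = FALSE)
}

#' Phenotype every member of a population
#'
#' Computes genetic values under `arch` and adds fresh environmental noise
#' via [sim_phenotypes()]. Noise is redrawn on every call (each cycle's
#' phenotyping is an independent trial).
#'
#' @param pop a `population`.
#' @param arch a `trait_arch` on the same loci.
#' @param h2 heritability in (0, 1].
#' @param sigma2_g reference genetic variance (default 1).
#' @return Data frame as in [sim_phenotypes()].
#' @export
phenotype_population <- function(pop, arch, h2, sigma2_g = 1) {
  sim_phenotypes(setNames(genetic_values(pop, arch), pop$ids), h2, sigma2_g)
}

#' Write / read a phenotype table
#'
#' Tab-separated `individual_id  gv  phenotype` (the `gv` column may be
#' absent in empirical data).
#'
#' @param pheno data frame with columns `id`, `phenotype` and optionally
#'   `gv`.
#' @param path file path.
#' @return `read_phenotypes` returns the data frame; writers return the
#'   path invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  cols <- intersect(c("id", "gv", "phenotype"), names(pheno))
  write.table(pheno[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("id", "phenotype") %in% names(df)))
    stop("phenotype file must have 'id' and 'phenotype' columns: ", path)
  df
}
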