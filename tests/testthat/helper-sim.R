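# Shared builders for small, fully specified genomes and populations.
# Everything goes through the package's public text formats so the tests
# also exercise the readers.

# A genetic map with explicit loci: positions is a list of numeric vectors,
# one per linkage group.
toy_map <- function(positions, ids = NULL) {
  pos <- unlist(positions)
  grp <- rep(seq_along(positions), lengths(positions))
  ids <- ids %||% sprintf("L%02d", seq_along(pos))
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(locus_id = ids, group = grp, pos_cM = pos),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_map(path)
}

# A trait architecture with explicit effects / favorable alleles.
toy_arch <- function(map, effect, favorable = "A") {
  favorable <- rep_len(favorable, nrow(map))
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(locus_id = map$locus, effect = effect,
                         favorable_allele = favorable),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_effects(path)
}

# A fully specified (possibly heterozygous) population from a code matrix;
# rows = individuals, columns = loci in map order.
toy_pop <- function(map, codes, ids = NULL) {
  codes <- matrix(codes, ncol = nrow(map))
  rownames(codes) <- ids %||% sprintf("I%02d", seq_len(nrow(codes)))
  colnames(codes) <- map$locus
  suppressWarnings(population_from_codes(codes, map))
}

# A prediction model with explicit intercept / coefficients.
toy_model <- function(intercept, coefficients) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(sprintf("#intercept %s lambda 0.1", format(intercept)),
               "marker_id\tcoefficient",
               sprintf("%s\t%s", names(coefficients),
                       vapply(coefficients, format, ""))), path)
  read_model(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
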