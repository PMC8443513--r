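# File interchange: genetic maps, genotype tables and population
# haplotypes as plain tab-separated text.

#' Write / read a genetic map
#'
#' Tab-separated `locus_id  group  pos_cM`. On read, loci are validated and
#' sorted by (group, position); each group's map length is taken as the
#' largest observed position in the group (positions, not physical
#' coordinates, define the map).
#'
#' @param map a `genetic_map`.
#' @param path file path.
#' @return `read_map` returns a `genetic_map`; `write_map` returns the
#'   path invisibly.
#' @export
write_map <- function(map, path) {
  df <- data.frame(locus_id = map$locus, group = map$group,
                   pos_cM = format(map$pos, digits = 17, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("locus_id", "group", "pos_cM")
  if (!all(need %in% names(df)))
    stop("map file must have columns locus_id, group, pos_cM: ", path)
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus id in map file: ",
         df$locus_id[duplicated(df$locus_id)][1])
  if (any(df$pos_cM < 0)) stop("negative map position in ", path)
  loci <- data.frame(locus = as.character(df$locus_id), group = df$group,
                     pos = as.numeric(df$pos_cM), stringsAsFactors = FALSE)
  len <- tapply(loci$pos, loci$group, max)
  len[len <= 0] <- 1
  new_genetic_map(loci, setNames(as.numeric(len), names(len)))
}

#' Write / read a trait architecture
#'
#' Tab-separated `locus_id  effect  favorable_allele`.
#'
#' @param arch a `trait_arch`.
#' @param path file path.
#' @return `read_effects` returns a `trait_arch` (marked unscaled);
#'   `write_effects` returns the path invisibly.
#' @export
write_effects <- function(arch, path) {
  df <- data.frame(locus_id = arch$locus,
                   effect = format(arch$effect, digits = 17, trim = TRUE),
                   favorable_allele = arch$favorable)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("locus_id", "effect", "favorable_allele")
  if (!all(need %in% names(df)))
    stop("effects file must have columns locus_id, effect, ",
         "favorable_allele: ", path)
  structure(data.frame(locus = as.character(df$locus_id),
                       effect = as.numeric(df$effect),
                       favorable = as.character(df$favorable_allele),
                       stringsAsFactors = FALSE),
            scaled = FALSE, class = c("trait_arch", "data.frame"))
}

#' Write a genotype code table
#'
#' Tab-separated table with an `id` column followed by one column per
#' marker, values in `{-1, 0, 1}`.
#'
#' @param codes n x m code matrix with individual ids as rownames and
#'   marker ids as colnames (e.g. from [genotype_codes()]).
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(codes, path) {
  df <- data.frame(id = rownames(codes) %||%
                     as.character(seq_len(nrow(codes))),
                   codes, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Read a genotype table
#'
#' Reads a tab-separated genotype table (first column individual id, one
#' column per marker). Numeric tables must contain only `-1`, `0`, `1`.
#' Allele-pair tables (`"AA"`, `"AB"`, ...) are translated via
#' `allele_key`, a named character vector giving, per marker, which allele
#' letter corresponds to founder allele A; the code is then (number of
#' A-alleles carried) - 1. Without a key, letters `A`/`B` are assumed
#' literally. Missing cells are an error naming the offending row and
#' column (no silent imputation).
#'
#' @param path file path.
#' @param allele_key optional named character vector, marker id ->
#'   founder-A allele letter.
#' @return n x m integer matrix of codes, rownames = individual ids.
#' @export
read_genotypes <- function(path, allele_key = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("genotype file needs an id column plus markers: ",
                         path)
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  markers <- colnames(mat)
  na_idx <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(na_idx)) {
    stop("missing genotype cells at: ",
         paste(sprintf("(%s, %s)", ids[na_idx[, 1]],
                       markers[na_idx[, 2]])[seq_len(min(5,
                                                         nrow(na_idx)))],
               collapse = ", "))
  }
  suppressWarnings(num <- matrix(as.numeric(mat), nrow(mat), ncol(mat)))
  if (!anyNA(num)) {
    if (!all(num %in% c(-1, 0, 1)))
      stop("numeric genotype codes must be -1, 0 or 1: ", path)
    codes <- num
  } else {
    if (any(nchar(mat) != 2))
      stop("genotype strings must be two-letter allele pairs: ", path)
    key <- if (is.null(allele_key)) {
      setNames(rep("A", length(markers)), markers)
    } else {
      miss <- setdiff(markers, names(allele_key))
      if (length(miss))
        stop("allele_key missing markers: ", paste(miss, collapse = ", "))
      allele_key[markers]
    }
    codes <- matrix(0, nrow(mat), ncol(mat))
    for (jcol in seq_along(markers)) {
      a <- key[[jcol]]
      n_a <- (substr(mat[, jcol], 1, 1) == a) +
        (substr(mat[, jcol], 2, 2) == a)
      codes[, jcol] <- n_a - 1
    }
  }
  storage.mode(codes) <- "integer"
  dimnames(codes) <- list(ids, markers)
  codes
}

#' Write / read population haplotypes
#'
#' Lossless round-trip of a population's founder-labelled haplotypes: two
#' rows per individual (`hap` 1 and 2), values `A`/`B` per locus.
#'
#' @param pop a `population`.
#' @param path file path.
#' @param map the `genetic_map` the file's loci refer to (reader only).
#' @param generation generation label for the reconstructed population.
#' @return `read_population` returns a `population`; the writer returns
#'   the path invisibly.
#' @export
write_population <- function(pop, path) {
  lab <- matrix(c("A", "B")[cbind(pop$hap1 + 1L)], nrow(pop$hap1))
  lab2 <- matrix(c("A", "B")[cbind(pop$hap2 + 1L)], nrow(pop$hap2))
  n <- n_individuals(pop)
  rows <- rbind(t(lab), t(lab2))[rep(seq_len(n), each = 2) +
                                   rep(c(0L, n), times = n), ,
                                 drop = FALSE]
  df <- data.frame(id = rep(pop$ids, each = 2),
                   hap = rep(1:2, times = n), rows, check.names = FALSE)
  names(df)[-(1:2)] <- pop$map$locus
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path, map, generation = NA_character_) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "hap") %in% names(df[, 1:2])))
    stop("haplotype file must start with columns id, hap: ", path)
  loci <- names(df)[-(1:2)]
  if (!identical(loci, map$locus))
    stop("haplotype file loci do not match the map")
  ids <- unique(df$id)
  h1 <- t(as.matrix(df[df$hap == 1, -(1:2)] == "B")) * 1L
  h2 <- t(as.matrix(df[df$hap == 2, -(1:2)] == "B")) * 1L
  new_population(h1, h2, map, ids, generation)
}
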