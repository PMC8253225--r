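#' Genotypes and populations
#'
#' A genotype is an `N x 2` binary integer matrix: one row per mapped locus,
#' one column per homolog, `1` marking the desirable allele. A population is
#' an `N x 2 x K` binary array (class `mati_population`) with a generation
#' index. These are abstract desirability indicators, not called variants, so
#' no genotyping file format applies.
#'
#' @param alleles `N x 2` matrix of 0/1 values.
#' @param map The `genetic_map` the genotype refers to.
#' @return An integer `N x 2` matrix (invisibly validated).
#' @export
as_genotype <- function(alleles, map) {
  a <- as.matrix(alleles)
  if (ncol(a) != 2 || nrow(a) != map$n_loci)
    stop("genotype must be an N x 2 matrix matching the map")
  if (!all(a %in% c(0L, 1L))) stop("alleles must be 0 or 1")
  storage.mode(a) <- "integer"
  rownames(a) <- map$marker
  a
}

new_population <- function(geno, generation = 0L) {
  structure(list(geno = geno, K = dim(geno)[3],
                 generation = as.integer(generation)),
            class = "mati_population")
}

#' @export
print.mati_population <- function(x, ...) {
  cs <- colSums(x$geno[, 1, , drop = FALSE] + x$geno[, 2, , drop = FALSE],
                dims = 2)
  cat("Population of", x$K, "individuals at generation", x$generation, "\n")
  cat("  desirable-allele counts: min", min(cs), "max", max(cs),
      "of", 2 * dim(x$geno)[1], "\n")
  invisible(x)
}

#' Construct founder genotypes
#'
#' Builds the homozygous elite recipient and donor for an introgression
#' project: the donor carries the desirable allele (homozygous) exactly at
#' `donor_loci`, the elite at every other locus. The two founders are
#' complementary at every locus, so their F1 is heterozygous throughout.
#'
#' @param map A `genetic_map`.
#' @param donor_loci Character vector of marker names at which only the donor
#'   carries the desirable allele (may be empty, making the elite ideal).
#' @return A list with elements `elite` and `donor`, each an `N x 2` genotype.
#' @examples
#' map <- generate_map(seed = 1)
#' fd <- make_founders(map, c("C1M4", "C1M6", "C2M9", "C3M1",
#'                            "C5M4", "C6M3", "C6M8"))
#' sum(fd$elite) / 2  # loci where the elite is homozygous desirable
#' @export
make_founders <- function(map, donor_loci = character(0)) {
  unknown <- setdiff(donor_loci, map$marker)
  if (length(unknown))
    stop("unknown marker name(s): ", paste(unknown, collapse = ", "))
  donor_row <- map$marker %in% donor_loci
  elite <- matrix(as.integer(!donor_row), map$n_loci, 2)
  donor <- matrix(as.integer(donor_row), map$n_loci, 2)
  list(elite = as_genotype(elite, map), donor = as_genotype(donor, map))
}

#' The ideal genotype
#'
#' Homozygous desirable at every locus (allele sum `2N`).
#'
#' @param map A `genetic_map`.
#' @return An `N x 2` genotype of ones.
#' @export
ideal_genotype <- function(map) {
  as_genotype(matrix(1L, map$n_loci, 2), map)
}

#' Simulate reproduction (meiosis with independent crossovers)
#'
#' Produces `K` progeny of two parents. Each progeny receives one gamete from
#' each parent; a gamete starts on either homolog with probability 1/2 and
#' switches homolog between adjacent loci `i, i+1` independently with
#' probability `f_i`. Because boundary loci have `f = 0.5`, one Markov chain
#' over all loci reproduces independent assortment of chromosomes exactly.
#'
#' Randomness comes from R's global RNG; set `seed` (or call [set.seed()]
#' beforehand) for reproducibility.
#'
#' @param L1,L2 Parent genotypes (`N x 2` matrices matching `map`).
#' @param map A `genetic_map`.
#' @param K Number of progeny (positive integer).
#' @param generation Generation index stored on the result.
#' @param seed Optional integer seed.
#' @return A `mati_population` holding an `N x 2 x K` binary array.
#' @export
reproduce <- function(L1, L2, map, K, generation = 0L, seed = NULL) {
  if (K < 1) stop("K must be a positive integer")
  if (nrow(L1) != map$n_loci || nrow(L2) != map$n_loci)
    stop("genotypes must match the map")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  g1 <- gametes_cpp(L1, map$f, as.integer(K))
  g2 <- gametes_cpp(L2, map$f, as.integer(K))
  geno <- array(0L, dim = c(map$n_loci, 2, K),
                dimnames = list(map$marker, c("hom1", "hom2"), NULL))
  geno[, 1, ] <- g1
  geno[, 2, ] <- g2
  new_population(geno, generation)
}

#' Test for an ideal individual
#'
#' Checks whether any population member is homozygous desirable at all loci
#' (allele sum `2N`), the success condition of the introgression process.
#'
#' @param pop A `mati_population`.
#' @return Logical scalar with attribute `index`: the first ideal member's
#'   index, or `NA_integer_` if none.
#' @export
is_ideal <- function(pop) {
  stopifnot(inherits(pop, "mati_population"))
  if (pop$K < 1) stop("population must be non-empty")
  n2 <- 2L * dim(pop$geno)[1]
  sums <- allele_counts(pop)
  idx <- which(sums == n2)
  structure(length(idx) > 0,
            index = if (length(idx)) idx[1] else NA_integer_)
}

#' Per-individual desirable-allele counts
#'
#' @param pop A `mati_population`.
#' @return Integer vector of length `K`: each member's total count of
#'   desirable alleles (maximum `2N`).
#' @export
allele_counts <- function(pop) {
  as.integer(colSums(pop$geno, dims = 2))
}

#' Read / write genotypes as CSV
#'
#' Genotype files have columns `marker`, `hom1`, `hom2` with 0/1 entries.
#' Population files are long-format tables with columns `generation`,
#' `individual`, `marker`, `hom1`, `hom2`.
#'
#' @param g A genotype (`N x 2` matrix) for writing.
#' @param map A `genetic_map` (for validation on read).
#' @param path File path.
#' @param pop A `mati_population` for writing.
#' @return Readers return the parsed object; writers return `path` invisibly.
#' @export
read_genotype_csv <- function(path, map) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("marker", "hom1", "hom2") %in% names(d)))
    stop("genotype CSV must have columns marker, hom1, hom2")
  if (!identical(as.character(d$marker), map$marker))
    stop("marker order must match the map")
  as_genotype(cbind(d$hom1, d$hom2), map)
}

#' @rdname read_genotype_csv
#' @export
write_genotype_csv <- function(g, path) {
  utils::write.csv(data.frame(marker = rownames(g), hom1 = g[, 1],
                              hom2 = g[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_genotype_csv
#' @export
write_population_csv <- function(pop, path) {
  N <- dim(pop$geno)[1]
  d <- data.frame(generation = pop$generation,
                  individual = rep(seq_len(pop$K), each = N),
                  marker = rep(dimnames(pop$geno)[[1]], pop$K),
                  hom1 = as.vector(pop$geno[, 1, ]),
                  hom2 = as.vector(pop$geno[, 2, ]))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
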