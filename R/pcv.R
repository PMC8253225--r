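#' Predicted cross value (PCV)
#'
#' The PCV of a parental pair is the exact probability that a gamete produced
#' by a random progeny of the cross carries the desirable allele at every
#' locus. It is computed by a forward dynamic program over the 8 joint origin
#' states \eqn{(c_1, c_2, g)}: \eqn{c_1, c_2 \in \{1,2\}} track which homolog
#' each parental gamete currently copies, and \eqn{g \in \{1,2\}} tracks which
#' of the progeny's two chromosomes the final gamete currently copies. The
#' initial distribution is uniform over the 8 states; between adjacent loci
#' each coordinate switches independently with the local recombination
#' frequency; a state survives a locus only if the allele it addresses is
#' desirable. The PCV is the total surviving mass after the last locus.
#'
#' @param L1,L2 Parent genotypes (`N x 2` binary matrices matching `map`).
#' @param map A `genetic_map`.
#' @return An object of class `pcv_value`: list with `p` (probability) and
#'   `log10_p` (`-Inf` when `p = 0`).
#' @examples
#' map <- generate_map(n_chrom = 2, markers_per_chrom = c(3, 3),
#'                     total_markers = 6, seed = 1)
#' fd <- make_founders(map, "C1M2")
#' pcv(fd$elite, fd$donor, map)
#' @export
pcv <- function(L1, L2, map) {
  if (nrow(L1) != map$n_loci || nrow(L2) != map$n_loci)
    stop("genotypes must match the map")
  p <- pcv_cpp(L1, L2, map$f)
  new_pcv_value(p)
}

new_pcv_value <- function(p) {
  structure(list(p = p, log10_p = if (p > 0) log10(p) else -Inf),
            class = "pcv_value")
}

#' @export
print.pcv_value <- function(x, ...) {
  cat(sprintf("PCV = %.6g (log10 = %.4f)\n", x$p, x$log10_p))
  invisible(x)
}

#' Monte-Carlo oracle for the PCV
#'
#' Estimates the PCV by simulation: `n_samples` progeny are produced with
#' [reproduce()], one gamete is then sampled from each progeny by the same
#' meiosis process, and the fraction of all-desirable gametes is returned
#' with its binomial standard error. Used to validate the exact dynamic
#' program; the estimate, not the DP, is the arbiter in agreement tests.
#'
#' @param L1,L2 Parent genotypes.
#' @param map A `genetic_map`.
#' @param n_samples Number of simulated gametes (default `1e5`).
#' @param seed Optional integer seed.
#' @return List with `estimate`, `se` and `n`.
#' @export
pcv_mc_oracle <- function(L1, L2, map, n_samples = 1e5, seed = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  pop <- reproduce(L1, L2, map, K = n_samples)
  gam <- gametes_each_cpp(pop$geno, map$f)
  hit <- colSums(gam) == map$n_loci
  p <- mean(hit)
  list(estimate = p, se = sqrt(p * (1 - p) / n_samples), n = n_samples)
}

#' PCV-maximising parental selection
#'
#' Selects the unordered pair of candidates maximising the PCV. The candidate
#' pool is the population plus, when supplied, the two retained parents of
#' the previous generation (retention guarantees the selected-pair PCV never
#' decreases across generations). With `screen_top` set, only the
#' `screen_top` candidates with the highest desirable-allele counts enter the
#' pairwise search; otherwise the search is exhaustive. Self-crosses are
#' excluded; ties are broken towards the lowest `(k1, k2)` index pair.
#'
#' @param pop A `mati_population`.
#' @param map A `genetic_map`.
#' @param retained Optional list of two genotypes (previous parents),
#'   appended to the pool after the population members.
#' @param screen_top Optional count: pre-screen the pool to this many
#'   candidates ranked by desirable-allele count (ties by index).
#' @return An object of class `selected_pair`: `k1`, `k2` (pool indices,
#'   `k1 < k2`; indices above `pop$K` refer to retained parents), `pcv` (a
#'   `pcv_value`), and `parents` (the two genotypes).
#' @export
select_parents <- function(pop, map, retained = NULL, screen_top = NULL) {
  geno <- pop$geno
  if (!is.null(retained)) {
    stopifnot(length(retained) == 2)
    aug <- array(0L, dim = dim(geno) + c(0, 0, 2),
                 dimnames = dimnames(geno))
    aug[, , seq_len(pop$K)] <- geno
    aug[, , pop$K + 1] <- retained[[1]]
    aug[, , pop$K + 2] <- retained[[2]]
    geno <- aug
  }
  n_cand <- dim(geno)[3]
  if (n_cand < 2) stop("candidate pool must contain at least 2 members")
  cand <- seq_len(n_cand)
  if (!is.null(screen_top) && screen_top < n_cand) {
    counts <- colSums(geno, dims = 2)
    cand <- sort(order(-counts, cand)[seq_len(screen_top)])
  }
  pairs <- utils::combn(cand, 2)  # lexicographic over ascending indices
  vals <- pcv_pairs_cpp(geno, as.integer(pairs[1, ] - 1L),
                        as.integer(pairs[2, ] - 1L), map$f)
  best <- which.max(vals)  # first maximum = lowest lexicographic pair
  k1 <- pairs[1, best]; k2 <- pairs[2, best]
  N <- dim(geno)[1]
  structure(list(k1 = k1, k2 = k2, pcv = new_pcv_value(vals[best]),
                 parents = list(matrix(geno[, , k1], N, 2),
                                matrix(geno[, , k2], N, 2))),
            class = "selected_pair")
}

#' @export
print.selected_pair <- function(x, ...) {
  cat(sprintf("Selected pair (%d, %d): PCV = %.6g (log10 = %.4f)\n",
              x$k1, x$k2, x$pcv$p, x$pcv$log10_p))
  invisible(x)
}
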