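#' Haldane map function
#'
#' Converts a genetic map distance into a recombination frequency under the
#' assumption of independent (no-interference) crossovers:
#' \eqn{f = 0.5 (1 - e^{-2d/100})} for a distance `d` in centimorgans.
#'
#' @param d Non-negative map distance(s) in centimorgans.
#' @return Recombination frequencies in `[0, 0.5)`.
#' @examples
#' haldane(c(0, 10, 100))
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("map distances must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

new_genetic_map <- function(chrom, marker, pos_cM, f) {
  structure(list(n_loci = length(marker), chrom = chrom, marker = marker,
                 pos_cM = pos_cM, f = f),
            class = "genetic_map")
}

#' Validate a genetic map
#'
#' Checks the structural invariants of a [genetic_map]: `f` has length
#' `n_loci - 1` with all values in `[0, 0.5]`, `f` equals 0.5 exactly at every
#' linkage-group boundary, and loci are sorted by (chromosome, position).
#'
#' @param map A `genetic_map` object.
#' @return `map`, invisibly; errors if any invariant fails.
#' @export
validate_map <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  n <- map$n_loci
  if (length(map$chrom) != n || length(map$marker) != n || length(map$pos_cM) != n)
    stop("chrom, marker and position must each have one entry per locus")
  if (length(map$f) != n - 1)
    stop("f must have length n_loci - 1")
  if (any(map$f < 0 | map$f > 0.5))
    stop("recombination frequencies must lie in [0, 0.5]")
  boundary <- map$chrom[-n] != map$chrom[-1]
  if (any(map$f[boundary] != 0.5))
    stop("f must be exactly 0.5 across linkage-group boundaries")
  for (ch in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == ch]
    if (is.unsorted(p)) stop("loci must be sorted by position within chromosome")
  }
  if (anyDuplicated(map$marker)) stop("marker names must be unique")
  invisible(map)
}

#' Generate a synthetic genetic map
#'
#' Builds a random marker map of the kind used throughout the package's case
#' study: `total_markers` markers spread over `n_chrom` linkage groups, with
#' the per-group marker count drawn uniformly from `markers_per_chrom`,
#' marker positions uniform on `[0, map_length_cM]` within each group,
#' within-group recombination frequencies from the Haldane function, and
#' `f = 0.5` across group boundaries (independent assortment). Markers are
#' named `"CiMj"` (j-th marker of chromosome i).
#'
#' @param n_chrom Number of linkage groups (default 10).
#' @param markers_per_chrom Integer interval `c(min, max)` of markers per
#'   group (default `c(8, 12)`).
#' @param total_markers Total marker count (default 100).
#' @param map_length_cM Genetic length of each linkage group in centimorgans
#'   (default 100).
#' @param seed Optional integer seed; when given, the map is bit-reproducible.
#' @return A `genetic_map` object.
#' @examples
#' map <- generate_map(seed = 1)
#' map
#' @export
generate_map <- function(n_chrom = 10, markers_per_chrom = c(8, 12),
                         total_markers = 100, map_length_cM = 100,
                         seed = NULL) {
  lo <- markers_per_chrom[1]; hi <- markers_per_chrom[2]
  if (total_markers < n_chrom * lo || total_markers > n_chrom * hi)
    stop("infeasible marker counts: ", n_chrom, " groups of ", lo, "..", hi,
         " markers cannot total ", total_markers)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  # rejection-sample a composition of total_markers into n_chrom parts
  for (i in seq_len(100000)) {
    counts <- sample(lo:hi, n_chrom, replace = TRUE)
    if (sum(counts) == total_markers) break
  }
  if (sum(counts) != total_markers)
    stop("failed to sample a feasible marker composition")
  chrom <- character(0); marker <- character(0)
  pos <- numeric(0); f <- numeric(0)
  for (c in seq_len(n_chrom)) {
    m <- counts[c]
    p <- sort(stats::runif(m, 0, map_length_cM))
    chrom <- c(chrom, rep(paste0("C", c), m))
    marker <- c(marker, paste0("C", c, "M", seq_len(m)))
    pos <- c(pos, p)
    if (c > 1) f <- c(f, 0.5)
    if (m > 1) f <- c(f, haldane(diff(p)))
  }
  validate_map(new_genetic_map(chrom, marker, pos, f))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", x$n_loci, "markers on", length(unique(x$chrom)),
      "linkage groups\n")
  tab <- table(factor(x$chrom, levels = unique(x$chrom)))
  cat("  markers per group:", paste(as.integer(tab), collapse = " "), "\n")
  within <- x$f[x$f < 0.5]
  cat(sprintf("  within-group f: min %.4f, median %.4f, max %.4f\n",
              min(within), stats::median(within), max(within)))
  invisible(x)
}

#' Read / write a genetic map as CSV
#'
#' The file format has columns `chrom`, `marker`, `position_cM` and
#' `f_to_next`; `f_to_next` on the last row of each chromosome is 0.5 (or
#' empty on the final row of the file). `read_map_csv` validates all map
#' invariants on load.
#'
#' @param map A `genetic_map` (for writing).
#' @param path File path.
#' @return `read_map_csv` returns a `genetic_map`; `write_map_csv` returns
#'   `path` invisibly.
#' @export
read_map_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chrom", "marker", "position_cM", "f_to_next")
  if (!all(need %in% names(d))) stop("map CSV must have columns ",
                                     paste(need, collapse = ", "))
  f <- as.numeric(d$f_to_next[-nrow(d)])
  if (anyNA(f)) stop("f_to_next may only be empty on the final row")
  validate_map(new_genetic_map(as.character(d$chrom), as.character(d$marker),
                               as.numeric(d$position_cM), f))
}

#' @rdname read_map_csv
#' @export
write_map_csv <- function(map, path) {
  validate_map(map)
  utils::write.csv(data.frame(chrom = map$chrom, marker = map$marker,
                              position_cM = map$pos_cM,
                              f_to_next = c(map$f, NA)),
                   path, row.names = FALSE, na = "")
  invisible(path)
}
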