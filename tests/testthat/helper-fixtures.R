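# shared fixtures, built in code; expensive ones are cached for the session

.fixtures <- new.env(parent = emptyenv())

# construct a genetic_map directly from an f vector (hand-set maps)
map_from_f <- function(f, chrom = NULL) {
  n <- length(f) + 1
  if (is.null(chrom)) chrom <- rep("C1", n)
  j <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  m <- structure(list(n_loci = n, chrom = chrom,
                      marker = paste0(chrom, "M", j),
                      pos_cM = as.numeric(j), f = f),
                 class = "genetic_map")
  validate_map(m)
}

# 10-marker, 2-chromosome toy genome with two donor loci
toy_map <- function() {
  if (is.null(.fixtures$map))
    .fixtures$map <- generate_map(n_chrom = 2, markers_per_chrom = c(5, 5),
                                  total_markers = 10, seed = 3)
  .fixtures$map
}

toy_founders <- function() make_founders(toy_map(), c("C1M2", "C2M4"))

toy_config <- function() mati_config(T = 4, budget_max = 10000,
                                     budgets = seq(3000, 10000, 1000),
                                     actions = c(0, 100, 200))

# fitted model on the toy genome (cached; drives mdp/process/experiment tests)
toy_fit <- function() {
  if (is.null(.fixtures$fit))
    .fixtures$fit <- fit_mati_mdp(toy_map(), donor_loci = c("C1M2", "C2M4"),
                                  config = toy_config(), n_prelim = 12,
                                  screen_top = 50, seed = 42)
  .fixtures$fit
}

# random genotype with a given density of desirable alleles
random_genotype <- function(n, p = 0.7) {
  matrix(rbinom(2 * n, 1, p), n, 2)
}

# random finite-horizon MDP small enough for policy enumeration
random_fh_mdp <- function(n_s, n_a, T, lambda = NULL) {
  P <- lapply(seq_len(n_a), function(a) {
    M <- matrix(rexp(n_s * n_s), n_s, n_s)
    M / rowSums(M)
  })
  reward <- matrix(runif(n_s * n_a, -1, 1), n_s, n_a)
  terminal <- runif(n_s, -1, 1)
  feasible <- matrix(runif(n_s * n_a) < 0.8, n_s, n_a)
  feasible[rowSums(feasible) == 0, 1] <- TRUE
  if (is.null(lambda)) lambda <- runif(1)
  new_fh_mdp(P, reward, terminal, feasible, lambda, T,
             actions = seq_len(n_a))
}

# hand-made preliminary-simulation object with fixed PCV trajectories
fake_prelim <- function(traj, m0 = 1e-6) {
  structure(list(
    trajectories = traj,
    G = max(vapply(traj, `[[`, integer(1), "Ts")),
    m0 = m0,
    actions = sort(unique(vapply(traj, `[[`, numeric(1), "a"))),
    n_reps = NA_integer_), class = "mati_prelim")
}
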