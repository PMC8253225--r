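#' Allocation policies
#'
#' An allocation policy decides the number of progeny to produce at each
#' generation. `static_policy(K)` always requests `K`, truncated to the
#' largest affordable multiple of `step` when the remaining budget runs short
#' (so e.g. a 600-per-generation strategy on a $32,000 budget produces 600 in
#' generations 1-5 and 200 in generation 6). `mdp_policy(fit)` looks the
#' action up in the backward-induction solution of a fitted model, using the
#' interval of the current best-pair PCV and the remaining budget in units;
#' at generation 0 it spends the smallest non-zero action (founders are
#' homozygous, so every F1 is identical and larger F1 families buy nothing),
#' and beyond the solved horizon it returns 0 (deadline exceeded).
#'
#' @param K Fixed progeny count per generation.
#' @param step Granularity of affordable truncation (default 100, the action
#'   spacing).
#' @param fit A `mati_mdp` object from [fit_mati_mdp()].
#' @return An object of class `mati_allocation`.
#' @export
static_policy <- function(K, step = 100) {
  structure(list(kind = "static", K = as.integer(K), step = as.integer(step),
                 label = paste0("static-", K)),
            class = "mati_allocation")
}

#' @rdname static_policy
#' @export
mdp_policy <- function(fit) {
  stopifnot(inherits(fit, "mati_mdp"))
  structure(list(kind = "dynamic", partition = fit$partition,
                 policy_array = fit$policy_array, config = fit$config,
                 G = fit$partition$G, B_units = fit$mdp$B_units,
                 label = "dynamic"),
            class = "mati_allocation")
}

#' @export
print.mati_allocation <- function(x, ...) {
  if (x$kind == "static")
    cat("Static allocation policy: K =", x$K, "per generation\n")
  else
    cat("Dynamic (MDP) allocation policy over", x$G - 1, "PCV intervals,",
        x$B_units, "budget units, horizon T =", x$config$T, "\n")
  invisible(x)
}

#' Allocate progeny for the current generation
#'
#' Applies an allocation policy to the observed project state. Static
#' policies return `min(K, largest affordable multiple of step)`; dynamic
#' policies return the solved decision rule at
#' `(interval of best-pair PCV, remaining budget units)` for epoch `t`. The
#' returned count is always affordable; 0 signals that the project must stop
#' (failure upstream unless an ideal genotype already exists).
#'
#' @param policy A `mati_allocation`.
#' @param t Current generation number (founders are generation 0).
#' @param pop Current `mati_population`.
#' @param budget_remaining Remaining budget in dollars.
#' @param map A `genetic_map`.
#' @param retained Optional retained parents (previous generation's pair).
#' @param best_pcv Optional precomputed best-pair PCV (avoids re-running the
#'   pair search when the caller has already selected parents).
#' @param config A `mati_config` (for the cost coefficient).
#' @param screen_top Pre-screening size for the pair search when `best_pcv`
#'   is not supplied.
#' @return Non-negative integer progeny count.
#' @export
allocate <- function(policy, t, pop, budget_remaining, map, retained = NULL,
                     best_pcv = NULL, config = mati_config(),
                     screen_top = 100) {
  stopifnot(inherits(policy, "mati_allocation"))
  cost1 <- config$cost_per_progeny
  if (policy$kind == "static") {
    afford <- floor(budget_remaining / (cost1 * policy$step)) * policy$step
    return(as.integer(min(policy$K, afford)))
  }
  # dynamic
  cfg <- policy$config
  acts <- cfg$actions[cfg$actions > 0]
  if (t == 0) {
    a0 <- acts[cfg$cost_per_progeny * acts <= budget_remaining]
    return(if (length(a0)) as.integer(min(a0)) else 0L)
  }
  if (t >= cfg$T) return(0L)
  b <- floor(budget_remaining / cfg$budget_unit)
  if (b < 1) return(0L)
  b <- min(b, policy$B_units)
  if (is.null(best_pcv)) {
    sel <- select_parents(pop, map, retained, screen_top)
    best_pcv <- sel$pcv$p
  }
  g <- interval_of(best_pcv, policy$partition)
  g <- min(max(g, 1L), policy$G - 1L)
  as.integer(policy$policy_array[t, g, b])
}

#' Run the introgression process
#'
#' Executes the full breeding loop: check the population for an ideal
#' genotype (success returns the current generation); allocate progeny for
#' this generation (0, or a generation past the deadline, fails the
#' project); select the PCV-maximising parent pair from the progeny plus the
#' retained previous parents; reproduce and decrement the budget. Fully
#' reproducible under a fixed seed.
#'
#' @param elite,donor Founder genotypes.
#' @param map A `genetic_map`.
#' @param budget Total budget in dollars (positive).
#' @param policy A `mati_allocation`.
#' @param T Deadline in generations (default from `config`).
#' @param config A `mati_config`.
#' @param partition Optional `pcv_partition` used to annotate the trace with
#'   interval indices (taken from a dynamic policy automatically).
#' @param screen_top Pre-screening size for parental selection.
#' @param seed Optional integer seed.
#' @param max_gen Safety cap on generations.
#' @return An object of class `mati_run`: `Ts` (terminal generation, `Inf`
#'   on failure), `success`, `trace` (one row per generation: `t`, `K`,
#'   `budget_before`, `k1`, `k2`, `log10_pcv`, `interval`), `total_cost`,
#'   `revenue` and `reward` (revenue minus cost).
#' @export
run_mati <- function(elite, donor, map, budget, policy,
                     T = config$T, config = mati_config(),
                     partition = NULL, screen_top = 100, seed = NULL,
                     max_gen = 100) {
  if (budget <= 0) stop("budget must be positive")
  if (T < 1) stop("T must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(partition) && policy$kind == "dynamic")
    partition <- policy$partition
  geno0 <- array(0L, dim = c(map$n_loci, 2, 2),
                 dimnames = list(map$marker, c("hom1", "hom2"), NULL))
  geno0[, , 1] <- elite; geno0[, , 2] <- donor
  pop <- new_population(geno0, 0L)
  retained <- NULL
  B_t <- budget
  t <- 0L
  rows <- list()
  Ts <- Inf
  repeat {
    if (is_ideal(pop)) { Ts <- t; break }
    sel <- select_parents(pop, map, retained, screen_top)
    K <- allocate(policy, t, pop, B_t, map, retained,
                  best_pcv = sel$pcv$p, config = config,
                  screen_top = screen_top)
    if (K == 0 || t > T) break
    cost <- config$cost_per_progeny * K
    if (cost > B_t)
      stop("allocation policy emitted an unaffordable progeny count (",
           K, " at budget ", B_t, ")")
    rows[[length(rows) + 1]] <- data.frame(
      t = t, K = K, budget_before = B_t, k1 = sel$k1, k2 = sel$k2,
      log10_pcv = sel$pcv$log10_p,
      interval = if (is.null(partition)) NA_integer_
                 else interval_of(sel$pcv$p, partition))
    pop <- reproduce(sel$parents[[1]], sel$parents[[2]], map, K,
                     generation = t + 1L)
    retained <- sel$parents
    B_t <- B_t - cost
    t <- t + 1L
    if (t > max_gen) stop("run exceeded ", max_gen, " generations")
  }
  trace <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = integer(0), K = integer(0), budget_before = numeric(0),
               k1 = integer(0), k2 = integer(0), log10_pcv = numeric(0),
               interval = integer(0))
  total_cost <- sum(config$cost_per_progeny * trace$K)
  revenue <- if (is.finite(Ts) && Ts <= T && Ts > 0)
    config$revenue_intercept - config$revenue_slope * Ts else 0
  if (is.finite(Ts) && Ts == 0) revenue <- config$revenue_intercept
  structure(list(Ts = Ts, success = is.finite(Ts), trace = trace,
                 total_cost = total_cost, revenue = revenue,
                 reward = revenue - total_cost, budget = budget,
                 policy = policy$label, T = T),
            class = "mati_run")
}

#' @export
print.mati_run <- function(x, ...) {
  if (x$success)
    cat("Introgression succeeded at generation", x$Ts, "\n")
  else
    cat("Introgression failed (budget/deadline exhausted)\n")
  cat(sprintf("  policy %s, budget $%s, spent $%s, reward $%s\n",
              x$policy, format(x$budget, big.mark = ","),
              format(x$total_cost, big.mark = ","),
              format(x$reward, big.mark = ",")))
  if (nrow(x$trace)) {
    cat("  per-generation progeny:", paste(x$trace$K, collapse = " "), "\n")
    cat("  log10 PCV trace:",
        paste(sprintf("%.2f", x$trace$log10_pcv), collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname run_mati
#' @param run A `mati_run`.
#' @param path File path (CSV for the trace).
#' @export
write_run_trace <- function(run, path) {
  utils::write.csv(run$trace, path, row.names = FALSE)
  invisible(path)
}
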