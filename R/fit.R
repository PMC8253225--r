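#' Fit the introgression resource-allocation model
#'
#' The model-fitting pipeline of the package: run preliminary simulations of
#' the unconstrained breeding loop for every non-zero action, discretise the
#' observed selected-pair PCV trajectories into the interval partition, count
#' and normalise the empirical interval transitions per action, assemble the
#' finite-horizon Markov decision process over (PCV interval, remaining
#' budget) states, and solve it by backward induction. The result is a
#' fitted-model object whose decision rules can be queried with
#' [predict.mati_mdp()], simulated forward with [simulate.mati_mdp()], and
#' fed to the experiment suite ([ctp_analysis()], [compare_strategies()],
#' [optimize_budget()], [allocation_breakdown()]).
#'
#' @param map A `genetic_map`.
#' @param donor_loci Marker names at which only the donor carries the
#'   desirable allele. The default is the seven-locus case the package's
#'   examples are built around; every name must exist in `map` (random maps
#'   occasionally draw too few markers on a chromosome, in which case
#'   regenerate with another seed).
#' @param config A `mati_config` with the economic and horizon parameters.
#' @param n_prelim Preliminary repetitions per non-zero action (default 100).
#' @param screen_top Candidate pre-screening size for the pair search.
#' @param seed Optional integer seed controlling the whole fit.
#' @param verbose Print progress.
#' @return An object of class `mati_mdp` with components `map`, `elite`,
#'   `donor`, `prelim`, `partition`, `transitions`, `mdp`, `solution`
#'   (values `u` and decision table `d`), `policy_array`
#'   (`[epoch, interval, budget-units]` action lookup) and `config`.
#' @examples
#' \donttest{
#' map <- generate_map(seed = 1)
#' fit <- fit_mati_mdp(map, n_prelim = 10, screen_top = 50, seed = 1)
#' print(fit)
#' predict(fit, data.frame(t = 2, pcv = 1e-6, budget = 20000))
#' }
#' @export
fit_mati_mdp <- function(map,
                         donor_loci = c("C1M4", "C1M6", "C2M9", "C3M1",
                                        "C5M4", "C6M3", "C6M8"),
                         config = mati_config(), n_prelim = 100,
                         screen_top = 100, seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  fd <- make_founders(map, donor_loci)
  if (verbose) message("running preliminary simulations ...")
  prelim <- preliminary_simulation(fd$elite, fd$donor, map,
                                   actions = config$actions[config$actions > 0],
                                   n_reps = n_prelim, screen_top = screen_top)
  partition <- build_intervals(prelim)
  trans <- estimate_transitions(prelim, partition)
  if (verbose) message("assembling and solving the decision model ...")
  mdp <- assemble_mdp(trans, config)
  sol <- backward_induction(mdp)
  new_mati_mdp(map, fd$elite, fd$donor, donor_loci, prelim, partition,
               trans, mdp, sol, config)
}

new_mati_mdp <- function(map, elite, donor, donor_loci, prelim, partition,
                         trans, mdp, sol, config) {
  G <- partition$G
  Tm1 <- max(config$T - 1, 0)
  pol <- array(NA_integer_, dim = c(Tm1, G - 1, mdp$B_units))
  for (t in seq_len(Tm1)) for (b in seq_len(mdp$B_units))
    pol[t, , b] <- sol$d[t, mdp$state_index(seq_len(G - 1), b)]
  structure(list(map = map, elite = elite, donor = donor,
                 donor_loci = donor_loci, prelim = prelim,
                 partition = partition, transitions = trans, mdp = mdp,
                 solution = sol, policy_array = pol, config = config),
            class = "mati_mdp")
}

#' In-model value of an allocation strategy
#'
#' Expected total discounted reward, inside the fitted transition model, of
#' either the backward-induction policy or a static `K`-per-generation
#' strategy, starting from the post-F1 state (interval 1, total budget minus
#' the F1 cross) at epoch 1. The deterministic generation-0 F1 cross costs
#' the smallest non-zero action under both strategies and is excluded, so
#' values are directly comparable across strategies.
#'
#' @param fit A `mati_mdp`.
#' @param budget Total budget in dollars.
#' @param K `NULL` for the solved dynamic policy, otherwise the static
#'   per-generation progeny count.
#' @return Expected discounted reward (dollars).
#' @export
in_model_value <- function(fit, budget, K = NULL) {
  mdp <- fit$mdp
  cfg <- fit$config
  b0 <- budget / cfg$budget_unit - min(cfg$actions[cfg$actions > 0]) *
    cfg$cost_per_progeny / cfg$budget_unit
  if (b0 < 1 || b0 != round(b0))
    stop("budget must be a multiple of the unit and cover the F1 cross")
  s0 <- mdp$state_index(1L, as.integer(b0))
  if (is.null(K)) return(fit$solution$u[1, s0])
  d_idx <- static_decision_table(mdp, K)
  evaluate_policy(mdp, d_idx)[1, s0]
}

# decision table of a static strategy inside the model: at (g, b) request
# min(K, largest affordable multiple of 100)
static_decision_table <- function(mdp, K) {
  acts <- mdp$actions
  a0 <- which(acts == 0)
  n <- mdp$n_states
  Tm1 <- max(mdp$T - 1, 0)
  d <- matrix(a0, Tm1, n)
  step <- min(acts[acts > 0])
  for (s in seq_len(n - 2)) {
    b <- mdp$state_df$budget_units[s]
    # affordable multiples of step: cost_per_progeny * a <= b * unit
    a <- min(K, floor(b * mdp$unit / (mdp$config$cost_per_progeny * step)) *
               step)
    ai <- which(acts == a)
    if (length(ai) != 1) stop("static K must map into the action grid")
    d[, s] <- ai
  }
  d
}

#' @export
print.mati_mdp <- function(x, ...) {
  cfg <- x$config
  cat("Introgression resource-allocation model (finite-horizon MDP)\n")
  cat(sprintf("  genome: %d markers, %d linkage groups; donor loci: %s\n",
              x$map$n_loci, length(unique(x$map$chrom)),
              paste(x$donor_loci, collapse = " ")))
  cat(sprintf("  PCV intervals: G = %d (states: %d); actions: %s\n",
              x$partition$G, x$mdp$n_states,
              paste(cfg$actions, collapse = " ")))
  cat(sprintf("  horizon T = %d, lambda = %.2f, budget unit $%s, max $%s\n",
              cfg$T, cfg$lambda, format(cfg$budget_unit, big.mark = ","),
              format(cfg$budget_max, big.mark = ",")))
  for (B in intersect(c(11000, 32000, 80000), cfg$budgets))
    cat(sprintf("  value at $%s total budget: $%s\n",
                format(B, big.mark = ","),
                format(round(in_model_value(x, B)), big.mark = ",")))
  invisible(x)
}

#' @export
summary.mati_mdp <- function(object, ...) {
  ts <- vapply(object$prelim$trajectories, `[[`, integer(1), "Ts")
  out <- list(G = object$partition$G,
              breaks_log10 = log10(object$partition$breaks),
              terminal_generations = table(ts),
              n_states = object$mdp$n_states,
              actions = object$config$actions,
              success_cols = lapply(object$transitions$W, function(W)
                W[, ncol(W)]),
              config = object$config)
  class(out) <- "summary.mati_mdp"
  out
}

#' @export
print.summary.mati_mdp <- function(x, ...) {
  cat("Fitted introgression MDP\n")
  cat("  G =", x$G, " states =", x$n_states, "\n")
  cat("  log10 interval breakpoints:",
      paste(sprintf("%.2f", x$breaks_log10), collapse = ", "), "\n")
  cat("  preliminary terminal generations:\n")
  print(x$terminal_generations)
  cat("  P(next interval is terminal) by action, from interval G-1:\n")
  g <- x$G - 1
  for (a in names(x$success_cols))
    cat(sprintf("    a = %4s: %.3f\n", a, x$success_cols[[a]][g]))
  invisible(x)
}

#' Recommended progeny allocation for observed project states
#'
#' Looks up the backward-induction decision rule. `newdata` needs columns
#' `t` (generation), `budget` (remaining dollars) and either `pcv` (best
#' selected-pair PCV, converted through the fitted interval partition) or
#' `interval` (the index directly).
#'
#' @param object A `mati_mdp`.
#' @param newdata Data frame of states.
#' @param ... Unused.
#' @return Integer vector of progeny counts.
#' @export
predict.mati_mdp <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  pol <- mdp_policy(object)
  vapply(seq_len(nrow(newdata)), function(i) {
    g <- if ("interval" %in% names(newdata)) newdata$interval[i]
         else interval_of(newdata$pcv[i], object$partition)
    t <- newdata$t[i]
    if (t == 0) return(allocate(pol, 0L, NULL, newdata$budget[i],
                                object$map, config = object$config))
    if (t >= object$config$T) return(0L)
    b <- floor(newdata$budget[i] / object$config$budget_unit)
    if (b < 1) return(0L)
    g <- min(max(g, 1L), object$partition$G - 1L)
    as.integer(object$policy_array[t, g, min(b, object$mdp$B_units)])
  }, integer(1))
}

#' Simulate introgression projects under the fitted model's policy
#'
#' Runs [run_mati()] `nsim` times with either the solved dynamic policy or a
#' static strategy, on the genome and economics stored in the fit.
#'
#' @param object A `mati_mdp`.
#' @param nsim Number of replications.
#' @param seed Optional integer seed.
#' @param budget Total budget in dollars.
#' @param policy `"dynamic"` or `"static"`.
#' @param K Static per-generation progeny count (when `policy = "static"`).
#' @param screen_top Pre-screening size for parental selection.
#' @param keep_traces Keep full per-run traces (attribute `"runs"`).
#' @param ... Unused.
#' @return A data frame of class `mati_sim` with one row per run (`Ts`,
#'   `success`, `total_cost`, `revenue`, `reward`) and an attribute
#'   `"spend"`: an `nsim x max-generation` matrix of per-generation dollar
#'   spend.
#' @importFrom stats simulate
#' @export
simulate.mati_mdp <- function(object, nsim = 1, seed = NULL,
                              budget = 32000, policy = c("dynamic", "static"),
                              K = 400, screen_top = 100,
                              keep_traces = FALSE, ...) {
  policy <- match.arg(policy)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  pol <- if (policy == "dynamic") mdp_policy(object) else static_policy(K)
  runs <- vector("list", nsim)
  for (i in seq_len(nsim))
    runs[[i]] <- run_mati(object$elite, object$donor, object$map, budget,
                          pol, T = object$config$T, config = object$config,
                          partition = object$partition,
                          screen_top = screen_top)
  maxg <- max(1, vapply(runs, function(r) nrow(r$trace), integer(1)))
  spend <- matrix(0, nsim, maxg)
  for (i in seq_len(nsim)) {
    tr <- runs[[i]]$trace
    if (nrow(tr)) spend[i, tr$t + 1] <- object$config$cost_per_progeny * tr$K
  }
  out <- data.frame(
    run = seq_len(nsim),
    Ts = vapply(runs, `[[`, numeric(1), "Ts"),
    success = vapply(runs, `[[`, logical(1), "success"),
    total_cost = vapply(runs, `[[`, numeric(1), "total_cost"),
    revenue = vapply(runs, `[[`, numeric(1), "revenue"),
    reward = vapply(runs, `[[`, numeric(1), "reward"))
  attr(out, "spend") <- spend
  attr(out, "budget") <- budget
  attr(out, "policy") <- pol$label
  if (keep_traces) attr(out, "runs") <- runs
  class(out) <- c("mati_sim", "data.frame")
  out
}

#' Plot the solved allocation policy
#'
#' Displays the decision rule at one epoch as an image over remaining budget
#' (x, in units) and PCV interval (y): cell colour is the progeny count the
#' policy requests.
#'
#' @param x A `mati_mdp`.
#' @param t Epoch (generation) to display.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.mati_mdp <- function(x, t = 2, ...) {
  Tm1 <- dim(x$policy_array)[1]
  if (t < 1 || t > Tm1) stop("t must lie in 1..", Tm1)
  pol <- t(x$policy_array[t, , , drop = TRUE])  # budget x interval
  acts <- x$config$actions
  cols <- grDevices::gray.colors(length(acts), start = 0.95, end = 0.05)
  graphics::image(x = seq_len(nrow(pol)), y = seq_len(ncol(pol)),
                  z = matrix(match(pol, acts), nrow(pol), ncol(pol)),
                  col = cols, zlim = c(1, length(acts)),
                  xlab = "remaining budget (units of $1,000)",
                  ylab = "PCV interval",
                  main = paste0("Allocation policy at generation ", t), ...)
  invisible(x)
}
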