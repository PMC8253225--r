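#' Preliminary simulations for state-space construction
#'
#' Runs the unconstrained introgression loop (fixed population size `a`,
#' PCV-maximising selection with parent retention) to success, `n_reps` times
#' for every non-zero action, recording the selected-pair PCV at each
#' generation. These trajectories define the PCV-interval state space and the
#' empirical transition matrices of the decision model.
#'
#' @param elite,donor Founder genotypes (see [make_founders()]).
#' @param map A `genetic_map`.
#' @param actions Non-zero progeny counts to simulate (default
#'   `seq(100, 1000, by = 100)`).
#' @param n_reps Repetitions per action (default 100).
#' @param screen_top Candidate pre-screening size passed to
#'   [select_parents()] (default 100).
#' @param max_gen Safety cap on generations per run.
#' @param seed Optional integer seed.
#' @return An object of class `mati_prelim`: list with `trajectories` (one
#'   element per run: action `a`, PCV sequence `p` for generations
#'   `0..Ts` with the final entry 1, terminal generation `Ts`), `G` (largest
#'   terminal generation), `m0` (founder-pair PCV) and `actions`.
#' @export
preliminary_simulation <- function(elite, donor, map,
                                   actions = seq(100, 1000, by = 100),
                                   n_reps = 100, screen_top = 100,
                                   max_gen = 200, seed = NULL) {
  if (length(actions) == 0 || any(actions <= 0))
    stop("actions must be non-empty and positive")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  m0 <- pcv(elite, donor, map)$p
  trajectories <- vector("list", length(actions) * n_reps)
  i <- 0L
  G <- 0L
  for (a in actions) {
    for (n in seq_len(n_reps)) {
      run <- mati_unconstrained_run(elite, donor, map, a, screen_top, max_gen)
      i <- i + 1L
      trajectories[[i]] <- list(a = a, p = run$p, Ts = run$Ts)
      G <- max(G, run$Ts)
    }
  }
  structure(list(trajectories = trajectories, G = G, m0 = m0,
                 actions = actions, n_reps = n_reps),
            class = "mati_prelim")
}

# one budget-free run to success with fixed population size a;
# returns p = (p_0, ..., p_{Ts-1}, 1) and Ts
mati_unconstrained_run <- function(elite, donor, map, a, screen_top, max_gen) {
  geno0 <- array(0L, dim = c(map$n_loci, 2, 2),
                 dimnames = list(map$marker, c("hom1", "hom2"), NULL))
  geno0[, , 1] <- elite; geno0[, , 2] <- donor
  pop <- new_population(geno0, 0L)
  retained <- NULL
  p <- numeric(0)
  g <- 0L
  while (!is_ideal(pop)) {
    sel <- select_parents(pop, map, retained, screen_top)
    p <- c(p, sel$pcv$p)
    pop <- reproduce(sel$parents[[1]], sel$parents[[2]], map, a,
                     generation = g + 1L)
    retained <- sel$parents
    g <- g + 1L
    if (g > max_gen)
      stop("run exceeded ", max_gen, " generations without success")
  }
  list(p = c(p, 1), Ts = g)
}

#' @export
print.mati_prelim <- function(x, ...) {
  ts <- vapply(x$trajectories, `[[`, integer(1), "Ts")
  cat("Preliminary simulations:", length(x$trajectories), "runs,",
      length(x$actions), "actions x", x$n_reps, "reps\n")
  cat("  terminal generations:", paste(names(table(ts)), collapse = "/"),
      "with counts", paste(as.integer(table(ts)), collapse = "/"), "\n")
  cat("  G =", x$G, " founder-pair PCV =", format(x$m0, digits = 6), "\n")
  invisible(x)
}

#' Build the PCV interval partition
#'
#' Converts preliminary-simulation trajectories into the discrete progress
#' scale of the decision model: `m_0` is the founder-pair PCV, `m_1` the
#' (unique) F1-pair PCV, `m_g = [min p_g, min p_{g+1})` for
#' `2 <= g <= G - 1` with minima taken over all runs and actions, and
#' `m_G = 1`, the PCV of an ideal pair.
#'
#' @param prelim A `mati_prelim` object.
#' @param founders_pcv Optional founder-pair PCV (`pcv_value` or number);
#'   defaults to the value recorded in `prelim`.
#' @return An object of class `pcv_partition`: list with `G` and `breaks`,
#'   the vector `(m_0, m_1, lower bounds of m_2..m_{G-1}, 1)`.
#' @export
build_intervals <- function(prelim, founders_pcv = NULL) {
  if (length(prelim$trajectories) == 0) stop("no trajectories supplied")
  m0 <- if (is.null(founders_pcv)) prelim$m0
        else if (inherits(founders_pcv, "pcv_value")) founders_pcv$p
        else as.numeric(founders_pcv)
  G <- prelim$G
  p1 <- vapply(prelim$trajectories, function(tr) tr$p[2], numeric(1))
  if (diff(range(p1)) > 1e-12)
    stop("inconsistent F1 PCV across runs; founders must be homozygous")
  m1 <- p1[1]
  lows <- if (G >= 3) vapply(2:(G - 1), function(g) {
    vals <- vapply(prelim$trajectories, function(tr)
      if (length(tr$p) >= g + 1) tr$p[g + 1] else NA_real_, numeric(1))
    min(vals, na.rm = TRUE)
  }, numeric(1)) else numeric(0)
  breaks <- c(m0, m1, lows, 1)
  if (is.unsorted(breaks)) stop("interval breakpoints are not non-decreasing")
  if (anyDuplicated(breaks))
    warning("partition has empty intervals (duplicate breakpoints); ",
            "consider more preliminary repetitions")
  structure(list(G = G, breaks = breaks), class = "pcv_partition")
}

#' @export
print.pcv_partition <- function(x, ...) {
  cat("PCV interval partition with G =", x$G, "\n")
  cat("  log10 breakpoints:",
      paste(sprintf("%.3f", log10(x$breaks)), collapse = ", "), "\n")
  invisible(x)
}

#' Map a PCV value to its interval index
#'
#' Intervals follow the half-open convention `[lo, hi)`; `p = 1` maps to the
#' terminal index `G`, `p` equal to the F1 value maps to 1, and values below
#' the lowest defined breakpoint clamp to index 0 (the founder point).
#'
#' @param p PCV value(s) in `[0, 1]`.
#' @param partition A `pcv_partition`.
#' @return Integer interval indices in `0..G`.
#' @export
interval_of <- function(p, partition) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  pmax(findInterval(p, partition$breaks) - 1L, 0L)
}

#' Estimate empirical transition matrices
#'
#' Counts, per action, the observed interval-to-interval transitions of the
#' selected-pair PCV along every preliminary trajectory, then row-normalises
#' the counts: `W^a[i, j] = N^a[i, j] / sum_j N^a[i, j]`. Parent retention
#' makes progress monotone, so all matrices are upper triangular. Rows with
#' no observations default to a self-transition of 1 (no free progress).
#'
#' @param prelim A `mati_prelim` object.
#' @param partition A `pcv_partition`.
#' @return An object of class `mati_transitions`: list with `counts` and `W`
#'   (named lists of `G x G` matrices, one per action) and `actions`.
#' @export
estimate_transitions <- function(prelim, partition) {
  if (length(prelim$trajectories) == 0) stop("no trajectories supplied")
  G <- partition$G
  counts <- lapply(prelim$actions, function(a) matrix(0L, G, G))
  names(counts) <- as.character(prelim$actions)
  for (tr in prelim$trajectories) {
    key <- as.character(tr$a)
    iv <- interval_of(tr$p, partition)
    # p[2] is generation 1 (the F1 pair); last entry is 1 -> interval G
    for (i in seq(2, length(tr$p) - 1))
      counts[[key]][iv[i], iv[i + 1]] <- counts[[key]][iv[i], iv[i + 1]] + 1L
  }
  W <- lapply(counts, function(N) {
    M <- matrix(0, G, G)
    rs <- rowSums(N)
    for (i in seq_len(G)) {
      if (rs[i] > 0) M[i, ] <- N[i, ] / rs[i] else M[i, i] <- 1
    }
    M
  })
  structure(list(counts = counts, W = W, actions = prelim$actions, G = G),
            class = "mati_transitions")
}

#' Economic and horizon configuration
#'
#' Default parameters of the decision model: cost of $10 per progeny, nominal
#' market value `2,000,000 - 100,000 t` dollars when the ideal genotype is
#' reached at generation `t <= T`, deadline `T = 8` generations, action space
#' `{0, 100, ..., 1000}` progeny, budget unit $1,000 (the cost of the
#' smallest non-zero action) and budgets from $11,000 to $80,000. The
#' discount factor `lambda` defaults to 0.95 (a net-present-value objective;
#' set `lambda = 1` for the undiscounted model).
#'
#' @param cost_per_progeny Dollars per progeny produced.
#' @param revenue_intercept,revenue_slope Revenue at generation `t` of first
#'   success is `revenue_intercept - revenue_slope * t`.
#' @param lambda Discount factor in `[0, 1]`.
#' @param T Deadline in generations.
#' @param budget_unit Dollars per budget unit; every action cost must be a
#'   multiple of it.
#' @param budget_max Largest total budget modelled (dollars).
#' @param budgets Budget scenarios for the experiment suite (dollars).
#' @param actions Action space, progeny counts including 0.
#' @return A list of class `mati_config`.
#' @export
mati_config <- function(cost_per_progeny = 10,
                        revenue_intercept = 2e6,
                        revenue_slope = 1e5,
                        lambda = 0.95,
                        T = 8,
                        budget_unit = 1000,
                        budget_max = 80000,
                        budgets = seq(11000, 80000, by = 1000),
                        actions = seq(0, 1000, by = 100)) {
  cfg <- list(cost_per_progeny = cost_per_progeny,
              revenue_intercept = revenue_intercept,
              revenue_slope = revenue_slope,
              lambda = lambda, T = as.integer(T),
              budget_unit = budget_unit, budget_max = budget_max,
              budgets = budgets, actions = sort(unique(as.integer(actions))))
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (cfg$T < 1) stop("T must be >= 1")
  if (budget_max %% budget_unit != 0)
    stop("budget_max must be a multiple of the budget unit")
  costs <- cost_per_progeny * cfg$actions
  if (any(costs %% budget_unit != 0))
    stop("every action cost must be a multiple of the budget unit")
  if (!0 %in% cfg$actions) stop("the action space must include 0")
  structure(cfg, class = "mati_config")
}

#' Per-epoch reward of the decision model
#'
#' `r_t(a, s, T) = -C(a) + R_t(s, T)`: producing `a` progeny always costs
#' `cost_per_progeny * a`; the revenue `revenue_intercept - revenue_slope * t`
#' accrues only on the epoch at which the process first reaches success, and
#' only when `t <= T`. An absorbed success state earns nothing further.
#'
#' @param a Action (progeny count).
#' @param s State label; revenue applies iff `s == "success"` (entry into
#'   success at epoch `t`).
#' @param t Epoch (generation index).
#' @param config A `mati_config`.
#' @return Reward in dollars.
#' @export
step_reward <- function(a, s, t, config = mati_config()) {
  rev <- if (identical(s, "success") && t <= config$T)
    config$revenue_intercept - config$revenue_slope * t else 0
  -config$cost_per_progeny * a + rev
}

#' Assemble the introgression decision model
#'
#' Builds the finite-horizon Markov decision process over states
#' `(m_g, b)` for interval `g in 1..G-1` and remaining budget `b` in units of
#' `config$budget_unit`, plus absorbing `failure` and `success` states. Under
#' action `a` with unit cost `c_a`, a state `(m_g, b)` with `c_a <= b` moves
#' its budget to `b - c_a` and its interval according to `W^a`; mass reaching
#' interval `G` transitions to success; non-success mass left without budget
#' for any non-zero action transitions to failure; choosing `a = 0` in a
#' non-absorbing state fails the project. Expected rewards fold the revenue
#' collected on entry into success (at epoch `t + 1`, discounted one step)
#' into the epoch-`t` reward; the terminal value is 0 everywhere.
#'
#' @param trans A `mati_transitions` object (or a named list of `G x G`
#'   row-stochastic matrices keyed by action).
#' @param config A `mati_config`.
#' @return An object of class `mati_mdp_model` (also `fh_mdp`): transition
#'   matrices `P` per action, `reward(t)` function, feasibility matrix,
#'   terminal values, state labels, and the index helpers `G`, `B_units`.
#' @export
assemble_mdp <- function(trans, config = mati_config()) {
  W <- if (inherits(trans, "mati_transitions")) trans$W else trans
  G <- nrow(W[[1]])
  actions <- config$actions
  nz <- setdiff(as.character(actions), "0")
  if (!all(nz %in% names(W)))
    stop("transition matrices missing for action(s): ",
         paste(setdiff(nz, names(W)), collapse = ", "))
  unit <- config$budget_unit
  B_units <- config$budget_max / unit
  cost_units <- config$cost_per_progeny * actions / unit
  if (any(cost_units != round(cost_units)))
    stop("action costs must be whole budget units")
  n_gb <- (G - 1) * B_units
  n <- n_gb + 2L
  i_fail <- n_gb + 1L
  i_succ <- n_gb + 2L
  idx <- function(g, b) (b - 1L) * (G - 1L) + g
  state_df <- data.frame(
    label = c(paste0("m", rep(seq_len(G - 1), B_units), ".b",
                     rep(seq_len(B_units), each = G - 1)),
              "failure", "success"),
    interval = c(rep(seq_len(G - 1), B_units), NA, NA),
    budget_units = c(rep(seq_len(B_units), each = G - 1), NA, NA))
  P <- vector("list", length(actions))
  names(P) <- as.character(actions)
  feasible <- matrix(FALSE, n, length(actions),
                     dimnames = list(NULL, actions))
  for (ai in seq_along(actions)) {
    a <- actions[ai]
    c_a <- cost_units[ai]
    M <- matrix(0, n, n)
    M[i_fail, i_fail] <- 1
    M[i_succ, i_succ] <- 1
    if (a == 0) {
      for (b in seq_len(B_units)) for (g in seq_len(G - 1))
        M[idx(g, b), i_fail] <- 1
      feasible[, ai] <- TRUE
    } else {
      Wa <- W[[as.character(a)]]
      for (b in seq_len(B_units)) {
        bp <- b - c_a
        for (g in seq_len(G - 1)) {
          s <- idx(g, b)
          if (bp < 0) { M[s, i_fail] <- 1; next }
          feasible[s, ai] <- TRUE
          M[s, i_succ] <- Wa[g, G]
          stay <- Wa[g, seq_len(G - 1)]
          if (bp >= 1) {
            M[s, idx(seq_len(G - 1), bp)] <- stay
          } else {
            M[s, i_fail] <- M[s, i_fail] + sum(stay)
          }
        }
      }
      feasible[c(i_fail, i_succ), ai] <- FALSE
    }
    P[[ai]] <- M
  }
  feasible[c(i_fail, i_succ), which(actions == 0)] <- TRUE
  rev_at <- function(t) if (t <= config$T)
    config$revenue_intercept - config$revenue_slope * t else 0
  reward <- function(t) {
    r <- matrix(0, n, length(actions))
    for (ai in seq_along(actions)) {
      a <- actions[ai]
      r[seq_len(n_gb), ai] <- -config$cost_per_progeny * a +
        config$lambda * rev_at(t + 1) * P[[ai]][seq_len(n_gb), i_succ]
    }
    r[c(i_fail, i_succ), ] <- 0
    r
  }
  mdp <- new_fh_mdp(P = P, reward = reward, terminal = rep(0, n),
                    feasible = feasible, lambda = config$lambda,
                    T = config$T, actions = actions,
                    state_labels = state_df$label)
  mdp$G <- G
  mdp$B_units <- B_units
  mdp$unit <- unit
  mdp$config <- config
  mdp$state_df <- state_df
  mdp$i_fail <- i_fail
  mdp$i_succ <- i_succ
  mdp$state_index <- idx
  class(mdp) <- c("mati_mdp_model", class(mdp))
  mdp
}

#' Construct a finite-horizon MDP
#'
#' Generic container used by [backward_induction()] and
#' [enumerate_policies_oracle()]. Rewards may be stationary (a single
#' `n x |A|` matrix) or epoch-dependent (`function(t)` returning one).
#'
#' @param P List (one per action) of `n x n` row-stochastic matrices.
#' @param reward `n x |A|` matrix or `function(t)` returning one.
#' @param terminal Length-`n` vector of terminal values `u_T`.
#' @param feasible `n x |A|` logical matrix; every state needs at least one
#'   feasible action.
#' @param lambda Discount factor.
#' @param T Horizon (decisions at epochs `1..T-1`).
#' @param actions Action labels (numeric).
#' @param state_labels Optional character labels.
#' @return An object of class `fh_mdp`.
#' @export
new_fh_mdp <- function(P, reward, terminal, feasible, lambda, T, actions,
                       state_labels = NULL) {
  n <- nrow(P[[1]])
  for (M in P) {
    if (!all(dim(M) == c(n, n))) stop("all transition matrices must be n x n")
    if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-12))
      stop("transition matrix rows must be non-negative and sum to 1")
  }
  if (length(terminal) != n) stop("terminal values must have length n")
  if (!all(dim(feasible) == c(n, length(P))))
    stop("feasibility matrix must be n x |A|")
  if (any(rowSums(feasible) == 0))
    stop("every state needs at least one feasible action")
  r_fun <- if (is.function(reward)) reward else function(t) reward
  structure(list(P = P, reward = r_fun, terminal = terminal,
                 feasible = feasible, lambda = lambda, T = as.integer(T),
                 actions = actions, n_states = n,
                 state_labels = state_labels),
            class = "fh_mdp")
}

#' Solve a finite-horizon MDP by backward induction
#'
#' Computes the optimal value function `u_t*` and decision rules `d_t*` for
#' `t = T-1, ..., 1` by the backward recursion
#' `u_t*(s) = max_a { r_t(s, a) + lambda * sum_s' P(s'|s, a) u_{t+1}*(s') }`
#' with `u_T* = ` the terminal values. Ties are broken towards the smallest
#' action.
#'
#' @param mdp An `fh_mdp` (e.g. from [assemble_mdp()]).
#' @return An object of class `mati_policy`: `u` (`T x n` value matrix),
#'   `d_idx` (`(T-1) x n` matrix of action indices), `d` (same, as action
#'   values) and `actions`.
#' @export
backward_induction <- function(mdp) {
  stopifnot(inherits(mdp, "fh_mdp"))
  n <- mdp$n_states; T <- mdp$T; A <- length(mdp$actions)
  u <- matrix(0, T, n)
  u[T, ] <- mdp$terminal
  d_idx <- matrix(NA_integer_, max(T - 1, 0), n)
  if (T >= 2) for (t in (T - 1):1) {
    Q <- mdp$reward(t)
    for (ai in seq_len(A))
      Q[, ai] <- Q[, ai] + mdp$lambda * as.vector(mdp$P[[ai]] %*% u[t + 1, ])
    Q[!mdp$feasible] <- -Inf
    d_idx[t, ] <- max.col(Q, ties.method = "first")
    u[t, ] <- Q[cbind(seq_len(n), d_idx[t, ])]
  }
  structure(list(u = u, d_idx = d_idx,
                 d = matrix(mdp$actions[d_idx], nrow(d_idx), n),
                 actions = mdp$actions, T = T,
                 state_labels = mdp$state_labels),
            class = "mati_policy")
}

#' Evaluate a fixed deterministic Markov policy in-model
#'
#' Exact expected-reward recursion for a given decision-rule table, on the
#' same reward and discounting conventions as [backward_induction()]. Useful
#' for valuing static allocation strategies inside the fitted model.
#'
#' @param mdp An `fh_mdp`.
#' @param d_idx `(T-1) x n` matrix of action indices (or a
#'   `function(t, s) -> action index`).
#' @return `T x n` matrix of values `u_t^pi`.
#' @export
evaluate_policy <- function(mdp, d_idx) {
  n <- mdp$n_states; T <- mdp$T
  if (is.function(d_idx)) {
    f <- d_idx
    d_idx <- matrix(0L, T - 1, n)
    for (t in seq_len(T - 1)) for (s in seq_len(n)) d_idx[t, s] <- f(t, s)
  }
  if (any(!mdp$feasible[cbind(rep(seq_len(n), times = max(T - 1, 0)),
                              as.vector(t(d_idx)))]))
    stop("policy uses an infeasible action")
  u <- matrix(0, T, n)
  u[T, ] <- mdp$terminal
  if (T >= 2) for (t in (T - 1):1) {
    r <- mdp$reward(t)
    Pu <- vapply(seq_along(mdp$P),
                 function(ai) as.vector(mdp$P[[ai]] %*% u[t + 1, ]),
                 numeric(n))
    sel <- cbind(seq_len(n), d_idx[t, ])
    u[t, ] <- r[sel] + mdp$lambda * Pu[sel]
  }
  u
}

#' Brute-force policy enumeration oracle
#'
#' Evaluates every feasible deterministic Markov policy of a (small)
#' finite-horizon MDP by exact recursion and returns the per-state maximum of
#' `u_1`, together with the first policy attaining the maximum at the first
#' state. Exists to validate [backward_induction()]; refuses instances whose
#' policy count exceeds `cap`.
#'
#' @param mdp An `fh_mdp`.
#' @param cap Maximum number of policies to enumerate.
#' @return List with `value` (length-`n` vector, per-state optimum of `u_1`),
#'   `best_d_idx` (`(T-1) x n` matrix) and `n_policies`.
#' @export
enumerate_policies_oracle <- function(mdp, cap = 2e5) {
  n <- mdp$n_states; T <- mdp$T; A <- length(mdp$actions)
  cells <- expand.grid(s = seq_len(n), t = seq_len(max(T - 1, 0)))
  choice <- lapply(seq_len(nrow(cells)),
                   function(i) which(mdp$feasible[cells$s[i], ]))
  n_pol <- prod(vapply(choice, length, numeric(1)))
  if (n_pol > cap) stop("policy space too large to enumerate (", n_pol,
                        " > cap ", cap, ")")
  pol <- as.matrix(expand.grid(choice))  # n_pol x n_cells, cell = (s, t)
  u <- matrix(rep(mdp$terminal, each = n_pol), n_pol, n)
  if (T >= 2) for (t in (T - 1):1) {
    r <- mdp$reward(t)
    u_new <- matrix(0, n_pol, n)
    Pu <- lapply(mdp$P, function(M) u %*% t(M))  # n_pol x n, per action
    for (s in seq_len(n)) {
      acts <- pol[, (t - 1) * n + s]
      for (ai in unique(acts)) {
        rows <- which(acts == ai)
        u_new[rows, s] <- r[s, ai] + mdp$lambda * Pu[[ai]][rows, s]
      }
    }
    u <- u_new
  }
  value <- apply(u, 2, max)
  best <- which.max(u[, 1] >= value[1] - 0)  # first policy optimal at state 1
  best_d <- if (T >= 2)
    matrix(pol[best, ], T - 1, n, byrow = TRUE) else matrix(0L, 0, n)
  list(value = value, best_d_idx = best_d, n_policies = n_pol)
}

#' Serialise / load a fitted model bundle
#'
#' Writes the fitted decision model (map, configuration, interval partition,
#' empirical transition matrices, policy table and value function) to a
#' single JSON file, and reads it back as a `mati_mdp` object (without the
#' raw preliminary trajectories).
#'
#' @param fit A `mati_mdp` from [fit_mati_mdp()].
#' @param path File path for the JSON bundle.
#' @return `write_mati_model` returns `path` invisibly; `read_mati_model`
#'   returns a `mati_mdp`.
#' @export
write_mati_model <- function(fit, path) {
  stopifnot(inherits(fit, "mati_mdp"))
  bundle <- list(
    config = unclass(fit$config),
    map = list(chrom = fit$map$chrom, marker = fit$map$marker,
               pos_cM = fit$map$pos_cM, f = fit$map$f),
    donor_loci = fit$donor_loci,
    partition = list(G = fit$partition$G, breaks = fit$partition$breaks),
    W = fit$transitions$W,
    counts = fit$transitions$counts,
    policy = list(u = fit$solution$u, d = fit$solution$d),
    state_labels = fit$mdp$state_labels)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mati_model
#' @export
read_mati_model <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(mati_config, b$config[setdiff(names(b$config), NULL)])
  map <- validate_map(new_genetic_map(b$map$chrom, b$map$marker,
                                      b$map$pos_cM, b$map$f))
  partition <- structure(list(G = b$partition$G, breaks = b$partition$breaks),
                         class = "pcv_partition")
  W <- lapply(b$W, as.matrix)
  counts <- lapply(b$counts, as.matrix)
  trans <- structure(list(counts = counts, W = W,
                          actions = as.numeric(names(W)), G = b$partition$G),
                     class = "mati_transitions")
  mdp <- assemble_mdp(trans, cfg)
  sol <- backward_induction(mdp)
  fd <- make_founders(map, b$donor_loci)
  new_mati_mdp(map, fd$elite, fd$donor, b$donor_loci, NULL, partition,
               trans, mdp, sol, cfg)
}
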