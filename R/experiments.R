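#' Cost/time/probability (CTP) analysis
#'
#' Replicates the introgression process across a sweep of total budgets and
#' tabulates, per budget, the probability of reaching success at each
#' generation and the probability of failure, with Monte-Carlo standard
#' errors. The joint view of cost (budget), time (terminal generation) and
#' probability of success is the package's primary summary of a breeding
#' strategy.
#'
#' @param fit A `mati_mdp`.
#' @param budgets Total budgets in dollars (default from the fit's config).
#' @param policy `"dynamic"`, `"static"`, or a `function(budget)` returning
#'   a `mati_allocation`.
#' @param K Static per-generation progeny count (for `policy = "static"`).
#' @param n_reps Replications per budget (default 500).
#' @param screen_top Pre-screening size for parental selection.
#' @param seed Optional integer seed.
#' @return A data frame of class `mati_ctp` with columns `budget`, `outcome`
#'   (`"G<t>"` or `"failure"`), `probability`, `se`, `n`, and an attribute
#'   `"sims"`: the per-budget `mati_sim` objects for reuse by
#'   [optimize_budget()] and [allocation_breakdown()].
#' @export
ctp_analysis <- function(fit, budgets = fit$config$budgets,
                         policy = "dynamic", K = 400, n_reps = 500,
                         screen_top = 100, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  sims <- vector("list", length(budgets))
  names(sims) <- as.character(budgets)
  rows <- list()
  for (i in seq_along(budgets)) {
    B <- budgets[i]
    sim <- if (is.function(policy)) {
      pol <- policy(B)
      simulate_with_policy(fit, pol, n_reps, B, screen_top)
    } else {
      simulate(fit, nsim = n_reps, budget = B, policy = policy, K = K,
               screen_top = screen_top)
    }
    sims[[i]] <- sim
    rows[[i]] <- outcome_table(sim, B, n_reps)
  }
  out <- do.call(rbind, rows)
  attr(out, "sims") <- sims
  class(out) <- c("mati_ctp", "data.frame")
  out
}

# run a batch with an explicit allocation policy object
simulate_with_policy <- function(fit, pol, nsim, budget, screen_top) {
  runs <- vector("list", nsim)
  for (i in seq_len(nsim))
    runs[[i]] <- run_mati(fit$elite, fit$donor, fit$map, budget, pol,
                          T = fit$config$T, config = fit$config,
                          partition = fit$partition, screen_top = screen_top)
  maxg <- max(1, vapply(runs, function(r) nrow(r$trace), integer(1)))
  spend <- matrix(0, nsim, maxg)
  for (i in seq_len(nsim)) {
    tr <- runs[[i]]$trace
    if (nrow(tr)) spend[i, tr$t + 1] <- fit$config$cost_per_progeny * tr$K
  }
  out <- data.frame(run = seq_len(nsim),
                    Ts = vapply(runs, `[[`, numeric(1), "Ts"),
                    success = vapply(runs, `[[`, logical(1), "success"),
                    total_cost = vapply(runs, `[[`, numeric(1), "total_cost"),
                    revenue = vapply(runs, `[[`, numeric(1), "revenue"),
                    reward = vapply(runs, `[[`, numeric(1), "reward"))
  attr(out, "spend") <- spend
  attr(out, "budget") <- budget
  attr(out, "policy") <- pol$label
  class(out) <- c("mati_sim", "data.frame")
  out
}

outcome_table <- function(sim, budget, n_reps) {
  gens <- sort(unique(sim$Ts[is.finite(sim$Ts)]))
  outcomes <- c(if (length(gens)) paste0("G", gens) else character(0),
                "failure")
  counts <- c(vapply(gens, function(g) sum(sim$Ts == g), numeric(1)),
              sum(!sim$success))
  p <- counts / n_reps
  data.frame(budget = budget, outcome = outcomes, probability = p,
             se = sqrt(p * (1 - p) / n_reps), n = n_reps)
}

#' Compare static and dynamic allocation strategies at a fixed budget
#'
#' Side-by-side terminal-generation histograms for a set of static
#' per-generation strategies and the solved dynamic policy, all at the same
#' total budget, plus each strategy's exact in-model expected discounted
#' reward ([in_model_value()]).
#'
#' @param fit A `mati_mdp`.
#' @param budget Total budget in dollars (default $32,000).
#' @param static_Ks Static progeny counts to compare (default 100..700).
#' @param n_reps Replications per strategy (default 500).
#' @param screen_top Pre-screening size for parental selection.
#' @param seed Optional integer seed.
#' @return A list of class `mati_comparison`: `table` (strategy x outcome
#'   probabilities with standard errors), `values` (in-model expected
#'   rewards) and `budget`.
#' @export
compare_strategies <- function(fit, budget = 32000,
                               static_Ks = seq(100, 700, by = 100),
                               n_reps = 500, screen_top = 100, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  strategies <- c(paste0("static-", static_Ks), "dynamic")
  rows <- list()
  sims <- list()
  for (K in static_Ks) {
    sim <- simulate(fit, nsim = n_reps, budget = budget, policy = "static",
                    K = K, screen_top = screen_top)
    tab <- outcome_table(sim, budget, n_reps)
    tab$strategy <- paste0("static-", K)
    rows[[length(rows) + 1]] <- tab
    sims[[paste0("static-", K)]] <- sim
  }
  sim <- simulate(fit, nsim = n_reps, budget = budget, policy = "dynamic",
                  screen_top = screen_top)
  tab <- outcome_table(sim, budget, n_reps)
  tab$strategy <- "dynamic"
  rows[[length(rows) + 1]] <- tab
  sims[["dynamic"]] <- sim
  values <- data.frame(
    strategy = strategies,
    in_model_value = c(vapply(static_Ks, function(K)
      in_model_value(fit, budget, K), numeric(1)),
      in_model_value(fit, budget)),
    mean_realized_reward = vapply(sims, function(s) mean(s$reward),
                                  numeric(1)))
  structure(list(table = do.call(rbind, rows), values = values,
                 budget = budget, sims = sims),
            class = "mati_comparison")
}

#' @export
print.mati_comparison <- function(x, ...) {
  cat("Strategy comparison at total budget $",
      format(x$budget, big.mark = ","), "\n", sep = "")
  print(x$values, row.names = FALSE)
  invisible(x)
}

#' Optimal total budget by marginal-revenue analysis
#'
#' Estimates the mean realised net revenue (revenue minus incurred cost,
#' zero revenue on failure) at each total budget, fits the saturating curve
#' `y = a1 + a2 * exp(a3 * x)` (with `x` the budget in $1,000 units,
#' `a2 < 0`, `a3 < 0`) by nonlinear least squares with multi-start
#' initialisation, and locates the optimal budget where the marginal return
#' `a2 * a3 * exp(a3 * x)` per extra $1,000 falls to $1,000.
#'
#' @param fit A `mati_mdp`.
#' @param budgets Budgets in dollars (at least 4 for the 3-parameter fit).
#' @param policy,K,n_reps,screen_top,seed As in [ctp_analysis()].
#' @param ctp Optional precomputed `mati_ctp` over the same budgets; reuses
#'   its simulations instead of re-running them.
#' @return A list of class `mati_budget_curve`: `data` (budget, mean and SE
#'   of realised net revenue), `coef` (`a1`, `a2`, `a3`), `marginal`
#'   (function of budget in dollars), `optimal_budget` (dollars) and `unit`.
#' @export
optimize_budget <- function(fit, budgets = fit$config$budgets,
                            policy = "dynamic", K = 400, n_reps = 100,
                            screen_top = 100, seed = NULL, ctp = NULL) {
  if (is.null(ctp)) {
    if (length(budgets) < 4) stop("need at least 4 budget levels")
    ctp <- ctp_analysis(fit, budgets, policy, K, n_reps, screen_top, seed)
  }
  sims <- attr(ctp, "sims")
  budgets <- as.numeric(names(sims))
  y <- unname(vapply(sims, function(s) mean(s$reward), numeric(1)))
  se <- unname(vapply(sims, function(s) stats::sd(s$reward) / sqrt(nrow(s)),
                      numeric(1)))
  curve <- fit_revenue_curve(budgets, y, unit = fit$config$budget_unit)
  curve$data <- data.frame(budget = budgets, mean_revenue = y, se = se,
                           n = unname(vapply(sims, nrow, integer(1))))
  curve
}

#' Fit the saturating revenue curve and locate the optimal budget
#'
#' Nonlinear least-squares fit of `y = a1 + a2 * exp(a3 * x)` (with `x` the
#' budget in units, `a2 < 0`, `a3 < 0`) to mean-revenue observations, using
#' multi-start initialisation over the decay rate. The optimal total budget
#' is where the marginal return per extra unit equals the unit itself.
#'
#' @param budgets Budgets in dollars.
#' @param revenue Mean realised net revenue at each budget (dollars).
#' @param unit Budget unit in dollars (default $1,000).
#' @return A list of class `mati_budget_curve` (see [optimize_budget()]).
#' @export
fit_revenue_curve <- function(budgets, revenue, unit = 1000) {
  if (length(budgets) < 4) stop("need at least 4 budget levels")
  x <- budgets / unit
  y <- as.numeric(revenue)
  dat <- data.frame(x = x, y = y)
  best <- NULL
  for (a3 in c(-0.02, -0.05, -0.1, -0.2, -0.5)) {
    a1 <- max(y) + 0.05 * diff(range(y))
    a2 <- (y[1] - a1) / exp(a3 * x[1])
    fit_try <- tryCatch(
      minpack.lm::nlsLM(y ~ a1 + a2 * exp(a3 * x), data = dat,
                        start = list(a1 = a1, a2 = a2, a3 = a3),
                        upper = c(a1 = Inf, a2 = 0, a3 = 0),
                        lower = c(a1 = -Inf, a2 = -Inf, a3 = -5),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit_try)) {
      rss <- sum(stats::residuals(fit_try)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit_try, rss = rss)
    }
  }
  if (is.null(best))
    stop("nonlinear revenue regression failed to converge; ",
         "inspect the mean-revenue data")
  cf <- stats::coef(best$fit)
  marginal <- function(budget_dollars)
    cf[["a2"]] * cf[["a3"]] * exp(cf[["a3"]] * budget_dollars / unit)
  opt_x <- log(unit / (cf[["a2"]] * cf[["a3"]])) / cf[["a3"]]
  optimal_budget <- opt_x * unit
  if (!is.finite(optimal_budget) ||
      optimal_budget < min(budgets) || optimal_budget > max(budgets)) {
    warning("marginal return does not cross the unit increment inside the ",
            "budget range; optimal budget reported at the nearest boundary")
    optimal_budget <- min(max(optimal_budget, min(budgets)), max(budgets))
  }
  structure(list(data = data.frame(budget = budgets, mean_revenue = y),
                 coef = cf, marginal = marginal,
                 optimal_budget = optimal_budget, unit = unit,
                 nls_fit = best$fit),
            class = "mati_budget_curve")
}

#' @export
print.mati_budget_curve <- function(x, ...) {
  cat("Revenue curve fit: y = a1 + a2 * exp(a3 * x), x in $1,000 units\n")
  cat(sprintf("  a1 = %.4g, a2 = %.4g, a3 = %.4g\n",
              x$coef[["a1"]], x$coef[["a2"]], x$coef[["a3"]]))
  cat(sprintf("  optimal total budget (marginal return = $%s): $%s\n",
              format(x$unit, big.mark = ","),
              format(round(x$optimal_budget), big.mark = ",")))
  invisible(x)
}

#' Per-generation budget allocation breakdown
#'
#' Averages the realised spend per generation across replications and
#' normalises by the total spend, per budget level. Failed runs contribute
#' their partial spend.
#'
#' @param fit A `mati_mdp`.
#' @param budgets,policy,K,n_reps,screen_top,seed As in [ctp_analysis()].
#' @param ctp Optional precomputed `mati_ctp`; reuses its simulations.
#' @return A data frame of class `mati_breakdown`: `budget`, `generation`,
#'   `mean_spend` (dollars) and `proportion` (of total spend at that
#'   budget).
#' @export
allocation_breakdown <- function(fit, budgets = fit$config$budgets,
                                 policy = "dynamic", K = 400, n_reps = 100,
                                 screen_top = 100, seed = NULL, ctp = NULL) {
  if (is.null(ctp))
    ctp <- ctp_analysis(fit, budgets, policy, K, n_reps, screen_top, seed)
  sims <- attr(ctp, "sims")
  rows <- list()
  for (B in names(sims)) {
    spend <- attr(sims[[B]], "spend")
    ms <- colMeans(spend)
    rows[[B]] <- data.frame(budget = as.numeric(B),
                            generation = seq_along(ms) - 1L,
                            mean_spend = ms,
                            proportion = ms / sum(ms))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mati_breakdown", "data.frame")
  out
}

#' Plot methods for the experiment suite
#'
#' `plot.mati_ctp` draws the stacked success-probability histogram over
#' budgets; `plot.mati_budget_curve` the mean-revenue points, fitted curve
#' and marginal-return curve with the unit-increment line;
#' `plot.mati_breakdown` the stacked per-generation spend proportions.
#'
#' @param x The experiment result object.
#' @param ... Passed to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @name mati-plots
NULL

#' @rdname mati-plots
#' @export
plot.mati_ctp <- function(x, ...) {
  budgets <- unique(x$budget)
  outcomes <- unique(x$outcome)
  gens <- sort(as.integer(sub("^G", "", setdiff(outcomes, "failure"))))
  levels <- c(paste0("G", gens), "failure")
  m <- matrix(0, length(levels), length(budgets),
              dimnames = list(levels, budgets))
  for (i in seq_len(nrow(x)))
    m[x$outcome[i], as.character(x$budget[i])] <- x$probability[i]
  cols <- c(grDevices::gray.colors(length(gens), start = 0.2, end = 0.85),
            "firebrick")
  graphics::barplot(m, col = cols, border = NA,
                    xlab = "total budget ($)", ylab = "probability",
                    legend.text = levels,
                    args.legend = list(x = "topright", bty = "n", cex = 0.7),
                    ...)
  invisible(x)
}

#' @rdname mati-plots
#' @export
plot.mati_budget_curve <- function(x, ...) {
  d <- x$data
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(d$budget, d$mean_revenue, pch = 8, col = "blue",
                 xlab = "total budget ($)",
                 ylab = "expected net revenue ($)", ...)
  xs <- seq(min(d$budget), max(d$budget), length.out = 200)
  ys <- x$coef[["a1"]] + x$coef[["a2"]] * exp(x$coef[["a3"]] * xs / x$unit)
  graphics::lines(xs, ys, col = "blue")
  mr <- x$marginal(xs)
  graphics::par(new = TRUE)
  graphics::plot(xs, mr, type = "l", col = "red", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4, col.axis = "red")
  graphics::mtext("marginal return per $1,000", side = 4, line = 2.5,
                  col = "red", cex = 0.9)
  graphics::abline(h = x$unit, col = "red", lty = 2)
  graphics::abline(v = x$optimal_budget, col = "gray50", lty = 3)
  invisible(x)
}

#' @rdname mati-plots
#' @export
plot.mati_breakdown <- function(x, ...) {
  budgets <- unique(x$budget)
  gens <- sort(unique(x$generation))
  m <- matrix(0, length(gens), length(budgets),
              dimnames = list(paste0("G", gens), budgets))
  for (i in seq_len(nrow(x)))
    m[paste0("G", x$generation[i]), as.character(x$budget[i])] <-
      x$proportion[i]
  graphics::barplot(m, col = grDevices::gray.colors(length(gens)),
                    border = NA, xlab = "total budget ($)",
                    ylab = "proportion of budget",
                    legend.text = rownames(m),
                    args.legend = list(x = "topright", bty = "n", cex = 0.7),
                    ...)
  invisible(x)
}
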