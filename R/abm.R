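# Agent-based simulation of the full stochastic evolutionary process.
#
# One generation: a movement realization with one round of games assigns
# each individual its realized payoff as fitness; everyone returns home; a
# fresh movement realization (no games) sets the replacement groups; one
# birth-death event follows (BDB: reproducer proportional to fitness,
# victim uniform in the reproducer's group; BDD: reproducer uniform, victim
# proportional to inverse fitness in the group; a lone parent is replaced
# by its own offspring). Repeats until fixation or extinction.

#' Simulation configuration
#'
#' @param movement A [movement_spec()] with `N = M`.
#' @param game A [game_spec()].
#' @param dynamics `"BDB"` or `"BDD"`.
#' @param mutant_role `"A"` or `"B"`: the invading game type (the cooperator
#'   and the hawk are type A; the defector and the dove type B).
#' @param replicates Number of independent runs.
#' @param seed Master seed; each replicate uses a counter-derived substream.
#' @param max_steps Per-run safeguard; runs that have not absorbed by then
#'   are counted and excluded from the estimate.
#' @param idealized Replace realized one-round payoffs with state-dependent
#'   mean fitnesses (for direct comparison with the analytic process); the
#'   tables are supplied to [estimate_fixation()].
#' @param bdb_include_parent Let the BDB victim draw include the parent even
#'   when co-members exist (default `FALSE`: "another member of the group").
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(movement, game, dynamics = c("BDB", "BDD"),
                       mutant_role = c("A", "B"), replicates = 10000L,
                       seed = 1L, max_steps = 1e7, idealized = FALSE,
                       bdb_include_parent = FALSE) {
  stopifnot(inherits(movement, "movement_spec"), inherits(game, "game_spec"))
  dynamics <- match.arg(dynamics)
  mutant_role <- match.arg(mutant_role)
  if (movement$N != movement$M) {
    stop("The evolutionary setting requires N = M.", call. = FALSE)
  }
  replicates <- check_count(replicates, "replicates")
  if (max_steps < 1) stop("`max_steps` must be at least 1.", call. = FALSE)
  structure(list(movement = movement, game = game, dynamics = dynamics,
                 mutant_role = mutant_role, replicates = replicates,
                 seed = as.numeric(seed), max_steps = as.numeric(max_steps),
                 idealized = isTRUE(idealized),
                 bdb_include_parent = isTRUE(bdb_include_parent)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s / %s, mutant %s, N = %d, %d replicates, seed %g\n",
    x$game$kind, x$dynamics, x$mutant_role, x$movement$N, x$replicates,
    x$seed))
  invisible(x)
}

#' State-dependent fitness tables for the idealized simulation mode
#'
#' Builds the mean-fitness lookup used when the simulator runs in idealized
#' mode: Public Goods via the pair-meeting closed form (any mechanism,
#' given `d_N`), Hawk-Dove via the independent-movement closed forms.
#'
#' @param game A [game_spec()].
#' @param N Population size.
#' @param mutant_role `"A"` or `"B"`.
#' @param d_N Pair-meeting weight (Public Goods).
#' @param h Home fidelity (Hawk-Dove, independent movement).
#' @return List with numeric vectors `mutant` and `resident` indexed by the
#'   mutant count `k = 1..N-1`.
#' @export
fitness_tables <- function(game, N, mutant_role, d_N = NULL, h = NULL) {
  k <- seq_len(N - 1L)
  if (game$kind == "public_goods") {
    if (is.null(d_N)) stop("Public Goods tables need `d_N`.", call. = FALSE)
    if (mutant_role == "A") {
      f <- pgg_fitness_closed(game, k, N, d_N)
      list(mutant = f$F_C, resident = f$F_D)
    } else {
      f <- pgg_fitness_closed(game, N - k, N, d_N)
      list(mutant = f$F_D, resident = f$F_C)
    }
  } else {
    if (is.null(h)) stop("Hawk-Dove tables need `h`.", call. = FALSE)
    if (mutant_role == "B") {
      f <- purrr::map_dfr(k, function(kk) hd_fitness_closed(game, h, N, kk))
      list(mutant = f$F_dove, resident = f$F_hawk)
    } else {
      f <- purrr::map_dfr(k, function(kk) hd_fitness_closed(game, h, N,
                                                            N - kk))
      list(mutant = f$F_hawk, resident = f$F_dove)
    }
  }
}

#' Run a single evolutionary replicate
#'
#' @param config A [sim_config()] (its `replicates` field is ignored).
#' @param seed Seed for this run (defaults to the config's master seed).
#' @param tables Fitness tables for idealized mode (see [fitness_tables()]).
#' @return List with `fixed` (`TRUE`/`FALSE`/`NA` if not absorbed) and
#'   `steps`.
#' @export
run_single <- function(config, seed = config$seed, tables = NULL) {
  res <- abm_call(config, replicates = 1L, seed = seed, tables = tables)
  out <- res$outcome[1]
  list(fixed = if (out < 0) NA else out == 1L, steps = res$steps[1])
}

abm_call <- function(config, replicates, seed, tables = NULL) {
  mv <- config$movement
  g <- config$game
  minpay <- min_realizable_payoff(g, mv$N)
  if (!config$idealized && minpay <= 0) {
    stop(sprintf(paste0("Realizable payoffs must be strictly positive for ",
                        "the stochastic dynamics (minimum here: %g)."),
                 minpay), call. = FALSE)
  }
  if (config$idealized) {
    if (is.null(tables)) {
      stop("Idealized mode needs fitness `tables`.", call. = FALSE)
    }
    if (any(tables$mutant <= 0) || any(tables$resident <= 0)) {
      stop("Idealized fitness tables must be strictly positive.",
           call. = FALSE)
    }
  } else {
    tables <- list(mutant = rep(1, mv$N - 1L), resident = rep(1, mv$N - 1L))
  }
  abm_estimate_cpp(
    mechanism_code(mv$mechanism), mv$h, mv$N, mv$B %||% 0,
    wheel_step_or_zero(mv),
    if (g$kind == "public_goods") 1L else 2L, g$R, g$V, g$C,
    if (config$dynamics == "BDB") 1L else 2L,
    if (config$mutant_role == "A") 1L else 0L,
    as.integer(replicates), as.numeric(seed), config$max_steps,
    config$bdb_include_parent, config$idealized,
    tables$mutant, tables$resident
  )
}

#' Estimate a fixation probability by simulation
#'
#' Runs the configured number of replicates on counter-derived substreams
#' and reports the fixation frequency with a Wilson 95% interval.
#'
#' @inheritParams run_single
#' @return An object of class `fixation_sim`; see [tidy()] and [glance()].
#' @export
#' @examples
#' mv <- movement_spec("follow_majority", h = 1, N = 5)
#' g <- game_spec("public_goods", R = 10, V = 2, C = 1)
#' estimate_fixation(sim_config(mv, g, "BDB", "A", replicates = 200))
estimate_fixation <- function(config, tables = NULL) {
  res <- abm_call(config, config$replicates, config$seed, tables = tables)
  absorbed <- res$outcome >= 0
  n_bad <- sum(!absorbed)
  if (n_bad > 0) {
    warning(sprintf("%d of %d runs did not absorb within max_steps.",
                    n_bad, config$replicates))
  }
  n <- sum(absorbed)
  x <- sum(res$outcome == 1L)
  ci <- wilson_interval(x, n)
  structure(list(
    estimate = x / n,
    conf_low = ci[1], conf_high = ci[2],
    replicates = config$replicates, absorbed = n, non_absorbed = n_bad,
    mean_steps = mean(res$steps[absorbed]),
    config = config, seed = config$seed
  ), class = "fixation_sim")
}

wilson_interval <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- x / n
  centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' @export
print.fixation_sim <- function(x, ...) {
  cat(sprintf(
    "<fixation_sim> estimate %.5f [%.5f, %.5f] (%d runs, mean %.1f steps)\n",
    x$estimate, x$conf_low, x$conf_high, x$absorbed, x$mean_steps))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fixation_sim <- function(x, ...) {
  mv <- x$config$movement
  tibble::tibble(
    mechanism = mv$mechanism, h = mv$h, N = mv$N,
    B = mv$B %||% NA_real_, theta = mv$theta %||% NA_real_,
    game = x$config$game$kind, dynamics = x$config$dynamics,
    mutant_role = x$config$mutant_role,
    estimate = x$estimate, conf_low = x$conf_low, conf_high = x$conf_high,
    method = if (x$config$idealized) "simulation_idealized" else "simulation",
    replicates = x$replicates, seed = x$seed
  )
}

#' @exportS3Method generics::glance
glance.fixation_sim <- function(x, ...) {
  tibble::tibble(
    replicates = x$replicates, absorbed = x$absorbed,
    non_absorbed = x$non_absorbed, mean_steps = x$mean_steps,
    seed = x$seed
  )
}
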