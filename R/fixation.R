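# Fixation probability analytics on the complete graph.
#
# Everything is built on the standard birth-death chain identity
#   rho = 1 / (1 + sum_j prod_{k<=j} delta_k / beta_k),
# with the ratio constructions for BDB (selection on birth) and BDD
# (selection on death) dynamics, plus a full Markov linear solve that serves
# as an independent oracle for the closed forms.

#' Fixation probability from birth-death ratio sequence
#'
#' Evaluates `1 / (1 + sum_{j=1}^{N-1} prod_{k=1}^{j} ratios[k])` with the
#' products accumulated in log space.
#'
#' @param ratios Positive finite vector of `delta_k / beta_k`, `k = 1..N-1`.
#' @return Fixation probability of a single mutant.
#' @export
#' @examples
#' fixation_from_ratios(rep(1, 9)) # neutral, 1/10
fixation_from_ratios <- function(ratios) {
  if (length(ratios) < 1L || any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("`ratios` must be positive and finite.", call. = FALSE)
  }
  logcum <- cumsum(log(ratios))
  m <- max(0, logcum)
  # rho = exp(-m) / (exp(-m) + sum exp(logcum - m)), stable for long chains
  denom <- exp(-m) + sum(exp(logcum - m))
  exp(-m) / denom
}

#' BDB ratio sequence from state-dependent fitnesses
#'
#' Under BDB dynamics on the complete graph the death-to-birth ratio at
#' mutant count `k` collapses to `F_resident(k) / F_mutant(k)`.
#'
#' @param F_mutant,F_resident Positive vectors of mean fitnesses at mutant
#'   counts `k = 1..N-1`.
#' @return Vector of ratios.
#' @export
bdb_ratios <- function(F_mutant, F_resident) {
  check_fitness_positive(F_mutant, F_resident)
  F_resident / F_mutant
}

#' BDD ratio sequence from state-dependent fitnesses
#'
#' With selection on the death event the ratio at mutant count `k` is
#' `(N - k + (k + w*) F_R/F_M) / (k + (N - k + w*) F_M/F_R)`, where
#' `w* = (w_s - w)/w` compares the self replacement weight with the
#' pairwise one.
#'
#' @inheritParams bdb_ratios
#' @param w_star Finite self-vs-pair weight contrast.
#' @return Vector of ratios.
#' @export
bdd_ratios <- function(F_mutant, F_resident, w_star) {
  check_fitness_positive(F_mutant, F_resident)
  if (!is.finite(w_star)) stop("`w_star` must be finite.", call. = FALSE)
  N <- length(F_mutant) + 1L
  k <- seq_len(N - 1L)
  r <- F_resident / F_mutant
  (N - k + (k + w_star) * r) / (k + (N - k + w_star) / r)
}

check_fitness_positive <- function(F_mutant, F_resident) {
  if (length(F_mutant) != length(F_resident)) {
    stop("Fitness vectors must have equal length.", call. = FALSE)
  }
  bad <- which(!is.finite(F_mutant) | !is.finite(F_resident) |
                 F_mutant <= 0 | F_resident <= 0)
  if (length(bad)) {
    stop(sprintf("Non-positive or non-finite fitness at state k = %s.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

#' Closed-form fixation probability of a mutant cooperator (Public Goods)
#'
#' Composes the pair-meeting fitness closed form with the birth-death chain
#' formula for any movement mechanism summarized by `d_N` (and `w_star`
#' under BDD).
#'
#' @param game A `"public_goods"` [game_spec()].
#' @param N Population size.
#' @param d_N Pair-meeting weight.
#' @param dynamics `"BDB"` or `"BDD"`.
#' @param w_star Required for BDD.
#' @return Fixation probability of a single mutant cooperator.
#' @export
fixation_pgg <- function(game, N, d_N, dynamics = c("BDB", "BDD"),
                         w_star = NULL) {
  dynamics <- match.arg(dynamics)
  k <- seq_len(N - 1L)
  f <- pgg_fitness_closed(game, k, N, d_N)
  ratios <- switch(dynamics,
    BDB = bdb_ratios(f$F_C, f$F_D),
    BDD = bdd_ratios(f$F_C, f$F_D, require_w_star(w_star))
  )
  fixation_from_ratios(ratios)
}

#' Closed-form fixation probability of a mutant dove (Hawk-Dove)
#'
#' Uses the independent-movement closed-form fitnesses; the mutant type is
#' the dove, invading a hawk population.
#'
#' @param game A `"hawk_dove"` [game_spec()].
#' @param N Population size.
#' @param h Home fidelity.
#' @param dynamics `"BDB"` or `"BDD"`.
#' @param w_star Required for BDD.
#' @param fitness_fun Closed-form fitness route:
#'   [hd_fitness_closed()] (default) or [hd_fitness_independent()].
#' @return Fixation probability of a single mutant dove.
#' @export
fixation_hd <- function(game, N, h, dynamics = c("BDB", "BDD"),
                        w_star = NULL, fitness_fun = hd_fitness_closed) {
  dynamics <- match.arg(dynamics)
  f <- purrr::map_dfr(seq_len(N - 1L), function(k) fitness_fun(game, h, N, k))
  ratios <- switch(dynamics,
    BDB = bdb_ratios(f$F_dove, f$F_hawk),
    BDD = bdd_ratios(f$F_dove, f$F_hawk, require_w_star(w_star))
  )
  fixation_from_ratios(ratios)
}

require_w_star <- function(w_star) {
  if (is.null(w_star)) {
    stop("BDD dynamics need `w_star`.", call. = FALSE)
  }
  w_star
}

#' Markov-chain fixation oracle
#'
#' Builds the full `(N+1)`-state birth-death chain of the mutant count from
#' the dynamics' primitive transition rules (reproducer choice, then victim
#' choice through the replacement weights) and solves the boundary-value
#' linear system for the fixation probabilities. Independent of the product
#' closed form, which it is used to validate.
#'
#' @param F_mutant,F_resident Mean fitnesses at mutant counts `1..N-1`.
#' @param w Off-diagonal replacement weight (pair weight).
#' @param w_s Self replacement weight.
#' @param dynamics `"BDB"` or `"BDD"`.
#' @param start Mutant count whose fixation probability to return
#'   (default 1); `start = "all"` returns the whole vector `p_0..p_N`.
#' @return Fixation probability (or vector of all state probabilities).
#' @export
markov_fixation <- function(F_mutant, F_resident, w, w_s,
                            dynamics = c("BDB", "BDD"), start = 1L) {
  dynamics <- match.arg(dynamics)
  check_fitness_positive(F_mutant, F_resident)
  N <- length(F_mutant) + 1L
  if (w <= 0) {
    stop("w = 0: pairs never meet, absorption is unreachable.", call. = FALSE)
  }
  k <- seq_len(N - 1L)
  FM <- F_mutant
  FR <- F_resident
  if (dynamics == "BDB") {
    tot <- k * FM + (N - k) * FR
    up <- (k * FM / tot) * (N - k) * w
    down <- ((N - k) * FR / tot) * k * w
  } else {
    DM <- w_s / FM + w * ((k - 1) / FM + (N - k) / FR)
    DR <- w_s / FR + w * (k / FM + (N - k - 1) / FR)
    up <- (k / N) * (N - k) * (w / FR) / DM
    down <- ((N - k) / N) * k * (w / FM) / DR
  }
  if (any(up <= 0) || any(down <= 0)) {
    stop("Degenerate chain: a transition probability vanished.",
         call. = FALSE)
  }
  # (p_k - p_{k-1}) recurrence avoided: solve the tridiagonal system directly
  A <- matrix(0, N - 1L, N - 1L)
  bvec <- numeric(N - 1L)
  for (i in k) {
    A[i, i] <- up[i] + down[i]
    if (i > 1L) A[i, i - 1L] <- -down[i]
    if (i < N - 1L) A[i, i + 1L] <- -up[i]
  }
  bvec[N - 1L] <- up[N - 1L]
  p <- solve(A, bvec)
  if (identical(start, "all")) c(0, p, 1) else p[start]
}

#' Weak-selection fixation probability of a mutant cooperator
#'
#' First-order expansions in `1/R` of the Public Goods closed forms:
#' BDB `(1/N) (1 - (N-1)(V d_N + C) / (2R))`;
#' BDD `(1/N) (1 - (N + 2 w*)(N-1)(V d_N + C) / (2R (N + w*)))`.
#' The two coincide exactly when `w* = 0`.
#'
#' @inheritParams fixation_pgg
#' @param w_star Self-vs-pair weight contrast (BDD; defaults to 0).
#' @return Approximate fixation probability.
#' @export
weak_selection_pgg <- function(game, N, d_N, w_star = 0,
                               dynamics = c("BDB", "BDD")) {
  dynamics <- match.arg(dynamics)
  load <- (game$V * d_N + game$C) * (N - 1) / (2 * game$R)
  switch(dynamics,
    BDB = (1 / N) * (1 - load),
    BDD = (1 / N) * (1 - load * (N + 2 * w_star) / (N + w_star))
  )
}

#' Dove neutrality condition: the cost-to-reward ratio at rho = 1/N
#'
#' Solves numerically for the `C/V` ratio at which the mutant dove's
#' fixation probability equals the neutral value `1/N`, at given home
#' fidelity and population size under weak selection (large background
#' payoff `R`). A closed-form weak-selection expression involving the
#' Euler-Mascheroni constant and a generalized harmonic sum
#' `H[n, a] = sum_{k=1}^{n} a^k / k` with `a = (h+N-1)/(h+N-2)` is also
#' evaluated for comparison; the numeric root is the authoritative value.
#'
#' @param h Home fidelity.
#' @param N Population size.
#' @param R Background payoff (large; weak selection).
#' @param dynamics `"BDB"` or `"BDD"`.
#' @param w_star Needed for BDD (defaults to the independent-movement value).
#' @param interval Initial bracketing interval for `C/V`, expanded
#'   geometrically when needed.
#' @return One-row tibble: `ratio` (numeric root for C/V), `ratio_series`
#'   (the closed weak-selection expression), `discrepancy`, `residual`.
#' @export
dove_neutral_ratio <- function(h, N, R = 1e6, dynamics = c("BDB", "BDD"),
                               w_star = NULL, interval = c(0.5, 4)) {
  dynamics <- match.arg(dynamics)
  if (dynamics == "BDD" && is.null(w_star)) {
    ps <- pair_statistics_independent(h, N)
    w_star <- ps$w_star
  }
  target <- function(cv) {
    game <- game_spec("hawk_dove", R = R, V = 1, C = cv)
    fixation_hd(game, N, h, dynamics, w_star = w_star) - 1 / N
  }
  lo <- interval[1]
  hi <- interval[2]
  for (tries in 1:40) {
    if (target(lo) * target(hi) <= 0) break
    lo <- lo / 2
    hi <- hi * 2
    if (tries == 40) stop("No sign change found for the neutrality root.",
                          call. = FALSE)
  }
  root <- uniroot(target, c(lo, hi), tol = 1e-12)$root
  series <- dove_neutral_series(h, N)
  tibble::tibble(ratio = root, ratio_series = series,
                 discrepancy = root - series,
                 residual = abs(target(root)))
}

# weak-selection closed expression for the dove neutrality C/V ratio,
# under the documented interpretation of its symbols (Euler-Mascheroni
# constant; generalized harmonic number in the base (h+N-1)/(h+N-2))
dove_neutral_series <- function(h, N) {
  euler_gamma <- 0.57721566490153286
  a <- (h + N - 1) / (h + N - 2)
  kk <- seq_len(N - 1)
  H <- sum(a^kk / kk)
  f <- H - log(N - 1)
  # V = (1/2 - 1/e) / ((1/e)(gamma - 1 - f) + 1) * C  =>  C/V is the inverse
  ((1 / exp(1)) * (euler_gamma - 1 - f) + 1) / (1 / 2 - 1 / exp(1))
}

#' Infinite-population Hawk-Dove equilibrium ratio
#'
#' The reward-to-cost ratio `V/C` at which dove and hawk fitnesses are equal
#' in an infinite well-mixed population with dove proportion `p`:
#' `V/C = e p (e^(p-1) - p) / ((1 - e^(p-1)) e p - (e^p - 1)(1 - p))`.
#'
#' @param p Dove proportion in (0, 1).
#' @return The equilibrium `V/C` ratio.
#' @export
#' @examples
#' equilibrium_ratio(0.5) # ~ 0.688
equilibrium_ratio <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 ||
      p >= 1) {
    stop("`p` must lie strictly between 0 and 1.", call. = FALSE)
  }
  num <- exp(1) * p * (exp(p - 1) - p)
  den <- (1 - exp(p - 1)) * exp(1) * p - (exp(p) - 1) * (1 - p)
  if (abs(den) < 1e-14) {
    stop("Equilibrium ratio is singular at this `p`.", call. = FALSE)
  }
  num / den
}
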