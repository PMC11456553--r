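# State-dependent mean fitnesses.
#
# The reference route averages realized payoffs over the full group
# distribution; the closed forms (pair-meeting form for the Public Goods
# game, the tau/omega/nu expressions for the Hawk-Dove game under
# independent movement) are fast paths checked against it.

#' Mean fitness by state, averaged over the group distribution
#'
#' Places `k` mutants on homes `1..k` (any choice is equivalent by
#' exchangeability) and averages each type's payoff over every placement
#' configuration. Exact when the distribution is enumerable; otherwise a
#' Monte-Carlo placement distribution may be supplied or requested.
#'
#' @param spec A [movement_spec()] with `N = M`.
#' @param game A [game_spec()].
#' @param k Mutant count, `1 <= k <= N-1`.
#' @param mutant_role `"A"` or `"B"`: which game type invades.
#' @param dist Optional precomputed `placement_dist` for `spec`.
#' @param cap Enumeration cap when `dist` is not given.
#' @param samples If non-`NULL` and `N` exceeds `cap`, estimate from this
#'   many Monte-Carlo draws instead of failing.
#' @param seed Optional seed for the Monte-Carlo fallback.
#' @return One-row tibble: `k`, `F_mutant`, `F_resident`, `mutant_role`,
#'   `exact`. The per-individual fitnesses are attached as attribute
#'   `"per_individual"` for exchangeability checks.
#' @export
mean_fitness <- function(spec, game, k, mutant_role = c("A", "B"),
                         dist = NULL, cap = 6L, samples = NULL, seed = NULL) {
  mutant_role <- match.arg(mutant_role)
  N <- spec$N
  k <- check_count(k, "k")
  if (k < 1L || k > N - 1L) {
    stop("`k` must satisfy 1 <= k <= N - 1.", call. = FALSE)
  }
  if (is.null(dist)) {
    dist <- if (N <= cap) {
      enumerate_placements(spec, cap = cap)
    } else if (!is.null(samples)) {
      estimate_placements(spec, samples, seed = seed)
    } else {
      stop(sprintf(paste0("N = %d exceeds the enumeration cap (%d); pass ",
                          "`samples` to enable the Monte-Carlo fallback."),
                   N, cap), call. = FALSE)
    }
  }
  roles <- rep(if (mutant_role == "A") "B" else "A", N)
  roles[seq_len(k)] <- mutant_role
  per <- per_individual_fitness(dist, game, roles)
  tibble::tibble(
    k = k,
    F_mutant = mean(per[roles == mutant_role]),
    F_resident = mean(per[roles != mutant_role]),
    mutant_role = mutant_role,
    exact = dist$exact
  ) -> out
  attr(out, "per_individual") <- per
  out
}

per_individual_fitness <- function(dist, game, roles) {
  places <- dist$places
  N <- ncol(places)
  Aset <- which(roles == "A")
  sizes <- group_sizes_by_individual(places)
  countA <- matrix(0L, nrow(places), N)
  if (length(Aset)) {
    for (i in seq_len(N)) {
      countA[, i] <- rowSums(places[, Aset, drop = FALSE] == places[, i])
    }
  }
  vapply(seq_len(N), function(i) {
    a <- countA[, i]
    b <- sizes[, i] - a
    sum(dist$prob * group_payoff(game, a, b, roles[i]))
  }, numeric(1))
}

#' Closed-form Public Goods fitnesses via the pair-meeting weight
#'
#' For any movement mechanism, with `k` cooperators among `N` individuals
#' and pair-meeting weight `d_N`:
#' `F_C = R - C + (k-1) V d_N`, `F_D = R + k V d_N`.
#'
#' @param game A `"public_goods"` [game_spec()].
#' @param k Cooperator count.
#' @param N Population size.
#' @param d_N Pair-meeting weight in `[0, 1]`.
#' @return One-row tibble with `F_C` and `F_D`.
#' @export
pgg_fitness_closed <- function(game, k, N, d_N) {
  stopifnot(inherits(game, "game_spec"), game$kind == "public_goods")
  if (d_N < 0 || d_N > 1) stop("`d_N` must lie in [0, 1].", call. = FALSE)
  tibble::tibble(
    F_C = game$R - game$C + (k - 1) * game$V * d_N,
    F_D = game$R + k * game$V * d_N
  )
}

#' Closed-form Hawk-Dove fitnesses under independent movement
#'
#' With `k` doves and `N - k` hawks on the independent territorial raider,
#' the dove's fitness is `R + tau V` and the hawk's `R + omega V - nu C`,
#' with `tau`, `omega`, `nu` explicit functions of `(h, N, k)`. The dove
#' terms need `k >= 1`; the hawk terms need `k <= N - 1`.
#'
#' @param game A `"hawk_dove"` [game_spec()].
#' @param h Home fidelity.
#' @param N Population size.
#' @param k Dove count.
#' @return One-row tibble with `F_dove`, `F_hawk`, `tau`, `omega`, `nu`
#'   (`NA` where out of domain).
#' @export
hd_fitness_closed <- function(game, h, N, k) {
  stopifnot(inherits(game, "game_spec"), game$kind == "hawk_dove")
  if (k < 0 || k > N) stop("`k` must be in 0..N.", call. = FALSE)
  u <- h + N - 2
  v <- h + N - 1
  tau <- if (k >= 1) {
    (u / v)^(N - k) -
      (u^(N - 1) / v^N) * ((k * (N - 1) + (N - k) * (N - 1)) / k) +
      (N - k) * (N - 1) * u^(N - k - 1) / (k * v^(N - k))
  } else NA_real_
  if (k <= N - 1) {
    omega <- 1 + k / (N - k) -
      (N - 1) * u^(N - k - 1) / v^(N - k) -
      k * u^(N - k) / ((N - k) * v^(N - k))
    nu <- (k - N + 1) / v - k / (N - k) +
      (h * (N - k - 1) + (N - k - 1) * (N - 1)) / v^2 +
      k * u^(N - k) / ((N - k) * v^(N - k)) +
      (N - 1) * u^(N - k - 1) / v^(N - k)
  } else {
    omega <- NA_real_
    nu <- NA_real_
  }
  tibble::tibble(
    F_dove = game$R + tau * game$V,
    F_hawk = game$R + omega * game$V - nu * game$C,
    tau = tau, omega = omega, nu = nu
  )
}

#' Hawk-Dove fitnesses under independent movement by direct probability sums
#'
#' Independent derivation of the same quantities as [hd_fitness_closed()]
#' via binomial sums over the occupancy of the focal individual's place
#' (conditioning on whether the place owner is the focal individual, a dove
#' or a hawk). Valid for any `N`, including very large populations, which
#' makes it the route for infinite-population limit checks.
#'
#' @inheritParams hd_fitness_closed
#' @return One-row tibble with `F_dove`, `F_hawk`, `tau`, `omega`, `nu`.
#' @export
hd_fitness_independent <- function(game, h, N, k) {
  stopifnot(inherits(game, "game_spec"), game$kind == "hawk_dove")
  q <- 1 / (h + N - 1)
  qh <- h / (h + N - 1)
  e_inv_bin <- function(n, shift = 1) {
    if (n < 0) return(1 / shift)
    x <- 0:n
    sum(dbinom(x, n, q) / (shift + x))
  }
  e_inv_bern_bin <- function(n) {
    (1 - qh) * e_inv_bin(n, 1) + qh * e_inv_bin(n, 2)
  }
  tau <- if (k >= 1) {
    qh * (1 - q)^(N - k) * e_inv_bin(k - 1) +
      q * (N - k) * (1 - qh) * (1 - q)^(N - k - 1) * e_inv_bin(k - 1) +
      q * (k - 1) * (1 - q)^(N - k) * e_inv_bern_bin(k - 2)
  } else NA_real_
  if (k <= N - 1) {
    omega <- (qh + q * k) * e_inv_bin(N - k - 1) +
      q * (N - k - 1) * e_inv_bern_bin(N - k - 2)
    nu <- 1 - omega
  } else {
    omega <- NA_real_
    nu <- NA_real_
  }
  tibble::tibble(
    F_dove = game$R + tau * game$V,
    F_hawk = game$R + omega * game$V - nu * game$C,
    tau = tau, omega = omega, nu = nu
  )
}

#' Infinite-population Hawk-Dove fitnesses
#'
#' Limits of the finite-population dove and hawk fitnesses as `N` grows with
#' a fixed dove proportion `p` (well-mixed, `h = 1`):
#' dove `R + ((e^p - 1)/(e p)) V`;
#' hawk `R + ((1 - e^(p-1))/(1 - p)) V - ((e^(p-1) - p)/(1 - p)) C`.
#'
#' @param game A `"hawk_dove"` [game_spec()].
#' @param p Dove proportion, strictly between 0 and 1.
#' @return One-row tibble with `F_dove` and `F_hawk`.
#' @export
infinite_population_fitness <- function(game, p) {
  stopifnot(inherits(game, "game_spec"), game$kind == "hawk_dove")
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 ||
      p >= 1) {
    stop("`p` must lie strictly between 0 and 1.", call. = FALSE)
  }
  tibble::tibble(
    F_dove = game$R + (exp(p) - 1) / (exp(1) * p) * game$V,
    F_hawk = game$R + (1 - exp(p - 1)) / (1 - p) * game$V -
      (exp(p - 1) - p) / (1 - p) * game$C
  )
}
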