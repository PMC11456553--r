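# Group distributions and the derived replacement-weight statistics.

#' Group distribution induced by co-location
#'
#' Aggregates a placement distribution into the probability mass over
#' co-location partitions of the population. With `labelled = TRUE` the
#' partition keys retain the place label of each group (needed for
#' faithfulness checks); without labels only the grouping matters (all the
#' game payoffs need).
#'
#' @param dist A `placement_dist` from [enumerate_placements()] or
#'   [estimate_placements()].
#' @param labelled Keep place labels in the partition keys?
#' @return A tibble with columns `partition` and `probability`, sorted by
#'   decreasing probability.
#' @export
#' @examples
#' spec <- movement_spec("follow_majority", h = 2, N = 3)
#' group_distribution(enumerate_placements(spec))
group_distribution <- function(dist, labelled = FALSE) {
  stopifnot(inherits(dist, "placement_dist"))
  N <- ncol(dist$places)
  keys <- apply(dist$places, 1L, function(pl) {
    grp <- split(seq_len(N), pl)
    lab <- vapply(names(grp), function(m) {
      members <- paste(grp[[m]], collapse = ",")
      if (labelled) paste0("P", m, ":", members) else members
    }, character(1))
    paste(lab[order(vapply(grp, min, numeric(1)))], collapse = "|")
  })
  agg <- rowsum(dist$prob, keys)
  tibble::tibble(partition = rownames(agg), probability = as.vector(agg)) |>
    dplyr::arrange(dplyr::desc(.data$probability))
}

#' Per-individual marginal place distribution
#'
#' @inheritParams group_distribution
#' @return `N` by `M` matrix; row `i` is individual `i`'s marginal.
#' @export
placement_marginals <- function(dist) {
  stopifnot(inherits(dist, "placement_dist"))
  N <- ncol(dist$places)
  M <- dist$spec$M
  marg <- matrix(0, N, M)
  for (m in seq_len(M)) {
    marg[, m] <- colSums(dist$prob * (dist$places == m))
  }
  marg
}

# group size of each individual's group, per configuration: K x N matrix
group_sizes_by_individual <- function(places) {
  N <- ncol(places)
  sizes <- matrix(0L, nrow(places), N)
  for (i in seq_len(N)) {
    sizes[, i] <- rowSums(places == places[, i])
  }
  sizes
}

#' Pair-meeting and replacement-weight statistics
#'
#' Computes the pair-meeting weight `d_N = sum_S gamma_{S+2} / (S+1)` (the
#' probability-weighted chance that a fixed pair shares a group, discounted
#' by the number of co-members), the off-diagonal replacement weight
#' `w = d_N`, the self-weight `w_s` (probability of being alone), and
#' `w_star = (w_s - w) / w`. On the complete graph every pair gives the same
#' `d`; the average is reported together with the maximum per-pair spread.
#'
#' @inheritParams group_distribution
#' @return One-row tibble with columns `d`, `w`, `w_s`, `w_star`, `N`,
#'   `pair_spread`, `exact`.
#' @export
pair_statistics <- function(dist) {
  stopifnot(inherits(dist, "placement_dist"))
  N <- ncol(dist$places)
  if (N < 2L) stop("Pair statistics need at least two individuals.",
                   call. = FALSE)
  sizes <- group_sizes_by_individual(dist$places)
  d_pairs <- numeric(0)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      together <- dist$places[, i] == dist$places[, j]
      d_pairs <- c(d_pairs,
                   sum(dist$prob[together] / (sizes[together, i] - 1L)))
    }
  }
  w_s <- mean(vapply(seq_len(N), function(i) {
    sum(dist$prob[sizes[, i] == 1L])
  }, numeric(1)))
  w <- mean(d_pairs)
  if (w <= 0) {
    stop("w = 0: the process never brings a pair together, so w* is undefined.",
         call. = FALSE)
  }
  tibble::tibble(d = w, w = w, w_s = w_s, w_star = (w_s - w) / w, N = N,
                 pair_spread = max(d_pairs) - min(d_pairs),
                 exact = dist$exact)
}

#' Exact pair statistics under independent movement, any population size
#'
#' Closed computation of `d_N` and `w_s` for the independent territorial
#' raider on the complete graph with `N = M`, via binomial sums over the
#' occupancy of the meeting place (the place owner has visiting probability
#' `h/(h+N-1)`; everyone else `1/(h+N-1)`).
#'
#' @param h Home fidelity.
#' @param N Population size (`= M`).
#' @return One-row tibble as in [pair_statistics()].
#' @export
pair_statistics_independent <- function(h, N) {
  N <- check_count(N, "N")
  q <- 1 / (h + N - 1)
  qh <- h / (h + N - 1)
  # E[1 / (1 + X)] for X ~ Bin(n, q)
  e_inv_bin <- function(n, shift = 1) {
    if (n < 0) return(1 / shift)
    x <- 0:n
    sum(dbinom(x, n, q) / (shift + x))
  }
  # meeting place of the focal pair {1, 2}:
  # at 1's home, at 2's home, or at one of the N-2 third-party places
  e_third <- qh * e_inv_bin(N - 3L, 2) + (1 - qh) * e_inv_bin(N - 3L, 1)
  d <- qh * q * e_inv_bin(N - 2L) +
    q * qh * e_inv_bin(N - 2L) +
    q * q * (N - 2L) * e_third
  w_s <- qh * (1 - q)^(N - 1L) +
    (N - 1L) * q * (1 - qh) * (1 - q)^(N - 2L)
  tibble::tibble(d = d, w = d, w_s = w_s, w_star = (w_s - d) / d, N = N,
                 pair_spread = 0, exact = TRUE)
}

#' Monte-Carlo pair statistics
#'
#' Estimates `d_N`, `w_s` and `w_star` directly from sampled configurations
#' without tabulating the full distribution (cheap at `N = 10` and beyond).
#'
#' @inheritParams enumerate_placements
#' @param samples Number of draws.
#' @param seed Optional integer seed for the compiled sampler stream.
#' @return One-row tibble as in [pair_statistics()] (with `exact = FALSE`
#'   and an extra `samples` column).
#' @export
estimate_pair_statistics <- function(spec, samples, seed = NULL) {
  draws <- sample_configurations(spec, samples, seed = seed)
  N <- ncol(draws)
  sizes <- group_sizes_by_individual(draws)
  d_pairs <- numeric(0)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      together <- draws[, i] == draws[, j]
      d_pairs <- c(d_pairs, sum(1 / (sizes[together, i] - 1L)) / nrow(draws))
    }
  }
  w <- mean(d_pairs)
  w_s <- mean(sizes == 1L)
  if (w <= 0) {
    stop("w = 0: no pair ever met in the sample; w* is undefined.",
         call. = FALSE)
  }
  tibble::tibble(d = w, w = w, w_s = w_s, w_star = (w_s - w) / w, N = N,
                 pair_spread = max(d_pairs) - min(d_pairs),
                 exact = FALSE, samples = nrow(draws))
}
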