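# Exact group-formation distributions.
#
# A `placement_dist` stores the probability mass over full placement
# configurations (who is at which place) as a pattern matrix plus a
# probability vector. Exact distributions are computed by summing over
# participation sets and mechanism outcomes; empirical ones tabulate draws.

new_placement_dist <- function(places, prob, spec, exact, samples = NA_real_) {
  structure(list(places = places, prob = prob, spec = spec, exact = exact,
                 samples = samples),
            class = "placement_dist")
}

#' @export
print.placement_dist <- function(x, ...) {
  cat(sprintf("<placement_dist> %s over %d configurations (N = %d, M = %d)\n",
              if (x$exact) "exact" else
                sprintf("empirical (%g samples)", x$samples),
              nrow(x$places), ncol(x$places), x$spec$M))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.placement_dist <- function(x, ...) {
  keys <- apply(x$places, 1L, paste, collapse = ",")
  tibble::tibble(placement = keys, probability = x$prob)
}

# Exact distribution of mechanism participants' places (uniform random order
# where the order matters), as a pattern matrix (rows: outcomes, cols:
# participants in their index order) and probability vector.
mech_pattern_dist <- function(spec, p, apriori = rep(1 / spec$M, spec$M)) {
  M <- length(apriori)
  if (p == 0L) {
    return(list(pat = matrix(integer(0), nrow = 1L, ncol = 0L), prob = 1))
  }
  switch(spec$mechanism,
    independent = independent_patterns(p, apriori),
    follow_majority = cluster_patterns(p, apriori),
    polya_urn = if (spec$B == 0) cluster_patterns(p, apriori)
                else urn_patterns(p, apriori, spec$B),
    wheel = wheel_patterns(p, apriori, wheel_step(spec))
  )
}

independent_patterns <- function(p, apriori) {
  M <- length(apriori)
  pat <- as.matrix(expand.grid(rep(list(seq_len(M)), p)))
  dimnames(pat) <- NULL
  prob <- apply(pat, 1L, function(r) prod(apriori[r]))
  list(pat = pat, prob = prob)
}

cluster_patterns <- function(p, apriori) {
  M <- length(apriori)
  list(pat = matrix(rep(seq_len(M), each = p), nrow = M, byrow = TRUE),
       prob = apriori)
}

# Polya-urn draws are exchangeable, so enumerating one participant order
# gives the correct joint distribution of the placement vector.
urn_patterns <- function(p, apriori, B) {
  M <- length(apriori)
  pat <- matrix(integer(0), nrow = 1L, ncol = 0L)
  prob <- 1
  for (j in seq_len(p)) {
    K <- nrow(pat)
    newpat <- matrix(0L, K * M, j)
    newprob <- numeric(K * M)
    for (k in seq_len(K)) {
      occ <- tabulate(pat[k, ], nbins = M)
      wts <- B * apriori + occ
      wts <- wts / sum(wts)
      idx <- (k - 1L) * M + seq_len(M)
      if (j > 1L) newpat[idx, seq_len(j - 1L)] <-
          matrix(pat[k, ], M, j - 1L, byrow = TRUE)
      newpat[idx, j] <- seq_len(M)
      newprob[idx] <- prob[k] * wts
    }
    keep <- newprob > 0
    pat <- newpat[keep, , drop = FALSE]
    prob <- newprob[keep]
  }
  list(pat = pat, prob = prob)
}

# Exact wheel distribution: the rotation phi is uniform on [0, 1); spike j
# sits at (j-1)*t + phi. The map phi -> placement pattern is piecewise
# constant with breakpoints where a spike crosses an arc boundary; the
# probability of a pattern is the total length of its rotation intervals.
# Spikes are assigned to participants in a uniformly random order, so the
# spike-level patterns are averaged over all assignments.
wheel_patterns <- function(p, apriori, t_frac) {
  M <- length(apriori)
  cuts <- cumsum(apriori)
  offs <- (seq_len(p) - 1) * t_frac
  bps <- sort(unique(as.vector(outer(cuts, offs, function(cm, o)
    (cm - o) %% 1))))
  bps <- bps[c(TRUE, diff(bps) > 1e-13)]
  if (length(bps) == 0L || bps[1] > 1e-13) bps <- c(0, bps)
  ends <- c(bps[-1L], bps[1L] + 1)
  lens <- ends - bps
  mids <- (bps + ends) / 2
  spike_pat <- matrix(0L, length(mids), p)
  for (j in seq_len(p)) {
    pos <- (mids + offs[j]) %% 1
    spike_pat[, j] <- pmin(findInterval(pos, cuts, left.open = FALSE) + 1L, M)
  }
  # average over assignments of spikes to participants
  perms <- all_permutations(p)
  K <- nrow(spike_pat)
  nperm <- nrow(perms)
  pat <- matrix(0L, K * nperm, p)
  prob <- numeric(K * nperm)
  for (q in seq_len(nperm)) {
    idx <- (q - 1L) * K + seq_len(K)
    pat[idx, perms[q, ]] <- spike_pat
    prob[idx] <- lens / nperm
  }
  collapse_patterns(pat, prob)
}

all_permutations <- function(p) {
  if (p == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(p - 1L)
  out <- matrix(0L, nrow(sub) * p, p)
  r <- 0L
  for (pos in seq_len(p)) {
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- append(sub[i, ], p, after = pos - 1L)
      out[r, ] <- row
    }
  }
  out
}

collapse_patterns <- function(pat, prob) {
  keys <- apply(pat, 1L, paste, collapse = ",")
  agg <- rowsum(prob, keys)
  first <- !duplicated(keys)
  upat <- pat[first, , drop = FALSE]
  ukeys <- keys[first]
  list(pat = upat, prob = as.vector(agg[match(ukeys, rownames(agg)), ]))
}

#' Exact group-formation distribution
#'
#' Enumerates the exact probability of every placement configuration in the
#' evolutionary setting (`N = M`, homes on the diagonal), summing over
#' participation sets, mechanism outcomes, and non-participant choices.
#' Independent movement short-circuits to the product of the
#' territorial-raider marginals.
#'
#' @param spec A [movement_spec()] with `N = M`.
#' @param cap Enumeration cap on `N`; larger populations should use
#'   [estimate_placements()].
#' @return A `placement_dist` object (see [group_distribution()],
#'   [pair_statistics()], [placement_marginals()]).
#' @export
enumerate_placements <- function(spec, cap = 6L) {
  stopifnot(inherits(spec, "movement_spec"))
  if (spec$N != spec$M) {
    stop("The evolutionary setting requires N = M.", call. = FALSE)
  }
  N <- spec$N
  if (N > cap) {
    stop(sprintf(paste0("N = %d exceeds the enumeration cap (%d); use ",
                        "estimate_placements() for a Monte-Carlo estimate."),
                 N, cap), call. = FALSE)
  }
  M <- spec$M
  if (spec$mechanism == "independent") {
    pmat <- t(vapply(seq_len(N), function(i) territorial_apriori(spec$h, M, i),
                     numeric(M)))
    out <- independent_patterns(N, rep(1 / M, M))
    prob <- vapply(seq_len(nrow(out$pat)), function(r) {
      prod(pmat[cbind(seq_len(N), out$pat[r, ])])
    }, numeric(1))
    keep <- prob > 0
    return(new_placement_dist(out$pat[keep, , drop = FALSE], prob[keep],
                              spec, exact = TRUE))
  }
  split <- participation_split(spec$h, M)
  pm <- split$p_mechanism
  pother <- if (spec$h > 1) split$p_direct_home else split$p_random_nonhome
  pat_list <- list()
  prob_list <- list()
  masks <- if (spec$h == 1) (2^N - 1L) else 0:(2^N - 1L)
  for (mask in masks) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(N - 1L))) != 0L)
    p <- length(S)
    q <- N - p
    prob_act <- pm^p * pother^q
    if (prob_act == 0) next
    mech <- mech_pattern_dist(spec, p)
    nonS <- setdiff(seq_len(N), S)
    if (spec$h >= 1 || q == 0L) {
      non_pat <- matrix(nonS, nrow = 1L)
      non_prob <- 1
    } else {
      choices <- lapply(nonS, function(i) setdiff(seq_len(M), i))
      non_pat <- as.matrix(expand.grid(choices))
      dimnames(non_pat) <- NULL
      non_prob <- rep((1 / (M - 1))^q, nrow(non_pat))
    }
    qa <- nrow(mech$pat)
    qb <- nrow(non_pat)
    full <- matrix(0L, qa * qb, N)
    if (p > 0L) full[, S] <- mech$pat[rep(seq_len(qa), each = qb), ,
                                      drop = FALSE]
    if (q > 0L) full[, nonS] <- non_pat[rep(seq_len(qb), qa), , drop = FALSE]
    pat_list[[length(pat_list) + 1L]] <- full
    prob_list[[length(prob_list) + 1L]] <-
      prob_act * mech$prob[rep(seq_len(qa), each = qb)] *
      non_prob[rep(seq_len(qb), qa)]
  }
  pat <- do.call(rbind, pat_list)
  prob <- unlist(prob_list)
  out <- collapse_patterns(pat, prob)
  new_placement_dist(out$pat, out$prob, spec, exact = TRUE)
}

#' Monte-Carlo group-formation distribution
#'
#' @inheritParams enumerate_placements
#' @param samples Number of configurations to draw (at least 1).
#' @param seed Optional integer seed for the compiled sampler stream.
#' @return A `placement_dist` with empirical frequencies; raw counts are
#'   recoverable as `probability * samples`.
#' @export
estimate_placements <- function(spec, samples, seed = NULL) {
  stopifnot(inherits(spec, "movement_spec"))
  samples <- check_count(samples, "samples")
  draws <- sample_configurations(spec, samples, seed = seed)
  out <- collapse_patterns(draws, rep(1 / samples, samples))
  new_placement_dist(out$pat, out$prob, spec, exact = FALSE,
                     samples = samples)
}

#' Probability that a given group forms at a given place (independent model)
#'
#' For fully independent movement with placement probabilities `p[n, m]`,
#' the probability that exactly the group `G` is present at place `m` is
#' `prod_{i in G} p[i, m] * prod_{j not in G} (1 - p[j, m])`.
#'
#' @param placement_probs `N` by `M` matrix with rows summing to 1.
#' @param m Place index.
#' @param G Integer vector of individual indices (non-empty).
#' @return A probability.
#' @export
chi_independent <- function(placement_probs, m, G) {
  if (!is.matrix(placement_probs) ||
      any(abs(rowSums(placement_probs) - 1) > 1e-10)) {
    stop("`placement_probs` rows must sum to 1.", call. = FALSE)
  }
  if (length(G) < 1L) stop("`G` must be non-empty.", call. = FALSE)
  others <- setdiff(seq_len(nrow(placement_probs)), G)
  prod(placement_probs[G, m]) * prod(1 - placement_probs[others, m])
}
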