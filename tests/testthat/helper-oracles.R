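# Shared fixtures and small independent oracles used across the suite.

pgg10 <- game_spec("public_goods", R = 10, V = 2, C = 1)
hd10 <- game_spec("hawk_dove", R = 10, V = 2, C = 1)

# every mechanism at a given (h, N), for grid tests
mechanism_specs <- function(h, N) {
  list(
    independent = movement_spec("independent", h = h, N = N),
    follow_majority = movement_spec("follow_majority", h = h, N = N),
    polya_urn = movement_spec("polya_urn", h = h, N = N, B = 2),
    wheel = movement_spec("wheel", h = h, N = N, theta = pi / N)
  )
}

# worked exact partition probabilities for follow-the-majority at N = 3,
# h >= 1: closed rational expressions in h
ftm3_exact <- function(h) {
  d <- (h + 2)^3
  c(all_together = (27 + 9 * (h - 1)) / d,
    one_pair = (2 * (h - 1)^2 + 6 * (h - 1)) / d,
    all_alone = (3 * (h - 1)^2 + (h - 1)^3) / d)
}

# brute-force fixation probability of a birth-death chain by first-step
# simulation-free enumeration: solve p_k = up p_{k+1} + down p_{k-1} + stay p_k
# with dense linear algebra, from explicit up/down vectors
chain_solve <- function(up, down) {
  n <- length(up)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    A[i, i] <- up[i] + down[i]
    if (i > 1) A[i, i - 1] <- -down[i]
    if (i < n) A[i, i + 1] <- -up[i]
  }
  b[n] <- up[n]
  solve(A, b)[1]
}

# target marginal matrix for the territorial raider
apriori_matrix <- function(h, N) {
  t(vapply(seq_len(N), function(i) territorial_apriori(h, N, i), numeric(N)))
}
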