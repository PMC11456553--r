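test_that("territorial apriori weights home by h and the rest uniformly", {
  expect_equal(territorial_apriori(1, 3), rep(1 / 3, 3))
  expect_equal(territorial_apriori(2, 3), c(1 / 2, 1 / 4, 1 / 4))
  expect_equal(territorial_apriori(2, 3, home = 3), c(1 / 4, 1 / 4, 1 / 2))
  expect_error(territorial_apriori(0, 3), "positive")
  expect_error(territorial_apriori(1, 1), "at least 2")
})

test_that("participation split matches the three home-fidelity cases and
           composes to the apriori target", {
  expect_equal(unlist(participation_split(2, 3)),
               c(p_direct_home = 0.25, p_mechanism = 0.75,
                 p_random_nonhome = 0))
  expect_equal(unlist(participation_split(1, 3)),
               c(p_direct_home = 0, p_mechanism = 1, p_random_nonhome = 0))
  expect_equal(unlist(participation_split(0.5, 3)),
               c(p_direct_home = 0, p_mechanism = 0.6,
                 p_random_nonhome = 0.4))
  for (h in c(0.3, 0.7, 1, 1.5, 5)) {
    for (M in c(2, 5, 9)) {
      sp <- participation_split(h, M)
      expect_equal(sp$p_direct_home + sp$p_mechanism + sp$p_random_nonhome, 1,
                   tolerance = 1e-12)
      # composed marginal: home = direct + uniform mechanism share
      p_home <- sp$p_direct_home + sp$p_mechanism / M
      p_other <- sp$p_mechanism / M + sp$p_random_nonhome / (M - 1)
      expect_equal(p_home, h / (h + M - 1), tolerance = 1e-14)
      expect_equal(p_other, 1 / (h + M - 1), tolerance = 1e-14)
    }
  }
  expect_error(participation_split(-1, 3), "positive")
})

test_that("follow-the-majority co-locates every participant", {
  set.seed(42)
  apriori <- c(0.5, 0.3, 0.2)
  expect_length(sample_follow_majority(integer(0), apriori), 0)
  for (i in 1:50) {
    pl <- sample_follow_majority(1:4, apriori)
    expect_length(unique(pl), 1L)
  }
  # single participant follows the apriori marginal
  draws <- replicate(6000, sample_follow_majority(7L, apriori))
  freq <- tabulate(draws, 3) / 6000
  se <- sqrt(apriori * (1 - apriori) / 6000)
  expect_true(all(abs(freq - apriori) < 4 * se))
})

test_that("polya-urn second mover joins the first with probability
           (B a + 1)/(B + 1)", {
  set.seed(7)
  hits <- replicate(20000, {
    pl <- sample_polya_urn(1:2, rep(1 / 3, 3), B = 2)
    pl[1] == pl[2]
  })
  p <- 5 / 9
  expect_lt(abs(mean(hits) - p), 4 * sqrt(p * (1 - p) / 20000))
  expect_error(sample_polya_urn(1:2, rep(1 / 3, 3), B = -1),
               "non-negative")
  # B = 0 collapses to a single cluster like follow-the-majority
  set.seed(8)
  for (i in 1:50) {
    expect_length(unique(sample_polya_urn(1:4, rep(1 / 4, 4), B = 0)), 1L)
  }
})

test_that("wheel spins: theta 0 herds, theta 2*pi/N with equal arcs
           disperses, and arbitrary arcs keep faithful marginals", {
  set.seed(11)
  for (i in 1:50) {
    expect_length(unique(sample_wheel(1:5, rep(1 / 5, 5), theta = 0)), 1L)
  }
  for (i in 1:50) {
    pl <- sample_wheel(1:4, rep(1 / 4, 4), theta = 2 * pi / 4,
                       theta_precision = NULL)
    expect_length(unique(pl), 4L)
  }
  arcs <- c(1 / 3, 1 / 6, 1 / 2)
  draws <- t(replicate(8000, sample_wheel(1:2, arcs, theta = 1.1)))
  for (j in 1:2) {
    freq <- tabulate(draws[, j], 3) / 8000
    se <- sqrt(arcs * (1 - arcs) / 8000)
    expect_true(all(abs(freq - arcs) < 4 * se))
  }
  expect_error(sample_wheel(1:2, arcs, theta = 7), "2\\*pi")
})

test_that("sample_configuration respects the embedding and is reproducible", {
  spec <- movement_spec("follow_majority", h = 1e6, N = 4)
  set.seed(1)
  for (i in 1:20) expect_equal(sample_configuration(spec), 1:4)
  spec1 <- movement_spec("polya_urn", h = 1, N = 4, B = 2)
  set.seed(2)
  det <- sample_configuration(spec1, detail = TRUE)
  expect_true(all(det$action == "mechanism"))
  expect_error(sample_configuration(movement_spec("independent", h = 1,
                                                  N = 3, M = 4)),
               "N = M")
  set.seed(99)
  a <- sample_configuration(spec1)
  set.seed(99)
  b <- sample_configuration(spec1)
  expect_identical(a, b)
  expect_identical(sample_configurations(spec1, 50, seed = 5),
                   sample_configurations(spec1, 50, seed = 5))
})

test_that("compiled bulk sampler agrees with the exact distribution", {
  # pattern frequencies from C++ vs exact enumeration, N = 3
  for (mech in names(mechanism_specs(2, 3))) {
    spec <- mechanism_specs(2, 3)[[mech]]
    dist <- enumerate_placements(spec)
    draws <- sample_configurations(spec, 30000, seed = 13)
    keys <- apply(draws, 1, paste, collapse = ",")
    ekeys <- apply(dist$places, 1, paste, collapse = ",")
    freq <- table(factor(keys, levels = ekeys)) / nrow(draws)
    se <- sqrt(dist$prob * (1 - dist$prob) / nrow(draws))
    expect_true(all(abs(as.vector(freq) - dist$prob) < 4.5 * se + 1e-9),
                label = paste("bulk sampler matches enumeration:", mech))
  }
})

test_that("mechanism participants never see non-participants", {
  # conditional on the participant set, the participants' placement follows
  # the raw mechanism distribution: FtM participants form one uniform
  # cluster no matter where the home-stayers sit
  spec <- movement_spec("follow_majority", h = 3, N = 3)
  set.seed(21)
  cluster_place <- c()
  for (i in 1:30000) {
    det <- sample_configuration(spec, detail = TRUE)
    parts <- which(det$action == "mechanism")
    if (length(parts) == 2L) {
      expect_length(unique(det$place_of[parts]), 1L)
      cluster_place <- c(cluster_place, det$place_of[parts[1]])
    }
  }
  freq <- tabulate(cluster_place, 3) / length(cluster_place)
  se <- sqrt((1 / 3) * (2 / 3) / length(cluster_place))
  expect_true(all(abs(freq - 1 / 3) < 4 * se))
})
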