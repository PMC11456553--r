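test_that("chi_independent multiplies marginals and normalizes over groups", {
  p <- matrix(0.5, 2, 2)
  expect_equal(chi_independent(p, 1, c(1, 2)), 0.25)
  # summing over every subset (including the empty one) gives 1 per place
  pm <- apriori_matrix(2, 3)
  for (m in 1:3) {
    tot <- prod(1 - pm[, m]) # empty group
    for (sz in 1:3) {
      combs <- combn(3, sz)
      for (j in seq_len(ncol(combs))) {
        tot <- tot + chi_independent(pm, m, combs[, j])
      }
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  # N = 3, h = 1: P(all together) = 3 (1/3)^3 = 1/9
  pm1 <- apriori_matrix(1, 3)
  expect_equal(sum(vapply(1:3, function(m) chi_independent(pm1, m, 1:3),
                          numeric(1))), 1 / 9, tolerance = 1e-12)
  expect_error(chi_independent(matrix(0.4, 2, 2), 1, 1), "sum to 1")
})

test_that("exact enumeration reproduces the worked follow-the-majority
           distribution at N = 3", {
  for (h in c(1, 2, 5)) {
    spec <- movement_spec("follow_majority", h = h, N = 3)
    gd <- group_distribution(enumerate_placements(spec))
    expected <- ftm3_exact(h)
    get <- function(key) {
      x <- gd$probability[gd$partition == key]
      if (length(x)) x else 0
    }
    expect_equal(get("1,2,3"), expected[["all_together"]],
                 tolerance = 1e-12)
    expect_equal(get("1,2|3"), expected[["one_pair"]], tolerance = 1e-12)
    expect_equal(get("1,3|2"), expected[["one_pair"]], tolerance = 1e-12)
    expect_equal(get("1|2,3"), expected[["one_pair"]], tolerance = 1e-12)
    expect_equal(get("1|2|3"), expected[["all_alone"]], tolerance = 1e-12)
    expect_equal(sum(gd$probability), 1, tolerance = 1e-12)
  }
})

test_that("independent-mechanism enumeration equals the product form", {
  spec <- movement_spec("independent", h = 1.7, N = 3)
  dist <- enumerate_placements(spec)
  pm <- apriori_matrix(1.7, 3)
  for (r in seq_len(nrow(dist$places))) {
    expect_equal(dist$prob[r],
                 prod(pm[cbind(1:3, dist$places[r, ])]),
                 tolerance = 1e-14)
  }
  # and aggregates to chi_independent for any (m, G)
  p_all_at_1 <- sum(dist$prob[rowSums(dist$places == 1) == 3])
  expect_equal(p_all_at_1, chi_independent(pm, 1, 1:3), tolerance = 1e-14)
})

test_that("enumeration refuses N above the cap and suggests Monte Carlo", {
  expect_error(enumerate_placements(movement_spec("independent", h = 1,
                                                  N = 8)),
               "Monte")
})

test_that("empirical distribution converges to the exact one and is
           seed-reproducible", {
  spec <- movement_spec("follow_majority", h = 2, N = 3)
  exact <- enumerate_placements(spec)
  emp <- estimate_placements(spec, 100000, seed = 31)
  ekeys <- apply(exact$places, 1, paste, collapse = ",")
  keys <- apply(emp$places, 1, paste, collapse = ",")
  freq <- emp$prob[match(ekeys, keys)]
  freq[is.na(freq)] <- 0
  se <- sqrt(exact$prob * (1 - exact$prob) / emp$samples)
  expect_true(all(abs(freq - exact$prob) < 4 * se + 1e-9))
  emp2 <- estimate_placements(spec, 1000, seed = 8)
  emp3 <- estimate_placements(spec, 1000, seed = 8)
  expect_identical(emp2$places, emp3$places)
  expect_identical(emp2$prob, emp3$prob)
  # wheel at theta = 0, h = 1: complete herding
  whl <- estimate_placements(movement_spec("wheel", h = 1, N = 3,
                                           theta = 0), 2000, seed = 5)
  gd <- group_distribution(whl)
  expect_equal(gd$probability[gd$partition == "1,2,3"], 1)
})

test_that("pair statistics: worked values, conservation, identity d = w,
           and exchangeability across mechanisms", {
  # N = 2 independent: d = 2h/(h+1)^2 (two-individual enumeration)
  for (h in c(0.5, 1, 3)) {
    ps <- pair_statistics(
      enumerate_placements(movement_spec("independent", h = h, N = 2)))
    expect_equal(ps$d, 2 * h / (h + 1)^2, tolerance = 1e-12)
  }
  # follow-the-majority at h = 1: all together, d = 1/(N-1)
  for (N in 2:4) {
    ps <- pair_statistics(
      enumerate_placements(movement_spec("follow_majority", h = 1, N = N)))
    expect_equal(ps$d, 1 / (N - 1), tolerance = 1e-12)
  }
  for (N in 3:4) {
    for (h in c(0.5, 1, 2, 10)) {
      for (spec in mechanism_specs(h, N)) {
        ps <- pair_statistics(enumerate_placements(spec))
        expect_equal(ps$w_s + (N - 1) * ps$w, 1, tolerance = 1e-10)
        expect_equal(ps$d, ps$w, tolerance = 1e-10)
        expect_lt(ps$pair_spread, 1e-10)
      }
    }
  }
})

test_that("closed independent-movement pair statistics match enumeration", {
  for (N in 3:5) {
    for (h in c(0.5, 1, 2, 10)) {
      exact <- pair_statistics(
        enumerate_placements(movement_spec("independent", h = h, N = N)))
      closed <- pair_statistics_independent(h, N)
      expect_equal(closed$d, exact$d, tolerance = 1e-10)
      expect_equal(closed$w_s, exact$w_s, tolerance = 1e-10)
      expect_equal(closed$w_s + (N - 1) * closed$w, 1, tolerance = 1e-10)
    }
  }
})

test_that("an always-alone process has undefined w*", {
  dist <- coopmove:::new_placement_dist(matrix(1:3, nrow = 1), 1,
                                        movement_spec("independent", h = 1,
                                                      N = 3),
                                        exact = TRUE)
  expect_error(pair_statistics(dist), "w\\*")
})

test_that("herding decreases the pair-meeting weight: d is non-increasing
           in the urn scale B", {
  ds <- vapply(c(0, 2, 6, 10000), function(B) {
    estimate_pair_statistics(movement_spec("polya_urn", h = 1, N = 10,
                                           B = B), 30000, seed = 9)$d
  }, numeric(1))
  expect_true(all(diff(ds) <= 0))
  # B = 0 is exact herding: everyone together, d = 1/(N-1)
  expect_equal(ds[1], 1 / 9, tolerance = 1e-12)
})

test_that("labelled and unlabelled group distributions agree in mass", {
  spec <- movement_spec("polya_urn", h = 0.5, N = 3, B = 1)
  dist <- enumerate_placements(spec)
  plain <- group_distribution(dist)
  lab <- group_distribution(dist, labelled = TRUE)
  expect_equal(sum(plain$probability), 1, tolerance = 1e-12)
  expect_equal(sum(lab$probability), 1, tolerance = 1e-12)
  expect_gte(nrow(lab), nrow(plain))
})
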