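#' Territorial-raider apriori distribution
#'
#' Marginal target distribution of a single individual over the `M` places of
#' a complete graph: weight `h/(h+M-1)` on the home place and `1/(h+M-1)` on
#' each of the other `M-1` places.
#'
#' @param h Home fidelity, positive.
#' @param M Number of places, at least 2.
#' @param home Index of the individual's home place.
#' @return Numeric vector of length `M` summing to 1.
#' @export
#' @examples
#' territorial_apriori(2, 3) # home 1/2, others 1/4 each
territorial_apriori <- function(h, M, home = 1L) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("`h` must be a single positive finite number.", call. = FALSE)
  }
  M <- check_count(M, "M")
  if (M < 2L) stop("`M` must be at least 2.", call. = FALSE)
  home <- check_count(home, "home")
  if (home > M) stop("`home` must be in 1..M.", call. = FALSE)
  a <- rep(1 / (h + M - 1), M)
  a[home] <- h / (h + M - 1)
  a
}

#' Participation split of the generalised movement embedding
#'
#' Decomposes an individual's move on the complete territorial-raider graph
#' into three actions: sit directly at home, take part in the movement
#' mechanism (which then uses a uniform internal apriori over all `M`
#' places), or jump to a uniformly random non-home place. The three
#' probabilities depend on the sign of `h - 1` and are chosen so that the
#' composed marginal is exactly [territorial_apriori()].
#'
#' @inheritParams territorial_apriori
#' @return A one-row tibble with columns `p_direct_home`, `p_mechanism`,
#'   `p_random_nonhome`.
#' @export
#' @examples
#' participation_split(2, 3) # (1/4, 3/4, 0)
participation_split <- function(h, M) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("`h` must be a single positive finite number.", call. = FALSE)
  }
  M <- check_count(M, "M")
  if (M < 2L) stop("`M` must be at least 2.", call. = FALSE)
  denom <- h + M - 1
  if (h > 1) {
    out <- c((h - 1) / denom, M / denom, 0)
  } else if (h == 1) {
    out <- c(0, 1, 0)
  } else {
    out <- c(0, M * h / denom, (M - 1) * (1 - h) / denom)
  }
  tibble::tibble(p_direct_home = out[1], p_mechanism = out[2],
                 p_random_nonhome = out[3])
}

check_apriori <- function(apriori, tol = 1e-12) {
  if (!is.numeric(apriori) || length(apriori) < 2L ||
      any(!is.finite(apriori)) || any(apriori < 0) ||
      abs(sum(apriori) - 1) > tol) {
    stop("`apriori` must be non-negative and sum to 1.", call. = FALSE)
  }
  invisible(apriori)
}

#' Raw follow-the-majority sampler
#'
#' Places the given participants sequentially in a uniformly random order.
#' The first mover samples from `apriori`; each later mover joins the place
#' with maximal current participant occupancy. Ties (which only arise
#' degenerately) are broken proportionally to the apriori weights restricted
#' to the tied places, or uniformly.
#'
#' @param participants Integer vector of individual indices (may be empty).
#' @param apriori Probability vector over places.
#' @param tie_break `"apriori"` (default) or `"uniform"`.
#' @return Named integer vector of places, one per participant.
#' @export
sample_follow_majority <- function(participants, apriori,
                                   tie_break = c("apriori", "uniform")) {
  check_apriori(apriori)
  tie_break <- match.arg(tie_break)
  p <- length(participants)
  out <- setNames(integer(p), participants)
  if (p == 0L) return(out)
  M <- length(apriori)
  ord <- sample.int(p)
  occ <- integer(M)
  for (j in ord) {
    if (all(occ == 0L)) {
      place <- sample.int(M, 1L, prob = apriori)
    } else {
      tied <- which(occ == max(occ))
      if (length(tied) == 1L) {
        place <- tied
      } else if (tie_break == "apriori" && sum(apriori[tied]) > 0) {
        place <- tied[sample.int(length(tied), 1L, prob = apriori[tied])]
      } else {
        place <- tied[sample.int(length(tied), 1L)]
      }
    }
    occ[place] <- occ[place] + 1L
    out[j] <- place
  }
  out
}

#' Raw Polya-urn sampler
#'
#' Sequential placement in a uniformly random order; a mover chooses place
#' `m` with probability proportional to `B * apriori[m] + Y[m]`, where `Y[m]`
#' counts previously placed participants. `B = 0` is the follow-the-majority
#' limit: the first mover uses `apriori` directly and everyone else joins
#' the occupied cluster.
#'
#' @inheritParams sample_follow_majority
#' @param B Non-negative urn scale.
#' @return Named integer vector of places, one per participant.
#' @export
sample_polya_urn <- function(participants, apriori, B) {
  check_apriori(apriori)
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B < 0) {
    stop("`B` must be a single non-negative number.", call. = FALSE)
  }
  p <- length(participants)
  out <- setNames(integer(p), participants)
  if (p == 0L) return(out)
  M <- length(apriori)
  ord <- sample.int(p)
  occ <- integer(M)
  first <- TRUE
  for (j in ord) {
    wts <- B * apriori + occ
    if (first && sum(wts) == 0) wts <- apriori
    place <- sample.int(M, 1L, prob = wts)
    occ[place] <- occ[place] + 1L
    out[j] <- place
    first <- FALSE
  }
  out
}

#' Raw wheel-and-base sampler
#'
#' The circle of circumference 1 carries consecutive half-open arcs of
#' lengths `apriori` in place order. Spikes sit at fractional positions
#' `(j-1) * theta/(2*pi) + phi (mod 1)` with `phi` uniform, and are assigned
#' to the participants in a uniformly random order; a participant lands in
#' the arc containing its spike.
#'
#' @inheritParams sample_follow_majority
#' @param theta Spike separation in radians, in `[0, 2*pi)`.
#' @param theta_precision Decimal places for quantizing `theta`; `NULL`
#'   disables quantization.
#' @return Named integer vector of places, one per participant.
#' @export
sample_wheel <- function(participants, apriori, theta, theta_precision = 3L) {
  check_apriori(apriori)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0 || theta >= 2 * pi) {
    stop("`theta` must lie in [0, 2*pi).", call. = FALSE)
  }
  p <- length(participants)
  out <- setNames(integer(p), participants)
  if (p == 0L) return(out)
  if (!is.null(theta_precision)) theta <- round(theta, theta_precision)
  t_frac <- (theta / (2 * pi)) %% 1
  cuts <- cumsum(apriori)
  phi <- runif(1)
  spikes <- (phi + (seq_len(p) - 1) * t_frac) %% 1
  ord <- sample.int(p) # spike j -> participant ord[j]
  places <- findInterval(spikes, cuts, left.open = FALSE) + 1L
  # findInterval on cuts gives 0 for x < cuts[1]; arcs are [c_{m-1}, c_m)
  places <- pmin(places, length(apriori))
  out[ord] <- places
  out
}

#' Sample one placement configuration in the evolutionary setting
#'
#' Requires `N = M` with individual `i` living at place `i`. Each individual
#' independently draws an action from [participation_split()]; direct-home
#' individuals sit at home, random-non-home individuals pick uniformly among
#' their `M - 1` other places, and mechanism participants are placed by the
#' mechanism sampler with a uniform internal apriori. Mechanism participants
#' never see non-participants, so the participants' joint distribution does
#' not depend on the rest of the population. The per-individual marginal is
#' exactly [territorial_apriori()].
#'
#' @param spec A [movement_spec()] with `N = M`.
#' @param detail If `TRUE`, also return the action drawn by each individual.
#' @return Integer vector `place_of` of length `N` (or a list with
#'   `place_of` and `action` when `detail = TRUE`).
#' @export
sample_configuration <- function(spec, detail = FALSE) {
  stopifnot(inherits(spec, "movement_spec"))
  if (spec$N != spec$M) {
    stop("The evolutionary setting requires N = M (one home per place).",
         call. = FALSE)
  }
  N <- spec$N
  M <- spec$M
  split <- participation_split(spec$h, M)
  u <- runif(N)
  action <- ifelse(u < split$p_mechanism, "mechanism",
                   if (spec$h > 1) "home" else "nonhome")
  if (spec$h == 1) action[] <- "mechanism"
  place <- seq_len(N) # homes
  nh <- which(action == "nonhome")
  if (length(nh)) {
    place[nh] <- vapply(nh, function(i) {
      sample(setdiff(seq_len(M), i), 1L)
    }, integer(1))
  }
  parts <- which(action == "mechanism")
  if (length(parts)) {
    apriori <- rep(1 / M, M)
    placed <- switch(spec$mechanism,
      independent = setNames(sample.int(M, length(parts), replace = TRUE,
                                        prob = apriori), parts),
      follow_majority = sample_follow_majority(parts, apriori),
      polya_urn = sample_polya_urn(parts, apriori, spec$B),
      wheel = sample_wheel(parts, apriori, spec$theta,
                           if (spec$quantize_theta) spec$theta_precision
                           else NULL)
    )
    place[parts] <- placed
  }
  if (detail) list(place_of = place, action = action) else place
}

#' Sample many placement configurations (bulk, compiled)
#'
#' Draws `n` independent configurations from the same distribution as
#' [sample_configuration()], using the compiled sampler with an explicit
#' seed stream (derived from R's RNG when `seed` is `NULL`).
#'
#' @inheritParams sample_configuration
#' @param n Number of configurations.
#' @param seed Optional integer seed for the compiled stream.
#' @return An `n` by `N` integer matrix of places.
#' @export
sample_configurations <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "movement_spec"))
  if (spec$N != spec$M) {
    stop("The evolutionary setting requires N = M (one home per place).",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  sample_configurations_cpp(mechanism_code(spec$mechanism), spec$h, spec$N,
                            spec$B %||% 0, wheel_step_or_zero(spec),
                            as.integer(n), as.numeric(seed))
}

wheel_step_or_zero <- function(spec) {
  if (spec$mechanism == "wheel") wheel_step(spec) else 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
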