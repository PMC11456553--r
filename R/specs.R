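#' Movement specification
#'
#' Bundles a movement mechanism and its parameters. The evolutionary setting
#' is the complete territorial-raider graph with one home vertex per
#' individual, so `N = M` there; the raw samplers also accept `M != N`.
#'
#' @param mechanism One of `"independent"`, `"follow_majority"`,
#'   `"polya_urn"`, `"wheel"`.
#' @param h Home fidelity, a positive real. `h > 1` favours staying home,
#'   `h < 1` favours leaving, `h = 1` is indifference.
#' @param N Number of individuals (positive integer).
#' @param M Number of places; defaults to `N` (the evolutionary setting).
#' @param B Urn scale (Polya-urn only), non-negative. `B = 0` is the
#'   follow-the-majority limit; `B -> Inf` approaches independent movement.
#' @param theta Spike separation in radians (wheel only), in `[0, 2*pi)`.
#'   `theta = 0` is full herding; `theta = 2*pi/N` near-complete dispersal.
#' @param theta_precision Decimal places to which `theta` is rounded before
#'   sampling (wheel only). Rounding makes co-location events possible at the
#'   dispersal angle so that evolutionary runs can absorb.
#' @param quantize_theta Set to `FALSE` to disable the rounding for pure
#'   distribution studies.
#'
#' @return An object of class `movement_spec`.
#' @export
#' @examples
#' movement_spec("follow_majority", h = 2, N = 3)
#' movement_spec("polya_urn", h = 1, N = 10, B = 2)
movement_spec <- function(mechanism = c("independent", "follow_majority",
                                        "polya_urn", "wheel"),
                          h, N, M = N, B = NULL, theta = NULL,
                          theta_precision = 3L, quantize_theta = TRUE) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("`h` must be a single positive finite number.", call. = FALSE)
  }
  N <- check_count(N, "N")
  M <- check_count(M, "M")
  if (M < 2L) stop("`M` must be at least 2.", call. = FALSE)
  spec <- list(mechanism = mechanism, h = h, N = N, M = M)
  if (mechanism == "polya_urn") {
    if (is.null(B) || !is.numeric(B) || length(B) != 1L || !is.finite(B) ||
        B < 0) {
      stop("Polya-urn movement needs a single non-negative `B`.",
           call. = FALSE)
    }
    spec$B <- as.numeric(B)
  }
  if (mechanism == "wheel") {
    if (is.null(theta) || !is.numeric(theta) || length(theta) != 1L ||
        !is.finite(theta) || theta < 0 || theta >= 2 * pi) {
      stop("Wheel movement needs `theta` in [0, 2*pi).", call. = FALSE)
    }
    spec$theta <- as.numeric(theta)
    spec$theta_precision <- as.integer(theta_precision)
    spec$quantize_theta <- isTRUE(quantize_theta)
  }
  structure(spec, class = "movement_spec")
}

#' @export
print.movement_spec <- function(x, ...) {
  extra <- switch(x$mechanism,
    polya_urn = sprintf(", B = %g", x$B),
    wheel = sprintf(", theta = %g (rounded to %d dp: %s)", x$theta,
                    x$theta_precision,
                    if (x$quantize_theta) "yes" else "no"),
    ""
  )
  cat(sprintf("<movement_spec> %s, h = %g, N = %d, M = %d%s\n",
              x$mechanism, x$h, x$N, x$M, extra))
  invisible(x)
}

#' Game specification
#'
#' @param kind `"public_goods"` (cooperators A vs defectors B) or
#'   `"hawk_dove"` (hawks A vs doves B).
#' @param R Background payoff received regardless of the game.
#' @param V Reward: the shared benefit in the Public Goods game, the contested
#'   resource in the Hawk-Dove game.
#' @param C Cost: the cooperator's contribution, or the losing hawk's injury.
#'
#' @return An object of class `game_spec`.
#' @export
#' @examples
#' game_spec("public_goods", R = 10, V = 2, C = 1)
game_spec <- function(kind = c("public_goods", "hawk_dove"), R, V, C) {
  kind <- match.arg(kind)
  for (nm in c("R", "V", "C")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop(sprintf("`%s` must be a single finite number.", nm), call. = FALSE)
    }
  }
  if (V < 0 || C < 0) stop("`V` and `C` must be non-negative.", call. = FALSE)
  structure(list(kind = kind, R = R, V = V, C = C), class = "game_spec")
}

#' @export
print.game_spec <- function(x, ...) {
  cat(sprintf("<game_spec> %s, R = %g, V = %g, C = %g\n",
              x$kind, x$R, x$V, x$C))
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single positive integer.", name),
         call. = FALSE)
  }
  as.integer(x)
}

# wheel spike step as a fraction of the circumference, after quantization
wheel_step <- function(spec) {
  th <- spec$theta
  if (isTRUE(spec$quantize_theta)) th <- round(th, spec$theta_precision)
  (th / (2 * pi)) %% 1
}

mechanism_code <- function(mechanism) {
  match(mechanism, c("independent", "follow_majority", "polya_urn", "wheel"))
}
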