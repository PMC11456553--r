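# Multiplayer game payoffs on group compositions.

#' Public Goods payoff
#'
#' A group holds `a` cooperators (type A) and `b` defectors (type B). Each
#' cooperator pays `C` and its contribution `V` is shared equally among the
#' *other* group members; a lone cooperator still pays. Defectors pay
#' nothing. The background payoff `R` is received by everyone.
#'
#' @param game A [game_spec()] of kind `"public_goods"`.
#' @param a,b Counts of cooperators and defectors in the group (vectorized).
#' @param role `"A"` (cooperator) or `"B"` (defector).
#' @return Payoff(s) for one individual of the given role.
#' @export
#' @examples
#' g <- game_spec("public_goods", R = 10, V = 2, C = 1)
#' pgg_payoff(g, a = 2, b = 1, role = "A") # 10 - 1 + 2/2
pgg_payoff <- function(game, a, b, role = c("A", "B")) {
  stopifnot(inherits(game, "game_spec"), game$kind == "public_goods")
  role <- match.arg(role)
  check_composition(a, b, role)
  n <- a + b
  if (role == "A") {
    ifelse(a == 1, game$R - game$C,
           game$R - game$C + (a - 1) / (n - 1) * game$V)
  } else {
    ifelse(a == 0, game$R, game$R + a / (n - 1) * game$V)
  }
}

#' Hawk-Dove payoff
#'
#' A group holds `a` hawks (type A) and `b` doves (type B), competing for a
#' reward `V`. If any hawk is present the doves concede and the hawks fight:
#' one wins `V`, the losers each pay `C`, so a hawk's expected game payoff is
#' `(V - (a-1) C) / a`. All-dove groups split the reward equally.
#'
#' @param game A [game_spec()] of kind `"hawk_dove"`.
#' @inheritParams pgg_payoff
#' @return Payoff(s) for one individual of the given role.
#' @export
#' @examples
#' g <- game_spec("hawk_dove", R = 10, V = 2, C = 1)
#' hd_payoff(g, a = 2, b = 0, role = "A") # 10 + (2 - 1)/2
hd_payoff <- function(game, a, b, role = c("A", "B")) {
  stopifnot(inherits(game, "game_spec"), game$kind == "hawk_dove")
  role <- match.arg(role)
  check_composition(a, b, role)
  if (role == "A") {
    game$R + (game$V - (a - 1) * game$C) / a
  } else {
    ifelse(a > 0, game$R, game$R + game$V / b)
  }
}

#' Payoff dispatcher over game kinds
#'
#' @inheritParams pgg_payoff
#' @return Payoff(s) for one individual of the given role.
#' @export
group_payoff <- function(game, a, b, role = c("A", "B")) {
  role <- match.arg(role)
  switch(game$kind,
    public_goods = pgg_payoff(game, a, b, role),
    hawk_dove = hd_payoff(game, a, b, role)
  )
}

check_composition <- function(a, b, role) {
  if (any(a < 0) || any(b < 0) || any(a + b < 1)) {
    stop("A composition needs a, b >= 0 and a + b >= 1.", call. = FALSE)
  }
  if (role == "A" && any(a < 1)) {
    stop("Role A payoff requested but the group has no A individuals.",
         call. = FALSE)
  }
  if (role == "B" && any(b < 1)) {
    stop("Role B payoff requested but the group has no B individuals.",
         call. = FALSE)
  }
  invisible(NULL)
}

# smallest payoff any individual can realize in a group of size <= N;
# the stochastic dynamics need this to be strictly positive
min_realizable_payoff <- function(game, N) {
  comps <- expand.grid(a = 0:N, b = 0:N)
  comps <- comps[comps$a + comps$b >= 1 & comps$a + comps$b <= N, ]
  vals <- c()
  withA <- comps[comps$a >= 1, ]
  vals <- c(vals, group_payoff(game, withA$a, withA$b, "A"))
  withB <- comps[comps$b >= 1, ]
  vals <- c(vals, group_payoff(game, withB$a, withB$b, "B"))
  min(vals)
}
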