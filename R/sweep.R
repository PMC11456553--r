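# Parameter-sweep orchestration and result serialization.

#' Analytic fixation probabilities over a parameter grid
#'
#' Takes a tibble of parameter cells (columns `mechanism`, `h`, `N`, and
#' optionally `B`, `theta`, `dynamics`, `game_kind`) and computes the
#' closed-form fixation probability of the invading cooperator (Public
#' Goods) or dove (Hawk-Dove) in every cell, with full provenance columns.
#' Pair statistics come from exact enumeration up to `cap` and Monte Carlo
#' beyond it.
#'
#' @param grid Tibble of parameter cells; missing columns fall back to the
#'   arguments below.
#' @param game A [game_spec()]; a `game_kind` grid column may override the
#'   kind cell-wise.
#' @param dynamics Default dynamics when the grid has no `dynamics` column.
#' @param cap Enumeration cap for exact pair statistics.
#' @param mc_samples Monte-Carlo draws used beyond the cap.
#' @param seed Seed for Monte-Carlo pair statistics.
#' @return A tibble: one row per cell with `probability`, `method`, `d`,
#'   `w_star` and the cell parameters.
#' @export
fixation_sweep <- function(grid, game, dynamics = "BDB", cap = 6L,
                           mc_samples = 20000L, seed = 1L) {
  stopifnot(is.data.frame(grid), inherits(game, "game_spec"))
  grid <- tibble::as_tibble(grid)
  if (!"dynamics" %in% names(grid)) grid$dynamics <- dynamics
  if (!"game_kind" %in% names(grid)) grid$game_kind <- game$kind
  purrr::pmap_dfr(grid, function(...) {
    cell <- list(...)
    mv <- movement_spec(cell$mechanism, h = cell$h, N = cell$N,
                        B = cell$B %||% NULL, theta = cell$theta %||% NULL)
    g <- game_spec(cell$game_kind, R = game$R, V = game$V, C = game$C)
    ps <- sweep_pair_stats(mv, cap, mc_samples, seed)
    prob <- if (g$kind == "public_goods") {
      fixation_pgg(g, mv$N, ps$d, cell$dynamics, w_star = ps$w_star)
    } else {
      if (mv$mechanism != "independent") {
        stop(paste0("Closed-form Hawk-Dove fixation covers independent ",
                    "movement only; use the simulator for row-dependent ",
                    "mechanisms."), call. = FALSE)
      }
      fixation_hd(g, mv$N, mv$h, cell$dynamics, w_star = ps$w_star)
    }
    tibble::tibble(
      mechanism = mv$mechanism, h = mv$h, N = mv$N,
      B = mv$B %||% NA_real_, theta = mv$theta %||% NA_real_,
      game = g$kind, dynamics = cell$dynamics,
      probability = prob,
      method = "closed_form",
      d = ps$d, w_star = ps$w_star,
      pair_stats_exact = ps$exact
    )
  }) |>
    structure(class = c("fixation_sweep", class(tibble::tibble())))
}

sweep_pair_stats <- function(mv, cap, mc_samples, seed) {
  if (mv$mechanism == "independent") {
    pair_statistics_independent(mv$h, mv$N)
  } else if (mv$N <= cap) {
    pair_statistics(enumerate_placements(mv, cap = cap))
  } else {
    estimate_pair_statistics(mv, mc_samples, seed = seed)
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.fixation_sweep <- function(object, x = "h", ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[x]], y = .data$probability,
    colour = .data$mechanism, linetype = .data$dynamics)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(y = "fixation probability") +
    ggplot2::theme_minimal()
}

#' Plot a group-size distribution
#'
#' @param dist A `placement_dist`.
#' @return A ggplot: probability mass of the focal individual's group size.
#' @export
plot_group_sizes <- function(dist) {
  sizes <- group_sizes_by_individual(dist$places)
  df <- purrr::map_dfr(seq_len(ncol(sizes)), function(i) {
    tibble::tibble(size = sizes[, i], prob = dist$prob)
  }) |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(probability = sum(.data$prob) / ncol(sizes),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$size),
                                   y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "group size of a focal individual",
                  y = "probability") +
    ggplot2::theme_minimal()
}

#' Serialize a simulation configuration to JSON
#'
#' Flat-key JSON mirroring the CLI flags; [sim_config_from_json()] inverts
#' it exactly.
#'
#' @param config A [sim_config()].
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when writing to a file.
#' @export
sim_config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mv <- config$movement
  g <- config$game
  x <- list(
    mechanism = mv$mechanism, h = mv$h, N = mv$N,
    game = g$kind, R = g$R, V = g$V, C = g$C,
    dynamics = config$dynamics, mutant_role = config$mutant_role,
    replicates = config$replicates, seed = config$seed,
    max_steps = config$max_steps, idealized = config$idealized,
    bdb_include_parent = config$bdb_include_parent
  )
  if (mv$mechanism == "polya_urn") x$B <- mv$B
  if (mv$mechanism == "wheel") {
    x$theta <- mv$theta
    x$theta_precision <- mv$theta_precision
    x$quantize_theta <- mv$quantize_theta
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname sim_config_to_json
#' @param json JSON string or path to a JSON file.
#' @export
sim_config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  mv <- movement_spec(x$mechanism, h = x$h, N = x$N,
                      B = x$B %||% NULL, theta = x$theta %||% NULL,
                      theta_precision = x$theta_precision %||% 3L,
                      quantize_theta = x$quantize_theta %||% TRUE)
  g <- game_spec(x$game, R = x$R, V = x$V, C = x$C)
  sim_config(mv, g, dynamics = x$dynamics, mutant_role = x$mutant_role,
             replicates = x$replicates, seed = x$seed,
             max_steps = x$max_steps, idealized = x$idealized,
             bdb_include_parent = x$bdb_include_parent)
}
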