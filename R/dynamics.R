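#' Pairwise prisoner's dilemma payoff
#'
#' Payoff earned by the focal player against one neighbor: mutual
#' cooperation pays R = 1, a defector exploiting a cooperator earns the
#' temptation T = b, and both the punishment P and the sucker's payoff S
#' are 0.
#'
#' @param s_x focal strategy: `"C"`/`"D"` or the integer coding 1/0.
#' @param s_y neighbor strategy (may be a vector).
#' @param game a [game_params()].
#' @return Numeric payoff(s) to the focal player, each in \[0, b\].
#' @export
pairwise_payoff <- function(s_x, s_y, game) {
  stopifnot(inherits(game, "game_params"))
  n <- max(length(s_x), length(s_y))
  sx <- rep_len(as_strategy(s_x), n)
  sy <- rep_len(as_strategy(s_y), n)
  out <- numeric(n)
  out[sx == 1L & sy == 1L] <- game$R
  out[sx == 1L & sy == 0L] <- game$S
  out[sx == 0L & sy == 1L] <- game$T
  out[sx == 0L & sy == 0L] <- game$P
  out
}

as_strategy <- function(s) {
  if (is.character(s)) {
    out <- match(s, c("D", "C")) - 1L
    if (anyNA(out)) stop("strategies must be 'C' or 'D'", call. = FALSE)
    out
  } else {
    s <- as.integer(s)
    if (!all(s %in% c(0L, 1L)))
      stop("integer strategies must be 1 (C) or 0 (D)", call. = FALSE)
    s
  }
}

#' Accumulated utility of a focal player
#'
#' The focal player's utility is the weighted sum of its eight pairwise
#' payoffs, `U_x = sum over neighbors y of w_xy * P_xy`, with the current
#' strategies and current link weights.  The record also carries the mean
#' pairwise payoff `avg_payoff = mean(P_xy)`, the reference level of the
#' weight-adjustment rule.  Accumulation runs over the neighbors in the
#' fixed table order so the value is bit-identical to the compiled
#' kernel's.
#'
#' @param state a [sim_state()].
#' @param site 1-based linear site index.
#' @param game a [game_params()].
#' @return A list with `U` (accumulated utility), `avg_U` (`U / 8`),
#'   `avg_payoff` (mean of the eight pairwise payoffs) and `payoffs` (the
#'   eight pairwise payoffs, in neighbor-table order).
#' @export
utility <- function(state, site, game) {
  nb <- state$nbr[site, ]
  ed <- state$edge[site, ]
  p <- pairwise_payoff(state$strategies[site], state$strategies[nb], game)
  U <- 0
  praw <- 0
  for (j in 1:8) {
    U <- U + state$weights[ed[j]] * p[j]
    praw <- praw + p[j]
  }
  list(U = U, avg_U = U / 8, avg_payoff = praw / 8, payoffs = p)
}

#' Reinforce and punish the focal player's links
#'
#' For each of the focal player's eight links: if the pairwise payoff
#' earned over that link strictly exceeds the player's mean pairwise
#' payoff, the link weight is rewarded by +Delta; if it falls strictly
#' below, it is punished by -Delta; the result is clamped into
#' \[1 - delta, 1 + delta\].  An exact tie is possible only when all eight
#' payoffs are equal (a strategy-uniform neighborhood); it discriminates
#' nothing and leaves the link unchanged.  Because each undirected edge is
#' stored once, the neighbor immediately feels the change.
#'
#' @param state a [sim_state()].
#' @param site focal site (1-based linear index).
#' @param record the [utility()] record computed from the current state.
#' @param wp a [weight_params()].
#' @return The updated state.
#' @export
adjust_weights <- function(state, site, record, wp) {
  stopifnot(inherits(wp, "weight_params"))
  if (wp$Delta == 0) return(state)
  ed <- state$edge[site, ]
  for (j in 1:8) {
    if (record$payoffs[j] == record$avg_payoff) next
    w <- state$weights[ed[j]] +
      if (record$payoffs[j] > record$avg_payoff) wp$Delta else -wp$Delta
    state$weights[ed[j]] <- min(max(w, 1 - wp$delta), 1 + wp$delta)
  }
  state
}

#' Strategy-adoption probability
#'
#' A focal player x that picked neighbor y adopts y's strategy with
#' probability `(U_y - U_x) / (D * k_max)` when `U_y > U_x`, and keeps its
#' strategy otherwise (ties included).  D = b is the maximal payoff
#' difference and `k_max` the larger of the two degrees (8 everywhere on
#' this lattice).  Because weighted utilities can reach `8 * (1 + delta) * b`
#' while the normalizer is `8 * b`, the raw ratio can exceed 1 and is
#' clipped at 1.
#'
#' @param U_x,U_y utilities of the focal player and the model neighbor
#'   (vectorized).
#' @param game a [game_params()].
#' @param k_max larger degree of the pair (default 8).
#' @return Adoption probability in \[0, 1\].
#' @export
adoption_probability <- function(U_x, U_y, game, k_max = 8L) {
  stopifnot(inherits(game, "game_params"))
  W <- pmin(1, (U_y - U_x) / (game$D * k_max))
  W[U_y <= U_x] <- 0
  W
}

#' One asynchronous elementary step (reference implementation)
#'
#' Executes, in order: (1) draw a focal player x uniformly; (2) compute x's
#' pairwise payoffs and accumulated utility with the current weights;
#' (3) reinforce/punish x's eight links against x's mean pairwise payoff;
#' (4) draw one neighbor y uniformly from the Moore neighborhood;
#' (5) recompute U_x and compute U_y with the post-adjustment weights;
#' (6) if U_y > U_x, x adopts s_y with probability
#' `min(1, (U_y - U_x) / (8 b))`.  At most one site's strategy changes.
#'
#' The RNG draw order (focal uniform, neighbor uniform, adoption uniform
#' drawn only when U_y > U_x) is frozen and shared with the compiled
#' kernel, so this pure-R stepper is trace-identical to [run_simulation()]
#' under the same seed.  It exists for transparency and for step-level
#' testing; long runs should use [run_simulation()].
#'
#' @param state a [sim_state()].
#' @param config a [run_config()] supplying game and weight parameters.
#' @return The updated state.
#' @export
elementary_step <- function(state, config) {
  N <- state$spec$N
  x <- floor(runif(1) * N) + 1
  if (x > N) x <- N
  rec <- utility(state, x, config$game)
  state <- adjust_weights(state, x, rec, config$weight)
  jy <- floor(runif(1) * 8) + 1
  if (jy > 8) jy <- 8
  y <- state$nbr[x, jy]
  U_x <- utility(state, x, config$game)$U
  U_y <- utility(state, y, config$game)$U
  if (U_y > U_x) {
    W <- min(1, (U_y - U_x) / (config$game$D * 8))
    if (runif(1) < W) state$strategies[x] <- state$strategies[y]
  }
  state
}

#' One full Monte Carlo step (N elementary steps)
#'
#' In one MCS each player is selected once on average: N = L^2 elementary
#' steps with focal players drawn uniformly with replacement.  Increments
#' the state's MCS counter by 1.  Reference implementation in R; long runs
#' should use [run_simulation()].
#'
#' @inheritParams elementary_step
#' @return The updated state.
#' @export
monte_carlo_step <- function(state, config) {
  for (k in seq_len(state$spec$N)) state <- elementary_step(state, config)
  state$mcs <- state$mcs + 1L
  state
}

#' Run a full coevolution simulation
#'
#' Initializes the state from the configuration, iterates the asynchronous
#' Monte Carlo dynamics for `total_mcs` steps in the compiled kernel, and
#' records the cooperation fraction after every MCS (plus optional
#' link-weight summaries and strategy snapshots).  All randomness comes
#' from R's global RNG stream, seeded from `seed`, so runs are exactly
#' reproducible.
#'
#' @param config a [run_config()].
#' @param seed RNG seed for this realization; defaults to `config$seed`,
#'   and a fresh seed is drawn (and echoed in the result) when both are
#'   `NULL`.
#' @param record_weights if `TRUE`, record the mean and population variance
#'   of the 4N edge weights after every MCS.
#' @param snapshot_steps integer vector of MCS values (0 = initial state)
#'   at which to capture strategy snapshots.
#' @param stop_when_uniform if `TRUE`, stop as soon as the strategy field
#'   is uniform (all-C or all-D are absorbing for strategies) and extend
#'   the trajectory as a constant.  This freezes the weight field too, so
#'   leave it off when the stable weight distribution is of interest (in an
#'   all-C population weights keep evolving).
#' @param check_bounds if `TRUE`, verify after every MCS that every edge
#'   weight lies in \[1 - delta, 1 + delta\] (debug mode).
#' @return An object of class `coevo_run`: a list with `trajectory` (a
#'   data frame with columns `mcs`, `rho_c` and, when recorded,
#'   `mean_weight`, `var_weight`), `stationary` (mean `rho_c` over the
#'   trailing `measure_window` MCS), `state` (final [sim_state()]),
#'   `snapshots` (list of [capture_snapshot()] objects keyed by MCS),
#'   `seed`, `absorbed_at` (first MCS at which the strategy field was
#'   uniform, `NA` if never), and `config`.
#' @examples
#' cfg <- desk_protocol(b = 1.34, delta = 0.4, Delta = 0.2, total_mcs = 200,
#'                      measure_window = 50)
#' run <- run_simulation(cfg, seed = 1)
#' run$stationary
#' @export
run_simulation <- function(config, seed = config$seed,
                           record_weights = FALSE,
                           snapshot_steps = integer(0),
                           stop_when_uniform = FALSE,
                           check_bounds = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  seed <- as.integer(seed)
  set.seed(seed)
  strat <- init_strategies(config$lattice, config$init_mode)
  wts <- init_weights(config$lattice)
  res <- cpp_run_kernel(as.integer(strat), wts, config$lattice$L,
                        config$game$b, config$weight$delta,
                        config$weight$Delta, config$total_mcs,
                        as.integer(snapshot_steps), record_weights,
                        stop_when_uniform, check_bounds)
  if (check_bounds && !res$bounds_ok)
    stop("internal error: an edge weight escaped [1-delta, 1+delta]")
  traj <- data.frame(mcs = 0:config$total_mcs, rho_c = res$rho)
  if (record_weights) {
    traj$mean_weight <- res$mean_weight
    traj$var_weight <- res$var_weight
  }
  L <- config$lattice$L
  final <- sim_state(config$lattice, matrix(res$strategies, L, L),
                     res$weights, mcs = config$total_mcs)
  snaps <- lapply(names(res$snapshots), function(nm) {
    structure(list(grid = matrix(res$snapshots[[nm]], L, L),
                   mcs = as.integer(nm)),
              class = "strategy_snapshot")
  })
  names(snaps) <- names(res$snapshots)
  structure(list(trajectory = traj,
                 stationary = mean(traj$rho_c[
                   seq.int(nrow(traj) - config$measure_window + 1L,
                           nrow(traj))]),
                 state = final, snapshots = snaps, seed = seed,
                 absorbed_at = if (res$absorbed_at < 0) NA_integer_
                               else res$absorbed_at,
                 config = config),
            class = "coevo_run")
}

#' @export
print.coevo_run <- function(x, ...) {
  cfg <- x$config
  cat("<coevo_run> ", cfg$lattice$L, "x", cfg$lattice$L, ", b = ",
      cfg$game$b, ", delta = ", cfg$weight$delta, ", Delta = ",
      cfg$weight$Delta, ", seed = ", x$seed, "\n  ", cfg$total_mcs,
      " MCS; stationary rho_C over last ", cfg$measure_window, " MCS = ",
      format(x$stationary, digits = 4), "\n", sep = "")
  invisible(x)
}
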