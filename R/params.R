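#' Prisoner's dilemma payoff parameters
#'
#' The weak prisoner's dilemma is parameterized by the temptation to defect
#' alone: T = b, reward for mutual cooperation R = 1, punishment P and
#' sucker's payoff S both 0.  The payoff ranking requires 1 < b < 2.  The
#' maximal payoff difference D = T - P = b normalizes the imitation
#' probability.
#'
#' @param b temptation to defect, strictly between 1 and 2.
#' @return An object of class `game_params` with fields `b`, `T`, `R`, `P`,
#'   `S` and `D`.
#' @examples
#' gp <- game_params(1.34)
#' gp$D  # equals b
#' @export
game_params <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 1 || b >= 2)
    stop("invalid temptation parameter: 1 < b < 2 is required, got b = ",
         format(b), call. = FALSE)
  structure(list(b = as.numeric(b), T = as.numeric(b), R = 1, P = 0, S = 0,
                 D = as.numeric(b)),
            class = "game_params")
}

#' Link-weight coevolution parameters
#'
#' Link weights live in the closed interval \[1 - delta, 1 + delta\] and move
#' in steps of Delta per reinforcement/punishment event.  The dimensionless
#' amplitude Delta/delta is the key control parameter of the model; it is
#' defined only when delta > 0.  With delta = 0 or Delta = 0 every weight
#' stays pinned at 1 and the dynamics reduce to the classical (unweighted)
#' spatial prisoner's dilemma.
#'
#' @param delta half-width of the weight interval, in \[0, 1\].
#' @param Delta per-event weight step, >= 0.
#' @return An object of class `weight_params` with fields `delta`, `Delta`
#'   and `ratio` (`NA` when delta = 0; use [weight_ratio()] to retrieve it
#'   safely).
#' @seealso [weight_ratio()]
#' @export
weight_params <- function(delta, Delta) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0 || delta > 1)
    stop("invalid weight bound: 0 <= delta <= 1 is required, got delta = ",
         format(delta), call. = FALSE)
  if (!is.numeric(Delta) || length(Delta) != 1L || !is.finite(Delta) ||
      Delta < 0)
    stop("invalid weight step: Delta >= 0 is required, got Delta = ",
         format(Delta), call. = FALSE)
  structure(list(delta = as.numeric(delta), Delta = as.numeric(Delta),
                 ratio = if (delta > 0) Delta / delta else NA_real_),
            class = "weight_params")
}

#' Link-weight amplitude Delta/delta
#'
#' @param wp a [weight_params()] object.
#' @return The ratio Delta/delta.  Requesting the ratio with delta = 0 is an
#'   error: the amplitude Delta/delta is only defined for delta != 0.
#' @export
weight_ratio <- function(wp) {
  stopifnot(inherits(wp, "weight_params"))
  if (wp$delta == 0)
    stop("the amplitude Delta/delta is undefined: it requires delta != 0",
         call. = FALSE)
  wp$Delta / wp$delta
}

#' Square-lattice specification
#'
#' A periodic L-by-L square lattice (N = L^2 players) with Moore
#' neighborhoods: every site has exactly eight neighbors (orthogonal and
#' diagonal) with toroidal wraparound, so the coordination number k is 8
#' everywhere.
#'
#' @param L side length, an integer >= 3 (smaller lattices would collapse
#'   the Moore neighbor multiplicity).
#' @return An object of class `lattice_spec` with fields `L`, `N`,
#'   `neighborhood`, `boundary` and `k`.
#' @export
lattice_spec <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L != round(L) ||
      L < 3)
    stop("invalid lattice side: an integer L >= 3 is required, got L = ",
         format(L), call. = FALSE)
  L <- as.integer(L)
  structure(list(L = L, N = L * L, neighborhood = "moore",
                 boundary = "periodic", k = 8L),
            class = "lattice_spec")
}

#' Simulation run configuration
#'
#' Bundles the lattice, game and weight parameters with the Monte Carlo
#' protocol: initial condition, total number of Monte Carlo steps (MCS; one
#' MCS is N = L^2 asynchronous elementary updates, so each player is
#' selected once on average), the trailing measurement window used for the
#' stationary cooperation level, the number of independent realizations, and
#' the RNG seed.
#'
#' @param L lattice side length (players N = L^2).
#' @param b temptation to defect, 1 < b < 2.
#' @param delta weight-bound half-width, in \[0, 1\].
#' @param Delta per-event weight step, >= 0.
#' @param init_mode `"random"` (each site C or D with probability 1/2) or
#'   `"half_plane"` (left half-columns cooperate, right half defect;
#'   requires even L so the initial cooperation fraction is exactly 0.5).
#' @param total_mcs Monte Carlo steps to run.
#' @param measure_window trailing MCS over which the stationary cooperation
#'   fraction is averaged; must not exceed `total_mcs`.
#' @param replicates number of independent realizations (>= 1) used by the
#'   experiment drivers.
#' @param seed RNG seed, or `NULL` to draw one at run time (the seed
#'   actually used is always echoed in outputs).
#' @return An object of class `run_config` with nested fields `lattice`,
#'   `game`, `weight`, plus `init_mode`, `total_mcs`, `measure_window`,
#'   `replicates` and `seed`.
#' @seealso [full_protocol()], [desk_protocol()], [run_simulation()]
#' @export
run_config <- function(L = 100, b = 1.34, delta = 0.4, Delta = 0.2,
                       init_mode = c("random", "half_plane"),
                       total_mcs = 61000, measure_window = 1000,
                       replicates = 10, seed = NULL) {
  init_mode <- match.arg(init_mode)
  lattice <- lattice_spec(L)
  if (init_mode == "half_plane" && lattice$L %% 2L != 0L)
    stop("half_plane initial state requires an even lattice side L ",
         "(so that the cooperation fraction starts at exactly 0.5)",
         call. = FALSE)
  if (!is.numeric(total_mcs) || total_mcs < 0 || total_mcs != round(total_mcs))
    stop("total_mcs must be a non-negative integer", call. = FALSE)
  if (!is.numeric(measure_window) || measure_window < 1 ||
      measure_window != round(measure_window))
    stop("measure_window must be a positive integer", call. = FALSE)
  if (measure_window > total_mcs + 1)
    stop("measure_window must not exceed the trajectory length ",
         "(total_mcs + 1)", call. = FALSE)
  if (!is.numeric(replicates) || replicates < 1 ||
      replicates != round(replicates))
    stop("replicates must be an integer >= 1", call. = FALSE)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
      stop("seed must be a single integer", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(list(lattice = lattice, game = game_params(b),
                 weight = weight_params(delta, Delta), init_mode = init_mode,
                 total_mcs = as.integer(total_mcs),
                 measure_window = as.integer(measure_window),
                 replicates = as.integer(replicates), seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> ", x$lattice$L, "x", x$lattice$L,
      " Moore torus | b = ", x$game$b, ", delta = ", x$weight$delta,
      ", Delta = ", x$weight$Delta, "\n  init = ", x$init_mode,
      ", total_mcs = ", x$total_mcs, ", window = ", x$measure_window,
      ", replicates = ", x$replicates,
      if (!is.null(x$seed)) paste0(", seed = ", x$seed) else "", "\n",
      sep = "")
  invisible(x)
}

#' Named simulation protocols
#'
#' `full_protocol()` is the full-scale protocol (100 x 100 lattice, 61000
#' MCS, 1000-MCS measurement window, 10 realizations).  `desk_protocol()` is
#' the scaled routine protocol used throughout the test suite and the
#' acceptance experiments (50 x 50 lattice, 5000 MCS, 500-MCS window, 3
#' realizations), which reproduces the same stationary regimes at a fraction
#' of the cost.
#'
#' @param ... overrides passed on to [run_config()] (e.g. `b`, `delta`,
#'   `Delta`, `init_mode`, `seed`).
#' @return A [run_config()] object.
#' @export
full_protocol <- function(...) {
  args <- modifyList(list(L = 100, total_mcs = 61000, measure_window = 1000,
                          replicates = 10), list(...))
  do.call(run_config, args)
}

#' @rdname full_protocol
#' @export
desk_protocol <- function(...) {
  args <- modifyList(list(L = 50, total_mcs = 5000, measure_window = 500,
                          replicates = 3), list(...))
  do.call(run_config, args)
}

#' Deterministic per-replicate sub-seeds
#'
#' One global seed spawns sub-seeds for replicate `i` through a fixed Lehmer
#' step, `(seed * 48271 + i) mod (2^31 - 1)`, so adding replicates never
#' perturbs existing ones and every replicate can be replayed in isolation.
#'
#' @param seed global integer seed.
#' @param i replicate index (>= 1), may be a vector.
#' @return Integer sub-seed(s) in \[1, 2^31 - 1\].
#' @export
split_seed <- function(seed, i) {
  m <- 2147483647
  s <- as.double(seed %% m)
  as.integer((s * 48271 + as.double(i)) %% m + 1)
}
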