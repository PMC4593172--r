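# Moore offsets (dr, dc), fixed order: NW N NE W E SW S SE.
# Slot 7-d+... : the opposite of slot d (1-based) is slot 9-d.
.moore_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
.moore_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)

#' Moore neighbor table on the periodic lattice
#'
#' Maps every site to its eight Moore neighbors with toroidal wraparound.
#' Sites are 1-based linear indices in R's column-major matrix layout
#' (site of row r, column c is `(c-1)*L + r`).  Column order is the fixed
#' offset order NW, N, NE, W, E, SW, S, SE; the opposite of column `d` is
#' column `9 - d`.
#'
#' @param spec a [lattice_spec()].
#' @return An `N x 8` integer matrix of neighbor site indices.  The
#'   relation is symmetric: `y` appears among the neighbors of `x` exactly
#'   when `x` appears among the neighbors of `y`.
#' @export
build_neighbor_table <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  L <- spec$L
  i0 <- seq_len(spec$N) - 1L
  r <- i0 %% L
  cc <- i0 %/% L
  out <- matrix(0L, spec$N, 8L)
  for (d in 1:8) {
    rr <- (r + .moore_dr[d]) %% L
    c2 <- (cc + .moore_dc[d]) %% L
    out[, d] <- c2 * L + rr + 1L
  }
  out
}

# Edge-id table: each site owns the four edges towards slots 5..8
# (E, SW, S, SE); edge id = 4*(site-1) + slot - 4.  The edge towards slot
# d <= 4 is owned by the neighbor, at its opposite slot: 4*(nbr-1) + (5-d).
# Every undirected edge thus has exactly one id in 1..4N, shared by its two
# endpoints, which makes the weight field symmetric by construction.
build_edge_table <- function(spec, nbr = build_neighbor_table(spec)) {
  out <- matrix(0L, spec$N, 8L)
  i0 <- seq_len(spec$N) - 1L
  for (d in 1:4) out[, d] <- 4L * (nbr[, d] - 1L) + (5L - d)
  for (d in 5:8) out[, d] <- 4L * i0 + (d - 4L)
  out
}

#' Initial strategy grid
#'
#' @param spec a [lattice_spec()].
#' @param mode `"random"`: each site is independently a cooperator or a
#'   defector with probability 1/2 (consumes `N` uniform draws from the
#'   current RNG stream).  `"half_plane"`: the left half of the columns
#'   cooperate and the right half defect, a prepared state whose initial
#'   cooperation fraction is exactly 0.5 (requires even L).
#' @return An `L x L` integer matrix, 1 = cooperator, 0 = defector.
#' @export
init_strategies <- function(spec, mode = c("random", "half_plane")) {
  stopifnot(inherits(spec, "lattice_spec"))
  mode <- match.arg(mode)
  L <- spec$L
  if (mode == "random") {
    matrix(as.integer(runif(spec$N) < 0.5), L, L)
  } else {
    if (L %% 2L != 0L)
      stop("half_plane initial state requires an even lattice side L",
           call. = FALSE)
    matrix(rep(c(1L, 0L), each = L * L / 2L), L, L)
  }
}

#' Initial link-weight field
#'
#' Before the game every link carries weight exactly 1.  An optional
#' heterogeneous mode draws initial weights uniformly from
#' \[1 - delta, 1 + delta\]; it is provided for sensitivity checks of the
#' claim that the initial weight distribution does not affect the final
#' equilibrium, and no specific distribution is canonical.
#'
#' @param spec a [lattice_spec()].
#' @param mode `"uniform"` (all weights 1, the default) or `"random"`.
#' @param wp a [weight_params()], required for `mode = "random"`.
#' @return A numeric vector of length `4 * N`, one entry per undirected
#'   edge of the Moore torus.
#' @export
init_weights <- function(spec, mode = c("uniform", "random"), wp = NULL) {
  stopifnot(inherits(spec, "lattice_spec"))
  mode <- match.arg(mode)
  n_edges <- 4L * spec$N
  if (mode == "uniform") {
    rep(1, n_edges)
  } else {
    if (is.null(wp)) stop("random weight initialization needs weight_params",
                          call. = FALSE)
    runif(n_edges, 1 - wp$delta, 1 + wp$delta)
  }
}

#' Simulation state
#'
#' Bundles the strategy grid, the symmetric link-weight field and the
#' elapsed MCS count, together with cached neighbor and edge tables.
#' Weights are stored once per undirected edge; both endpoints of a link
#' resolve to the same stored value (see [edge_weight()]).
#'
#' @param spec a [lattice_spec()].
#' @param strategies `L x L` integer matrix (1 = C, 0 = D).
#' @param weights numeric vector of length `4 * N`, or `NULL` for the
#'   uniform all-ones field.
#' @param mcs elapsed Monte Carlo steps.
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(spec, strategies, weights = NULL, mcs = 0L) {
  stopifnot(inherits(spec, "lattice_spec"))
  strategies <- as.matrix(strategies)
  storage.mode(strategies) <- "integer"
  if (!all(dim(strategies) == c(spec$L, spec$L)))
    stop("strategy grid must be L x L", call. = FALSE)
  if (!all(strategies %in% c(0L, 1L)))
    stop("strategies must be coded 1 (C) or 0 (D)", call. = FALSE)
  if (is.null(weights)) weights <- init_weights(spec)
  if (length(weights) != 4L * spec$N)
    stop("weight field must have one value per undirected edge (4*N)",
         call. = FALSE)
  nbr <- build_neighbor_table(spec)
  structure(list(spec = spec, strategies = strategies,
                 weights = as.numeric(weights), mcs = as.integer(mcs),
                 nbr = nbr, edge = build_edge_table(spec, nbr)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state> ", x$spec$L, "x", x$spec$L, " torus, mcs = ", x$mcs,
      ", rho_C = ", format(cooperation_fraction(x), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Fresh state for a run configuration
#'
#' @param config a [run_config()].
#' @return A [sim_state()] with the configured initial strategies and all
#'   link weights equal to 1.
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim_state(config$lattice,
            init_strategies(config$lattice, config$init_mode))
}

# internal: edge id for the link between neighboring sites x and y
edge_index <- function(state, x, y) {
  d <- match(y, state$nbr[x, ])
  if (is.na(d))
    stop("sites ", x, " and ", y, " are not lattice neighbors", call. = FALSE)
  state$edge[x, d]
}

#' Symmetric link-weight accessor
#'
#' Both orientations of a link resolve to the identical stored value, so
#' `edge_weight(state, x, y)` always equals `edge_weight(state, y, x)`.
#'
#' @param state a [sim_state()].
#' @param x,y 1-based linear site indices of two neighboring sites.
#' @param value replacement weight.
#' @return The weight of the undirected edge `{x, y}`.
#' @export
edge_weight <- function(state, x, y) {
  state$weights[edge_index(state, x, y)]
}

#' @rdname edge_weight
#' @export
`edge_weight<-` <- function(state, x, y, value) {
  state$weights[edge_index(state, x, y)] <- value
  state
}
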