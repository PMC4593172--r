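# Independent oracles used across the test suite.

# Brute-force utility: enumerates the eight Moore offsets with direct
# toroidal coordinate arithmetic and reads weights only through the public
# symmetric accessor; independent of the cached neighbor/edge tables and of
# the loop inside utility().
brute_force_utility <- function(state, site, game) {
  L <- state$spec$L
  r <- (site - 1L) %% L
  cc <- (site - 1L) %/% L
  U <- 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- ((cc + dc) %% L) * L + ((r + dr) %% L) + 1L
    p <- if (state$strategies[site] == 1L) {
      if (state$strategies[nb] == 1L) game$R else game$S
    } else {
      if (state$strategies[nb] == 1L) game$T else game$P
    }
    U <- U + edge_weight(state, site, nb) * p
  }
  U
}

# Independent classical spatial prisoner's dilemma (no weights anywhere),
# consuming the same RNG draw order as the coevolution kernel so that with
# Delta = 0 the two are trace-identical under a shared seed:
#   u1 focal, u2 neighbor slot, u3 adoption uniform only when U_y > U_x.
# Neighbor slots follow the same fixed offset order NW N NE W E SW S SE.
classical_spd_steps <- function(strat, b, n_steps) {
  L <- nrow(strat)
  N <- L * L
  s <- as.integer(strat)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  pay <- function(sx, sy) if (sx == 1L) (if (sy == 1L) 1 else 0) else
    (if (sy == 1L) b else 0)
  usum <- function(i) {
    r <- (i - 1L) %% L
    cc <- (i - 1L) %/% L
    u <- 0
    for (j in 1:8) {
      nb <- ((cc + dc[j]) %% L) * L + ((r + dr[j]) %% L) + 1L
      u <- u + pay(s[i], s[nb])
    }
    u
  }
  for (k in seq_len(n_steps)) {
    x <- floor(runif(1) * N) + 1L
    if (x > N) x <- N
    jy <- floor(runif(1) * 8) + 1L
    if (jy > 8L) jy <- 8L
    r <- (x - 1L) %% L
    cc <- (x - 1L) %/% L
    y <- ((cc + dc[jy]) %% L) * L + ((r + dr[jy]) %% L) + 1L
    Ux <- usum(x)
    Uy <- usum(y)
    if (Uy > Ux) {
      W <- min(1, (Uy - Ux) / (8 * b))
      if (runif(1) < W) s[x] <- s[y]
    }
  }
  matrix(s, L, L)
}

# random small state for property tests
random_state <- function(L = 5, delta = 0.4) {
  spec <- lattice_spec(L)
  sim_state(spec,
            matrix(sample(c(0L, 1L), spec$N, replace = TRUE), L, L),
            weights = runif(4L * spec$N, 1 - delta, 1 + delta))
}
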