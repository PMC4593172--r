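# Experiment drivers: replicate loops over parameter grids, with
# deterministic per-replicate sub-seeds from split_seed(), returning tidy
# one-row-per-replicate data frames of class "sweep_result".

run_replicates <- function(config, seed, stop_when_uniform = TRUE) {
  seeds <- split_seed(seed, seq_len(config$replicates))
  vapply(seeds, function(s) {
    run_simulation(config, seed = s,
                   stop_when_uniform = stop_when_uniform)$stationary
  }, numeric(1))
}

new_sweep_result <- function(df, config) {
  attr(df, "config") <- config
  class(df) <- c("sweep_result", "data.frame")
  df
}

#' Sweep the link-weight amplitude Delta/delta
#'
#' For each ratio in the grid, runs `replicates` independent realizations
#' with `Delta = ratio * delta` and records the stationary cooperation
#' fraction.  The cooperation level is non-monotonic in the amplitude: an
#' intermediate Delta/delta resolves the dilemma best.
#'
#' @param b temptation to defect.
#' @param delta weight-bound half-width; must be positive (the ratio
#'   parameterization Delta/delta requires delta != 0).
#' @param ratios numeric vector of Delta/delta values (>= 0).
#' @param config protocol template, a [run_config()]; its `b`, `delta` and
#'   `Delta` fields are overridden point by point.
#' @param seed global seed; per-replicate sub-seeds come from
#'   [split_seed()].
#' @param stop_when_uniform stop runs early once the strategy field
#'   fixates (sound for stationary rho_C; default `TRUE`).
#' @return A `sweep_result` data frame with columns `ratio`, `Delta`,
#'   `replicate`, `seed`, `rho_c`.
#' @seealso [aggregate_sweep()]
#' @export
sweep_amplitude <- function(b, delta, ratios, config = desk_protocol(),
                            seed = 1L, stop_when_uniform = TRUE) {
  if (!is.numeric(delta) || delta <= 0)
    stop("the amplitude parameterization Delta/delta requires delta != 0 ",
         "(delta > 0)", call. = FALSE)
  if (any(ratios < 0)) stop("ratios must be >= 0", call. = FALSE)
  rows <- lapply(seq_along(ratios), function(i) {
    r <- ratios[i]
    cfg <- run_config(L = config$lattice$L, b = b, delta = delta,
                      Delta = r * delta, init_mode = config$init_mode,
                      total_mcs = config$total_mcs,
                      measure_window = config$measure_window,
                      replicates = config$replicates)
    seeds <- split_seed(seed + (i - 1L) * 1000L, seq_len(cfg$replicates))
    data.frame(ratio = r, Delta = r * delta,
               replicate = seq_len(cfg$replicates), seed = seeds,
               rho_c = vapply(seeds, function(s)
                 run_simulation(cfg, seed = s,
                                stop_when_uniform = stop_when_uniform)$stationary,
                 numeric(1)))
  })
  new_sweep_result(do.call(rbind, rows), config)
}

#' Sweep the temptation parameter b
#'
#' Stationary cooperation fraction as a function of b, one curve per
#' weight step Delta at fixed delta.  In the traditional case (Delta = 0)
#' cooperation decays with b and goes extinct near b = 1.24; moderate
#' Delta extends cooperator survival to much larger b.
#'
#' @param delta weight-bound half-width.
#' @param Deltas numeric vector of weight steps, one curve each.
#' @param b_grid temptation values, all in (1, 2).
#' @inheritParams sweep_amplitude
#' @return A `sweep_result` data frame with columns `Delta`, `b`,
#'   `replicate`, `seed`, `rho_c`.
#' @export
sweep_temptation <- function(delta, Deltas, b_grid, config = desk_protocol(),
                             seed = 1L, stop_when_uniform = TRUE) {
  if (any(b_grid <= 1 | b_grid >= 2))
    stop("all temptation values must satisfy 1 < b < 2", call. = FALSE)
  grid <- expand.grid(Delta = Deltas, b = b_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- run_config(L = config$lattice$L, b = grid$b[i], delta = delta,
                      Delta = grid$Delta[i], init_mode = config$init_mode,
                      total_mcs = config$total_mcs,
                      measure_window = config$measure_window,
                      replicates = config$replicates)
    seeds <- split_seed(seed + (i - 1L) * 1000L, seq_len(cfg$replicates))
    data.frame(Delta = grid$Delta[i], b = grid$b[i],
               replicate = seq_len(cfg$replicates), seed = seeds,
               rho_c = vapply(seeds, function(s)
                 run_simulation(cfg, seed = s,
                                stop_when_uniform = stop_when_uniform)$stationary,
                 numeric(1)))
  })
  new_sweep_result(do.call(rbind, rows), config)
}

#' Aggregate a sweep over replicates
#'
#' @param result a `sweep_result` from [sweep_amplitude()],
#'   [sweep_temptation()] or [phase_diagram()].
#' @param by grouping columns; defaults to whichever of `ratio`, `Delta`,
#'   `b` are present.
#' @return A data frame with per-point `mean`, `se` (standard error of the
#'   mean, `NA` with fewer than 2 replicates) and `n`.
#' @export
aggregate_sweep <- function(result,
                            by = intersect(c("ratio", "Delta", "b"),
                                           names(result))) {
  stopifnot(length(by) >= 1, all(by %in% names(result)),
            "rho_c" %in% names(result))
  df <- as.data.frame(result)
  agg <- aggregate(df["rho_c"], df[by], function(x)
    c(mean = mean(x), se = if (length(x) >= 2) sd(x) / sqrt(length(x))
                           else NA_real_, n = length(x)))
  out <- cbind(agg[by], as.data.frame(agg$rho_c))
  names(out) <- c(by, "mean", "se", "n")
  out$n <- as.integer(out$n)
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Time course of the cooperation fraction
#'
#' Runs one realization recording rho_C at every MCS, typically from the
#' prepared half-plane state, with strategy snapshots at requested steps.
#' Early termination is off: the full time course (and the evolving weight
#' field) is of interest here.
#'
#' @param config a [run_config()].
#' @param record_every thin the returned trajectory to every
#'   `record_every`-th MCS (row 0 and the final row are always kept).
#' @param snapshot_steps MCS values at which to capture snapshots
#'   (0 = initial state).
#' @param seed RNG seed (defaults to `config$seed`).
#' @param record_weights record mean/variance of the weight field per MCS.
#' @return A `coevo_run` (see [run_simulation()]), with its `trajectory`
#'   thinned as requested.
#' @export
time_course <- function(config, record_every = 1L,
                        snapshot_steps = integer(0), seed = config$seed,
                        record_weights = FALSE) {
  run <- run_simulation(config, seed = seed,
                        record_weights = record_weights,
                        snapshot_steps = snapshot_steps,
                        stop_when_uniform = FALSE)
  if (record_every > 1L) {
    keep <- unique(c(seq(1L, nrow(run$trajectory), by = record_every),
                     nrow(run$trajectory)))
    run$trajectory <- run$trajectory[keep, , drop = FALSE]
    rownames(run$trajectory) <- NULL
  }
  run
}

#' Interpolated extinction threshold from a temptation sweep
#'
#' For cooperators: the largest b at which the mean stationary rho_C still
#' exceeds the extinction tolerance, linearly interpolated towards the
#' first grid point at or below it.  For defectors: the same construction
#' on the dominance level 1 - tol (the b below which defectors are
#' extinct, i.e. cooperation is complete).
#'
#' @param result a `sweep_result` or aggregated data frame containing a
#'   single curve (one `Delta`/`ratio` value) with columns `b` and `rho_c`
#'   or `mean`.
#' @param target `"cooperators"` or `"defectors"`.
#' @param tol extinction tolerance on rho_C; defaults to `1/N^2` for the
#'   lattice the sweep was run on (any mean rho_C below that is
#'   indistinguishable from extinction).  Raising the tolerance never
#'   raises the cooperator threshold.
#' @return The interpolated critical b, or `NA` with attribute `status`
#'   (`"below_range"`/`"above_range"`) when the transition is not
#'   bracketed by the scanned b range.
#' @examples
#' curve <- data.frame(b = seq(1.1, 1.4, 0.01))
#' curve$mean <- pmax(0, 1 - 5 * (curve$b - 1.1))
#' find_extinction_threshold(curve, tol = 1e-9)  # crosses zero at b = 1.30
#' @export
find_extinction_threshold <- function(result,
                                      target = c("cooperators", "defectors"),
                                      tol = NULL) {
  target <- match.arg(target)
  df <- as.data.frame(result)
  if (!"mean" %in% names(df)) {
    for (col in c("ratio", "Delta")) {
      if (col %in% names(df) && length(unique(df[[col]])) > 1L)
        stop("result mixes several ", col,
             " values; extract one curve first", call. = FALSE)
    }
    df <- aggregate_sweep(df, by = "b")
  }
  df <- df[order(df$b), , drop = FALSE]
  if (is.null(tol)) {
    cfg <- attr(result, "config")
    tol <- if (!is.null(cfg)) 1 / cfg$lattice$N^2 else 1e-6
  }
  lvl <- if (target == "cooperators") tol else 1 - tol
  m <- df$mean
  b <- df$b
  above <- which(m > lvl)
  if (length(above) == 0L)
    return(structure(NA_real_, status = "below_range"))
  i <- max(above)
  if (i == length(b))
    return(structure(NA_real_, status = "above_range"))
  b[i] + (m[i] - lvl) / (m[i] - m[i + 1L]) * (b[i + 1L] - b[i])
}

#' Phase diagram in the Delta/delta--b plane
#'
#' Stationary cooperation fraction over a full (ratio, b) grid at fixed
#' delta, with per-ratio extinction boundaries for cooperators and
#' defectors extracted by [find_extinction_threshold()].  Both boundary
#' curves peak at intermediate Delta/delta: an intermediate amplitude is
#' most favorable for cooperator survival and domination.
#'
#' @param ratio_grid Delta/delta values (>= 0).
#' @param b_grid temptation values, all in (1, 2).
#' @param delta weight-bound half-width (> 0).
#' @inheritParams sweep_amplitude
#' @param tol extinction tolerance passed to
#'   [find_extinction_threshold()].
#' @return An object of class `phase_diagram`: a list with `grid` (the
#'   per-replicate `sweep_result`), `surface` (aggregated mean rho_C per
#'   (ratio, b)), and `boundaries` (data frame `ratio`,
#'   `b_c_cooperators`, `b_c_defectors`; `NA` where a boundary is not
#'   bracketed by `b_grid`).
#' @export
phase_diagram <- function(ratio_grid, b_grid, delta,
                          config = desk_protocol(), seed = 1L, tol = NULL) {
  if (!length(ratio_grid) || !length(b_grid))
    stop("ratio_grid and b_grid must be non-empty", call. = FALSE)
  if (delta <= 0)
    stop("the amplitude parameterization Delta/delta requires delta != 0",
         call. = FALSE)
  rows <- lapply(seq_along(ratio_grid), function(i) {
    sw <- sweep_temptation(delta, ratio_grid[i] * delta, b_grid,
                           config = config,
                           seed = seed + (i - 1L) * 100000L)
    sw$ratio <- ratio_grid[i]
    sw
  })
  grid <- new_sweep_result(do.call(rbind, rows), config)
  surface <- aggregate_sweep(grid, by = c("ratio", "b"))
  boundaries <- do.call(rbind, lapply(ratio_grid, function(r) {
    cur <- surface[surface$ratio == r, c("b", "mean")]
    attr(cur, "config") <- config
    data.frame(ratio = r,
               b_c_cooperators = as.numeric(
                 find_extinction_threshold(cur, "cooperators", tol = tol)),
               b_c_defectors = as.numeric(
                 find_extinction_threshold(cur, "defectors", tol = tol)))
  }))
  structure(list(grid = grid, surface = surface, boundaries = boundaries),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram> ", length(unique(x$surface$ratio)), " ratios x ",
      length(unique(x$surface$b)), " b values\n", sep = "")
  print(x$boundaries)
  invisible(x)
}
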