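#' Fraction of cooperators
#'
#' The order parameter of the model: the number of cooperating sites
#' divided by N = L^2.
#'
#' @param state a [sim_state()], or any integer strategy grid (1 = C).
#' @return The cooperation fraction rho_C in \[0, 1\].
#' @export
cooperation_fraction <- function(state) {
  g <- if (inherits(state, "sim_state")) state$strategies else state
  mean(g == 1L)
}

#' Stationary cooperation fraction
#'
#' Arithmetic mean of rho_C over the trailing measurement window of a
#' trajectory, the standard estimate of the stationary cooperation level.
#'
#' @param traj a `coevo_run`, or a data frame with columns `mcs` and
#'   `rho_c`.
#' @param window number of trailing MCS records to average over.
#' @return Mean rho_C over the last `window` records.
#' @export
stationary_fraction <- function(traj, window) {
  if (inherits(traj, "coevo_run")) traj <- traj$trajectory
  n <- nrow(traj)
  if (!is.numeric(window) || window < 1 || window > n)
    stop("window must be between 1 and the trajectory length (", n, ")",
         call. = FALSE)
  mean(traj$rho_c[seq.int(n - window + 1L, n)])
}

#' Link-weight distribution summary
#'
#' Histogram, mean and population variance of the 4N undirected edge
#' weights.  When `Delta > 0` the attainable weights form the lattice
#' `{1 + k*Delta}` clamped to \[1 - delta, 1 + delta\], so the default
#' bins are centered on those attainable values (one bin per value), which
#' avoids split-value artifacts at bin edges; pass `bins` for a plain
#' uniform binning of \[1 - delta, 1 + delta\] instead.
#'
#' The variance of any variable confined to an interval of half-width
#' delta is at most delta^2 (attained by the two-point distribution at the
#' bounds); this hard bound is asserted on every summary.
#'
#' @param state a [sim_state()].
#' @param wp the [weight_params()] governing the run.
#' @param bins number of uniform bins, or `NULL` for the default
#'   Delta-aligned binning.
#' @return An object of class `weight_summary`: a list with `histogram`
#'   (data frame `bin_left`, `bin_right`, `count`), `mean` and `variance`.
#' @export
weight_summary <- function(state, wp, bins = NULL) {
  stopifnot(inherits(state, "sim_state"), inherits(wp, "weight_params"))
  w <- state$weights
  lo <- 1 - wp$delta
  hi <- 1 + wp$delta
  if (is.null(bins) && wp$Delta > 0) {
    K <- ceiling(wp$delta / wp$Delta) + 1
    vals <- sort(unique(pmin(pmax(1 + wp$Delta * (-K:K), lo), hi)))
    if (length(vals) == 1L) {
      breaks <- c(vals - wp$Delta / 2, vals + wp$Delta / 2)
    } else {
      mids <- (vals[-1] + vals[-length(vals)]) / 2
      breaks <- c(vals[1] - (mids[1] - vals[1]), mids,
                  vals[length(vals)] + (vals[length(vals)] -
                                          mids[length(mids)]))
    }
  } else {
    if (is.null(bins)) bins <- 64L
    if (!is.numeric(bins) || bins < 1) stop("bins must be >= 1",
                                            call. = FALSE)
    if (hi > lo) {
      breaks <- seq(lo, hi, length.out = bins + 1L)
    } else {
      breaks <- c(lo - 0.5, hi + 0.5)  # degenerate delta = 0: one bin at 1
    }
  }
  idx <- findInterval(w, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  m <- mean(w)
  v <- mean((w - m)^2)  # population variance over all 4N edges
  stopifnot(sum(counts) == length(w), v <= wp$delta^2 + 1e-12)
  structure(list(histogram = data.frame(bin_left = breaks[-length(breaks)],
                                        bin_right = breaks[-1],
                                        count = counts),
                 mean = m, variance = v),
            class = "weight_summary")
}

#' @export
print.weight_summary <- function(x, ...) {
  cat("<weight_summary> mean = ", format(x$mean, digits = 4),
      ", variance = ", format(x$variance, digits = 4), ", ",
      nrow(x$histogram), " bins / ", sum(x$histogram$count), " edges\n",
      sep = "")
  invisible(x)
}

#' Immutable strategy snapshot
#'
#' Copies the strategy field with its MCS stamp; the copy is isolated from
#' further simulation.
#'
#' @param state a [sim_state()].
#' @return An object of class `strategy_snapshot`: a list with `grid`
#'   (integer `L x L` matrix, 1 = C, 0 = D) and `mcs`.
#' @seealso [write_snapshot_pgm()]
#' @export
capture_snapshot <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  structure(list(grid = state$strategies + 0L, mcs = state$mcs),
            class = "strategy_snapshot")
}

#' @export
print.strategy_snapshot <- function(x, ...) {
  cat("<strategy_snapshot> ", nrow(x$grid), "x", ncol(x$grid), " at mcs = ",
      x$mcs, ", rho_C = ", format(mean(x$grid), digits = 4), "\n", sep = "")
  invisible(x)
}
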