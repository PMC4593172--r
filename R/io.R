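# Configuration serialization (JSON / YAML), delimited-text exports,
# snapshot images, run manifests and deterministic test fixtures.

config_to_list <- function(config) {
  stopifnot(inherits(config, "run_config"))
  list(lattice = list(L = config$lattice$L,
                      neighborhood = config$lattice$neighborhood,
                      boundary = config$lattice$boundary,
                      k = config$lattice$k),
       game = list(b = config$game$b, R = config$game$R, P = config$game$P,
                   S = config$game$S),
       weight = list(delta = config$weight$delta,
                     Delta = config$weight$Delta),
       init_mode = config$init_mode, total_mcs = config$total_mcs,
       measure_window = config$measure_window,
       replicates = config$replicates, seed = config$seed)
}

config_from_list <- function(x) {
  run_config(L = x$lattice$L, b = x$game$b, delta = x$weight$delta,
             Delta = x$weight$Delta, init_mode = x$init_mode,
             total_mcs = x$total_mcs, measure_window = x$measure_window,
             replicates = x$replicates, seed = x$seed)
}

#' Read and write run configurations
#'
#' Configurations are serialized as JSON or YAML (chosen from the file
#' extension: `.json` vs `.yaml`/`.yml`) with the canonical nested field
#' names `lattice` (L, neighborhood, boundary, k), `game` (b, R, P, S),
#' `weight` (delta, Delta), `init_mode`, `total_mcs`, `measure_window`,
#' `replicates`, `seed`.  The serialize - parse - serialize round trip is
#' byte-stable.
#'
#' @param config a [run_config()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a validated [run_config()].
#' @export
write_run_config <- function(config, path) {
  lst <- config_to_list(config)
  fmt <- config_format(path)
  if (fmt == "json") {
    writeLines(jsonlite::toJSON(lst, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"), path)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  fmt <- config_format(path)
  lst <- if (fmt == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  config_from_list(lst)
}

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "json"
  else if (ext %in% c("yaml", "yml")) "yaml"
  else stop("config files must end in .json, .yaml or .yml", call. = FALSE)
}

#' Export a trajectory as CSV
#'
#' Columns `mcs`, `rho_c`, `mean_weight`, `var_weight` (the weight columns
#' are `NA` when they were not recorded), with `.` as the decimal
#' separator regardless of locale.
#'
#' @param run a `coevo_run` (or a trajectory data frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(run, path) {
  traj <- if (inherits(run, "coevo_run")) run$trajectory else run
  for (col in c("mean_weight", "var_weight"))
    if (!col %in% names(traj)) traj[[col]] <- NA_real_
  write.table(traj[, c("mcs", "rho_c", "mean_weight", "var_weight")], path,
              sep = ",", dec = ".", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export sweep results as tidy CSV
#'
#' One row per parameter point per replicate; use [aggregate_sweep()] and
#' write that as well for the aggregated view.
#'
#' @param result a `sweep_result` or any data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  write.table(as.data.frame(result), path, sep = ",", dec = ".",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a strategy snapshot
#'
#' `write_snapshot_matrix()` writes the raw 0/1 grid (rows = lattice rows,
#' space-separated).  `write_snapshot_pgm()` writes a plain-text (P2) PGM
#' image, cooperators white (1), defectors black (0).
#' `write_snapshot_png()` writes a color PNG with the conventional
#' mapping, cooperators blue and defectors red (requires the `png`
#' package).
#'
#' @param snapshot a `strategy_snapshot` (see [capture_snapshot()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshot_matrix <- function(snapshot, path) {
  write.table(snapshot$grid, path, sep = " ", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot_matrix
#' @export
write_snapshot_pgm <- function(snapshot, path) {
  g <- snapshot$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "1"), con)
  writeLines(apply(g, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_snapshot_matrix
#' @export
write_snapshot_png <- function(snapshot, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  g <- snapshot$grid
  img <- array(0, dim = c(nrow(g), ncol(g), 3L))
  img[, , 1] <- 1 - g  # defectors red
  img[, , 3] <- g      # cooperators blue
  png::writePNG(img, path)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON sidecar recording the fully resolved configuration, the seeds of
#' every replicate, the code version and the inventory of output files, so
#' any replicate can be replayed bit-exactly.
#'
#' @param config a [run_config()].
#' @param seeds integer vector of per-replicate seeds actually used.
#' @param files character vector of output files produced.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seeds, files, path) {
  lst <- list(config = config_to_list(config), seeds = as.integer(seeds),
              code_version = as.character(packageVersion("coevoPD")),
              start_mcs = 0L, end_mcs = config$total_mcs,
              outputs = as.character(files))
  writeLines(jsonlite::toJSON(lst, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}

# reference enumerator for fixture sidecars: loops sites x neighbors with
# direct toroidal coordinate arithmetic, independent of the cached tables
enumerate_utilities <- function(state, game) {
  L <- state$spec$L
  U <- numeric(state$spec$N)
  P <- matrix(0, state$spec$N, 8L)
  for (site in seq_len(state$spec$N)) {
    r <- (site - 1L) %% L
    cc <- (site - 1L) %/% L
    j <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      j <- j + 1L
      nb <- ((cc + dc) %% L) * L + ((r + dr) %% L) + 1L
      p <- pairwise_payoff(state$strategies[site], state$strategies[nb],
                           game)
      P[site, j] <- p
      U[site] <- U[site] + edge_weight(state, site, nb) * p
    }
  }
  list(U = U, avg_U = U / 8, avg_payoff = rowMeans(P), payoffs = P)
}

#' Deterministic test fixtures
#'
#' Small named states together with a sidecar of utilities and pairwise
#' payoffs computed by a direct coordinate-arithmetic enumerator (a code
#' path independent of the cached neighbor/edge tables), for unit tests.
#'
#' @param name one of `"all-C"`, `"all-D"`, `"half-plane"`,
#'   `"checkerboard"` (all 4 x 4) or `"random-5x5"` (fixed internal seed).
#' @param b temptation used for the sidecar payoffs.
#' @return A list with `state` (a [sim_state()]), `game` and `expected`
#'   (list `U`, `avg_U`, `payoffs`; payoff columns follow the enumerator's
#'   row-major offset order, which matches the neighbor-table order).
#' @export
make_fixture <- function(name, b = 1.5) {
  game <- game_params(b)
  state <- switch(
    name,
    "all-C" = sim_state(lattice_spec(4), matrix(1L, 4, 4)),
    "all-D" = sim_state(lattice_spec(4), matrix(0L, 4, 4)),
    "half-plane" = sim_state(lattice_spec(4),
                             init_strategies(lattice_spec(4), "half_plane")),
    "checkerboard" = sim_state(lattice_spec(4),
                               outer(1:4, 1:4, function(r, c)
                                 (r + c) %% 2L)),
    "random-5x5" = {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(550137L)
      spec <- lattice_spec(5)
      st <- sim_state(spec, init_strategies(spec, "random"),
                      weights = runif(4L * spec$N, 0.6, 1.4))
      st
    },
    stop("unknown fixture name: ", name, call. = FALSE))
  list(state = state, game = game,
       expected = enumerate_utilities(state, game))
}
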