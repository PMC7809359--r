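#' Deterministic per-cell seed derivation
#'
#' Every simulation cell of a sweep gets its own RNG seed, derived from the
#' master seed and the cell coordinates by a fixed integer hash, so that
#' (a) cells are statistically independent streams, (b) any single cell can
#' be re-run in isolation from its provenance row, and (c) results never
#' depend on sweep execution order. Values stay below 2^31.
#'
#' @param master_seed integer master seed.
#' @param iteration pruning-iteration index.
#' @param p_index,h_index 1-based grid coordinates.
#' @return an integer seed in \[1, 2147483629\].
#' @export
cell_seed <- function(master_seed, iteration, p_index, h_index) {
  m <- 2147483629
  x <- (as.numeric(master_seed) %% m) * 1000003
  x <- (x + as.numeric(iteration) * 7919) %% m
  x <- (x * 31 + as.numeric(p_index) * 104729) %% m
  x <- (x * 31 + as.numeric(h_index) * 15485863) %% m
  as.integer(x %% m) + 1L
}

#' Pipeline configuration
#'
#' Bundles everything a full pruning-dynamics run needs: the input
#' morphology (an SWC path, a [morphology] object, or a generator spec), the
#' pruning iterations to evaluate, the (P, h) grid, the simulation
#' parameters and the master seed. A persisted configuration plus the same
#' package version reproduces a run exactly.
#'
#' @param input an SWC file path, a `morphology`, or a list
#'   `list(kind = "chain"|"star"|"cayley"|"random"|"pyramidal", ...)` with
#'   the matching generator arguments.
#' @param iterations pruning iterations to evaluate (default 0).
#' @param P_values,h_values parameter grid (defaults: [default_grid()]).
#' @param n_steps counted steps per cell.
#' @param master_seed integer master seed.
#' @param dt,refractory_steps,drive_soma,transient_steps simulation
#'   parameters, see [dynamics_params()].
#' @param out_dir directory for result files, or `NULL` to skip writing.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, iterations = 0L,
                       P_values = default_grid()$P,
                       h_values = default_grid()$h,
                       n_steps = 20000L, master_seed = 1L,
                       dt = 0.001, refractory_steps = 7L,
                       drive_soma = TRUE, transient_steps = 0L,
                       out_dir = NULL) {
  structure(list(input = input, iterations = sort(unique(as.integer(iterations))),
                 P_values = P_values, h_values = h_values,
                 n_steps = as.integer(n_steps),
                 master_seed = as.integer(master_seed),
                 dt = dt, refractory_steps = as.integer(refractory_steps),
                 drive_soma = isTRUE(drive_soma),
                 transient_steps = as.integer(transient_steps),
                 out_dir = out_dir),
            class = "run_config")
}

.resolve_input <- function(input) {
  if (inherits(input, "morphology")) return(input)
  if (is.character(input) && length(input) == 1L) {
    if (!file.exists(input)) stop("input SWC not found: ", input)
    m <- read_swc(input)
    return(strip_axon(collapse_soma(m)))
  }
  if (is.list(input) && !is.null(input$kind)) {
    args <- input[setdiff(names(input), "kind")]
    gen <- switch(input$kind,
                  chain = make_chain, star = make_star,
                  cayley = make_cayley, random = make_random_tree,
                  pyramidal = make_synthetic_pyramidal,
                  stop("unknown generator kind: ", input$kind))
    return(do.call(gen, args))
  }
  stop("input must be an SWC path, a morphology, or a generator spec list")
}

#' Run the full pruning-dynamics pipeline
#'
#' For every requested pruning iteration: materialise the pruned
#' morphology, record its morphometrics, sweep the (P, h) grid (per-cell
#' seeds from [cell_seed()]), extract the soma response curve and dynamic
#' range per P, compute parameter-space mean E and E_rel, and classify the
#' stage in branch-centrality space. Optionally writes `results.csv` (long,
#' one row per cell with seed provenance), `summary.csv` (one row per
#' iteration), `delta.csv` (iteration x P) and `config.json` to
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages (default `FALSE`).
#' @return A list of class `pipeline_result`: `cells` (long data frame),
#'   `summary` (per-iteration data frame), `delta` (iteration x P data
#'   frame), `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  m <- .resolve_input(config$input)
  traj <- prune_trajectory(m)
  max_it <- traj$landmarks$fully_pruned_iteration
  bad <- config$iterations[config$iterations > max_it]
  if (length(bad))
    stop("iteration(s) beyond the fully-pruned iteration (", max_it, "): ",
         paste(bad, collapse = ", "))

  cells <- list(); summ <- list(); deltas <- list()
  for (it in config$iterations) {
    say("iteration %d: pruning and sweeping %d x %d grid",
        it, length(config$P_values), length(config$h_values))
    mi <- snapshot_at(m, it)
    mm <- morphometrics(mi)
    sw <- sweep_grid(mi, config$P_values, config$h_values,
                     n_steps = config$n_steps,
                     master_seed = config$master_seed, iteration = it,
                     dt = config$dt, refractory_steps = config$refractory_steps,
                     drive_soma = config$drive_soma,
                     transient_steps = config$transient_steps)
    cells[[length(cells) + 1L]] <- sw
    dl <- vapply(config$P_values, function(P) {
      dr <- tryCatch(delta_from_sweep(sw, P), error = function(e) NULL)
      if (is.null(dr)) NA_real_ else dr$delta
    }, numeric(1))
    deltas[[length(deltas) + 1L]] <-
      data.frame(iteration = it, P = config$P_values, delta = dl)
    mean_E <- tryCatch(as.numeric(parameter_space_mean(sw, "E")),
                       error = function(e) NA_real_)
    mean_E_rel <- tryCatch(as.numeric(parameter_space_mean(sw, "E_rel")),
                           error = function(e) NA_real_)
    summ[[length(summ) + 1L]] <- data.frame(
      iteration = it,
      n_compartments = mm$n_compartments,
      n_bifurcations = mm$n_bifurcations,
      n_somatic_branches = mm$n_somatic_branches,
      soma_centrality = mm$soma_centrality,
      mean_E = mean_E, mean_E_rel = mean_E_rel,
      n_undefined_cells = sum(!sw$defined),
      type_label = classify_neuron(mm$n_somatic_branches, mm$soma_centrality)
    )
  }
  out <- structure(list(cells = do.call(rbind, cells),
                        summary = do.call(rbind, summ),
                        delta = do.call(rbind, deltas),
                        landmarks = traj$landmarks,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$cells, file.path(config$out_dir, "results.csv"),
              row.names = FALSE)
    write.csv(out$summary, file.path(config$out_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(out$delta, file.path(config$out_dir, "delta.csv"),
              row.names = FALSE)
    cfg <- config
    cfg$input <- if (inherits(cfg$input, "morphology")) "<morphology object>" else cfg$input
    jsonlite::write_json(unclass(cfg), file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    say("results written to %s", config$out_dir)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d iteration(s), %d cells each>\n",
              nrow(x$summary), nrow(x$cells) / max(1L, nrow(x$summary))))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
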