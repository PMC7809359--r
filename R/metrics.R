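#' Response function of a compartment
#'
#' Mean firing rate of a target compartment (the soma by default) as a
#' function of the external input rate `h`, at fixed propagation
#' probability `P`. One independent simulation is run per grid point, with
#' per-point seeds derived deterministically from `master_seed` via
#' [cell_seed()].
#'
#' @param m a collapsed, axon-stripped [morphology].
#' @param P propagation probability.
#' @param h_grid strictly increasing vector of input rates (Hz).
#' @param n_steps counted steps per simulation.
#' @param master_seed integer master seed.
#' @param target compartment id whose rate is reported; default the soma.
#' @param ... further arguments for [dynamics_params()] (`dt`,
#'   `refractory_steps`, `drive_soma`, `transient_steps`).
#' @return An object of class `response_curve`: data frame columns `h`, `F`
#'   (Hz), with attributes `P`, `target`, `n_steps`, `master_seed`.
#' @export
response_curve <- function(m, P, h_grid, n_steps, master_seed,
                           target = NULL, ...) {
  if (length(h_grid) == 0L) stop("h_grid must be non-empty")
  if (is.unsorted(h_grid, strictly = TRUE))
    stop("h_grid must be strictly increasing")
  if (is.null(target)) target <- m$soma_id
  F <- vapply(seq_along(h_grid), function(j) {
    p <- dynamics_params(P = P, h = h_grid[j], n_steps = n_steps,
                         seed = cell_seed(master_seed, 0L, 1L, j), ...)
    firing_rate(simulate_dynamics(m, p), id = target)
  }, numeric(1))
  structure(data.frame(h = h_grid, F = unname(F)),
            class = c("response_curve", "data.frame"),
            P = P, target = target, n_steps = n_steps,
            master_seed = master_seed)
}

#' Dynamic range of a response curve
#'
#' The dynamic range summarises how wide a band of input rates a
#' response function maps into distinguishable outputs:
#' `delta = 10 * log10(h90 / h10)`, where `h10` and `h90` are the input
#' rates producing 10% and 90% of the maximal firing rate `F_max`.
#' `F_max` is the maximum of the sampled curve; `h10`/`h90` are located by
#' linear interpolation of `F` against `log10(h)` at the first upward
#' crossing. When a threshold is not bracketed by the grid the affected
#' bound is reported in `out_of_grid` and `delta` is `NA`.
#'
#' @param curve a [response_curve()], or any data frame with columns `h`
#'   (positive, strictly increasing) and `F`.
#' @return An object of class `dynamic_range`: list with `F_max`, `F10`,
#'   `F90`, `h10`, `h90`, `delta` and `out_of_grid` (character vector,
#'   empty when both bounds were bracketed).
#' @export
dynamic_range <- function(curve) {
  h <- curve$h; F <- curve$F
  if (length(h) < 2L) stop("dynamic range needs a curve with >= 2 points")
  if (any(h <= 0)) stop("h grid must be positive (log scale)")
  if (max(F) <= 0) stop("dynamic range undefined: response curve is identically zero")
  F_max <- max(F)
  cross <- function(Fx) {
    j <- which(F >= Fx)[1L]
    if (is.na(j)) return(NA_real_)      # never reached (cannot happen for Fx <= F_max)
    if (j == 1L) {
      if (F[1L] == Fx) return(h[1L])
      return(NA_real_)                  # already above threshold at the grid start
    }
    lg <- log10(h)
    10^(lg[j - 1L] + (Fx - F[j - 1L]) / (F[j] - F[j - 1L]) * (lg[j] - lg[j - 1L]))
  }
  F10 <- 0.1 * F_max; F90 <- 0.9 * F_max
  h10 <- cross(F10); h90 <- cross(F90)
  oog <- c(if (is.na(h10)) "h10", if (is.na(h90)) "h90")
  delta <- if (length(oog)) NA_real_ else 10 * log10(h90 / h10)
  structure(list(F_max = F_max, F10 = F10, F90 = F90,
                 h10 = h10, h90 = h90, delta = delta,
                 out_of_grid = if (length(oog)) oog else character(0)),
            class = "dynamic_range")
}

#' @export
print.dynamic_range <- function(x, ...) {
  cat(sprintf("<dynamic_range: delta = %.3f (F_max = %.2f Hz, h10 = %.4g, h90 = %.4g)>\n",
              x$delta, x$F_max, x$h10, x$h90))
  if (length(x$out_of_grid))
    cat("  out of grid:", paste(x$out_of_grid, collapse = ", "), "\n")
  invisible(x)
}

#' Energy consumption of a simulation
#'
#' Total energy consumption `E` is the number of dendritic spikes per
#' somatic spike, `E = sum(S_i, i = 1..N) / S_0`; relative energy
#' consumption divides by the number of dendritic compartments,
#' `E_rel = E / N`. `E_rel < 1` marks the energy-efficient regime (the
#' dendritic tree amplifies somatic output); `E_rel > 1` the inefficient
#' one. When the soma never fired (`S_0 = 0`) both measures are undefined
#' and returned as `NA` with `defined = FALSE`, never as infinities.
#'
#' @param counts a `spike_counts` from [simulate_dynamics()] (soma first).
#' @return An object of class `energy_result`: list with `E`, `E_rel`, `N`,
#'   `S0`, `defined`.
#' @export
energy <- function(counts) {
  stopifnot(inherits(counts, "spike_counts"))
  S0 <- counts$S[[1L]]
  N <- length(counts$S) - 1L
  dend <- sum(counts$S[-1L])
  if (S0 == 0) {
    return(structure(list(E = NA_real_, E_rel = NA_real_, N = N, S0 = S0,
                          defined = FALSE), class = "energy_result"))
  }
  E <- dend / S0
  E_rel <- if (N > 0L) E / N else NA_real_
  structure(list(E = E, E_rel = E_rel, N = N, S0 = S0, defined = TRUE),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  if (!x$defined) {
    cat("<energy_result: undefined (soma never fired)>\n")
  } else {
    cat(sprintf("<energy_result: E = %.3f, E_rel = %.4f over N = %d dendritic compartments>\n",
                x$E, x$E_rel, x$N))
  }
  invisible(x)
}

#' Sweep the (P, h) parameter grid
#'
#' Runs one simulation per grid cell and collects the soma rate and energy
#' measures in long format. Per-cell seeds are derived from `master_seed`
#' with [cell_seed()], so any single cell can be reproduced from its row.
#'
#' @param m a collapsed, axon-stripped [morphology].
#' @param P_values vector of propagation probabilities.
#' @param h_values strictly increasing vector of input rates (Hz).
#' @param n_steps counted steps per cell.
#' @param master_seed integer master seed.
#' @param iteration pruning-iteration index recorded in the output (also
#'   folded into the per-cell seeds), default 0.
#' @param ... further arguments for [dynamics_params()].
#' @return A data frame with one row per cell: `iteration`, `P`, `h`,
#'   `seed`, `soma_rate` (Hz), `E`, `E_rel`, `defined`.
#' @export
sweep_grid <- function(m, P_values, h_values, n_steps, master_seed,
                       iteration = 0L, ...) {
  if (is.unsorted(h_values, strictly = TRUE))
    stop("h_values must be strictly increasing")
  rows <- vector("list", length(P_values) * length(h_values))
  k <- 0L
  for (pi in seq_along(P_values)) {
    for (hi in seq_along(h_values)) {
      k <- k + 1L
      seed <- cell_seed(master_seed, iteration, pi, hi)
      params <- dynamics_params(P = P_values[pi], h = h_values[hi],
                                n_steps = n_steps, seed = seed, ...)
      counts <- simulate_dynamics(m, params)
      en <- energy(counts)
      rows[[k]] <- data.frame(
        iteration = iteration, P = P_values[pi], h = h_values[hi],
        seed = seed,
        soma_rate = firing_rate(counts)[[1L]],
        E = en$E, E_rel = en$E_rel, defined = en$defined
      )
    }
  }
  do.call(rbind, rows)
}

#' Default parameter grid
#'
#' The grid the sweeps average over: `P` from 0.5 to 1 (propagation below
#' 0.5 is not considered — signals die out too quickly to sustain
#' dendritic activity) and `h` log-spaced over five decades,
#' `1e-2` to `1e3` Hz.
#'
#' @param n_P number of `P` values (default 11: step 0.05).
#' @param n_h number of `h` values (default 51: 10 per decade).
#' @return list with components `P` and `h`.
#' @export
default_grid <- function(n_P = 11L, n_h = 51L) {
  list(P = seq(0.5, 1, length.out = n_P),
       h = 10^seq(-2, 3, length.out = n_h))
}

#' Parameter-space mean of an energy measure
#'
#' Unweighted arithmetic mean of `E` or `E_rel` over all (P, h) cells of a
#' sweep where the measure is defined; cells in which the soma never fired
#' are excluded and their count is reported in the `n_undefined` attribute.
#'
#' @param sweep either a sweep data frame from [sweep_grid()] or a
#'   [morphology] (in which case a sweep is run first).
#' @param quantity `"E"` or `"E_rel"`.
#' @param P_values,h_values,n_steps,master_seed,... used only when `sweep`
#'   is a morphology; defaults from [default_grid()].
#' @return the mean (numeric scalar) with attribute `n_undefined`.
#' @export
parameter_space_mean <- function(sweep, quantity = c("E", "E_rel"),
                                 P_values = default_grid()$P,
                                 h_values = default_grid()$h,
                                 n_steps = NULL, master_seed = NULL, ...) {
  quantity <- match.arg(quantity)
  if (inherits(sweep, "morphology")) {
    if (is.null(n_steps) || is.null(master_seed))
      stop("n_steps and master_seed are required when sweeping a morphology")
    sweep <- sweep_grid(sweep, P_values, h_values, n_steps, master_seed, ...)
  }
  vals <- sweep[[quantity]]
  ok <- sweep$defined & !is.na(vals)
  if (!any(ok)) stop("parameter-space mean undefined: the soma fired in no cell")
  structure(mean(vals[ok]), n_undefined = sum(!ok))
}

#' Branch-centrality functional classification
#'
#' Classifies a neuron's expected energy behaviour from two topological
#' features: the number of dendritic branches connected to the soma and the
#' soma centrality. Single-stem neurons are Type 2 (mixed
#' efficient/inefficient); bitufted neurons (two stems) are the
#' transitional Type T; with three or more stems the split between
#' energy-efficient Type 1 and inefficient Type 3 falls at a centrality
#' threshold, 0.3 by default (relative energy consumption crosses 1 only
#' below centrality ~0.3).
#'
#' @param n_somatic_branches integer number of dendritic stems at the soma.
#' @param soma_centrality centrality in \[0, 1\].
#' @param threshold Type 1 / Type 3 centrality boundary (default 0.3).
#' @return one of `"Type 1"`, `"Type 2"`, `"Type 3"`, `"Type T"`.
#' @export
classify_neuron <- function(n_somatic_branches, soma_centrality,
                            threshold = 0.3) {
  stopifnot(length(n_somatic_branches) == 1L, length(soma_centrality) == 1L)
  if (n_somatic_branches == 1L) return("Type 2")
  if (n_somatic_branches == 2L) return("Type T")
  if (soma_centrality >= threshold) "Type 1" else "Type 3"
}

#' Dynamic range from sweep rows at fixed P
#'
#' Convenience: extracts the soma response curve at one `P` from a sweep
#' data frame and applies [dynamic_range()].
#'
#' @param sweep a data frame from [sweep_grid()].
#' @param P the propagation probability to select (matched within 1e-9).
#' @return a [dynamic_range()] result.
#' @export
delta_from_sweep <- function(sweep, P) {
  rows <- sweep[abs(sweep$P - P) < 1e-9, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no sweep rows at P = ", P)
  rows <- rows[order(rows$h), , drop = FALSE]
  dynamic_range(data.frame(h = rows$h, F = rows$soma_rate))
}

#' @rdname response_curve
#' @param x a `response_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.response_curve <- function(x, ...) {
  graphics::plot(x$h, x$F, log = "x", type = "b", pch = 16,
                 xlab = "input rate h (Hz)", ylab = "firing rate F (Hz)", ...)
  invisible(x)
}
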