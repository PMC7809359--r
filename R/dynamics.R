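#' Parameters of the excitable compartment dynamics
#'
#' Each compartment is a three-stage excitable unit updated synchronously:
#' susceptible compartments can be activated by an active tree neighbour
#' (probability `P` per active neighbour, independent attempts) or by
#' external synaptic drive with rate `h` (per-step probability
#' `r = 1 - exp(-h * dt)`); an active compartment is refractory for
#' `refractory_steps` steps afterwards and becomes susceptible again one
#' step later, so the minimum inter-spike interval is
#' `refractory_steps + 2` steps and the maximal attainable rate is
#' `1 / ((refractory_steps + 2) * dt)` (111.1 Hz at the defaults).
#'
#' @param P propagation probability, in \[0, 1\].
#' @param h external input rate in Hz, >= 0.
#' @param n_steps number of counted simulation steps (>= 1).
#' @param seed integer seed; identical (morphology, params) pairs reproduce
#'   identical spike counts.
#' @param dt time resolution in seconds (default 0.001).
#' @param refractory_steps length of the refractory stage in steps
#'   (default 7).
#' @param drive_soma should the external drive also reach the soma
#'   (default `TRUE`)? With `FALSE` only dendritic compartments receive
#'   external input.
#' @param transient_steps steps to run and discard before counting
#'   (default 0).
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(P, h, n_steps, seed,
                            dt = 0.001, refractory_steps = 7L,
                            drive_soma = TRUE, transient_steps = 0L) {
  if (!is.numeric(P) || length(P) != 1L || P < 0 || P > 1)
    stop("P must be a probability in [0, 1]")
  if (!is.numeric(h) || length(h) != 1L || h < 0)
    stop("h must be a non-negative rate (Hz)")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("n_steps must be >= 1")
  refractory_steps <- as.integer(refractory_steps)
  if (is.na(refractory_steps) || refractory_steps < 0L)
    stop("refractory_steps must be >= 0")
  transient_steps <- as.integer(transient_steps)
  if (is.na(transient_steps) || transient_steps < 0L)
    stop("transient_steps must be >= 0")
  structure(list(P = P, h = h, dt = dt,
                 refractory_steps = refractory_steps,
                 n_steps = n_steps, seed = as.integer(seed),
                 drive_soma = isTRUE(drive_soma),
                 transient_steps = transient_steps),
            class = "dynamics_params")
}

#' Per-step external activation probability
#'
#' Probability that the stochastic synaptic drive of rate `h` activates a
#' susceptible compartment within one step of length `dt`:
#' `r = 1 - exp(-h * dt)`.
#'
#' @param h external input rate in Hz, >= 0.
#' @param dt time resolution in seconds.
#' @return a probability in \[0, 1).
#' @export
external_activation_prob <- function(h, dt) {
  if (any(h < 0)) stop("h must be non-negative")
  if (any(dt <= 0)) stop("dt must be positive")
  1 - exp(-h * dt)
}

#' Simulate the excitable dynamics on a morphology
#'
#' Runs the synchronous cellular automaton from an all-susceptible initial
#' condition for `transient_steps + n_steps` steps, tallying per-compartment
#' activations over the counted steps. The soma is always the first entry of
#' the returned counts (compartment 0 of the energy equations).
#'
#' @param m a collapsed, axon-stripped [morphology].
#' @param params a [dynamics_params].
#' @param occupancy also tally how often each compartment occupied each
#'   automaton state (used for distributional checks).
#' @return An object of class `spike_counts`: list with `S` (named numeric
#'   vector of activation counts, soma first), `n_counted_steps`, `dt`,
#'   `soma_id`, `params` and optionally `occupancy` (a
#'   `(refractory_steps + 2) x n` matrix; row 1 = susceptible, last row =
#'   active, middle rows = refractory countdown).
#' @export
simulate_dynamics <- function(m, params, occupancy = FALSE) {
  stopifnot(inherits(params, "dynamics_params"))
  nodes <- m$nodes
  n <- nrow(nodes)
  s <- .soma_pos(m)
  ord <- c(s, setdiff(seq_len(n), s))   # soma first
  ids <- nodes$id[ord]
  pos <- match(nodes$id, ids)           # old position -> new position

  # CSR adjacency over the reordered compartments
  pidx <- match(nodes$parent, nodes$id)
  e_from <- pos[which(!is.na(pidx))]
  e_to <- pos[pidx[!is.na(pidx)]]
  deg <- tabulate(c(e_from, e_to), nbins = n)
  ptr <- c(0L, cumsum(deg))
  adj <- integer(2L * length(e_from))
  fill <- ptr[-length(ptr)]
  for (k in seq_along(e_from)) {
    a <- e_from[k]; b <- e_to[k]
    fill[a] <- fill[a] + 1L; adj[fill[a]] <- b - 1L
    fill[b] <- fill[b] + 1L; adj[fill[b]] <- a - 1L
  }

  driven <- rep(1L, n)
  if (!params$drive_soma) driven[1L] <- 0L
  r <- external_activation_prob(params$h, params$dt)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(params$seed)
  res <- ca_simulate_core(adj, ptr, n, params$P, r, driven,
                          params$refractory_steps, params$n_steps,
                          params$transient_steps, occupancy)
  S <- res$spikes
  names(S) <- ids
  out <- list(S = S, n_counted_steps = res$n_counted_steps,
              dt = params$dt, soma_id = nodes$id[s], params = params)
  if (occupancy) out$occupancy <- res$occupancy
  structure(out, class = "spike_counts")
}

#' Firing rate of compartments
#'
#' Converts activation counts into rates: `S_i / (n_counted_steps * dt)`.
#'
#' @param counts a `spike_counts` object from [simulate_dynamics()].
#' @param id compartment id(s); default: all compartments, soma first.
#' @param dt time resolution; defaults to the one the simulation used.
#' @return rate(s) in Hz, named by compartment id.
#' @export
firing_rate <- function(counts, id = NULL, dt = counts$dt) {
  stopifnot(inherits(counts, "spike_counts"))
  rates <- counts$S / (counts$n_counted_steps * dt)
  if (is.null(id)) return(rates)
  pos <- match(as.character(as.integer(id)), names(rates))
  if (anyNA(pos)) stop("unknown compartment id: ",
                       paste(id[is.na(pos)], collapse = ", "))
  rates[pos]
}

#' @export
print.spike_counts <- function(x, ...) {
  cat(sprintf("<spike_counts: %d compartments, %d counted steps>\n",
              length(x$S), x$n_counted_steps))
  cat(sprintf("  soma (id %d): %d spikes (%.2f Hz); dendritic total: %d\n",
              x$soma_id, as.integer(x$S[1L]),
              x$S[1L] / (x$n_counted_steps * x$dt),
              as.integer(sum(x$S[-1L]))))
  invisible(x)
}
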