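# Independent oracles used to cross-check the implementation.
# These deliberately use different algorithms/libraries than the package:
# igraph shortest paths for tree distances, and exhaustive enumeration of
# the synchronous Markov chain for the dynamics.

# all-pairs eccentricity (distance to farthest childless compartment)
oracle_eccentricities <- function(m) {
  nodes <- m$nodes
  ids <- as.character(nodes$id)
  has_par <- !is.na(nodes$parent)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(nodes$id[has_par]),
                   to = as.character(nodes$parent[has_par])),
    directed = FALSE,
    vertices = data.frame(name = ids))
  d <- igraph::distances(g)
  termini <- ids[!(nodes$id %in% nodes$parent[has_par])]
  ecc <- apply(d[ids, termini, drop = FALSE], 1L, max)
  as.integer(ecc)
}

# iterations to remove every dendritic compartment = tree height from soma
oracle_fully_pruned <- function(m) {
  nodes <- m$nodes
  has_par <- !is.na(nodes$parent)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(nodes$id[has_par]),
                   to = as.character(nodes$parent[has_par])),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id)))
  d <- igraph::distances(g, v = as.character(m$soma_id))
  as.integer(max(d))
}

# exact stationary marginals of the synchronous automaton on a tiny
# morphology (n <= 3 compartments), by enumerating all (refractory+2)^n
# joint states and solving pi = pi T. Rows of the result follow the state
# coding of simulate_dynamics occupancy: row 1 susceptible, rows
# 2..(refractory+1) refractory countdown, last row active. Columns are
# compartments in soma-first order.
oracle_stationary_marginals <- function(m, P, h, dt = 0.001,
                                        refractory = 7L, drive_soma = TRUE) {
  nodes <- m$nodes
  n <- nrow(nodes)
  stopifnot(n <= 3L)
  soma_pos <- match(m$soma_id, nodes$id)
  ord <- c(soma_pos, setdiff(seq_len(n), soma_pos))
  nodes <- nodes[ord, , drop = FALSE]
  pidx <- match(nodes$parent, nodes$id)
  nbrs <- lapply(seq_len(n), function(v) {
    c(pidx[v], which(pidx == v))
  })
  nbrs <- lapply(nbrs, function(x) x[!is.na(x)])

  ns <- refractory + 2L
  active_code <- refractory + 1L
  r <- 1 - exp(-h * dt)
  driven <- rep(TRUE, n)
  if (!drive_soma) driven[1L] <- FALSE

  codes <- as.matrix(expand.grid(rep(list(0:(ns - 1L)), n)))
  nstates <- nrow(codes)
  idx_of <- function(st) sum(st * ns^(seq_len(n) - 1L)) + 1L
  Tm <- matrix(0, nstates, nstates)
  for (si in seq_len(nstates)) {
    s <- codes[si, ]
    opts <- vector("list", n)
    for (i in seq_len(n)) {
      if (s[i] > 0L) {
        opts[[i]] <- list(st = s[i] - 1L, pr = 1)
      } else {
        k <- sum(s[nbrs[[i]]] == active_code)
        rr <- if (driven[i]) r else 0
        p <- 1 - (1 - rr) * (1 - P)^k
        opts[[i]] <- list(st = c(active_code, 0L), pr = c(p, 1 - p))
      }
    }
    choice <- as.matrix(expand.grid(lapply(opts, function(o) seq_along(o$st))))
    for (gi in seq_len(nrow(choice))) {
      st <- integer(n); pr <- 1
      for (i in seq_len(n)) {
        j <- choice[gi, i]
        st[i] <- opts[[i]]$st[j]
        pr <- pr * opts[[i]]$pr[j]
      }
      if (pr > 0) {
        ti <- idx_of(st)
        Tm[si, ti] <- Tm[si, ti] + pr
      }
    }
  }
  # stationary distribution: solve (T' - I) pi = 0 with sum(pi) = 1
  A <- rbind(t(Tm) - diag(nstates), rep(1, nstates))
  b <- c(rep(0, nstates), 1)
  pi_st <- qr.solve(A, b)
  marg <- matrix(0, ns, n)
  for (i in seq_len(n)) for (cc in 0:(ns - 1L))
    marg[cc + 1L, i] <- sum(pi_st[codes[, i] == cc])
  marg
}

# "within 3 standard errors" with a small-sample correction: the normal
# z = 3 two-sided level (0.27%) mapped onto the t distribution of the
# replicate mean
expect_within_3se <- function(estimates, target, label = "") {
  n <- length(estimates)
  se <- stats::sd(estimates) / sqrt(n)
  crit <- stats::qt(1 - 0.0027 / 2, df = n - 1) * se
  expect_true(abs(mean(estimates) - target) < crit + 1e-9,
              info = sprintf("%s: %.4f vs %.4f (crit %.4f)",
                             label, mean(estimates), target, crit))
}

# replicate-based estimate of a simulated quantity and its standard error
replicate_rates <- function(m, P, h, n_steps, n_rep, seed0, ...) {
  vapply(seq_len(n_rep), function(k) {
    p <- dynamics_params(P = P, h = h, n_steps = n_steps, seed = seed0 + k, ...)
    firing_rate(simulate_dynamics(m, p))[[1L]]
  }, numeric(1))
}
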