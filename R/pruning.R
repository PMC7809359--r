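#' One pruning pass: remove all terminal dendritic compartments
#'
#' The aging model removes, in each iteration, every dendritic compartment
#' that has no children (a terminus), all simultaneously. The soma is never
#' removed, even when childless. Applying this repeatedly retracts every
#' branch towards the soma.
#'
#' @param m a collapsed, axon-stripped [morphology].
#' @return The pruned `morphology` (identical ids and labels for surviving
#'   compartments). A soma-only morphology is returned unchanged.
#' @export
prune_once <- function(m) {
  nodes <- m$nodes
  n <- nrow(nodes)
  s <- .soma_pos(m)
  pidx <- match(nodes$parent, nodes$id)
  nchild <- tabulate(pidx[!is.na(pidx)], nbins = n)
  drop <- nchild == 0L
  drop[s] <- FALSE
  if (!any(drop)) return(m)
  morphology(nodes[!drop, , drop = FALSE], soma_id = m$soma_id)
}

#' Full pruning trajectory with landmarks
#'
#' Applies [prune_once()] until no dendritic compartment remains, recording
#' a [morphometrics()] summary at every iteration (iteration 0 is the intact
#' morphology) plus three landmark iterations:
#' \describe{
#'   \item{single_stem_iteration}{first iteration with exactly one somatic
#'     branch (`NA` when the stem count skips from >= 2 straight to 0).}
#'   \item{last_bifurcation_iteration}{first iteration with zero dendritic
#'     bifurcations while at least one dendritic compartment remains.}
#'   \item{fully_pruned_iteration}{first iteration with zero dendritic
#'     compartments.}
#' }
#'
#' @param m a collapsed, axon-stripped [morphology].
#' @return An object of class `prune_trajectory`: list with `per_iteration`
#'   (data frame: iteration, n_compartments, n_compartments_total,
#'   n_bifurcations, n_somatic_branches, soma_centrality) and `landmarks`.
#' @export
prune_trajectory <- function(m) {
  rows <- list()
  it <- 0L
  cur <- m
  repeat {
    mm <- morphometrics(cur)
    rows[[it + 1L]] <- data.frame(
      iteration = it,
      n_compartments = mm$n_compartments,
      n_compartments_total = mm$n_compartments_total,
      n_bifurcations = mm$n_bifurcations,
      n_somatic_branches = mm$n_somatic_branches,
      soma_centrality = mm$soma_centrality
    )
    if (mm$n_compartments == 0L) break
    cur <- prune_once(cur)
    it <- it + 1L
  }
  per <- do.call(rbind, rows)

  first_where <- function(cond) {
    i <- which(cond)
    if (length(i)) per$iteration[i[1L]] else NA_integer_
  }
  landmarks <- list(
    single_stem_iteration = first_where(per$n_somatic_branches == 1L),
    last_bifurcation_iteration = first_where(per$n_bifurcations == 0L &
                                               per$n_compartments >= 1L),
    fully_pruned_iteration = first_where(per$n_compartments == 0L)
  )
  structure(list(per_iteration = per, landmarks = landmarks),
            class = "prune_trajectory")
}

#' Morphology after a given number of pruning passes
#'
#' @param m a collapsed, axon-stripped [morphology].
#' @param iteration number of [prune_once()] passes to apply;
#'   `snapshot_at(m, 0)` is `m` itself.
#' @return The pruned `morphology`.
#' @export
snapshot_at <- function(m, iteration) {
  iteration <- as.integer(iteration)
  if (is.na(iteration) || iteration < 0L)
    stop("iteration must be a non-negative integer")
  cur <- m
  for (k in seq_len(iteration)) {
    if (n_compartments(cur) == 0L)
      stop("iteration ", iteration, " is beyond the fully-pruned iteration (",
           k - 1L, ")")
    cur <- prune_once(cur)
  }
  cur
}

#' @export
print.prune_trajectory <- function(x, ...) {
  lm <- x$landmarks
  cat(sprintf("<prune_trajectory: %d iterations>\n",
              nrow(x$per_iteration) - 1L))
  cat(sprintf("  intact: %d dendritic compartments, %d bifurcations, %d stems\n",
              x$per_iteration$n_compartments[1L],
              x$per_iteration$n_bifurcations[1L],
              x$per_iteration$n_somatic_branches[1L]))
  cat(sprintf("  landmarks: single stem at %s, last bifurcation gone at %s, fully pruned at %s\n",
              lm$single_stem_iteration, lm$last_bifurcation_iteration,
              lm$fully_pruned_iteration))
  invisible(x)
}

#' @rdname prune_trajectory
#' @param x a `prune_trajectory`.
#' @param which panels to draw: any of "compartments", "bifurcations",
#'   "stems", "centrality".
#' @param ... passed to [graphics::plot()].
#' @export
plot.prune_trajectory <- function(x,
                                  which = c("compartments", "bifurcations", "centrality"),
                                  ...) {
  per <- x$per_iteration
  panels <- list(
    compartments = list(per$n_compartments, "compartments"),
    bifurcations = list(per$n_bifurcations, "bifurcations"),
    stems = list(per$n_somatic_branches, "somatic branches"),
    centrality = list(per$soma_centrality, "soma centrality")
  )[which]
  old <- graphics::par(mfrow = c(length(panels), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in panels) {
    graphics::plot(per$iteration, p[[1]], type = "l", xlab = "pruning iteration",
                   ylab = p[[2]], ...)
    lmk <- x$landmarks$single_stem_iteration
    if (!is.na(lmk)) graphics::abline(v = lmk, col = "red", lty = 2)
  }
  invisible(x)
}
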