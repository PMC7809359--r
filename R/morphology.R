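#' Compartmental morphology objects
#'
#' A `morphology` is a rooted tree of compartments, each with an SWC
#' structure label, a 3D position and a radius. It is the common currency of
#' the package: parsers, generators, the pruning algorithm and the dynamics
#' all consume and produce `morphology` objects. Compartment ids are stable:
#' no operation ever renumbers them, so pruned stages can be aligned with
#' the intact reconstruction.
#'
#' @param nodes data frame with columns `id` (positive integer), `parent`
#'   (integer id or `NA` for the root), `type` (SWC structure code: 1 soma,
#'   2 axon, 3 basal dendrite, 4 apical dendrite, other codes kept as
#'   "other"), `x`, `y`, `z` (micrometres) and `radius` (micrometres).
#' @param soma_id id of the unique soma compartment, or `NA` before
#'   [collapse_soma()] has been applied.
#' @param validate check structural invariants (unique ids, resolvable
#'   parents, single root, acyclic and connected).
#' @return An object of class `morphology`.
#' @seealso [read_swc()], [collapse_soma()], [strip_axon()], [morphometrics()]
#' @export
morphology <- function(nodes, soma_id = NA_integer_, validate = TRUE) {
  stopifnot(is.data.frame(nodes))
  required <- c("id", "parent", "type", "x", "y", "z", "radius")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols))
    stop("nodes is missing columns: ", paste(missing_cols, collapse = ", "))
  nodes <- nodes[required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$type <- as.integer(nodes$type)
  rownames(nodes) <- NULL
  m <- structure(list(nodes = nodes, soma_id = as.integer(soma_id)),
                 class = "morphology")
  if (validate) validate_morphology(m)
  m
}

#' @rdname morphology
#' @param m a `morphology`.
#' @export
validate_morphology <- function(m) {
  nodes <- m$nodes
  n <- nrow(nodes)
  if (n == 0L) stop("morphology has no compartments")
  if (anyNA(nodes$id) || any(nodes$id <= 0L))
    stop("compartment ids must be positive integers")
  if (anyDuplicated(nodes$id))
    stop("duplicate compartment id: ",
         nodes$id[duplicated(nodes$id)][1L])
  pidx <- match(nodes$parent, nodes$id)
  bad <- which(!is.na(nodes$parent) & is.na(pidx))
  if (length(bad))
    stop("compartment ", nodes$id[bad[1L]],
         " references nonexistent parent ", nodes$parent[bad[1L]])
  self <- which(!is.na(nodes$parent) & nodes$parent == nodes$id)
  if (length(self))
    stop("compartment ", nodes$id[self[1L]], " lists itself as parent")
  roots <- which(is.na(nodes$parent))
  if (length(roots) == 0L)
    stop("no root compartment (cycle: every compartment has a parent)")
  if (length(roots) > 1L)
    stop("multiple roots (", length(roots), "): morphology is a forest, not a tree")
  # connectivity from the root implies acyclicity for n nodes and n-1 edges
  reached <- .bfs_order(pidx, roots)
  if (length(reached) != n)
    stop("morphology is not connected (", n - length(reached),
         " compartment(s) unreachable from the root, or in a cycle)")
  if (!is.na(m$soma_id) && !(m$soma_id %in% nodes$id))
    stop("soma_id ", m$soma_id, " not present in the morphology")
  invisible(m)
}

# breadth-first order of node positions starting from `roots`, following
# child links derived from the parent-index vector; parents precede children
.bfs_order <- function(parent_idx, roots) {
  n <- length(parent_idx)
  kids <- .children_index(parent_idx, n)
  ord <- integer(n)
  ord[seq_along(roots)] <- roots
  lo <- 1L; hi <- length(roots)
  while (lo <= hi) {
    v <- ord[lo]; lo <- lo + 1L
    ch <- kids[[v]]
    if (length(ch)) {
      ord[(hi + 1L):(hi + length(ch))] <- ch
      hi <- hi + length(ch)
    }
  }
  ord[seq_len(hi)]
}

# list of child positions for each node position
.children_index <- function(parent_idx, n) {
  kids <- rep(list(integer(0)), n)
  has_parent <- which(!is.na(parent_idx))
  if (length(has_parent)) {
    grouped <- split(has_parent, parent_idx[has_parent])
    kids[as.integer(names(grouped))] <- grouped
  }
  kids
}

.root_pos <- function(m) which(is.na(m$nodes$parent))

.soma_pos <- function(m) {
  if (is.na(m$soma_id)) stop("morphology has no designated soma; run collapse_soma() first")
  match(m$soma_id, m$nodes$id)
}

#' Number of compartments
#'
#' @param m a `morphology`.
#' @param include_soma count the soma compartment as well? The dendritic
#'   count (default) is the one used throughout the pruning and energy
#'   analyses, where dendritic compartments are indexed 1..N and the soma is
#'   compartment 0.
#' @return integer count.
#' @export
n_compartments <- function(m, include_soma = FALSE) {
  n <- nrow(m$nodes)
  if (include_soma) return(n)
  if (is.na(m$soma_id)) n else n - 1L
}

#' Collapse a multi-point soma into a single compartment
#'
#' NeuroMorpho reconstructions often describe the soma with several sample
#' points. The dynamics treat the soma as one compartment, so all contiguous
#' soma-labelled points are merged into a single compartment placed at their
#' centroid (mean radius); dendrites that attached to any merged point
#' re-attach to the single soma, and the tree is re-rooted at the soma.
#'
#' @param m a `morphology` with at least one soma-labelled (type 1)
#'   compartment forming a connected subtree.
#' @return A `morphology` with exactly one soma compartment, which is the
#'   root; its id is the id of the soma point that headed the soma subtree.
#' @export
collapse_soma <- function(m) {
  nodes <- m$nodes
  soma <- which(nodes$type == 1L)
  if (length(soma) == 0L)
    stop("no soma-labelled compartment; designate a root by labelling one point type 1")
  soma_ids <- nodes$id[soma]
  # the soma subtree head: the unique soma point whose parent is not a soma point
  head_flag <- is.na(nodes$parent[soma]) | !(nodes$parent[soma] %in% soma_ids)
  if (sum(head_flag) != 1L)
    stop("soma-labelled compartments do not form a single connected subtree")
  keep_id <- soma_ids[head_flag]

  if (length(soma) > 1L) {
    centroid <- c(mean(nodes$x[soma]), mean(nodes$y[soma]), mean(nodes$z[soma]))
    mrad <- mean(nodes$radius[soma])
    drop_ids <- setdiff(soma_ids, keep_id)
    reparent <- nodes$parent %in% drop_ids
    nodes$parent[reparent] <- keep_id
    nodes <- nodes[!(nodes$id %in% drop_ids), , drop = FALSE]
    k <- match(keep_id, nodes$id)
    nodes$x[k] <- centroid[1]; nodes$y[k] <- centroid[2]; nodes$z[k] <- centroid[3]
    nodes$radius[k] <- mrad
  }
  nodes <- .reroot(nodes, keep_id)
  morphology(nodes, soma_id = keep_id)
}

# re-orient all parent pointers so that `root_id` is the root
.reroot <- function(nodes, root_id) {
  n <- nrow(nodes)
  idx <- match(nodes$id, nodes$id)  # identity, for clarity
  pidx <- match(nodes$parent, nodes$id)
  # undirected adjacency
  adj <- rep(list(integer(0)), n)
  for (v in which(!is.na(pidx))) {
    p <- pidx[v]
    adj[[v]] <- c(adj[[v]], p)
    adj[[p]] <- c(adj[[p]], v)
  }
  r <- match(root_id, nodes$id)
  newpar <- rep(NA_integer_, n)
  visited <- logical(n); visited[r] <- TRUE
  queue <- r
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!visited[w]) {
      visited[w] <- TRUE
      newpar[w] <- v
      queue <- c(queue, w)
    }
  }
  nodes$parent <- ifelse(is.na(newpar), NA_integer_, nodes$id[newpar])
  nodes$parent <- as.integer(nodes$parent)
  nodes
}

#' Remove axon-labelled compartments
#'
#' The model simulates dendrites and soma only; axonal sample points (SWC
#' type 2) and everything attached below them are discarded. A morphology
#' without axon points is returned unchanged.
#'
#' @param m a collapsed `morphology`.
#' @return A `morphology` without axon compartments.
#' @export
strip_axon <- function(m) {
  nodes <- m$nodes
  pidx <- match(nodes$parent, nodes$id)
  drop <- nodes$type == 2L
  if (!any(drop)) return(m)
  ord <- .bfs_order(pidx, .root_pos(m))
  for (v in ord) {           # parents first: descendants inherit the flag
    p <- pidx[v]
    if (!is.na(p) && drop[p]) drop[v] <- TRUE
  }
  morphology(nodes[!drop, , drop = FALSE], soma_id = m$soma_id)
}

#' Eccentricity of compartments
#'
#' The eccentricity of a compartment is the number of edges on the tree path
#' to its farthest terminal compartment (a compartment with no children). It
#' is the distance measure underlying soma centrality. `eccentricity()`
#' returns one value; `eccentricities()` returns the full vector (named by
#' compartment id), computed in O(n) by a two-pass dynamic program over the
#' rooted tree (down-pass: farthest terminus within the subtree; up-pass:
#' farthest terminus through the parent).
#'
#' @param m a `morphology`.
#' @param id compartment id.
#' @return `eccentricity()`: an integer; `eccentricities()`: a named integer
#'   vector.
#' @export
eccentricity <- function(m, id) {
  ecc <- eccentricities(m)
  pos <- match(as.integer(id), m$nodes$id)
  if (is.na(pos)) stop("unknown compartment id: ", id)
  ecc[[pos]]
}

#' @rdname eccentricity
#' @export
eccentricities <- function(m) {
  nodes <- m$nodes
  n <- nrow(nodes)
  pidx <- match(nodes$parent, nodes$id)
  kids <- .children_index(pidx, n)
  ord <- .bfs_order(pidx, .root_pos(m))

  down <- numeric(n)            # farthest terminus within the subtree
  for (v in rev(ord)) {
    ch <- kids[[v]]
    down[v] <- if (length(ch)) 1 + max(down[ch]) else 0
  }
  up <- rep(-Inf, n)            # farthest terminus outside the subtree
  for (v in ord) {
    ch <- kids[[v]]
    if (length(ch) == 0L) next
    dch <- 1 + down[ch]
    # top-two of the child contributions, for sibling exclusion
    o <- order(dch, decreasing = TRUE)
    best1 <- dch[o[1L]]
    best2 <- if (length(ch) > 1L) dch[o[2L]] else -Inf
    for (j in seq_along(ch)) {
      sib <- if (dch[j] == best1 && j == o[1L]) best2 else best1
      up[ch[j]] <- 1 + max(up[v], sib)
    }
  }
  ecc <- as.integer(pmax(down, up))
  names(ecc) <- nodes$id
  ecc
}

#' Soma centrality
#'
#' Min-max normalisation of the soma's eccentricity against all compartments
#' of the tree: `(ecc_max - ecc_soma) / (ecc_max - ecc_min)`. The most
#' central compartment(s) — shortest distance to their farthest terminus —
#' score 1; the least central score 0. A morphology in which all
#' compartments are equally eccentric (e.g. a lone soma) scores 1 by
#' convention.
#'
#' @param m a collapsed `morphology`.
#' @return a number in \[0, 1\].
#' @export
soma_centrality <- function(m) {
  ecc <- eccentricities(m)
  s <- .soma_pos(m)
  lo <- min(ecc); hi <- max(ecc)
  if (hi == lo) return(1)
  (hi - ecc[[s]]) / (hi - lo)
}

#' Morphometric summary
#'
#' Counts and centrality of a collapsed, axon-stripped morphology:
#' number of dendritic compartments (soma excluded; `n_compartments_total`
#' includes it), number of dendritic bifurcations (dendritic compartments
#' with two or more children), number of somatic branches (dendritic
#' children of the soma) and soma centrality.
#'
#' @param m a collapsed, axon-stripped `morphology`.
#' @return An object of class `morphometric_summary` (a one-row list).
#' @export
morphometrics <- function(m) {
  nodes <- m$nodes
  n <- nrow(nodes)
  s <- .soma_pos(m)
  pidx <- match(nodes$parent, nodes$id)
  nchild <- tabulate(pidx[!is.na(pidx)], nbins = n)
  dend <- setdiff(seq_len(n), s)
  structure(list(
    n_compartments = length(dend),
    n_compartments_total = n,
    n_bifurcations = sum(nchild[dend] >= 2L),
    n_somatic_branches = nchild[s],
    soma_centrality = soma_centrality(m)
  ), class = "morphometric_summary")
}

#' @rdname morphometrics
#' @param object a `morphology`.
#' @param ... unused.
#' @export
summary.morphology <- function(object, ...) morphometrics(object)

#' @export
print.morphometric_summary <- function(x, ...) {
  cat("Morphometric summary\n")
  cat(sprintf("  dendritic compartments: %d (with soma: %d)\n",
              x$n_compartments, x$n_compartments_total))
  cat(sprintf("  bifurcations:           %d\n", x$n_bifurcations))
  cat(sprintf("  somatic branches:       %d\n", x$n_somatic_branches))
  cat(sprintf("  soma centrality:        %.3f\n", x$soma_centrality))
  invisible(x)
}

#' @export
print.morphology <- function(x, ...) {
  n <- nrow(x$nodes)
  types <- table(factor(x$nodes$type, levels = 1:4,
                        labels = c("soma", "axon", "basal", "apical")))
  cat(sprintf("<morphology: %d compartments%s>\n", n,
              if (!is.na(x$soma_id)) sprintf(", soma id %d", x$soma_id) else ""))
  cat("  ", paste(sprintf("%s: %d", names(types), as.integer(types)),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}
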