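#' Read an SWC reconstruction
#'
#' Parses the standardized SWC dialect used by NeuroMorpho.org: seven
#' whitespace-separated columns (sample id, structure type, x, y, z, radius,
#' parent id), `#` comment lines, parent `-1` for the root. One sample point
#' becomes one compartment; no resampling or merging of unbranched runs is
#' performed, and multi-point somas are kept as read (collapse them with
#' [collapse_soma()]).
#'
#' @param path path to an SWC file.
#' @return A [morphology] (soma not yet designated).
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineno <- which(keep)
  dat <- raw[keep]
  if (length(dat) == 0L) stop("SWC file has no data lines: ", path)

  fields <- strsplit(trimws(dat), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    i <- which(nf != 7L)[1L]
    stop(sprintf("SWC parse error at line %d of %s: expected 7 fields, found %d",
                 lineno[i], path, nf[i]))
  }
  mat <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(mat)) {
    i <- which(apply(is.na(mat), 1L, any))[1L]
    stop(sprintf("SWC parse error at line %d of %s: non-numeric field",
                 lineno[i], path))
  }
  nodes <- data.frame(
    id = as.integer(mat[, 1L]),
    parent = ifelse(mat[, 7L] < 0, NA_integer_, as.integer(mat[, 7L])),
    type = as.integer(mat[, 2L]),
    x = mat[, 3L], y = mat[, 4L], z = mat[, 5L],
    radius = mat[, 6L]
  )
  nodes$parent <- as.integer(nodes$parent)
  morphology(nodes, soma_id = NA_integer_)
}

#' Write a morphology as SWC
#'
#' Emits a valid 7-column SWC file preserving compartment ids, labels,
#' topology and geometry, so that `read_swc(write_swc(m))` round-trips
#' exactly. Rows are written parents-before-children.
#'
#' @param m a [morphology].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  nodes <- m$nodes
  pidx <- match(nodes$parent, nodes$id)
  ord <- .bfs_order(pidx, which(is.na(nodes$parent)))
  nodes <- nodes[ord, , drop = FALSE]
  lines <- sprintf("%d %d %s %s %s %s %d",
                   nodes$id, nodes$type,
                   formatC(nodes$x, format = "g", digits = 10),
                   formatC(nodes$y, format = "g", digits = 10),
                   formatC(nodes$z, format = "g", digits = 10),
                   formatC(nodes$radius, format = "g", digits = 10),
                   ifelse(is.na(nodes$parent), -1L, nodes$parent))
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}
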