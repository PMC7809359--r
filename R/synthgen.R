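# Synthetic morphology generators. Geometry is decorative throughout: the
# dynamics and all morphometrics are purely topological, so segments get
# unit lengths and unit radii along convenient axes.

# run code under a temporary RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# incremental node-table builder: soma is id 1 at the origin
.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$id <- 1L; env$parent <- NA_integer_; env$type <- 1L
  env$x <- 0; env$y <- 0; env$z <- 0; env$radius <- 1
  env$next_id <- 2L
  env
}

# append a chain of `len` compartments below `from`; returns the node ids
.add_chain <- function(b, from, len, type = 3L, dir = c(1, 0, 0)) {
  if (len <= 0L) return(integer(0))
  ids <- seq.int(b$next_id, length.out = len)
  b$next_id <- b$next_id + len
  at <- match(from, b$id)
  base <- c(b$x[at], b$y[at], b$z[at])
  k <- seq_len(len)
  b$id <- c(b$id, ids)
  b$parent <- c(b$parent, c(from, ids[-len]))
  b$type <- c(b$type, rep(as.integer(type), len))
  b$x <- c(b$x, base[1] + dir[1] * k)
  b$y <- c(b$y, base[2] + dir[2] * k)
  b$z <- c(b$z, base[3] + dir[3] * k)
  b$radius <- c(b$radius, rep(1, len))
  ids
}

.build <- function(b) {
  morphology(data.frame(id = b$id, parent = b$parent, type = b$type,
                        x = b$x, y = b$y, z = b$z, radius = b$radius),
             soma_id = 1L)
}

#' Synthetic chain morphology
#'
#' A soma plus a path of `n` dendritic compartments — the minimal
#' one-dimensional network of coupled excitable units. With the soma at the
#' `"center"`, `n` is split into two arms as evenly as possible.
#'
#' @param n number of dendritic compartments (>= 0).
#' @param soma `"end"` (default) or `"center"`.
#' @return a [morphology].
#' @export
make_chain <- function(n, soma = c("end", "center")) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  soma <- match.arg(soma)
  b <- .new_builder()
  if (soma == "end") {
    .add_chain(b, 1L, n)
  } else {
    .add_chain(b, 1L, n %/% 2L + n %% 2L, dir = c(1, 0, 0))
    .add_chain(b, 1L, n %/% 2L, dir = c(-1, 0, 0))
  }
  .build(b)
}

#' Synthetic star morphology
#'
#' A soma at the center of `arms` straight dendritic arms of `arm_length`
#' compartments each. By symmetry the soma is the most central compartment.
#'
#' @param arms number of arms (>= 1).
#' @param arm_length compartments per arm (>= 1).
#' @return a [morphology].
#' @export
make_star <- function(arms, arm_length) {
  arms <- as.integer(arms); arm_length <- as.integer(arm_length)
  if (is.na(arms) || arms < 1L) stop("arms must be >= 1")
  if (is.na(arm_length) || arm_length < 1L) stop("arm_length must be >= 1")
  b <- .new_builder()
  for (a in seq_len(arms)) {
    th <- 2 * pi * (a - 1) / arms
    .add_chain(b, 1L, arm_length, dir = c(cos(th), sin(th), 0))
  }
  .build(b)
}

#' Synthetic Cayley-tree morphology
#'
#' Regular tree in which the soma and every internal compartment have
#' exactly `branching` children, down to `depth` levels: the idealized
#' dendritic topology of the theoretical excitable-tree literature. Total
#' dendritic compartments: `branching * (branching^depth - 1) / (branching - 1)`.
#'
#' @param branching children per internal compartment (>= 2).
#' @param depth number of levels below the soma (>= 1).
#' @return a [morphology].
#' @export
make_cayley <- function(branching, depth) {
  branching <- as.integer(branching); depth <- as.integer(depth)
  if (is.na(branching) || branching < 2L) stop("branching must be >= 2")
  if (is.na(depth) || depth < 1L) stop("depth must be >= 1")
  b <- .new_builder()
  frontier <- 1L
  for (lev in seq_len(depth)) {
    newfrontier <- integer(0)
    for (f in seq_along(frontier)) {
      for (cidx in seq_len(branching)) {
        id <- .add_chain(b, frontier[f], 1L,
                         dir = c(1, (f - 1) * branching + cidx, 0))
        newfrontier <- c(newfrontier, id)
      }
    }
    frontier <- newfrontier
  }
  .build(b)
}

#' Random recursive attachment tree
#'
#' Grows `n` dendritic compartments one at a time, attaching each to a
#' uniformly random existing compartment (soma included). Reproducible
#' given `seed`; used as the property-test fixture family.
#'
#' @param n number of dendritic compartments (>= 1).
#' @param seed integer seed.
#' @return a [morphology].
#' @export
make_random_tree <- function(n, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  .with_seed(seed, {
    parent <- integer(n)
    for (i in seq_len(n)) parent[i] <- sample.int(i, 1L)  # among ids 1..i
    morphology(data.frame(id = seq_len(n + 1L),
                          parent = c(NA_integer_, parent),
                          type = c(1L, rep(3L, n)),
                          x = c(0, seq_len(n)), y = 0, z = 0, radius = 1),
               soma_id = 1L)
  })
}

#' Synthetic pyramidal-like morphology (stand-in reconstruction)
#'
#' Generates a synthetic morphology with the gross topology of a human
#' pyramidal cell: several short, branched basal stems plus one long apical
#' stem carrying oblique side branches and a terminal tuft bifurcation.
#' This is a synthetic stand-in — it reproduces the qualitative topological
#' features that drive the pruning dynamics (multiple stems, a dominant
#' apical shaft that outlives the basal arbor, bifurcations that persist
#' after the stem count drops to one, intermediate soma centrality), not
#' any particular reconstruction.
#'
#' @param seed integer seed.
#' @param n_basal number of basal stems (default 9; together with the
#'   apical stem: 10 somatic branches).
#' @param basal_height_range min/max height (in compartments) of the basal
#'   stems (default 8–22).
#' @param basal_size target compartments per basal stem (default 45).
#' @param apical_trunk length of the apical shaft below the tuft
#'   bifurcation (default 19).
#' @param tuft_range min/max length of the two tuft branches
#'   (default 22–30).
#' @return a [morphology] with ~600 dendritic compartments.
#' @export
make_synthetic_pyramidal <- function(seed, n_basal = 9L,
                                     basal_height_range = c(8L, 22L),
                                     basal_size = 45L,
                                     apical_trunk = 19L,
                                     tuft_range = c(22L, 30L)) {
  .with_seed(seed, {
    b <- .new_builder()
    heights <- sample(seq(basal_height_range[1], basal_height_range[2]),
                      n_basal, replace = TRUE)
    heights[1L] <- basal_height_range[2]   # at least one stem at max height
    for (s in seq_len(n_basal)) {
      th <- 2 * pi * (s - 0.5) / (n_basal + 1)
      dir <- c(cos(th), -abs(sin(th)), 0)
      trunk <- .add_chain(b, 1L, heights[s], type = 3L, dir = dir)
      size <- heights[s]
      guard <- 0L
      while (size < basal_size && guard < 200L) {
        guard <- guard + 1L
        at <- sample(seq_len(heights[s] - 1L), 1L)      # not the tip
        len <- sample.int(min(4L, heights[s] - at), 1L) # never taller than trunk
        .add_chain(b, trunk[at], len, type = 3L,
                   dir = dir + c(0, 0, stats::runif(1, -1, 1)))
        size <- size + len
      }
    }
    shaft <- .add_chain(b, 1L, apical_trunk, type = 4L, dir = c(0, 1, 0))
    # oblique side branches along the lower shaft
    for (at in seq(2L, apical_trunk - 2L, by = 3L)) {
      len <- sample(3:8, 1L)
      .add_chain(b, shaft[at], len, type = 4L,
                 dir = c(stats::runif(1, -1, 1), 1, stats::runif(1, -1, 1)))
    }
    tufts <- sample(seq(tuft_range[1], tuft_range[2]), 2L, replace = TRUE)
    .add_chain(b, shaft[apical_trunk], tufts[1L], type = 4L, dir = c(0.5, 1, 0))
    .add_chain(b, shaft[apical_trunk], tufts[2L], type = 4L, dir = c(-0.5, 1, 0))
    .build(b)
  })
}

#' Closed-form firing rate of an isolated driven compartment
#'
#' Under the timing convention of the automaton (1 active step,
#' `refractory_steps` refractory steps, 1 forced susceptible step, then a
#' geometric wait with per-step success `r = 1 - exp(-h * dt)`), the mean
#' inter-spike interval of an isolated compartment is
#' `refractory_steps + 1 + 1/r` steps, hence
#' `rate = 1 / ((refractory_steps + 1 + 1/r) * dt)`. At saturating drive
#' this approaches `1 / ((refractory_steps + 2) * dt)` — 111.1 Hz at the
#' defaults. Serves as the independent oracle for soma-only simulations.
#'
#' @param h external input rate(s), Hz.
#' @param dt time resolution (s), default 0.001.
#' @param refractory_steps refractory length, default 7.
#' @return rate(s) in Hz.
#' @export
isolated_rate_oracle <- function(h, dt = 0.001, refractory_steps = 7L) {
  if (any(h < 0)) stop("h must be non-negative")
  r <- 1 - exp(-h * dt)
  ifelse(r == 0, 0, 1 / (((refractory_steps + 1) + 1 / r) * dt))
}
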