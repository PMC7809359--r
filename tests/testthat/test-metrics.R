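test_that("dynamic range formula and interpolation rule are applied exactly", {
  # crossings exactly at grid points: h10 = 1, h90 = 100 -> delta = 20
  cv <- data.frame(h = c(0.1, 1, 10, 100, 1000), F = c(0, 10, 50, 90, 100))
  dr <- dynamic_range(cv)
  expect_equal(dr$F_max, 100)
  expect_equal(dr$h10, 1)
  expect_equal(dr$h90, 100)
  expect_equal(dr$delta, 20)
  expect_length(dr$out_of_grid, 0)

  # hand-computed log-linear interpolation on a decade grid:
  # F_max = 125, F10 = 12.5 crosses between h = 0.1 (F = 0) and 1 (F = 30)
  # at log10 h = -1 + 12.5/30; F90 = 112.5 crosses between 100 (F = 90) and
  # 1000 (F = 120) at log10 h = 2 + 22.5/30
  cv2 <- data.frame(h = 10^(-1:4), F = c(0, 30, 60, 90, 120, 125))
  dr2 <- dynamic_range(cv2)
  expect_equal(dr2$h10, 10^(-1 + 12.5 / 30))
  expect_equal(dr2$h90, 10^(2 + 0.75))
  expect_equal(dr2$delta, 10 * (2.75 - (-1 + 12.5 / 30)))
  expect_equal(dr2$delta, 100 / 3, tolerance = 1e-12)

  # degenerate/invalid curves
  expect_error(dynamic_range(data.frame(h = 1, F = 5)), ">= 2 points")
  expect_error(dynamic_range(data.frame(h = c(1, 10), F = c(0, 0))),
               "identically zero")
  # threshold already exceeded at the grid start: reported, not interpolated
  dro <- dynamic_range(data.frame(h = c(1, 10, 100), F = c(50, 90, 100)))
  expect_true("h10" %in% dro$out_of_grid)
  expect_true(is.na(dro$delta))
})

test_that("dynamic range is stable under h-grid refinement of a smooth curve", {
  f <- function(h) 120 * h / (h + 30)    # saturating response, F(0+) -> 0
  g1 <- 10^seq(-2, 4, by = 0.5)
  g2 <- 10^seq(-2, 4, by = 0.25)
  d1 <- dynamic_range(data.frame(h = g1, F = f(g1)))$delta
  d2 <- dynamic_range(data.frame(h = g2, F = f(g2)))$delta
  expect_true(abs(d1 - d2) < 0.2)
})

test_that("energy equations follow E = sum(S_i)/S_0 and E_rel = E/N", {
  fake <- function(S) structure(list(S = S, n_counted_steps = 100, dt = 0.001,
                                     soma_id = 1L), class = "spike_counts")
  e <- energy(fake(c(10, 5, 15)))
  expect_equal(e$E, 2.0)
  expect_equal(e$E_rel, 1.0)
  expect_true(e$defined)

  # silent dendrites
  e0 <- energy(fake(c(10, 0, 0)))
  expect_equal(e0$E, 0); expect_equal(e0$E_rel, 0)

  # every compartment fires as often as the soma: the efficiency boundary
  eb <- energy(fake(rep(7, 6)))
  expect_equal(eb$E, eb$N)
  expect_equal(eb$E_rel, 1)

  # soma silent: undefined, flagged, finite
  eu <- energy(fake(c(0, 3, 4)))
  expect_false(eu$defined)
  expect_true(is.na(eu$E) && is.na(eu$E_rel))

  # E = N * E_rel identically on simulated counts
  m <- make_random_tree(25, seed = 2)
  p <- dynamics_params(P = 0.8, h = 50, n_steps = 4000, seed = 77)
  es <- energy(simulate_dynamics(m, p))
  expect_equal(es$E, es$N * es$E_rel)
})

test_that("parameter-space means average defined cells and count the rest", {
  sw <- data.frame(iteration = 0, P = c(0.5, 0.5, 1, 1), h = c(1, 2, 1, 2),
                   seed = 1:4, soma_rate = 1,
                   E = c(1, 2, 3, 4), E_rel = c(1, 2, 3, 4) / 10,
                   defined = TRUE)
  expect_equal(as.numeric(parameter_space_mean(sw, "E")), 2.5)
  expect_equal(as.numeric(parameter_space_mean(sw, "E_rel")), 0.25)
  sw$defined[2] <- FALSE; sw$E[2] <- NA
  pm <- parameter_space_mean(sw, "E")
  expect_equal(as.numeric(pm), mean(c(1, 3, 4)))
  expect_equal(attr(pm, "n_undefined"), 1L)
  sw$defined <- FALSE
  expect_error(parameter_space_mean(sw, "E"), "undefined")
  # constant field: mean equals the constant
  swc <- transform(sw, E = 7, defined = TRUE)
  expect_equal(as.numeric(parameter_space_mean(swc, "E")), 7)
})

test_that("branch-centrality classification follows the documented boundaries", {
  expect_equal(classify_neuron(1, 0.9), "Type 2")
  expect_equal(classify_neuron(1, 0.1), "Type 2")
  expect_equal(classify_neuron(2, 0.5), "Type T")
  expect_equal(classify_neuron(8, 0.9), "Type 1")
  expect_equal(classify_neuron(5, 0.1), "Type 3")
  expect_equal(classify_neuron(5, 0.1, threshold = 0.05), "Type 1")
})

test_that("response curves: quiescent grid, closed-form match, saturating shape", {
  solo <- make_chain(0)
  rc0 <- response_curve(solo, P = 0.5, h_grid = 0, n_steps = 500,
                        master_seed = 1)
  expect_equal(rc0$F, 0)
  expect_error(response_curve(solo, 0.5, numeric(0), 100, 1), "non-empty")
  expect_error(response_curve(solo, 0.5, c(1, 1), 100, 1), "strictly increasing")

  # isolated-compartment response matches the renewal closed form pointwise
  hs <- c(20, 200, 2000)
  for (h in hs) {
    rates <- replicate_rates(solo, P = 0.5, h = h, n_steps = 10000,
                             n_rep = 24, seed0 = 40 + h,
                             transient_steps = 1000)
    expect_within_3se(rates, isolated_rate_oracle(h), paste("h =", h))
  }

  # a branched tree yields a saturating monotone response curve
  m <- make_cayley(2, 4)
  rc <- response_curve(m, P = 0.9, h_grid = 10^seq(-1, 3, by = 1),
                       n_steps = 6000, master_seed = 3)
  expect_true(all(diff(rc$F) >= 0))
  expect_true(max(rc$F) <= 1 / (9 * 0.001) + 1e-9)
  dr <- dynamic_range(rc)
  expect_true(dr$delta > 0)
})

test_that("delta_from_sweep recovers the per-P soma response curve", {
  m <- make_chain(4)
  sw <- sweep_grid(m, P_values = c(0.6, 0.9), h_values = 10^seq(-1, 3, by = 1),
                   n_steps = 4000, master_seed = 5)
  expect_equal(nrow(sw), 10L)
  d <- delta_from_sweep(sw, 0.9)
  expect_s3_class(d, "dynamic_range")
  expect_error(delta_from_sweep(sw, 0.7), "no sweep rows")
})
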