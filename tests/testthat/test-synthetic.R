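test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(q1 = 0.7, q2 = 0.7), "q1 \\+ q2")
  expect_error(sim_params(p_oblique = 0.9, p_terminate = 0.3), "p_oblique")
  expect_error(sim_params(growth_factor = 0.9), "growth_factor")
  expect_error(sim_params(p_trichome = 1.5), "probability")
  expect_error(sim_params(meristem_fraction = 0), "meristem_fraction")
})

test_that("zero windows yield a single spore and no events", {
  s <- simulate_gametophyte(sim_params(n_windows = 0))
  expect_length(s$snapshots, 1)
  expect_length(s$snapshots[[1]]$cells, 1)
  expect_equal(s$snapshots[[1]]$cells[[1]]$role, "spore")
  expect_equal(nrow(s$events), 0)
  expect_equal(nrow(s$lineage), 0)
})

test_that("a forced oblique self-renewal produces the wedge grammar", {
  s <- simulate_gametophyte(sim_params(n_windows = 1, p_oblique = 1,
                                       p_terminate = 0, q1 = 0, q2 = 0,
                                       q3 = 0, q4 = 0, p_trichome = 0))
  expect_equal(nrow(s$events), 1)
  expect_equal(s$events$orientation, "oblique")
  expect_equal(s$events$wall_angle, 45)
  roles <- vapply(s$snapshots[[2]]$cells, `[[`, character(1), "role")
  expect_setequal(roles, c("apical_initial", "derivative"))
})

test_that("the default six-window run proliferates consistently with its log", {
  s <- simulate_gametophyte(sim_params())
  counts <- vapply(s$snapshots, function(sn) length(sn$cells), integer(1))
  ev_per_window <- tabulate(s$events$window, nbins = 6)
  # each division replaces one cell with two, so the emitted event log fully
  # accounts for the per-window cell-count increments
  expect_equal(diff(counts), ev_per_window)
  expect_gt(counts[7], counts[1])
  expect_gt(nrow(s$events), 0)
  # division is confined to the proliferative margin layers: every event's
  # parent sat in the marginal or submarginal layer, never in the quiescent
  # interior of ordinary cells
  for (i in seq_len(nrow(s$events))) {
    st <- snapshot_table(s, s$events$window[i])
    ly <- st$layer[st$id == s$events$parent_id[i]]
    expect_true(ly %in% c("marginal", "submarginal"))
  }
})

test_that("simulation is deterministic for a fixed seed", {
  a <- simulate_gametophyte(sim_params(n_windows = 3, init_rows = 3,
                                       init_cols = 4, rng_seed = 9,
                                       p_trichome = 0.1))
  b <- simulate_gametophyte(sim_params(n_windows = 3, init_rows = 3,
                                       init_cols = 4, rng_seed = 9,
                                       p_trichome = 0.1))
  expect_identical(a, b)
})

test_that("truth-series invariants hold across seeds", {
  for (seed in 1:4) {
    s <- simulate_gametophyte(sim_params(n_windows = 3, init_rows = 4,
                                         init_cols = 5, rng_seed = seed,
                                         p_trichome = 0.05))
    # lineage is a forest: every daughter appears exactly once
    expect_false(any(duplicated(s$lineage$daughter_id)))
    # daughters tile their parent at the division moment
    for (i in seq_len(nrow(s$events))) {
      pa <- prothallus:::poly_area(s$events$parent_poly[[i]])
      da <- sum(vapply(s$events$daughter_polys[[i]],
                       prothallus:::poly_area, numeric(1)))
      expect_lt(abs(da - pa) / pa, 1e-6)
    }
    # total tissue area is non-decreasing
    areas <- vapply(s$snapshots, function(sn)
      sum(vapply(sn$cells, function(cl) prothallus:::poly_area(cl$poly),
                 numeric(1))), numeric(1))
    expect_true(all(diff(areas) > -1e-9))
    # orientation bookkeeping on the emitted geometry
    ev <- s$events
    expect_true(all(ev$wall_angle[ev$orientation == "anticlinal"] > 60))
    expect_true(all(ev$wall_angle[ev$orientation == "periclinal"] < 30))
  }
})

test_that("marginal periclinal division frequency converges to q2", {
  # 30 replicate single-window meristems; every marginal cell is a packet
  # upper cell with periclinal probability q2 = 0.4
  q2 <- 0.4
  hits <- 0; n <- 0
  for (seed in 1:30) {
    s <- simulate_gametophyte(sim_params(
      n_windows = 1, init_rows = 4, init_cols = 6, rng_seed = seed * 37,
      q1 = 0, q2 = q2, q3 = 0, q4 = 0, meristem_fraction = 1,
      size_gate = 0, p_trichome = 0))
    st <- snapshot_table(s, 1)
    marg <- st$id[st$layer == "marginal"]
    n <- n + length(marg)
    ev <- s$events
    hits <- hits + sum(ev$orientation == "periclinal" &
                         ev$parent_id %in% marg)
  }
  phat <- hits / n
  ci <- q2 + c(-1, 1) * 1.96 * sqrt(q2 * (1 - q2) / n)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
})

test_that("exceeding the viability limit fails with a named error", {
  expect_error(
    simulate_gametophyte(sim_params(n_windows = 8, init_rows = 5,
                                    init_cols = 8, rng_seed = 1,
                                    meristem_fraction = 1, size_gate = 0,
                                    max_cells = 60)),
    "max_cells")
})

test_that("trichome initiation cuts a corner triangle that protrudes later", {
  s <- simulate_gametophyte(sim_params(n_windows = 3, init_rows = 4,
                                       init_cols = 6, rng_seed = 5,
                                       p_trichome = 0.15))
  tri <- Filter(function(cl) cl$trichome,
                s$snapshots[[length(s$snapshots)]]$cells)
  expect_gt(length(tri), 0)
  ev <- s$events[s$events$trichome_init, ]
  expect_gt(nrow(ev), 0)
  # asymmetric: the trichome daughter is the smaller one
  for (i in seq_len(nrow(ev))) {
    a <- vapply(ev$daughter_polys[[i]], prothallus:::poly_area, numeric(1))
    expect_lt(a[1], a[2])
  }
})
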