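# Helpers to read net current at a contracted group from a pair solve.
net_current_at <- function(ps, group) {
  ec <- ps$edge_currents
  sum(ec$current[ec$from == group]) - sum(ec$current[ec$to == group])
}

test_that("graph construction follows the mean-resistance edge rule", {
  f <- resistance_surface_from_matrix(matrix(2, 1, 3), matrix(0L, 1, 3))
  # a pure-sea surface has no islands; the graph itself is still valid
  g <- build_graph(f$surface, neighborhood = 4)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$resistance, c(2, 2))

  f2 <- resistance_surface_from_matrix(matrix(c(1, 3), 1, 2), matrix(0L, 1, 2))
  g2 <- build_graph(f2$surface, neighborhood = 4)
  expect_equal(g2$edges$resistance, 2)   # (1 + 3) / 2

  f3 <- resistance_surface_from_matrix(matrix(2, 2, 2), matrix(0L, 2, 2))
  g3 <- build_graph(f3$surface, neighborhood = 8)
  expect_equal(nrow(g3$edges), 6)        # 4 orthogonal + 2 diagonals
  expect_equal(sort(unique(round(g3$edges$resistance, 10))),
               round(c(2, 2 * sqrt(2)), 10))

  expect_error(build_graph(resistance_surface_from_matrix(
    matrix(Inf, 2, 2), matrix(0L, 2, 2)
  )$surface), "no passable")
})

test_that("impassable cells never enter the graph", {
  res <- matrix(c(2, Inf, 2, 2), 2, 2)
  f <- resistance_surface_from_matrix(res, matrix(0L, 2, 2))
  g <- build_graph(f$surface, neighborhood = 8)
  expect_equal(nrow(g$nodes), 3)
  expect_true(all(is.finite(g$edges$resistance)))
  expect_true(all(g$edges$conductance > 0))
})

test_that("contraction merges focal islands and leaves third parties alone", {
  # single-cell islands: contraction changes nothing but the grouping
  fx <- strip_fixture()
  g <- build_graph(fx$surface, neighborhood = 4)
  con <- contract_islands(g, fx$islands, c(1, 2))
  expect_equal(nrow(con$edges), nrow(g$edges))
  expect_equal(sort(con$edges$conductance), sort(g$edges$conductance))

  # two island cells touching one sea cell: conductances add in parallel
  lab <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  res <- matrix(c(2, 2, 2, Inf), 2, 2)
  f <- resistance_surface_from_matrix(res, lab)
  g2 <- build_graph(f$surface, neighborhood = 8)
  lab2 <- matrix(c(1L, 1L, 0L, 2L), 2, 2)
  res2 <- matrix(2, 2, 2)
  f2 <- resistance_surface_from_matrix(res2, lab2)
  g2 <- build_graph(f2$surface, neighborhood = 8)
  con2 <- contract_islands(g2, f2$islands, c(1, 2))
  # supernode 1 reaches the sea cell (1,2) along an orthogonal and a
  # diagonal edge; the merged conductance is their sum
  sea_node <- g2$node_of_cell[1 + (2 - 1) * 2]  # cell (1,2)
  grp_sea <- con2$group_of_node[sea_node]
  e <- con2$edges[(con2$edges$from == con2$source_group & con2$edges$to == grp_sea) |
                  (con2$edges$to == con2$source_group & con2$edges$from == grp_sea), ]
  expect_equal(e$conductance, 1 / 2 + 1 / (2 * sqrt(2)))

  # contracting A and B leaves island C's internal edge untouched
  lab3 <- matrix(c(1L, 0L, 3L, 3L, 0L, 2L), 1, 6)
  res3 <- matrix(c(2, 20, 2, 2, 20, 3), 1, 6)
  f3 <- resistance_surface_from_matrix(res3, lab3)
  g3 <- build_graph(f3$surface, neighborhood = 4)
  con3 <- contract_islands(g3, f3$islands, c(1, 2))
  c_nodes <- g3$node_of_cell[c(1 + 2 * 1, 1 + 3 * 1)]  # cells (1,3), (1,4)
  c_groups <- con3$group_of_node[c_nodes]
  e3 <- con3$edges[con3$edges$from == min(c_groups) &
                   con3$edges$to == max(c_groups), ]
  expect_equal(e3$conductance, 1 / 2)   # edge resistance (2+2)/2 unchanged

  expect_error(contract_islands(g3, f3$islands, c(1, 9)), "absent")
})

test_that("series and parallel fixtures give the closed-form resistance", {
  fx <- strip_fixture(sea_res = 20)
  g <- build_graph(fx$surface, neighborhood = 4)
  ps <- solve_pair(g, fx$islands, 1, 2)
  # unique path: edge resistances 11, 20, 20, 11.5
  expect_equal(ps$effective_resistance, 11 + 20 + 20 + 11.5, tolerance = 1e-10)

  # the same strip duplicated into two disjoint parallel strips halves R_eff
  res <- rbind(c(2, 20, 20, 20, 3),
               c(2, Inf, Inf, Inf, 3),
               c(2, 20, 20, 20, 3))
  lab <- matrix(0L, 3, 5); lab[, 1] <- 1L; lab[, 5] <- 2L
  f2 <- resistance_surface_from_matrix(res, lab)
  g2 <- build_graph(f2$surface, neighborhood = 4)
  ps2 <- solve_pair(g2, f2$islands, 1, 2)
  expect_equal(ps2$effective_resistance, 62.5 / 2, tolerance = 1e-10)

  # chain of n equal edges: uniform single-row sea between 1-cell islands
  res3 <- matrix(10, 1, 6)
  lab3 <- matrix(0L, 1, 6); lab3[1, 1] <- 1L; lab3[1, 6] <- 2L
  f3 <- resistance_surface_from_matrix(res3, lab3)
  ps3 <- solve_pair(build_graph(f3$surface, 4), f3$islands, 1, 2)
  expect_equal(ps3$effective_resistance, 5 * 10, tolerance = 1e-10)
})

test_that("one amp enters at the source, leaves at ground, and Kirchhoff holds", {
  fx <- make_worked_fixture()
  land <- bin_habitat_probability(fx$habitat$spring, spring_bin_table())
  surf <- combine_surfaces(land, sic_to_resistance(fx$sic), fx$islands)
  g <- build_graph(surf, neighborhood = 8)
  ps <- solve_pair(g, fx$islands, 1, 2)
  expect_true(ps$solvable)
  con <- ps$contracted
  expect_equal(net_current_at(ps, con$source_group), 1, tolerance = 1e-8)
  expect_equal(net_current_at(ps, con$ground_group), -1, tolerance = 1e-8)
  interior <- setdiff(unique(c(con$edges$from, con$edges$to)),
                      c(con$source_group, con$ground_group))
  resid <- vapply(interior, function(grp) net_current_at(ps, grp), numeric(1))
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("effective resistance and currents are reciprocal in the terminals", {
  fx <- make_worked_fixture()
  land <- bin_habitat_probability(fx$habitat$spring, spring_bin_table())
  surf <- combine_surfaces(land, sic_to_resistance(fx$sic), fx$islands)
  g <- build_graph(surf, neighborhood = 8)
  ab <- solve_pair(g, fx$islands, 1, 2)
  ba <- solve_pair(g, fx$islands, 2, 1)
  expect_equal(ab$effective_resistance, ba$effective_resistance,
               tolerance = 1e-10)
  expect_equal(ab$current, ba$current, tolerance = 1e-10)
})

test_that("solver matches the dense pseudoinverse oracle on random grids", {
  for (seed in 1:20) {
    case <- random_two_island_case(seed, max_dim = 6, neighborhood = 4)
    f <- resistance_surface_from_matrix(case$res, case$labels)
    ps <- solve_pair(build_graph(f$surface, case$neighborhood),
                     f$islands, 1, 2)
    or <- oracle_solve(case$res, case$labels, 1, 2, case$neighborhood)
    expect_equal(ps$solvable, or$solvable, info = paste("seed", seed))
    if (or$solvable) {
      expect_equal(ps$effective_resistance, or$effective_resistance,
                   tolerance = 1e-9, info = paste("seed", seed))
      expect_equal(ps$current, or$current, tolerance = 1e-8,
                   info = paste("seed", seed))
    } else {
      expect_identical(ps$effective_resistance, Inf)
      expect_true(all(ps$current == 0, na.rm = TRUE))
    }
  }
})

test_that("multi-cell focal islands match the oracle too", {
  fx <- make_worked_fixture()
  land <- bin_habitat_probability(fx$habitat$winter, winter_bin_table())
  surf <- combine_surfaces(land, sic_to_resistance(fx$sic), fx$islands)
  g <- build_graph(surf, neighborhood = 8)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    ps <- solve_pair(g, fx$islands, pair[1], pair[2])
    or <- oracle_solve(surf$resistance, fx$islands$labels,
                       pair[1], pair[2], 8)
    expect_equal(ps$solvable, or$solvable)
    if (or$solvable) {
      expect_equal(ps$effective_resistance, or$effective_resistance,
                   tolerance = 1e-9)
      expect_equal(ps$current, or$current, tolerance = 1e-8)
    }
  }
})

test_that("disconnected pairs are unsolvable results, not errors", {
  res <- matrix(c(2, Inf, 3), 1, 3)
  lab <- matrix(c(1L, 0L, 2L), 1, 3)
  f <- resistance_surface_from_matrix(res, lab)
  ps <- solve_pair(build_graph(f$surface, 4), f$islands, 1, 2)
  expect_false(ps$solvable)
  expect_identical(ps$effective_resistance, Inf)
  expect_true(all(ps$current == 0, na.rm = TRUE))
})

test_that("blocking cells never lowers effective resistance (Rayleigh)", {
  set.seed(99)
  for (seed in 1:10) {
    case <- random_two_island_case(seed + 300, max_dim = 6, neighborhood = 4)
    f <- resistance_surface_from_matrix(case$res, case$labels)
    base <- solve_pair(build_graph(f$surface, 4), f$islands, 1, 2)
    sea_cells <- which(is.finite(case$res) & case$labels == 0L)
    if (!length(sea_cells)) next
    for (k in 1:5) {
      res2 <- case$res
      res2[sample(sea_cells, 1)] <- Inf
      f2 <- resistance_surface_from_matrix(res2, case$labels)
      pert <- solve_pair(build_graph(f2$surface, 4), f2$islands, 1, 2)
      expect_gte(pert$effective_resistance,
                 base$effective_resistance - 1e-9)
    }
  }
})

test_that("cumulative current sums pair maps with the expected structure", {
  # two islands: the cumulative map is the single pair's map
  fx <- strip_fixture()
  cm <- cumulative_current(fx$surface, fx$islands, neighborhood = 4)
  ps <- solve_pair(build_graph(fx$surface, 4), fx$islands, 1, 2)
  expect_equal(cm$current, ps$current)
  expect_equal(nrow(cm$pairs), 1)

  # three collinear islands: the middle segments stack pair currents and
  # the map is mirror-symmetric
  cf <- collinear_fixture()
  cm3 <- cumulative_current(cf$surface, cf$islands, neighborhood = 4)
  g <- build_graph(cf$surface, 4)
  total <- solve_pair(g, cf$islands, 1, 2)$current +
    solve_pair(g, cf$islands, 1, 3)$current +
    solve_pair(g, cf$islands, 2, 3)$current
  expect_equal(cm3$current, total, tolerance = 1e-10)
  expect_equal(cm3$current[1, 2], cm3$current[1, 6], tolerance = 1e-10)
  expect_equal(cm3$current[1, 3], cm3$current[1, 5], tolerance = 1e-10)
  # a sea cell between A and B carries current from pairs (A,B) and (A,C)
  expect_gt(cm3$current[1, 2], 1)

  # fully impassable sea: all pairs unsolvable, zero current everywhere
  res0 <- matrix(Inf, 1, 5)
  res0[1, c(1, 5)] <- 2
  lab0 <- matrix(0L, 1, 5); lab0[1, 1] <- 1L; lab0[1, 5] <- 2L
  f0 <- resistance_surface_from_matrix(res0, lab0)
  cm0 <- cumulative_current(f0$surface, f0$islands, neighborhood = 4)
  expect_true(all(cm0$current == 0, na.rm = TRUE))
  expect_false(any(cm0$pairs$solvable))
  expect_equal(cm0$island_means$mean_current, c(0, 0))
})
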