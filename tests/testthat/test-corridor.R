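test_that("cost distance is exact on uniform fields and blocked rings", {
  # uniform resistance r, 4-neighbourhood: cost = r * orthogonal distance
  res <- matrix(10, 5, 5)
  lab <- matrix(0L, 5, 5); lab[3, 3] <- 1L
  f <- resistance_surface_from_matrix(res, lab)
  d <- cost_distance(f$surface, f$islands, 1, neighborhood = 4)
  manh <- abs(row(res) - 3) + abs(col(res) - 3)
  expect_equal(d, manh * 10, tolerance = 1e-12)
  expect_equal(d[3, 3], 0)

  # an impassable ring isolates the outside entirely
  res2 <- matrix(5, 5, 5)
  res2[2, 2:4] <- Inf; res2[4, 2:4] <- Inf
  res2[2:4, 2] <- Inf; res2[2:4, 4] <- Inf
  f2 <- resistance_surface_from_matrix(res2, lab)
  d2 <- cost_distance(f2$surface, f2$islands, 1, neighborhood = 8)
  outside <- matrix(TRUE, 5, 5); outside[2:4, 2:4] <- FALSE
  expect_true(all(is.infinite(d2[outside])))
  expect_equal(d2[3, 3], 0)
})

test_that("cost distances match exhaustive enumeration and Floyd-Warshall", {
  set.seed(7)
  for (rep in 1:3) {
    res <- matrix(round(runif(36, 1, 40), 1), 6, 6)
    res[sample(36, 5)] <- Inf
    lab <- matrix(0L, 6, 6)
    # two 1-cell islands at free corners
    res[1, 1] <- 2; res[6, 6] <- 3
    lab[1, 1] <- 1L; lab[6, 6] <- 2L
    f <- resistance_surface_from_matrix(res, lab)
    link <- least_cost_path(f$surface, f$islands, 1, 2, neighborhood = 4)
    brute <- oracle_lcp(res, lab, 1, 2, neighborhood = 4)
    expect_equal(link$cwd, brute, tolerance = 1e-10,
                 info = paste("rep", rep))
    fw <- oracle_floyd_warshall(res, neighborhood = 4)
    i <- match(which(lab == 1L), fw$pass); j <- match(which(lab == 2L), fw$pass)
    expect_equal(link$cwd, fw$D[i, j], tolerance = 1e-10)
    # the returned path realises the reported cost
    if (is.finite(link$cwd)) {
      p <- link$path
      steps <- vapply(seq_len(nrow(p) - 1), function(k) {
        (res[p[k, 1], p[k, 2]] + res[p[k + 1, 1], p[k + 1, 2]]) / 2 *
          (if (all(p[k + 1, ] != p[k, ])) sqrt(2) else 1)
      }, numeric(1))
      expect_equal(sum(steps), link$cwd, tolerance = 1e-10)
    }
  }
})

test_that("least-cost links carry hand-checkable costs and statuses", {
  fx <- strip_fixture(sea_res = 20)
  link <- least_cost_path(fx$surface, fx$islands, 1, 2, neighborhood = 4)
  expect_equal(link$status, "active")
  expect_equal(link$cwd, 62.5)                        # series sum
  expect_equal(nrow(link$path), 5)                    # the strip itself

  # fully impassable sea severs the link
  res0 <- matrix(Inf, 1, 5); res0[1, c(1, 5)] <- 2
  lab0 <- matrix(0L, 1, 5); lab0[1, 1] <- 1L; lab0[1, 5] <- 2L
  f0 <- resistance_surface_from_matrix(res0, lab0)
  sev <- least_cost_path(f0$surface, f0$islands, 1, 2, neighborhood = 4)
  expect_equal(sev$status, "severed")
  expect_identical(sev$cwd, Inf)
  expect_null(sev$path)
})

test_that("equal-cost alternatives break ties to the smallest cell sequence", {
  # two symmetric routes around an impassable block; costs identical
  res <- matrix(10, 3, 4)
  res[2, 2:3] <- Inf
  lab <- matrix(0L, 3, 4); lab[2, 1] <- 1L; lab[2, 4] <- 2L
  f <- resistance_surface_from_matrix(res, lab)
  l1 <- least_cost_path(f$surface, f$islands, 1, 2, neighborhood = 4)
  l2 <- least_cost_path(f$surface, f$islands, 1, 2, neighborhood = 4)
  expect_identical(l1$path, l2$path)        # deterministic
  expect_true(all(l1$path[, 1] <= 2))       # the northern detour is chosen
})

test_that("islands touching within one cell get an active zero-cost link", {
  lab <- matrix(0L, 3, 3)
  lab[1, 1] <- 1L; lab[2, 2] <- 2L
  f <- resistance_surface_from_matrix(matrix(20, 3, 3), lab)
  link <- least_cost_path(f$surface, f$islands, 1, 2, neighborhood = 8)
  expect_equal(link$cwd, 0)
  expect_equal(link$status, "active")
})

test_that("network building prunes intercepted links and counts the rest", {
  cf <- collinear_fixture()
  net <- build_network(cf$surface, cf$islands, neighborhood = 4)
  links <- tidy(net)
  get <- function(a, b) links[links$a == a & links$b == b, ]
  expect_equal(get(1, 2)$status, "active")
  expect_equal(get(2, 3)$status, "active")
  expect_equal(get(1, 3)$status, "pruned_intermediate")  # runs through B
  expect_equal(count_connections(net), 2)

  # two islands: a single link that can never be pruned
  fx <- strip_fixture()
  net2 <- build_network(fx$surface, fx$islands, neighborhood = 4)
  expect_equal(nrow(net2$links), 1)
  expect_equal(count_connections(net2), 1)

  # repeated runs are identical
  net3 <- build_network(cf$surface, cf$islands, neighborhood = 4)
  expect_identical(tidy(net), tidy(net3))
})

test_that("LCP cost upper-bounds the pair's effective resistance", {
  fixtures <- list(strip_fixture(), collinear_fixture())
  fx <- make_worked_fixture()
  land <- bin_habitat_probability(fx$habitat$spring, spring_bin_table())
  surf <- combine_surfaces(land, sic_to_resistance(fx$sic), fx$islands)
  fixtures[[3]] <- list(surface = surf, islands = fx$islands)
  for (f in fixtures) {
    ids <- f$islands$island_ids
    g <- build_graph(f$surface, neighborhood = 4)
    for (pair in utils::combn(ids, 2, simplify = FALSE)) {
      link <- least_cost_path(f$surface, f$islands, pair[1], pair[2],
                              neighborhood = 4)
      ps <- solve_pair(g, f$islands, pair[1], pair[2])
      if (is.finite(link$cwd)) {
        expect_gte(link$cwd, ps$effective_resistance - 1e-9)
      } else {
        expect_false(ps$solvable)
      }
    }
  }
})

test_that("blocking a cell never shortens a route or revives a severed link", {
  set.seed(123)
  cf <- collinear_fixture()
  base <- build_network(cf$surface, cf$islands, neighborhood = 4)
  sea <- which(is.finite(cf$surface$resistance) & cf$islands$labels == 0L)
  for (cell in sea) {
    res2 <- cf$surface$resistance
    res2[cell] <- Inf
    f2 <- resistance_surface_from_matrix(res2, cf$islands$labels)
    net2 <- build_network(f2$surface, f2$islands, neighborhood = 4)
    merged <- merge(tidy(base), tidy(net2), by = c("a", "b"),
                    suffixes = c("_base", "_pert"))
    expect_true(all(merged$cwd_pert >= merged$cwd_base - 1e-9))
    expect_false(any(merged$status_base == "severed" &
                     merged$status_pert == "active"))
  }
})
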