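test_that("trivial closed-set cases behave by definition", {
  expect_identical(solve_min_closed_set(c(1, 2, 3)), integer(0))
  expect_identical(solve_min_closed_set(-5), 1L)
  expect_identical(solve_min_closed_set(numeric(0)), integer(0))
  # a negative tail drags its positive successor in when worthwhile
  expect_identical(solve_min_closed_set(c(-5, 2), rbind(c(1L, 2L))), c(1L, 2L))
  expect_identical(solve_min_closed_set(c(-1, 2), rbind(c(1L, 2L))), integer(0))
})

test_that("closed-set solver matches exhaustive enumeration on random DAGs", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(3:11, 1)
    w <- sample(-9:9, n, replace = TRUE)
    e <- random_dag(n, p = runif(1, 0.1, 0.5))
    got <- solve_min_closed_set(w, e)
    want <- brute_min_closed_set(w, e)
    expect_equal(sum(w[got]), want$weight, label = sprintf("dag %d", i))
    # closedness of the returned set
    if (nrow(e) > 0)
      expect_true(all(!(e[, 1] %in% got) | (e[, 2] %in% got)))
  }
})

test_that("closed-set weight agrees with an independent max-flow computation", {
  # duality: min closed-set weight = max-flow value - sum of |negative
  # weights|; checked against igraph's push-relabel on instances too
  # large for enumeration
  set.seed(777)
  for (i in 1:10) {
    n <- 400L
    w <- round(rnorm(n, 0, 5), 3)
    e <- random_dag(n, p = 0.01)
    got <- solve_min_closed_set(w, e)
    s <- n + 1L; t <- n + 2L
    neg <- which(w < 0); pos <- which(w > 0)
    from <- c(rep(s, length(neg)), pos, e[, 1])
    to <- c(neg, rep(t, length(pos)), e[, 2])
    cap <- c(-w[neg], w[pos], rep(sum(abs(w)) + 1, nrow(e)))
    g <- igraph::add_edges(igraph::make_empty_graph(n + 2L), rbind(from, to))
    fl <- igraph::max_flow(g, s, t, capacity = cap)$value
    expect_equal(sum(w[got]), fl - sum(abs(w[neg])), tolerance = 1e-6)
  }
})

test_that("single-column detection is the argmin with lowest-index tie-break", {
  cost <- array(c(5, 1, 3, 2, 9, 8), dim = c(1, 1, 6))
  r <- detect_surface(cost, surface_constraints(1, 1, 0, 5, c(1, 1, 6)))
  expect_equal(as.vector(r$z), 1L)
  expect_equal(r$total_cost, 1)

  tied <- array(c(4, 2, 7, 2, 9), dim = c(1, 1, 5))
  r <- detect_surface(tied, surface_constraints(0, 0, 0, 4, c(1, 1, 5)))
  expect_equal(as.vector(r$z), 1L)  # first of the two cost-2 voxels
})

test_that("uniform zero cost yields a flat surface at the bottom of the region", {
  cost <- array(0, dim = c(4, 3, 7))
  r <- detect_surface(cost, surface_constraints(1, 1, 2, 5, c(4, 3, 7)))
  expect_true(all(r$z == 2L))
})

test_that("detection matches brute force over all feasible surfaces", {
  set.seed(202)
  for (i in 1:60) {
    nx <- sample(1:4, 1); ny <- sample(1:3, 1)
    nz <- sample(3:6, 1)
    if (nz^(nx * ny) > 25000) next
    dx <- sample(0:2, 1); dy <- sample(0:2, 1)
    cost <- array(sample(-9:9, nx * ny * nz, TRUE), dim = c(nx, ny, nz))
    want <- brute_min_surface(cost, dx, dy, 0, nz - 1)
    got <- detect_surface(cost,
                          surface_constraints(dx, dy, 0, nz - 1, c(nx, ny, nz)))
    expect_equal(got$total_cost, want$cost, label = sprintf("case %d", i))
  }
})

test_that("the detected surface respects the smoothness deltas", {
  set.seed(303)
  cost <- array(rnorm(6 * 5 * 10), dim = c(6, 5, 10))
  for (dl in c(0L, 1L, 3L)) {
    r <- detect_surface(cost, surface_constraints(dl, dl, 0, 9, c(6, 5, 10)))
    z <- r$z
    expect_lte(max(abs(z[-1, ] - z[-6, ])), dl)
    expect_lte(max(abs(z[, -1] - z[, -5])), dl)
  }
})

test_that("relaxing the smoothness constraint never increases the optimum", {
  set.seed(404)
  for (i in 1:10) {
    cost <- array(rnorm(4 * 4 * 8), dim = c(4, 4, 8))
    costs <- vapply(0:3, function(dl)
      detect_surface(cost,
                     surface_constraints(dl, dl, 0, 7, c(4, 4, 8)))$total_cost,
      numeric(1))
    expect_true(all(diff(costs) <= 1e-9))
  }
})

test_that("identical inputs give identical surfaces (determinism)", {
  set.seed(505)
  cost <- array(sample(-5:5, 5 * 4 * 8, TRUE), dim = c(5, 4, 8))
  con <- surface_constraints(1, 1, 0, 7, c(5, 4, 8))
  expect_identical(detect_surface(cost, con)$z, detect_surface(cost, con)$z)
})

test_that("infeasible constraint systems are reported with the column pair", {
  cost <- array(0, dim = c(2, 1, 10))
  lo <- matrix(c(0L, 8L), 2, 1); hi <- matrix(c(1L, 9L), 2, 1)
  con <- surface_constraints(2, 2, lo, hi, c(2, 1, 10))
  expect_error(detect_surface(cost, con), "columns \\(x=")
})

test_that("multiscale with one level equals direct full-volume detection", {
  spec <- tiny_phantom_spec(speckle_shape = Inf, additive_sd = 0,
                            n_shadows = 0)
  ph <- generate_phantom(spec)
  pol <- c("ILM" = "dark-to-bright")
  one <- detect_surfaces_multiscale(ph$volume, polarity = pol, levels = 1L)
  cost <- z_gradient_cost(ph$volume, "dark-to-bright")
  d <- dim(cost)
  direct <- detect_surface(cost,
    surface_constraints(default_deltas(ph$volume$spacing, 0.25)[1],
                        default_deltas(ph$volume$spacing, 0.25)[2],
                        0, d[3] - 1, d))
  expect_identical(get_surface(one, 1L), direct$z)
})

test_that("multiscale recovery on a small noiseless phantom is near exact", {
  spec <- tiny_phantom_spec(speckle_shape = Inf, additive_sd = 0,
                            n_shadows = 0)
  ph <- generate_phantom(spec)
  est <- detect_surfaces_multiscale(ph$volume)
  err <- surface_error(est, ph$truth)
  expect_lt(max(err$mae_vox), 1)
  # output ordering with the default minimum separation
  for (k in 1:10)
    expect_true(all(est$z[, , k + 1] - est$z[, , k] >= 2L))
})
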