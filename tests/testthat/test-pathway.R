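test_that("transverse projector identities hold", {
  expect_equal(projector(c(1, 0, 0)), diag(c(0, 1, 1)))
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(3)
    A <- projector(x)
    expect_equal(as.vector(A %*% x), rep(0, 3), tolerance = 1e-12)
    expect_equal(A %*% A, A, tolerance = 1e-12)
    expect_equal(sum(diag(A)), 2, tolerance = 1e-12)
    expect_equal(A, t(A))
  }
  expect_error(projector(c(0, 0, 1e-12)), class = "ngeni_data_error")
})

test_that("target distances interpolate linearly between end points", {
  pair <- hinge_pair_10()
  net <- build_network(pair, rule = "union")
  t0 <- target_distances(pair, net, 0)
  t1 <- target_distances(pair, net, 1)
  th <- target_distances(pair, net, 0.5)
  rs <- ngeni:::edge_lengths(pair$start$coords, net$edges[, 1], net$edges[, 2])
  re <- ngeni:::edge_lengths(pair$end$coords, net$edges[, 1], net$edges[, 2])
  expect_equal(t0$l, rs, tolerance = 1e-12)
  expect_equal(t1$l, re, tolerance = 1e-12)
  expect_equal(th$l, (rs + re) / 2, tolerance = 1e-12)
  expect_error(target_distances(pair, net, 1.2), class = "ngeni_usage_error")
})

test_that("quadratic model matches the exact cost at zero displacement", {
  pair <- hinge_pair_10()
  cur <- pair$start
  basis <- compute_modes(build_hessian(cur, build_network(cur)), 5)
  net <- build_network(pair, rule = "union")
  targets <- target_distances(pair, net, 0.5)
  cost <- assemble_cost(cur, basis, targets)
  expect_equal(cost$lambda1, t(cost$lambda1), tolerance = 1e-10)
  expect_gte(cost$lambda3, 0)
  z <- numeric(5)
  expect_identical(quadratic_cost_value(cost, z), cost$lambda3)
  expect_equal(exact_cost(cur, basis, z, targets), cost$lambda3,
               tolerance = 1e-10)
  # already-satisfied constraints: targets equal current distances
  t0 <- target_distances(pair, net, 0)
  cost0 <- assemble_cost(cur, basis, t0)
  expect_equal(cost0$lambda3, 0, tolerance = 1e-10)
  expect_equal(cost0$lambda2, numeric(5), tolerance = 1e-10)
})

test_that("model gradient at zero matches finite differences of the exact cost", {
  pair <- hinge_pair_10()
  cur <- pair$start
  basis <- compute_modes(build_hessian(cur, build_network(cur)), 6)
  targets <- target_distances(pair, build_network(pair, rule = "union"), 0.4)
  cost <- assemble_cost(cur, basis, targets)
  h <- 1e-6
  g_fd <- vapply(1:6, function(k) {
    e <- numeric(6); e[k] <- h
    (exact_cost(cur, basis, e, targets) -
       exact_cost(cur, basis, -e, targets)) / (2 * h)
  }, numeric(1))
  expect_equal(g_fd, 0.5 * cost$lambda2, tolerance = 1e-5)
})

test_that("weight solve: stationarity, scalar closed form, trust region", {
  mk_cost <- function(l1, l2, l3 = 1) {
    structure(list(lambda1 = l1, lambda2 = l2, lambda3 = l3),
              class = "quadratic_cost")
  }
  # lambda2 = 0: stationary at the origin
  expect_equal(solve_weights(mk_cost(diag(2), c(0, 0))), c(0, 0))
  # m = 1 closed form c = -b / (2a)
  a <- 1.7; b <- -0.6
  expect_equal(solve_weights(mk_cost(matrix(a), b)), -b / (2 * a),
               tolerance = 1e-12)
  # random SPD model: solution beats 1000 random directions of equal norm
  set.seed(42)
  M <- crossprod(matrix(rnorm(25), 5))
  l2 <- rnorm(5)
  cost <- mk_cost(M, l2, 3)
  cw <- solve_weights(cost)
  qstar <- quadratic_cost_value(cost, cw)
  r <- sqrt(sum(cw^2))
  rand_vals <- replicate(1000, {
    d <- rnorm(5); d <- d / sqrt(sum(d^2)) * r
    quadratic_cost_value(cost, d)
  })
  expect_true(all(qstar <= rand_vals + 1e-10))
  # trust region caps the step norm
  ct <- solve_weights(cost, trust = r / 3)
  expect_lte(sqrt(sum(ct^2)), r / 3 + 1e-9)
  expect_lte(quadratic_cost_value(cost, ct), cost$lambda3 + 1e-10)
})

test_that("quadratic model is accurate at the solved step size", {
  pair <- hinge_pair_10()
  cur <- pair$start
  basis <- compute_modes(build_hessian(cur, build_network(cur)), 10)
  targets <- target_distances(pair, build_network(pair, rule = "union"), 0.2)
  cost <- assemble_cost(cur, basis, targets)
  cw <- solve_weights(cost, trust = 0.15 * sqrt(10))
  ec <- exact_cost(cur, basis, cw, targets)
  qc <- quadratic_cost_value(cost, cw)
  expect_lt(abs(ec - qc) / max(ec, 1e-12), 0.05)
})

test_that("iteration count follows the 10-per-Angstrom rule", {
  expect_identical(iteration_count(7.1), 71L)
  expect_identical(iteration_count(15.4), 154L)
  expect_identical(iteration_count(0), 0L)
  expect_error(iteration_count(-1), class = "ngeni_usage_error")
})

test_that("identical end points give a trivial single-conformation pathway", {
  pair <- hinge_pair_10()
  same <- pair_structures(pair$start, pair$start)
  for (pw in list(run_ngeni(same, modes = 5), run_eni(same))) {
    expect_length(pw$conformations, 1L)
    expect_equal(pw$final_residual, 0, tolerance = 1e-12)
  }
})

test_that("pathway runs are deterministic and carry per-step records", {
  pair <- hinge_pair_10()
  p1 <- quiet(run_ngeni(pair, modes = 8))
  p2 <- quiet(run_ngeni(pair, modes = 8))
  expect_identical(p1$per_step, p2$per_step)
  expect_identical(p1$weights, p2$weights)
  s <- iteration_count(rmsd_ca(pair$start, pair$end))
  expect_length(p1$conformations, s + 1L)
  expect_equal(p1$per_step$alpha, (0:s) / s)
  expect_equal(p1$per_step$rmsd_to_end[1], rmsd_ca(pair$start, pair$end))
  expect_equal(dim(p1$weights), c(s, 8L))
  expect_identical(p1$conformations[[1]]$coords, pair$start$coords)
})

test_that("full-mode NGENI and Cartesian ENI agree per coordinate", {
  pair <- hinge_pair_20()
  pf <- run_ngeni(pair, modes = "full")
  pe <- run_eni(pair)
  expect_length(pe$conformations, length(pf$conformations))
  for (k in seq_along(pf$conformations)) {
    expect_lt(max(abs(pf$conformations[[k]]$coords -
                      pe$conformations[[k]]$coords)), 1e-6)
  }
})

test_that("reversed end points return to the original start", {
  pair <- hinge_pair_20()
  rev <- reverse_pair(pair)
  pw <- run_ngeni(rev, modes = "full")
  expect_lt(rmsd_ca(pw$conformations[[length(pw$conformations)]],
                    pair$start), 0.1)
})

test_that("safeguard and config validation behave", {
  pair <- hinge_pair_10()
  pw <- quiet(run_ngeni(pair, modes = 5, safeguard = TRUE, steps = 5))
  expect_s3_class(pw, "transition_pathway")
  expect_error(run_ngeni(pair, modes = 0), class = "ngeni_usage_error")
  expect_error(run_ngeni(pair, modes = 5, steps = -2),
               class = "ngeni_usage_error")
  expect_error(run_ngeni(pair, modes = 5, refine = 0),
               class = "ngeni_usage_error")
})
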