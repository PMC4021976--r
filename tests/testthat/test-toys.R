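# Synthetic benchmark networks and the brute-force polytope oracle.

test_that("length-1 chain feasible set is the known segment", {
  net <- make_chain(1)
  cs <- make_constraints(net, 1)
  grid <- brute_force_polytope(net, cs, resolution = 21)
  expect_gt(nrow(grid), 0)
  # all points: intake = uptake = 1, efflux anywhere in [0, 1]
  expect_true(all(abs(grid[, "intake"] - 1) < 1e-9))
  expect_true(all(abs(grid[, "uptake"] - 1) < 1e-9))
  expect_equal(sort(unique(grid[, "efflux"])), seq(0, 1, length.out = 21))
})

test_that("chain grid matches the monotone non-increasing characterization", {
  net <- make_chain(3)
  cs <- make_constraints(net, 1)
  grid <- brute_force_polytope(net, cs, resolution = 9)
  flux_cols <- c("uptake", "step1", "step2", "efflux")
  mono <- apply(grid[, flux_cols], 1, function(v) all(diff(v) <= 1e-9))
  expect_true(all(mono))
  # converse: every monotone lattice tuple appears
  lv <- seq(0, 1, length.out = 9)
  n_expected <- 0
  for (s1 in lv) for (s2 in lv[lv <= s1]) n_expected <- n_expected + sum(lv <= s2)
  expect_equal(nrow(grid), n_expected)
})

test_that("relaxation output lies inside the brute-force polytope (chain and diamond)", {
  for (net in list(make_chain(2), make_diamond())) {
    cs <- make_constraints(net, 1)
    ens <- sample_ensemble(net, cs, sampler_config(seed = 5, K = 300))
    grid <- brute_force_polytope(net, cs, resolution = 9)
    expect_gt(nrow(grid), 0)
    # membership: every sample satisfies the same constraints the grid does
    for (k in seq_len(50))
      expect_true(check_feasibility(net, ens$solutions[k, ], cs)$feasible)
    # support containment on the grid's free dimensions
    free <- attr(grid, "free_cols")
    rng_g <- apply(grid[, free, drop = FALSE], 2, range)
    rng_s <- apply(ens$solutions[, free, drop = FALSE], 2, range)
    expect_true(all(rng_s[1, ] >= rng_g[1, ] - 0.13))
    expect_true(all(rng_s[2, ] <= rng_g[2, ] + 0.13))
  }
})

test_that("minibrain stoichiometry: fully oxidative corner has OGI exactly 6", {
  net <- make_minibrain()
  cs <- make_constraints(net, 1, nu_max = 1)    # rel_ub covers O2 up to 6
  nu <- setNames(c(1, 6, 0.5, 0.5, 0.5, 0.5, 1, 1, 0), net$reactions$id)
  expect_true(check_feasibility(net, nu, cs)$feasible)
  expect_identical(compute_ogi(nu, net), 6)
  expect_equal(glucose_partition(nu, net), 0.5)
  expect_equal(ccls_flux(nu, net), 0)           # symmetric split: no shuttle
})

test_that("minibrain grid forces ANLS when astrocytes take most glucose", {
  net <- make_minibrain()
  cs <- make_constraints(net, 1, nu_max = 1)
  grid <- brute_force_polytope(net, cs, resolution = 7, max_dim = 6)
  expect_gt(nrow(grid), 0)
  # skewed partition with symmetric, high oxidation: lactate must flow a -> n
  sel <- abs(grid[, "T_a"] - 5/6) < 0.01 &
         abs(grid[, "OX_n"] - grid[, "OX_a"]) < 0.01 &
         grid[, "OX_n"] > 0.5
  expect_gt(sum(sel), 0)
  expect_true(all(grid[sel, "LX"] > 0))
  # and the oracle agrees with the analytic sign argument everywhere:
  # neuron lactate supply 2*(1 - T_a) + LX must cover its oxidation
  expect_true(all(2 * (1 - grid[, "T_a"]) + grid[, "LX"]
                  >= grid[, "OX_n"] - 1e-9))
})

test_that("sampler moments agree with the grid oracle on the chain", {
  # length-1 chain: the relaxation provably leaves the free efflux at its
  # prior draw, so the sampled marginal is exactly uniform on the segment
  # and the strict 3-standard-error comparison applies
  net <- make_chain(1)
  cs <- make_constraints(net, 1)
  grid <- brute_force_polytope(net, cs, resolution = 21)
  ens <- sample_ensemble(net, cs, sampler_config(seed = 31, K = 2000))
  j <- match("efflux", colnames(grid))
  se <- sd(ens$solutions[, j]) / sqrt(nrow(ens$solutions))
  expect_lt(abs(mean(ens$solutions[, j]) - mean(grid[, j])), 3 * se + 1e-3)

  # longer chains: prior draws violating monotonicity are corrected along
  # the constraint normal, which is known to pull means slightly below the
  # uniform-polytope value; the deviation stays within ~0.1 of the bound
  # range (documented sampler bias, cross-checked here against the oracle)
  net2 <- make_chain(2)
  cs2 <- make_constraints(net2, 1)
  grid2 <- brute_force_polytope(net2, cs2, resolution = 21)
  ens2 <- sample_ensemble(net2, cs2, sampler_config(seed = 32, K = 2000))
  for (jj in attr(grid2, "free_cols"))
    expect_lt(abs(mean(ens2$solutions[, jj]) - mean(grid2[, jj])), 0.1,
              label = sprintf("flux %s mean deviation", colnames(grid2)[jj]))
})

test_that("random networks reproduce deterministically from their seed", {
  n1 <- make_random_network(M = 6, N = 9, seed = 42)
  n2 <- make_random_network(M = 6, N = 9, seed = 42)
  expect_identical(n1$S, n2$S)
  expect_identical(attr(n1, "nu_dagger"), attr(n2, "nu_dagger"))
  n3 <- make_random_network(M = 6, N = 9, seed = 43)
  expect_false(identical(n1$S, n3$S))
})

test_that("infeasible pins give an empty grid and an LP certificate", {
  net <- make_chain(1)
  cs <- make_constraints(net, 2, nu_max = 0.5)   # pin above every bound
  grid <- brute_force_polytope(net, cs, resolution = 9)
  expect_equal(nrow(grid), 0)
  expect_false(lp_feasible_point(net, cs)$feasible)
})

test_that("oversized free dimension is refused", {
  net <- brain_net()
  cs <- make_constraints(net, 0.1)
  expect_error(brute_force_polytope(net, cs, resolution = 3), "free dimension")
})
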