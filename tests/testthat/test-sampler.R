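# Von Neumann constraint assembly and the prior-seeded relaxation sampler.

test_that("constraint assembly puts equalities on nutrient intakes only", {
  net <- brain_net()
  cs <- make_constraints(net, 0.1, nu_max = 1)
  eq_species <- net$species$id[cs$eq_rows]
  expect_setequal(eq_species, c("glc[c]", "o2[c]"))
  expect_length(intersect(cs$eq_rows, cs$ineq_rows), 0)
  expect_equal(length(cs$eq_rows) + length(cs$ineq_rows), nrow(net$S))
  expect_equal(unname(cs$pins), 0.1)
  expect_named(cs$pins, "GLC_in")
  # oxygen supply is never pinned
  expect_false("O2_in" %in% names(cs$pins))
  # bounds: reversible symmetric, irreversible non-negative, ROS capped
  rev <- net$reactions$reversible
  expect_true(all(cs$lb[rev] == -cs$ub[rev]))
  expect_true(all(cs$lb[!rev] == 0))
  expect_equal(cs$ub[match("ROS_n", net$reactions$id)], 0.1)

  cs7 <- make_constraints(net, 0.1, glc_e_balance = "strict")
  expect_true("glc[e]" %in% net$species$id[cs7$eq_rows])
})

test_that("feasibility checker accepts the homogeneous zero solution and flags violations", {
  net <- make_chain(2)
  cs <- make_constraints(net, 1)
  cs$pins[] <- 0                       # homogeneous system: S v >= 0, pin 0
  zero <- rep(0, ncol(net$S))
  expect_true(check_feasibility(net, zero, cs)$feasible)

  cs1 <- make_constraints(net, 1)
  nu <- c(1, 1, 1, 1)                  # intake, uptake, step, efflux
  expect_true(check_feasibility(net, nu, cs1)$feasible)
  nu_bad <- nu; nu_bad[4] <- -0.5      # negated irreversible component
  chk <- check_feasibility(net, nu_bad, cs1)
  expect_false(chk$feasible)
  expect_gte(chk$max_violation, 0.5)
})

test_that("uniform prior respects bounds, pins and the seeded stream", {
  net <- brain_net()
  cs <- make_constraints(net, 0.2, nu_max = 1)
  set.seed(7); a <- sample_prior(net, cs, 5)
  set.seed(7); b <- sample_prior(net, cs, 5)
  expect_identical(a, b)
  expect_true(all(sweep(a, 2, cs$lb, ">=") & sweep(a, 2, cs$ub, "<=")))
  expect_true(all(a[, "GLC_in"] == 0.2))

  # per-component empirical mean ~ bound midpoint (CLT, 4 sigma guard band)
  set.seed(8); big <- sample_prior(net, cs, 10000)
  free <- setdiff(seq_len(ncol(big)), match("GLC_in", colnames(big)))
  mid <- (cs$lb + cs$ub) / 2
  se <- (cs$ub - cs$lb) / sqrt(12 * nrow(big))
  dev <- abs(colMeans(big)[free] - mid[free]) / se[free]
  expect_lt(max(dev), 4)
})

test_that("relaxation is a fixed point on feasible starts and deterministic", {
  net <- make_chain(3)
  cs <- make_constraints(net, 1)
  nu <- c(1, 1, 0.8, 0.5, 0.2)         # feasible monotone chain profile
  r <- relax(net, nu, cs)
  expect_equal(r$iterations, 0L)
  expect_equal(drop(r$nu), nu, ignore_attr = TRUE)

  set.seed(3)
  nu0 <- sample_prior(net, cs, 4)
  r1 <- relax(net, nu0, cs, sampler_config(seed = 1))
  r2 <- relax(net, nu0, cs, sampler_config(seed = 1))
  expect_identical(r1$nu, r2$nu)
})

test_that("relaxation projects onto a segment solution set orthogonally", {
  net <- make_chain(1)                 # solution set: uptake = 1, efflux free
  cs <- make_constraints(net, 1)
  set.seed(4)
  for (i in 1:25) {
    nu0 <- sample_prior(net, cs, 1)
    r <- relax(net, nu0, cs)
    expect_true(r$converged)
    proj <- c(1, 1, min(max(nu0[1, 3], 0), 1))   # closed-form projection
    expect_lt(max(abs(drop(r$nu) - proj)), 1e-8)
  }
})

test_that("ensembles are reproducible, feasible row-wise and span the chain segment", {
  net <- make_chain(1)
  cs <- make_constraints(net, 1)
  cfg <- sampler_config(seed = 21, K = 1000)
  e1 <- sample_ensemble(net, cs, cfg)
  e2 <- sample_ensemble(net, cs, cfg)
  expect_identical(e1$solutions, e2$solutions)
  for (k in seq_len(nrow(e1$solutions)))
    expect_true(check_feasibility(net, e1$solutions[k, ], cs)$feasible)
  eff <- e1$solutions[, "efflux"]
  expect_lt(min(eff), 0.05)            # 1-D marginal covers the segment
  expect_gt(max(eff), 0.95)
  expect_gt(stats::ks.test(eff, "punif")$p.value, 0.001)
})

test_that("LP oracle agrees with the sampler on polytope non-emptiness", {
  net <- make_chain(2)
  cs <- make_constraints(net, 1)
  lp <- lp_feasible_point(net, cs)
  expect_true(lp$feasible)
  expect_true(check_feasibility(net, lp$nu, cs, 1e-7)$feasible)

  # contradictory pin: uptake cannot exceed its bound
  cs_bad <- make_constraints(net, 2, nu_max = 0.5)
  lp_bad <- lp_feasible_point(net, cs_bad)
  expect_false(lp_bad$feasible)
  r <- relax(net, sample_prior(net, cs_bad, 1), cs_bad,
             sampler_config(max_iter = 3000))
  expect_false(r$converged[1])
})

test_that("random stress networks embed a feasible point and relax converges", {
  for (seed in 1:10) {
    net <- make_random_network(M = 7, N = 11, density = 0.35, seed = seed)
    nu_d <- attr(net, "nu_dagger")
    cs <- make_constraints(net, glucose_level = nu_d[1],
                           nu_max = 2 * max(abs(nu_d)))
    cs$lb <- pmin(cs$lb, 0)            # random nets: allow both signs
    expect_true(check_feasibility(net, nu_d, cs)$feasible, info = seed)
    set.seed(seed)
    r <- relax(net, sample_prior(net, cs, 20), cs,
               sampler_config(max_iter = 5e4))
    expect_gte(mean(r$converged), 0.95)
  }
})
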