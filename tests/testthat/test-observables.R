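# Per-solution observables, conditional statistics and correlation structure.

test_that("OGI is the oxygen-to-glucose intake ratio", {
  net <- make_minibrain()
  nu <- setNames(rep(0, ncol(net$S)), net$reactions$id)
  nu["GLC_in"] <- 1; nu["O2_in"] <- 5.5
  expect_equal(compute_ogi(nu, net), 5.5)
  nu["O2_in"] <- 0                      # pure glycolysis: no oxygen intake
  expect_equal(compute_ogi(nu, net), 0)
  nu["GLC_in"] <- 0
  expect_error(compute_ogi(nu, net), "zero")
})

test_that("V_cyc equals the glutamine synthetase component exactly", {
  net <- brain_net()
  nu <- rep(0, ncol(net$S))
  j <- role_column(net, "GS_a")
  nu[j] <- 0.07
  expect_identical(compute_vcyc(nu, net), 0.07)
  nu[j] <- 0
  expect_identical(compute_vcyc(nu, net), 0)
  # independent index check on a sampled solution
  sol <- brain_ensemble()$solutions[1, ]
  expect_identical(compute_vcyc(sol, net),
                   unname(sol[which(net$reactions$id == "GS_a")]))
})

test_that("neuronal oxidative glucose is exactly half the PDH flux", {
  net <- brain_net()
  nu <- rep(0, ncol(net$S))
  j <- role_column(net, "PDH_n")
  nu[j] <- 1.0
  expect_identical(compute_cmr_glc_ox_n(nu, net), 0.5)
  nu[j] <- 0
  expect_identical(compute_cmr_glc_ox_n(nu, net), 0)
  sols <- brain_ensemble()$solutions
  pdh <- sols[, j]
  ok <- pdh > 0
  expect_equal(apply(sols[ok, ], 1, compute_cmr_glc_ox_n, net = net) / pdh[ok],
               rep(0.5, sum(ok)), ignore_attr = TRUE)
})

test_that("glucose partition sums the astrocytic routes over the pin", {
  net <- brain_net()
  nu <- rep(0, ncol(net$S))
  nu[role_column(net, "GLC_to_c")] <- 1
  nu[role_column(net, "GLC_c_to_a")] <- 0.3
  nu[role_column(net, "GLC_e_to_a")] <- 0.2
  expect_equal(glucose_partition(nu, net), 0.5)
  nu[role_column(net, "GLC_c_to_a")] <- 1
  nu[role_column(net, "GLC_e_to_a")] <- 0
  expect_equal(glucose_partition(nu, net), 1.0)
})

test_that("lactate shuttle sign convention: positive is astrocyte-to-neuron", {
  net <- brain_net()
  nu <- setNames(rep(0, ncol(net$S)), net$reactions$id)
  nu["LACt_a"] <- 0.4                   # astrocyte exports 0.4
  nu["LACt_n"] <- -0.4                  # neuron imports 0.4
  expect_equal(ccls_flux(nu, net), 0.4)
  expect_equal(ccls_flux(nu, net, side = "neuron"), 0.4)
  nu["LACt_a"] <- -0.3; nu["LACt_n"] <- 0.3   # reversed: NALS
  expect_equal(ccls_flux(nu, net), -0.3)
  expect_equal(ccls_flux(nu, net, side = "neuron"), -0.3)
  nu["LACt_a"] <- 0; nu["LACt_n"] <- 0
  expect_equal(ccls_flux(nu, net), 0)
})

test_that("activity classification uses a strict null-flux threshold", {
  net <- brain_net()
  nu <- rep(0, ncol(net$S))
  j <- role_column(net, "GS_a")
  nu[j] <- 5e-7
  expect_equal(classify_active(nu, net), "silent")
  nu[j] <- 0.06
  expect_equal(classify_active(nu, net), "active")
  nu[j] <- 1e-6                         # exactly the threshold: null
  expect_equal(classify_active(nu, net), "silent")
})

test_that("observable records match the scalar computations row-wise", {
  net <- brain_net()
  ens <- brain_ensemble()
  rec <- observable_records(ens, net)
  expect_equal(nrow(rec), nrow(ens$solutions))
  i <- c(1, 17, 101)
  expect_equal(rec$ogi[i],
               apply(ens$solutions[i, ], 1, compute_ogi, net = net))
  expect_equal(rec$lac_a_to_n[i],
               apply(ens$solutions[i, ], 1, ccls_flux, net = net))
  expect_true(all(rec$astro_glc_fraction >= -1e-6 &
                  rec$astro_glc_fraction <= 1 + 1e-6))
  expect_true(all(rec$ogi >= 0))
})

test_that("conditional averages recover structure of synthetic records", {
  set.seed(11)
  x <- runif(4000)
  rec <- data.frame(x = x, y_const = 3, y_lin = 2 * x,
                    active = rep(c(TRUE, FALSE), 2000))
  flat <- conditional_average(rec, "x", "y_const", "all", bins = 10)
  expect_true(all(flat$y_mean == 3))
  expect_true(all(flat$y_se == 0))

  lin <- conditional_average(rec, "x", "y_lin", "all", bins = 25)
  fit <- piecewise_slopes(lin, breakpoint_x = 0.5)
  expect_equal(fit$slope_low, 2, tolerance = 1e-6)
  expect_equal(fit$slope_high, 2, tolerance = 1e-6)

  act <- conditional_average(rec, "x", "y_lin", "active", bins = 10)
  expect_equal(sum(act$count), 2000)
  expect_error(conditional_average(rec[rec$active, ], "x", "y_lin", "silent"),
               "condition")
})

test_that("piecewise slopes recover an exact two-regime curve", {
  x <- seq(0, 1, length.out = 40)
  brk <- 0.5
  y <- ifelse(x < brk, 0.7 * x, 0.7 * brk + 0.3 * (x - brk))
  curve <- structure(data.frame(x_center = x, y_mean = y, y_se = 0, count = 50),
                     class = c("conditional_curve", "data.frame"))
  s <- piecewise_slopes(curve, brk)
  expect_equal(s$slope_low, 0.7, tolerance = 1e-9)
  expect_equal(s$slope_high, 0.3, tolerance = 1e-9)
  line <- structure(data.frame(x_center = x, y_mean = 2 * x, y_se = 0, count = 1),
                    class = c("conditional_curve", "data.frame"))
  s2 <- piecewise_slopes(line, 0.4)
  expect_equal(s2$slope_low, s2$slope_high, tolerance = 1e-9)
  expect_error(piecewise_slopes(curve, 1.5), "bins")
})

test_that("pearson matrix is symmetric with unit diagonal and masks null fluxes", {
  net <- make_minibrain()
  set.seed(12)
  K <- 400
  base <- runif(K)
  sols <- matrix(runif(K * ncol(net$S)), K,
                 dimnames = list(NULL, net$reactions$id))
  sols[, "T_n"] <- base                 # duplicated pair
  sols[, "T_a"] <- base
  sols[, "LX"] <- 0                     # null flux
  cm <- pearson_matrix(sols, net, condition = "all")
  v <- cm$values
  expect_equal(v, t(v))
  expect_equal(unname(v["T_n", "T_a"]), 1)
  expect_true(all(diag(v)[!cm$null_mask] == 1))
  expect_true(cm$null_mask[["LX"]])
  expect_true(all(is.na(v["LX", ])))
  expect_true(all(abs(v[!is.na(v)]) <= 1))
  # independent columns: coefficients near zero (3/sqrt(K) guard band)
  off <- v["GLY_n", "GLY_a"]
  expect_lt(abs(off), 3 / sqrt(K))
})

test_that("pearson matrix conditions on cycling activity and reports pair classes", {
  net <- brain_net()
  pooled <- brain_ensemble()$solutions
  cm <- pearson_matrix(pooled, net, condition = "active")
  expect_equal(cm$n_solutions,
               sum(pooled[, role_column(net, "GS_a")] > 1e-6))
  expect_named(cm$histograms, c("neuron", "astrocyte", "between"))
  expect_gt(cm$pair_counts[["between"]], 0)
  expect_error(pearson_matrix(pooled[1:5, ], net, "all"), "fewer than 10")
})

test_that("OGI histogram is normalized and consistent with the direct mean", {
  net <- brain_net()
  ens <- brain_ensemble()
  h <- ogi_distribution(ens, net)
  expect_equal(sum(h$histogram$density), 1, tolerance = 1e-12)
  rec <- observable_records(ens, net)
  expect_equal(h$mean, mean(rec$ogi))
  same <- data.frame(ogi = rep(5.2, 50))
  h2 <- ogi_distribution(same)
  expect_equal(sum(h2$histogram$count > 0), 1)
})

test_that("basal calibration interpolates the OGI = 5.5 crossing", {
  sweep <- data.frame(glucose_level = seq(0.04, 0.12, 0.02),
                      mean_ogi = 9.5 - 50 * seq(0.04, 0.12, 0.02))
  cal <- basal_calibration(sweep)
  expect_equal(cal$g_basal, 0.08, tolerance = 1e-12)
  expect_equal(cal$g_activated, 0.092, tolerance = 1e-12)
  expect_error(basal_calibration(data.frame(glucose_level = 1:2,
                                            mean_ogi = c(9, 8))),
               "bracket")
})
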