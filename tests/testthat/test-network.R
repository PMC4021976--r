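# Network reconstruction: compartments, stoichiometry, elemental audits,
# role resolution and topology of the glucose/oxygen routes.

test_that("compartment table has the seven codes with vesicles in neurons only", {
  cmp <- compartments()
  expect_setequal(cmp$code, c("c", "e", "nc", "nm", "nv", "ac", "am"))
  expect_match(cmp$label[cmp$code == "nv"], "neuron")
})

test_that("equation parser handles coefficients, sides and exchanges", {
  st <- parse_equation("2 a[nc] + b[e] -> c[ac]")
  expect_equal(st[["a[nc]"]], -2)
  expect_equal(st[["b[e]"]], -1)
  expect_equal(st[["c[ac]"]], 1)
  expect_equal(parse_equation("0.5 o2[c] -> h2o2[nc]")[["o2[c]"]], -0.5)
  expect_equal(parse_equation("-> glc[c]"), c("glc[c]" = 1))
  expect_equal(parse_equation("co2[c] ->"), c("co2[c]" = -1))
  expect_error(parse_equation("a[nc] b[e]"), "arrow")
})

test_that("brain reconstruction has the expected size and resolves all roles", {
  net <- brain_net()
  N <- ncol(net$S); M <- nrow(net$S)
  expect_gt(N, M)                       # underdetermined system
  expect_true(N >= 110 && N <= 165)     # pathway-level vicinity of the study
  expect_true(M >= 95 && M <= 135)
  roles <- c("GS_a", "PDH_n", "GLC_to_c", "O2_to_c", "GLC_c_to_a",
             "GLC_c_to_e", "GLC_e_to_a", "GLC_e_to_n", "O2_c_to_a",
             "O2_c_to_n", "LAC_a_to_n")
  for (r in roles) expect_false(any(is.na(role_column(net, r))), info = r)
})

test_that("glutamine synthetase and Na/K-ATPase carry the fixed stoichiometries", {
  net <- brain_net()
  gs <- net$S[, role_column(net, "GS_a")]
  expect_equal(gs[["glu[ac]"]], -1)
  expect_equal(gs[["nh4[ac]"]], -1)
  expect_equal(gs[["atp[ac]"]], -1)
  expect_equal(gs[["gln[ac]"]], 1)
  expect_equal(gs[["adp[ac]"]], 1)
  expect_equal(sum(gs != 0), 5)

  pump <- net$S[, match("NaK_n", net$reactions$id)]
  expect_equal(pump[["na[nc]"]], -3)
  expect_equal(pump[["na[e]"]], 3)
  expect_equal(pump[["k[e]"]], -2)
  expect_equal(pump[["k[nc]"]], 2)
  expect_equal(pump[["atp[nc]"]], -1)
  expect_equal(pump[["adp[nc]"]], 1)

  eaat <- net$S[, match("EAAT_a", net$reactions$id)]
  expect_equal(eaat[["na[e]"]], -3)    # 3 Na+ co-transport
  expect_equal(eaat[["k[ac]"]], -1)    # 1 K+ counter-transport
})

test_that("carbon and nitrogen audits are clean and detect injected faults", {
  net <- brain_net()
  expect_equal(nrow(carbon_balance_check(net)$violations), 0)
  expect_equal(nrow(carbon_balance_check(net, "nitrogen")$violations), 0)
  # exchange columns are exempt but listed
  exch <- carbon_balance_check(net)$exchanges
  expect_true(all(c("GLC_in", "O2_in", "CO2_out") %in% exch$reaction))

  bad <- net
  j <- match("ALD_n", bad$reactions$id)
  bad$S["gap[nc]", j] <- 2              # corrupt aldolase
  viol <- carbon_balance_check(bad)$violations
  expect_true("ALD_n" %in% viol$reaction)
  expect_equal(viol$imbalance[viol$reaction == "ALD_n"], 3)
})

test_that("builder options remove optional subsystems without breaking invariants", {
  net <- build_brain_network(glycogen = FALSE)
  expect_false(any(c("GLYCS", "GLYCP") %in% net$reactions$id))
  expect_false("glyc[ac]" %in% net$species$id)
  expect_equal(nrow(carbon_balance_check(net)$violations), 0)

  net2 <- build_brain_network(antioxidant = FALSE, g3p_shuttle = FALSE)
  expect_false(any(grepl("^GPX|^GSHS|^G3PDH", net2$reactions$id)))
  expect_equal(nrow(carbon_balance_check(net2)$violations), 0)
  for (r in names(net2$role_index))
    expect_false(any(is.na(role_column(net2, r))), info = r)
})

test_that("oxidative phosphorylation P/O ratios are configurable", {
  net <- build_brain_network(p_o_nadh = 3, p_o_fadh2 = 2)
  opn <- net$S[, match("OPN_n", net$reactions$id)]
  expect_equal(opn[["atp[nc]"]], 3)
  expect_equal(opn[["adp[nc]"]], -3)
  expect_equal(opn[["o2[nc]"]], -0.5)
})

test_that("stoichiometric matrix matches reaction definitions", {
  toy <- metabolic_network(
    list(rxn("r1", "A[e] -> B[e]")),
    chem = data.frame(base = c("A", "B"), carbon = 1, nitrogen = 0))
  expect_equal(unname(stoichiometric_matrix(toy)), matrix(c(-1, 1), 2, 1))

  net <- brain_net()
  S <- stoichiometric_matrix(net)
  expect_equal(dim(S), c(nrow(net$species), nrow(net$reactions)))
  expect_equal(rownames(S), net$species$id)
})

test_that("production vector is S v and matches a naive loop oracle", {
  net <- brain_net()
  expect_equal(unname(production_vector(net, rep(0, ncol(net$S)))),
               rep(0, nrow(net$S)))
  set.seed(5)
  nu <- runif(ncol(net$S), -1, 1)
  slow <- vapply(seq_len(nrow(net$S)),
                 function(i) sum(net$S[i, ] * nu), 0)
  expect_equal(unname(production_vector(net, nu)), slow)
  expect_error(production_vector(net, nu[-1]), "length")
})

test_that("cells interact only through extracellular space or capillary", {
  net <- brain_net()
  n_comp <- c("nc", "nm", "nv"); a_comp <- c("ac", "am")
  comp <- net$species$compartment
  for (j in seq_len(ncol(net$S))) {
    touched <- comp[net$S[, j] != 0]
    expect_false(any(touched %in% n_comp) && any(touched %in% a_comp),
                 info = net$reactions$id[j])
  }
})

test_that("glucose routes follow the capillary/extracellular topology", {
  net <- brain_net()
  consumers <- function(sp) net$reactions$id[net$S[sp, ] < 0]
  expect_setequal(consumers("glc[c]"), c("GLC_c_a", "GLC_c_e"))
  expect_setequal(consumers("glc[e]"), c("GLC_e_a", "GLC_e_n"))
  # no direct capillary -> neuron glucose route exists
  expect_false(any(net$S["glc[c]", ] < 0 &
                   net$reactions$cell_scope == "neuron"))
})
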