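# Small stoichiometric networks with enumerable feasible sets: independent
# oracles for the sampler and the observables. They reproduce the structure
# the analysis assumes (pinned intake, S v >= 0 internals, reversible
# exchanges) at a scale where the polytope can be characterized analytically
# or scanned on a grid.

toy_chem <- function(bases) {
  data.frame(base = bases, carbon = 0, nitrogen = 0, stringsAsFactors = FALSE)
}

#' Linear chain toy network
#'
#' `intake -> C -> A1 -> ... -> A_L -> efflux` with the capillary-like
#' species C flagged as a nutrient intake (mass-balance equality row). With
#' the intake pinned to `g` the feasible set is exactly: uptake = g and flux
#' non-increasing along the chain, everything within bounds -- fully
#' characterizable, so relaxation output can be checked by membership.
#'
#' @param length number of internal chain species (>= 1).
#' @return a `metabolic_network`.
#' @export
make_chain <- function(length = 3) {
  stopifnot(length >= 1)
  rxs <- list(rxn("intake", "-> C0[c]", pathway = "intake", scope = "capillary"),
              rxn("uptake", "C0[c] -> A1[e]", pathway = "transport"))
  if (length > 1)
    for (i in seq_len(length - 1))
      rxs[[length(rxs) + 1L]] <-
        rxn(sprintf("step%d", i), sprintf("A%d[e] -> A%d[e]", i, i + 1),
            pathway = "transport")
  rxs[[length(rxs) + 1L]] <-
    rxn("efflux", sprintf("A%d[e] ->", length), pathway = "efflux")
  metabolic_network(rxs,
                    roles = list(GLC_to_c = "intake"),
                    intake_ids = "intake",
                    chem = toy_chem(c("C0", paste0("A", seq_len(length)))))
}

#' Diamond toy network
#'
#' `intake -> A; A -> B; A -> C; B -> D; C -> D; D -> efflux` with A as the
#' pinned nutrient (equality row): the split between the two branches and
#' the downstream pass-through fluxes span a 4-dimensional polytope.
#'
#' @return a `metabolic_network`.
#' @export
make_diamond <- function() {
  rxs <- list(
    rxn("intake", "-> A[c]", pathway = "intake", scope = "capillary"),
    rxn("branch_b", "A[c] -> B[e]", pathway = "transport"),
    rxn("branch_c", "A[c] -> C[e]", pathway = "transport"),
    rxn("join_b", "B[e] -> D[e]", pathway = "transport"),
    rxn("join_c", "C[e] -> D[e]", pathway = "transport"),
    rxn("efflux", "D[e] ->", pathway = "efflux"))
  metabolic_network(rxs, roles = list(GLC_to_c = "intake"),
                    intake_ids = "intake",
                    chem = toy_chem(c("A", "B", "C", "D")))
}

#' Minibrain caricature network
#'
#' Nine reactions: pinned glucose supply splitting to two cells, a
#' glycolysis lump (1 glucose -> 2 lactate) and an oxidation lump
#' (1 lactate + 3 O2 -> 3 CO2) per cell drawing on a free oxygen intake,
#' and a reversible inter-cell lactate exchange. The 6:1 oxygen:glucose
#' lump stoichiometry makes the fully oxidative corner have OGI = 6
#' exactly; the sign of the lactate exchange is forced by the imbalance
#' between a cell's glucose share and its oxidation flux. Glucose
#' partitioning, OGI and the lactate shuttle are all defined, and the
#' polytope is low-dimensional enough to grid-enumerate.
#'
#' @return a `metabolic_network`.
#' @export
make_minibrain <- function() {
  rxs <- list(
    rxn("GLC_in", "-> glc[c]", pathway = "intake", scope = "capillary"),
    rxn("O2_in", "-> o2[c]", pathway = "intake", scope = "capillary"),
    rxn("T_n", "glc[c] -> glc[nc]", pathway = "transport", scope = "neuron"),
    rxn("T_a", "glc[c] -> glc[ac]", pathway = "transport", scope = "astrocyte"),
    rxn("GLY_n", "glc[nc] -> 2 lac[nc]", pathway = "glycolysis", scope = "neuron"),
    rxn("GLY_a", "glc[ac] -> 2 lac[ac]", pathway = "glycolysis", scope = "astrocyte"),
    rxn("OX_n", "lac[nc] + 3 o2[c] -> 3 co2[c]", pathway = "oxphos", scope = "neuron"),
    rxn("OX_a", "lac[ac] + 3 o2[c] -> 3 co2[c]", pathway = "oxphos", scope = "astrocyte"),
    rxn("LX", "lac[ac] -> lac[nc]", rev = TRUE, pathway = "transport"))
  net <- metabolic_network(rxs,
                           roles = list(GLC_to_c = "GLC_in", O2_to_c = "O2_in",
                                        GLC_c_to_a = "T_a", LAC_a_to_n = "LX"),
                           intake_ids = c("GLC_in", "O2_in"))
  # per-reaction caps sized to the polytope so that, with nu_max set to the
  # glucose pin, the prior box snugly contains the feasible set
  net$reactions$rel_ub <- c(GLC_in = 1, O2_in = 6, T_n = 1, T_a = 1,
                            GLY_n = 1, GLY_a = 1, OX_n = 2, OX_a = 2,
                            LX = 2)[net$reactions$id]
  net
}

#' Random sparse network with an embedded feasible point
#'
#' Generates random sparse integer stoichiometry, then appends one
#' repair column so that a known flux vector `nu_dagger` (stored as an
#' attribute) satisfies `S nu >= 0` -- guaranteeing a non-empty polytope
#' for sampler stress tests. Column 1 acts as the pinned intake.
#'
#' @param M number of species.
#' @param N number of reactions before the repair column (N > M required).
#' @param density expected fraction of nonzero coefficients.
#' @param seed integer seed.
#' @return a `metabolic_network` with attribute `nu_dagger`.
#' @export
make_random_network <- function(M = 8, N = 12, density = 0.3, seed = 1) {
  stopifnot(N > M)
  set.seed(seed)
  repeat {
    S <- matrix(0, M, N)
    nz <- matrix(runif(M * N) < density, M, N)
    S[nz] <- sample(c(-2, -1, 1, 2), sum(nz), replace = TRUE)
    used <- colSums(S != 0) > 0 | seq_len(N) == 1
    S[1, 1] <- 1   # column 1: intake into species 1
    if (all(rowSums(S != 0) > 0)) break
  }
  nu_d <- runif(N, 0.2, 0.8)
  r <- drop(S %*% nu_d)
  fix <- pmax(0, -r)            # repair column carried at flux 1
  S <- cbind(S, fix)
  nu_d <- c(nu_d, 1)
  bases <- paste0("x", seq_len(M))
  sp_ids <- paste0(bases, "[e]")
  rxs <- vector("list", N + 1)
  for (j in seq_len(N + 1)) {
    st <- S[, j]; names(st) <- sp_ids
    st <- st[st != 0]
    # exact stoichiometry (the repair column carries arbitrary reals, so the
    # reaction is built directly rather than via an equation string)
    id <- sprintf("r%02d", j)
    rxs[[j]] <- list(id = id, name = id, stoichiometry = st,
                     reversible = FALSE,
                     pathway = if (j == 1) "intake" else
                               if (j == N + 1) "repair" else "transport",
                     scope = "shared")
  }
  net <- metabolic_network(rxs, roles = list(GLC_to_c = "r01"),
                           chem = toy_chem(bases), validate = FALSE)
  attr(net, "nu_dagger") <- nu_d
  net
}

#' Brute-force enumeration of the feasible polytope on a grid
#'
#' Eliminates the variables determined by the equality rows and pins
#' (Gauss-Jordan pivoting), scans the remaining free components on a
#' regular grid over their bounds, and keeps the points satisfying every
#' constraint. Only usable when the free dimension is small; serves as the
#' independent oracle for sampler support and moments.
#'
#' @param net a `metabolic_network`.
#' @param cs a [make_constraints()] object.
#' @param resolution grid points per free dimension.
#' @param tol feasibility tolerance for grid membership.
#' @param max_dim largest allowed free dimension.
#' @return matrix of feasible flux vectors (possibly 0 rows), with
#'   attributes `free_cols` (indices of grid dimensions) and `resolution`.
#' @export
brute_force_polytope <- function(net, cs, resolution = 21, tol = 1e-9,
                                 max_dim = 6) {
  S <- net$S; N <- ncol(S)
  pc <- cs_pin_cols(net, cs)
  # equality system: species equality rows + pin rows
  E <- S[cs$eq_rows, , drop = FALSE]
  d <- rep(0, length(cs$eq_rows))
  for (i in seq_along(pc)) {
    row <- rep(0, N); row[pc[i]] <- 1
    E <- rbind(E, row); d <- c(d, cs$pins[i])
  }
  # Gauss-Jordan with partial pivoting -> pivot/free split
  piv <- integer(0)
  Ework <- cbind(E, d)
  r <- 1
  for (j in seq_len(N)) {
    if (r > nrow(Ework)) break
    k <- which.max(abs(Ework[r:nrow(Ework), j])) + r - 1
    if (abs(Ework[k, j]) < 1e-10) next
    Ework[c(r, k), ] <- Ework[c(k, r), ]
    Ework[r, ] <- Ework[r, ] / Ework[r, j]
    for (q in seq_len(nrow(Ework)))
      if (q != r && Ework[q, j] != 0)
        Ework[q, ] <- Ework[q, ] - Ework[q, j] * Ework[r, ]
    piv <- c(piv, j); r <- r + 1
  }
  free <- setdiff(seq_len(N), piv)
  if (length(free) > max_dim)
    stop("free dimension ", length(free), " exceeds max_dim = ", max_dim)
  R <- Ework[seq_along(piv), , drop = FALSE]
  # nu[piv] = rhs - F nu[free]
  Fm <- R[, free, drop = FALSE]; rhs <- R[, N + 1]

  grids <- lapply(free, function(j) seq(cs$lb[j], cs$ub[j], length.out = resolution))
  total <- prod(vapply(grids, length, 0L))
  chunk <- 200000L
  out <- list()
  done <- 0L
  while (done < total) {
    take <- min(chunk, total - done)
    idx <- done + seq_len(take)
    # decode mixed-radix indices into grid coordinates
    G <- matrix(0, take, length(free))
    rem <- idx - 1L
    for (q in seq_along(free)) {
      G[, q] <- grids[[q]][(rem %% resolution) + 1L]
      rem <- rem %/% resolution
    }
    V <- matrix(0, take, N)
    V[, free] <- G
    V[, piv] <- matrix(rhs, take, length(piv), byrow = TRUE) - G %*% t(Fm)
    okb <- rowSums(sweep(V, 2, cs$lb, "<") | sweep(V, 2, cs$ub, ">")) == 0
    if (any(okb)) {
      P <- V[okb, , drop = FALSE] %*% t(S[cs$ineq_rows, , drop = FALSE])
      oki <- rowSums(P < -tol) == 0
      if (any(oki)) out[[length(out) + 1L]] <- V[okb, , drop = FALSE][oki, , drop = FALSE]
    }
    done <- done + take
  }
  res <- if (length(out)) do.call(rbind, out) else matrix(0, 0, N)
  colnames(res) <- net$reactions$id
  attr(res, "free_cols") <- free
  attr(res, "resolution") <- resolution
  res
}
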