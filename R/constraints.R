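# Von Neumann constraint assembly: S v >= 0 for every internal species,
# S v = 0 (mass balance) for the capillary nutrient species, bounds from the
# reversibility assignment, and the pinned capillary glucose uptake that sets
# the scale of the flux units.

#' Sampler configuration
#'
#' @param nu_max generic flux bound (flux units). This is an absolute bound
#'   held fixed across a glucose sweep; scaling it jointly with the glucose
#'   pin rescales the whole solution polytope.
#' @param epsilon feasibility tolerance on constraint residuals.
#' @param max_iter relaxation iteration cap per sample.
#' @param step relaxation gain in (0, 2).
#' @param seed integer seed; all per-sample seeds derive from it.
#' @param K number of samples requested.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(nu_max = 1, epsilon = 1e-9, max_iter = 1e5,
                           step = 1.0, seed = 1L, K = 1000L) {
  stopifnot(nu_max > 0, epsilon > 0, step > 0, step < 2, max_iter >= 1, K >= 1)
  structure(list(nu_max = nu_max, epsilon = epsilon,
                 max_iter = as.integer(max_iter), step = step,
                 seed = as.integer(seed), K = as.integer(K)),
            class = "sampler_config")
}

#' Assemble the constraint set for a fixed glucose uptake
#'
#' Builds inequality rows (`S v >= 0`) for every species except the capillary
#' nutrient intakes (glucose, oxygen), which get mass-balance equality rows;
#' pins the capillary glucose supply reaction to `glucose_level` (the oxygen
#' influx is always left free); and sets per-reaction bounds
#' `[0, nu_max]` (irreversible) or `[-nu_max, nu_max]` (reversible), scaled
#' by any per-reaction relative cap the network defines.
#'
#' @param net a `metabolic_network` whose `GLC_to_c` role resolves.
#' @param glucose_level positive pinned capillary glucose uptake.
#' @param nu_max generic flux bound.
#' @param glc_e_balance `"soft"` (default): extracellular glucose is an ordinary
#'   `S v >= 0` row, so it may be weakly net-produced; `"strict"`: its row is
#'   promoted to an equality, forcing the capillary-to-interstitium glucose
#'   flow to exactly match cellular uptake from the interstitium.
#' @return list of class `constraint_set` with `eq_rows`, `ineq_rows`
#'   (species indices), `pins` (named flux values), `lb`, `ub`.
#' @export
make_constraints <- function(net, glucose_level, nu_max = 1,
                             glc_e_balance = c("soft", "strict")) {
  glc_e_balance <- match.arg(glc_e_balance)
  stopifnot(inherits(net, "metabolic_network"), glucose_level > 0, nu_max > 0)
  pin_col <- role_column(net, "GLC_to_c")
  M <- nrow(net$S)
  eq <- which(net$species$is_intake)
  if (glc_e_balance == "strict") {
    gle <- which(net$species$id == "glc[e]")
    eq <- sort(union(eq, gle))
  }
  rel <- net$reactions$rel_ub
  if (is.null(rel)) rel <- rep(1, ncol(net$S))
  ub <- rel * nu_max
  lb <- ifelse(net$reactions$reversible, -ub, 0)
  pins <- setNames(glucose_level, net$reactions$id[pin_col])
  structure(list(eq_rows = eq, ineq_rows = setdiff(seq_len(M), eq),
                 pins = pins, lb = lb, ub = ub, glc_e_balance = glc_e_balance),
            class = "constraint_set")
}

cs_pin_cols <- function(net, cs) match(names(cs$pins), net$reactions$id)

#' Check feasibility of a flux vector
#'
#' @param net a `metabolic_network`.
#' @param nu flux vector (length N).
#' @param cs a [make_constraints()] object.
#' @param epsilon tolerance.
#' @return list with `feasible` (logical) and `max_violation` (the largest
#'   residual magnitude over inequality rows, equality rows, bounds and pins).
#' @export
check_feasibility <- function(net, nu, cs, epsilon = 1e-9) {
  p <- production_vector(net, nu)
  v_ineq <- if (length(cs$ineq_rows)) max(0, -min(p[cs$ineq_rows])) else 0
  v_eq <- if (length(cs$eq_rows)) max(abs(p[cs$eq_rows])) else 0
  v_bnd <- max(0, cs$lb - nu, nu - cs$ub)
  pc <- cs_pin_cols(net, cs)
  v_pin <- max(abs(nu[pc] - cs$pins))
  mv <- max(v_ineq, v_eq, v_bnd, v_pin)
  list(feasible = mv <= epsilon, max_violation = mv)
}

#' Draw flux vectors from the uncorrelated uniform prior
#'
#' Each component is drawn independently and uniformly within its bounds;
#' pinned components are set to their pinned values. Uses R's RNG stream
#' (seed the stream before calling for reproducibility).
#'
#' @param net a `metabolic_network`.
#' @param cs a [make_constraints()] object.
#' @param n number of draws.
#' @return n x N matrix of prior flux vectors.
#' @export
sample_prior <- function(net, cs, n = 1L) {
  N <- length(cs$lb)
  x <- matrix(runif(n * N), n, N)
  x <- sweep(sweep(x, 2, cs$ub - cs$lb, "*"), 2, cs$lb, "+")
  x[, cs_pin_cols(net, cs)] <- matrix(cs$pins, n, length(cs$pins), byrow = TRUE)
  colnames(x) <- net$reactions$id
  x
}

#' Relax a starting flux vector onto the solution polytope
#'
#' Agmon-Motzkin-Schoenberg scheme: at each iteration the most violated
#' species constraint is selected and the flux vector moves along that row's
#' normal (restricted to non-pinned components) by
#' `step * violation / ||row||^2`; components are re-clipped to their bounds
#' after every move and pinned components never change. Equality rows are
#' treated as two-sided violations. The result is deterministic given the
#' starting point and configuration.
#'
#' @param net a `metabolic_network`.
#' @param nu0 starting flux vector (single vector or n x N matrix of
#'   starting points; pins/bounds are imposed on entry).
#' @param cs a [make_constraints()] object.
#' @param config a [sampler_config()].
#' @return list with `nu` (matrix of relaxed vectors), `iterations`,
#'   `max_violation`, `converged` per starting point.
#' @export
relax <- function(net, nu0, cs, config = sampler_config()) {
  if (is.null(dim(nu0))) nu0 <- matrix(nu0, nrow = 1)
  stopifnot(ncol(nu0) == ncol(net$S))
  row_type <- integer(nrow(net$S)); row_type[cs$eq_rows] <- 1L
  pc <- cs_pin_cols(net, cs)
  nu0 <- pmin(pmax(nu0, matrix(cs$lb, nrow(nu0), ncol(nu0), byrow = TRUE)),
              matrix(cs$ub, nrow(nu0), ncol(nu0), byrow = TRUE))
  nu0[, pc] <- matrix(cs$pins, nrow(nu0), length(pc), byrow = TRUE)
  res <- relax_kernel(net$S, row_type, cs$lb, cs$ub, pc - 1L, nu0,
                      config$step, config$epsilon, config$max_iter)
  colnames(res$nu) <- net$reactions$id
  res
}

#' Sample an ensemble of feasible flux configurations
#'
#' Draws `config$K` independent starting points from the uniform prior (one
#' recorded sub-seed per sample), relaxes each onto the polytope, and keeps
#' the converged ones.
#'
#' @param net a `metabolic_network`.
#' @param cs a [make_constraints()] object.
#' @param config a [sampler_config()].
#' @return object of class `solution_ensemble`: `solutions` (K x N matrix of
#'   feasible flux vectors), `glucose_level`, `config`, `convergence`
#'   (iteration counts, residuals, number discarded), `seeds`.
#' @export
sample_ensemble <- function(net, cs, config = sampler_config()) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$K)
  # one prior draw per recorded sub-seed: exchangeable and reproducible
  N <- ncol(net$S)
  nu0 <- matrix(NA_real_, config$K, N)
  for (k in seq_len(config$K)) {
    set.seed(seeds[k])
    nu0[k, ] <- sample_prior(net, cs, 1L)
  }
  res <- relax(net, nu0, cs, config)
  ok <- res$converged
  if (sum(ok) < config$K / 2)
    stop("fewer than half of the prior draws converged (",
         sum(ok), "/", config$K, ")")
  structure(list(solutions = res$nu[ok, , drop = FALSE],
                 glucose_level = unname(cs$pins[1]),
                 config = config, seeds = seeds,
                 convergence = list(iterations = res$iterations[ok],
                                    max_violation = res$max_violation[ok],
                                    n_discarded = sum(!ok))),
            class = "solution_ensemble")
}

#' @export
print.solution_ensemble <- function(x, ...) {
  cat(sprintf(
    "solution_ensemble: %d feasible solutions x %d fluxes @ glucose pin %g\n",
    nrow(x$solutions), ncol(x$solutions), x$glucose_level))
  cat(sprintf("  discarded: %d | median iterations: %g\n",
              x$convergence$n_discarded,
              stats::median(x$convergence$iterations)))
  invisible(x)
}

#' Independent LP feasibility oracle
#'
#' Runs a linear-programming feasibility phase over the same constraint set
#' (via `pracma::linprog`) and returns one feasible point, or an
#' infeasibility certificate. Used to cross-check that the sampler and the
#' polytope agree on non-emptiness; it plays no part in sampling.
#'
#' @param net a `metabolic_network`.
#' @param cs a [make_constraints()] object.
#' @param objective optional linear objective over fluxes (default 0:
#'   pure feasibility).
#' @param maxiter simplex iteration cap.
#' @return list with `feasible` (logical), `nu` (a feasible flux vector or
#'   NULL), `message`.
#' @export
lp_feasible_point <- function(net, cs, objective = NULL, maxiter = 5000L) {
  S <- net$S; N <- ncol(S)
  pc <- cs_pin_cols(net, cs)
  lb <- cs$lb; ub <- cs$ub
  lb[pc] <- ub[pc] <- unname(cs$pins)
  # shift to x = nu - lb >= 0 (pracma::linprog works on x >= 0)
  A <- rbind(-S[cs$ineq_rows, , drop = FALSE],   # -S nu <= 0
             diag(N))                            # nu <= ub
  b <- c(drop(S[cs$ineq_rows, , drop = FALSE] %*% lb), ub - lb)
  Aeq <- S[cs$eq_rows, , drop = FALSE]
  beq <- drop(-Aeq %*% lb)
  cc <- if (is.null(objective)) rep(0, N) else objective
  res <- tryCatch(
    suppressWarnings(pracma::linprog(cc, A = A, b = b, Aeq = Aeq, beq = beq,
                                     maxiter = maxiter)),
    error = function(e) list(errno = -99, message = conditionMessage(e)))
  if (!is.null(res$errno) && res$errno == 1) {
    nu <- res$x + lb
    names(nu) <- net$reactions$id
    list(feasible = TRUE, nu = nu, message = res$message)
  } else {
    list(feasible = FALSE, nu = NULL,
         message = if (is.null(res$message)) "LP solver failure" else res$message)
  }
}
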