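# Per-solution observables (Eqs of the flux model): oxygen-to-glucose index,
# glutamate-glutamine cycle rate, neuronal oxidative glucose use, glucose
# partitioning, cell-to-cell lactate shuttle; plus conditional statistics and
# flux correlation structure over solution ensembles.

NULL_FLUX_THRESHOLD <- 1e-6   # numerical null-flux classification threshold

flux_at <- function(net, nu, role) {
  j <- role_column(net, role)
  unname(nu[j])
}

#' Oxygen-to-glucose index of one flux configuration
#'
#' OGI = CMRO2 / CMRGlc = nu_O2(->c) / nu_Glc(->c): the ratio of the oxygen
#' and glucose supply fluxes to the capillary. 6 is the stoichiometric
#' maximum for complete aerobic oxidation of glucose.
#'
#' @param nu flux vector.
#' @param net network with roles `GLC_to_c`, `O2_to_c`.
#' @return dimensionless ratio.
#' @export
compute_ogi <- function(nu, net) {
  g <- flux_at(net, nu, "GLC_to_c")
  if (g <= 0) stop("glucose intake is zero; OGI undefined")
  flux_at(net, nu, "O2_to_c") / g
}

#' Glutamate-glutamine cycle rate V_cyc
#'
#' Identified with the astrocytic glutamine synthetase flux.
#'
#' @param nu flux vector.
#' @param net network with role `GS_a`.
#' @return flux value.
#' @export
compute_vcyc <- function(nu, net) flux_at(net, nu, "GS_a")

#' Neuronal oxidative glucose metabolism
#'
#' Half the neuronal pyruvate dehydrogenase flux (glycolysis yields two
#' pyruvate per glucose, so PDH counts glucose equivalents twice).
#'
#' @param nu flux vector.
#' @param net network with role `PDH_n`.
#' @return flux value (glucose units).
#' @export
compute_cmr_glc_ox_n <- function(nu, net) 0.5 * flux_at(net, nu, "PDH_n")

#' Astrocytic share of total glucose uptake
#'
#' (nu_Glc(c->a) + nu_Glc(e->a)) / nu_Glc(->c). Routes a network does not
#' define (e.g. toy models with a single astrocytic route) contribute zero.
#'
#' @param nu flux vector.
#' @param net network.
#' @return fraction in `[0, 1]` (up to the feasibility tolerance).
#' @export
glucose_partition <- function(nu, net) {
  g <- flux_at(net, nu, "GLC_to_c")
  if (g <= 0) stop("glucose intake is zero; partition undefined")
  tot <- 0; found <- FALSE
  for (role in c("GLC_c_to_a", "GLC_e_to_a")) {
    j <- role_column(net, role, optional = TRUE)
    if (!is.na(j)) { tot <- tot + nu[j]; found <- TRUE }
  }
  if (!found) stop("no astrocytic glucose route resolved")
  unname(tot) / g
}

#' Net cell-to-cell lactate shuttle flux
#'
#' Positive values denote astrocyte-to-neuron transfer (ANLS), negative
#' neuron-to-astrocyte (NALS). With two reversible cellular lactate
#' transporters exchanging through the extracellular pool the astrocyte-side
#' net export and the neuron-side net import may differ by any net
#' extracellular lactate production; the astrocyte-side value is canonical.
#'
#' @param nu flux vector.
#' @param net network whose `LAC_a_to_n` role names either a single direct
#'   transfer reaction or the pair `c(astrocyte transporter, neuron
#'   transporter)`.
#' @param side `"astrocyte"` (default) or `"neuron"`.
#' @return signed flux.
#' @export
ccls_flux <- function(nu, net, side = c("astrocyte", "neuron")) {
  side <- match.arg(side)
  tgt <- net$role_index[["LAC_a_to_n"]]
  if (is.null(tgt)) stop("role 'LAC_a_to_n' is not resolved on this network")
  j <- match(tgt, net$reactions$id)
  if (length(j) == 1L) return(unname(nu[j]))
  # orient each transporter by the sign of its extracellular lactate
  # coefficient: +1 means the written direction exports to the e pool
  lac_e <- which(net$species$id == "lac[e]")
  sgn <- sign(net$S[lac_e, j])
  if (side == "astrocyte") unname(nu[j[1]] * sgn[1])
  else -unname(nu[j[2]] * sgn[2])
}

#' Classify a solution as active or silent
#'
#' Active means the glutamate-glutamine cycle runs above the numerical
#' null-flux threshold (strictly; a flux exactly at the threshold is null).
#'
#' @param nu flux vector.
#' @param net network.
#' @param theta null-flux threshold.
#' @return `"active"` or `"silent"`.
#' @export
classify_active <- function(nu, net, theta = NULL_FLUX_THRESHOLD) {
  if (compute_vcyc(nu, net) > theta) "active" else "silent"
}

cell_o2_consumption <- function(net, sols, cell) {
  # net enzymatic O2 consumption by reactions scoped to the cell
  # (transport columns excluded, so delivered-but-accumulated O2 not counted)
  o2_rows <- which(species_base(net$species$id) == "o2")
  cols <- which(net$reactions$cell_scope == cell &
                !(net$reactions$pathway %in% c("transport", "intake", "efflux")))
  if (!length(cols) || !length(o2_rows)) return(rep(0, nrow(sols)))
  W <- net$S[o2_rows, cols, drop = FALSE]
  -drop(sols[, cols, drop = FALSE] %*% colSums(W))
}

#' Per-solution observable records for an ensemble
#'
#' @param ens a `solution_ensemble`, or a plain solutions matrix (then
#'   `glucose_level` must be given).
#' @param net the network the ensemble was sampled from.
#' @param glucose_level pinned glucose uptake (taken from the ensemble if
#'   not supplied).
#' @param theta null-flux threshold for the active/silent split.
#' @return data.frame with one row per solution: `glucose_level`, `ogi`,
#'   `vcyc`, `cmr_glc_ox_n`, `astro_glc_fraction`, `lac_a_to_n` (astrocyte
#'   side), `lac_a_to_n_neuron_side`, `cmro2_n`, `cmro2_a`, `active`.
#' @export
observable_records <- function(ens, net, glucose_level = NULL,
                               theta = NULL_FLUX_THRESHOLD) {
  sols <- if (inherits(ens, "solution_ensemble")) ens$solutions else ens
  if (is.null(glucose_level))
    glucose_level <- if (inherits(ens, "solution_ensemble")) ens$glucose_level
                     else stop("glucose_level required for a plain matrix")
  g <- glucose_level
  col <- function(role) sols[, role_column(net, role)]
  col_opt <- function(role) {
    j <- role_column(net, role, optional = TRUE)
    if (is.na(j)) rep(NA_real_, nrow(sols)) else sols[, j]
  }
  tgt <- net$role_index[["LAC_a_to_n"]]
  if (is.null(tgt)) {
    lac_a <- lac_n <- rep(NA_real_, nrow(sols))
  } else {
    j <- match(tgt, net$reactions$id)
    if (length(j) == 2L) {
      lac_e <- which(net$species$id == "lac[e]")
      sgn <- sign(net$S[lac_e, j])
      lac_a <- sols[, j[1]] * sgn[1]
      lac_n <- -sols[, j[2]] * sgn[2]
    } else {
      lac_a <- lac_n <- sols[, j]
    }
  }
  astro_frac <- rep(0, nrow(sols))
  for (role in c("GLC_c_to_a", "GLC_e_to_a")) {
    jj <- role_column(net, role, optional = TRUE)
    if (!is.na(jj)) astro_frac <- astro_frac + sols[, jj]
  }
  vcyc <- col_opt("GS_a")
  data.frame(
    glucose_level = g,
    ogi = col("O2_to_c") / g,
    vcyc = vcyc,
    cmr_glc_ox_n = 0.5 * col_opt("PDH_n"),
    astro_glc_fraction = astro_frac / g,
    lac_a_to_n = lac_a,
    lac_a_to_n_neuron_side = lac_n,
    cmro2_n = cell_o2_consumption(net, sols, "neuron"),
    cmro2_a = cell_o2_consumption(net, sols, "astrocyte"),
    active = vcyc > theta)
}

select_condition <- function(records, condition) {
  switch(condition,
         all = rep(TRUE, nrow(records)),
         active = records$active,
         silent = !records$active,
         stop("unknown condition: ", condition))
}

#' Conditional average curve of one observable against another
#'
#' Bins records on `x_field` and reports per-bin means and standard errors
#' of `y_field` over the records meeting the condition (all solutions,
#' solutions with active glutamate-glutamine cycling, or silent solutions).
#'
#' @param records data.frame from [observable_records()] (levels may be
#'   pooled by row-binding).
#' @param x_field,y_field column names.
#' @param condition `"all"`, `"active"` or `"silent"`.
#' @param bins number of bins.
#' @param binning `"quantile"` (equal-count, default) or `"width"`.
#' @return data.frame of class `conditional_curve`: `x_center`, `y_mean`,
#'   `y_se`, `count`, with the condition stored as an attribute.
#' @export
conditional_average <- function(records, x_field, y_field,
                                condition = c("all", "active", "silent"),
                                bins = 20, binning = c("quantile", "width")) {
  condition <- match.arg(condition)
  binning <- match.arg(binning)
  sel <- select_condition(records, condition)
  if (!any(sel)) stop("no records meet condition '", condition, "'")
  x <- records[[x_field]][sel]; y <- records[[y_field]][sel]
  brk <- if (binning == "quantile") {
    unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  } else seq(min(x), max(x), length.out = bins + 1)
  if (length(brk) < 3) brk <- c(min(x) - 1e-12, max(x) + 1e-12)
  bin <- cut(x, breaks = brk, include.lowest = TRUE)
  agg <- function(v, f) as.numeric(tapply(v, bin, f))
  out <- data.frame(x_center = agg(x, mean),
                    y_mean = agg(y, mean),
                    y_se = agg(y, function(v) {
                      if (length(v) < 2) 0 else sd(v) / sqrt(length(v))
                    }),
                    count = agg(y, length))
  out <- out[!is.na(out$count) & out$count >= 1, ]
  attr(out, "condition") <- condition
  attr(out, "fields") <- c(x = x_field, y = y_field)
  class(out) <- c("conditional_curve", "data.frame")
  out
}

#' Two-regime slopes of a conditional curve
#'
#' Weighted least-squares lines fitted separately to the bins below and
#' above a breakpoint on the x axis (weights = bin counts).
#'
#' @param curve a [conditional_average()] result.
#' @param breakpoint_x regime boundary on the x axis.
#' @return list with `slope_low`, `slope_high`, `intercept_low`,
#'   `intercept_high`, `n_low`, `n_high`.
#' @export
piecewise_slopes <- function(curve, breakpoint_x) {
  lo <- curve$x_center < breakpoint_x
  if (sum(lo) < 2 || sum(!lo) < 2)
    stop("need at least 2 bins on each side of the breakpoint")
  fit <- function(d) {
    co <- coef(stats::lm(y_mean ~ x_center, data = d, weights = d$count))
    unname(co)
  }
  flo <- fit(curve[lo, ]); fhi <- fit(curve[!lo, ])
  list(slope_low = flo[2], slope_high = fhi[2],
       intercept_low = flo[1], intercept_high = fhi[1],
       n_low = sum(lo), n_high = sum(!lo))
}

#' Pearson correlation matrix over a conditioned solution subset
#'
#' Pearson coefficient for every reaction pair over the solutions meeting
#' the condition. Reactions whose flux magnitude stays below `theta` in
#' every conditioned solution, or whose flux has zero variance, are masked
#' (NA) rather than reported. Also summarizes the coefficients as three
#' histograms over within-neuron, within-astrocyte and between-cell pairs.
#'
#' @param ens ensemble, solutions matrix, or pooled matrix.
#' @param net the network.
#' @param condition `"all"`, `"active"` or `"silent"` (on V_cyc).
#' @param theta null-flux threshold.
#' @param breaks histogram breaks for the pair-class summaries.
#' @return list of class `correlation_matrix`: `values` (N x N), `null_mask`
#'   (logical per reaction), `condition`, `histograms` (per pair class),
#'   `pair_counts`.
#' @export
pearson_matrix <- function(ens, net, condition = c("all", "active", "silent"),
                           theta = NULL_FLUX_THRESHOLD,
                           breaks = seq(-1, 1, 0.1)) {
  condition <- match.arg(condition)
  sols <- if (inherits(ens, "solution_ensemble")) ens$solutions else ens
  sel <- if (condition == "all") rep(TRUE, nrow(sols)) else {
    vcyc <- sols[, role_column(net, "GS_a")]
    if (condition == "active") vcyc > theta else vcyc <= theta
  }
  if (sum(sel) < 10)
    stop("conditioned subset has fewer than 10 solutions (", sum(sel), ")")
  s <- sols[sel, , drop = FALSE]
  null_mask <- apply(abs(s), 2, max) < theta
  sdv <- apply(s, 2, sd)
  masked <- null_mask | sdv == 0
  vals <- matrix(NA_real_, ncol(s), ncol(s),
                 dimnames = list(net$reactions$id, net$reactions$id))
  if (any(!masked))
    vals[!masked, !masked] <- cor(s[, !masked, drop = FALSE])
  scope <- net$reactions$cell_scope
  pair_class <- function(a, b) {
    if (scope[a] == "neuron" && scope[b] == "neuron") return("neuron")
    if (scope[a] == "astrocyte" && scope[b] == "astrocyte") return("astrocyte")
    if ((scope[a] == "neuron" && scope[b] == "astrocyte") ||
        (scope[a] == "astrocyte" && scope[b] == "neuron")) return("between")
    "other"
  }
  idx <- which(!masked)
  cls <- list(neuron = numeric(0), astrocyte = numeric(0), between = numeric(0))
  if (length(idx) >= 2) {
    pr <- utils::combn(idx, 2)
    for (q in seq_len(ncol(pr))) {
      cl <- pair_class(pr[1, q], pr[2, q])
      if (cl != "other") cls[[cl]] <- c(cls[[cl]], vals[pr[1, q], pr[2, q]])
    }
  }
  hists <- lapply(cls, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) {
      mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
      return(data.frame(mid = mids, count = 0L, density = 0))
    }
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts,
               density = h$counts / max(1, length(v)))
  })
  structure(list(values = vals, null_mask = masked, condition = condition,
                 histograms = hists,
                 pair_counts = vapply(cls, length, 0L),
                 n_solutions = sum(sel)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix (condition: %s, %d solutions): %d x %d, %d masked\n",
              x$condition, x$n_solutions, nrow(x$values), ncol(x$values),
              sum(x$null_mask)))
  invisible(x)
}

#' Normalized histogram of per-solution OGI values
#'
#' @param ens ensemble or records data.frame with an `ogi` column.
#' @param net network (needed when `ens` is an ensemble).
#' @param binwidth histogram bin width on the OGI axis.
#' @return list: `histogram` (data.frame mid/density/count), `mean`, `se`, `n`.
#' @export
ogi_distribution <- function(ens, net = NULL, binwidth = 0.05) {
  ogi <- if (is.data.frame(ens)) ens$ogi
         else observable_records(ens, net)$ogi
  lo <- floor(min(ogi) / binwidth) * binwidth
  hi <- ceiling(max(ogi) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  h <- graphics::hist(ogi, breaks = seq(lo, hi, binwidth), plot = FALSE)
  list(histogram = data.frame(mid = h$mids, count = h$counts,
                              density = h$density * binwidth),
       mean = mean(ogi), se = sd(ogi) / sqrt(length(ogi)), n = length(ogi))
}

#' Calibrate the basal glucose uptake from a sweep
#'
#' Interpolates the glucose pin at which the ensemble-mean OGI equals the
#' awake-resting value (5.5); the activated level is 15% above basal.
#'
#' @param sweep data.frame with columns `glucose_level` and `mean_ogi`
#'   (one row per sweep level).
#' @param target resting-state OGI (default 5.5).
#' @param activation_factor activated / basal uptake ratio (default 1.15).
#' @return list with `g_basal`, `g_activated`, `target`.
#' @export
basal_calibration <- function(sweep, target = 5.5, activation_factor = 1.15) {
  o <- order(sweep$mean_ogi)
  g <- sweep$glucose_level[o]; ogi <- sweep$mean_ogi[o]
  if (min(ogi) > target || max(ogi) < target)
    stop("sweep does not bracket OGI = ", target)
  gb <- approx(ogi, g, xout = target, ties = "ordered")$y
  list(g_basal = unname(gb), g_activated = unname(gb) * activation_factor,
       target = target)
}
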