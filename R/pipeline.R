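# Study orchestration: sweep the pinned capillary glucose uptake, sample an
# ensemble per level, pool per-solution observables, calibrate the basal
# state on the OGI = 5.5 crossing, and emit the figure data tables.

#' Run a glucose-uptake sweep
#'
#' For each pinned glucose level: assembles the constraint set, samples a
#' solution ensemble, and computes per-solution observables. Pooled records
#' are row-bound across levels. Per-level seeds derive deterministically
#' from `seed`, so the whole bundle is a pure function of its arguments.
#'
#' @param net a `metabolic_network` (default: the brain reconstruction).
#' @param glucose_levels vector of pinned capillary glucose uptakes.
#' @param K samples per level.
#' @param nu_max generic flux bound (held fixed across the sweep so that
#'   larger uptakes probe relatively tighter polytopes).
#' @param seed master seed.
#' @param glc_e_balance extracellular-glucose balance mode (see [make_constraints()]).
#' @param max_iter relaxation iteration cap.
#' @param keep_solutions keep the raw ensembles in the result (memory).
#' @return object of class `sweep_result`: `levels` (per-level summary:
#'   glucose level, mean/se OGI, mean V_cyc, silent fraction, samples),
#'   `records` (pooled observable data.frame), `ensembles` (list or NULL),
#'   `manifest` (arguments, seeds, convergence statistics).
#' @export
run_sweep <- function(net = build_brain_network(), glucose_levels,
                      K = 1000, nu_max = 1, seed = 1L,
                      glc_e_balance = c("soft", "strict"), max_iter = 1e5,
                      keep_solutions = TRUE) {
  glc_e_balance <- match.arg(glc_e_balance)
  stopifnot(length(glucose_levels) >= 1, all(glucose_levels > 0), K >= 1)
  set.seed(seed)
  level_seeds <- sample.int(.Machine$integer.max - 1L, length(glucose_levels))
  ensembles <- list(); recs <- list(); summ <- list(); conv <- list()
  for (i in seq_along(glucose_levels)) {
    g <- glucose_levels[i]
    cs <- make_constraints(net, g, nu_max, glc_e_balance = glc_e_balance)
    cfg <- sampler_config(nu_max = nu_max, seed = level_seeds[i], K = K,
                          max_iter = max_iter)
    ens <- sample_ensemble(net, cs, cfg)
    r <- observable_records(ens, net)
    recs[[i]] <- r
    summ[[i]] <- data.frame(
      glucose_level = g,
      mean_ogi = mean(r$ogi), se_ogi = sd(r$ogi) / sqrt(nrow(r)),
      mean_vcyc = mean(r$vcyc),
      silent_fraction = mean(!r$active),
      n = nrow(r))
    conv[[i]] <- list(glucose_level = g, seed = level_seeds[i],
                      n_discarded = ens$convergence$n_discarded,
                      median_iterations = stats::median(ens$convergence$iterations))
    ensembles[[i]] <- if (keep_solutions) ens else NULL
  }
  structure(list(
    levels = do.call(rbind, summ),
    records = do.call(rbind, recs),
    ensembles = if (keep_solutions) ensembles else NULL,
    manifest = list(glucose_levels = glucose_levels, K = K, nu_max = nu_max,
                    seed = seed, level_seeds = level_seeds, glc_e_balance = glc_e_balance,
                    convergence = conv)),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d glucose levels, %d pooled solutions\n",
              nrow(x$levels), nrow(x$records)))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

pooled_solutions <- function(sweep) {
  if (is.null(sweep$ensembles))
    stop("sweep was run with keep_solutions = FALSE")
  do.call(rbind, lapply(sweep$ensembles, function(e) e$solutions))
}

#' Hand-constructed full-oxidation flux configuration
#'
#' Routes the whole pinned glucose uptake through glycolysis (via the
#' extracellular space into the neuron), pyruvate dehydrogenase, the TCA
#' cycle and oxidative phosphorylation to complete oxidation; cytosolic
#' NADH enters mitochondria through the malate-aspartate shuttle, and the
#' ATP yield is turned over by Na+/K+ channel fluxes balanced by the
#' Na/K-ATPase. Oxygen intake is set by stoichiometry (6 per glucose).
#'
#' @param net the brain network.
#' @param g pinned glucose uptake.
#' @param p_o_nadh,p_o_fadh2 P/O ratios matching the network build.
#' @return named flux vector.
#' @export
full_oxidation_flux <- function(net, g = 1, p_o_nadh = 2.5, p_o_fadh2 = 1.5) {
  nu <- setNames(rep(0, ncol(net$S)), net$reactions$id)
  set <- function(id, v) nu[id] <<- v
  set("GLC_in", g); set("GLC_c_e", g); set("GLC_e_n", g)
  for (r in c("HK", "PGI", "PFK", "ALD", "TPI")) set(paste0(r, "_n"), g)
  set("TPI_n", g)
  for (r in c("GAPDH", "ENO", "PK")) set(paste0(r, "_n"), 2 * g)
  set("PYRt_n", 2 * g); set("PDH_n", 2 * g)
  for (r in c("CS", "IDH", "AKGDH", "SDH")) set(paste0(r, "_n"), 2 * g)
  # malate-aspartate shuttle moves the 2 glycolytic NADH into mitochondria;
  # mitochondrial MDH carries TCA malate plus the shuttle malate
  set("MDHm_n", 4 * g)
  for (r in c("MDHc", "OGC", "AATc", "AATm", "AGC")) set(paste0(r, "_n"), 2 * g)
  nadh_m <- 10 * g   # PDH 2 + IDH 2 + AKGDH 2 + MDHm 2 + shuttle 2
  fadh_m <- 2 * g    # SDH
  set("OPN_n", nadh_m); set("OPF_n", fadh_m)
  o2 <- 0.5 * (nadh_m + fadh_m)
  set("O2_in", o2); set("O2_c_n", o2)
  set("CO2t_n", 6 * g); set("CO2_out", 6 * g)
  # ATP balance: net yield cycled through Na+/K+ fluxes and the pump
  atp <- 2 * g + 2 * g + 2 * g + p_o_nadh * nadh_m + p_o_fadh2 * fadh_m - 2 * g
  set("NaK_n", atp); set("NaC", 3 * atp); set("KC", 2 * atp)
  nu
}

#' Reproduce the study's headline analyses
#'
#' Runs the full workflow: a calibration sweep locating the basal glucose
#' uptake (ensemble-mean OGI = 5.5), a refined sweep spanning basal and
#' activated (+15%) conditions, pooled observable records, and every
#' headline quantity: the full-oxidation OGI check, the activated-state
#' mean OGI, the astrocytic share of oxidative metabolism, the glucose
#' partitioning at which the lactate shuttle reverses, the gain of the
#' basal glutamate-glutamine cycle rate under active-only conditioning,
#' and the low-activity slope of neuronal oxidative glucose versus V_cyc.
#'
#' @param net brain network.
#' @param seed master seed.
#' @param g0 initial guess for the basal glucose uptake.
#' @param nu_max generic flux bound (fixed across the sweep).
#' @param K_calibration samples per level in the calibration sweep.
#' @param K samples per level in the refined sweep.
#' @param glc_e_balance extracellular-glucose balance mode.
#' @param bins bins for conditional curves.
#' @return list of class `study_report`: `calibration`, `sweep` (refined
#'   sweep summary), `quantities` (named list of computed headline values),
#'   `curves`.
#' @export
reproduce_study <- function(net = build_brain_network(), seed = 1L,
                            g0 = 0.1, nu_max = 1,
                            K_calibration = 1500, K = 4000,
                            glc_e_balance = c("soft", "strict"), bins = 20) {
  glc_e_balance <- match.arg(glc_e_balance)

  ## full-oxidation identity (analytic configuration)
  nu_ox <- full_oxidation_flux(net, g = 1)
  cs_ox <- make_constraints(net, 1, nu_max = 2 * max(nu_ox))
  chk <- check_feasibility(net, nu_ox, cs_ox, epsilon = 1e-9)
  if (!chk$feasible)
    stop("full-oxidation configuration infeasible (violation ",
         chk$max_violation, ")")
  ogi_full_ox <- compute_ogi(nu_ox, net)

  ## calibration sweep: log-spaced levels bracket the OGI = 5.5 crossing
  cal_levels <- g0 * exp(seq(log(0.5), log(2.4), length.out = 6))
  cal <- run_sweep(net, cal_levels, K = K_calibration, nu_max = nu_max,
                   seed = seed, glc_e_balance = glc_e_balance, keep_solutions = FALSE)
  calib <- basal_calibration(cal$levels)

  ## refined sweep spanning basal and activated states
  g_star <- calib$g_basal
  factors <- c(0.55, 0.75, 0.9, 1.0, 1.15, 1.35, 1.7)
  sweep <- run_sweep(net, g_star * factors, K = K, nu_max = nu_max,
                     seed = seed + 1L, glc_e_balance = glc_e_balance, keep_solutions = FALSE)
  rec <- sweep$records

  ## activated-state mean OGI (level at 1.15 x basal)
  i_act <- which.min(abs(sweep$levels$glucose_level - 1.15 * g_star))
  mean_ogi_activated <- sweep$levels$mean_ogi[i_act]

  ## astrocytic share of oxidative metabolism, pooled
  tot_o2 <- rec$cmro2_a + rec$cmro2_n
  ok <- tot_o2 > NULL_FLUX_THRESHOLD
  astro_ox_share_pct <- 100 * mean(rec$cmro2_a[ok] / tot_o2[ok])

  ## lactate-shuttle reversal point on the glucose-partition axis
  part_curve <- conditional_average(
    transform(rec, lac_norm = lac_a_to_n / glucose_level),
    "astro_glc_fraction", "lac_norm", condition = "all",
    bins = bins, binning = "width")
  o <- order(part_curve$x_center)
  anls_crossing_pct <- 100 * approx(part_curve$y_mean[o],
                                    part_curve$x_center[o], xout = 0,
                                    ties = "ordered")$y

  ## V_cyc-vs-OGI conditional curves; value at the awake resting state
  cv_all <- conditional_average(rec, "ogi", "vcyc", "all", bins = bins)
  cv_act <- conditional_average(rec, "ogi", "vcyc", "active", bins = bins)
  v_at <- function(curve) {
    o <- order(curve$x_center)
    approx(curve$x_center[o], curve$y_mean[o], xout = 5.5, ties = "ordered")$y
  }
  vcyc_basal_all <- v_at(cv_all)
  vcyc_basal_active <- v_at(cv_act)
  vcyc_restriction_pct <- 100 * (vcyc_basal_active / vcyc_basal_all - 1)

  ## neuronal oxidative glucose vs V_cyc: low-activity slope (active set)
  rec_a <- rec[rec$active, ]
  ogi_vs_vcyc <- conditional_average(rec_a, "vcyc", "ogi", "all", bins = bins)
  oo <- order(ogi_vs_vcyc$x_center)
  vcyc_break <- approx(ogi_vs_vcyc$y_mean[oo], ogi_vs_vcyc$x_center[oo],
                       xout = 5.5, ties = "ordered")$y
  if (is.na(vcyc_break)) vcyc_break <- vcyc_basal_active
  cmr_curve <- conditional_average(rec_a, "vcyc", "cmr_glc_ox_n", "all",
                                   bins = bins)
  slopes <- piecewise_slopes(cmr_curve, vcyc_break)

  structure(list(
    calibration = c(calib, list(sweep = cal$levels)),
    sweep = sweep$levels,
    quantities = list(
      ogi_full_oxidation = ogi_full_ox,
      mean_ogi_activated = mean_ogi_activated,
      astro_oxidative_share_pct = astro_ox_share_pct,
      anls_crossing_pct = anls_crossing_pct,
      vcyc_basal_all = vcyc_basal_all,
      vcyc_basal_active = vcyc_basal_active,
      vcyc_restriction_increase_pct = vcyc_restriction_pct,
      cmr_vs_vcyc_slope_low = slopes$slope_low,
      cmr_vs_vcyc_slope_high = slopes$slope_high,
      vcyc_breakpoint = vcyc_break),
    curves = list(vcyc_vs_ogi_all = cv_all, vcyc_vs_ogi_active = cv_act,
                  cmr_vs_vcyc_active = cmr_curve,
                  lac_vs_partition = part_curve),
    records = rec,
    n_pooled = nrow(rec)),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  cat(sprintf("  basal glucose uptake g* = %.4f (mean OGI = %.1f), activated = %.4f\n",
              x$calibration$g_basal, x$calibration$target,
              x$calibration$g_activated))
  q <- x$quantities
  cat(sprintf("  OGI of full oxidation: %g\n", q$ogi_full_oxidation))
  cat(sprintf("  mean OGI at +15%% glucose: %.2f\n", q$mean_ogi_activated))
  cat(sprintf("  astrocytic oxidative share: %.1f%%\n",
              q$astro_oxidative_share_pct))
  cat(sprintf("  lactate shuttle reverses at astro glucose share: %.1f%%\n",
              q$anls_crossing_pct))
  cat(sprintf("  V_cyc at OGI 5.5: %.4f (all) vs %.4f (active): +%.1f%%\n",
              q$vcyc_basal_all, q$vcyc_basal_active,
              q$vcyc_restriction_increase_pct))
  cat(sprintf("  CMR_Glc(ox)(n) vs V_cyc slopes: %.3f (low), %.3f (high)\n",
              q$cmr_vs_vcyc_slope_low, q$cmr_vs_vcyc_slope_high))
  invisible(x)
}

#' Write the per-figure data tables for a sweep
#'
#' Emits `fig2_hist.tsv` (OGI histograms per glucose level),
#' `fig3_matrix.tsv` and `fig3_hist.tsv` (flux correlation structure under
#' silent/active conditioning), `fig4_curve.tsv` (conditional V_cyc vs OGI),
#' `fig5_curve.tsv` (conditional neuronal oxidative glucose vs V_cyc),
#' `fig6_scatter.tsv` (lactate shuttle vs glucose partitioning),
#' `fig7_scatter.tsv` (shuttle and partitioning vs V_cyc) and
#' `manifest.json`.
#'
#' @param sweep a [run_sweep()] result with solutions kept.
#' @param net the network.
#' @param dir output directory (created if needed).
#' @param bins bins for conditional curves.
#' @return `dir`, invisibly.
#' @export
write_figure_tables <- function(sweep, net, dir, bins = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- sweep$records
  wt <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)

  h2 <- do.call(rbind, lapply(split(rec, rec$glucose_level), function(r) {
    h <- ogi_distribution(r)
    data.frame(glucose_level = r$glucose_level[1], ogi_bin = h$histogram$mid,
               probability = h$histogram$count / sum(h$histogram$count))
  }))
  wt(h2, "fig2_hist.tsv")

  pooled <- pooled_solutions(sweep)
  mats <- list()
  for (cond in c("silent", "active")) {
    cm <- tryCatch(pearson_matrix(pooled, net, cond),
                   error = function(e) NULL)
    if (is.null(cm)) next
    v <- cm$values
    long <- data.frame(condition = cond,
                       reaction_i = rep(rownames(v), ncol(v)),
                       reaction_j = rep(colnames(v), each = nrow(v)),
                       r = as.vector(v))
    mats[[cond]] <- long[!is.na(long$r), ]
  }
  if (length(mats)) wt(do.call(rbind, mats), "fig3_matrix.tsv")
  hl <- list()
  for (cond in names(mats)) {
    cm <- pearson_matrix(pooled, net, cond)
    for (cls in names(cm$histograms)) {
      h <- cm$histograms[[cls]]
      if (nrow(h))
        hl[[paste(cond, cls)]] <- data.frame(condition = cond,
                                             pair_class = cls, h)
    }
  }
  if (length(hl)) wt(do.call(rbind, hl), "fig3_hist.tsv")

  c4 <- rbind(data.frame(condition = "all",
                         conditional_average(rec, "ogi", "vcyc", "all", bins)),
              data.frame(condition = "active",
                         conditional_average(rec, "ogi", "vcyc", "active", bins)))
  wt(c4, "fig4_curve.tsv")

  c5 <- rbind(data.frame(condition = "all",
                         conditional_average(rec, "vcyc", "cmr_glc_ox_n", "all", bins)),
              data.frame(condition = "active",
                         conditional_average(rec, "vcyc", "cmr_glc_ox_n", "active", bins)))
  wt(c5, "fig5_curve.tsv")

  wt(rec[, c("glucose_level", "astro_glc_fraction", "lac_a_to_n", "vcyc")],
     "fig6_scatter.tsv")
  wt(rec[, c("glucose_level", "vcyc", "lac_a_to_n", "astro_glc_fraction")],
     "fig7_scatter.tsv")

  jsonlite::write_json(sweep$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
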