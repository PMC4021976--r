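---
title: "Constraint-based modeling of neuron-astrocyte energy metabolism with brainflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of neuron-astrocyte energy metabolism with brainflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainflux)
```

## The model

brainflux studies the stationary energetics of the metabolic partnership
between glutamatergic neurons and astrocytes. The system is represented as a
stoichiometric network over four compartments — blood capillary (c),
extracellular/interstitial space (e), neuron and astrocyte, the cells further
split into cytosol (nc, ac), mitochondria (nm, am) and, for the neuron,
synaptic vesicles (nv). Fluxes $\nu$ over the $N$ reactions act on the $M$
species through the stoichiometric matrix $S$. Rather than full flux balance
($S\nu = b$), the feasible set follows a Von Neumann production-network
scheme:

* $ (S\nu)_m \ge 0$ for every internal species $m$ — net production is
  allowed (it stands in for drains into pathways outside the reconstruction),
  net consumption is not;
* $(S\nu)_m = 0$ for the capillary nutrient species (glucose, oxygen) — what
  enters the capillary is passed on;
* reversibility bounds per reaction, and a *pinned* capillary glucose supply
  $\nu_{Glc(\to c)} = g$ that sets the flux scale. The oxygen supply is never
  pinned.

An important and deliberate consequence of the inequality scheme is that
conserved-moiety pairs (ATP/ADP, NAD(H), NADP(H), FAD(H$_2$),
creatine/phosphocreatine) are forced to exact balance: since the paired rows
are (near-)opposite, $\ge 0$ on both sides pins net interconversion to zero.
ATP production must therefore be spent by the functional machinery — ion
pumping, glutamine synthesis, vesicle loading, biosynthesis — which is what
couples oxidative metabolism to signaling in this model. For the same reason
the reconstruction contains **no** generic ATP "maintenance" sink: one would
silently decouple respiration from function.

## The reconstruction

`build_brain_network()` assembles the network at pathway level:
stepwise glycolysis (with GAPDH+PGK and PGM+enolase as near-equilibrium
lumps) and reversible LDH in both cells; the pentose phosphate shunt as an
oxidative lump (2 NADPH + CO$_2$ per G6P) plus a reversible non-oxidative
return; pyruvate import, PDH, a full TCA cycle (aconitase+IDH,
AKG-dehydrogenase+succinyl-CoA synthetase, SDH+fumarase lumped) and
oxidative phosphorylation lumped per cofactor with configurable P/O ratios
(defaults 2.5 for NADH, 1.5 for FADH$_2$, the modern consensus); a separate
mitochondrial ROS reaction producing H$_2$O$_2$, capped at a small fraction
(default 0.10) of the generic flux bound so that peroxide detoxification
drives a plausible pentose-phosphate share; malate–aspartate and
glycerol-3-phosphate shuttles; pyruvate carboxylase and glycogen cycling in
the astrocyte only; malic enzyme in both cells; the complete
glutamate–glutamine cycle (vesicular loading at 1 ATP, release, astrocytic
uptake with 3 Na$^+$ co- / 1 K$^+$ counter-transport, glutamine synthetase
at 1 ATP, glutamine return, neuronal glutaminase, ammonium recycling, GDH);
neuronal Na$^+$/K$^+$ channels, the astrocytic Na–K cotransporter (1:1) and
the 3 Na$^+$ : 2 K$^+$ : 1 ATP pump in both cells; creatine and adenylate
kinase buffering; and a glutathione/ascorbate antioxidant system whose
synthesis (2 ATP) and cystine supply are astrocytic, with a lumped
glutathione transfer route astrocyte $\to$ e $\to$ neuron.

Glucose reaches astrocytes directly from the capillary (basal lamina) or via
the interstitium; neurons only via the interstitium. Oxygen diffuses from
capillary to either cell; lactate is exchanged between the cells through the
extracellular pool only (no capillary lactate exchange). Cells never share a
reaction: all coupling passes through e or c.

Some standard reactions the source text does not name explicitly are
included for completeness and to keep the system under-determined
($N > M$): aspartate exchange through the interstitium, catalase, an
NADPH-dependent dehydroascorbate reductase, peroxiporin-like H$_2$O$_2$
diffusion, and creatine transporters. None carries an energy coupling that
could substitute for the pathways above. The default build has
`r ncol(build_brain_network()$S)` reactions over
`r nrow(build_brain_network()$S)` species.

**Tracked elements.** The elemental audit (`carbon_balance_check()`) tracks
substrate skeleton carbons and nitrogens. Conserved cofactor moieties
(adenine nucleotides, NAD(P), FAD, the CoA/acetyl carrier, creatine) count
zero carbons, and glutathione counts its Glu+Cys skeleton (8 C, 2 N) with
the glycine residue part of the untracked moiety; water, protons and
inorganic phosphate are not balanced. Every coefficient in the build is a
dyadic rational, hence exact in double precision; audits are drift-free.

**Reversibility.** Transports of lactate, ascorbate/dehydroascorbate,
ammonium, aspartate and creatine, the malate–aspartate shuttle carriers,
LDH, both MDHs, the aminotransferases, GDH, adenylate and creatine kinase,
and the near-equilibrium glycolytic steps are reversible; kinase steps,
PDH, the TCA decarboxylations, glutamine synthetase, pumps, channels,
vesicle operations and intakes are irreversible. The TSV export records
every assignment.

## Sampling the solution polytope

Statistics are taken over feasible flux configurations sampled by a
prior-seeded relaxation (`sample_ensemble()`):

1. draw a starting point from *uncorrelated uniform priors* over the bounds,
   pinned components fixed;
2. repeatedly select the most violated species constraint and move along its
   normal (restricted to free components) by
   `step × violation / ‖row‖²` (Agmon–Motzkin–Schoenberg), re-clipping to
   bounds after every move;
3. because conserved-moiety rows and long transport chains are nearly
   parallel, the pure scheme zigzags; the kernel therefore periodically
   applies a joint minimum-norm correction that zeroes all currently
   violated rows while holding the currently tight rows tight (an
   active-set-aware block version of the same violated-constraint
   correction). The final residual is recomputed exactly.

Convergence is declared at residual $\le \varepsilon = 10^{-9}$ (distinct
from the $10^{-6}$ null-flux threshold used downstream to classify a flux
as zero). Non-converged draws are discarded, not repaired. Per-sample seeds
are drawn once from the configuration seed and recorded, so ensembles are
exchangeable and exactly reproducible. `lp_feasible_point()` provides an
independent linear-programming oracle for non-emptiness, and
`brute_force_polytope()` grid-enumerates small polytopes.

The sampler minimizes the distance travelled from each prior draw, so its
measure is the prior pushed onto the polytope, not the uniform measure on
it. On a single segment it *is* the orthogonal projection (tested to
closed form); on higher-dimensional toys small systematic deviations of
per-flux means from uniform-polytope means are expected and are measured
against the grid oracle in the test suite. All ensemble statistics in this
package are therefore statements about this explicitly specified sampling
measure.

**Flux units and bounds.** The glucose pin sets the scale. The generic
bound `nu_max` is an *absolute* cap (default 1, i.e. ten times the default
basal-uptake guess `g0 = 0.1`), deliberately held fixed across a glucose
sweep: scaling `nu_max` jointly with the pin rescales the whole polytope
(scale covariance, tested), so only a fixed cap lets increasing uptake
probe relatively tighter oxidative capacity — which is what produces the
declining mean OGI across the sweep.

## Observables and calibration

Per solution: the oxygen–glucose index $OGI = \nu_{O_2(\to c)}/\nu_{Glc(\to
c)}$ (6 = complete oxidation); the glutamate–glutamine cycle rate $V_{cyc}
= \nu_{GS(a)}$; neuronal oxidative glucose use $CMR_{Glc(ox)}^{(n)} =
\tfrac12 \nu_{PDH(n)}$; the astrocytic glucose share $(\nu_{Glc(c\to a)} +
\nu_{Glc(e\to a)})/\nu_{Glc(\to c)}$; and the cell-to-cell lactate shuttle,
reported on the astrocyte side (positive = astrocyte-to-neuron), with the
neuron-side value stored alongside since the extracellular pool may be
weakly net-produced. Per-cell oxygen consumption sums the O$_2$-consuming
enzymatic fluxes of that cell (transports excluded).

A solution is *active* when $V_{cyc} > 10^{-6}$, *silent* otherwise
(strict inequality). Conditional curves bin records on one observable
(20 equal-count bins by default; OGI histograms use fixed 0.05-wide bins)
and report per-bin means with standard errors ($s/\sqrt{n}$). Correlation
matrices are Pearson coefficients per reaction pair over a conditioned
subset, with reactions that stay below the null threshold masked, and are
summarized as within-neuron / within-astrocyte / between-cell histograms.
Sweep-level statistics pool solutions across all glucose levels; OGI
histograms stay per-level.

The *basal* state is calibrated by interpolating the sweep level at which
the ensemble-mean OGI equals 5.5 (the awake resting value); the *activated*
state is 15% above basal. `reproduce_study()` chains calibration
(6 log-spaced levels over 0.5–2.4× the initial guess), a refined sweep
(factors 0.55–1.7× basal including the activated level), and all headline
quantities. The extracellular-glucose balance can be treated as a soft
inequality (default: the interstitium may weakly accumulate glucose) or
pinned to strict equality (`glc_e_balance = "strict"`); both modes are reported by
the acceptance script.

## Synthetic benchmarks

`make_chain()`, `make_diamond()`, `make_minibrain()` and
`make_random_network()` generate networks whose polytopes are known in
closed form or enumerable: the chain's feasible set is "pinned intake,
non-increasing flux"; the minibrain is a two-cell caricature whose 6:1
oxidation stoichiometry makes the fully oxidative corner sit exactly at
OGI 6 and whose lactate-exchange sign is forced by the glucose-share /
oxidation imbalance. They emulate the structural features the analysis
relies on (pinned intake, internal $S\nu \ge 0$, reversible exchange,
intake equality rows) but none of the brain network's pathway richness,
moiety coupling density, or its ion-flux energetics — so passing toy
oracles validates the sampler and the observable plumbing, not the
physiology of the reconstruction.

## Problem sizes and numerical choices

Default test-suite runs use 150–10,000 samples per condition; the bundled
acceptance script uses 1,200 samples per calibration level and 3,000 per
refined-sweep level (seven levels), which keeps standard errors of
ensemble means near the percent level on a single CPU. Relaxation uses
step 1.0, an iteration cap of $10^5$, block corrections every 50
iterations (every iteration once the worst violation is below $10^{-3}$),
and a $10^{-12}$-regularized Gram solve. Equality rows are handled as
two-sided violations; pins by variable elimination. Degenerate inputs
(zero-variance fluxes in correlations, empty conditioning subsets, sweeps
that do not bracket OGI 5.5) raise or mask explicitly rather than
propagating NaN.

## Known limitations

* The reconstruction is a pathway-level rebuild from the published
  description, not the original reaction list; reaction counts and some
  secondary stoichiometries (Na–K cotransport, ascorbate cycle, CO$_2$
  routing, glutaminase localization) follow documented conventions rather
  than a deposited model. Quantities that depend on the fine split of ionic
  ATP demand between the cell types (the astrocytic share of oxidative
  metabolism, the exact lactate-shuttle reversal point) inherit this
  uncertainty.
* Ensemble statistics depend on the sampling measure. The relaxation
  sampler concentrates less mass on the $V_{cyc}=0$ face and disperses
  $V_{cyc}$ more within a glucose level than samplers that pile mass near
  zero flux; conditional statistics that contrast active against silent
  solutions, or read slopes off pooled conditional curves, are sensitive
  to exactly this.
* The model is stationary: no kinetics, no regulation, no link from
  neurotransmission to channel fluxes (channel priors are independent of
  $V_{cyc}$), no consumption of pre-stored glycogen, no
  alanine/ammonia shuttle, no nucleotide or amino-acid biosynthesis.

## A minimal session

```{r example, eval = FALSE}
net <- build_brain_network()
cs <- make_constraints(net, glucose_level = 0.15, nu_max = 1)
ens <- sample_ensemble(net, cs, sampler_config(seed = 1, K = 2000))
rec <- observable_records(ens, net)
summary(rec$ogi); mean(rec$vcyc)

sw <- run_sweep(net, glucose_levels = c(0.08, 0.12, 0.16, 0.22),
                K = 2000, seed = 1)
basal_calibration(sw$levels)
```
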