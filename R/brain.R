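# Four-compartment neuron-astrocyte reconstruction.
#
# Compartment codes: c capillary, e extracellular, nc/nm/nv neuron cytosol /
# mitochondria / synaptic vesicles, ac/am astrocyte cytosol / mitochondria.
# Cells interact only through e and c (no direct nc<->ac coupling).
# Adenylate, NAD(P)H and CO2 pools of mitochondria are lumped with the cell
# cytosol (the shuttles that matter for the flux balance - MAS, G3P - act on
# the NAD pools, which are kept separate per sub-compartment).

#' Build the brain metabolic network
#'
#' Reconstructs the neuron-astrocyte-extracellular-capillary stoichiometric
#' network at pathway level: capillary glucose/oxygen intakes and CO2 efflux,
#' the four glucose routes (c->a, c->e, e->a, e->n; neurons are reached via
#' the extracellular space only), stepwise glycolysis with reversible LDH and
#' lactate transport in both cells, the pentose phosphate shunt, pyruvate
#' import + PDH + TCA cycle + lumped oxidative phosphorylation with ROS side
#' production, malate-aspartate and glycerol-3-phosphate shuttles, astrocytic
#' pyruvate carboxylase and glycogen, malic enzyme in both cells, the full
#' glutamate-glutamine cycle (vesicular loading at 1 ATP, release, astrocytic
#' 3 Na+/1 K+ coupled uptake, glutamine synthetase at 1 ATP, glutamine return,
#' neuronal glutaminase), Na+/K+ machinery (neuronal channels, astrocytic
#' Na-K cotransport, 3:2 Na/K-ATPase), creatine/adenylate kinase buffering,
#' and the glutathione/ascorbate antioxidant system (synthesis and cystine
#' uptake in astrocytes only).
#'
#' @param glycogen include astrocytic glycogen synthesis/degradation.
#' @param antioxidant include the glutathione/ascorbate detoxification system.
#' @param g3p_shuttle include the glycerol-3-phosphate shuttle.
#' @param p_o_nadh,p_o_fadh2 P/O ratios of the lumped oxidative
#'   phosphorylation reactions (ATP per NADH / FADH2 oxidized).
#' @param ros_fraction relative cap of the mitochondrial ROS-producing
#'   reaction (fraction of the generic flux bound `nu_max`), sized so that
#'   peroxide detoxification routes a plausible share of glucose through the
#'   pentose phosphate pathway.
#' @return a [metabolic_network()] with the eleven named roles resolved
#'   (`GS_a`, `PDH_n`, `GLC_to_c`, `O2_to_c`, `GLC_c_to_a`, `GLC_c_to_e`,
#'   `GLC_e_to_a`, `GLC_e_to_n`, `O2_c_to_a`, `O2_c_to_n`, `LAC_a_to_n`).
#' @examples
#' net <- build_brain_network()
#' net
#' nrow(carbon_balance_check(net)$violations)  # 0
#' @export
build_brain_network <- function(glycogen = TRUE, antioxidant = TRUE,
                                g3p_shuttle = TRUE,
                                p_o_nadh = 2.5, p_o_fadh2 = 1.5,
                                ros_fraction = 0.10) {
  rx <- list()
  add <- function(...) rx[[length(rx) + 1L]] <<- rxn(...)

  ## -- exchange with the environment -----------------------------------
  add("GLC_in", "-> glc[c]", pathway = "intake", scope = "capillary",
      name = "glucose supply to capillary")
  add("O2_in", "-> o2[c]", pathway = "intake", scope = "capillary",
      name = "oxygen supply to capillary")
  add("CO2_out", "co2[c] ->", pathway = "efflux", scope = "capillary",
      name = "CO2 efflux from capillary")
  add("GLC_c_e", "glc[c] -> glc[e]", pathway = "transport",
      name = "glucose diffusion capillary -> extracellular")

  ## -- per-cell core carbon machinery ----------------------------------
  for (s in c("n", "a")) {
    cc <- paste0(s, "c"); mm <- paste0(s, "m")
    scope <- if (s == "n") "neuron" else "astrocyte"
    p <- function(tpl) {            # substitute compartment placeholders
      tpl <- gsub("CC", cc, tpl, fixed = TRUE)
      gsub("MM", mm, tpl, fixed = TRUE)
    }
    a2 <- function(id, tpl, ...) add(paste0(id, "_", s), p(tpl), scope = scope, ...)

    # glycolysis (GAPDH lumped with PGK, PGM with enolase)
    a2("HK",   "glc[CC] + atp[CC] -> g6p[CC] + adp[CC]",
       pathway = "glycolysis", name = "hexokinase")
    a2("PGI",  "g6p[CC] -> f6p[CC]", rev = TRUE, pathway = "glycolysis",
       name = "phosphoglucose isomerase")
    a2("PFK",  "f6p[CC] + atp[CC] -> fbp[CC] + adp[CC]",
       pathway = "glycolysis", name = "phosphofructokinase")
    a2("ALD",  "fbp[CC] -> dhap[CC] + gap[CC]", rev = TRUE,
       pathway = "glycolysis", name = "aldolase")
    a2("TPI",  "dhap[CC] -> gap[CC]", rev = TRUE, pathway = "glycolysis",
       name = "triose phosphate isomerase")
    a2("GAPDH", "gap[CC] + nad[CC] + adp[CC] -> pg3[CC] + nadh[CC] + atp[CC]",
       rev = TRUE, pathway = "glycolysis", name = "GAPDH + phosphoglycerate kinase")
    a2("ENO",  "pg3[CC] -> pep[CC]", rev = TRUE, pathway = "glycolysis",
       name = "phosphoglycerate mutase + enolase")
    a2("PK",   "pep[CC] + adp[CC] -> pyr[CC] + atp[CC]",
       pathway = "glycolysis", name = "pyruvate kinase")
    a2("LDH",  "pyr[CC] + nadh[CC] -> lac[CC] + nad[CC]", rev = TRUE,
       pathway = "glycolysis", name = "lactate dehydrogenase")

    # pentose phosphate shunt
    a2("G6PD", "g6p[CC] + 2 nadp[CC] -> ru5p[CC] + co2[CC] + 2 nadph[CC]",
       pathway = "ppp", name = "oxidative PPP branch (lumped)")
    a2("PPPne", "3 ru5p[CC] -> 2 f6p[CC] + gap[CC]", rev = TRUE,
       pathway = "ppp", name = "non-oxidative PPP return (lumped)")

    # pyruvate oxidation and TCA cycle
    a2("PYRt", "pyr[CC] -> pyr[MM]", pathway = "transport",
       name = "mitochondrial pyruvate carrier")
    a2("PDH",  "pyr[MM] + nad[MM] -> ace[MM] + co2[CC] + nadh[MM]",
       pathway = "tca", name = "pyruvate dehydrogenase")
    a2("CS",   "ace[MM] + oaa[MM] -> cit[MM]", pathway = "tca",
       name = "citrate synthase")
    a2("IDH",  "cit[MM] + nad[MM] -> akg[MM] + co2[CC] + nadh[MM]",
       pathway = "tca", name = "aconitase + isocitrate dehydrogenase")
    a2("AKGDH", "akg[MM] + nad[MM] + adp[CC] -> suc[MM] + co2[CC] + nadh[MM] + atp[CC]",
       pathway = "tca", name = "AKG dehydrogenase + succinyl-CoA synthetase")
    a2("SDH",  "suc[MM] + fad[MM] -> mal[MM] + fadh2[MM]", pathway = "tca",
       name = "succinate dehydrogenase + fumarase")
    a2("MDHm", "mal[MM] + nad[MM] -> oaa[MM] + nadh[MM]", rev = TRUE,
       pathway = "tca", name = "mitochondrial malate dehydrogenase")

    # oxidative phosphorylation (lumped; P/O ratios configurable) + ROS
    a2("OPN", sprintf("nadh[MM] + 0.5 o2[CC] + %g adp[CC] -> nad[MM] + %g atp[CC]",
                      p_o_nadh, p_o_nadh),
       pathway = "oxphos", name = "oxidative phosphorylation (NADH)")
    a2("OPF", sprintf("fadh2[MM] + 0.5 o2[CC] + %g adp[CC] -> fad[MM] + %g atp[CC]",
                      p_o_fadh2, p_o_fadh2),
       pathway = "oxphos", name = "oxidative phosphorylation (FADH2)")
    a2("ROS", "nadh[MM] + o2[CC] -> nad[MM] + h2o2[CC]",
       pathway = "oxphos", name = "mitochondrial ROS production")

    # malate-aspartate shuttle
    a2("MDHc", "oaa[CC] + nadh[CC] -> mal[CC] + nad[CC]", rev = TRUE,
       pathway = "mas", name = "cytosolic malate dehydrogenase")
    a2("OGC",  "mal[CC] + akg[MM] -> mal[MM] + akg[CC]", rev = TRUE,
       pathway = "mas", name = "malate/alpha-ketoglutarate antiporter")
    a2("AATc", "asp[CC] + akg[CC] -> oaa[CC] + glu[CC]", rev = TRUE,
       pathway = "mas", name = "cytosolic aspartate aminotransferase")
    a2("AATm", "oaa[MM] + glu[MM] -> asp[MM] + akg[MM]", rev = TRUE,
       pathway = "mas", name = "mitochondrial aspartate aminotransferase")
    a2("AGC",  "asp[MM] + glu[CC] -> asp[CC] + glu[MM]", rev = TRUE,
       pathway = "mas", name = "aspartate/glutamate carrier")

    # glycerol-3-phosphate shuttle
    if (g3p_shuttle) {
      a2("G3PDHc", "dhap[CC] + nadh[CC] -> g3p[CC] + nad[CC]", rev = TRUE,
         pathway = "g3p_shuttle", name = "cytosolic glycerol-3P dehydrogenase")
      a2("G3PDHm", "g3p[CC] + fad[MM] -> dhap[CC] + fadh2[MM]",
         pathway = "g3p_shuttle", name = "mitochondrial glycerol-3P dehydrogenase")
    }

    # anaplerosis/cataplerosis
    a2("ME", "mal[CC] + nadp[CC] -> pyr[CC] + co2[CC] + nadph[CC]",
       pathway = "tca", name = "malic enzyme")

    # energy buffering and maintenance
    a2("NaK", "3 na[CC] + 2 k[e] + atp[CC] -> 3 na[e] + 2 k[CC] + adp[CC]",
       pathway = "ions", name = "Na/K-ATPase")
    a2("CK", "pcr[CC] + adp[CC] -> cr[CC] + atp[CC]", rev = TRUE,
       pathway = "buffering", name = "creatine kinase")
    a2("AK", "2 adp[CC] -> atp[CC] + amp[CC]", rev = TRUE,
       pathway = "buffering", name = "adenylate kinase")
    a2("CRT", "cr[CC] -> cr[e]", rev = TRUE, pathway = "transport",
       name = "creatine transporter")

    # antioxidant system (synthesis is astrocyte-only, added below)
    if (antioxidant) {
      a2("GPX", "h2o2[CC] + 2 gsh[CC] -> gssg[CC]", pathway = "antioxidant",
         name = "glutathione peroxidase")
      a2("GR", "gssg[CC] + nadph[CC] -> 2 gsh[CC] + nadp[CC]",
         pathway = "antioxidant", name = "glutathione reductase")
      a2("CAT", "2 h2o2[CC] -> o2[CC]", pathway = "antioxidant",
         name = "catalase")
      a2("APX", "h2o2[CC] + asc[CC] -> dha[CC]", pathway = "antioxidant",
         name = "ascorbate-dependent peroxide reduction")
      a2("DHAR", "dha[CC] + 2 gsh[CC] -> asc[CC] + gssg[CC]",
         pathway = "antioxidant", name = "GSH-dependent DHA reductase")
      a2("DHARn", "dha[CC] + nadph[CC] -> asc[CC] + nadp[CC]",
         pathway = "antioxidant", name = "NADPH-dependent DHA reductase")
      a2("ASCt", "asc[CC] -> asc[e]", rev = TRUE, pathway = "transport",
         name = "ascorbate transporter")
      a2("DHAt", "dha[CC] -> dha[e]", rev = TRUE, pathway = "transport",
         name = "dehydroascorbate transporter")
      a2("H2O2t", "h2o2[CC] -> h2o2[e]", rev = TRUE, pathway = "transport",
         name = "peroxiporin-mediated H2O2 diffusion")
    }

    # exchange of CO2 and aspartate with the shared compartments
    a2("CO2t", "co2[CC] -> co2[c]", pathway = "transport",
       name = "CO2 release to capillary")
    a2("ASPt", "asp[CC] -> asp[e]", rev = TRUE, pathway = "transport",
       name = "aspartate transporter")
  }

  ## -- neuron-specific --------------------------------------------------
  add("GLC_e_n", "glc[e] -> glc[nc]", scope = "neuron",
      name = "neuronal glucose uptake")
  add("O2_c_n", "o2[c] -> o2[nc]", scope = "neuron",
      name = "oxygen diffusion to neuron")
  add("LACt_n", "lac[nc] -> lac[e]", rev = TRUE, scope = "neuron",
      name = "neuronal lactate transporter (export positive)")
  add("VGLUT", "glu[nc] + atp[nc] -> glu[nv] + adp[nc]",
      pathway = "glu_gln_cycle", scope = "neuron",
      name = "vesicular glutamate loading")
  add("VREL", "glu[nv] -> glu[e]", pathway = "glu_gln_cycle", scope = "neuron",
      name = "vesicular glutamate release")
  add("EAAT_n", "glu[e] + 3 na[e] + k[nc] -> glu[nc] + 3 na[nc] + k[e]",
      pathway = "glu_gln_cycle", scope = "neuron",
      name = "neuronal glutamate uptake (minor route)")
  add("GLS", "gln[nc] -> glu[nc] + nh4[nc]", pathway = "glu_gln_cycle",
      scope = "neuron", name = "glutaminase")
  add("GLN_e_n", "gln[e] -> gln[nc]", pathway = "glu_gln_cycle",
      scope = "neuron", name = "neuronal glutamine uptake")
  add("NaC", "na[e] -> na[nc]", pathway = "ions", scope = "neuron",
      name = "neuronal Na+ channel")
  add("KC", "k[nc] -> k[e]", pathway = "ions", scope = "neuron",
      name = "neuronal K+ channel")
  add("NH4t_n", "nh4[nc] -> nh4[e]", rev = TRUE, scope = "neuron",
      name = "neuronal ammonium transporter")
  add("GDH_n", "glu[nm] + nad[nm] -> akg[nm] + nadh[nm] + nh4[nc]",
      rev = TRUE, pathway = "glu_gln_cycle", scope = "neuron",
      name = "neuronal glutamate dehydrogenase")

  ## -- astrocyte-specific ------------------------------------------------
  add("GLC_c_a", "glc[c] -> glc[ac]", scope = "astrocyte",
      name = "astrocytic glucose uptake via basal lamina")
  add("GLC_e_a", "glc[e] -> glc[ac]", scope = "astrocyte",
      name = "astrocytic glucose uptake from interstitium")
  add("O2_c_a", "o2[c] -> o2[ac]", scope = "astrocyte",
      name = "oxygen diffusion to astrocyte")
  add("LACt_a", "lac[ac] -> lac[e]", rev = TRUE, scope = "astrocyte",
      name = "astrocytic lactate transporter (export positive)")
  add("EAAT_a", "glu[e] + 3 na[e] + k[ac] -> glu[ac] + 3 na[ac] + k[e]",
      pathway = "glu_gln_cycle", scope = "astrocyte",
      name = "astrocytic glutamate uptake (3 Na+ co / 1 K+ counter)")
  add("GS_a", "glu[ac] + nh4[ac] + atp[ac] -> gln[ac] + adp[ac]",
      pathway = "glu_gln_cycle", scope = "astrocyte",
      name = "glutamine synthetase")
  add("GLN_a_e", "gln[ac] -> gln[e]", pathway = "glu_gln_cycle",
      scope = "astrocyte", name = "astrocytic glutamine release")
  add("NKCC", "na[e] + k[e] -> na[ac] + k[ac]", pathway = "ions",
      scope = "astrocyte", name = "astrocytic Na-K cotransporter")
  add("NH4t_a", "nh4[e] -> nh4[ac]", rev = TRUE, scope = "astrocyte",
      name = "astrocytic ammonium transporter")
  add("GDH_a", "glu[am] + nad[am] -> akg[am] + nadh[am] + nh4[ac]",
      rev = TRUE, pathway = "glu_gln_cycle", scope = "astrocyte",
      name = "astrocytic glutamate dehydrogenase")
  add("PC", "pyr[am] + co2[ac] + atp[ac] -> oaa[am] + adp[ac]",
      pathway = "tca", scope = "astrocyte", name = "pyruvate carboxylase")
  if (glycogen) {
    add("GLYCS", "g6p[ac] + atp[ac] -> glyc[ac] + adp[ac]",
        pathway = "glycogen", scope = "astrocyte", name = "glycogen synthesis")
    add("GLYCP", "glyc[ac] -> g6p[ac]", pathway = "glycogen",
        scope = "astrocyte", name = "glycogen phosphorylase")
  }
  if (antioxidant) {
    add("CYS2t", "cys2[e] -> cys2[ac]", scope = "astrocyte",
        name = "astrocytic cystine uptake")
    add("GSHS", "glu[ac] + 0.5 cys2[ac] + 2 atp[ac] -> gsh[ac] + 2 adp[ac]",
        pathway = "antioxidant", scope = "astrocyte",
        name = "glutathione synthesis (2 ATP)")
    add("GSH_a_e", "gsh[ac] -> gsh[e]", pathway = "antioxidant",
        scope = "astrocyte", name = "astrocytic glutathione release")
    add("GSH_e_n", "gsh[e] -> gsh[nc]", pathway = "antioxidant",
        scope = "neuron", name = "neuronal glutathione(-equivalent) uptake")
  }

  roles <- list(
    GS_a = "GS_a", PDH_n = "PDH_n",
    GLC_to_c = "GLC_in", O2_to_c = "O2_in",
    GLC_c_to_a = "GLC_c_a", GLC_c_to_e = "GLC_c_e",
    GLC_e_to_a = "GLC_e_a", GLC_e_to_n = "GLC_e_n",
    O2_c_to_a = "O2_c_a", O2_c_to_n = "O2_c_n",
    LAC_a_to_n = c("LACt_a", "LACt_n"))

  net <- metabolic_network(rx, roles = roles,
                           intake_ids = c("GLC_in", "O2_in"))
  # relative flux caps: ROS production is limited to a small fraction of the
  # generic bound so that peroxide detoxification drives a plausible PPP share
  rel_ub <- rep(1, nrow(net$reactions))
  rel_ub[net$reactions$id %in% c("ROS_n", "ROS_a")] <- ros_fraction
  net$reactions$rel_ub <- rel_ub
  net
}
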