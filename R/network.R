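#' @useDynLib brainflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor runif sd approx setNames quantile coef lm median
#' @importFrom utils read.delim write.table head tail
NULL

# Seven compartment codes of the model. Synaptic vesicles (nv) exist in the
# neuron only; nc/ac = cytosol, nm/am = mitochondria, e = extracellular
# (interstitial) space, c = blood capillary.
COMPARTMENTS <- c(
  c  = "blood capillary",
  e  = "extracellular space",
  nc = "neuron cytosol",
  nm = "neuron mitochondria",
  nv = "neuron synaptic vesicles",
  ac = "astrocyte cytosol",
  am = "astrocyte mitochondria"
)

#' Compartment table
#'
#' @return data.frame with columns `code` and `label` for the seven
#'   compartments of the brain model.
#' @export
compartments <- function() {
  data.frame(code = names(COMPARTMENTS), label = unname(COMPARTMENTS),
             stringsAsFactors = FALSE)
}

# Tracked-element counts per chemical identity (independent of compartment).
# Carbon counts are substrate skeleton carbons; conserved cofactor moieties
# (adenine nucleotides, NAD(P), FAD, the acetyl/CoA carrier, creatine) count
# zero so that moiety-interconverting reactions balance identically.
# Glutathione counts its Glu+Cys skeleton (8 C, 2 N); the glycine residue is
# part of the untracked moiety.
CHEM_TABLE <- local({
  tab <- rbind(
    c("glc", 6, 0), c("g6p", 6, 0), c("f6p", 6, 0), c("fbp", 6, 0),
    c("dhap", 3, 0), c("gap", 3, 0), c("pg3", 3, 0), c("pep", 3, 0),
    c("pyr", 3, 0), c("lac", 3, 0), c("ru5p", 5, 0), c("g3p", 3, 0),
    c("ace", 2, 0), c("cit", 6, 0), c("akg", 5, 0), c("suc", 4, 0),
    c("fum", 4, 0), c("mal", 4, 0), c("oaa", 4, 0), c("glyc", 6, 0),
    c("glu", 5, 1), c("gln", 5, 2), c("asp", 4, 1), c("nh4", 0, 1),
    c("gsh", 8, 2), c("gssg", 16, 4), c("cys2", 6, 2),
    c("asc", 6, 0), c("dha", 6, 0), c("h2o2", 0, 0),
    c("o2", 0, 0), c("co2", 1, 0),
    c("atp", 0, 0), c("adp", 0, 0), c("amp", 0, 0),
    c("nad", 0, 0), c("nadh", 0, 0), c("nadp", 0, 0), c("nadph", 0, 0),
    c("fad", 0, 0), c("fadh2", 0, 0), c("cr", 0, 0), c("pcr", 0, 0),
    c("na", 0, 0), c("k", 0, 0)
  )
  data.frame(base = tab[, 1], carbon = as.numeric(tab[, 2]),
             nitrogen = as.numeric(tab[, 3]), stringsAsFactors = FALSE)
})

SPECIES_NAMES <- c(
  glc = "glucose", g6p = "glucose-6-phosphate", f6p = "fructose-6-phosphate",
  fbp = "fructose-1,6-bisphosphate", dhap = "dihydroxyacetone phosphate",
  gap = "glyceraldehyde-3-phosphate", pg3 = "3-phosphoglycerate",
  pep = "phosphoenolpyruvate", pyr = "pyruvate", lac = "lactate",
  ru5p = "ribulose-5-phosphate", g3p = "glycerol-3-phosphate",
  ace = "acetyl unit (CoA-bound)", cit = "citrate", akg = "alpha-ketoglutarate",
  suc = "succinate", fum = "fumarate", mal = "malate", oaa = "oxaloacetate",
  glyc = "glycogen (glucosyl unit)", glu = "glutamate", gln = "glutamine",
  asp = "aspartate", nh4 = "ammonium", gsh = "glutathione (reduced)",
  gssg = "glutathione (oxidized)", cys2 = "cystine", asc = "ascorbate",
  dha = "dehydroascorbate", h2o2 = "hydrogen peroxide", o2 = "oxygen",
  co2 = "carbon dioxide", atp = "ATP", adp = "ADP", amp = "AMP",
  nad = "NAD+", nadh = "NADH", nadp = "NADP+", nadph = "NADPH",
  fad = "FAD", fadh2 = "FADH2", cr = "creatine", pcr = "phosphocreatine",
  na = "Na+", k = "K+"
)

species_base <- function(id) sub("\\[.*$", "", id)
species_comp <- function(id) sub("^.*\\[(.*)\\]$", "\\1", id)

#' Define one reaction
#'
#' Reactions are written as equation strings in the form
#' `"2 a[nc] + b[e] -> c[ac]"`: species are `base[compartment]` tokens,
#' coefficients are optional (default 1) and may be fractional. Intake
#' reactions have an empty left-hand side, effluxes an empty right-hand side.
#'
#' @param id unique reaction identifier.
#' @param eq equation string.
#' @param rev logical; is the reaction reversible?
#' @param pathway pathway tag (glycolysis, ppp, tca, oxphos, mas,
#'   g3p_shuttle, glu_gln_cycle, ions, antioxidant, buffering, glycogen,
#'   transport, intake, efflux, maintenance).
#' @param scope one of `"neuron"`, `"astrocyte"`, `"shared"`, `"capillary"`.
#' @param name human-readable name (defaults to `id`).
#' @return a list describing the reaction.
#' @export
rxn <- function(id, eq, rev = FALSE, pathway = "transport",
                scope = "shared", name = id) {
  st <- parse_equation(eq)
  list(id = id, name = name, equation = eq, stoichiometry = st,
       reversible = isTRUE(rev), pathway = pathway, scope = scope)
}

#' Parse an equation string into a named coefficient vector
#'
#' @param eq equation string, e.g. `"glc[c] + atp[nc] -> g6p[nc] + adp[nc]"`.
#'   `"<->"` is accepted as an arrow synonym.
#' @return named numeric vector of signed coefficients
#'   (negative = consumed, positive = produced).
#' @export
parse_equation <- function(eq) {
  arrow <- regmatches(eq, regexpr("<?->", eq))
  if (length(arrow) == 0L) stop("no '->' arrow in equation: ", eq)
  sides <- strsplit(eq, "<?->")[[1]]
  lhs <- if (length(sides) >= 1L) sides[1] else ""
  rhs <- if (length(sides) >= 2L) sides[2] else ""
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec(
        "^([0-9]*\\.?[0-9]*(?:/[0-9]+)?)\\s*([A-Za-z0-9_]+\\[[a-z]+\\])$", tm))[[1]]
      if (length(m) == 0L) stop("cannot parse term '", tm, "' in: ", eq)
      coef <- m[2]
      coef <- if (!nzchar(coef)) 1 else if (grepl("/", coef)) {
        pq <- as.numeric(strsplit(coef, "/", fixed = TRUE)[[1]]); pq[1] / pq[2]
      } else as.numeric(coef)
      sp <- m[3]
      out[sp] <- (if (is.na(out[sp])) 0 else out[sp]) + sign * coef
    }
    out
  }
  l <- parse_side(lhs, -1)
  r <- parse_side(rhs, +1)
  st <- numeric(0)
  for (sp in union(names(l), names(r))) {
    v <- (if (sp %in% names(l)) l[[sp]] else 0) +
         (if (sp %in% names(r)) r[[sp]] else 0)
    if (v != 0) st[sp] <- v
  }
  st
}

format_equation <- function(st) {
  side <- function(v) {
    if (length(v) == 0L) return("")
    coef <- sub("\\.$", "", sub("0+$", "", sprintf("%.10f", v)))
    paste(ifelse(v == 1, names(v), paste(coef, names(v))), collapse = " + ")
  }
  lhs <- -st[st < 0]; rhs <- st[st > 0]
  paste(side(lhs), "->", side(rhs))
}

#' Assemble a metabolic network from reaction definitions
#'
#' Collects species from the reaction stoichiometries, assigns tracked-element
#' counts from the chemical identity of each species, builds the M x N
#' stoichiometric matrix and validates carbon balance and role resolution.
#'
#' @param reactions list of reactions created with [rxn()].
#' @param roles named list mapping role names (e.g. `GS_a`, `PDH_n`,
#'   `GLC_to_c`) to reaction ids. `LAC_a_to_n` may name a length-2 character
#'   vector `c(astro_side, neuron_side)` of the two reversible lactate
#'   transports.
#' @param intake_ids reaction ids of the nutrient supply columns
#'   (capillary glucose and oxygen intakes).
#' @param chem optional extra chemistry rows (data.frame base/carbon/nitrogen)
#'   for species not in the built-in table.
#' @param validate check carbon balance and role resolution (default TRUE).
#' @return an object of class `metabolic_network` with fields `species`
#'   (data.frame), `reactions` (data.frame), `S` (dense M x N matrix),
#'   `intake_reactions`, `role_index`.
#' @export
metabolic_network <- function(reactions, roles = list(),
                              intake_ids = character(0),
                              chem = NULL, validate = TRUE) {
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  chem_tab <- CHEM_TABLE
  if (!is.null(chem)) chem_tab <- rbind(chem_tab, chem)

  sp_ids <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  sp_ids <- sort(sp_ids)
  comp <- species_comp(sp_ids)
  bad <- setdiff(unique(comp), names(COMPARTMENTS))
  if (length(bad)) stop("unknown compartment code(s): ", paste(bad, collapse = ", "))
  base <- species_base(sp_ids)
  idx <- match(base, chem_tab$base)
  if (anyNA(idx)) stop("no chemistry entry for species base(s): ",
                       paste(unique(base[is.na(idx)]), collapse = ", "))
  nm <- unname(SPECIES_NAMES[base])
  nm[is.na(nm)] <- base[is.na(nm)]
  species <- data.frame(
    id = sp_ids, name = nm, compartment = comp,
    carbon = chem_tab$carbon[idx], nitrogen = chem_tab$nitrogen[idx],
    is_intake = FALSE, stringsAsFactors = FALSE)

  M <- nrow(species); N <- length(reactions)
  S <- matrix(0, M, N, dimnames = list(species$id, ids))
  for (j in seq_len(N)) {
    st <- reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }

  rx <- data.frame(
    id = ids,
    name = vapply(reactions, `[[`, "", "name"),
    equation = vapply(reactions, function(r) format_equation(r$stoichiometry), ""),
    reversible = vapply(reactions, `[[`, TRUE, "reversible"),
    pathway = vapply(reactions, `[[`, "", "pathway"),
    cell_scope = vapply(reactions, `[[`, "", "scope"),
    stringsAsFactors = FALSE)

  # intake species: the capillary species injected by the intake columns
  if (length(intake_ids)) {
    if (!all(intake_ids %in% ids)) stop("unknown intake reaction id(s)")
    for (id in intake_ids) {
      st <- reactions[[match(id, ids)]]$stoichiometry
      species$is_intake[species$id %in% names(st[st > 0])] <- TRUE
    }
  }

  net <- structure(list(species = species, reactions = rx, S = S,
                        intake_reactions = intake_ids, role_index = roles),
                   class = "metabolic_network")
  if (validate) {
    viol <- carbon_balance_check(net)
    if (nrow(viol$violations))
      stop("carbon-unbalanced reaction(s): ",
           paste(sprintf("%s (%+g C)", viol$violations$reaction,
                         viol$violations$imbalance), collapse = ", "))
    for (role in names(roles)) {
      tgt <- roles[[role]]
      if (!all(tgt %in% ids))
        stop("role ", role, " does not resolve to a reaction")
    }
  }
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d reactions x %d species (%d compartments)\n",
              ncol(x$S), nrow(x$S), length(unique(x$species$compartment))))
  cat(sprintf("  reversible: %d | intakes: %s | roles: %d\n",
              sum(x$reactions$reversible),
              paste(x$intake_reactions, collapse = ", "),
              length(x$role_index)))
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param net a `metabolic_network`.
#' @return dense M x N numeric matrix; entry (i, j) is the signed coefficient
#'   of species i in reaction j.
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  net$S
}

#' Net per-species production S v of a flux vector
#'
#' @param net a `metabolic_network`.
#' @param nu numeric flux vector of length N (one entry per reaction).
#' @return named numeric vector of length M.
#' @export
production_vector <- function(net, nu) {
  S <- stoichiometric_matrix(net)
  if (length(nu) != ncol(S))
    stop("flux vector length ", length(nu), " != number of reactions ", ncol(S))
  drop(S %*% as.numeric(nu))
}

#' Elemental audit of the reconstruction
#'
#' Checks that every non-exchange reaction conserves the tracked elements
#' (carbon and nitrogen). Intake and efflux columns are exempt and listed
#' separately.
#'
#' @param net a `metabolic_network`.
#' @param element `"carbon"` (default) or `"nitrogen"`.
#' @return list with `violations` (data.frame reaction/imbalance for
#'   non-exchange reactions) and `exchanges` (data.frame for exempt columns).
#' @export
carbon_balance_check <- function(net, element = c("carbon", "nitrogen")) {
  element <- match.arg(element)
  w <- net$species[[element]]
  imb <- drop(crossprod(net$S, w))
  exempt <- net$reactions$pathway %in% c("intake", "efflux")
  bad <- abs(imb) > 1e-9 & !exempt
  list(
    violations = data.frame(reaction = net$reactions$id[bad],
                            imbalance = unname(imb[bad]),
                            stringsAsFactors = FALSE),
    exchanges = data.frame(reaction = net$reactions$id[exempt],
                           imbalance = unname(imb[exempt]),
                           stringsAsFactors = FALSE))
}

#' Look up the column index of a named role
#'
#' @param net a `metabolic_network`.
#' @param role role name, e.g. `"GS_a"`.
#' @param optional if TRUE return NA instead of erroring when absent.
#' @return integer column index (or indices for composite roles).
#' @export
role_column <- function(net, role, optional = FALSE) {
  tgt <- net$role_index[[role]]
  if (is.null(tgt)) {
    if (optional) return(NA_integer_)
    stop("role '", role, "' is not resolved on this network")
  }
  match(tgt, net$reactions$id)
}
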