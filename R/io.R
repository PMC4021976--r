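# Network exchange: a TSV reaction-table dialect and an SBML Level 3
# Version 1 (core) subset written and parsed with xml2. Role and pathway
# annotations are carried in both formats so a round trip reproduces the
# stoichiometric matrix, reversibility flags and role index exactly.

fmt_num <- function(x) {
  # exact decimal for the dyadic coefficients used throughout
  s <- sprintf("%.10f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Export a network to TSV or SBML
#'
#' The TSV dialect is UTF-8, tab-separated with a header row and columns
#' `id`, `name`, `equation`, `reversible`, `pathway_tag`, `cell_scope`,
#' `rel_ub`; equation strings use the `"2 a[nc] + b[e] -> c[ac]"` form with
#' the compartment in square brackets. Metadata lines starting with `#!`
#' carry the role index, the intake reactions and the chemistry of any
#' species missing from the built-in table. SBML output is Level 3 Version 1
#' core with the same metadata in reaction/species annotations.
#'
#' @param net a `metabolic_network`.
#' @param file output path.
#' @param format `"tsv"` or `"sbml"`.
#' @return `file`, invisibly.
#' @export
export_network <- function(net, file, format = c("tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "tsv") export_tsv(net, file) else export_sbml(net, file)
  invisible(file)
}

export_tsv <- function(net, file) {
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (role in names(net$role_index))
    writeLines(sprintf("#! role\t%s\t%s", role,
                       paste(net$role_index[[role]], collapse = ",")), con)
  if (length(net$intake_reactions))
    writeLines(sprintf("#! intake\t%s",
                       paste(net$intake_reactions, collapse = ",")), con)
  base <- unique(species_base(net$species$id))
  extra <- setdiff(base, CHEM_TABLE$base)
  for (b in extra) {
    i <- match(b, species_base(net$species$id))
    writeLines(sprintf("#! chem\t%s\t%d\t%d", b,
                       net$species$carbon[i], net$species$nitrogen[i]), con)
  }
  rel <- net$reactions$rel_ub
  if (is.null(rel)) rel <- rep(1, nrow(net$reactions))
  eqs <- vapply(seq_len(ncol(net$S)), function(j) {
    st <- net$S[, j]; st <- st[st != 0]
    format_equation(st)
  }, "")
  df <- data.frame(id = net$reactions$id, name = net$reactions$name,
                   equation = eqs,
                   reversible = net$reactions$reversible,
                   pathway_tag = net$reactions$pathway,
                   cell_scope = net$reactions$cell_scope,
                   rel_ub = rel)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Import a network from TSV or SBML
#'
#' Files produced by [export_network()] round-trip exactly (same S, same
#' reversibility, same roles). Conforming third-party tables load too; when
#' role annotations are absent the role index is left empty and observables
#' needing a role fail fast.
#'
#' @param file path.
#' @param format `"tsv"` or `"sbml"`.
#' @param validate run the carbon audit on load (warning, not error, for
#'   imported files).
#' @return a `metabolic_network`.
#' @export
import_network <- function(file, format = c("tsv", "sbml"), validate = TRUE) {
  format <- match.arg(format)
  net <- if (format == "tsv") import_tsv(file) else import_sbml(file)
  if (validate) {
    viol <- carbon_balance_check(net)$violations
    if (nrow(viol))
      warning("imported network has carbon-unbalanced reactions: ",
              paste(viol$reaction, collapse = ", "))
  }
  net
}

import_tsv <- function(file) {
  lines <- readLines(file, encoding = "UTF-8")
  meta <- lines[startsWith(lines, "#!")]
  body <- lines[!startsWith(lines, "#!")]
  roles <- list(); intake <- character(0)
  chem <- NULL
  for (ln in meta) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "#! role") {
      roles[[f[2]]] <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    } else if (f[1] == "#! intake") {
      intake <- strsplit(f[2], ",", fixed = TRUE)[[1]]
    } else if (f[1] == "#! chem") {
      chem <- rbind(chem, data.frame(base = f[2], carbon = as.numeric(f[3]),
                                     nitrogen = as.numeric(f[4])))
    }
  }
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id))
    stop("duplicate reaction ids in ", file)
  rxs <- lapply(seq_len(nrow(df)), function(i)
    rxn(df$id[i], df$equation[i], rev = df$reversible[i],
        pathway = df$pathway_tag[i], scope = df$cell_scope[i],
        name = df$name[i]))
  net <- metabolic_network(rxs, roles = roles, intake_ids = intake,
                           chem = chem, validate = FALSE)
  if ("rel_ub" %in% names(df)) net$reactions$rel_ub <- df$rel_ub
  net
}

BF_NS <- "https://brainflux.r-pkg/ns"

sbml_sid <- function(ids) {
  # SBML SIds cannot contain brackets; the original id is kept in annotation
  gsub("[^A-Za-z0-9_]", "_", paste0("M_", ids))
}

export_sbml <- function(net, file) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:bf" = BF_NS, level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "brainflux_network")

  ann <- xml2::xml_add_child(mdl, "annotation")
  meta <- xml2::xml_add_child(ann, "bf:metadata")
  for (role in names(net$role_index))
    xml2::xml_add_child(meta, "bf:role", name = role,
                        target = paste(net$role_index[[role]], collapse = ","))
  xml2::xml_add_child(meta, "bf:intake",
                      target = paste(net$intake_reactions, collapse = ","))

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cc in unique(net$species$compartment))
    xml2::xml_add_child(lc, "compartment", id = paste0("comp_", cc),
                        name = unname(COMPARTMENTS[cc]), constant = "true")

  sid <- sbml_sid(net$species$id)
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(net$species))) {
    sp <- xml2::xml_add_child(
      ls, "species", id = sid[i], name = net$species$name[i],
      compartment = paste0("comp_", net$species$compartment[i]),
      hasOnlySubstanceUnits = "true",
      boundaryCondition = if (net$species$is_intake[i]) "true" else "false",
      constant = "false")
    a <- xml2::xml_add_child(sp, "annotation")
    xml2::xml_add_child(a, "bf:species", id = net$species$id[i],
                        carbon = as.character(net$species$carbon[i]),
                        nitrogen = as.character(net$species$nitrogen[i]))
  }

  rel <- net$reactions$rel_ub
  if (is.null(rel)) rel <- rep(1, nrow(net$reactions))
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(ncol(net$S))) {
    rx <- xml2::xml_add_child(
      lr, "reaction", id = net$reactions$id[j], name = net$reactions$name[j],
      reversible = if (net$reactions$reversible[j]) "true" else "false",
      fast = "false")
    a <- xml2::xml_add_child(rx, "annotation")
    xml2::xml_add_child(a, "bf:reaction",
                        pathway = net$reactions$pathway[j],
                        scope = net$reactions$cell_scope[j],
                        rel_ub = fmt_num(rel[j]))
    st <- net$S[, j]
    rs <- which(st < 0); ps <- which(st > 0)
    if (length(rs)) {
      lrct <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in rs)
        xml2::xml_add_child(lrct, "speciesReference", species = sid[i],
                            stoichiometry = fmt_num(-st[i]), constant = "true")
    }
    if (length(ps)) {
      lprd <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in ps)
        xml2::xml_add_child(lprd, "speciesReference", species = sid[i],
                            stoichiometry = fmt_num(st[i]), constant = "true")
    }
  }
  xml2::write_xml(doc, file)
}

import_sbml <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core", bf = BF_NS)

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sbml_ids <- xml2::xml_attr(sp_nodes, "id")
  ann <- lapply(sp_nodes, function(n)
    xml2::xml_find_first(n, ".//bf:species", ns))
  orig <- vapply(seq_along(sp_nodes), function(i) {
    a <- ann[[i]]
    if (!inherits(a, "xml_missing")) xml2::xml_attr(a, "id")
    else sub("^M_", "", sbml_ids[i])
  }, "")
  carbon <- vapply(seq_along(sp_nodes), function(i) {
    a <- ann[[i]]
    if (!inherits(a, "xml_missing")) as.numeric(xml2::xml_attr(a, "carbon"))
    else NA_real_
  }, 0)
  nitrogen <- vapply(seq_along(sp_nodes), function(i) {
    a <- ann[[i]]
    if (!inherits(a, "xml_missing")) as.numeric(xml2::xml_attr(a, "nitrogen"))
    else NA_real_
  }, 0)
  id_map <- setNames(orig, sbml_ids)

  base <- species_base(orig)
  newb <- !duplicated(base) & !(base %in% CHEM_TABLE$base) & !is.na(carbon)
  chem <- if (any(newb)) data.frame(base = base[newb], carbon = carbon[newb],
                                    nitrogen = nitrogen[newb]) else NULL

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxs <- lapply(rx_nodes, function(n) {
    stoich <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(n, sprintf("./s:%s/s:speciesReference", side), ns)
      sgn <- if (side == "listOfReactants") -1 else 1
      for (rf in refs) {
        sp <- id_map[[xml2::xml_attr(rf, "species")]]
        stoich[sp] <- (if (is.na(stoich[sp])) 0 else stoich[sp]) +
          sgn * as.numeric(xml2::xml_attr(rf, "stoichiometry"))
      }
    }
    a <- xml2::xml_find_first(n, ".//bf:reaction", ns)
    list(id = xml2::xml_attr(n, "id"),
         name = if (is.na(xml2::xml_attr(n, "name"))) xml2::xml_attr(n, "id")
                else xml2::xml_attr(n, "name"),
         stoichiometry = stoich[stoich != 0],
         reversible = identical(xml2::xml_attr(n, "reversible"), "true"),
         pathway = if (!inherits(a, "xml_missing")) xml2::xml_attr(a, "pathway")
                   else "transport",
         scope = if (!inherits(a, "xml_missing")) xml2::xml_attr(a, "scope")
                 else "shared",
         rel_ub = if (!inherits(a, "xml_missing"))
                    as.numeric(xml2::xml_attr(a, "rel_ub")) else 1)
  })
  if (anyDuplicated(vapply(rxs, `[[`, "", "id"))) stop("duplicate reaction ids")

  roles <- list()
  for (n in xml2::xml_find_all(doc, ".//bf:metadata/bf:role", ns))
    roles[[xml2::xml_attr(n, "name")]] <-
      strsplit(xml2::xml_attr(n, "target"), ",", fixed = TRUE)[[1]]
  intake <- character(0)
  ni <- xml2::xml_find_first(doc, ".//bf:metadata/bf:intake", ns)
  if (!inherits(ni, "xml_missing") && nzchar(xml2::xml_attr(ni, "target")))
    intake <- strsplit(xml2::xml_attr(ni, "target"), ",", fixed = TRUE)[[1]]

  net <- metabolic_network(rxs, roles = roles, intake_ids = intake,
                           chem = chem, validate = FALSE)
  net$reactions$rel_ub <- vapply(rxs, `[[`, 0, "rel_ub")[
    match(net$reactions$id, vapply(rxs, `[[`, "", "id"))]
  net
}

#' Persist a solution ensemble as a flux table with provenance sidecar
#'
#' @param ens a `solution_ensemble`.
#' @param file TSV path (header = reaction ids, one row per solution); a
#'   JSON sidecar `<file>.json` records the configuration and convergence.
#' @return `file`, invisibly.
#' @export
write_ensemble <- function(ens, file) {
  df <- as.data.frame(ens$solutions)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(glucose_level = ens$glucose_level,
               config = unclass(ens$config),
               n_solutions = nrow(ens$solutions),
               n_discarded = ens$convergence$n_discarded,
               median_iterations = stats::median(ens$convergence$iterations),
               max_violation = max(ens$convergence$max_violation))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Load a persisted solution ensemble
#'
#' @param file TSV path written by [write_ensemble()].
#' @return a `solution_ensemble` (convergence details reduced to what the
#'   sidecar records).
#' @export
read_ensemble <- function(file) {
  df <- read.delim(file, sep = "\t", check.names = FALSE)
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  cfg <- do.call(sampler_config, side$config[c("nu_max", "epsilon", "max_iter",
                                               "step", "seed", "K")])
  structure(list(solutions = as.matrix(df),
                 glucose_level = side$glucose_level,
                 config = cfg, seeds = NULL,
                 convergence = list(iterations = rep(NA_integer_, nrow(df)),
                                    max_violation = side$max_violation,
                                    n_discarded = side$n_discarded)),
            class = "solution_ensemble")
}
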