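#' Write a model as SBML Level 3 with the fbc extension
#'
#' Emits SBML L3v1 + fbc-v2: species with compartments (and chemical
#' formulas when present), reactions with stoichiometry, flux-bound
#' parameters, nested fbc gene-product associations for the GPR rules, the
#' active objective, and SUBSYSTEM/TRANSPORT tags in reaction notes.
#' Identifiers follow the COBRA convention (M_/R_/G_ prefixes), stripped
#' again on read.
#'
#' @param model a \code{metabolic_model}.
#' @param path output file.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
      'level="3" version="1" fbc:required="false">')
  add('<model id="', esc(model$id), '" fbc:strict="true">')
  add("<listOfCompartments>")
  for (cp in unique(model$metabolites$compartment)) {
    add('<compartment id="', esc(cp), '" constant="true"/>')
  }
  add("</listOfCompartments>")
  add("<listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    frm <- if (!is.null(mt$formula) && !is.na(mt$formula) && nzchar(mt$formula))
      paste0(' fbc:chemicalFormula="', esc(mt$formula), '"') else ""
    add('<species id="M_', esc(mt$id), '" name="', esc(mt$name),
        '" compartment="', esc(mt$compartment),
        '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
        'constant="false"', frm, "/>")
  }
  add("</listOfSpecies>")
  add("<listOfParameters>")
  for (r in model$reactions) {
    add('<parameter id="bnd_R_', esc(r$id), '_lb" value="',
        num(r$lower_bound), '" constant="true"/>')
    add('<parameter id="bnd_R_', esc(r$id), '_ub" value="',
        num(r$upper_bound), '" constant="true"/>')
  }
  add("</listOfParameters>")
  gpr_xml <- function(tree) {
    if (is.character(tree)) {
      return(paste0('<fbc:geneProductRef fbc:geneProduct="G_', esc(tree), '"/>'))
    }
    inner <- paste(vapply(tree$args, gpr_xml, character(1)), collapse = "")
    paste0("<fbc:", tree$op, ">", inner, "</fbc:", tree$op, ">")
  }
  add("<listOfReactions>")
  for (r in model$reactions) {
    add('<reaction id="R_', esc(r$id), '" reversible="',
        tolower(r$lower_bound < 0), '" fast="false" fbc:lowerFluxBound="bnd_R_',
        esc(r$id), '_lb" fbc:upperFluxBound="bnd_R_', esc(r$id), '_ub">')
    add('<notes><body xmlns="http://www.w3.org/1999/xhtml">',
        "<p>SUBSYSTEM: ", esc(r$subsystem), "</p>",
        "<p>TRANSPORT: ", tolower(isTRUE(r$is_transport)), "</p>",
        "</body></notes>")
    st <- r$stoichiometry
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      add("<listOfReactants>")
      for (m in names(subs)) {
        add('<speciesReference species="M_', esc(m), '" stoichiometry="',
            num(-subs[[m]]), '" constant="true"/>')
      }
      add("</listOfReactants>")
    }
    if (length(prods)) {
      add("<listOfProducts>")
      for (m in names(prods)) {
        add('<speciesReference species="M_', esc(m), '" stoichiometry="',
            num(prods[[m]]), '" constant="true"/>')
      }
      add("</listOfProducts>")
    }
    if (!is.null(r$gpr_tree)) {
      add("<fbc:geneProductAssociation>", gpr_xml(r$gpr_tree),
          "</fbc:geneProductAssociation>")
    }
    add("</reaction>")
  }
  add("</listOfReactions>")
  add('<fbc:listOfObjectives fbc:activeObjective="obj">')
  add('<fbc:objective fbc:id="obj" fbc:type="maximize">')
  add("<fbc:listOfFluxObjectives>")
  for (rn in names(model$objective)) {
    add('<fbc:fluxObjective fbc:reaction="R_', esc(rn), '" fbc:coefficient="',
        num(model$objective[[rn]]), '"/>')
  }
  add("</fbc:listOfFluxObjectives>")
  add("</fbc:objective>")
  add("</fbc:listOfObjectives>")
  add("<fbc:listOfGeneProducts>")
  for (g in model$genes) {
    add('<fbc:geneProduct fbc:id="G_', esc(g), '" fbc:label="', esc(g), '"/>')
  }
  add("</fbc:listOfGeneProducts>")
  add("</model>")
  add("</sbml>")
  writeLines(L, path)
  invisible(path)
}

#' Read a metabolic model from SBML
#'
#' Accepts the SBML subset this package writes (Level 3 + fbc v2) plus
#' common legacy variants: GPRs either as fbc gene-product associations or
#' note-encoded \code{GENE_ASSOCIATION:} lines, bounds either as fbc
#' parameter references or, when missing, defaulted to (-1000, 1000) for
#' reversible and (0, 1000) for irreversible reactions with a warning.
#'
#' @param path SBML file.
#' @param default_bound magnitude used when bounds are missing.
#' @return a \code{metabolic_model}.
#' @export
read_sbml <- function(path, default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("SBML parse error in '", path, "': ", conditionMessage(e))
  })
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, "//model")
  if (inherits(model_node, "xml_missing")) {
    stop("SBML parse error: no <model> element in ", path)
  }
  strip_prefix <- function(x, pre) {
    ifelse(startsWith(x, pre), substring(x, nchar(pre) + 1L), x)
  }
  sp <- xml2::xml_find_all(doc, "//listOfSpecies/species")
  if (!length(sp)) stop("SBML parse error: no species in ", path)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  mets$species <- mets$name
  pars <- xml2::xml_find_all(doc, "//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  gene_nodes <- xml2::xml_find_all(doc, "//*[local-name()='geneProduct']")
  gene_label <- stats::setNames(xml2::xml_attr(gene_nodes, "label"),
                                xml2::xml_attr(gene_nodes, "id"))
  gpr_from_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      lbl <- gene_label[gid]
      return(if (!is.na(lbl)) unname(lbl) else strip_prefix(gid, "G_"))
    }
    kids <- xml2::xml_children(node)
    list(op = nm, args = lapply(kids, gpr_from_node))
  }
  rx_nodes <- xml2::xml_find_all(doc, "//listOfReactions/reaction")
  missing_bounds <- character(0)
  reactions <- lapply(rx_nodes, function(rn) {
    rid <- strip_prefix(xml2::xml_attr(rn, "id"), "R_")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      mid <- strip_prefix(xml2::xml_attr(sr, "species"), "M_")
      st[mid] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      mid <- strip_prefix(xml2::xml_attr(sr, "species"), "M_")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      st[mid] <- if (mid %in% names(st)) st[mid] + coef else coef
    }
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(parval)) {
      lb <- parval[[lb_ref]]; ub <- parval[[ub_ref]]
    } else {
      missing_bounds <<- c(missing_bounds, rid)
      rev <- isTRUE(xml2::xml_attr(rn, "reversible") == "true")
      lb <- if (rev) -default_bound else 0
      ub <- default_bound
    }
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gpr <- ""
    if (!inherits(gpa, "xml_missing")) {
      tree <- gpr_from_node(xml2::xml_child(gpa))
      gpr <- gpr_deparse(tree)
    } else {
      notes_txt <- xml2::xml_text(xml2::xml_find_all(rn, ".//notes//p"))
      ga <- grep("^\\s*GENE_ASSOCIATION:", notes_txt, value = TRUE)
      if (length(ga)) gpr <- trimws(sub("^\\s*GENE_ASSOCIATION:", "", ga[[1]]))
    }
    notes_txt <- xml2::xml_text(xml2::xml_find_all(rn, ".//notes//p"))
    ss <- grep("^\\s*SUBSYSTEM:", notes_txt, value = TRUE)
    tr <- grep("^\\s*TRANSPORT:", notes_txt, value = TRUE)
    list(id = rid, stoichiometry = st, lower_bound = unname(lb),
         upper_bound = unname(ub),
         gpr = gpr,
         subsystem = if (length(ss)) trimws(sub("^\\s*SUBSYSTEM:", "", ss[[1]])) else "",
         is_transport = length(tr) && grepl("true", tr[[1]]))
  })
  if (length(missing_bounds)) {
    warning("missing flux bounds for ", length(missing_bounds),
            " reaction(s); defaulted to +/-", default_bound, " (",
            paste(utils::head(missing_bounds, 5), collapse = ", "), ")")
  }
  fo <- xml2::xml_find_all(doc, "//*[local-name()='fluxObjective']")
  objective <- stats::setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                               strip_prefix(xml2::xml_attr(fo, "reaction"), "R_"))
  genes <- if (length(gene_label)) unname(gene_label) else NULL
  metabolic_model(mets, reactions, genes = genes, objective = objective,
                  id = xml2::xml_attr(model_node, "id"))
}
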