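## SBML Level 3 (+ FBC v2) I/O, via xml2.
##
## Conventions follow the files distributed by BiGG: reaction ids carry an
## "R_" prefix and species an "M_" prefix in SBML; both are stripped on read
## and restored on write. Flux bounds come from fbc:lowerFluxBound /
## fbc:upperFluxBound parameter references; reactions without FBC bound
## annotations default to [-1000, 1000] (or [0, 1000] when marked
## irreversible). The active FBC objective supplies the weight vector c. A
## small <strainDesign> annotation records the substrate and product
## exchange designations so models written here round-trip.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
STRAIN_DESIGN_NS <- "https://dbfba.r-pkg/strainDesign"

strip_prefix <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

num_attr <- function(node, attr) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) NA_real_ else as.numeric(v)
}

read_model_sbml <- function(path, biomass = NULL, substrate = NULL,
                            product = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed SBML file '", path, "': ",
                         conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mnode, "xml_missing"))
    stop("malformed SBML file '", path, "': no <model> element")

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_raw <- xml2::xml_attr(sp_nodes, "id")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = strip_prefix(sp_raw[!boundary], "M"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")[!boundary]),
                  strip_prefix(sp_raw[!boundary], "M"),
                  xml2::xml_attr(sp_nodes, "name")[!boundary]),
    compartment = xml2::xml_attr(sp_nodes, "compartment")[!boundary],
    stringsAsFactors = FALSE)
  boundary_ids <- sp_raw[boundary]

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx_nodes))
    stop("malformed SBML file '", path, "': no reactions")

  rxns <- lapply(rx_nodes, function(rn) {
    rid_raw <- xml2::xml_attr(rn, "id")
    if (is.na(rid_raw)) stop("malformed SBML file '", path,
                             "': reaction without id")
    rid <- strip_prefix(rid_raw, "R")
    st <- numeric(0)
    for (side in c(-1, 1)) {
      xp <- if (side < 0) "./listOfReactants/speciesReference"
            else "./listOfProducts/speciesReference"
      refs <- xml2::xml_find_all(rn, xp)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        if (sp %in% boundary_ids) next
        coef <- num_attr(ref, "stoichiometry")
        if (is.na(coef)) coef <- 1
        st[strip_prefix(sp, "M")] <- side * coef
      }
    }
    if (!length(st))
      stop("reaction '", rid, "' in '", path,
           "': no (non-boundary) metabolites")
    rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref)) {
      if (!lb_ref %in% names(pvals))
        stop("reaction '", rid, "': unresolved bound parameter '", lb_ref, "'")
      pvals[[lb_ref]]
    } else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref)) {
      if (!ub_ref %in% names(pvals))
        stop("reaction '", rid, "': unresolved bound parameter '", ub_ref, "'")
      pvals[[ub_ref]]
    } else 1000
    nm <- xml2::xml_attr(rn, "name")
    reaction(id = rid, name = if (is.na(nm)) rid else nm,
             stoichiometry = st, lower_bound = lb, upper_bound = ub)
  })

  fo <- xml2::xml_find_all(doc, ".//listOfFluxObjectives/fluxObjective")
  objective <- numeric(0)
  if (length(fo)) {
    objective <- stats::setNames(
      as.numeric(xml2::xml_attr(fo, "coefficient")),
      strip_prefix(xml2::xml_attr(fo, "reaction"), "R"))
    objective <- objective[objective != 0]
  }

  ann <- xml2::xml_find_first(doc, ".//annotation/strainDesign")
  ann_attr <- function(a) if (inherits(ann, "xml_missing")) NULL else {
    v <- xml2::xml_attr(ann, a); if (is.na(v)) NULL else v
  }
  biomass <- biomass %||% ann_attr("biomass") %||%
    (if (length(objective)) names(objective)[1] else
      stop("SBML model '", path, "' has no FBC objective; supply 'biomass'"))
  substrate <- substrate %||% ann_attr("substrate") %||%
    stop("model '", path, "' does not designate a substrate exchange; ",
         "supply 'substrate'")
  product <- product %||% ann_attr("product") %||%
    stop("model '", path, "' does not designate a product exchange; ",
         "supply 'product'")
  if (!length(objective)) objective <- stats::setNames(1, biomass)

  mid <- xml2::xml_attr(mnode, "id")
  metabolic_model(reactions = rxns, metabolites = mets,
                  biomass_id = biomass, substrate_id = substrate,
                  product_id = product, objective = objective,
                  id = if (is.na(mid)) "model" else mid)
}

write_model_sbml <- function(model, path) {
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_CORE_NS, SBML_FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', xml_esc(model$id)),
    '    <annotation>',
    sprintf('      <strainDesign xmlns="%s" biomass="%s" substrate="%s" product="%s"/>',
            STRAIN_DESIGN_NS, xml_esc(model$biomass_id),
            xml_esc(model$substrate_id), xml_esc(model$product_id)),
    '    </annotation>',
    '    <listOfCompartments>')
  for (cp in unique(model$metabolites$compartment))
    out <- c(out, sprintf('      <compartment id="%s" constant="true"/>',
                          xml_esc(cp)))
  out <- c(out, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites)))
    out <- c(out, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"/>'),
      xml_esc(model$metabolites$id[i]), xml_esc(model$metabolites$name[i]),
      xml_esc(model$metabolites$compartment[i])))
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>')
  rids <- reaction_ids(model)
  for (rid in rids) {
    r <- model$reactions[[rid]]
    out <- c(out,
      sprintf('      <parameter id="lb_R_%s" value="%s" constant="true"/>',
              xml_esc(rid), num(r$lower_bound)),
      sprintf('      <parameter id="ub_R_%s" value="%s" constant="true"/>',
              xml_esc(rid), num(r$upper_bound)))
  }
  out <- c(out, '    </listOfParameters>', '    <listOfReactions>')
  for (rid in rids) {
    r <- model$reactions[[rid]]
    out <- c(out, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="lb_R_%s" fbc:upperFluxBound="ub_R_%s">'),
      xml_esc(rid), xml_esc(r$name),
      if (r$lower_bound < 0) "true" else "false",
      xml_esc(rid), xml_esc(rid)))
    st <- r$stoichiometry
    for (side in c(-1, 1)) {
      sel <- if (side < 0) st < 0 else st > 0
      if (!any(sel)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      out <- c(out, sprintf('        <%s>', tag))
      for (mid in names(st)[sel])
        out <- c(out, sprintf(
          paste0('          <speciesReference species="M_%s" ',
                 'stoichiometry="%s" constant="true"/>'),
          xml_esc(mid), num(abs(st[[mid]]))))
      out <- c(out, sprintf('        </%s>', tag))
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>',
           '    <fbc:listOfObjectives fbc:activeObjective="obj">',
           '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
           '        <fbc:listOfFluxObjectives>')
  for (rid in names(model$objective))
    out <- c(out, sprintf(
      '          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="%s"/>',
      xml_esc(rid), num(model$objective[[rid]])))
  out <- c(out, '        </fbc:listOfFluxObjectives>',
           '      </fbc:objective>',
           '    </fbc:listOfObjectives>',
           '  </model>', '</sbml>')
  # parse before writing: guarantees the emitted file is well-formed XML
  doc <- xml2::read_xml(paste(out, collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a metabolic model from SBML or BiGG-style JSON
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @param biomass,substrate,product reaction ids designating the biomass
#'   reaction and the substrate / product exchanges. Required when the file
#'   itself does not carry the designation (plain BiGG downloads); files
#'   written by [write_model()] carry it. The biomass default is the
#'   objective reaction declared in the file.
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "sbml", "json"),
                       biomass = NULL, substrate = NULL, product = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "sbml") read_model_sbml(path, biomass, substrate, product)
  else read_model_json(path, biomass, substrate, product)
}

#' Write a metabolic model to SBML or BiGG-style JSON
#'
#' The written file records the biomass / substrate / product designations,
#' so [read_model()] round-trips without extra arguments.
#'
#' @param model a validated `"metabolic_model"`.
#' @param path output path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "sbml") write_model_sbml(model, path)
  else write_model_json(model, path)
}
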