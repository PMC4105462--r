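## BiGG-style JSON I/O.
##
## The layout follows the JSON distributed by the BiGG database: top-level
## "metabolites", "reactions" (each with a "metabolites" coefficient map,
## "lower_bound"/"upper_bound" and "objective_coefficient") and "genes"
## (ignored; knockouts operate at reaction level). A "strain_design" block
## records the biomass / substrate / product designations so models written
## by this package round-trip without re-specifying them.

read_model_json <- function(path, biomass = NULL, substrate = NULL,
                            product = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON model '", path, "': ",
                         conditionMessage(e)))
  if (is.null(doc$reactions) || !length(doc$reactions))
    stop("malformed model '", path, "': no \"reactions\" array")

  mets <- NULL
  if (length(doc$metabolites)) {
    mets <- data.frame(
      id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
      name = vapply(doc$metabolites, function(m)
        as.character(m$name %||% m$id), character(1)),
      compartment = vapply(doc$metabolites, function(m)
        as.character(m$compartment %||% "c"), character(1)),
      stringsAsFactors = FALSE)
  }

  objective <- numeric(0)
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("malformed model '", path, "': reaction without id")
    st <- unlist(r$metabolites)
    if (!length(st))
      stop("reaction '", r$id, "': empty stoichiometry")
    oc <- as.numeric(r$objective_coefficient %||% 0)
    if (oc != 0) objective[[r$id]] <<- oc
    reaction(id = as.character(r$id),
             name = as.character(r$name %||% r$id),
             stoichiometry = st,
             lower_bound = as.numeric(r$lower_bound %||% -1000),
             upper_bound = as.numeric(r$upper_bound %||% 1000),
             is_exchange = if (is.null(r$is_exchange)) NA else
               isTRUE(as.logical(r$is_exchange)),
             deletable = if (is.null(r$deletable)) TRUE else
               isTRUE(as.logical(r$deletable)))
  })

  sd <- doc$strain_design
  biomass <- biomass %||% sd$biomass %||%
    (if (length(objective)) names(objective)[1] else
      stop("model '", path, "' has no objective; supply 'biomass'"))
  substrate <- substrate %||% sd$substrate %||%
    stop("model '", path, "' does not designate a substrate exchange; ",
         "supply 'substrate'")
  product <- product %||% sd$product %||%
    stop("model '", path, "' does not designate a product exchange; ",
         "supply 'product'")
  if (!length(objective)) objective <- stats::setNames(1, biomass)

  metabolic_model(reactions = rxns, metabolites = mets,
                  biomass_id = as.character(biomass),
                  substrate_id = as.character(substrate),
                  product_id = as.character(product),
                  objective = objective,
                  id = as.character(doc$id %||% "model"))
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i)
    list(id = model$metabolites$id[i],
         name = model$metabolites$name[i],
         compartment = model$metabolites$compartment[i]))
  rxns <- lapply(model$reactions, function(r)
    list(id = r$id, name = r$name,
         metabolites = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         objective_coefficient =
           unname(model$objective[r$id] %|na|% 0),
         is_exchange = r$is_exchange,
         deletable = r$deletable))
  doc <- list(id = model$id,
              metabolites = mets,
              reactions = unname(rxns),
              genes = list(),
              strain_design = list(biomass = model$biomass_id,
                                   substrate = model$substrate_id,
                                   product = model$product_id))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%|na|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a
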