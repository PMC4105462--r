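## Core data structures for constraint-based metabolic models.
##
## A model holds an ordered metabolite table, an ordered reaction table with
## flux bounds, per-reaction stoichiometry (named coefficient vectors), the
## designated biomass / substrate-exchange / product-exchange reactions and
## the linear objective weights c.

#' Construct a reaction
#'
#' @param id short unique identifier (BiGG-style, e.g. `"PYK"`, `"EX_glc_e"`).
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed, positive = produced). Must be
#'   non-empty.
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h; must satisfy
#'   `lower_bound <= upper_bound`.
#' @param name free-text name.
#' @param is_exchange logical; if `NA` it is inferred: a reaction whose
#'   stoichiometry has metabolites on one side only (all coefficients of one
#'   sign) is treated as an exchange.
#' @param deletable logical; whether the reaction may be knocked out.
#' @return an object of class `"mm_reaction"`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000,
                     upper_bound = 1000, name = id,
                     is_exchange = NA, deletable = TRUE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("reaction id must be a non-empty string")
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)))
    stop("reaction '", id, "': stoichiometry must be a named, non-empty vector")
  if (!all(nzchar(names(stoichiometry))))
    stop("reaction '", id, "': empty metabolite id in stoichiometry")
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  if (!is.finite(lower_bound) || !is.finite(upper_bound))
    stop("reaction '", id, "': bounds must be finite")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  if (is.na(is_exchange)) {
    s <- sign(stoichiometry)
    is_exchange <- all(s >= 0) || all(s <= 0)
  }
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 is_exchange = isTRUE(is_exchange),
                 deletable = isTRUE(deletable)),
            class = "mm_reaction")
}

#' Construct a metabolic model
#'
#' @param reactions list of [reaction()] objects, order preserved.
#' @param biomass_id id of the biomass (growth) reaction; never deletable.
#' @param substrate_id id of the substrate exchange reaction (e.g. glucose
#'   uptake); never deletable.
#' @param product_id id of the product exchange reaction whose flux is the
#'   production rate.
#' @param metabolites optional data frame with columns `id`, `name`,
#'   `compartment`; if `NULL`, metabolites are inferred from the
#'   stoichiometries (compartment `"c"`).
#' @param objective named numeric vector of objective weights c; defaults to
#'   weight 1 on the biomass reaction.
#' @param id model identifier.
#' @return a validated object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(reactions, biomass_id, substrate_id, product_id,
                            metabolites = NULL, objective = NULL,
                            id = "model") {
  if (!length(reactions)) stop("model needs at least one reaction")
  if (!all(vapply(reactions, inherits, logical(1), "mm_reaction")))
    stop("'reactions' must be a list of reaction() objects")
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicated reaction id: ", rids[duplicated(rids)][1])
  names(reactions) <- rids

  if (is.null(metabolites)) {
    mids <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
    metabolites <- data.frame(id = mids, name = mids, compartment = "c",
                              stringsAsFactors = FALSE)
  }
  if (is.null(objective)) objective <- stats::setNames(1, biomass_id)

  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      biomass_id = biomass_id,
                      substrate_id = substrate_id,
                      product_id = product_id,
                      objective = objective),
                 class = "metabolic_model")
  m <- validate_model(m)
  # structural protections: biomass and exchanges are never knockout targets
  m$reactions[[biomass_id]]$deletable <- FALSE
  for (rid in rids)
    if (m$reactions[[rid]]$is_exchange) m$reactions[[rid]]$deletable <- FALSE
  m
}

#' Validate a metabolic model
#'
#' Checks referential integrity (every stoichiometry key resolves to a
#' metabolite; designated reactions resolve), bound ordering and finite
#' objective weights. Returns the model invisibly-validated (for chaining).
#'
#' @param model a `"metabolic_model"`.
#' @return the model, if valid; otherwise an error.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mids <- model$metabolites$id
  if (anyDuplicated(mids)) stop("duplicated metabolite id: ",
                                mids[duplicated(mids)][1])
  if (!all(nzchar(mids))) stop("empty metabolite id")
  rids <- names(model$reactions)
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), mids)
    if (length(missing))
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    if (r$lower_bound > r$upper_bound)
      stop("reaction '", r$id, "': lower_bound > upper_bound")
  }
  for (field in c("biomass_id", "substrate_id", "product_id")) {
    rid <- model[[field]]
    if (!rid %in% rids)
      stop(field, " '", rid, "' does not resolve to a reaction")
  }
  if (!all(names(model$objective) %in% rids))
    stop("objective references unknown reaction(s)")
  if (!all(is.finite(model$objective)))
    stop("objective weights must be finite")
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  nr <- length(x$reactions)
  nd <- sum(vapply(x$reactions, `[[`, logical(1), "deletable"))
  cat("Metabolic model '", x$id, "': ",
      nrow(x$metabolites), " metabolites, ", nr, " reactions (",
      nd, " deletable)\n", sep = "")
  cat("  biomass:   ", x$biomass_id, "\n", sep = "")
  cat("  substrate: ", x$substrate_id, "\n", sep = "")
  cat("  product:   ", x$product_id, "\n", sep = "")
  invisible(x)
}

## ---- accessors -----------------------------------------------------------

reaction_ids <- function(model) names(model$reactions)

#' Ids of reactions available for knockout
#' @param model a `"metabolic_model"`.
#' @return character vector of reaction ids with `deletable = TRUE`.
#' @export
deletable_reactions <- function(model) {
  ids <- reaction_ids(model)
  ids[vapply(model$reactions, `[[`, logical(1), "deletable")]
}

bounds_matrix <- function(model) {
  cbind(lb = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
        ub = vapply(model$reactions, `[[`, numeric(1), "upper_bound"))
}

#' Stoichiometric matrix S
#'
#' Builds the sparse m x n stoichiometric matrix: rows are metabolites (model
#' order), columns reactions (model order), entry (i, j) the signed
#' coefficient of metabolite i in reaction j.
#'
#' @param model a validated `"metabolic_model"`.
#' @return a `Matrix::sparseMatrix` with dimnames (metabolite ids, reaction
#'   ids).
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- reaction_ids(model)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rids)) {
    st <- model$reactions[[j]]$stoichiometry
    ii <- c(ii, match(names(st), mids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

#' Export the stoichiometric matrix in MatrixMarket format
#'
#' @param model a `"metabolic_model"`.
#' @param path output `.mtx` file path.
#' @return the path, invisibly.
#' @export
write_stoichiometry_mtx <- function(model, path) {
  Matrix::writeMM(stoichiometric_matrix(model), path)
  invisible(path)
}

## ---- knockouts -----------------------------------------------------------

# close both flux bounds of the given reactions; no deletability check
force_knockout <- function(model, knockout_ids) {
  for (rid in knockout_ids) {
    model$reactions[[rid]]$lower_bound <- 0
    model$reactions[[rid]]$upper_bound <- 0
  }
  model
}

#' Apply reaction knockouts
#'
#' Returns a copy of the model in which each listed reaction has both flux
#' bounds set to zero (the constraint-based encoding of a deletion). The
#' input model is unmodified. Only reactions flagged `deletable` may be
#' knocked out; the biomass reaction and all exchanges are protected.
#'
#' @param model a validated `"metabolic_model"`.
#' @param knockout_ids character vector (possibly empty) of reaction ids.
#' @return the knockout model.
#' @export
apply_knockouts <- function(model, knockout_ids) {
  knockout_ids <- unique(as.character(knockout_ids))
  if (!length(knockout_ids)) return(model)
  unknown <- setdiff(knockout_ids, reaction_ids(model))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  del <- deletable_reactions(model)
  bad <- setdiff(knockout_ids, del)
  if (length(bad))
    stop("reaction(s) not deletable (biomass, exchange or protected): ",
         paste(bad, collapse = ", "))
  force_knockout(model, knockout_ids)
}
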