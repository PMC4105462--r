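## Model reduction before the knockout search.
##
## Two screens shrink and guard the search space: flux variability analysis
## finds blocked (dead-end) reactions, which are removed, and a
## single-deletion essentiality scan finds reactions whose loss drops
## maximal growth below the viability gate; those are protected from
## knockout (not removed - deleting an in-silico viable reaction would
## change wild-type behaviour). FVA runs with the exchange bounds as given
## by the model file.

#' Blocked (dead-end) reactions by flux variability analysis
#'
#' A reaction is blocked when both its minimal and maximal feasible flux
#' are zero (within `tol`) at steady state under the model's bounds.
#'
#' @param model a validated [metabolic_model()].
#' @param tol absolute flux tolerance (default 1e-9).
#' @return character vector of blocked reaction ids.
#' @export
find_dead_end_reactions <- function(model, tol = 1e-9) {
  rids <- reaction_ids(model)
  S <- as.matrix(stoichiometric_matrix(model))
  b <- bounds_matrix(model)
  dirs <- rep("=", nrow(S)); rhs <- numeric(nrow(S))
  blocked <- character(0)
  for (j in seq_along(rids)) {
    obj <- numeric(length(rids)); obj[j] <- 1
    hi <- lp_solve(obj, S, dirs, rhs, b[, "lb"], b[, "ub"], maximize = TRUE)
    if (hi$status != "optimal")
      stop("base model infeasible during FVA (reaction '", rids[j], "')")
    if (abs(hi$objective) > tol) next
    lo <- lp_solve(obj, S, dirs, rhs, b[, "lb"], b[, "ub"], maximize = FALSE)
    if (abs(lo$objective) <= tol) blocked <- c(blocked, rids[j])
  }
  blocked
}

#' Essential (lethal) reactions by single-deletion scan
#'
#' Knocks out each deletable reaction in turn and reports those whose loss
#' drops maximal growth to at most `growth_threshold`.
#'
#' @param model a validated [metabolic_model()]; wild-type maximal growth
#'   must exceed `growth_threshold`.
#' @param growth_threshold viability gate (per hour), the same 0.1 gate used
#'   by the fitness pipeline.
#' @return character vector of essential reaction ids.
#' @export
find_lethal_reactions <- function(model, growth_threshold = 0.1) {
  wt <- solve_fba(model, objective_id = model$biomass_id)
  if (wt$status != "optimal" || wt$objective_value <= growth_threshold)
    stop("wild-type maximal growth must exceed the viability gate (",
         growth_threshold, ")")
  del <- deletable_reactions(model)
  lethal <- character(0)
  for (rid in del) {
    ko <- solve_fba(force_knockout(model, rid),
                    objective_id = model$biomass_id)
    if (ko$status != "optimal" || ko$objective_value <= growth_threshold)
      lethal <- c(lethal, rid)
  }
  lethal
}

#' Reduce a model for knockout search
#'
#' Removes blocked reactions (and any metabolite left orphaned), then marks
#' essential, exchange, biomass and user-protected reactions as
#' non-deletable. The operation is idempotent and does not change wild-type
#' maximal growth or maximal product flux.
#'
#' @param model a validated [metabolic_model()].
#' @param user_protected additional reaction ids to protect from knockout.
#' @param growth_threshold viability gate for the essentiality scan.
#' @return list with `model` (the reduced model) and `report` (removed ids,
#'   protected ids, and before/after reaction counts).
#' @export
reduce_model <- function(model, user_protected = character(0),
                         growth_threshold = 0.1) {
  n_before <- length(model$reactions)
  dead <- find_dead_end_reactions(model)
  keep <- setdiff(reaction_ids(model), dead)
  model$reactions <- model$reactions[keep]
  used <- unique(unlist(lapply(model$reactions,
                               function(r) names(r$stoichiometry))))
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, ,
                                         drop = FALSE]
  model$objective <- model$objective[names(model$objective) %in% keep]
  validate_model(model)

  lethal <- find_lethal_reactions(model, growth_threshold)
  protect <- unique(c(lethal, intersect(user_protected, keep)))
  for (rid in protect) model$reactions[[rid]]$deletable <- FALSE

  list(model = model,
       report = list(removed = dead,
                     lethal = lethal,
                     user_protected = intersect(user_protected, keep),
                     n_reactions_before = n_before,
                     n_reactions_after = length(model$reactions),
                     n_deletable = length(deletable_reactions(model))))
}
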