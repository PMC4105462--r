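## Flux balance analysis and the knockout fitness score.
##
## FBA solves max (or min) c'v subject to steady state S v = 0 and flux
## bounds lb <= v <= ub. The knockout fitness used by the search is the
## biomass-product coupled yield (BPCY): after maximizing growth on the
## knockout model, growth is fixed at a fraction (default 90%) of its
## optimum, the product exchange flux is maximized, and
##   BPCY = product_flux * growth / |substrate uptake|.
## Mutants whose maximal growth does not exceed a viability gate (default
## 0.1 /h) score zero.

#' Solve the FBA linear program
#'
#' @param model a validated [metabolic_model()].
#' @param objective_id reaction id to optimize; defaults to the model's
#'   declared objective (weight vector c), usually biomass.
#' @param direction `"max"` or `"min"`.
#' @return an object of class `"fba_result"`: list with `status`
#'   (`"optimal"` or `"infeasible"`), `objective_value`, and `fluxes`
#'   (named vector over all reactions).
#' @export
solve_fba <- function(model, objective_id = NULL,
                      direction = c("max", "min")) {
  direction <- match.arg(direction)
  rids <- reaction_ids(model)
  if (is.null(objective_id)) {
    obj <- stats::setNames(numeric(length(rids)), rids)
    obj[names(model$objective)] <- model$objective
  } else {
    if (!objective_id %in% rids)
      stop("objective reaction '", objective_id, "' not in model")
    obj <- stats::setNames(numeric(length(rids)), rids)
    obj[objective_id] <- 1
  }
  S <- as.matrix(stoichiometric_matrix(model))
  b <- bounds_matrix(model)
  res <- lp_solve(obj = unname(obj),
                  A = S, dir = rep("=", nrow(S)), rhs = numeric(nrow(S)),
                  lb = b[, "lb"], ub = b[, "ub"],
                  maximize = direction == "max")
  structure(list(status = res$status,
                 objective_value = res$objective,
                 fluxes = stats::setNames(res$solution, rids)),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("FBA result: status ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective ", format(x$objective_value), sep = "")
  cat("\n")
  invisible(x)
}

#' Production yield
#'
#' Product flux generated per unit of substrate taken up (mmol product per
#' mmol substrate).
#'
#' @param product_flux product exchange flux (mmol/gDW/h).
#' @param substrate_uptake magnitude of the substrate uptake flux; must be
#'   positive.
#' @return `product_flux / substrate_uptake`.
#' @export
production_yield <- function(product_flux, substrate_uptake) {
  if (!is.finite(substrate_uptake) || substrate_uptake <= 0)
    stop("degenerate yield: substrate uptake must be positive")
  product_flux / substrate_uptake
}

#' Biomass-product coupled yield (BPCY)
#'
#' The fitness score coupling production to growth:
#' `(product_flux * growth) / substrate_uptake`.
#'
#' @param growth growth rate (per hour).
#' @param product_flux product exchange flux (mmol/gDW/h).
#' @param substrate_uptake magnitude of the substrate uptake flux; positive.
#' @return the BPCY value.
#' @export
bpcy <- function(growth, product_flux, substrate_uptake) {
  if (!is.finite(substrate_uptake) || substrate_uptake <= 0)
    stop("degenerate yield: substrate uptake must be positive")
  (product_flux * growth) / substrate_uptake
}

#' Score a knockout set by BPCY
#'
#' Implements the two-stage fitness evaluation: (1) maximize growth on the
#' knockout model; (2) if maximal growth exceeds `growth_threshold`, fix the
#' biomass flux at `growth_fraction` of that optimum and maximize the
#' product exchange flux; report the yield and BPCY at that point. Product
#' is maximized at sub-maximal growth because at the growth optimum the
#' product flux of a growth-coupled design is typically zero.
#'
#' @param model a validated [metabolic_model()].
#' @param knockouts character vector of deletable reaction ids (may be
#'   empty: wild type).
#' @param growth_threshold viability gate (per hour); mutants with maximal
#'   growth `<= growth_threshold` are scored infeasible with BPCY 0.
#' @param growth_fraction fraction of maximal growth at which the biomass
#'   flux is fixed (both bounds; the upper relaxed by 1e-9) before product
#'   maximization.
#' @return an object of class `"fitness_result"`: list with `growth`
#'   (the fixed growth rate), `product_flux`, `yield`, `bpcy`, `feasible`,
#'   plus `mu_max` (unfixed maximal growth) and `substrate_uptake`.
#' @export
evaluate_knockout_fitness <- function(model, knockouts = character(0),
                                      growth_threshold = 0.1,
                                      growth_fraction = 0.9) {
  ko_model <- apply_knockouts(model, knockouts)
  stage1 <- solve_fba(ko_model, objective_id = ko_model$biomass_id)
  mu_max <- stage1$objective_value
  infeasible <- structure(
    list(growth = 0, product_flux = 0, yield = 0, bpcy = 0,
         feasible = FALSE,
         mu_max = if (stage1$status == "optimal") mu_max else NA_real_,
         substrate_uptake = NA_real_),
    class = "fitness_result")
  # viability gate is strict: growth must exceed the threshold
  if (stage1$status != "optimal" || mu_max <= growth_threshold)
    return(infeasible)

  fixed <- growth_fraction * mu_max
  ko_model$reactions[[ko_model$biomass_id]]$lower_bound <- fixed
  ko_model$reactions[[ko_model$biomass_id]]$upper_bound <- fixed + 1e-9
  stage2 <- solve_fba(ko_model, objective_id = ko_model$product_id)
  if (stage2$status != "optimal") return(infeasible)

  p <- stage2$objective_value
  uptake <- abs(stage2$fluxes[[ko_model$substrate_id]])
  tol <- 1e-9
  if (uptake <= tol) {
    if (p > tol)
      stop("degenerate yield: product formed with zero flux through the ",
           "designated substrate exchange '", ko_model$substrate_id, "'")
    y <- 0; fit <- 0
  } else {
    y <- production_yield(p, uptake)
    fit <- bpcy(fixed, p, uptake)
  }
  structure(list(growth = fixed, product_flux = p, yield = y,
                 bpcy = max(fit, 0), feasible = TRUE,
                 mu_max = mu_max, substrate_uptake = uptake),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  if (!x$feasible) {
    cat("Knockout fitness: infeasible (growth below gate), BPCY 0\n")
  } else {
    cat("Knockout fitness: growth ", format(x$growth),
        " /h, product ", format(x$product_flux),
        " mmol/gDW/h, yield ", format(x$yield),
        ", BPCY ", format(x$bpcy), "\n", sep = "")
  }
  invisible(x)
}

#' Export a flux distribution as two-column CSV
#'
#' @param result an `"fba_result"`.
#' @param path output CSV path (columns `reaction`, `flux`).
#' @return the path, invisibly.
#' @export
write_fluxes_csv <- function(result, path) {
  stopifnot(inherits(result, "fba_result"))
  utils::write.csv(data.frame(reaction = names(result$fluxes),
                              flux = unname(result$fluxes)),
                   path, row.names = FALSE)
  invisible(path)
}
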