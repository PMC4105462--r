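## Synthetic toy networks with known optima, and exhaustive oracles.
##
## The generators build small constraint-based models whose best knockout
## sets are known by enumeration, so the search and MILP layers can be
## tested end to end without any model download. The branched generator
## plants a knockout optimum through an alternative biomass route that
## co-produces a by-product convertible to product: pure linear branch
## competition never rewards a knockout under growth-maximising FBA, which
## is exactly why real strain design is nontrivial.

#' Linear chain toy model with a product branch
#'
#' Substrate exchange (upper bound `uptake`) feeds a hub metabolite `G`;
#' `CONV` turns `G` into the biomass precursor `X`, drained by the
#' `BIOMASS` reaction (the objective); `GTOP` turns `G` into the product
#' `P`, exported by `EX_P`. Wild type: maximal growth = `uptake`; at 90%
#' growth fixation the spare substrate yields `product_yield * uptake/10`
#' units of product. `CONV` is essential; knocking it out zeroes growth.
#'
#' @param uptake substrate uptake upper bound (mmol/gDW/h).
#' @param product_yield stoichiometric yield of `GTOP` (P per G).
#' @return a validated [metabolic_model()].
#' @export
make_chain_model <- function(uptake = 10, product_yield = 1) {
  stopifnot(uptake > 0, product_yield > 0)
  rxns <- list(
    reaction("EX_glc", c(G = 1), 0, uptake, name = "substrate exchange"),
    reaction("CONV", c(G = -1, X = 1), 0, 1000,
             name = "biomass precursor synthesis"),
    reaction("BIOMASS", c(X = -1), 0, 1000, name = "biomass drain",
             is_exchange = FALSE, deletable = FALSE),
    reaction("GTOP", c(G = -1, P = product_yield), 0, 1000,
             name = "product synthesis"),
    reaction("EX_P", c(P = -1), 0, 1000, name = "product exchange"))
  m <- metabolic_model(rxns, biomass_id = "BIOMASS",
                       substrate_id = "EX_glc", product_id = "EX_P",
                       id = "chain_toy")
  assert_viable(m)
}

#' Branched toy model with a planted knockout optimum
#'
#' A substrate exchange (upper bound 10) feeds a hub metabolite `G` from
#' which `n_branches` routes compete: a biomass branch (`BIO`:
#' `G -> X`, with `X` drained by the objective reaction `BIOMASS`), a
#' product branch (`GTOP`: `G -> P`, exported), and `n_branches - 2`
#' competing drains (`GTOD<i>`). With `byproduct = TRUE` an alternative,
#' less substrate-efficient biomass route `BIOALT` (`2 G -> X + W`)
#' co-produces a by-product `W` that can either be wasted (`WDRAIN`) or
#' converted to product (`WTOP`); knocking out the efficient route `BIO`
#' then couples product formation to growth and raises the BPCY, so the
#' planted optimum is the single knockout `{BIO}`. With
#' `byproduct = FALSE` no knockout beats the wild type.
#'
#' @param n_branches total branches from the hub (>= 2).
#' @param branch_yields stoichiometric yield per branch, one value per
#'   branch (biomass, product, then drains).
#' @param byproduct logical; plant the knockout optimum (default `TRUE`).
#' @return a validated [metabolic_model()].
#' @export
make_branched_model <- function(n_branches = 3,
                                branch_yields = rep(1, n_branches),
                                byproduct = TRUE) {
  if (n_branches < 2) stop("n_branches must be at least 2")
  if (length(branch_yields) != n_branches)
    stop("branch_yields must have one entry per branch (",
         n_branches, "), got ", length(branch_yields))
  if (any(branch_yields <= 0)) stop("branch yields must be positive")
  y_bio <- branch_yields[1]
  y_prod <- branch_yields[2]

  rxns <- list(
    reaction("EX_glc", c(G = 1), 0, 10, name = "substrate exchange"),
    reaction("BIO", c(G = -1, X = y_bio), 0, 1000,
             name = "efficient biomass route"),
    reaction("BIOMASS", c(X = -1), 0, 1000, name = "biomass drain",
             is_exchange = FALSE, deletable = FALSE),
    reaction("GTOP", c(G = -1, P = y_prod), 0, 1000,
             name = "direct product route"),
    reaction("EX_P", c(P = -1), 0, 1000, name = "product exchange"))
  if (byproduct) {
    rxns <- c(rxns, list(
      reaction("BIOALT", c(G = -2, X = y_bio, W = 1), 0, 1000,
               name = "by-product-coupled biomass route"),
      reaction("WTOP", c(W = -1, P = 1), 0, 1000,
               name = "by-product to product"),
      reaction("WDRAIN", c(W = -1, Dw = 1), 0, 1000,
               name = "by-product waste"),
      reaction("EX_Dw", c(Dw = -1), 0, 1000,
               name = "by-product waste exchange")))
  }
  if (n_branches > 2) {
    for (i in seq_len(n_branches - 2)) {
      di <- paste0("D", i)
      st <- stats::setNames(c(-1, branch_yields[i + 2]), c("G", di))
      rxns <- c(rxns, list(
        reaction(paste0("GTOD", i), st, 0, 1000,
                 name = paste("competing drain", i)),
        reaction(paste0("EX_D", i),
                 stats::setNames(-1, di), 0, 1000,
                 name = paste("drain exchange", i))))
    }
  }
  m <- metabolic_model(rxns, biomass_id = "BIOMASS",
                       substrate_id = "EX_glc", product_id = "EX_P",
                       id = sprintf("branched_toy_%db%s", n_branches,
                                    if (byproduct) "_byp" else ""))
  assert_viable(m)
}

# constructive guarantee: generated fixtures are viable wild type
assert_viable <- function(model, growth_threshold = 0.1) {
  wt <- solve_fba(model, objective_id = model$biomass_id)
  if (wt$status != "optimal" || wt$objective_value <= growth_threshold)
    stop("generated model is not viable (wild-type growth <= ",
         growth_threshold, ")")
  model
}

# all index subsets of sizes 0..k
subsets_up_to <- function(n, k) {
  out <- list(integer(0))
  for (size in seq_len(min(k, n)))
    out <- c(out, utils::combn(n, size, simplify = FALSE))
  out
}

#' Exhaustive knockout enumeration oracle
#'
#' Scores every knockout set of size at most `max_k` (over the deletable
#' reactions) with [evaluate_knockout_fitness()] and returns the full
#' ranked table, best BPCY first, ties broken by smaller set then
#' lexicographic ids. Refuses models with more than 15 deletable reactions.
#'
#' @param model a validated [metabolic_model()].
#' @param max_k maximal knockout-set size.
#' @param growth_threshold,growth_fraction fitness parameters.
#' @return data frame with columns `knockouts` (ids joined by `"+"`), `k`,
#'   `growth`, `product_flux`, `yield`, `bpcy`, `feasible`; the knockout id
#'   sets as a list in attribute `"sets"`.
#' @export
brute_force_knockouts <- function(model, max_k,
                                  growth_threshold = 0.1,
                                  growth_fraction = 0.9) {
  del <- deletable_reactions(model)
  if (length(del) > 15)
    stop("refusing exhaustive enumeration over ", length(del),
         " deletable reactions (limit 15)")
  sets <- lapply(subsets_up_to(length(del), max_k),
                 function(ix) del[ix])
  rows <- lapply(sets, function(ko) {
    f <- evaluate_knockout_fitness(model, ko, growth_threshold,
                                   growth_fraction)
    data.frame(knockouts = paste(ko, collapse = "+"),
               k = length(ko), growth = f$growth,
               product_flux = f$product_flux, yield = f$yield,
               bpcy = f$bpcy, feasible = f$feasible,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$bpcy, tab$k, tab$knockouts)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "sets") <- sets[ord]
  tab
}

#' Exhaustive bilevel enumeration oracle
#'
#' For every knockout set of size at most `K`: maximise growth on the
#' knockout model (inner LP); if the optimum reaches `growth_floor`,
#' maximise product at that fixed growth. Returns the set with the highest
#' product rate (ties: fewer knockouts, then lexicographic ids). This is
#' the reference the bilevel MILP solver is checked against.
#'
#' @param model a validated [metabolic_model()].
#' @param K maximal knockout-set size.
#' @param growth_floor minimal acceptable inner-optimal growth (per hour).
#' @return list with `knockout_ids`, `product_rate`, `growth`, and
#'   `n_evaluated`.
#' @export
brute_force_bilevel <- function(model, K, growth_floor = 0.1) {
  del <- deletable_reactions(model)
  if (length(del) > 15)
    stop("refusing exhaustive enumeration over ", length(del),
         " deletable reactions (limit 15)")
  sets <- lapply(subsets_up_to(length(del), K), function(ix) del[ix])
  best <- NULL
  for (ko in sets) {
    ev <- bilevel_inner_eval(model, ko, growth_floor)
    if (is.null(ev)) next
    if (is.null(best) || ev$rate > best$rate + 1e-9 ||
        (ev$rate > best$rate - 1e-9 &&
         (length(ko) < length(best$ko) ||
          (length(ko) == length(best$ko) &&
           paste(ko, collapse = "+") < paste(best$ko, collapse = "+"))))) {
      best <- list(ko = ko, rate = ev$rate, growth = ev$growth)
    }
  }
  if (is.null(best))
    stop("no knockout set reaches the growth floor ", growth_floor)
  list(knockout_ids = best$ko, product_rate = best$rate,
       growth = best$growth, n_evaluated = length(sets))
}

# shared inner evaluation of the bilevel program for a fixed knockout set:
# max growth; if >= floor, max product at that (inner-optimal) growth
bilevel_inner_eval <- function(model, knockout_ids, growth_floor) {
  km <- force_knockout(model, knockout_ids)
  inner <- solve_fba(km, objective_id = km$biomass_id)
  if (inner$status != "optimal") return(NULL)
  mu <- inner$objective_value
  if (mu + 1e-9 < growth_floor) return(NULL)
  km$reactions[[km$biomass_id]]$lower_bound <- mu
  km$reactions[[km$biomass_id]]$upper_bound <- mu + 1e-9
  outer <- solve_fba(km, objective_id = km$product_id)
  if (outer$status != "optimal") return(NULL)
  list(rate = outer$objective_value, growth = mu)
}

#' Write the synthetic fixtures to disk
#'
#' Emits each toy model in both JSON and SBML together with its exhaustive
#' knockout oracle table as CSV, so every layer of the package can be
#' exercised from identical on-disk inputs.
#'
#' @param dir output directory (created if missing).
#' @param max_k oracle enumeration depth.
#' @return character vector of written paths, invisibly.
#' @export
write_fixtures <- function(dir, max_k = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- list(chain = make_chain_model(),
                 branched = make_branched_model(3, byproduct = TRUE),
                 branched_plain = make_branched_model(3, byproduct = FALSE))
  paths <- character(0)
  for (nm in names(models)) {
    m <- models[[nm]]
    pj <- file.path(dir, paste0(nm, ".json"))
    px <- file.path(dir, paste0(nm, ".xml"))
    pc <- file.path(dir, paste0(nm, "_oracle.csv"))
    write_model(m, pj)
    write_model(m, px)
    utils::write.csv(brute_force_knockouts(m, max_k), pc,
                     row.names = FALSE)
    paths <- c(paths, pj, px, pc)
  }
  invisible(paths)
}
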