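## The DE-hybridised bees search.
##
## Global structure is the classic bees algorithm: a population of scout
## bees is evaluated, the best sites are selected (at most m, and never more
## than a quarter of the population), the selected sites undergo
## neighbourhood search, and the remaining bees are re-scattered at random.
## The neighbourhood search is differential evolution over the selected
## sites: donor = x_r1 + F*(x_r2 - x_r3), binomial crossover with rate CR,
## greedy replacement. Every genotype is a trait vector in [0,1]^d; in the
## knockout space traits are binarised at 0.5 (trait < 0.5 = reaction
## absent), which lets the real-valued DE arithmetic act on binary bees.

#' Search hyper-parameters
#'
#' Defaults follow the tuned settings of the method: `m_sites = 15`,
#' `F = 1`, `CR = 0.5`, and a selected-site cap of a quarter of the
#' population. The effective number of sites is
#' `min(m_sites, ceiling(selected_cap_fraction * n_scouts))`.
#'
#' @param n_scouts population size (scout bees).
#' @param m_sites requested number of selected sites.
#' @param selected_cap_fraction cap on selected sites as a fraction of the
#'   population.
#' @param F DE mutation factor, in `[0, 2]`.
#' @param CR DE crossover probability, in `[0, 1]`.
#' @param de_generations DE generations run on the selected sites per bees
#'   iteration.
#' @param ko_init_prob probability that a reaction is absent in an initial
#'   bee (knockout space); `NULL` means `min(0.5, 3 / d)`, so initial
#'   mutants carry about three knockouts on genome-scale spaces while tiny
#'   spaces stay unbiased rather than fully knocked out.
#' @param max_knockouts cap on simultaneous knockouts per bee at
#'   initialisation and scouting; `Inf` disables the cap.
#' @param growth_threshold,growth_fraction fitness-pipeline parameters, see
#'   [evaluate_knockout_fitness()].
#' @param max_iterations bees iterations (0 = score the initial population
#'   only).
#' @param convergence_window stop early when the best fitness has improved
#'   by less than 1e-9 for this many consecutive iterations.
#' @param ba_recruits recruited bees per site for the classic-BA
#'   neighbourhood (comparison variant).
#' @param ba_ngh neighbourhood patch radius (trait units) for classic BA.
#' @param ba_shrink multiplicative per-iteration shrink of `ba_ngh`; the
#'   classic algorithm keeps the patch size fixed (`1.0`, the default).
#' @param seed integer seed; all stochastic draws flow from it.
#' @return an object of class `"optimizer_config"`.
#' @export
optimizer_config <- function(n_scouts = 50, m_sites = 15,
                             selected_cap_fraction = 0.25,
                             F = 1, CR = 0.5, de_generations = 5,
                             ko_init_prob = NULL, max_knockouts = 5,
                             growth_threshold = 0.1, growth_fraction = 0.9,
                             max_iterations = 50, convergence_window = 20,
                             ba_recruits = 5, ba_ngh = 0.1,
                             ba_shrink = 1.0, seed = 1) {
  stopifnot(n_scouts >= 2, m_sites >= 1,
            selected_cap_fraction > 0, selected_cap_fraction <= 1,
            F >= 0, F <= 2, CR >= 0, CR <= 1,
            de_generations >= 1, max_iterations >= 0,
            convergence_window >= 1, max_knockouts >= 0)
  structure(list(n_scouts = as.integer(n_scouts),
                 m_sites = as.integer(m_sites),
                 selected_cap_fraction = selected_cap_fraction,
                 F = F, CR = CR,
                 de_generations = as.integer(de_generations),
                 ko_init_prob = ko_init_prob,
                 max_knockouts = max_knockouts,
                 growth_threshold = growth_threshold,
                 growth_fraction = growth_fraction,
                 max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window),
                 ba_recruits = as.integer(ba_recruits),
                 ba_ngh = ba_ngh, ba_shrink = ba_shrink,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

n_selected_sites <- function(config) {
  min(config$m_sites,
      as.integer(ceiling(config$selected_cap_fraction * config$n_scouts)))
}

## ---- search spaces -------------------------------------------------------

#' Knockout search space over a metabolic model
#'
#' Wraps a pre-processed model as a binary search space: dimension = number
#' of deletable reactions; trait j < 0.5 means reaction j is knocked out;
#' fitness is the BPCY from [evaluate_knockout_fitness()]. Fitness values
#' are memoised by phenotype, so duplicate genotypes cost one LP evaluation.
#'
#' @param model a validated [metabolic_model()].
#' @param growth_threshold,growth_fraction see
#'   [evaluate_knockout_fitness()].
#' @return an object of class `"search_space"`.
#' @export
knockout_space <- function(model, growth_threshold = 0.1,
                           growth_fraction = 0.9) {
  ids <- deletable_reactions(model)
  if (!length(ids)) stop("model has no deletable reactions")
  cache <- new.env(parent = emptyenv())
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  fitness <- function(phenotype) {
    key <- paste(phenotype, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    counter$n <- counter$n + 1L
    fit <- evaluate_knockout_fitness(model, ids[phenotype == 0L],
                                     growth_threshold = growth_threshold,
                                     growth_fraction = growth_fraction)$bpcy
    cache[[key]] <- fit
    fit
  }
  structure(list(type = "binary", d = length(ids), ids = ids,
                 decode = function(traits) as.integer(traits >= 0.5),
                 fitness = fitness, counter = counter),
            class = "search_space")
}

#' Continuous search space over a benchmark function
#'
#' @param fn a [make_benchmark()] object (maximisation sense).
#' @return an object of class `"search_space"`.
#' @export
continuous_space <- function(fn) {
  stopifnot(inherits(fn, "benchmark_function"))
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  span <- fn$upper - fn$lower
  structure(list(type = "continuous", d = fn$dimension, ids = NULL,
                 decode = function(traits) fn$lower + traits * span,
                 fitness = function(x) {
                   counter$n <- counter$n + 1L
                   fn$evaluate(x)
                 },
                 counter = counter),
            class = "search_space")
}

as_search_space <- function(x, config) {
  if (inherits(x, "search_space")) x
  else if (inherits(x, "metabolic_model"))
    knockout_space(x, config$growth_threshold, config$growth_fraction)
  else if (inherits(x, "benchmark_function")) continuous_space(x)
  else stop("cannot search over an object of class ", class(x)[1])
}

eval_traits <- function(space, traits) space$fitness(space$decode(traits))

## ---- population ----------------------------------------------------------

random_bee <- function(space, config) {
  d <- space$d
  if (space$type == "continuous") return(stats::runif(d))
  p <- config$ko_init_prob %||% min(0.5, 3 / d)
  absent <- stats::runif(d) < p
  over <- sum(absent) - config$max_knockouts
  if (over > 0) {
    flip <- sample(which(absent), over)
    absent[flip] <- FALSE
  }
  ifelse(absent, stats::runif(d, 0, 0.5), stats::runif(d, 0.5, 1))
}

#' Initialise a scout-bee population
#'
#' Traits are drawn uniformly on `[0,1]^d`. In the knockout space each
#' reaction is set absent independently with probability `ko_init_prob`
#' (then capped at `max_knockouts` by re-flipping randomly chosen absent
#' reactions to present), so initial mutants are viable-sized.
#'
#' @param config an [optimizer_config()].
#' @param space a `"search_space"`.
#' @return numeric matrix, `n_scouts` rows of trait vectors.
#' @export
initialize_population <- function(config, space) {
  if (space$d == 0L) stop("search space has dimension 0")
  t(vapply(seq_len(config$n_scouts), function(i) random_bee(space, config),
           numeric(space$d)))
}

#' Select the best sites of an evaluated population
#'
#' Takes the top `min(m_sites, ceiling(n_scouts/4))` genotypes by fitness;
#' ties are broken by fewer knockouts (binary space) and then by
#' lexicographic phenotype, so selection is deterministic.
#'
#' @param traits population trait matrix.
#' @param fitness fitness per row.
#' @param config an [optimizer_config()].
#' @param space the `"search_space"` the population lives in.
#' @return integer vector of selected row indices, best first.
#' @export
select_sites <- function(traits, fitness, config, space) {
  n_sites <- min(n_selected_sites(config), nrow(traits))
  phen <- t(apply(traits, 1, space$decode))
  nko <- if (space$type == "binary") rowSums(phen == 0) else
    rep(0, nrow(traits))
  lex <- apply(phen, 1, paste, collapse = ",")
  ord <- order(-fitness, nko, lex)
  ord[seq_len(n_sites)]
}

clip01 <- function(x) pmin(1, pmax(0, x))

# pad a site pool to >= 4 rows: copies of random sites with one random
# coordinate perturbed (binary: reflected across 0.5; continuous: redrawn)
pad_pool <- function(traits, space) {
  while (nrow(traits) < 4L) {
    src <- traits[sample(nrow(traits), 1L), ]
    j <- sample(length(src), 1L)
    src[j] <- if (space$type == "binary") 1 - src[j] else stats::runif(1)
    traits <- rbind(traits, src)
  }
  traits
}

#' DE neighbourhood search over selected sites
#'
#' Runs `de_generations` rounds of differential evolution restricted to the
#' selected-site pool: for each site, a donor `x_r1 + F*(x_r2 - x_r3)`
#' (distinct partners, clipped to `[0,1]`) is recombined with the site by
#' binomial crossover (rate `CR`, one coordinate forced from the donor) and
#' replaces it only if the trial fitness is at least as good. When fewer
#' than four sites are available the pool is padded with singly-perturbed
#' copies, which act as donors only.
#'
#' @param traits matrix of selected-site trait vectors.
#' @param fitness their fitness values.
#' @param config an [optimizer_config()].
#' @param space the `"search_space"`.
#' @return list with updated `traits` and `fitness` (same number of rows as
#'   the input; never worse element-wise).
#' @export
de_neighborhood_search <- function(traits, fitness, config, space) {
  traits <- rbind(traits)  # keep matrix shape for a single site
  n_sites <- nrow(traits)
  pool <- pad_pool(traits, space)
  pool_fit <- c(fitness, rep(NA_real_, nrow(pool) - n_sites))
  d <- ncol(pool)
  for (gen in seq_len(config$de_generations)) {
    for (i in seq_len(n_sites)) {
      partners <- sample(setdiff(seq_len(nrow(pool)), i), 3L)
      donor <- clip01(pool[partners[1], ] +
                        config$F * (pool[partners[2], ] - pool[partners[3], ]))
      jrand <- sample(d, 1L)
      take <- stats::runif(d) < config$CR
      take[jrand] <- TRUE
      trial <- ifelse(take, donor, pool[i, ])
      trial_fit <- eval_traits(space, trial)
      if (trial_fit >= pool_fit[i]) {
        pool[i, ] <- trial
        pool_fit[i] <- trial_fit
      }
    }
  }
  list(traits = pool[seq_len(n_sites), , drop = FALSE],
       fitness = pool_fit[seq_len(n_sites)])
}

# classic bees-algorithm neighbourhood: per site, ba_recruits uniform draws
# within a shrinking radius; greedy keep-best
ba_neighborhood_search <- function(traits, fitness, config, space, ngh) {
  traits <- rbind(traits)
  for (i in seq_len(nrow(traits))) {
    for (r in seq_len(config$ba_recruits)) {
      trial <- clip01(traits[i, ] +
                        stats::runif(ncol(traits), -ngh, ngh))
      trial_fit <- eval_traits(space, trial)
      if (trial_fit >= fitness[i]) {
        traits[i, ] <- trial
        fitness[i] <- trial_fit
      }
    }
  }
  list(traits = traits, fitness = fitness)
}

## ---- main loops ----------------------------------------------------------

run_bees <- function(x, config, neighborhood) {
  stopifnot(inherits(config, "optimizer_config"))
  set.seed(config$seed)
  space <- as_search_space(x, config)

  traits <- initialize_population(config, space)
  fitness <- apply(traits, 1, function(tr) eval_traits(space, tr))

  best_i <- which.max(fitness)
  best_fit <- fitness[best_i]
  best_traits <- traits[best_i, ]
  history <- best_fit
  last_improved <- 0L
  iters_run <- 0L

  for (iter in seq_len(config$max_iterations)) {
    iters_run <- iter
    sel <- select_sites(traits, fitness, config, space)
    ngh <- config$ba_ngh * config$ba_shrink^(iter - 1)
    sites <- neighborhood(traits[sel, , drop = FALSE], fitness[sel],
                          config, space, ngh)
    n_scout <- config$n_scouts - length(sel)
    scout_traits <- t(vapply(seq_len(n_scout),
                             function(i) random_bee(space, config),
                             numeric(space$d)))
    scout_fit <- apply(scout_traits, 1,
                       function(tr) eval_traits(space, tr))
    traits <- rbind(sites$traits, scout_traits)
    fitness <- c(sites$fitness, scout_fit)

    it_best <- which.max(fitness)
    if (fitness[it_best] > best_fit + 1e-9) {
      best_fit <- fitness[it_best]
      best_traits <- traits[it_best, ]
      last_improved <- iter
    } else if (fitness[it_best] > best_fit) {
      best_fit <- fitness[it_best]
      best_traits <- traits[it_best, ]
    }
    history <- c(history, best_fit)
    if (iter - last_improved >= config$convergence_window) break
  }

  phenotype <- space$decode(best_traits)
  structure(list(
    best_genotype = list(traits = best_traits, phenotype = phenotype,
                         fitness = best_fit),
    best_fitness = best_fit,
    knockout_ids = if (space$type == "binary")
      space$ids[phenotype == 0L] else character(0),
    fitness_history = history,
    evaluations = space$counter$n,
    iterations = iters_run,
    seed = config$seed),
    class = "dbfba_result")
}

#' Run the DE-hybridised bees search
#'
#' Iterates evaluate -> select sites -> DE neighbourhood search -> random
#' re-scatter of the remaining scouts, with elitist tracking of the best
#' genotype ever seen, until `max_iterations` or until the best fitness has
#' stagnated for `convergence_window` iterations.
#'
#' @param x a [metabolic_model()] (knockout design), a
#'   [make_benchmark()] function, or a prebuilt `"search_space"`.
#' @param config an [optimizer_config()].
#' @return an object of class `"dbfba_result"`: best genotype, knockout ids
#'   (binary space), per-iteration best-fitness history (non-decreasing),
#'   evaluation count and seed.
#' @export
run_dbfba <- function(x, config = optimizer_config()) {
  run_bees(x, config, function(tr, fit, cfg, sp, ngh)
    de_neighborhood_search(tr, fit, cfg, sp))
}

#' Run the classic bees search (comparison variant)
#'
#' Identical global loop to [run_dbfba()], but the neighbourhood search is
#' the classic one: each selected site receives `ba_recruits` uniform
#' samples within a patch of radius `ba_ngh` (trait units), optionally
#' shrunk by `ba_shrink` per iteration (fixed by default, as in the
#' classic algorithm).
#'
#' @inheritParams run_dbfba
#' @return a `"dbfba_result"`.
#' @export
run_ba <- function(x, config = optimizer_config()) {
  run_bees(x, config, ba_neighborhood_search)
}

#' @export
print.dbfba_result <- function(x, ...) {
  cat("Bees search result (seed ", x$seed, "): best fitness ",
      format(x$best_fitness), " after ", x$iterations,
      " iterations, ", x$evaluations, " evaluations\n", sep = "")
  if (length(x$knockout_ids))
    cat("  knockouts: ", paste(x$knockout_ids, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
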