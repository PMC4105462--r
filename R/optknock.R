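## Bilevel OptKnock: outer maximisation of product flux over reaction
## knockouts, inner growth-maximising FBA.
##
## The bilevel program is collapsed to a single-level MILP by replacing the
## inner LP with its optimality conditions: primal feasibility, dual
## feasibility (with big-M deactivation of the dual constraint of a
## knocked-out reaction), and the strong-duality equality primal objective
## = dual objective, in which products y * mu between knockout binaries and
## dual variables are linearised with auxiliary variables. The MILP is
## solved exactly by branch and bound on the knockout binaries y (y_j = 0
## means reaction j is knocked out), using the LP relaxation for bounds.
## Integral incumbents are re-scored by the direct two-stage LP evaluation
## of the bilevel objective, so reported rates never carry big-M artefacts.

#' Solve the bilevel knockout MILP
#'
#' Finds, over all knockout sets of size at most `K` drawn from
#' `candidate_ids`, the set maximising the product exchange flux attained
#' at inner-optimal (maximal) growth, subject to that growth reaching
#' `growth_floor`. Among equal-rate optima, sets with fewer knockouts are
#' preferred (a `1e-6` objective penalty per knockout).
#'
#' @param model a validated, preferably reduced, [metabolic_model()].
#' @param K maximal number of knockouts (>= 0).
#' @param growth_floor minimal acceptable growth rate (per hour).
#' @param candidate_ids knockout candidates; defaults to all deletable
#'   reactions.
#' @param big_M deactivation constant for the dual constraints and bound on
#'   dual variables; default twice the largest absolute flux bound.
#' @param max_nodes branch-and-bound node budget; exceeding it returns the
#'   incumbent with status `"time_limit"`.
#' @return an object of class `"optknock_result"`: list with
#'   `knockout_ids`, `product_rate`, `growth`, `status` (`"optimal"`,
#'   `"infeasible"` or `"time_limit"`), `nodes` explored and
#'   `duality_gap` of the inner LP at the returned solution.
#' @export
solve_optknock <- function(model, K, growth_floor = 0.1,
                           candidate_ids = NULL, big_M = NULL,
                           max_nodes = 10000L) {
  stopifnot(inherits(model, "metabolic_model"), K >= 0)
  rids <- reaction_ids(model)
  if (is.null(candidate_ids)) candidate_ids <- deletable_reactions(model)
  bad <- setdiff(candidate_ids, deletable_reactions(model))
  if (length(bad))
    stop("candidate(s) not deletable: ", paste(bad, collapse = ", "))
  milp <- optknock_milp(model, candidate_ids, growth_floor, K, big_M)
  nc <- length(candidate_ids)
  penalty <- 1e-6

  # score an integral y exactly via the two-stage bilevel evaluation
  score_integral <- function(y) {
    ko <- candidate_ids[y < 0.5]
    ev <- bilevel_inner_eval(model, ko, growth_floor)
    if (is.null(ev)) return(NULL)
    list(ko = ko, rate = ev$rate, growth = ev$growth,
         score = ev$rate - penalty * length(ko))
  }

  incumbent <- score_integral(rep(1, nc))  # wild type, if viable
  nodes <- 0L
  hit_cap <- FALSE
  stack <- list(rep(NA_real_, nc))  # NA = free binary

  while (length(stack)) {
    fix <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > max_nodes) { hit_cap <- TRUE; break }

    rel <- optknock_lp(milp, fix)
    if (rel$status != "optimal") next
    if (!is.null(incumbent) && rel$objective <= incumbent$score + 1e-9)
      next
    y <- rel$y
    frac <- abs(y - round(y))
    if (max(frac) <= 1e-6) {
      cand <- score_integral(round(y))
      if (!is.null(cand) &&
          (is.null(incumbent) || cand$score > incumbent$score + 1e-12))
        incumbent <- cand
      next
    }
    j <- which.max(frac)  # most fractional binary
    child0 <- fix; child0[j] <- 0
    child1 <- fix; child1[j] <- 1
    # explore the keep-branch first (depth-first): knockouts are sparse
    stack <- c(stack, list(child0), list(child1))
  }

  if (is.null(incumbent))
    return(structure(list(knockout_ids = character(0),
                          product_rate = NA_real_, growth = NA_real_,
                          status = "infeasible", nodes = nodes,
                          duality_gap = NA_real_),
                     class = "optknock_result"))

  structure(list(knockout_ids = incumbent$ko,
                 product_rate = incumbent$rate,
                 growth = incumbent$growth,
                 status = if (hit_cap) "time_limit" else "optimal",
                 nodes = nodes,
                 duality_gap = inner_duality_gap(model, incumbent$ko)),
            class = "optknock_result")
}

#' @export
print.optknock_result <- function(x, ...) {
  cat("OptKnock result: status ", x$status, sep = "")
  if (!is.na(x$product_rate))
    cat(", product rate ", format(x$product_rate),
        " at growth ", format(x$growth), sep = "")
  cat("\n")
  if (length(x$knockout_ids))
    cat("  knockouts: ", paste(x$knockout_ids, collapse = ", "), "\n",
        sep = "")
  else cat("  knockouts: none\n")
  invisible(x)
}

## ---- MILP assembly -------------------------------------------------------

# Variable layout: v (n) | lambda (m) | mu_u (n) | mu_l (n) | z_u (nc) |
# z_l (nc) | y (nc).  Inner objective c = model objective (biomass).
optknock_milp <- function(model, candidate_ids, growth_floor, K,
                          big_M = NULL) {
  rids <- reaction_ids(model)
  n <- length(rids)
  S <- as.matrix(stoichiometric_matrix(model))
  m <- nrow(S)
  b <- bounds_matrix(model)
  lbv <- b[, "lb"]; ubv <- b[, "ub"]
  if (is.null(big_M)) big_M <- 2 * max(abs(c(lbv, ubv)), 1)
  cand <- match(candidate_ids, rids)
  nc <- length(cand)
  cvec <- stats::setNames(numeric(n), rids)
  cvec[names(model$objective)] <- model$objective

  nv <- n + m + n + n + nc + nc + nc
  off <- list(v = 0L, lam = n, mu_u = n + m, mu_l = n + m + n,
              z_u = 3L * n + m, z_l = 3L * n + m + nc,
              y = 3L * n + m + 2L * nc)

  lb <- numeric(nv); ub <- numeric(nv)
  lb[off$v + seq_len(n)] <- lbv; ub[off$v + seq_len(n)] <- ubv
  # knockout candidates may be driven to zero by y: relax v bounds to
  # include 0 so the y-coupling rows govern them
  lb[off$v + cand] <- pmin(lbv[cand], 0)
  ub[off$v + cand] <- pmax(ubv[cand], 0)
  lb[off$lam + seq_len(m)] <- -big_M; ub[off$lam + seq_len(m)] <- big_M
  ub[off$mu_u + seq_len(n)] <- big_M
  ub[off$mu_l + seq_len(n)] <- big_M
  ub[off$z_u + seq_len(nc)] <- big_M
  ub[off$z_l + seq_len(nc)] <- big_M
  ub[off$y + seq_len(nc)] <- 1

  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add_row <- function(ix, val, dir, b) {
    r <- numeric(nv); r[ix] <- val
    rows[[length(rows) + 1L]] <<- r
    dirs <<- c(dirs, dir); rhs <<- c(rhs, b)
  }

  # (1) steady state: S v = 0
  for (i in seq_len(m))
    add_row(off$v + seq_len(n), S[i, ], "=", 0)
  # (2) knockout coupling: lb_j*y_j <= v_j <= ub_j*y_j
  for (t in seq_len(nc)) {
    j <- cand[t]
    add_row(c(off$v + j, off$y + t), c(1, -ubv[j]), "<=", 0)
    add_row(c(off$v + j, off$y + t), c(1, -lbv[j]), ">=", 0)
  }
  # (3) dual feasibility: S_j' lam + mu_u_j - mu_l_j = c_j, relaxed by
  #     +/- big_M * (1 - y_j) for knockout candidates
  for (j in seq_len(n)) {
    ix <- c(off$lam + seq_len(m), off$mu_u + j, off$mu_l + j)
    val <- c(S[, j], 1, -1)
    t <- match(j, cand)
    if (is.na(t)) {
      add_row(ix, val, "=", cvec[j])
    } else {
      add_row(c(ix, off$y + t), c(val, big_M), "<=", cvec[j] + big_M)
      add_row(c(ix, off$y + t), c(val, -big_M), ">=", cvec[j] - big_M)
    }
  }
  # (4) strong duality: c'v = sum(ub*mu_u - lb*mu_l), with z = y*mu for
  #     candidates
  sd_ix <- off$v + seq_len(n); sd_val <- unname(cvec)
  noncand <- setdiff(seq_len(n), cand)
  sd_ix <- c(sd_ix, off$mu_u + noncand, off$mu_l + noncand,
             off$z_u + seq_len(nc), off$z_l + seq_len(nc))
  sd_val <- c(sd_val, -ubv[noncand], lbv[noncand],
              -ubv[cand], lbv[cand])
  add_row(sd_ix, sd_val, "=", 0)
  # (5) z linearisation: z <= M y ; z <= mu ; z >= mu - M(1 - y)
  for (t in seq_len(nc)) {
    j <- cand[t]
    for (side in c("u", "l")) {
      zo <- if (side == "u") off$z_u else off$z_l
      mo <- if (side == "u") off$mu_u else off$mu_l
      add_row(c(zo + t, off$y + t), c(1, -big_M), "<=", 0)
      add_row(c(zo + t, mo + j), c(1, -1), "<=", 0)
      add_row(c(zo + t, mo + j, off$y + t), c(1, -1, -big_M), ">=", -big_M)
    }
  }
  # (6) growth floor
  add_row(off$v + match(model$biomass_id, rids), 1, ">=", growth_floor)
  # (7) cardinality: at most K zeros among y
  add_row(off$y + seq_len(nc), rep(1, nc), ">=", nc - K)

  obj <- numeric(nv)
  obj[off$v + match(model$product_id, rids)] <- 1
  obj[off$y + seq_len(nc)] <- 1e-6  # prefer fewer knockouts

  list(A = do.call(rbind, rows), dirs = dirs, rhs = rhs,
       lb = lb, ub = ub, obj = obj, off = off, nc = nc, n = n,
       penalty_base = 1e-6 * nc)
}

# LP relaxation at a branch-and-bound node: fix the listed binaries.
# Returns the bound translated to the same scale as the integral score
# (rate - penalty * knockouts).
optknock_lp <- function(milp, fix) {
  lb <- milp$lb; ub <- milp$ub
  yix <- milp$off$y + seq_len(milp$nc)
  fixed <- !is.na(fix)
  lb[yix[fixed]] <- fix[fixed]
  ub[yix[fixed]] <- fix[fixed]
  res <- lp_solve(milp$obj, milp$A, milp$dirs, milp$rhs, lb, ub,
                  maximize = TRUE)
  if (res$status != "optimal")
    return(list(status = res$status))
  list(status = "optimal",
       # obj = rate + 1e-6*sum(y); score scale = rate - 1e-6*(nc - sum(y))
       objective = res$objective - milp$penalty_base,
       y = res$solution[yix])
}

# duality gap of the inner growth LP at a fixed knockout set: difference
# between the primal optimum and the dual objective built from the dual
# multipliers of an explicit dual solve
inner_duality_gap <- function(model, knockout_ids) {
  km <- force_knockout(model, knockout_ids)
  rids <- reaction_ids(km)
  S <- as.matrix(stoichiometric_matrix(km))
  b <- bounds_matrix(km)
  n <- length(rids); m <- nrow(S)
  cvec <- stats::setNames(numeric(n), rids)
  cvec[names(km$objective)] <- km$objective
  primal <- lp_solve(unname(cvec), S, rep("=", m), numeric(m),
                     b[, "lb"], b[, "ub"], maximize = TRUE)
  if (primal$status != "optimal") return(NA_real_)
  # dual: min ub'mu_u - lb'mu_l  s.t.  S'lam + mu_u - mu_l = c, mu >= 0
  big <- 2 * max(abs(b), 1) * 100
  nv <- m + 2 * n
  obj <- c(numeric(m), b[, "ub"], -b[, "lb"])
  A <- cbind(t(S), diag(n), -diag(n))
  lb <- c(rep(-big, m), numeric(2 * n))
  ub <- rep(big, nv)
  dual <- lp_solve(obj, A, rep("=", n), unname(cvec), lb, ub,
                   maximize = FALSE)
  if (dual$status != "optimal") return(NA_real_)
  abs(primal$objective - dual$objective)
}

#' Export the bilevel MILP in CPLEX LP format
#'
#' Writes the assembled single-level MILP (primal feasibility, big-M dual
#' feasibility, strong duality, knockout coupling and cardinality rows) to
#' a plain-text `.lp` file for inspection or debugging with an external
#' solver.
#'
#' @inheritParams solve_optknock
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_optknock_lp <- function(model, K, growth_floor = 0.1,
                              candidate_ids = NULL, big_M = NULL, path) {
  if (is.null(candidate_ids)) candidate_ids <- deletable_reactions(model)
  milp <- optknock_milp(model, candidate_ids, growth_floor, K, big_M)
  rids <- reaction_ids(model)
  n <- milp$n; nc <- milp$nc
  mids <- model$metabolites$id
  vn <- c(paste0("v_", rids),
          paste0("lam_", mids),
          paste0("muU_", rids), paste0("muL_", rids),
          paste0("zU_", candidate_ids), paste0("zL_", candidate_ids),
          paste0("y_", candidate_ids))
  term <- function(coefs) {
    ix <- which(abs(coefs) > 1e-12)
    paste(sprintf("%+.12g %s", coefs[ix], vn[ix]), collapse = " ")
  }
  lines <- c("\\ bilevel knockout MILP (strong-duality reformulation)",
             "Maximize", paste(" obj:", term(milp$obj)), "Subject To")
  op <- c("<=" = "<=", ">=" = ">=", "=" = "=")
  for (i in seq_len(nrow(milp$A)))
    lines <- c(lines, sprintf(" c%d: %s %s %.12g", i, term(milp$A[i, ]),
                              op[[milp$dirs[i]]], milp$rhs[i]))
  lines <- c(lines, "Bounds")
  for (j in seq_along(vn))
    lines <- c(lines, sprintf(" %.12g <= %s <= %.12g",
                              milp$lb[j], vn[j], milp$ub[j]))
  lines <- c(lines, "Binary",
             paste("", paste0("y_", candidate_ids), collapse = " "),
             "End")
  writeLines(lines, path)
  invisible(path)
}

## ---- validation ----------------------------------------------------------

#' Validate a heuristic knockout solution against the bilevel MILP
#'
#' Re-optimises the knockout design with [solve_optknock()] (same number of
#' knockouts, all deletable reactions as candidates) and accepts the
#' heuristic solution when the absolute difference between its value and
#' the MILP's maximal production rate is strictly below `threshold`.
#'
#' The default mode compares product *rates* at the same fixed growth: the
#' model's biomass upper bound is clamped to the heuristic's fixed growth,
#' so the MILP reports the best achievable product flux at that growth and
#' the two numbers share units. `mode = "bpcy"` instead compares the
#' heuristic's BPCY against the MILP rate literally (the procedure as
#' historically described, dimensionally inconsistent but available).
#'
#' @param model a validated [metabolic_model()].
#' @param knockout_ids the heuristic solution's knockout set.
#' @param dbfba_result the [evaluate_knockout_fitness()] result for that
#'   set; must be feasible.
#' @param mode `"product_rate"` (default) or `"bpcy"`.
#' @param threshold strict acceptance threshold on the absolute difference
#'   (default 0.001).
#' @param ... further arguments passed to [solve_optknock()].
#' @return an object of class `"validation_verdict"`: list with
#'   `dbfba_value`, `optknock_value`, `difference`, `valid`, `mode` and
#'   `status` of the MILP solve.
#' @export
validate_solution <- function(model, knockout_ids, dbfba_result,
                              mode = c("product_rate", "bpcy"),
                              threshold = 0.001, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(dbfba_result, "fitness_result"))
  if (!dbfba_result$feasible)
    stop("cannot validate an infeasible fitness result")
  floor <- dbfba_result$growth
  ok_model <- model
  if (mode == "product_rate") {
    # pin the MILP's inner optimum to the heuristic's fixed growth so the
    # compared rates are taken at the same growth
    bio <- ok_model$biomass_id
    ok_model$reactions[[bio]]$upper_bound <-
      min(ok_model$reactions[[bio]]$upper_bound, floor + 1e-9)
  }
  ok <- solve_optknock(ok_model, K = length(knockout_ids),
                       growth_floor = floor, ...)
  dbfba_value <- if (mode == "product_rate") dbfba_result$product_flux
                 else dbfba_result$bpcy
  if (ok$status == "infeasible" || is.na(ok$product_rate)) {
    verdict <- list(dbfba_value = dbfba_value, optknock_value = NA_real_,
                    difference = NA_real_, valid = FALSE, mode = mode,
                    status = ok$status)
    return(structure(verdict, class = "validation_verdict"))
  }
  difference <- abs(dbfba_value - ok$product_rate)
  structure(list(dbfba_value = dbfba_value,
                 optknock_value = ok$product_rate,
                 difference = difference,
                 valid = difference < threshold,  # strict
                 mode = mode, status = ok$status),
            class = "validation_verdict")
}

#' @export
print.validation_verdict <- function(x, ...) {
  cat("Validation (", x$mode, "): heuristic ", format(x$dbfba_value),
      " vs bilevel optimum ", format(x$optknock_value),
      ", |difference| = ", format(x$difference), " -> ",
      if (isTRUE(x$valid)) "VALID" else "NOT valid", "\n", sep = "")
  invisible(x)
}
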