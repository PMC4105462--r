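#' @keywords internal
"_PACKAGE"

## Internal linear-programming layer.
##
## All constraint-based computations in the package reduce to LPs of the
## form
##   max/min  obj' v
##   s.t.     A v (<=|>=|=) rhs,   lb <= v <= ub   (finite bounds)
## Flux bounds are finite by construction (files without bounds default to
## +/-1000), so unboundedness cannot occur in well-formed models.
##
## The solver is a self-contained two-phase dense tableau simplex with
## Bland's anti-cycling rule. FBA knockout problems are heavily degenerate
## (zero-span columns, redundant mass-balance rows), so before the simplex
## runs, variables pinned by their bounds are substituted out and
## constraint rows left empty by the substitution are checked and dropped.

# Two-phase tableau simplex on:  min cost' x  s.t.  A x dir b, x >= 0,
# with b >= 0 ensured by the caller. Bland's rule; reduced costs are
# recomputed from the original cost vector each iteration.
simplex_core <- function(cost, A, dir, b, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 200L * (m + n)

  # slack (+1) for <=, surplus (-1) for >=; artificials for >= and =
  n_slack <- sum(dir != "=")
  slack_of <- integer(m); art_of <- integer(m)
  Sl <- matrix(0, m, n_slack)
  k <- 0L
  for (i in seq_len(m)) {
    if (dir[i] != "=") {
      k <- k + 1L
      Sl[i, k] <- if (dir[i] == "<=") 1 else -1
      slack_of[i] <- n + k
    }
  }
  need_art <- dir != "<="
  n_art <- sum(need_art)
  Ar <- matrix(0, m, n_art)
  k <- 0L
  for (i in seq_len(m)) {
    if (need_art[i]) { k <- k + 1L; Ar[i, k] <- 1; art_of[i] <- n + n_slack + k }
  }
  Tb <- cbind(A, Sl, Ar, b)
  nc <- n + n_slack + n_art
  basis <- ifelse(need_art, art_of, slack_of)

  pivot <- function(pr, ent) {
    piv <- Tb[pr, ent]
    Tb[pr, ] <<- Tb[pr, ] / piv
    for (i in seq_len(m)) {
      if (i == pr) next
      f <- Tb[i, ent]
      if (abs(f) > 1e-13) Tb[i, ] <<- Tb[i, ] - f * Tb[pr, ]
    }
    basis[pr] <<- ent
  }

  run_phase <- function(cvec, allowed) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return("maxiter")
      cb <- cvec[basis]
      red <- cvec[seq_len(nc)] -
        as.vector(cb %*% Tb[, seq_len(nc), drop = FALSE])
      cand <- which(red < -tol & allowed)
      if (!length(cand)) return("optimal")
      ent <- cand[1L]                       # Bland: smallest index enters
      col <- Tb[, ent]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratios <- Tb[pos, nc + 1L] / col[pos]
      rmin <- min(ratios)
      ties <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
      pr <- ties[which.min(basis[ties])]    # Bland: smallest basic leaves
      pivot(pr, ent)
    }
  }

  # phase 1: drive the artificials to zero
  if (n_art) {
    c1 <- numeric(nc); c1[(n + n_slack + 1L):nc] <- 1
    st <- run_phase(c1, rep(TRUE, nc))
    if (st != "optimal") return(list(status = st))
    if (sum(c1[basis] * Tb[, nc + 1L]) > 1e-7)
      return(list(status = "infeasible"))
    # pivot any leftover zero-level artificials out of the basis
    for (i in which(basis > n + n_slack)) {
      entries <- which(abs(Tb[i, seq_len(n + n_slack)]) > tol)
      if (length(entries)) pivot(i, entries[1L])
      # an all-zero row is redundant; its artificial stays basic at zero
    }
  }

  c2 <- numeric(nc); c2[seq_len(n)] <- cost
  allowed <- c(rep(TRUE, n + n_slack), rep(FALSE, n_art))
  st <- run_phase(c2, allowed)
  if (st != "optimal") return(list(status = st))
  x <- numeric(nc)
  x[basis] <- Tb[, nc + 1L]
  list(status = "optimal", x = x[seq_len(n)],
       objective = sum(cost * x[seq_len(n)]))
}

#' Solve a bounded linear program
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (rows are constraints), or NULL for
#'   bounds-only problems.
#' @param dir character vector of row directions, each `"<="`, `">="` or
#'   `"="`.
#' @param rhs numeric right-hand sides.
#' @param lb,ub finite variable bounds, `lb <= ub` element-wise.
#' @param maximize logical; maximize (default) or minimize.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`
#'   or `"maxiter"`), `objective` and `solution` (on the original scale).
#' @keywords internal
#' @noRd
lp_solve <- function(obj, A = NULL, dir = NULL, rhs = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)))
  if (any(lb > ub + 1e-9)) {
    return(list(status = "infeasible", objective = NA_real_,
                solution = rep(NA_real_, n)))
  }
  ub <- pmax(ub, lb)
  span <- ub - lb

  # substitute out variables pinned by their bounds (knocked-out
  # reactions, fixed biomass flux): removes degenerate zero-span columns
  fixed <- span <= 1e-9
  keep <- which(!fixed)
  full_solution <- lb
  obj_const <- sum(obj[fixed] * lb[fixed])

  rows_A <- NULL; rows_b <- NULL; rows_dir <- NULL
  if (!is.null(A)) {
    A <- as.matrix(A)
    stopifnot(nrow(A) == length(dir), length(dir) == length(rhs))
    rhs <- rhs - as.vector(A[, fixed, drop = FALSE] %*% lb[fixed])
    A <- A[, keep, drop = FALSE]
    # rows left without variables must hold on their own
    empty <- if (ncol(A)) apply(A, 1, function(r) all(abs(r) < 1e-12)) else
      rep(TRUE, nrow(A))
    if (any(empty)) {
      viol <- (dir[empty] == "=" & abs(rhs[empty]) > 1e-7) |
        (dir[empty] == "<=" & rhs[empty] < -1e-7) |
        (dir[empty] == ">=" & rhs[empty] > 1e-7)
      if (any(viol))
        return(list(status = "infeasible", objective = NA_real_,
                    solution = rep(NA_real_, n)))
      A <- A[!empty, , drop = FALSE]
      dir <- dir[!empty]; rhs <- rhs[!empty]
    }
    if (nrow(A)) { rows_A <- A; rows_b <- rhs; rows_dir <- dir }
  }
  if (!length(keep)) {
    return(list(status = "optimal", objective = obj_const,
                solution = full_solution))
  }
  nk <- length(keep)
  obj_k <- obj[keep]; lb_k <- lb[keep]; span_k <- span[keep]
  if (!is.null(rows_A))
    rows_b <- rows_b - as.vector(rows_A %*% lb_k)
  # shift w = v - lb >= 0; variable upper bounds become <= rows
  rows_A <- rbind(rows_A, diag(nk))
  rows_b <- c(rows_b, span_k)
  rows_dir <- c(rows_dir, rep("<=", nk))

  # the simplex needs non-negative RHS: flip offending rows
  neg <- rows_b < 0
  if (any(neg)) {
    rows_A[neg, ] <- -rows_A[neg, , drop = FALSE]
    rows_b[neg] <- -rows_b[neg]
    rows_dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[rows_dir[neg]]
  }

  res <- simplex_core(cost = if (maximize) -obj_k else obj_k,
                      A = rows_A, dir = rows_dir, b = rows_b)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_,
                solution = rep(NA_real_, n)))
  full_solution[keep] <- res$x + lb_k
  obj_val <- sum(obj_k * (res$x + lb_k)) + obj_const
  list(status = "optimal", objective = obj_val, solution = full_solution)
}
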