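#' Solve a linear program
#'
#' Minimal LP interface used by every constraint-based routine in the
#' package: flux balance analysis, flux variability, FASTCC and the
#' extraction algorithms all reduce to calls of this function.  The solver is
#' a bounded-variable two-phase primal simplex implemented in compiled code;
#' it is deterministic (no random restarts, fixed pivot rules), which makes
#' every downstream flux state reproducible.
#'
#' @param obj numeric objective coefficient vector (length = number of
#'   columns of `mat`).
#' @param mat constraint matrix (dense or sparse; coerced to dense).
#' @param dir character vector of constraint directions, one of `"="`,
#'   `"<="`, `">="` per row.
#' @param rhs numeric right-hand side vector.
#' @param lower,upper variable bounds; `-Inf`/`Inf` allowed.
#' @param sense `"min"` or `"max"`.
#' @param max_iter simplex iteration cap.
#'
#' @return A list with elements `status` (one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`, `"iteration_limit"`), `objective`
#'   (in the requested sense) and `x` (primal solution).
#' @export
solve_lp <- function(obj, mat, dir, rhs, lower, upper, sense = c("min", "max"),
                     max_iter = 20000L) {
  sense <- match.arg(sense)
  mat <- as.matrix(mat)
  m <- nrow(mat)
  n <- ncol(mat)
  stopifnot(length(obj) == n, length(rhs) == m, length(dir) == m,
            length(lower) == n, length(upper) == n)
  if (any(lower > upper + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }

  # slack columns turn inequalities into equalities
  ineq <- which(dir != "=")
  if (length(ineq)) {
    slack <- matrix(0, m, length(ineq))
    s_lb <- s_ub <- numeric(length(ineq))
    for (k in seq_along(ineq)) {
      i <- ineq[k]
      slack[i, k] <- 1
      if (dir[i] == "<=") { s_lb[k] <- 0; s_ub[k] <- Inf }
      else if (dir[i] == ">=") { s_lb[k] <- -Inf; s_ub[k] <- 0 }
      else stop("unknown constraint direction: ", dir[i])
    }
    mat <- cbind(mat, slack)
    lower <- c(lower, s_lb)
    upper <- c(upper, s_ub)
    obj <- c(obj, numeric(length(ineq)))
  }

  cc <- if (sense == "max") -obj else obj

  # row equilibration: indicator-style constraints mix coefficients of very
  # different magnitude (activity thresholds ~1e-4 against capacity bounds
  # ~1e3); normalizing each row by its largest coefficient keeps the basis
  # well-conditioned without touching the variables or their bounds
  rhs <- as.numeric(rhs)
  if (nrow(mat)) {
    rs <- apply(abs(mat), 1, max)
    rs[rs < 1e-12] <- 1
    mat <- mat / rs
    rhs <- rhs / rs
  }
  res <- .simplex_core(mat, rhs, as.numeric(cc),
                       as.numeric(lower), as.numeric(upper),
                       max_iter = as.integer(max_iter))
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "iteration_limit")
  objective <- if (status %in% c("optimal", "iteration_limit")) {
    if (sense == "max") -res$objective else res$objective
  } else NA_real_
  x <- res$x[seq_len(n)]
  if (status == "infeasible") x <- rep(NA_real_, n)
  list(status = status, objective = objective, x = x,
       iterations = res$iterations)
}

#' Solve a mixed-integer linear program
#'
#' Depth-first branch and bound over the LP relaxation solved by
#' [solve_lp()].  Only the integrality pattern the extraction algorithms
#' need is supported: a subset of variables restricted to integers (in
#' practice binary indicators).  Branching is deterministic: the
#' most-fractional variable (ties broken by lowest index), floor branch
#' explored first.
#'
#' @inheritParams solve_lp
#' @param int_vars integer indices of variables constrained to be integral.
#' @param node_limit maximum number of branch-and-bound nodes; when hit the
#'   best incumbent is returned with `status = "node_limit"`.
#' @param int_tol integrality tolerance.
#'
#' @return As [solve_lp()], plus `nodes` (nodes explored).  `status`
#'   `"node_limit"` flags a possibly sub-optimal incumbent.
#' @export
solve_milp <- function(obj, mat, dir, rhs, lower, upper, int_vars,
                       sense = c("min", "max"), node_limit = 50000L,
                       int_tol = 1e-9) {
  sense <- match.arg(sense)
  sgn <- if (sense == "max") -1 else 1
  obj_min <- sgn * obj
  int_vars <- as.integer(int_vars)

  best <- list(objective = Inf, x = NULL)
  nodes <- 0L
  hit_limit <- FALSE

  # stack of nodes, each holding bound overrides
  stack <- list(list(lower = lower, upper = upper))
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (nodes >= node_limit) { hit_limit <- TRUE; break }
    nodes <- nodes + 1L
    rel <- solve_lp(obj_min, mat, dir, rhs, nd$lower, nd$upper, sense = "min")
    if (rel$status == "infeasible") next
    if (rel$status == "unbounded") {
      stop("MILP relaxation unbounded; add finite bounds to integer variables")
    }
    if (rel$objective >= best$objective - 1e-9) next  # bound prune
    # clamp into the node's bounds first: simplex solutions may overshoot a
    # bound by a hair, which must not masquerade as a fractional value
    xi <- pmin(pmax(rel$x[int_vars], nd$lower[int_vars]), nd$upper[int_vars])
    frac <- abs(xi - round(xi))
    if (all(frac <= int_tol)) {
      # refine: fix the integers and re-solve so the continuous part is
      # exactly consistent with the rounded assignment.  With big-M
      # indicator constraints a nearly-integral relaxation can still be
      # strictly infeasible at the rounded point; in that case fall through
      # and branch on the largest residual fraction instead of pruning.
      lo <- nd$lower; hi <- nd$upper
      lo[int_vars] <- round(xi); hi[int_vars] <- round(xi)
      fx <- solve_lp(obj_min, mat, dir, rhs, lo, hi, sense = "min")
      if (fx$status == "optimal") {
        if (fx$objective < best$objective - 1e-9) {
          x <- fx$x
          x[int_vars] <- round(xi)
          best <- list(objective = fx$objective, x = x)
        }
        next
      }
      if (max(frac) == 0) next  # exactly integral yet infeasible: dead node
    }
    j <- int_vars[which.max(frac)]
    v <- xi[which.max(frac)]
    lo <- nd$lower; hi <- nd$upper
    up_node <- list(lower = lo, upper = hi)
    up_node$lower[j] <- ceiling(v - int_tol)
    dn_node <- list(lower = lo, upper = hi)
    dn_node$upper[j] <- floor(v + int_tol)
    # floor branch explored first (pushed last)
    stack[[length(stack) + 1L]] <- up_node
    stack[[length(stack) + 1L]] <- dn_node
  }

  if (is.null(best$x)) {
    return(list(status = if (hit_limit) "node_limit" else "infeasible",
                objective = NA_real_, x = NULL, nodes = nodes))
  }
  list(status = if (hit_limit) "node_limit" else "optimal",
       objective = sgn * best$objective, x = best$x, nodes = nodes)
}

#' Solver tolerance configuration
#'
#' All numerical tolerances used by the constraint-based routines, in one
#' place.  `feas_tol` is what solutions are asserted against downstream
#' (steady state and bound violations), `opt_tol` the reduced-cost
#' threshold requested from the simplex, and `epsilon_floor` the smallest
#' flux-activity threshold accepted before clamping (values below the LP
#' feasibility tolerance cannot be certified).
#'
#' @param feas_tol asserted feasibility tolerance.
#' @param opt_tol simplex pricing tolerance.
#' @param epsilon_floor smallest usable activity threshold.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(feas_tol = 1e-6, opt_tol = 1e-9,
                          epsilon_floor = 1e-6) {
  structure(list(feas_tol = feas_tol, opt_tol = opt_tol,
                 epsilon_floor = epsilon_floor),
            class = "solver_config")
}
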