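#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction subject
#' to the steady-state constraint `S v = 0` and the model's flux bounds.
#' Because the optimal vertex of an FBA problem is generally degenerate,
#' the returned flux vector is fixed by a secondary parsimonious step:
#' total absolute flux `sum(|v|)` is minimized at the fixed optimal
#' objective value, making flux states unique enough to feed downstream
#' statistics reproducibly.
#'
#' @param model a [metabolic_model()].
#' @param objective reaction id; defaults to the model's declared objective.
#' @param sense `"max"` (default) or `"min"`.
#' @param parsimonious apply the L1 tie-break (default `TRUE`).
#' @param config a [solver_config()].
#'
#' @return A `flux_state`: list with `model_id`, `flux` (named vector over
#'   the model's reactions), `objective_value`, `objective_reaction` and
#'   `status`.  Infeasibility or unboundedness is reported in `status`
#'   (`flux` is then all-`NA`), not thrown.
#' @export
fba <- function(model, objective = model$objective, sense = c("max", "min"),
                parsimonious = TRUE, config = solver_config()) {
  sense <- match.arg(sense)
  rid <- reaction_ids(model)
  if (!objective %in% rid) stop("objective reaction not in model: ", objective)
  n <- length(rid)
  m <- length(model$metabolites)
  A <- as.matrix(model$S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  cvec <- as.numeric(rid == objective)

  res <- solve_lp(cvec, A, rep("=", m), numeric(m), lb, ub, sense = sense)
  if (res$status != "optimal") {
    return(structure(list(model_id = model$model_id,
                          flux = setNames(rep(NA_real_, n), rid),
                          objective_value = NA_real_,
                          objective_reaction = objective,
                          status = res$status), class = "flux_state"))
  }
  zstar <- res$objective
  v <- res$x

  if (parsimonious) {
    # split v = p - q, p,q >= 0; min sum(p + q) at fixed objective
    pl <- pmax(lb, 0); pu <- pmax(ub, 0)
    ql <- pmax(-ub, 0); qu <- pmax(-lb, 0)
    A2 <- cbind(A, -A)
    obj_row <- c(cvec, -cvec)
    tol <- config$feas_tol * max(1, abs(zstar))
    A2 <- rbind(A2, obj_row)
    dirs <- c(rep("=", m), if (sense == "max") ">=" else "<=")
    rhs <- c(numeric(m), if (sense == "max") zstar - tol else zstar + tol)
    res2 <- solve_lp(rep(1, 2 * n), A2, dirs, rhs, c(pl, ql), c(pu, qu),
                     sense = "min")
    if (res2$status == "optimal") v <- res2$x[1:n] - res2$x[(n + 1):(2 * n)]
  }

  v[abs(v) < config$feas_tol] <- 0
  structure(list(model_id = model$model_id,
                 flux = setNames(v, rid),
                 objective_value = zstar,
                 objective_reaction = objective,
                 status = "optimal"), class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("flux_state (", x$status, ") model '", x$model_id, "': objective ",
      x$objective_reaction, " = ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to steady state, bounds
#' and (optionally) near-optimality of the objective.
#'
#' @inheritParams fba
#' @param reactions reaction ids to scan (default: all).
#' @param fraction_of_optimum scalar in `[0, 1]`; when positive, the
#'   objective is constrained to at least this fraction of its optimum
#'   (the constraint is omitted at 0).
#' @return A data frame with columns `reaction_id`, `min`, `max`.
#' @export
fva <- function(model, reactions = reaction_ids(model),
                fraction_of_optimum = 0, objective = model$objective,
                config = solver_config()) {
  rid <- reaction_ids(model)
  stopifnot(all(reactions %in% rid))
  n <- length(rid)
  m <- length(model$metabolites)
  A <- as.matrix(model$S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  dirs <- rep("=", m)
  rhs <- numeric(m)
  if (fraction_of_optimum > 0) {
    base <- fba(model, objective, parsimonious = FALSE, config = config)
    if (base$status != "optimal") {
      stop("model is ", base$status, "; cannot run FVA with an optimum fraction")
    }
    A <- rbind(A, as.numeric(rid == objective))
    dirs <- c(dirs, ">=")
    rhs <- c(rhs, fraction_of_optimum * base$objective_value)
  }
  out <- data.frame(reaction_id = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    cvec <- as.numeric(rid == reactions[k])
    lo <- solve_lp(cvec, A, dirs, rhs, lb, ub, sense = "min")
    hi <- solve_lp(cvec, A, dirs, rhs, lb, ub, sense = "max")
    if (lo$status == "infeasible" || hi$status == "infeasible") {
      stop("FVA subproblem infeasible; model has no steady-state flux")
    }
    out$min[k] <- if (lo$status == "optimal") lo$objective else -Inf
    out$max[k] <- if (hi$status == "optimal") hi$objective else Inf
  }
  out
}

# LP-7-style support maximization: maximize the number of reactions in J
# carrying (signed) flux >= eps; returns the full flux vector of the optimum.
# Forces v_j >= 0 (forward) or v_j <= 0 (reverse) for all j in J, so callers
# must pass direction-safe sets (e.g. irreversible reactions when forward).
lp7_support <- function(model, J, eps, forward = TRUE) {
  if (!length(J)) return(NULL)
  rid <- reaction_ids(model)
  n <- length(rid)
  m <- length(model$metabolites)
  jidx <- match(J, rid)
  k <- length(jidx)
  A <- as.matrix(model$S)
  # variables: [v (n), z (k)]
  top <- cbind(A, matrix(0, m, k))
  sel <- matrix(0, k, n + k)
  for (t in seq_len(k)) {
    sel[t, jidx[t]] <- if (forward) 1 else -1
    sel[t, n + t] <- -1
  }
  mat <- rbind(top, sel)
  dirs <- c(rep("=", m), rep(">=", k))
  rhs <- numeric(m + k)
  lower <- c(model$reactions$lower_bound, numeric(k))
  upper <- c(model$reactions$upper_bound, rep(eps, k))
  obj <- c(numeric(n), rep(1, k))
  res <- solve_lp(obj, mat, dirs, rhs, lower, upper, sense = "max")
  if (res$status != "optimal") return(NULL)
  setNames(res$x[1:n], rid)
}

#' FASTCC flux-consistency check
#'
#' Partitions the model's reactions into the flux-consistent set (reactions
#' that can carry at least `epsilon` flux in some steady-state distribution
#' of the model) and its blocked complement.  The search runs the FASTCC
#' LP sequence -- batched LP-7-style support maximization in the forward
#' and reverse directions -- with a per-reaction flux-variability fallback
#' for stragglers, so the returned partition depends only on the model, not
#' on solver ordering.
#'
#' @inheritParams fba
#' @param epsilon flux-activity threshold (must be positive).  Values below
#'   the solver feasibility floor cannot be certified by an LP and are
#'   clamped, with a warning, to `config$epsilon_floor`.
#' @return A `consistency_result`: list with `consistent_reactions`,
#'   `removed_reactions`, `epsilon` and `consistent_model` (the induced
#'   submodel on the consistent set).
#' @export
fastcc <- function(model, epsilon = 1e-4, config = solver_config()) {
  stopifnot(epsilon > 0)
  if (epsilon < config$epsilon_floor) {
    warning("epsilon = ", epsilon, " is below the solver feasibility floor; ",
            "clamped to ", config$epsilon_floor)
    epsilon <- config$epsilon_floor
  }
  consistent <- certify_consistent(model, reaction_ids(model), epsilon, config)
  rid <- reaction_ids(model)
  removed <- setdiff(rid, consistent)
  structure(list(consistent_reactions = consistent,
                 removed_reactions = removed,
                 epsilon = epsilon,
                 consistent_model = induced_submodel(
                   model, consistent, model_id = paste0(model$model_id, "_consistent"))),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("consistency_result: ", length(x$consistent_reactions), " consistent, ",
      length(x$removed_reactions), " blocked (epsilon = ", x$epsilon, ")\n",
      sep = "")
  invisible(x)
}

# Determine which of `targets` can carry |v| >= eps in some feasible flux
# distribution of the model.  Batched LP-7 passes handle the direction-safe
# reactions (irreversible forward, reverse-only backward); every feasible
# optimum also certifies any other reaction it happens to drive above eps;
# leftovers (typically reversible exchanges) get exact per-reaction FVA.
# The returned set depends only on the model, not on solve order.
certify_consistent <- function(model, targets, eps, config = solver_config()) {
  rid <- reaction_ids(model)
  lb <- setNames(model$reactions$lower_bound, rid)
  ub <- setNames(model$reactions$upper_bound, rid)
  consistent <- character(0)
  run_batch <- function(Jall, forward) {
    repeat {
      J <- setdiff(Jall, consistent)
      if (!length(J)) return(invisible())
      v <- lp7_support(model, J, eps, forward = forward)
      if (is.null(v)) return(invisible())
      new <- names(v)[abs(v) >= eps * 0.999]
      if (!length(intersect(new, J))) return(invisible())
      consistent <<- union(consistent, new)
    }
  }
  run_batch(targets[lb[targets] >= 0 & ub[targets] > 0], forward = TRUE)
  run_batch(targets[ub[targets] <= 0 & lb[targets] < 0], forward = FALSE)
  rest <- setdiff(targets, consistent)
  if (length(rest)) {
    vv <- fva(model, rest, fraction_of_optimum = 0, config = config)
    ok <- pmax(abs(vv$min), abs(vv$max)) >= eps * 0.999
    consistent <- union(consistent, vv$reaction_id[ok])
  }
  rid[rid %in% intersect(consistent, targets)]
}

# steady-state / bound violation check used by tests and extraction
flux_violations <- function(model, v) {
  sv <- as.numeric(model$S %*% v[reaction_ids(model)])
  list(steady = max(abs(sv)),
       bounds = max(c(model$reactions$lower_bound - v, 0,
                      v - model$reactions$upper_bound)))
}
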