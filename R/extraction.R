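#' Configuration for context-specific model extraction
#'
#' The published descriptions of the four extraction algorithms leave
#' their thresholds open; the defaults here are package choices, recorded
#' in every extraction result.  Thresholds are quantiles of the
#' non-missing mapped reaction activities of the profile being integrated.
#'
#' @param algorithm one of `"gimme"`, `"imat"`, `"init"`, `"fastcore"`.
#' @param expression_threshold activity quantile separating expressed from
#'   non-expressed reactions (GIMME penalty threshold, INIT weight zero
#'   point, FASTCORE core membership).
#' @param high_quantile,low_quantile iMAT binarization quantiles
#'   (`low_quantile < high_quantile`).
#' @param epsilon_active flux threshold above which a reaction counts as
#'   active/carrying flux.
#' @param biomass_fraction GIMME: required fraction of the biomass optimum.
#' @param protected a [protect_reactions()] set (the model's objective is
#'   always protected in addition).
#' @param allow_accumulation INIT: metabolite ids allowed a small net
#'   accumulation (steady-state relaxation); none by default.
#' @param accumulation_max INIT: upper bound for the allowed accumulation.
#' @param node_limit branch-and-bound node cap for the MILP algorithms;
#'   when hit, the best incumbent is used and flagged in diagnostics.
#' @param solver a [solver_config()].
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(algorithm = c("gimme", "imat", "init", "fastcore"),
                              expression_threshold = 0.25,
                              high_quantile = 0.75, low_quantile = 0.25,
                              epsilon_active = 1e-4, biomass_fraction = 0.9,
                              protected = character(0),
                              allow_accumulation = character(0),
                              accumulation_max = 0.1,
                              node_limit = 20000L,
                              solver = solver_config()) {
  algorithm <- match.arg(algorithm)
  stopifnot(low_quantile < high_quantile,
            expression_threshold > 0, expression_threshold < 1,
            biomass_fraction > 0, biomass_fraction <= 1)
  if (epsilon_active < solver$epsilon_floor) {
    warning("epsilon_active below solver floor; clamped")
    epsilon_active <- solver$epsilon_floor
  }
  structure(list(algorithm = algorithm,
                 expression_threshold = expression_threshold,
                 high_quantile = high_quantile, low_quantile = low_quantile,
                 epsilon_active = epsilon_active,
                 biomass_fraction = biomass_fraction,
                 protected = as.character(protected),
                 allow_accumulation = allow_accumulation,
                 accumulation_max = accumulation_max,
                 node_limit = as.integer(node_limit),
                 solver = solver),
            class = "extraction_config")
}

new_extraction_result <- function(sample_id, algorithm, kept, model, diagnostics) {
  kept <- reaction_ids(model)[reaction_ids(model) %in% kept]
  structure(list(sample_id = sample_id, algorithm = algorithm,
                 parent_model_id = model$model_id,
                 kept_reactions = kept,
                 context_model = induced_submodel(
                   model, kept, model_id = paste0(model$model_id, "_", sample_id,
                                                  "_", algorithm)),
                 diagnostics = diagnostics),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("extraction_result [", x$algorithm, "] sample '", x$sample_id, "': ",
      length(x$kept_reactions), " reactions kept\n", sep = "")
  invisible(x)
}

# Reduce a candidate kept set to a flux-consistent submodel that still
# contains the protected reactions.  If consistency reduction would evict a
# protected reaction, its minimal support is pulled back in with the sparse
# support search (FASTCORE machinery) on the full model.
ensure_consistent_submodel <- function(model, candidate, protected, eps,
                                       config = solver_config()) {
  cand <- union(candidate, protected)
  sub <- induced_submodel(model, cand)
  cr <- tryCatch(fastcc(sub, eps, config = config), error = function(e) NULL)
  if (!is.null(cr) && all(protected %in% cr$consistent_reactions)) {
    return(cr$consistent_reactions)
  }
  # the candidate set does not support the protected reactions on its own
  # (or is outright infeasible, e.g. a demand reaction lost its producers):
  # grow the sparse support of the full candidate set on the parent model,
  # which is flux-consistent by precondition
  fastcore_support(model, core = cand, eps, config = config)
}

activity_values <- function(activity) {
  if (inherits(activity, "reaction_activity")) activity$values else activity
}

#' Extract a context-specific model
#'
#' Dispatcher over the four integration algorithms.  All algorithms
#' guarantee: the protected set and the model objective are kept; the
#' context model is flux-consistent at `epsilon_active`.
#'
#' @param model a flux-consistent [metabolic_model()].
#' @param activity a `reaction_activity` from [map_expression()].
#' @param config an [extraction_config()].
#' @return An `extraction_result`: `sample_id`, `algorithm`,
#'   `kept_reactions`, `context_model`, `diagnostics`.
#' @export
extract_context <- function(model, activity, config = extraction_config()) {
  fn <- switch(config$algorithm, gimme = extract_gimme, imat = extract_imat,
               init = extract_init, fastcore = extract_fastcore_activity)
  fn(model, activity, config)
}

# threshold on the non-missing activity scale; -Inf when nothing is mapped
activity_quantile <- function(act, q) {
  v <- act[!is.na(act)]
  if (!length(v)) -Inf else unname(quantile(v, q, type = 7))
}

#' GIMME extraction
#'
#' Two-stage scheme: (1) FBA fixes the achievable biomass optimum; (2) an
#' LP minimizes the weighted total flux through below-threshold reactions
#' (weight = threshold - activity; unmapped reactions are not penalized)
#' subject to retaining at least `biomass_fraction` of the optimum.  Kept
#' reactions: protected, above-threshold, and those carrying at least
#' `epsilon_active` flux in the stage-2 solution; the set is then reduced
#' to flux consistency.
#'
#' @inheritParams extract_context
#' @export
extract_gimme <- function(model, activity, config = extraction_config("gimme")) {
  act <- activity_values(activity)
  sid <- if (inherits(activity, "reaction_activity")) activity$sample_id else "sample"
  rid <- reaction_ids(model)
  stopifnot(identical(names(act), rid))
  eps <- config$epsilon_active
  protected <- intersect(union(config$protected, model$objective), rid)
  thr <- activity_quantile(act, config$expression_threshold)

  base <- fba(model, parsimonious = FALSE, config = config$solver)
  if (base$status != "optimal") stop("GIMME: model is ", base$status)
  zstar <- base$objective_value

  w <- pmax(0, thr - act)
  w[is.na(w)] <- 0
  n <- length(rid)
  m <- length(model$metabolites)
  A <- as.matrix(model$S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  # split v = p - q (p, q >= 0) so the objective is sum w * |v|
  pl <- pmax(lb, 0); pu <- pmax(ub, 0)
  ql <- pmax(-ub, 0); qu <- pmax(-lb, 0)
  obj_row <- as.numeric(rid == model$objective)
  A2 <- rbind(cbind(A, -A), c(obj_row, -obj_row))
  res <- solve_lp(c(w, w), A2, c(rep("=", m), ">="),
                  c(numeric(m), config$biomass_fraction * zstar),
                  c(pl, ql), c(pu, qu), sense = "min")
  if (res$status != "optimal") {
    stop("GIMME stage-2 LP ", res$status, " (biomass fraction ",
         config$biomass_fraction, ")")
  }
  v <- setNames(res$x[1:n] - res$x[(n + 1):(2 * n)], rid)

  candidate <- union(rid[abs(v) >= eps], rid[!is.na(act) & act >= thr])
  kept <- ensure_consistent_submodel(model, candidate, protected, eps,
                                     config$solver)
  new_extraction_result(sid, "gimme", kept, model,
                        list(config = config, threshold = thr,
                             biomass_optimum = zstar,
                             stage2_objective = res$objective,
                             stage2_flux = v))
}

#' iMAT extraction
#'
#' Splits mapped reactions into highly and poorly expressed sets by
#' activity quantiles and solves a MILP maximizing agreement: a high
#' reaction agrees when it carries at least `epsilon_active` flux (either
#' direction), a low reaction agrees when its flux stays within
#' `epsilon_active` of zero.  Kept reactions: protected, flux-carrying at
#' the optimum, and all unclassified reactions; reduced to consistency.
#'
#' @inheritParams extract_context
#' @export
extract_imat <- function(model, activity, config = extraction_config("imat")) {
  act <- activity_values(activity)
  sid <- if (inherits(activity, "reaction_activity")) activity$sample_id else "sample"
  rid <- reaction_ids(model)
  stopifnot(identical(names(act), rid))
  eps <- config$epsilon_active
  protected <- intersect(union(config$protected, model$objective), rid)
  hi_thr <- activity_quantile(act, config$high_quantile)
  lo_thr <- activity_quantile(act, config$low_quantile)
  RH <- rid[!is.na(act) & act >= hi_thr]
  RL <- rid[!is.na(act) & act <= lo_thr]
  RL <- setdiff(RL, RH)  # degenerate quantiles: high wins

  if (!length(RH) && !length(RL)) {
    kept <- ensure_consistent_submodel(model, rid, protected, eps, config$solver)
    return(new_extraction_result(sid, "imat", kept, model,
                                 list(config = config, agreement = 0L,
                                      high_set = RH, low_set = RL,
                                      milp_status = "trivial")))
  }

  n <- length(rid)
  m <- length(model$metabolites)
  A <- as.matrix(model$S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound

  # columns: v (n) | y+ (forward-activity, RH) | y- (reverse-activity,
  # reversible RH) | y0 (RL)
  hi_idx <- match(RH, rid)
  hi_rev <- hi_idx[lb[hi_idx] < -eps]
  lo_idx <- match(RL, rid)
  nyp <- length(hi_idx); nyn <- length(hi_rev); ny0 <- length(lo_idx)
  ncol_tot <- n + nyp + nyn + ny0
  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add_row <- function(cols, vals, dir, b) {
    r <- numeric(ncol_tot); r[cols] <- vals
    rows[[length(rows) + 1L]] <<- r
    dirs <<- c(dirs, dir); rhs <<- c(rhs, b)
  }
  for (t in seq_along(hi_idx)) {   # y+ = 1 => v >= eps
    j <- hi_idx[t]
    add_row(c(j, n + t), c(1, lb[j] - eps), ">=", lb[j])
  }
  for (t in seq_along(hi_rev)) {   # y- = 1 => v <= -eps
    j <- hi_rev[t]
    add_row(c(j, n + nyp + t), c(1, ub[j] + eps), "<=", ub[j])
  }
  # the low reward is |v| strictly below eps; the indicator window stops
  # well clear of eps so a flux of exactly eps cannot satisfy a high and a
  # low classification at once
  eps_low <- eps / 2
  for (t in seq_along(lo_idx)) {   # y0 = 1 => -eps_low <= v <= eps_low
    j <- lo_idx[t]
    add_row(c(j, n + nyp + nyn + t), c(1, ub[j] - eps_low), "<=", ub[j])
    add_row(c(j, n + nyp + nyn + t), c(1, lb[j] + eps_low), ">=", lb[j])
  }
  mat <- rbind(cbind(A, matrix(0, m, ncol_tot - n)), do.call(rbind, rows))
  dirs <- c(rep("=", m), dirs)
  rhs <- c(numeric(m), rhs)
  lower <- c(lb, numeric(ncol_tot - n))
  upper <- c(ub, rep(1, ncol_tot - n))
  objv <- c(numeric(n), rep(1, ncol_tot - n))
  int_vars <- (n + 1):ncol_tot
  sol <- solve_milp(objv, mat, dirs, rhs, lower, upper, int_vars,
                    sense = "max", node_limit = config$node_limit)
  if (!sol$status %in% c("optimal", "node_limit")) {
    stop("iMAT MILP ", sol$status)
  }
  v <- setNames(sol$x[1:n], rid)
  agreement <- sum(abs(v[RH]) >= eps * 0.999) + sum(abs(v[RL]) <= eps * 0.5 * 1.001)

  unclassified <- setdiff(rid, union(RH, RL))
  candidate <- union(rid[abs(v) >= eps], unclassified)
  kept <- ensure_consistent_submodel(model, candidate, protected, eps,
                                     config$solver)
  new_extraction_result(sid, "imat", kept, model,
                        list(config = config, agreement = agreement,
                             milp_objective = sol$objective,
                             milp_status = sol$status,
                             high_set = RH, low_set = RL, flux = v))
}

#' INIT extraction
#'
#' MILP maximizing the weighted sum of activity indicators: weight =
#' activity minus the expression threshold (positive for expressed,
#' negative for unexpressed, zero for unmapped reactions).  An indicator
#' forces at least `epsilon_active` flux in one direction; reactions whose
#' indicator stays off are not claimed active and are dropped from the
#' kept set (their flux is unconstrained, mirroring the relaxation that
#' tolerates small net accumulation).  Optionally, listed metabolites may
#' accumulate at a bounded rate.  Kept: protected plus claimed-active,
#' reduced to consistency.
#'
#' @inheritParams extract_context
#' @export
extract_init <- function(model, activity, config = extraction_config("init")) {
  act <- activity_values(activity)
  sid <- if (inherits(activity, "reaction_activity")) activity$sample_id else "sample"
  rid <- reaction_ids(model)
  stopifnot(identical(names(act), rid))
  eps <- config$epsilon_active
  protected <- intersect(union(config$protected, model$objective), rid)
  thr <- activity_quantile(act, config$expression_threshold)
  w <- act - thr
  w[is.na(w)] <- 0

  n <- length(rid)
  m <- length(model$metabolites)
  A <- as.matrix(model$S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound

  pos <- which(w > 0)
  fwd <- pos[ub[pos] >= eps]          # candidate forward indicators
  rev <- pos[lb[pos] <= -eps]         # candidate reverse indicators
  nacc <- length(config$allow_accumulation)
  acc_idx <- if (nacc) match(config$allow_accumulation, model$metabolites) else integer(0)
  if (anyNA(acc_idx)) stop("allow_accumulation metabolite not in model")
  ncol_tot <- n + length(fwd) + length(rev) + nacc

  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add_row <- function(cols, vals, dir, b) {
    r <- numeric(ncol_tot); r[cols] <- vals
    rows[[length(rows) + 1L]] <<- r
    dirs <<- c(dirs, dir); rhs <<- c(rhs, b)
  }
  for (t in seq_along(fwd)) {   # y+ = 1 => v >= eps
    j <- fwd[t]
    add_row(c(j, n + t), c(1, lb[j] - eps), ">=", lb[j])
  }
  for (t in seq_along(rev)) {   # y- = 1 => v <= -eps
    j <- rev[t]
    add_row(c(j, n + length(fwd) + t), c(1, ub[j] + eps), "<=", ub[j])
  }
  # steady state, relaxed to S v - b = 0 for accumulating metabolites
  top <- cbind(A, matrix(0, m, ncol_tot - n))
  if (nacc) for (t in seq_len(nacc)) top[acc_idx[t], n + length(fwd) + length(rev) + t] <- -1
  mat <- rbind(top, do.call(rbind, rows))
  dirs <- c(rep("=", m), dirs)
  rhs <- c(numeric(m), rhs)
  lower <- c(lb, numeric(ncol_tot - n))
  upper <- c(ub, rep(1, length(fwd) + length(rev)),
             rep(config$accumulation_max, nacc))
  # tiny negative bias keeps unused indicators off (deterministic kept set)
  objv <- c(numeric(n), w[fwd] - 1e-9, w[rev] - 1e-9, numeric(nacc))
  int_vars <- if (ncol_tot - nacc > n) (n + 1):(ncol_tot - nacc) else integer(0)

  if (!length(int_vars)) {
    kept <- ensure_consistent_submodel(model, character(0), protected, eps,
                                       config$solver)
    return(new_extraction_result(sid, "init", kept, model,
                                 list(config = config, threshold = thr,
                                      milp_status = "trivial", weights = w)))
  }
  sol <- solve_milp(objv, mat, dirs, rhs, lower, upper, int_vars,
                    sense = "max", node_limit = config$node_limit)
  if (!sol$status %in% c("optimal", "node_limit")) stop("INIT MILP ", sol$status)
  yp <- sol$x[n + seq_along(fwd)]
  yn <- sol$x[n + length(fwd) + seq_along(rev)]
  claimed <- union(rid[fwd[yp > 0.5]], rid[rev[yn > 0.5]])

  kept <- ensure_consistent_submodel(model, claimed, protected, eps,
                                     config$solver)
  new_extraction_result(sid, "init", kept, model,
                        list(config = config, threshold = thr,
                             milp_objective = sol$objective,
                             milp_status = sol$status, weights = w,
                             claimed_active = claimed))
}

# FASTCORE sparse support search: returns a flux-consistent reaction set
# containing `core` (LP-7 support maximization alternating with LP-10-style
# L1-sparse mode finding).  Errors if a core reaction cannot carry flux.
fastcore_support <- function(model, core, eps, config = solver_config()) {
  rid <- reaction_ids(model)
  stopifnot(all(core %in% rid))
  lb <- setNames(model$reactions$lower_bound, rid)
  ub <- setNames(model$reactions$upper_bound, rid)
  A_set <- character(0)
  remaining <- core

  sparse_mode <- function(K, signs, penalized) {
    # min sum |v_p| over penalized p subject to sign_k * v_k >= eps
    n <- length(rid); m <- length(model$metabolites)
    k <- length(penalized)
    A <- as.matrix(model$S)
    mat_top <- cbind(A, matrix(0, m, k))
    rows <- list(); dirs <- character(0); rhs <- numeric(0)
    for (t in seq_along(K)) {
      r <- numeric(n + k); r[match(K[t], rid)] <- signs[t]
      rows[[length(rows) + 1L]] <- r; dirs <- c(dirs, ">="); rhs <- c(rhs, eps)
    }
    for (t in seq_len(k)) {  # t_p >= |v_p|
      j <- match(penalized[t], rid)
      r1 <- numeric(n + k); r1[j] <- 1; r1[n + t] <- -1
      r2 <- numeric(n + k); r2[j] <- -1; r2[n + t] <- -1
      rows[[length(rows) + 1L]] <- r1; dirs <- c(dirs, "<="); rhs <- c(rhs, 0)
      rows[[length(rows) + 1L]] <- r2; dirs <- c(dirs, "<="); rhs <- c(rhs, 0)
    }
    mat <- rbind(mat_top, do.call(rbind, rows))
    dirs <- c(rep("=", m), dirs)
    rhs <- c(numeric(m), rhs)
    res <- solve_lp(c(numeric(n), rep(1, k)), mat, dirs, rhs,
                    c(lb, numeric(k)), c(ub, rep(Inf, k)), sense = "min")
    if (res$status != "optimal") return(NULL)
    setNames(res$x[1:n], rid)
  }

  guard <- 0L
  while (length(remaining)) {
    guard <- guard + 1L
    if (guard > 10L * length(core) + 10L) {
      stop("FASTCORE did not converge; core may be inconsistent")
    }
    K <- character(0); signs <- numeric(0)
    Jf <- remaining[lb[remaining] >= 0]        # direction-safe forward batch
    if (length(Jf)) {
      v <- lp7_support(model, Jf, eps, forward = TRUE)
      if (!is.null(v)) {
        K <- Jf[v[Jf] >= eps * 0.999]
        signs <- rep(1, length(K))
      }
    }
    if (!length(K)) {
      Jr <- remaining[ub[remaining] <= 0]      # reverse-only batch
      if (length(Jr)) {
        v <- lp7_support(model, Jr, eps, forward = FALSE)
        if (!is.null(v)) {
          K <- Jr[v[Jr] <= -eps * 0.999]
          signs <- rep(-1, length(K))
        }
      }
    }
    if (!length(K)) {
      # reversible straggler: establish its feasible direction exactly
      r <- remaining[1]
      vv <- fva(model, r, config = config)
      if (max(abs(vv$min), abs(vv$max)) < eps * 0.999) {
        stop("core reaction cannot carry flux in the model: ", r)
      }
      K <- r
      signs <- if (abs(vv$max) >= abs(vv$min)) 1 else -1
    }
    penalized <- setdiff(rid, union(core, A_set))
    v2 <- sparse_mode(K, signs, penalized)
    if (is.null(v2)) stop("FASTCORE sparse-mode LP infeasible")
    supp <- rid[abs(v2) > max(eps * 1e-3, 1e-8)]
    A_set <- union(A_set, union(supp, K))
    remaining <- setdiff(remaining, rid[abs(v2) >= eps * 0.999])
  }

  # prune redundant support: drop any added non-core reaction whose removal
  # leaves every remaining reaction able to carry eps flux (inclusion-
  # minimality over the additions; candidates are few, so this stays cheap)
  consistent_everywhere <- function(keep) {
    sub <- induced_submodel(model, keep)
    cr <- tryCatch(fastcc(sub, eps, config = config), error = function(e) NULL)
    !is.null(cr) && !length(cr$removed_reactions)
  }
  kept <- union(A_set, core)
  for (r in rev(intersect(rid, setdiff(kept, core)))) {
    trial <- setdiff(kept, r)
    if (length(trial) && consistent_everywhere(trial)) kept <- trial
  }

  # stabilize: consistency reduction must keep the core
  for (i in 1:5) {
    cr <- fastcc(induced_submodel(model, kept), eps, config = config)
    if (!length(cr$removed_reactions)) break
    if (all(core %in% cr$consistent_reactions)) { kept <- cr$consistent_reactions; next }
    # rare: reduction evicted core support; re-grow from scratch on the rest
    kept <- union(cr$consistent_reactions, core)
    remaining2 <- setdiff(core, cr$consistent_reactions)
    for (r in remaining2) {
      vv <- fva(model, r, config = config)
      dirn <- if (abs(vv$max) >= abs(vv$min)) 1 else -1
      v2 <- sparse_mode(r, dirn, setdiff(rid, kept))
      if (!is.null(v2)) kept <- union(kept, rid[abs(v2) > max(eps * 1e-3, 1e-8)])
    }
  }
  rid[rid %in% kept]
}

#' FASTCORE extraction
#'
#' Takes a core set of reactions that must be present and searches for a
#' small flux-consistent submodel containing it, by alternating support
#' maximization over unsatisfied core reactions with L1-sparse mode
#' finding that penalizes non-core flux.  The result is near-minimal
#' (heuristic, as in the original algorithm family), contains the core and
#' the protected set, and is flux-consistent.
#'
#' @param model a flux-consistent [metabolic_model()].
#' @param core character vector of core reaction ids.
#' @param config an [extraction_config()].
#' @param sample_id identifier recorded in the result.
#' @return An `extraction_result`.
#' @export
extract_fastcore <- function(model, core, config = extraction_config("fastcore"),
                             sample_id = "sample") {
  rid <- reaction_ids(model)
  missing <- setdiff(core, rid)
  if (length(missing)) stop("core reaction(s) not in model: ",
                            paste(missing, collapse = ", "))
  protected <- intersect(union(config$protected, model$objective), rid)
  core_all <- union(core, protected)
  kept <- fastcore_support(model, core_all, config$epsilon_active,
                           config = config$solver)
  new_extraction_result(sample_id, "fastcore", kept, model,
                        list(config = config, core = core_all))
}

# Activity-driven fastcore used by the dispatcher.  The core is the set of
# *confidently* expressed reactions (upper activity quantile): the algorithm
# family's contract is a high-confidence core plus its minimum essential
# support, which is what makes its submodels the leanest of the four.
extract_fastcore_activity <- function(model, activity,
                                      config = extraction_config("fastcore")) {
  act <- activity_values(activity)
  sid <- if (inherits(activity, "reaction_activity")) activity$sample_id else "sample"
  thr <- activity_quantile(act, config$high_quantile)
  core <- names(act)[!is.na(act) & act >= thr]
  res <- extract_fastcore(model, core, config, sample_id = sid)
  res$diagnostics$threshold <- thr
  res
}
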