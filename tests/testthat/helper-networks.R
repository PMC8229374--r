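# Shared fixtures and independent oracles for the test suite.

# linear chain: EX_a -> r1 -> r2 -> EX_b, bounds [0, 10]
chain_model <- function(ub1 = 10) {
  metabolic_model(
    "chain",
    data.frame(reaction_id = c("EX_a", "r1", "r2", "EX_b"),
               lower_bound = c(-10, 0, 0, 0),
               upper_bound = c(0, ub1, 10, 10),
               subsystem = c("exchange", "core", "core", "exchange")),
    list(c(a = -1), c(a = -1, b = 1), c(b = -1, c = 1), c(c = -1)),
    objective = "r2")
}

# random flux network: internal conversion chains between exchangeable
# metabolites, a fraction of deliberate dead ends; v = 0 always feasible
random_net <- function(n_rxns = 20, seed = 1, p_rev = 0.3, p_deadend = 0.2) {
  set.seed(seed)
  n_mets <- max(3, round(n_rxns * 0.8))
  mets <- sprintf("m%02d", seq_len(n_mets))
  rxn <- list()
  add <- function(id, sv, lb, ub) {
    rxn[[length(rxn) + 1L]] <<- list(id = id, sv = sv, lb = lb, ub = ub)
  }
  # exchanges for a third of metabolites keep part of the net alive
  n_ex <- max(2, n_mets %/% 3)
  for (i in seq_len(n_ex)) {
    add(paste0("EX_", mets[i]), setNames(-1, mets[i]), -10, 10)
  }
  n_int <- n_rxns - n_ex
  for (j in seq_len(max(1, n_int))) {
    k <- sample(1:2, 1)
    from <- sample(mets, k)
    dead <- runif(1) < p_deadend
    to <- if (dead) {
      # product chosen among non-exchangeable, rarely-consumed metabolites
      sample(mets[seq(n_ex + 1, n_mets)], 1)
    } else sample(setdiff(mets, from), 1)
    sv <- c(setNames(rep(-1, k), from), setNames(1, to))
    rev <- runif(1) < p_rev
    add(sprintf("R%02d", j), sv, if (rev) -10 else 0, 10)
  }
  df <- data.frame(reaction_id = vapply(rxn, `[[`, character(1), "id"),
                   lower_bound = vapply(rxn, `[[`, numeric(1), "lb"),
                   upper_bound = vapply(rxn, `[[`, numeric(1), "ub"),
                   stringsAsFactors = FALSE)
  metabolic_model(paste0("rand", seed), df, lapply(rxn, `[[`, "sv"),
                  objective = df$reaction_id[1])
}

# ---- scipy oracle bridge ----------------------------------------------------

has_python_scipy <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      ok <- tryCatch({
        out <- suppressWarnings(system2("python", c("-c", shQuote("import scipy.optimize")),
                                        stdout = TRUE, stderr = TRUE))
        is.null(attr(out, "status")) || attr(out, "status") == 0
      }, error = function(e) FALSE)
      cached <<- isTRUE(ok)
    }
    cached
  }
})

# solve a batch of LPs with scipy.optimize.linprog (HiGHS) as an
# implementation-independent oracle; each case: list(obj, mat, dir, rhs,
# lower, upper, sense)
scipy_lp_batch <- function(cases) {
  payload <- lapply(cases, function(cs) list(
    obj = as.numeric(cs$obj),
    mat = as.matrix(cs$mat), dir = cs$dir, rhs = as.numeric(cs$rhs),
    lower = ifelse(is.finite(cs$lower), cs$lower, -1e30),
    upper = ifelse(is.finite(cs$upper), cs$upper, 1e30),
    sense = cs$sense))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = TRUE)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
cases = json.load(open(sys.argv[1]))
out = []
for cs in cases:
    A = np.array(cs["mat"], dtype=float)
    if A.ndim == 1:
        A = A.reshape(len(cs["dir"]), -1)
    d = cs["dir"]; b = np.array(cs["rhs"], dtype=float)
    lo = np.array(cs["lower"], dtype=float); hi = np.array(cs["upper"], dtype=float)
    lo[lo <= -1e29] = -np.inf; hi[hi >= 1e29] = np.inf
    c = np.array(cs["obj"], dtype=float)
    if cs["sense"] == "max":
        c = -c
    eq = [i for i, x in enumerate(d) if x == "="]
    le = [i for i, x in enumerate(d) if x == "<="]
    ge = [i for i, x in enumerate(d) if x == ">="]
    A_eq = A[eq] if eq else None; b_eq = b[eq] if eq else None
    A_ub = np.vstack([A[le], -A[ge]]) if (le or ge) else None
    b_ub = np.concatenate([b[le], -b[ge]]) if (le or ge) else None
    r = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
                bounds=list(zip(lo, hi)), method="highs")
    st = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(r.status, "other")
    obj = None
    if st == "optimal":
        obj = r.fun if cs["sense"] == "min" else -r.fun
    out.append({"status": st, "objective": obj})
json.dump(out, open(sys.argv[2], "w"))
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, fin, fout), stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

# ---- brute-force oracles ----------------------------------------------------

# exhaustive two-LP flux range per reaction, built straight from S and the
# bounds (no shared code with fva beyond solve_lp)
brute_fva <- function(model, reactions = model$reactions$reaction_id) {
  A <- as.matrix(model$S)
  rid <- model$reactions$reaction_id
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  out <- data.frame(reaction_id = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    cv <- as.numeric(rid == reactions[k])
    lo <- solve_lp(cv, A, rep("=", nrow(A)), numeric(nrow(A)), lb, ub, "min")
    hi <- solve_lp(cv, A, rep("=", nrow(A)), numeric(nrow(A)), lb, ub, "max")
    out$min[k] <- lo$objective
    out$max[k] <- hi$objective
  }
  out
}

# is the induced submodel on `keep` flux-consistent at eps, i.e. can every
# kept reaction carry |v| >= eps within the submodel?  Early exit on the
# first blocked reaction.
submodel_consistent <- function(model, keep, eps = 1e-4) {
  sub <- fluxprint:::induced_submodel(model, keep)
  A <- as.matrix(sub$S)
  rid <- sub$reactions$reaction_id
  lb <- sub$reactions$lower_bound
  ub <- sub$reactions$upper_bound
  for (k in seq_along(rid)) {
    cv <- as.numeric(seq_along(rid) == k)
    hi <- solve_lp(cv, A, rep("=", nrow(A)), numeric(nrow(A)), lb, ub, "max")
    if (hi$status == "optimal" && hi$objective >= eps * 0.999) next
    lo <- solve_lp(cv, A, rep("=", nrow(A)), numeric(nrow(A)), lb, ub, "min")
    if (!(lo$status == "optimal" && lo$objective <= -eps * 0.999)) return(FALSE)
  }
  TRUE
}

# smallest flux-consistent superset of `core`: exhaustive search in order
# of increasing size, stopping at the first feasible one
brute_min_consistent_superset <- function(model, core, eps = 1e-4) {
  rid <- model$reactions$reaction_id
  rest <- setdiff(rid, core)
  for (s in 0:length(rest)) {
    picks <- if (s == 0) list(character(0)) else
      utils::combn(rest, s, simplify = FALSE)
    for (pick in picks) {
      if (submodel_consistent(model, c(core, pick), eps)) {
        return(length(core) + s)
      }
    }
  }
  Inf
}

# independent recursive GPR evaluator used as the mapping oracle
brute_eval_gpr <- function(rule, values) {
  if (is.null(rule)) return(NA_real_)
  if (rule$op == "leaf") {
    v <- unname(values[rule$gene])
    return(if (length(v) && !is.na(v)) v else NA_real_)
  }
  ch <- vapply(rule$children, brute_eval_gpr, numeric(1), values = values)
  ch <- ch[!is.na(ch)]
  if (!length(ch)) return(NA_real_)
  if (rule$op == "and") min(ch) else max(ch)
}

# random GPR tree over the given genes, depth-limited
random_gpr <- function(genes, depth = 3) {
  if (depth == 0 || runif(1) < 0.4) {
    return(parse_gpr(sample(genes, 1)))
  }
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- lapply(seq_len(k), function(i) random_gpr(genes, depth - 1))
  structure(list(op = op, children = kids), class = "gpr_rule")
}
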