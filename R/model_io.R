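#' Construct a metabolic model
#'
#' The central container of the package: a stoichiometric reconstruction
#' with flux bounds, gene-protein-reaction (GPR) rules and subsystem
#' annotations.  All downstream operations (FBA, consistency checking,
#' extraction, scoring) consume this class.
#'
#' @param model_id character scalar identifier.
#' @param reactions data frame with columns `reaction_id`, `lower_bound`,
#'   `upper_bound` and optionally `subsystem` (missing/NA entries are
#'   assigned to the sentinel subsystem `"unassigned"`).
#' @param stoichiometry named list, one element per reaction (same order as
#'   `reactions`), each a named numeric vector of metabolite coefficients
#'   (negative = consumed); or a matrix/sparse matrix (metabolites x
#'   reactions) with dimnames.
#' @param gpr character vector of GPR strings (or a list of parsed
#'   [parse_gpr()] trees), one per reaction; `NA`/`NULL` entries mean the
#'   reaction has no gene association.
#' @param objective reaction id of the objective (biomass) reaction.
#' @param genes optional character vector of the gene universe; defaults to
#'   the union of genes referenced by the GPR rules.
#'
#' @return An object of class `metabolic_model` with fields `model_id`,
#'   `metabolites`, `reactions`, `gpr`, `S` (sparse metabolite x reaction
#'   matrix), `objective` and `genes`.
#' @export
metabolic_model <- function(model_id, reactions, stoichiometry, gpr = NULL,
                            objective, genes = NULL) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  req <- c("reaction_id", "lower_bound", "upper_bound")
  if (!all(req %in% names(reactions))) {
    stop("reactions must have columns: ", paste(req, collapse = ", "))
  }
  rid <- as.character(reactions$reaction_id)
  if (anyDuplicated(rid)) {
    stop("duplicated reaction ids: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  reactions$subsystem <- as.character(reactions$subsystem)
  reactions$subsystem[is.na(reactions$subsystem) |
                        !nzchar(reactions$subsystem)] <- "unassigned"
  bad <- which(reactions$lower_bound > reactions$upper_bound)
  if (length(bad)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rid[bad], collapse = ", "))
  }

  if (is.list(stoichiometry) && !is.data.frame(stoichiometry)) {
    if (length(stoichiometry) != nrow(reactions)) {
      stop("stoichiometry list length must equal the number of reactions")
    }
    mets <- unique(unlist(lapply(stoichiometry, names)))
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (j in seq_along(stoichiometry)) {
      sv <- stoichiometry[[j]]
      if (length(sv)) {
        if (is.null(names(sv)) || any(!nzchar(names(sv)))) {
          stop("unnamed stoichiometry coefficient in reaction ", rid[j])
        }
        ii <- c(ii, match(names(sv), mets)); jj <- c(jj, rep(j, length(sv)))
        xx <- c(xx, as.numeric(sv))
      }
    }
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(length(mets), nrow(reactions)),
                              dimnames = list(mets, rid))
  } else {
    S <- methods::as(methods::as(Matrix::Matrix(stoichiometry, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    if (is.null(rownames(S)) || is.null(colnames(S))) {
      stop("matrix stoichiometry requires metabolite and reaction dimnames")
    }
    if (!identical(colnames(S), rid)) stop("stoichiometry columns must match reaction ids")
  }

  if (is.null(gpr)) gpr <- rep(list(NULL), nrow(reactions))
  if (is.character(gpr)) {
    gpr <- lapply(seq_along(gpr), function(j) {
      if (is.na(gpr[j]) || !nzchar(trimws(gpr[j]))) NULL else
        tryCatch(parse_gpr(gpr[j]),
                 error = function(e) stop("reaction ", rid[j], ": ",
                                          conditionMessage(e), call. = FALSE))
    })
  }
  if (length(gpr) != nrow(reactions)) stop("gpr length must equal the number of reactions")
  names(gpr) <- rid

  used_genes <- unique(unlist(lapply(gpr, gpr_genes)))
  if (is.null(genes)) genes <- used_genes
  missing_genes <- setdiff(used_genes, genes)
  if (length(missing_genes)) {
    stop("genes referenced by GPRs but absent from gene universe: ",
         paste(head(missing_genes, 5), collapse = ", "))
  }

  model <- structure(
    list(model_id = model_id, metabolites = rownames(S), reactions = reactions,
         gpr = gpr, S = S, objective = as.character(objective),
         genes = sort(unique(genes))),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's invariants
#'
#' Checks referential integrity: stoichiometry dimensions and names, unique
#' reaction ids, declared objective, GPR genes within the gene universe,
#' ordered bounds.  Called by the constructor and the loaders; useful after
#' manual surgery on a model object.
#'
#' @param model a [metabolic_model()].
#' @return The model, invisibly; errors describe the offending entity.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rid <- model$reactions$reaction_id
  if (!identical(colnames(model$S), rid)) {
    stop("stoichiometry column names disagree with reaction ids")
  }
  if (!identical(rownames(model$S), model$metabolites)) {
    stop("stoichiometry row names disagree with metabolite list")
  }
  if (!model$objective %in% rid) {
    stop("objective reaction not declared: ", model$objective)
  }
  if (any(model$reactions$lower_bound > model$reactions$upper_bound)) {
    stop("reversed bounds present")
  }
  used <- unique(unlist(lapply(model$gpr, gpr_genes)))
  extra <- setdiff(used, model$genes)
  if (length(extra)) stop("GPR references undeclared gene(s): ",
                          paste(head(extra, 5), collapse = ", "))
  invisible(model)
}

#' Model accessors
#'
#' @param model a [metabolic_model()].
#' @return `n_reactions`: the number of reactions; `reaction_ids`: the
#'   ordered character vector of reaction ids.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
reaction_ids <- function(model) model$reactions$reaction_id

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model '", x$model_id, "': ", nrow(x$reactions),
      " reactions, ", length(x$metabolites), " metabolites, ",
      length(x$genes), " genes\n", sep = "")
  cat("objective:", x$objective, "| subsystems:",
      length(unique(x$reactions$subsystem)), "\n")
  invisible(x)
}

#' Mark reactions as protected from extraction
#'
#' Reserved reactions (in the human-model analysis: biomass, the ATP
#' demand, GAPD, ATPS4mi, D_LACt2 and O2t) are prevented from deletion by
#' every extraction algorithm; the returned set is passed through
#' [extraction_config()].
#'
#' @param model a [metabolic_model()].
#' @param ids character vector of reaction ids (may be empty).
#' @return A character vector of class `protected_set`.
#' @export
protect_reactions <- function(model, ids) {
  ids <- unique(as.character(ids))
  missing <- setdiff(ids, reaction_ids(model))
  if (length(missing)) {
    stop("protected reaction id(s) not in model: ",
         paste(missing, collapse = ", "))
  }
  structure(ids, class = "protected_set")
}

# ---- GPR rules --------------------------------------------------------------

#' Parse a gene-protein-reaction rule
#'
#' Boolean grammar over gene tokens with case-insensitive `and`/`or`
#' keywords and parentheses.  Precedence follows the SBML-FBC community
#' convention: parentheses bind tightest, then `and`, then `or`, so
#' `"g1 and g2 or g3"` parses as `OR(AND(g1, g2), g3)`.
#'
#' @param rule_text character scalar.
#' @return A `gpr_rule` tree: either `list(op = "leaf", gene = <id>)` or
#'   `list(op = "and"/"or", children = <list of gpr_rule>)`.
#' @export
parse_gpr <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  txt <- trimws(rule_text)
  if (!nzchar(txt)) stop("empty GPR rule")
  # tokenize
  raw <- gsub("([()])", " \\1 ", txt)
  toks <- strsplit(trimws(raw), "\\s+")[[1]]
  pos <- 0L
  peek <- function() if (pos < length(toks)) toks[pos + 1L] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos] }
  is_kw <- function(tk, kw) !is.na(tk) && tolower(tk) == kw

  parse_or <- function() {
    kids <- list(parse_and())
    while (is_kw(peek(), "or")) { advance(); kids <- c(kids, list(parse_and())) }
    if (length(kids) == 1L) kids[[1L]] else gpr_node("or", kids)
  }
  parse_and <- function() {
    kids <- list(parse_atom())
    while (is_kw(peek(), "and")) { advance(); kids <- c(kids, list(parse_atom())) }
    if (length(kids) == 1L) kids[[1L]] else gpr_node("and", kids)
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.na(tk)) stop("unexpected end of GPR rule at token ", pos)
    if (tk == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) {
        stop("unbalanced parentheses in GPR rule at token ", pos)
      }
      advance()
      return(node)
    }
    if (tk == ")" || is_kw(tk, "and") || is_kw(tk, "or")) {
      stop("unexpected token '", tk, "' in GPR rule at position ", pos + 1L)
    }
    advance()
    structure(list(op = "leaf", gene = tk), class = "gpr_rule")
  }

  out <- parse_or()
  if (pos != length(toks)) {
    stop("trailing token '", peek(), "' in GPR rule at position ", pos + 1L)
  }
  out
}

gpr_node <- function(op, children) {
  structure(list(op = op, children = children), class = "gpr_rule")
}

#' Serialize a GPR tree back to text
#'
#' Inverse of [parse_gpr()] up to associativity: parsing the printed string
#' yields a tree with the same canonical form.
#'
#' @param rule a `gpr_rule` (or `NULL`, which prints as `""`).
#' @return character scalar.
#' @export
format_gpr <- function(rule) {
  if (is.null(rule)) return("")
  stopifnot(inherits(rule, "gpr_rule"))
  if (rule$op == "leaf") return(rule$gene)
  parts <- vapply(rule$children, function(ch) {
    s <- format_gpr(ch)
    # parenthesize an OR child under AND to preserve precedence
    if (rule$op == "and" && ch$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}

#' @export
print.gpr_rule <- function(x, ...) { cat(format_gpr(x), "\n"); invisible(x) }

# genes referenced by a GPR tree
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  if (rule$op == "leaf") return(rule$gene)
  unique(unlist(lapply(rule$children, gpr_genes)))
}

# canonical form: flatten nested same-op nodes, sort children; used to
# compare trees up to commutativity/associativity
canonical_gpr <- function(rule) {
  if (is.null(rule)) return(NULL)
  if (rule$op == "leaf") return(rule)
  kids <- list()
  for (ch in rule$children) {
    cc <- canonical_gpr(ch)
    if (cc$op == rule$op) kids <- c(kids, cc$children) else kids <- c(kids, list(cc))
  }
  keys <- vapply(kids, function(k) format_gpr(k), character(1))
  gpr_node(rule$op, kids[order(keys)])
}

# ---- load / save ------------------------------------------------------------

#' Load a metabolic model from file
#'
#' Supports SBML Level 3 with the FBC extension (for published
#' genome-scale models), plus two package-native plain-text dialects used
#' for fixtures and synthetic models: a JSON schema and a one-reaction-per-
#' row TSV (columns `reaction_id`, `lower_bound`, `upper_bound`, `gpr`,
#' `subsystem`, `objective`, `stoichiometry` with `met:coef;met:coef`
#' entries).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sbml"`, `"json"` or `"tsv"`.
#' @return A validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "sbml", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", json = "json",
                     tsv = "tsv", txt = "tsv",
                     stop("cannot infer model format from extension '.", ext, "'"))
  }
  switch(format,
         sbml = read_model_sbml(path),
         json = read_model_json(path),
         tsv = read_model_tsv(path))
}

#' Save a metabolic model
#'
#' Writes the package-native JSON or TSV dialect.  `save_model` then
#' [load_model()] is the identity on the model fields (see the format
#' description in [load_model()]).
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @param format `"json"` or `"tsv"` (default inferred from extension).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", tsv = "tsv",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  validate_model(model)
  if (format == "json") write_model_json(model, path) else write_model_tsv(model, path)
  invisible(path)
}

stoich_list <- function(model) {
  S <- model$S
  lapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    setNames(as.numeric(col[nz]), rownames(S)[nz])
  })
}

write_model_json <- function(model, path) {
  sl <- stoich_list(model)
  rx <- lapply(seq_len(n_reactions(model)), function(j) {
    r <- model$reactions[j, ]
    list(id = r$reaction_id, lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         gpr = format_gpr(model$gpr[[j]]),
         subsystem = r$subsystem,
         metabolites = as.list(sl[[j]]))
  })
  out <- list(model_id = model$model_id, metabolites = model$metabolites,
              genes = model$genes, objective = model$objective, reactions = rx)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("model_id", "objective", "reactions")) {
    if (is.null(x[[f]])) stop("malformed model JSON: missing field '", f, "'")
  }
  rx <- x$reactions
  df <- data.frame(
    reaction_id = vapply(rx, function(r) r$id, character(1)),
    lower_bound = vapply(rx, function(r) as.numeric(r$lower_bound), numeric(1)),
    upper_bound = vapply(rx, function(r) as.numeric(r$upper_bound), numeric(1)),
    subsystem = vapply(rx, function(r) r$subsystem %||% "unassigned", character(1)),
    stringsAsFactors = FALSE)
  sl <- lapply(rx, function(r) {
    mv <- r$metabolites
    if (!length(mv)) return(numeric(0))
    setNames(vapply(mv, as.numeric, numeric(1)), names(mv))
  })
  gpr <- vapply(rx, function(r) r$gpr %||% "", character(1))
  gpr[!nzchar(gpr)] <- NA_character_
  mdl <- metabolic_model(x$model_id, df, sl, gpr = gpr,
                         objective = x$objective,
                         genes = unlist(x$genes) %||% NULL)
  # preserve declared metabolite ordering where it covers all used metabolites
  mets <- unlist(x$metabolites)
  if (length(mets) && setequal(mets, mdl$metabolites)) {
    mdl$S <- mdl$S[mets, , drop = FALSE]
    mdl$metabolites <- mets
  }
  validate_model(mdl)
}

write_model_tsv <- function(model, path) {
  sl <- stoich_list(model)
  stoich <- vapply(sl, function(sv) {
    paste(sprintf("%s:%s", names(sv), format(sv, digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = ";")
  }, character(1))
  df <- data.frame(
    reaction_id = model$reactions$reaction_id,
    lower_bound = model$reactions$lower_bound,
    upper_bound = model$reactions$upper_bound,
    gpr = vapply(model$gpr, format_gpr, character(1)),
    subsystem = model$reactions$subsystem,
    objective = as.integer(model$reactions$reaction_id == model$objective),
    stoichiometry = stoich, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fluxprint model\t", model$model_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_model_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  model_id <- if (startsWith(first, "# fluxprint model")) {
    trimws(sub("^# fluxprint model\t?", "", first))
  } else tools::file_path_sans_ext(basename(path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("reaction_id", "lower_bound", "upper_bound", "stoichiometry")
  if (!all(req %in% names(df))) {
    stop("malformed model TSV: need columns ", paste(req, collapse = ", "))
  }
  sl <- lapply(seq_len(nrow(df)), function(j) {
    s <- df$stoichiometry[j]
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- vapply(kv, length, integer(1)) != 2L
    if (any(bad)) stop("malformed stoichiometry for reaction ",
                       df$reaction_id[j], ": '", s, "'")
    vals <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 2L)))
    if (anyNA(vals)) stop("non-numeric stoichiometric coefficient in reaction ",
                          df$reaction_id[j])
    setNames(vals, vapply(kv, `[`, character(1), 1L))
  })
  obj_col <- if ("objective" %in% names(df)) df$objective else integer(nrow(df))
  obj <- df$reaction_id[which(obj_col == 1L)]
  if (length(obj) != 1L) stop("model TSV must flag exactly one objective reaction")
  gpr <- if ("gpr" %in% names(df)) as.character(df$gpr) else rep(NA_character_, nrow(df))
  gpr[is.na(gpr) | !nzchar(gpr)] <- NA_character_
  metabolic_model(model_id, df[c("reaction_id", "lower_bound", "upper_bound", "subsystem")],
                  sl, gpr = gpr, objective = obj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- SBML Level 3 FBC reader ------------------------------------------------

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          g = "http://www.sbml.org/sbml/level3/version1/groups/version1")
  mnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(mnode) || inherits(mnode, "xml_missing")) stop("not an SBML L3 document: ", path)
  model_id <- xml2::xml_attr(mnode, "id") %||% "sbml_model"

  # flux bound parameters
  pars <- xml2::xml_find_all(mnode, ".//s:listOfParameters/s:parameter", ns)
  pv <- setNames(as.numeric(xml2::xml_attr(pars, "value")), xml2::xml_attr(pars, "id"))

  # gene products: id -> label
  gps <- xml2::xml_find_all(mnode, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_id <- xml2::xml_attr(gps, "id")
  gp_label <- xml2::xml_attr(gps, "label")
  gp_label[is.na(gp_label)] <- gp_id[is.na(gp_label)]
  gp_map <- setNames(gp_label, gp_id)

  gpa_to_rule <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      gene <- if (ref %in% names(gp_map)) gp_map[[ref]] else ref
      return(structure(list(op = "leaf", gene = gene), class = "gpr_rule"))
    }
    if (nm %in% c("and", "or")) {
      kids <- lapply(xml2::xml_children(node), gpa_to_rule)
      if (length(kids) < 1L) stop("empty ", nm, " node in geneProductAssociation")
      if (length(kids) == 1L) return(kids[[1L]])
      return(gpr_node(nm, kids))
    }
    stop("unsupported geneProductAssociation node: ", nm)
  }

  rx_nodes <- xml2::xml_find_all(mnode, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx_nodes)) stop("SBML model declares no reactions")
  n <- length(rx_nodes)
  rid <- xml2::xml_attr(rx_nodes, "id")
  lb <- ub <- numeric(n)
  sl <- vector("list", n)
  gpr <- vector("list", n)
  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[j] <- if (!is.na(lbp) && lbp %in% names(pv)) pv[[lbp]] else if (rev) -1000 else 0
    ub[j] <- if (!is.na(ubp) && ubp %in% names(pv)) pv[[ubp]] else 1000
    sv <- numeric(0)
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
      if (is.na(st)) stop("malformed stoichiometry in reaction ", rid[j])
      sv[sp] <- (if (sp %in% names(sv)) sv[[sp]] else 0) - st
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      st <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
      if (is.na(st)) stop("malformed stoichiometry in reaction ", rid[j])
      sv[sp] <- (if (sp %in% names(sv)) sv[[sp]] else 0) + st
    }
    sl[[j]] <- sv
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr[j] <- list(if (inherits(gpa, "xml_missing")) NULL else
      gpa_to_rule(xml2::xml_child(gpa)))
  }

  # boundary species do not enter the steady-state balance
  sp_nodes <- xml2::xml_find_all(mnode, ".//s:listOfSpecies/s:species", ns)
  boundary <- xml2::xml_attr(sp_nodes, "id")[
    xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"]
  if (length(boundary)) {
    sl <- lapply(sl, function(sv) sv[!(names(sv) %in% boundary)])
  }

  # subsystems from the groups package, when present
  subsystem <- rep("unassigned", n)
  for (grp in xml2::xml_find_all(mnode, ".//g:listOfGroups/g:group", ns)) {
    gname <- xml2::xml_attr(grp, "name") %||% xml2::xml_attr(grp, "id")
    members <- xml2::xml_attr(
      xml2::xml_find_all(grp, ".//g:member", ns), "idRef")
    subsystem[rid %in% members] <- gname
  }

  obj_node <- xml2::xml_find_first(
    mnode, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(obj_node, "xml_missing")) stop("SBML model declares no FBC objective")
  objective <- xml2::xml_attr(obj_node, "reaction")

  df <- data.frame(reaction_id = rid, lower_bound = lb, upper_bound = ub,
                   subsystem = subsystem, stringsAsFactors = FALSE)
  metabolic_model(model_id, df, sl, gpr = gpr, objective = objective)
}

# induced submodel on a kept reaction set (drops now-unused metabolites)
induced_submodel <- function(model, kept, model_id = NULL) {
  kept <- intersect(reaction_ids(model), kept)  # preserve order
  jj <- match(kept, reaction_ids(model))
  S <- model$S[, jj, drop = FALSE]
  use_met <- Matrix::rowSums(S != 0) > 0
  S <- S[use_met, , drop = FALSE]
  structure(
    list(model_id = model_id %||% paste0(model$model_id, "_sub"),
         metabolites = rownames(S),
         reactions = model$reactions[jj, , drop = FALSE],
         gpr = model$gpr[jj], S = S,
         objective = model$objective,
         genes = model$genes),
    class = "metabolic_model")
}
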