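#' Preprocess an expression matrix into per-sample profiles
#'
#' Replicates are averaged (missing entries ignored in the mean) and each
#' resulting profile is min-max scaled to `[0, 1]` independently:
#' `(value - min) / (max - min)` over the genes of that profile.  The
#' per-sample scaling scope is a package choice (the downstream expression
#' thresholds are quantile-based within profiles); see the methods
#' vignette.
#'
#' @param raw numeric gene x sample matrix (rownames = gene ids); `NA`
#'   entries mark unmeasured genes.
#' @param replicate_groups named character vector mapping each sample
#'   (column) to its replicate group; defaults to one group per column.
#' @param platform platform label attached to every profile
#'   (`"microarray"`, `"rnaseq"` or `"proteome"`).
#' @param group_labels optional named vector mapping replicate groups to a
#'   biological group (e.g. cancer type).
#'
#' @return A list of `expression_profile` objects (fields `sample_id`,
#'   `platform`, `values` -- named numeric in `[0, 1]` --, `group_label`).
#'   Groups with no finite measurements are dropped with a warning;
#'   constant profiles are set to all-zero with a warning.
#' @export
preprocess_expression <- function(raw,
                                  replicate_groups = setNames(colnames(raw), colnames(raw)),
                                  platform = c("rnaseq", "microarray", "proteome"),
                                  group_labels = NULL) {
  platform <- match.arg(platform)
  raw <- as.matrix(raw)
  if (is.null(rownames(raw))) stop("expression matrix needs gene ids as rownames")
  if (is.null(colnames(raw))) stop("expression matrix needs sample ids as colnames")
  if (!all(colnames(raw) %in% names(replicate_groups))) {
    stop("replicate_groups must cover every sample column")
  }
  groups <- unique(replicate_groups[colnames(raw)])
  out <- list()
  for (g in groups) {
    cols <- colnames(raw)[replicate_groups[colnames(raw)] == g]
    sub <- raw[, cols, drop = FALSE]
    avg <- rowMeans(sub, na.rm = TRUE)
    avg[!is.finite(avg)] <- NA_real_
    if (all(is.na(avg))) {
      warning("profile '", g, "' has no measured genes; dropped")
      next
    }
    rng <- range(avg, na.rm = TRUE)
    if (rng[1] == rng[2]) {
      warning("profile '", g, "' is constant; normalized values set to 0")
      vals <- ifelse(is.na(avg), NA_real_, 0)
    } else {
      vals <- (avg - rng[1]) / (rng[2] - rng[1])
    }
    out[[g]] <- structure(
      list(sample_id = g, platform = platform,
           values = setNames(as.numeric(vals), rownames(raw)),
           group_label = if (!is.null(group_labels)) unname(group_labels[g]) else NA_character_),
      class = "expression_profile")
  }
  out
}

#' @export
print.expression_profile <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("expression_profile '", x$sample_id, "' (", x$platform, "): ",
      length(v), "/", length(x$values), " genes measured",
      if (!is.na(x$group_label)) paste0(", group ", x$group_label) else "",
      "\n", sep = "")
  invisible(x)
}

# evaluate a GPR tree against a named value vector; AND -> min, OR -> max;
# children without data are dropped at each node, a node with all children
# missing is NA
eval_gpr <- function(rule, values) {
  if (is.null(rule)) return(NA_real_)
  if (rule$op == "leaf") {
    v <- values[rule$gene]
    if (length(v) == 0 || is.na(v)) return(NA_real_)
    return(unname(v))
  }
  kids <- vapply(rule$children, eval_gpr, numeric(1), values = values)
  kids <- kids[!is.na(kids)]
  if (!length(kids)) return(NA_real_)
  if (rule$op == "and") min(kids) else max(kids)
}

#' Map expression values onto reactions through GPR rules
#'
#' Recursive GPR evaluation: `AND` nodes (enzyme complexes) take the
#' minimum of their children, `OR` nodes (isozymes) the maximum.  A gene
#' with no measurement propagates as missing; a node whose children are all
#' missing is missing; a reaction with no GPR, or whose genes are all
#' unmeasured, gets no value.
#'
#' @param model a [metabolic_model()].
#' @param profile an `expression_profile` from [preprocess_expression()]
#'   (or any named numeric vector of per-gene values).
#' @return A `reaction_activity`: list with `sample_id` and `values`, a
#'   named numeric vector over all reactions with `NA` for unassigned
#'   reactions.
#' @export
map_expression <- function(model, profile) {
  values <- if (inherits(profile, "expression_profile")) profile$values else profile
  sample_id <- if (inherits(profile, "expression_profile")) profile$sample_id else "sample"
  act <- vapply(model$gpr, eval_gpr, numeric(1), values = values)
  structure(list(sample_id = sample_id,
                 values = setNames(act, reaction_ids(model))),
            class = "reaction_activity")
}

#' @export
print.reaction_activity <- function(x, ...) {
  cat("reaction_activity '", x$sample_id, "': ", sum(!is.na(x$values)), "/",
      length(x$values), " reactions assigned\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' First column gene id, remaining columns one sample each.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}
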