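#' Glycolytic-to-oxidative ATP flux ratio (AFR)
#'
#' The first Warburg-effect index: flux through the glycolytic marker
#' reaction (GAPD) divided by flux through mitochondrial ATP synthase
#' (ATPS4mi).  A positive AFR means both ATP routes run in their
#' physiological direction; larger values indicate a more glycolytic
#' (Warburg-shifted) flux state.
#'
#' @param flux a `flux_state` from [fba()] (or a named flux vector).
#' @param gapd,atps reaction ids of the glycolytic marker and the ATP
#'   synthase (toy models alias the human ids by default).
#' @return scalar ratio; `NaN` with attribute `zero_denominator = TRUE`
#'   when the synthase carries no flux.
#' @export
afr_score <- function(flux, gapd = "GAPD", atps = "ATPS4mi") {
  v <- if (inherits(flux, "flux_state")) flux$flux else flux
  for (r in c(gapd, atps)) {
    if (!r %in% names(v)) stop("reaction missing from flux state: ", r)
  }
  if (v[atps] == 0) {
    return(structure(NaN, zero_denominator = TRUE))
  }
  unname(v[gapd] / v[atps])
}

#' Lactate-secretion versus oxygen-uptake ratio (EOR)
#'
#' The second Warburg-effect index: flux through the lactate transporter
#' divided by flux through the oxygen transporter.  Both transporters are
#' oriented so that positive flux is uptake into the cell; a fermenting,
#' respiring cell secretes lactate (negative numerator) while consuming
#' oxygen (positive denominator), giving EOR < 0.
#'
#' @param flux a `flux_state` (or named flux vector).
#' @param lact,o2 reaction ids of the lactate and oxygen transporters.
#' @return scalar ratio; `NaN` with attribute `zero_denominator = TRUE`
#'   when no oxygen is exchanged.
#' @export
eor_score <- function(flux, lact = "D_LACt2", o2 = "O2t") {
  v <- if (inherits(flux, "flux_state")) flux$flux else flux
  for (r in c(lact, o2)) {
    if (!r %in% names(v)) stop("reaction missing from flux state: ", r)
  }
  if (v[o2] == 0) {
    return(structure(NaN, zero_denominator = TRUE))
  }
  unname(v[lact] / v[o2])
}

#' Hallmark gene-set activation of an extracted model
#'
#' Percentage of hallmark genes retained by a context-specific model:
#' the denominator counts hallmark genes present in the parent model's
#' gene universe, the numerator those referenced by a GPR of at least one
#' kept reaction.
#'
#' @param result an `extraction_result` from [extract_context()].
#' @param hallmark_genes character vector of hallmark gene ids (e.g. read
#'   with [read_gene_list()]).
#' @return percentage in `[0, 100]`.
#' @export
hallmark_activation <- function(result, hallmark_genes) {
  stopifnot(inherits(result, "extraction_result"))
  if (!length(hallmark_genes)) stop("hallmark gene set is empty")
  universe <- result$context_model$genes  # full parent universe is retained
  in_model <- intersect(hallmark_genes, universe)
  if (!length(in_model)) {
    stop("no hallmark gene appears in the model's gene universe")
  }
  cm <- result$context_model
  kept_genes <- unique(unlist(lapply(cm$gpr, gpr_genes)))
  100 * length(intersect(in_model, kept_genes)) / length(in_model)
}

#' Read a gene list (one id per line)
#'
#' @param path text file, one gene id per line; blank lines and `#`
#'   comments ignored.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Score one extracted model
#'
#' Convenience wrapper: runs FBA on the context model and assembles the
#' per-model score row (AFR, EOR, hallmark activation).
#'
#' @param result an `extraction_result`.
#' @param hallmark_genes character vector of hallmark gene ids.
#' @param config a [solver_config()].
#' @return one-row data frame: `sample_id`, `algorithm`, `afr`, `eor`,
#'   `hallmark_percent`, `biomass`, `status`.
#' @export
score_report <- function(result, hallmark_genes, config = solver_config()) {
  fs <- fba(result$context_model, config = config)
  afr <- if (fs$status == "optimal") afr_score(fs) else NA_real_
  eor <- if (fs$status == "optimal") eor_score(fs) else NA_real_
  data.frame(sample_id = result$sample_id, algorithm = result$algorithm,
             afr = as.numeric(afr), eor = as.numeric(eor),
             hallmark_percent = hallmark_activation(result, hallmark_genes),
             biomass = fs$objective_value, status = fs$status,
             stringsAsFactors = FALSE)
}
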