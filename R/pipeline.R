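#' Benchmark configuration
#'
#' Declarative description of one benchmark run: the model, the datasets
#' (simulated or loaded), the extraction algorithms and thresholds, the
#' hallmark list and the analyses to perform.  The configuration is echoed
#' verbatim into the report and the output directory, and the single seed
#' fans out deterministically to every stochastic stage.
#'
#' @param model a [metabolic_model()] or a model file path.
#' @param datasets named list of datasets: each either the result of
#'   [simulate_expression()] or a list with elements `matrix`,
#'   `replicate_groups`, `group_labels` and optionally `platform`.
#' @param algorithms subset of `c("gimme", "imat", "init", "fastcore")`.
#' @param hallmark_genes character vector (or path to a one-per-line file).
#' @param protected reaction ids protected from deletion; defaults to the
#'   six reserved reactions intersected with the model.
#' @param extraction named list of overrides passed to
#'   [extraction_config()] (e.g. `list(expression_threshold = 0.3)`).
#' @param analyses character subset of `c("jaccard", "bland_altman",
#'   "pca_rf")`.
#' @param ba_mode Bland-Altman difference mode (`"raw"` or `"percent"`).
#' @param alpha significance level for the disagreement fraction.
#' @param max_k largest cluster count tried by [pca_cluster()].
#' @param top_k features selected by [rf_importance()].
#' @param out_dir optional output directory for report tables.
#' @param seed integer master seed.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(model, datasets, algorithms = c("gimme", "imat",
                                                             "init", "fastcore"),
                             hallmark_genes = character(0),
                             protected = NULL,
                             extraction = list(),
                             analyses = c("jaccard", "bland_altman", "pca_rf"),
                             ba_mode = "raw", alpha = 0.05,
                             max_k = 6, top_k = 15,
                             out_dir = NULL, seed = 1L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.character(model)) model <- load_model(model)
  if (length(hallmark_genes) == 1 && file.exists(hallmark_genes)) {
    hallmark_genes <- read_gene_list(hallmark_genes)
  }
  if (is.null(names(datasets))) {
    names(datasets) <- sprintf("dataset%02d", seq_along(datasets))
  }
  structure(list(model = model, datasets = datasets, algorithms = algorithms,
                 hallmark_genes = hallmark_genes, protected = protected,
                 extraction = extraction, analyses = analyses,
                 ba_mode = ba_mode, alpha = alpha, max_k = max_k,
                 top_k = top_k, out_dir = out_dir, seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Run the full heterogeneity benchmark
#'
#' Orchestrates the complete workflow for every dataset x algorithm cell:
#' flux-consistency reduction of the model, preprocessing and GPR mapping
#' of every sample, context-specific extraction, FBA of each extracted
#' model, Warburg/hallmark scoring, pairwise subsystem-Jaccard and
#' Bland-Altman comparisons, PCA clusterability, and random-forest feature
#' selection aggregated into a subsystem barcode.  Per-sample failures are
#' recorded and skipped, not fatal.  With a fixed seed the report
#' (including all written tables) is reproducible byte for byte.
#'
#' @param cfg a [benchmark_config()].
#' @return A `heterogeneity_report`: list with `scores` (per-CGEM data
#'   frame), `jaccard`, `bland_altman` (pairwise tables), `disagreement`
#'   (per-cell percentages), `clusters`, `importance` (per-cell reports),
#'   `barcode`, `kept_sizes`, `errors` and `config_echo`.
#' @export
run_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "benchmark_config"))
  model <- cfg$model
  protected_ids <- cfg$protected %||% intersect(reserved_reactions(),
                                                reaction_ids(model))

  # stage seeds fan out from the master seed
  stage_seed <- function(i) (cfg$seed * 1009L + i * 9973L) %% .Machine$integer.max

  cr <- fastcc(model)
  cmodel <- cr$consistent_model
  protected <- protect_reactions(cmodel, intersect(protected_ids,
                                                   reaction_ids(cmodel)))

  scores <- list(); jac <- list(); ba <- list(); disag <- list()
  clusters <- list(); importance <- list(); errors <- list()
  kept_sizes <- list()
  cell_i <- 0L

  for (ds_name in names(cfg$datasets)) {
    ds <- cfg$datasets[[ds_name]]
    platform <- ds$platform %||% ds$ground_truth$design$platform %||% "rnaseq"
    profs <- preprocess_expression(ds$matrix, ds$replicate_groups,
                                   platform = platform,
                                   group_labels = ds$group_labels)
    activities <- lapply(profs, function(p) map_expression(cmodel, p))

    for (alg in cfg$algorithms) {
      cell_i <- cell_i + 1L
      cell <- paste(ds_name, alg, sep = "-")
      ecfg <- do.call(extraction_config,
                      c(list(algorithm = alg, protected = protected),
                        cfg$extraction))
      results <- list(); fluxes <- list()
      for (sid in names(activities)) {
        out <- tryCatch({
          res <- extract_context(cmodel, activities[[sid]], ecfg)
          fs <- fba(res$context_model)
          sc <- score_report(res, cfg$hallmark_genes)
          list(res = res, fs = fs, sc = sc)
        }, error = function(e) e)
        if (inherits(out, "error")) {
          errors[[length(errors) + 1L]] <- data.frame(
            dataset = ds_name, algorithm = alg, sample_id = sid,
            message = conditionMessage(out), stringsAsFactors = FALSE)
          next
        }
        results[[sid]] <- out$res
        fluxes[[sid]] <- out$fs
        sc <- out$sc
        sc$dataset <- ds_name
        sc$group <- unname(ds$group_labels[sid])
        sc$kept <- length(out$res$kept_reactions)
        scores[[length(scores) + 1L]] <- sc
        kept_sizes[[length(kept_sizes) + 1L]] <- data.frame(
          dataset = ds_name, algorithm = alg, sample_id = sid,
          kept = length(out$res$kept_reactions), stringsAsFactors = FALSE)
      }
      if (length(results) < 2) next

      if ("jaccard" %in% cfg$analyses) {
        ids <- names(results)
        for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
          jr <- jaccard_subsystem(results[[ids[i]]], results[[ids[j]]], cmodel)
          jac[[length(jac) + 1L]] <- data.frame(
            dataset = ds_name, algorithm = alg,
            sample_i = ids[i], sample_j = ids[j],
            mean_index = jr$mean_index, stringsAsFactors = FALSE)
        }
      }
      if ("bland_altman" %in% cfg$analyses) {
        dm <- disagreement_matrix(fluxes, alpha = cfg$alpha, mode = cfg$ba_mode)
        tab <- dm$table
        tab$dataset <- ds_name; tab$algorithm <- alg
        ba[[length(ba) + 1L]] <- tab
        disag[[length(disag) + 1L]] <- data.frame(
          dataset = ds_name, algorithm = alg,
          percent_disagreement = dm$percent_disagreement,
          n_failed = dm$n_failed, stringsAsFactors = FALSE)
      }
      if ("pca_rf" %in% cfg$analyses) {
        fm <- flux_matrix(fluxes, cmodel)
        cl <- pca_cluster(fm, max_k = cfg$max_k, seed = stage_seed(cell_i))
        clusters[[cell]] <- cl
        if (cl$n_clusters >= 2) {
          importance[[cell]] <- rf_importance(fm, cl$labels, model = cmodel,
                                              k = cfg$top_k,
                                              seed = stage_seed(cell_i) + 1L)
        }
      }
    }
  }

  report <- structure(list(
    scores = if (length(scores)) do.call(rbind, scores) else NULL,
    jaccard = if (length(jac)) do.call(rbind, jac) else NULL,
    bland_altman = if (length(ba)) do.call(rbind, ba) else NULL,
    disagreement = if (length(disag)) do.call(rbind, disag) else NULL,
    clusters = clusters,
    importance = importance,
    barcode = if (length(importance)) subsystem_barcode(importance) else NULL,
    kept_sizes = if (length(kept_sizes)) do.call(rbind, kept_sizes) else NULL,
    errors = if (length(errors)) do.call(rbind, errors) else NULL,
    config_echo = list(seed = cfg$seed, algorithms = cfg$algorithms,
                       analyses = cfg$analyses, ba_mode = cfg$ba_mode,
                       alpha = cfg$alpha, max_k = cfg$max_k, top_k = cfg$top_k,
                       extraction = cfg$extraction,
                       datasets = names(cfg$datasets),
                       n_consistent_reactions = n_reactions(cmodel))),
    class = "heterogeneity_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat("heterogeneity_report:\n")
  if (!is.null(x$scores)) {
    cat("  ", nrow(x$scores), " scored context models over ",
        length(unique(x$scores$dataset)), " dataset(s) x ",
        length(unique(x$scores$algorithm)), " algorithm(s)\n", sep = "")
  }
  if (!is.null(x$disagreement)) {
    cat("  mean flux disagreement: ",
        format(mean(x$disagreement$percent_disagreement), digits = 4), "%\n",
        sep = "")
  }
  if (length(x$clusters)) {
    ks <- vapply(x$clusters, `[[`, integer(1), "n_clusters")
    cat("  clusters per cell: ", paste(names(ks), ks, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$errors)) cat("  ", nrow(x$errors), " per-sample failures\n", sep = "")
  invisible(x)
}

# write the report tables as TSV/JSON under out_dir (text only, no
# timestamps, so identical runs produce identical bytes)
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return(invisible())
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$scores, "scores.tsv")
  wt(report$jaccard, "jaccard.tsv")
  wt(report$bland_altman, "bland_altman.tsv")
  wt(report$disagreement, "disagreement.tsv")
  wt(report$kept_sizes, "kept_sizes.tsv")
  wt(report$barcode, "barcode.tsv")
  wt(report$errors, "errors.tsv")
  if (length(report$clusters)) {
    cl_df <- do.call(rbind, lapply(names(report$clusters), function(cell) {
      cl <- report$clusters[[cell]]
      data.frame(cell = cell, n_clusters = cl$n_clusters,
                 silhouette = cl$silhouette,
                 pc12_variance = if (length(cl$explained_variance) >= 2)
                   sum(cl$explained_variance[1:2]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    wt(cl_df, "clusters.tsv")
  }
  if (length(report$importance)) {
    imp_df <- do.call(rbind, lapply(names(report$importance), function(cell) {
      rk <- head(report$importance[[cell]]$ranking,
                 length(report$importance[[cell]]$top_k))
      rk$cell <- cell
      rk
    }))
    wt(imp_df, "importance.tsv")
  }
  jsonlite::write_json(report$config_echo, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
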