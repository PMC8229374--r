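#' Assemble a flux matrix from flux states
#'
#' Stacks FBA flux vectors into a samples x reactions matrix, the "flux
#' fingerprint" feature set.  Reactions absent from an extracted model are
#' imputed as zero flux; the column order is the parent model's reaction
#' order.
#'
#' @param flux_states named list of `flux_state`s (names become row
#'   names).
#' @param model the parent [metabolic_model()] fixing the column order;
#'   when `NULL` the union of reaction names in input order is used.
#' @return numeric matrix (samples x reactions).
#' @export
flux_matrix <- function(flux_states, model = NULL) {
  stopifnot(length(flux_states) >= 1)
  ids <- names(flux_states) %||%
    vapply(flux_states, function(f) f$model_id, character(1))
  cols <- if (!is.null(model)) reaction_ids(model) else
    unique(unlist(lapply(flux_states, function(f) {
      names(if (inherits(f, "flux_state")) f$flux else f)
    })))
  fm <- matrix(0, length(flux_states), length(cols),
               dimnames = list(ids, cols))
  for (i in seq_along(flux_states)) {
    v <- if (inherits(flux_states[[i]], "flux_state")) flux_states[[i]]$flux
         else flux_states[[i]]
    v <- v[!is.na(v)]
    use <- intersect(names(v), cols)
    fm[i, use] <- v[use]
  }
  fm
}

#' PCA-based clusterability of flux states
#'
#' Columns are centered (not variance-scaled: flux magnitude is the
#' signal) and decomposed by SVD; k-means is run on the first two
#' principal-component scores for each candidate cluster count, and the
#' count maximizing the mean silhouette width is selected.  When even the
#' best silhouette is weak (< `silhouette_floor`) the configuration is
#' declared unclustered (`n_clusters = 1`), as is a constant matrix.
#' The default floor of 0.5 is the Kaufman-Rousseeuw "reasonable
#' structure" rubric; k-means imposes partitions on any 2-D point cloud,
#' and the silhouette such imposed partitions reach on isotropic noise
#' stays below this value while genuine group structure clears it.
#'
#' @param fm samples x reactions flux matrix from [flux_matrix()].
#' @param max_k largest cluster count tried (capped at `n - 1`).
#' @param silhouette_floor minimum mean silhouette accepted as real
#'   cluster structure.
#' @param scale. also scale columns to unit variance (off by default).
#' @param seed optional RNG seed for the k-means restarts.
#' @return A `cluster_report`: list with `pc_scores` (n x 2),
#'   `explained_variance` (all components), `n_clusters`, `labels`
#'   (named integer vector, `NULL` when `n_clusters == 1`), `silhouette`
#'   and `tried` (silhouette per candidate k).
#' @export
pca_cluster <- function(fm, max_k = 6, silhouette_floor = 0.5,
                        scale. = FALSE, seed = NULL) {
  stopifnot(nrow(fm) >= 3)
  keep <- apply(fm, 2, function(x) var(x) > 0)
  if (sum(keep) < 2) {
    return(structure(list(pc_scores = NULL,
                          explained_variance = numeric(0),
                          n_clusters = 1L, labels = NULL,
                          silhouette = NA_real_, tried = numeric(0)),
                     class = "cluster_report"))
  }
  pc <- prcomp(fm[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, 1:min(2, ncol(pc$x)), drop = FALSE]

  run <- function() {
    ks <- 2:min(max_k, nrow(fm) - 1)
    sil <- setNames(rep(NA_real_, length(ks)), ks)
    fits <- list()
    dd <- dist(scores)
    for (k in ks) {
      fit <- tryCatch(
        suppressWarnings(kmeans(scores, centers = k, nstart = 10,
                                iter.max = 50)),
        error = function(e) NULL)  # fewer distinct points than centers
      if (is.null(fit) || length(unique(fit$cluster)) < k) next
      sw <- cluster::silhouette(fit$cluster, dd)
      sil[as.character(k)] <- mean(sw[, "sil_width"])
      fits[[as.character(k)]] <- fit$cluster
    }
    list(sil = sil, fits = fits)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())

  if (all(is.na(res$sil)) || max(res$sil, na.rm = TRUE) < silhouette_floor) {
    return(structure(list(pc_scores = scores, explained_variance = ev,
                          n_clusters = 1L, labels = NULL,
                          silhouette = suppressWarnings(max(res$sil, na.rm = TRUE)),
                          tried = res$sil),
                     class = "cluster_report"))
  }
  best <- names(res$sil)[which.max(res$sil)]
  structure(list(pc_scores = scores, explained_variance = ev,
                 n_clusters = as.integer(best),
                 labels = setNames(res$fits[[best]], rownames(fm)),
                 silhouette = res$sil[[best]], tried = res$sil),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("cluster_report: ", x$n_clusters, " cluster(s)",
      if (!is.na(x$silhouette)) paste0(", silhouette ", format(x$silhouette, digits = 3)),
      if (length(x$explained_variance) >= 2)
        paste0(", PC1+PC2 variance ", format(100 * sum(x$explained_variance[1:2]),
                                             digits = 3), "%"),
      "\n", sep = "")
  invisible(x)
}

#' Random-forest selection of discriminative flux features
#'
#' Fits a random-forest classifier of the cluster (or group) labels on the
#' flux matrix with `ntree` trees and `floor(sqrt(p))` candidate
#' predictors per split, ranks reactions by mean impurity decrease (Gini),
#' and aggregates the top-k reactions by the parent model's subsystems.
#'
#' @param fm samples x reactions flux matrix.
#' @param labels vector of class labels (>= 2 classes), e.g.
#'   `cluster_report$labels` or known group labels.
#' @param model parent [metabolic_model()] for subsystem annotation
#'   (optional; without it `subsystem_frequency` is empty).
#' @param ntree number of trees.
#' @param k number of top features selected.
#' @param seed optional RNG seed (forest growth is stochastic).
#' @return An `importance_report`: list with `ranking` (data frame:
#'   `reaction_id`, `importance`, `subsystem`), `top_k` (character),
#'   `subsystem_frequency` (named count vector summing to `k`), `ntree`,
#'   `mtry`.
#' @export
rf_importance <- function(fm, labels, model = NULL, ntree = 500, k = 15,
                          seed = NULL) {
  if (!is.null(names(labels)) && !is.null(rownames(fm))) {
    labels <- labels[rownames(fm)]
  }
  y <- factor(labels)
  if (nlevels(y) < 2) {
    stop("random-forest feature selection needs at least 2 classes")
  }
  stopifnot(length(y) == nrow(fm))
  mtry <- max(1L, floor(sqrt(ncol(fm))))
  fit_fun <- function() randomForest::randomForest(
    x = fm, y = y, ntree = ntree, mtry = mtry, importance = FALSE)
  fit <- if (is.null(seed)) fit_fun() else with_seed(seed, fit_fun())
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, seq_along(imp))  # deterministic tie-break: column order
  sub <- if (!is.null(model)) {
    setNames(model$reactions$subsystem, reaction_ids(model))[names(imp)]
  } else rep(NA_character_, length(imp))
  ranking <- data.frame(reaction_id = names(imp)[ord],
                        importance = unname(imp[ord]),
                        subsystem = unname(sub[ord]),
                        stringsAsFactors = FALSE)
  top_k <- head(ranking$reaction_id, k)
  freq <- if (!is.null(model)) {
    tb <- table(head(ranking$subsystem, k))
    setNames(as.integer(tb), names(tb))
  } else integer(0)
  structure(list(ranking = ranking, top_k = top_k,
                 subsystem_frequency = freq, ntree = ntree, mtry = mtry),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("importance_report: top", length(x$top_k), "reactions (ntree =",
      x$ntree, ", mtry =", x$mtry, ")\n")
  if (length(x$subsystem_frequency)) {
    f <- sort(x$subsystem_frequency, decreasing = TRUE)
    cat(paste0("  ", names(f), ": ", f, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Aggregate subsystem barcodes across importance reports
#'
#' Sums the top-k subsystem frequencies across dataset-algorithm
#' importance reports: the data behind a subsystem "barcode" showing
#' which cellular subsystems concentrate the discriminative flux
#' features.
#'
#' @param reports list of `importance_report`s.
#' @return data frame `subsystem`, `count`, ordered by decreasing count.
#' @export
subsystem_barcode <- function(reports) {
  stopifnot(length(reports) >= 1)
  acc <- list()
  for (rp in reports) {
    f <- rp$subsystem_frequency
    for (s in names(f)) acc[[s]] <- (acc[[s]] %||% 0L) + f[[s]]
  }
  if (!length(acc)) return(data.frame(subsystem = character(0), count = integer(0)))
  df <- data.frame(subsystem = names(acc), count = unlist(acc, use.names = FALSE),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$subsystem), , drop = FALSE]
}
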