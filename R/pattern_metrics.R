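#' Subsystem-averaged Jaccard index between two extracted models
#'
#' For each subsystem of the parent model, the Jaccard index
#' `|A & B| / |A | B|` is computed over the two kept-reaction sets
#' restricted to that subsystem; subsystems untouched by both models are
#' skipped; the final index is the mean over the remaining subsystems.
#'
#' @param a,b `extraction_result`s from the same parent model.
#' @param model the parent [metabolic_model()] supplying subsystem
#'   annotations.
#' @return A `jaccard_report`: list with `pair`, `per_subsystem` (named
#'   numeric) and `mean_index`.
#' @export
jaccard_subsystem <- function(a, b, model) {
  stopifnot(inherits(a, "extraction_result"), inherits(b, "extraction_result"))
  if (!identical(a$parent_model_id, b$parent_model_id)) {
    stop("extraction results come from different parent models: ",
         a$parent_model_id, " vs ", b$parent_model_id)
  }
  sub <- setNames(model$reactions$subsystem, reaction_ids(model))
  ka <- a$kept_reactions; kb <- b$kept_reactions
  per <- c()
  for (s in unique(sub)) {
    rs <- names(sub)[sub == s]
    sa <- intersect(ka, rs); sb <- intersect(kb, rs)
    un <- union(sa, sb)
    if (!length(un)) next  # subsystem absent from both models
    per[s] <- length(intersect(sa, sb)) / length(un)
  }
  structure(list(pair = c(a$sample_id, b$sample_id),
                 per_subsystem = per,
                 mean_index = mean(per)),
            class = "jaccard_report")
}

#' @export
print.jaccard_report <- function(x, ...) {
  cat("jaccard_report ", x$pair[1], " vs ", x$pair[2], ": mean index ",
      format(x$mean_index, digits = 4), " over ", length(x$per_subsystem),
      " subsystems\n", sep = "")
  invisible(x)
}

#' Bland-Altman agreement between two flux states
#'
#' Pairs the two flux vectors over the union of their reactions (a
#' reaction absent from one model is imputed zero flux), computes
#' per-reaction differences -- raw `a - b`, or as percentages of the
#' pairwise mean `100 (a - b) / mean` with zero-mean pairs dropped -- and
#' summarizes them by the mean difference, its standard deviation, the
#' limits of agreement (mean difference +/- 1.96 SD) and a two-sided
#' one-sample location test of the differences against zero.
#'
#' @param flux_a,flux_b `flux_state`s (or named flux vectors).
#' @param mode `"raw"` or `"percent"`.
#' @param test `"t"` (one-sample t-test, default) or `"wilcoxon"` (signed
#'   rank, for heavy-tailed differences).
#' @return A `bland_altman_result`: list with `pair`, `mean_difference`,
#'   `sd_difference`, `loa_low`, `loa_high`, `p_value`, `n_pairs`,
#'   `n_dropped`, `mode` and the per-reaction `differences`/`means`.
#' @export
bland_altman <- function(flux_a, flux_b, mode = c("raw", "percent"),
                         test = c("t", "wilcoxon")) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  va <- if (inherits(flux_a, "flux_state")) flux_a$flux else flux_a
  vb <- if (inherits(flux_b, "flux_state")) flux_b$flux else flux_b
  ida <- if (inherits(flux_a, "flux_state")) flux_a$model_id else "a"
  idb <- if (inherits(flux_b, "flux_state")) flux_b$model_id else "b"
  all_r <- union(names(va), names(vb))
  a <- setNames(numeric(length(all_r)), all_r); a[names(va)] <- va
  b <- setNames(numeric(length(all_r)), all_r); b[names(vb)] <- vb
  mn <- (a + b) / 2
  if (mode == "raw") {
    d <- a - b
    dropped <- 0L
  } else {
    keep <- mn != 0
    d <- 100 * (a[keep] - b[keep]) / mn[keep]
    mn <- mn[keep]
    dropped <- sum(!keep)
  }
  if (length(d) < 3) stop("fewer than 3 usable reaction pairs")
  md <- mean(d); sdd <- sd(d)
  p <- if (sdd < 1e-12) {
    if (abs(md) < 1e-12) 1 else 0
  } else if (test == "t") t.test(d, mu = 0)$p.value else
    suppressWarnings(wilcox.test(d, mu = 0)$p.value)
  structure(list(pair = c(ida, idb), mean_difference = md,
                 sd_difference = sdd,
                 loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
                 p_value = p, n_pairs = length(d), n_dropped = dropped,
                 mode = mode, differences = d, means = mn),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat("bland_altman_result (", x$mode, "): mean diff ",
      format(x$mean_difference, digits = 4), ", LoA [",
      format(x$loa_low, digits = 4), ", ", format(x$loa_high, digits = 4),
      "], p = ", format(x$p_value, digits = 3), " (n = ", x$n_pairs, ")\n",
      sep = "")
  invisible(x)
}

#' Pairwise flux-state disagreement
#'
#' Runs [bland_altman()] on every unordered pair of flux states and
#' reports the percentage of pairs whose location test rejects agreement
#' at level `alpha` -- the "statistically significant disagreement"
#' fraction.
#'
#' @param flux_states list of `flux_state`s (named or with distinct
#'   `model_id`s); at least 2.
#' @param alpha significance level.
#' @inheritParams bland_altman
#' @return A list with `percent_disagreement`, `table` (long-format data
#'   frame: `sample_i`, `sample_j`, `mean_difference`, `p_value`,
#'   `significant`) and `n_failed` (pairs skipped due to errors).
#' @export
disagreement_matrix <- function(flux_states, alpha = 0.05,
                                mode = c("raw", "percent"), test = c("t", "wilcoxon")) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  stopifnot(length(flux_states) >= 2)
  ids <- names(flux_states) %||%
    vapply(flux_states, function(f) f$model_id, character(1))
  rows <- list()
  n_failed <- 0L
  for (i in seq_along(flux_states)[-length(flux_states)]) {
    for (j in (i + 1):length(flux_states)) {
      ba <- tryCatch(bland_altman(flux_states[[i]], flux_states[[j]],
                                  mode = mode, test = test),
                     error = function(e) NULL)
      if (is.null(ba)) { n_failed <- n_failed + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_i = ids[i], sample_j = ids[j],
        mean_difference = ba$mean_difference, sd_difference = ba$sd_difference,
        p_value = ba$p_value, significant = ba$p_value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no pair could be compared")
  tab <- do.call(rbind, rows)
  list(percent_disagreement = 100 * mean(tab$significant),
       table = tab, n_failed = n_failed)
}
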