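#' The six reserved reaction ids
#'
#' Reactions that extraction must never delete in the human-model analysis
#' and which the toy network aliases: the biomass reaction, the cytosolic
#' ATP demand, glyceraldehyde-3-phosphate dehydrogenase (glycolytic flux
#' marker), mitochondrial ATP synthase (oxidative flux marker), the lactate
#' transporter and the oxygen transporter.
#'
#' @return character vector of length 6.
#' @export
reserved_reactions <- function() {
  c("biomass_reaction", "DM_atp_c_", "GAPD", "ATPS4mi", "D_LACt2", "O2t")
}

#' Specification for the synthetic toy model
#'
#' @param n_pathways number of peripheral nutrient pathways decorating the
#'   Warburg core (each pathway gets its own subsystem, exchange,
#'   transporter and a 2-3 step conversion chain feeding pyruvate).
#' @param include_warburg_core when `TRUE` (default) the oxygen exchange is
#'   capped so that maximizing biomass forces overflow metabolism: both
#'   oxidative phosphorylation and lactate secretion are used at the
#'   optimum.  When `FALSE` oxygen is unconstrained and the optimum is
#'   purely oxidative.
#' @param subsystem_labels labels given to the peripheral pathways
#'   (recycled if fewer than `n_pathways`).
#' @param seed integer seed controlling GPR structure assignment.
#' @return A list of class `toy_model_spec`.
#' @export
toy_model_spec <- function(n_pathways = 8, include_warburg_core = TRUE,
                           subsystem_labels = c(
                             "pentose phosphate pathway", "fatty acid synthesis",
                             "peptide metabolism", "vitamin A metabolism",
                             "nucleotide interconversion", "fatty acid oxidation",
                             "glutathione metabolism", "cholesterol metabolism",
                             "arginine and proline metabolism",
                             "glycerophospholipid metabolism"),
                           seed = 1L) {
  stopifnot(n_pathways >= 1)
  structure(list(n_pathways = n_pathways,
                 include_warburg_core = include_warburg_core,
                 subsystem_labels = rep_len(subsystem_labels, n_pathways),
                 seed = as.integer(seed)),
            class = "toy_model_spec")
}

# run code under a local RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build the synthetic Warburg toy model
#'
#' A small flux-consistent metabolic network that can produce ATP both
#' glycolytically (glucose to lactate, secreted) and oxidatively (pyruvate
#' oxidation driving an ATP synthase that consumes oxygen), feeding one
#' biomass reaction.  Oxygen uptake is capped (when
#' `include_warburg_core`), so the biomass optimum saturates both routes:
#' the glycolytic marker GAPD and the synthase ATPS4mi both carry flux and
#' lactate is secreted while oxygen is taken up -- the flux-sign structure
#' of overflow (Warburg) metabolism.  Peripheral nutrient pathways (one
#' subsystem each) contribute ATP so that their presence or absence in an
#' extracted submodel shifts the optimal flux state.  Every enzymatic
#' reaction carries a GPR over a synthetic gene universe with AND
#' (complex) and OR (isozyme) structure.  Construction is deterministic
#' given `spec$seed`, and the result is verified flux-consistent (an error
#' is thrown otherwise).
#'
#' @param spec a [toy_model_spec()].
#' @return A [metabolic_model()] carrying an attribute
#'   `pathway_subsystems` (character vector of the peripheral subsystems).
#' @export
make_toy_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  rxn <- list()
  gene_counter <- 0L

  add <- function(id, mets, lb, ub, subsystem, gpr = NA_character_) {
    rxn[[length(rxn) + 1L]] <<- list(id = id, mets = mets, lb = lb, ub = ub,
                                     subsystem = subsystem, gpr = gpr)
  }
  next_genes <- function(k) {
    out <- sprintf("g%04d", gene_counter + seq_len(k))
    gene_counter <<- gene_counter + k
    out
  }
  # deterministic GPR shapes cycling complex/isozyme/single structure
  make_gpr <- function(shape) {
    switch(shape,
           single = next_genes(1),
           iso = paste(next_genes(2), collapse = " or "),
           cplx = paste(next_genes(2), collapse = " and "),
           mix = { g <- next_genes(3)
                   paste0(g[1], " and (", g[2], " or ", g[3], ")") })
  }

  o2_cap <- if (spec$include_warburg_core) -5 else -200

  add("EX_glc_e", c(glc_e = -1), -10, 200, "exchange/demand")
  add("GLCt", c(glc_e = -1, glc_c = 1), 0, 200, "transport, extracellular", make_gpr("iso"))
  add("HEX1", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1), 0, 200,
      "glycolysis", make_gpr("mix"))
  add("GAPD", c(g6p_c = -1, nad_c = -2, adp_c = -3, pyr_c = 2, nadh_c = 2, atp_c = 3),
      0, 200, "glycolysis", make_gpr("cplx"))
  add("LDH_L", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1), 0, 200,
      "glycolysis", make_gpr("iso"))
  add("D_LACt2", c(lac_e = -1, lac_c = 1), -200, 200, "transport, extracellular",
      make_gpr("single"))
  add("EX_lac_e", c(lac_e = -1), 0, 200, "exchange/demand")
  add("PDHm", c(pyr_c = -1, nad_c = -1, accoa_c = 1, nadh_c = 1), 0, 200,
      "citric acid cycle", make_gpr("cplx"))
  add("CSm", c(accoa_c = -1, nad_c = -3, adp_c = -1, nadh_c = 3, atp_c = 1), 0, 200,
      "citric acid cycle", make_gpr("mix"))
  add("ATPS4mi", c(nadh_c = -2, o2_c = -1, adp_c = -5, nad_c = 2, atp_c = 5), 0, 200,
      "oxidative phosphorylation", make_gpr("cplx"))
  add("O2t", c(o2_e = -1, o2_c = 1), -200, 200, "transport, extracellular",
      make_gpr("single"))
  add("EX_o2_e", c(o2_e = -1), o2_cap, 200, "exchange/demand")
  add("DM_atp_c_", c(atp_c = -1, adp_c = 1), 1, 200, "exchange/demand")
  add("biomass_reaction",
      c(g6p_c = -0.2, pyr_c = -0.3, accoa_c = -0.3, atp_c = -20, adp_c = 20, bm_c = 1),
      0, 200, "biomass")
  add("EX_biomass", c(bm_c = -1), 0, 200, "exchange/demand")

  with_seed(spec$seed, {
    shapes <- c("single", "iso", "cplx", "mix")
    for (p in seq_len(spec$n_pathways)) {
      sub_e <- sprintf("sub%d_e", p); sub_c <- sprintf("sub%d_c", p)
      lab <- spec$subsystem_labels[p]
      # heterogeneous pathway economics: uptake caps and ATP yields differ,
      # so which pathways an extracted model retains shifts its flux state
      # asymmetrically (not just by permutation)
      cap <- 3 + (p %% 4)
      yield <- 1 + (p %% 3)
      # the dedicated uptake and transporter belong to the pathway unit and
      # carry its subsystem label, so a planted pathway difference is
      # attributable to one subsystem
      add(sprintf("EX_sub%d_e", p), setNames(-1, sub_e), -cap, 200, lab)
      add(sprintf("SUB%dt", p), setNames(c(-1, 1), c(sub_e, sub_c)), 0, 200,
          lab, make_gpr(sample(shapes, 1)))
      len <- sample(1:2, 1)  # internal chain length before the ATP-yielding step
      prev <- sub_c
      for (s in seq_len(len)) {
        nxt <- sprintf("int%d_%d_c", p, s)
        add(sprintf("P%dR%d", p, s), setNames(c(-1, 1), c(prev, nxt)), 0, 200,
            lab, make_gpr(sample(shapes, 1)))
        prev <- nxt
      }
      # terminal step: substrate-level phosphorylation feeding pyruvate
      add(sprintf("P%dR%d", p, len + 1L),
          setNames(c(-1, -yield, -1, 1, yield, 1),
                   c(prev, "adp_c", "nad_c", "pyr_c", "atp_c", "nadh_c")),
          0, 200, lab, make_gpr(sample(shapes, 1)))
    }
  })

  df <- data.frame(
    reaction_id = vapply(rxn, `[[`, character(1), "id"),
    lower_bound = vapply(rxn, `[[`, numeric(1), "lb"),
    upper_bound = vapply(rxn, `[[`, numeric(1), "ub"),
    subsystem = vapply(rxn, `[[`, character(1), "subsystem"),
    stringsAsFactors = FALSE)
  model <- metabolic_model("warburg_toy", df, lapply(rxn, `[[`, "mets"),
                           gpr = vapply(rxn, `[[`, character(1), "gpr"),
                           objective = "biomass_reaction")
  attr(model, "pathway_subsystems") <- unique(spec$subsystem_labels)

  sol <- fba(model, parsimonious = FALSE)
  if (sol$status != "optimal" || sol$objective_value <= 0) {
    stop("toy model construction failed: biomass optimum not positive")
  }
  cr <- fastcc(model)
  if (length(cr$removed_reactions)) {
    stop("toy model construction failed: blocked reactions ",
         paste(cr$removed_reactions, collapse = ", "))
  }
  model
}

#' Pick a synthetic hallmark gene list from a toy model
#'
#' Deterministically samples genes across the model's GPRs to serve as the
#' hallmark-of-cancer gene set analogue in desk-scale runs.
#'
#' @param model a toy [metabolic_model()].
#' @param n number of genes.
#' @param seed RNG seed.
#' @return character vector of gene ids.
#' @export
toy_hallmark_genes <- function(model, n = 30, seed = 1L) {
  with_seed(seed, sort(sample(model$genes, min(n, length(model$genes)))))
}

#' Simulate a flux matrix with planted group structure
#'
#' Generates the "FBA-based feature" matrix directly at the flux level:
#' every sample is the model's parsimonious FBA flux vector plus iid
#' Gaussian measurement noise, and each group shifts the flux of a small
#' set of planted reactions (all within one subsystem) by a
#' group-specific offset.  This is the calibrated input for studying
#' [pca_cluster()] and [rf_importance()]: with `effect = 0` the matrix is
#' isotropic noise with no cluster structure; with a positive effect the
#' planted reactions are exactly the discriminative features.
#'
#' @param model a [metabolic_model()] (supplies flux scale, reaction
#'   names and subsystems).
#' @param n_groups,n_per_group group structure.
#' @param planted_subsystem subsystem holding the planted reactions;
#'   default: the model's first peripheral pathway subsystem.
#' @param n_planted number of planted reactions.
#' @param effect per-group flux offset step (group g is shifted by
#'   `effect * (g - 1)` on every planted reaction).
#' @param noise_sd iid Gaussian noise added to every entry.
#' @param seed RNG seed.
#' @return list with `matrix` (samples x reactions), `labels` (named
#'   group vector), `planted_reactions`, `planted_subsystem`.
#' @export
simulate_flux_matrix <- function(model, n_groups = 4, n_per_group = 8,
                                 planted_subsystem = NULL, n_planted = 5,
                                 effect = 1, noise_sd = 0.2, seed = 1L) {
  rid <- reaction_ids(model)
  planted_subsystem <- planted_subsystem %||%
    attr(model, "pathway_subsystems")[1] %||% model$reactions$subsystem[1]
  cand <- rid[model$reactions$subsystem == planted_subsystem]
  if (!length(cand)) stop("no reaction in subsystem: ", planted_subsystem)
  planted <- head(cand, n_planted)
  base <- fba(model)$flux
  with_seed(seed, {
    n <- n_groups * n_per_group
    fm <- matrix(rep(base, each = n), n, length(rid),
                 dimnames = list(sprintf("s%03d", seq_len(n)), rid))
    labels <- setNames(rep(sprintf("group%d", seq_len(n_groups)),
                           each = n_per_group), rownames(fm))
    for (g in seq_len(n_groups)) {
      rows <- which(labels == sprintf("group%d", g))
      fm[rows, planted] <- fm[rows, planted] + effect * (g - 1)
    }
    fm <- fm + matrix(rnorm(length(fm), 0, noise_sd), nrow(fm))
    list(matrix = fm, labels = labels, planted_reactions = planted,
         planted_subsystem = planted_subsystem)
  })
}

#' Simulation design for synthetic expression datasets
#'
#' Defines the generating conditions for a simulated gene-by-sample
#' expression matrix: group structure (cancer types), replication, platform
#' coverage and planted pathway effects.  Platform emulation is reduced to
#' gene-level coverage (proteome profiles cover markedly fewer genes) plus
#' replicate noise.
#'
#' @param n_groups number of planted groups (cancer types).
#' @param n_samples_per_group samples per group.
#' @param n_replicates technical replicates per sample (averaged during
#'   preprocessing).
#' @param platform `"rnaseq"`, `"microarray"` or `"proteome"`.
#' @param planted_subsystems optional list, one element per group, each a
#'   data frame with columns `subsystem`, `direction` (`"up"`/`"down"`).
#'   Default: group 1 is the reference; each later group up-regulates one
#'   distinct peripheral pathway and down-regulates another.
#' @param effect_size multiplicative fold change applied to genes of
#'   planted subsystems.
#' @param noise_sd standard deviation of additive replicate noise (on the
#'   expression scale; baseline expression is log-normal with median
#'   `exp(2)`).
#' @param missing_fraction fraction of genes unmeasured by the platform;
#'   default 0.05 (rnaseq), 0.10 (microarray), 0.40 (proteome).
#' @param seed RNG seed.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_groups = 4, n_samples_per_group = 5,
                              n_replicates = 2,
                              platform = c("rnaseq", "microarray", "proteome"),
                              planted_subsystems = NULL,
                              effect_size = 4, noise_sd = 0.5,
                              missing_fraction = NULL, seed = 1L) {
  platform <- match.arg(platform)
  if (is.null(missing_fraction)) {
    missing_fraction <- switch(platform, rnaseq = 0.05, microarray = 0.10,
                               proteome = 0.40)
  }
  if (missing_fraction >= 1) stop("missing_fraction must be < 1")
  stopifnot(missing_fraction >= 0, effect_size > 0, noise_sd >= 0)
  structure(list(n_groups = n_groups,
                 n_samples_per_group = n_samples_per_group,
                 n_replicates = n_replicates, platform = platform,
                 planted_subsystems = planted_subsystems,
                 effect_size = effect_size, noise_sd = noise_sd,
                 missing_fraction = missing_fraction, seed = as.integer(seed)),
            class = "simulation_design")
}

# default planted design: group 1 is the reference; each later group
# silences (down-regulates) one distinct peripheral pathway, the cleanest
# knockout-like contrast a planted-difference simulation can make
default_planting <- function(model, n_groups) {
  paths <- attr(model, "pathway_subsystems")
  if (is.null(paths)) paths <- setdiff(unique(model$reactions$subsystem),
                                       c("exchange/demand", "biomass"))
  planted <- vector("list", n_groups)
  planted[[1]] <- data.frame(subsystem = character(0), direction = character(0),
                             stringsAsFactors = FALSE)
  for (g in seq_len(n_groups - 1L)) {
    dn <- paths[((g - 1L) %% length(paths)) + 1L]
    planted[[g + 1L]] <- data.frame(subsystem = dn, direction = "down",
                                    stringsAsFactors = FALSE)
  }
  planted
}

# genes referenced by GPRs of reactions in the given subsystems
subsystem_genes <- function(model, subsystems) {
  jj <- which(model$reactions$subsystem %in% subsystems)
  unique(unlist(lapply(model$gpr[jj], gpr_genes)))
}

#' Simulate a multi-sample expression dataset over a toy model
#'
#' Baseline per-gene expression is log-normal; genes whose GPRs touch a
#' group's planted subsystems are shifted multiplicatively by the group
#' effect; each replicate adds independent Gaussian noise (truncated at 0);
#' platform coverage removes a fixed gene subset for the whole dataset.
#' The planted ground truth (group labels, planted subsystems, genes and
#' reactions) is returned alongside the matrix.
#'
#' @param model a [metabolic_model()] from [make_toy_model()].
#' @param design a [simulation_design()].
#' @return A list with `matrix` (gene x replicate-column matrix, `NA` for
#'   unmeasured genes), `replicate_groups` (column to sample map),
#'   `group_labels` (sample to group map) and `ground_truth` (planted
#'   effects, genes, reactions and the design).
#' @export
simulate_expression <- function(model, design = simulation_design()) {
  stopifnot(inherits(design, "simulation_design"))
  planted <- design$planted_subsystems %||% default_planting(model, design$n_groups)
  if (length(planted) != design$n_groups) {
    stop("planted_subsystems must have one element per group")
  }
  all_sub <- unique(model$reactions$subsystem)
  for (p in planted) {
    if (nrow(p) && !all(p$subsystem %in% all_sub)) {
      stop("planted subsystem(s) not in model: ",
           paste(setdiff(p$subsystem, all_sub), collapse = ", "))
    }
  }
  genes <- model$genes
  with_seed(design$seed, {
    base <- setNames(rlnorm(length(genes), meanlog = 2, sdlog = 0.6), genes)
    unmeasured_by_sample <- list()

    cols <- list()
    rep_groups <- character(0)
    grp_labels <- character(0)
    planted_genes <- character(0)
    for (g in seq_len(design$n_groups)) {
      mu <- base
      pg <- planted[[g]]
      if (nrow(pg)) {
        for (t in seq_len(nrow(pg))) {
          gg <- subsystem_genes(model, pg$subsystem[t])
          mu[gg] <- mu[gg] * if (pg$direction[t] == "up") design$effect_size
                             else 1 / design$effect_size
          planted_genes <- union(planted_genes, gg)
        }
      }
      for (i in seq_len(design$n_samples_per_group)) {
        sid <- sprintf("grp%d_s%02d", g, i)
        grp_labels[sid] <- sprintf("group%d", g)
        # detection failure is drawn per sample: platforms with poor
        # coverage (proteomics) therefore vary between samples, not just
        # in how many genes they see
        unmeasured <- if (design$missing_fraction > 0) {
          sample(genes, round(design$missing_fraction * length(genes)))
        } else character(0)
        unmeasured_by_sample[[sid]] <- sort(unmeasured)
        for (r in seq_len(design$n_replicates)) {
          cid <- sprintf("%s_r%d", sid, r)
          v <- pmax(mu + rnorm(length(mu), 0, design$noise_sd), 0)
          v[unmeasured] <- NA_real_
          cols[[cid]] <- v
          rep_groups[cid] <- sid
        }
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- genes

    planted_sub <- unique(unlist(lapply(planted, function(p) p$subsystem)))
    planted_rxn <- reaction_ids(model)[model$reactions$subsystem %in% planted_sub]
    list(matrix = mat,
         replicate_groups = rep_groups,
         group_labels = grp_labels,
         ground_truth = list(planted = planted,
                             planted_subsystems = planted_sub,
                             planted_genes = sort(planted_genes),
                             planted_reactions = planted_rxn,
                             unmeasured_genes = unmeasured_by_sample,
                             design = design))
  })
}
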