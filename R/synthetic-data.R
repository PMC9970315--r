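#' Configure a synthetic interaction-database simulation
#'
#' Describes a miniature heterogeneous regulatory network: one or more
#' planted source-to-target paths embedded among decoy genes, transcription
#' factors (TFs) and miRNAs, with a protein-protein interaction (PPI) layer,
#' a TF-to-miRNA regulation layer, and per-tool miRNA-target prediction
#' tables. [gen_interaction_db()] realises the configuration.
#'
#' Node types along a planted path are fixed by the `mirnas` and `tfs`
#' declarations (everything else is a gene), and each consecutive pair must
#' be a legal edge: gene/TF to gene/TF pairs become undirected PPI edges,
#' TF to miRNA becomes a directed regulation edge, and miRNA to gene becomes
#' a predicted-target edge. Any other transition (for example miRNA to
#' miRNA) is rejected with a message naming the offending edge.
#'
#' Decoy edges are constrained so that their head (the node an arc points
#' into) is always a decoy node; undirected decoy PPI edges are drawn only
#' among decoy genes and the declared source nodes. As a consequence no
#' decoy edge can create a new, or shorter, source-to-target path: every
#' source-to-target path in the generated network is a concatenation of
#' planted edges.
#'
#' @param planted_paths list of character vectors; each is a node-id
#'   sequence starting at a declared source and ending at a declared target,
#'   with at least one edge and no repeated nodes.
#' @param mirnas,tfs character vectors naming which planted node ids are
#'   miRNAs / transcription factors; unlisted planted ids are genes.
#' @param sources,targets designated source and target node ids; default to
#'   the first and last nodes of the planted paths.
#' @param n_decoy_genes,n_tfs,n_mirnas numbers of decoy genes, decoy TFs and
#'   decoy miRNAs to add.
#' @param ppi_edge_prob Erdos-Renyi edge probability of the decoy PPI layer.
#' @param tf_mirna_decoy_prob probability that a given (TF, decoy miRNA)
#'   pair receives a regulation edge.
#' @param tools names of the simulated target-prediction tools.
#' @param p_tool per-tool probability of emitting a true miRNA-target pair.
#' @param p_decoy per-tool probability of emitting a decoy pair.
#' @param min_tools minimum number of tools guaranteed to emit each true
#'   pair (enforced by resampling), so the downstream consensus vote at the
#'   same threshold always retains planted targets.
#' @param seed integer seed fixing all randomness.
#' @return A `network_sim_config` object (a validated list).
#' @seealso [gen_interaction_db()]
#' @export
network_sim_config <- function(planted_paths,
                               mirnas = character(),
                               tfs = character(),
                               sources = NULL,
                               targets = NULL,
                               n_decoy_genes = 20,
                               n_tfs = 2,
                               n_mirnas = 2,
                               ppi_edge_prob = 0.1,
                               tf_mirna_decoy_prob = 0.2,
                               tools = c("DIANA", "Miranda", "PicTar",
                                         "TargetScan", "miRDB"),
                               p_tool = 0.8,
                               p_decoy = 0.1,
                               min_tools = 3,
                               seed = 1L) {
  if (!is.list(planted_paths) || length(planted_paths) == 0L) {
    abort("`planted_paths` must be a non-empty list of node-id sequences")
  }
  planted_paths <- lapply(planted_paths, as.character)
  for (p in planted_paths) {
    if (length(p) < 2L) abort("every planted path needs at least one edge")
    if (anyDuplicated(p)) abort("planted paths must have distinct nodes")
  }
  sources <- sources %||% unique(vapply(planted_paths, `[`, "", 1L))
  targets <- targets %||% unique(vapply(planted_paths, function(p) p[length(p)], ""))
  for (p in planted_paths) {
    if (!p[1L] %in% sources || !p[length(p)] %in% targets) {
      abort("every planted path must start at a source and end at a target")
    }
  }
  if (length(intersect(sources, targets)) > 0L) {
    abort("source and target sets must be disjoint")
  }
  cfg <- list(
    planted_paths = planted_paths,
    mirnas = as.character(mirnas),
    tfs = as.character(tfs),
    sources = as.character(sources),
    targets = as.character(targets),
    n_decoy_genes = assert_scalar_count(n_decoy_genes, "n_decoy_genes"),
    n_tfs = assert_scalar_count(n_tfs, "n_tfs"),
    n_mirnas = assert_scalar_count(n_mirnas, "n_mirnas"),
    ppi_edge_prob = assert_prob(ppi_edge_prob, "ppi_edge_prob"),
    tf_mirna_decoy_prob = assert_prob(tf_mirna_decoy_prob, "tf_mirna_decoy_prob"),
    tools = as.character(tools),
    p_tool = assert_prob(p_tool, "p_tool"),
    p_decoy = assert_prob(p_decoy, "p_decoy"),
    min_tools = assert_scalar_count(min_tools, "min_tools", min = 1L),
    seed = assert_seed(seed)
  )
  if (cfg$min_tools > length(cfg$tools)) {
    abort("`min_tools` cannot exceed the number of tools")
  }
  # type every planted edge now so invalid transitions fail fast
  planted_node_type(cfg)
  planted_edges(cfg)
  structure(cfg, class = "network_sim_config")
}

planted_node_type <- function(cfg) {
  ids <- unique(unlist(cfg$planted_paths))
  both <- intersect(cfg$mirnas, cfg$tfs)
  if (length(both) > 0L) {
    abort(sprintf("ids declared both miRNA and TF: %s",
                  paste(both, collapse = ", ")))
  }
  type <- ifelse(ids %in% cfg$mirnas, "miRNA",
                 ifelse(ids %in% cfg$tfs, "TF", "gene"))
  stats::setNames(type, ids)
}

# Classify one directed planted edge into its carrier table.
edge_layer <- function(from, to, type_of) {
  ft <- type_of[[from]]
  tt <- type_of[[to]]
  if (ft %in% c("gene", "TF") && tt %in% c("gene", "TF")) return("ppi")
  if (ft == "TF" && tt == "miRNA") return("tf_mirna")
  if (ft == "miRNA" && tt == "gene") return("mirna_target")
  abort(sprintf(
    "planted edge %s (%s) -> %s (%s) has no legal layer: allowed transitions are gene/TF-gene/TF (PPI), TF->miRNA, miRNA->gene",
    from, ft, to, tt))
}

planted_edges <- function(cfg) {
  type_of <- planted_node_type(cfg)
  out <- list()
  for (p in cfg$planted_paths) {
    for (i in seq_len(length(p) - 1L)) {
      out[[length(out) + 1L]] <-
        list(from = p[i], to = p[i + 1L],
             layer = edge_layer(p[i], p[i + 1L], type_of))
    }
  }
  out
}

#' Generate synthetic interaction databases with planted paths
#'
#' Realises a [network_sim_config()] as the three delimited tables the
#' pipeline consumes -- an undirected PPI edge list, a TF-to-miRNA
#' regulation table and one miRNA-target prediction table per tool --
#' together with the planted-path ground truth. Every planted edge lands in
#' exactly one table according to its endpoint types, and each true
#' miRNA-target pair is emitted by at least `min_tools` tools so the default
#' consensus vote always retains it.
#'
#' @param config a [network_sim_config()].
#' @return An object of class `interaction_db`: a list with elements
#'   `ppi` (tibble `protein_a`, `protein_b`), `tf_mirna` (tibble `tf`,
#'   `mirna`), `predictions` (named list of per-tool tibbles `mirna`,
#'   `gene`, `score`), `truth` (list of planted paths, each with `nodes`
#'   and `edge_types`), `nodes` (tibble `id`, `node_type`, `origin`),
#'   plus `sources`, `targets`, `tf_ids`, `mirna_ids` and the `config`.
#' @examples
#' cfg <- network_sim_config(
#'   planted_paths = list(c("TGFB1", "SMAD3", "miR-378a-3p", "CTGF")),
#'   mirnas = "miR-378a-3p", tfs = "SMAD3",
#'   n_decoy_genes = 0, n_tfs = 0, n_mirnas = 0)
#' db <- gen_interaction_db(cfg)
#' db$ppi
#' db$predictions$DIANA
#' @export
gen_interaction_db <- function(config) {
  stopifnot(inherits(config, "network_sim_config"))
  with_seed(config$seed, gen_interaction_db_impl(config))
}

gen_interaction_db_impl <- function(cfg) {
  type_of <- planted_node_type(cfg)
  pe <- planted_edges(cfg)

  decoy_genes <- sprintf("DG%03d", seq_len(cfg$n_decoy_genes))
  decoy_tfs <- sprintf("DTF%02d", seq_len(cfg$n_tfs))
  decoy_mirnas <- sprintf("dmir-%02d", seq_len(cfg$n_mirnas))

  nodes <- dplyr::bind_rows(
    tibble(id = names(type_of), node_type = unname(type_of), origin = "planted"),
    tibble(id = decoy_genes, node_type = "gene", origin = "decoy"),
    tibble(id = decoy_tfs, node_type = "TF", origin = "decoy"),
    tibble(id = decoy_mirnas, node_type = "miRNA", origin = "decoy")
  )
  if (anyDuplicated(nodes$id)) {
    abort("decoy identifier collides with a planted node id")
  }

  layer_of <- vapply(pe, `[[`, "", "layer")
  ppi <- tibble(
    protein_a = vapply(pe[layer_of == "ppi"], `[[`, "", "from"),
    protein_b = vapply(pe[layer_of == "ppi"], `[[`, "", "to")
  )
  tf_mirna <- tibble(
    tf = vapply(pe[layer_of == "tf_mirna"], `[[`, "", "from"),
    mirna = vapply(pe[layer_of == "tf_mirna"], `[[`, "", "to")
  )
  true_pairs <- tibble(
    mirna = vapply(pe[layer_of == "mirna_target"], `[[`, "", "from"),
    gene = vapply(pe[layer_of == "mirna_target"], `[[`, "", "to")
  )

  # Decoy PPI: Erdos-Renyi among decoy genes plus the source nodes (arcs into
  # a source cannot extend a simple path that starts there, so sources are
  # safe endpoints; all other planted nodes are off limits).
  ppi_pool <- c(decoy_genes,
                cfg$sources[type_of[cfg$sources] %in% c("gene", "TF")])
  if (length(ppi_pool) >= 2L && cfg$ppi_edge_prob > 0) {
    pairs <- utils::combn(lex_sort(ppi_pool), 2L)
    src_only <- matrix(pairs %in% cfg$sources, nrow = 2L)
    eligible <- !(src_only[1L, ] & src_only[2L, ])
    keep <- eligible & (stats::runif(ncol(pairs)) < cfg$ppi_edge_prob)
    ppi <- dplyr::bind_rows(ppi, tibble(protein_a = pairs[1L, keep],
                                        protein_b = pairs[2L, keep]))
  }

  # Decoy TF regulation: planted or decoy TFs may regulate decoy miRNAs.
  all_tfs <- c(names(type_of)[type_of == "TF"], decoy_tfs)
  if (length(all_tfs) > 0L && length(decoy_mirnas) > 0L) {
    grid <- expand.grid(tf = lex_sort(all_tfs), mirna = decoy_mirnas,
                        stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < cfg$tf_mirna_decoy_prob
    tf_mirna <- dplyr::bind_rows(tf_mirna, as_tibble(grid[keep, , drop = FALSE]))
  }

  # Decoy prediction pairs: any miRNA may be claimed to target a decoy gene.
  all_mirnas <- c(names(type_of)[type_of == "miRNA"], decoy_mirnas)
  decoy_pairs <- if (length(all_mirnas) > 0L && length(decoy_genes) > 0L) {
    as_tibble(expand.grid(mirna = lex_sort(all_mirnas), gene = decoy_genes,
                          stringsAsFactors = FALSE))
  } else {
    tibble(mirna = character(), gene = character())
  }

  predictions <- emit_predictions(true_pairs, decoy_pairs, cfg)

  truth <- lapply(cfg$planted_paths, function(p) {
    list(nodes = p,
         edge_types = vapply(seq_len(length(p) - 1L), function(i) {
           edge_layer(p[i], p[i + 1L], type_of)
         }, ""))
  })

  structure(list(
    ppi = dplyr::distinct(ppi),
    tf_mirna = dplyr::distinct(tf_mirna),
    predictions = predictions,
    truth = truth,
    nodes = nodes,
    sources = cfg$sources,
    targets = cfg$targets,
    tf_ids = nodes$id[nodes$node_type == "TF"],
    mirna_ids = nodes$id[nodes$node_type == "miRNA"],
    config = cfg
  ), class = "interaction_db")
}

# Per-tool emission: true pairs Bernoulli(p_tool) per tool, resampled until
# at least min_tools emit; decoy pairs Bernoulli(p_decoy) with no guarantee.
emit_predictions <- function(true_pairs, decoy_pairs, cfg) {
  n_tools <- length(cfg$tools)
  per_tool <- stats::setNames(
    replicate(n_tools, tibble(mirna = character(), gene = character()),
              simplify = FALSE),
    cfg$tools)
  add_pair <- function(tool_hits, mirna, gene) {
    for (t in cfg$tools[tool_hits]) {
      per_tool[[t]] <<- dplyr::bind_rows(per_tool[[t]],
                                         tibble(mirna = mirna, gene = gene))
    }
  }
  for (i in seq_len(nrow(true_pairs))) {
    repeat {
      hits <- stats::runif(n_tools) < cfg$p_tool
      if (sum(hits) >= cfg$min_tools) break
    }
    add_pair(hits, true_pairs$mirna[i], true_pairs$gene[i])
  }
  for (i in seq_len(nrow(decoy_pairs))) {
    hits <- stats::runif(n_tools) < cfg$p_decoy
    if (any(hits)) add_pair(hits, decoy_pairs$mirna[i], decoy_pairs$gene[i])
  }
  lapply(per_tool, function(tb) {
    tb <- dplyr::distinct(tb)
    tb$score <- if (nrow(tb) > 0) round(stats::runif(nrow(tb)), 4) else numeric()
    tb
  })
}

#' Configure a synthetic qPCR experiment
#'
#' Plants group-wise relative-expression fold changes (versus a control
#' group) for a set of genes and simulates threshold-cycle (Ct) readings
#' with Gaussian replicate noise. The expected Ct of gene `g` in group `r`
#' is `baseline_ct - log2(fold[r, g])`, so the downstream delta-delta-Ct
#' estimate recovers the planted fold exactly when `ct_noise_sd = 0`. The
#' reference gene always has fold 1 in every group.
#'
#' @param genes character vector of measured gene ids (must include
#'   `reference_gene`).
#' @param folds named list: one element per non-control group, each a named
#'   numeric vector of planted folds (fold versus control) for a subset of
#'   `genes`; unnamed genes default to fold 1. All folds must be > 0.
#' @param control_group label of the control group (planted fold 1 for all
#'   genes).
#' @param n_replicates biological replicates per group.
#' @param ct_noise_sd Gaussian Ct noise standard deviation, in cycles.
#' @param reference_gene housekeeping gene used for normalisation.
#' @param baseline_ct expected control-group Ct, in cycles (default 24,
#'   mid dynamic range).
#' @param seed integer seed.
#' @return A `qpcr_sim_config` object.
#' @seealso [gen_qpcr()], [delta_delta_ct()]
#' @export
qpcr_sim_config <- function(genes,
                            folds,
                            control_group = "control",
                            n_replicates = 6,
                            ct_noise_sd = 0.25,
                            reference_gene = "GAPDH",
                            baseline_ct = 24,
                            seed = 1L) {
  genes <- as.character(genes)
  if (!reference_gene %in% genes) {
    abort("`reference_gene` must be one of `genes`")
  }
  if (!is.list(folds) || is.null(names(folds)) || any(names(folds) == "")) {
    abort("`folds` must be a named list of per-group fold vectors")
  }
  if (control_group %in% names(folds)) {
    abort("`folds` describes non-control groups; do not list the control group")
  }
  for (grp in names(folds)) {
    f <- folds[[grp]]
    if (length(f) > 0 &&
        (is.null(names(f)) || !all(names(f) %in% genes))) {
      abort(sprintf("folds for group '%s' name genes outside `genes`", grp))
    }
    if (any(f <= 0)) abort("planted folds must be > 0")
    if (reference_gene %in% names(f) && any(f[reference_gene] != 1)) {
      abort("the reference gene must keep fold 1 in every group")
    }
  }
  n_replicates <- assert_scalar_count(n_replicates, "n_replicates", min = 1L)
  if (!is.numeric(ct_noise_sd) || ct_noise_sd < 0) {
    abort("`ct_noise_sd` must be >= 0")
  }
  structure(list(
    genes = genes, folds = folds, control_group = control_group,
    n_replicates = n_replicates, ct_noise_sd = as.numeric(ct_noise_sd),
    reference_gene = reference_gene, baseline_ct = as.numeric(baseline_ct),
    seed = assert_seed(seed)
  ), class = "qpcr_sim_config")
}

#' Generate a synthetic qPCR table
#'
#' @param config a [qpcr_sim_config()].
#' @return A tibble with columns `sample`, `group`, `gene`, `ct` (one row
#'   per replicate and gene).
#' @examples
#' cfg <- qpcr_sim_config(
#'   genes = c("TGFB1", "GAPDH"),
#'   folds = list(OM = c(TGFB1 = 0.42)),
#'   ct_noise_sd = 0, seed = 1)
#' gen_qpcr(cfg)
#' @export
gen_qpcr <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  with_seed(config$seed, {
    groups <- c(config$control_group, names(config$folds))
    rows <- lapply(groups, function(grp) {
      fold <- stats::setNames(rep(1, length(config$genes)), config$genes)
      if (grp != config$control_group) {
        f <- config$folds[[grp]]
        fold[names(f)] <- f
      }
      expected <- config$baseline_ct - log2(fold)
      lapply(seq_len(config$n_replicates), function(rep_i) {
        tibble(
          sample = sprintf("%s_%d", grp, rep_i),
          group = grp,
          gene = config$genes,
          ct = expected + stats::rnorm(length(config$genes),
                                       sd = config$ct_noise_sd)
        )
      })
    })
    dplyr::bind_rows(unlist(rows, recursive = FALSE))
  })
}

#' Configure a synthetic two-group serum cohort
#'
#' Each group is described by its size, per-biomarker mean and SD, a sex
#' ratio and an age distribution. Biomarker and age values are drawn from
#' normal distributions; `nonnegative_clip` truncates draws at zero, a
#' deliberate simplification for concentration-like variables whose printed
#' SD exceeds the mean.
#'
#' @param group_specs list of per-group specs; each is a list with elements
#'   `label`, `n` (>= 2), `biomarkers` (named list of `c(mean, sd)`),
#'   `sex_ratio` (proportion in the reported sex category), `age_mean`,
#'   `age_sd`.
#' @param sex_levels length-2 character vector: the reported category first.
#' @param nonnegative_clip clip biomarker draws at 0.
#' @param seed integer seed.
#' @return A `cohort_sim_config` object.
#' @seealso [gen_cohort()], [aac_cohort_config()]
#' @export
cohort_sim_config <- function(group_specs,
                              sex_levels = c("male", "female"),
                              nonnegative_clip = FALSE,
                              seed = 1L) {
  if (!is.list(group_specs) || length(group_specs) == 0L) {
    abort("`group_specs` must be a non-empty list")
  }
  biomarker_names <- NULL
  for (gs in group_specs) {
    for (f in c("label", "n", "biomarkers", "sex_ratio", "age_mean", "age_sd")) {
      if (is.null(gs[[f]])) abort(sprintf("group spec is missing `%s`", f))
    }
    assert_scalar_count(gs$n, "n", min = 2L)
    assert_prob(gs$sex_ratio, "sex_ratio")
    if (gs$age_sd < 0) abort("`age_sd` must be >= 0")
    for (bm in names(gs$biomarkers)) {
      v <- gs$biomarkers[[bm]]
      if (length(v) != 2L || anyNA(v)) {
        abort(sprintf("biomarker '%s' needs c(mean, sd)", bm))
      }
      if (v[2L] < 0) abort(sprintf("biomarker '%s' has SD < 0", bm))
    }
    nm <- lex_sort(names(gs$biomarkers))
    biomarker_names <- biomarker_names %||% nm
    if (!identical(nm, biomarker_names)) {
      abort("all groups must declare the same biomarkers (mean and SD each)")
    }
  }
  structure(list(
    group_specs = group_specs,
    sex_levels = as.character(sex_levels),
    nonnegative_clip = isTRUE(nonnegative_clip),
    seed = assert_seed(seed)
  ), class = "cohort_sim_config")
}

#' Default cohort configuration for the vascular-calcification study
#'
#' Two groups of community-dwelling older adults: 24 without and 11 with
#' severe aortic arch calcification (AAC), with serum TGF-B1 and CTGF in
#' ng/mL and circulating miR-378a-3p in relative units, age about 76 +/- 6
#' years and a 37% male fraction.
#'
#' @param seed integer seed.
#' @param nonnegative_clip clip biomarker draws at 0 (default TRUE:
#'   concentrations cannot be negative).
#' @return A [cohort_sim_config()].
#' @export
aac_cohort_config <- function(seed = 1L, nonnegative_clip = TRUE) {
  cohort_sim_config(
    group_specs = list(
      list(label = "non-AAC", n = 24,
           biomarkers = list(TGFB1 = c(9.62, 8.25),
                             CTGF = c(24.93, 6.39),
                             `miR-378a-3p` = c(0.55, 0.763)),
           sex_ratio = 0.371, age_mean = 75.8, age_sd = 6.0),
      list(label = "AAC", n = 11,
           biomarkers = list(TGFB1 = c(1.85, 3.36),
                             CTGF = c(19.98, 7.11),
                             `miR-378a-3p` = c(0.134, 0.207)),
           sex_ratio = 0.371, age_mean = 75.8, age_sd = 6.0)
    ),
    nonnegative_clip = nonnegative_clip,
    seed = seed
  )
}

#' Generate a synthetic cohort table
#'
#' @param config a [cohort_sim_config()].
#' @return A tibble with columns `subject`, `group`, `sex`, `age` and one
#'   column per biomarker; exactly `n` rows per group.
#' @examples
#' head(gen_cohort(aac_cohort_config(seed = 1)))
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    rows <- lapply(config$group_specs, function(gs) {
      n <- gs$n
      n_cat <- round(n * gs$sex_ratio)
      out <- tibble(
        subject = sprintf("%s_%02d", gs$label, seq_len(n)),
        group = gs$label,
        sex = c(rep(config$sex_levels[1L], n_cat),
                rep(config$sex_levels[2L], n - n_cat)),
        age = stats::rnorm(n, gs$age_mean, gs$age_sd)
      )
      for (bm in lex_sort(names(gs$biomarkers))) {
        v <- gs$biomarkers[[bm]]
        x <- stats::rnorm(n, v[1L], v[2L])
        if (config$nonnegative_clip) x <- pmax(x, 0)
        out[[bm]] <- x
      }
      out
    })
    dplyr::bind_rows(rows)
  })
}
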