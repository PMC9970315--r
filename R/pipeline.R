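#' Validate a pipeline configuration
#'
#' Checks the configuration schema without running anything: presence of a
#' seed and output directory, a legal mode, a consensus threshold within the
#' tool count, a positive depth bound, legal planted-path node transitions
#' in synthetic mode, and existing input files (plus declared sources and
#' targets) in files mode.
#'
#' @param config a configuration list, or the path of a YAML file.
#' @return Character vector of human-readable violations; empty when the
#'   configuration is valid.
#' @seealso [run_pipeline()] for the schema.
#' @export
validate_config <- function(config) {
  config <- load_config(config)
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))

  if (is.null(config$seed)) {
    say("missing `seed`")
  } else if (!is.numeric(config$seed) || config$seed != floor(config$seed)) {
    say("`seed` must be an integer")
  }
  if (is.null(config$out_dir)) say("missing `out_dir`")

  mode <- config$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "files")) {
    say("`mode` must be 'synthetic' or 'files'")
  }

  n_tools <- if (mode == "synthetic") {
    length(config$network$tools %||%
             c("DIANA", "Miranda", "PicTar", "TargetScan", "miRDB"))
  } else {
    length(config$inputs$predictions %||% character())
  }
  min_tools <- config$min_tools %||% 3
  if (!is.numeric(min_tools) || min_tools < 1) {
    say("`min_tools` must be a positive integer")
  } else if (n_tools > 0 && min_tools > n_tools) {
    say("`min_tools` (%s) exceeds the number of tools (%d)", min_tools, n_tools)
  }

  max_depth <- config$max_depth %||% 4
  if (!is.numeric(max_depth) || max_depth < 1) say("`max_depth` must be >= 1")

  if (mode == "synthetic") {
    if (is.null(config$network$planted_paths)) {
      say("synthetic mode requires `network$planted_paths`")
    } else {
      ok <- tryCatch({
        do.call(network_sim_config,
                c(synthetic_network_args(config), list(seed = 0L)))
        TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) say("invalid synthetic network: %s", ok)
    }
  } else {
    for (f in c("ppi", "tf_mirna")) {
      p <- config$inputs[[f]]
      if (is.null(p)) say("files mode requires `inputs$%s`", f)
      else if (!file.exists(p)) say("input file not found: %s", p)
    }
    preds <- config$inputs$predictions %||% character()
    if (length(preds) == 0L) say("files mode requires `inputs$predictions`")
    for (p in preds) if (!file.exists(p)) say("input file not found: %s", p)
    if (length(config$sources %||% character()) == 0L) {
      say("files mode requires a non-empty `sources` list")
    }
    if (length(config$targets %||% character()) == 0L) {
      say("files mode requires a non-empty `targets` list")
    }
  }

  if (!is.null(config$qpcr)) {
    ok <- tryCatch({
      do.call(qpcr_sim_config, c(qpcr_args(config$qpcr), list(seed = 0L)))
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) say("invalid qpcr block: %s", ok)
  }
  v
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  config
}

synthetic_network_args <- function(config) {
  nw <- config$network
  args <- list(
    planted_paths = lapply(nw$planted_paths, as.character),
    mirnas = as.character(nw$mirnas %||% character()),
    tfs = as.character(nw$tfs %||% character())
  )
  for (f in c("sources", "targets")) {
    if (!is.null(config[[f]])) args[[f]] <- as.character(config[[f]])
  }
  for (f in c("n_decoy_genes", "n_tfs", "n_mirnas", "ppi_edge_prob",
              "tf_mirna_decoy_prob", "tools", "p_tool", "p_decoy")) {
    if (!is.null(nw[[f]])) args[[f]] <- nw[[f]]
  }
  args$min_tools <- config$min_tools %||% 3
  args
}

qpcr_args <- function(q) {
  args <- list(
    genes = as.character(q$genes),
    folds = lapply(q$folds, function(f) unlist(f))
  )
  for (f in c("control_group", "n_replicates", "ct_noise_sd",
              "reference_gene", "baseline_ct")) {
    if (!is.null(q[[f]])) args[[f]] <- q[[f]]
  }
  args
}

#' Run the full regulatory-path discovery pipeline
#'
#' Orchestrates generate/load, consensus voting, network integration, path
#' search and the expression/cohort statistics, writing every stage output
#' plus a run manifest under `out_dir`. Identical configuration and seed
#' give identical outputs (the manifest records an md5 checksum per file;
#' only the timestamp differs between reruns).
#'
#' The configuration (YAML file or list) understands:
#' \describe{
#'   \item{`seed`, `out_dir`}{run seed and output directory (required).}
#'   \item{`mode`}{`"synthetic"` (default) or `"files"`.}
#'   \item{`min_tools`, `max_depth`, `edge_types`}{consensus threshold
#'     (default 3), search depth bound (default 4), optional edge-type
#'     filter.}
#'   \item{`network`}{synthetic mode: arguments of [network_sim_config()]
#'     (`planted_paths`, `mirnas`, `tfs`, decoy counts, probabilities).}
#'   \item{`inputs`}{files mode: `ppi`, `tf_mirna`, `predictions` (list of
#'     per-tool files), optional `tools`; identifiers are matched case
#'     insensitively.}
#'   \item{`sources`, `targets`, `tf_ids`}{role declarations; synthetic
#'     mode infers them from the planted paths.}
#'   \item{`qpcr`}{optional: arguments of [qpcr_sim_config()]; every
#'     planted gene/group is then quantified by [delta_delta_ct()].}
#'   \item{`cohort`}{optional: `default: true` for the bundled two-group
#'     serum cohort ([aac_cohort_config()]); per-biomarker pooled t-tests
#'     are run between the two groups.}
#' }
#'
#' @param config configuration list or YAML path.
#' @param out_dir optional override of `config$out_dir`.
#' @return Invisibly, a list with the `manifest` plus the in-memory stage
#'   results (`db` or loaded inputs, `consensus`, `network`, `paths` table,
#'   `stats`).
#' @examples
#' cfg_path <- system.file("extdata", "demo-config.yaml", package = "regpath")
#' res <- run_pipeline(cfg_path, out_dir = tempfile("demo"))
#' res$paths
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- load_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  violations <- validate_config(config)
  if (length(violations) > 0L) {
    abort(paste0("pipeline stage 'config' failed:\n  ",
                 paste(violations, collapse = "\n  ")))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  mode <- config$mode %||% "synthetic"
  counts <- list()

  # --- stage: inputs (simulate or load) -------------------------------
  db <- NULL
  inp <- stage(if (mode == "synthetic") "simulate" else "load", {
    if (mode == "synthetic") {
      cfg <- do.call(network_sim_config,
                     c(synthetic_network_args(config), list(seed = seed)))
      db <- gen_interaction_db(cfg)
      readr::write_tsv(db$ppi, file.path(out_dir, "ppi.tsv"), progress = FALSE)
      readr::write_tsv(db$tf_mirna, file.path(out_dir, "tf_mirna.tsv"),
                       progress = FALSE)
      for (tool in names(db$predictions)) {
        readr::write_tsv(db$predictions[[tool]],
                         file.path(out_dir, sprintf("predictions_%s.tsv", tool)),
                         progress = FALSE)
      }
      jsonlite::write_json(db$truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(ppi = db$ppi, tf_mirna = db$tf_mirna,
           records = predictions_to_records(db$predictions),
           sources = db$sources, targets = db$targets, tf_ids = db$tf_ids)
    } else {
      preds <- as.character(config$inputs$predictions)
      tools <- as.character(config$inputs$tools %||%
                              tools::file_path_sans_ext(basename(preds)))
      records <- load_predictions(preds, tools)
      ppi <- readr::read_tsv(config$inputs$ppi, show_col_types = FALSE,
                             progress = FALSE)
      tfm <- readr::read_tsv(config$inputs$tf_mirna, show_col_types = FALSE,
                             progress = FALSE)
      # identifiers are matched case-insensitively across all layers
      ppi[[1L]] <- tolower(as.character(ppi[[1L]]))
      ppi[[2L]] <- tolower(as.character(ppi[[2L]]))
      tfm[[1L]] <- tolower(as.character(tfm[[1L]]))
      tfm[[2L]] <- tolower(as.character(tfm[[2L]]))
      list(ppi = ppi, tf_mirna = tfm, records = records,
           sources = tolower(as.character(config$sources)),
           targets = tolower(as.character(config$targets)),
           tf_ids = tolower(as.character(config$tf_ids %||% character())))
    }
  })
  counts$prediction_records <- nrow(inp$records)

  # --- stage: consensus ------------------------------------------------
  consensus <- stage("consensus", {
    cs <- consensus_targets(inp$records, min_tools = config$min_tools %||% 3)
    write_consensus(cs, file.path(out_dir, "consensus.tsv"),
                    file.path(out_dir, "consensus_summary.json"))
    cs
  })
  counts$consensus_pairs <- nrow(consensus)

  # --- stage: build ----------------------------------------------------
  net <- stage("build", {
    n <- build_network(inp$ppi, inp$tf_mirna, consensus,
                       sources = inp$sources, targets = inp$targets,
                       tf_ids = inp$tf_ids)
    report <- validate_network(n)
    if (nrow(report) > 0L) {
      abort(paste("built network violates invariants:",
                  paste(report$violation, report$detail, collapse = "; ")))
    }
    # conservation: directed edges = 2 * PPI pairs + TF rows + consensus rows
    expected <- 2L * n_unique_undirected(inp$ppi) +
      nrow(dplyr::distinct(inp$tf_mirna)) + nrow(consensus)
    if (nrow(n$edges) != expected) {
      warn(sprintf("edge-count conservation check: %d directed edges, expected %d",
                   nrow(n$edges), expected))
    }
    write_network(n, out_dir)
    n
  })
  counts$nodes <- nrow(net$nodes)
  counts$edges <- nrow(net$edges)

  # --- stage: search ---------------------------------------------------
  paths_tab <- stage("search", {
    scfg <- search_config(max_depth = config$max_depth %||% 4,
                          edge_types = config$edge_types)
    all_paths <- list()
    for (s in net$source_ids) {
      tree <- build_search_tree(net, s, scfg)
      writeLines(format(tree),
                 file.path(out_dir, sprintf("search_tree_%s.txt", s)))
      write_search_tree_json(tree,
                             file.path(out_dir, sprintf("search_tree_%s.json", s)))
      for (t in net$target_ids) {
        all_paths <- c(all_paths, enumerate_paths(net, s, t, scfg))
      }
    }
    tab <- paths_to_table(all_paths)
    readr::write_csv(tab, file.path(out_dir, "paths.csv"), progress = FALSE)
    tab
  })
  counts$paths <- nrow(paths_tab)

  # --- stage: stats ----------------------------------------------------
  stats_out <- list()
  if (!is.null(config$qpcr)) {
    stats_out$qpcr <- stage("stats", {
      qcfg <- do.call(qpcr_sim_config,
                      c(qpcr_args(config$qpcr), list(seed = seed + 1L)))
      qpcr <- gen_qpcr(qcfg)
      readr::write_csv(qpcr, file.path(out_dir, "qpcr.csv"), progress = FALSE)
      rows <- list()
      for (grp in names(qcfg$folds)) {
        for (g in setdiff(names(qcfg$folds[[grp]]), qcfg$reference_gene)) {
          fc <- delta_delta_ct(qpcr, g, qcfg$reference_gene,
                               treated = grp, control = qcfg$control_group)
          rows[[length(rows) + 1L]] <- tibble(
            gene = g, treated = grp, control = qcfg$control_group,
            delta_delta_ct = fc$delta_delta_ct,
            fold_change = fc$fold_change,
            percent_suppression = percent_suppression(fc$fold_change),
            percent_change = fc$percent_change)
        }
      }
      dplyr::bind_rows(rows)
    })
  }
  if (isTRUE(config$cohort$default)) {
    stats_out$cohort <- stage("stats", {
      cohort <- gen_cohort(aac_cohort_config(seed = seed + 2L))
      readr::write_csv(cohort, file.path(out_dir, "cohort.csv"),
                       progress = FALSE)
      cs <- cohort_summary(cohort)
      groups <- names(cs$group_n)
      tests <- list()
      if (length(groups) == 2L) {
        bms <- setdiff(unique(cs$stats$variable), "age")
        for (bm in bms) {
          tt <- pooled_t_test(cohort[[bm]][cohort$group == groups[1L]],
                              cohort[[bm]][cohort$group == groups[2L]])
          tests[[bm]] <- list(t = tt$t, df = tt$df, p = round(tt$p, 3))
        }
      }
      list(n_total = cs$n_total, sex_count = cs$sex_count,
           sex_percent = cs$sex_percent, group_n = as.list(cs$group_n),
           t_tests = tests)
    })
  }
  if (length(stats_out) > 0L) {
    jsonlite::write_json(
      stats_out, file.path(out_dir, "stats.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  }

  # --- manifest --------------------------------------------------------
  files <- lex_sort(setdiff(list.files(out_dir, recursive = TRUE),
                            "manifest.json"))
  manifest <- list(
    config = config,
    mode = mode,
    seed = seed,
    counts = counts,
    files = lapply(stats::setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }),
    versions = list(package = as.character(utils::packageVersion("regpath")),
                    r = R.version.string),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inform(sprintf(
    "pipeline done: %d prediction records -> %d consensus pairs -> %d nodes / %d edges -> %d paths",
    counts$prediction_records, counts$consensus_pairs, counts$nodes,
    counts$edges, counts$paths))
  invisible(list(manifest = manifest, db = db, inputs = inp,
                 consensus = consensus, network = net, paths = paths_tab,
                 stats = stats_out, out_dir = out_dir))
}

n_unique_undirected <- function(ppi) {
  if (is.null(ppi) || nrow(ppi) == 0L) return(0L)
  a <- as.character(ppi[[1L]])
  b <- as.character(ppi[[2L]])
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  length(unique(paste(lo, hi, sep = "\u0001")))
}
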