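#' Build the integrated miRNA-gene-TF regulatory network
#'
#' Merges three edge layers into one typed directed multigraph: undirected
#' protein-protein interactions (each pair materialised as two directed
#' arcs, so a single traversal engine serves all layers), directed
#' TF-to-miRNA regulation, and directed miRNA-to-target edges from a
#' consensus vote.
#'
#' Node types are inferred: ids appearing in the miRNA column of the TF
#' table or the consensus are miRNAs; ids in the TF column or in `tf_ids`
#' are TFs; everything else is a gene. A declared TF keeps the single type
#' TF even when it also occurs in the PPI layer. Source/target status is a
#' role overlay, not a type, because a path source such as TGF-B1 is
#' simultaneously an ordinary gene node. An id used with contradictory
#' types (for example as both a miRNA and a PPI protein) is rejected.
#' Self-loops are dropped with a warning.
#'
#' @param ppi data frame of undirected PPI pairs; first two columns are the
#'   interacting identifiers.
#' @param tf_mirna data frame with columns `tf`, `mirna` (or its first two
#'   columns in that order).
#' @param consensus a [consensus_targets()] result, or any data frame with
#'   columns `mirna`, `gene`.
#' @param sources,targets node ids to mark with the source / target role;
#'   added as isolated gene nodes when absent from every edge layer.
#' @param tf_ids ids to force to node type TF.
#' @return An object of class `reg_network`: a list with `nodes` (tibble
#'   `id`, `node_type`, `role`), `edges` (tibble `from`, `to`, `edge_type`,
#'   `provenance`, deduplicated on from/to/type), `source_ids`,
#'   `target_ids`.
#' @examples
#' net <- build_network(
#'   ppi = data.frame(a = "TGFB1", b = "SMAD3"),
#'   tf_mirna = data.frame(tf = "SMAD3", mirna = "miR-378a-3p"),
#'   consensus = data.frame(mirna = "miR-378a-3p", gene = "CTGF"),
#'   sources = "TGFB1", targets = "CTGF", tf_ids = "SMAD3")
#' net
#' @export
build_network <- function(ppi = NULL, tf_mirna = NULL, consensus = NULL,
                          sources, targets, tf_ids = character()) {
  sources <- as.character(sources)
  targets <- as.character(targets)
  if (length(sources) == 0L || length(targets) == 0L) {
    abort("`sources` and `targets` must be non-empty")
  }
  both <- intersect(sources, targets)
  if (length(both) > 0L) {
    abort(sprintf("id(s) declared both source and target: %s",
                  paste(both, collapse = ", ")))
  }

  ppi <- normalize_two_cols(ppi, c("protein_a", "protein_b"))
  tf_mirna <- normalize_two_cols(tf_mirna, c("tf", "mirna"))
  consensus <- if (is.null(consensus)) {
    tibble(mirna = character(), gene = character())
  } else {
    tb <- as_tibble(consensus)
    if (!all(c("mirna", "gene") %in% names(tb))) {
      abort("`consensus` must have columns mirna, gene")
    }
    tb[, c("mirna", "gene")]
  }

  loops <- ppi$protein_a == ppi$protein_b
  if (any(loops)) {
    warn(sprintf("dropping %d PPI self-loop(s)", sum(loops)))
    ppi <- ppi[!loops, ]
  }
  # canonical undirected orientation, then dedup
  swap <- ppi$protein_a > ppi$protein_b
  tmp <- ppi$protein_a[swap]
  ppi$protein_a[swap] <- ppi$protein_b[swap]
  ppi$protein_b[swap] <- tmp
  ppi <- dplyr::distinct(ppi)
  tf_mirna <- dplyr::distinct(tf_mirna)
  consensus <- dplyr::distinct(consensus)

  mirna_ids <- unique(c(tf_mirna$mirna, consensus$mirna))
  tf_set <- unique(c(tf_mirna$tf, as.character(tf_ids)))
  ppi_ids <- unique(c(ppi$protein_a, ppi$protein_b))

  conflict <- c(
    intersect(mirna_ids, tf_set),
    intersect(mirna_ids, ppi_ids),
    intersect(mirna_ids, consensus$gene)
  )
  if (length(conflict) > 0L) {
    abort(sprintf("id(s) used with contradictory node types: %s",
                  paste(unique(conflict), collapse = ", ")))
  }

  ids <- unique(c(ppi_ids, tf_mirna$tf, mirna_ids, consensus$gene,
                  sources, targets))
  node_type <- ifelse(ids %in% mirna_ids, "miRNA",
                      ifelse(ids %in% tf_set, "TF", "gene"))
  role <- ifelse(ids %in% sources, "source",
                 ifelse(ids %in% targets, "target", "none"))
  nodes <- tibble(id = ids, node_type = node_type, role = role)
  nodes <- nodes[lex_order(nodes$id), ]

  edges <- dplyr::bind_rows(
    tibble(from = ppi$protein_a, to = ppi$protein_b,
           edge_type = "ppi", provenance = "ppi"),
    tibble(from = ppi$protein_b, to = ppi$protein_a,
           edge_type = "ppi", provenance = "ppi"),
    tibble(from = tf_mirna$tf, to = tf_mirna$mirna,
           edge_type = "tf_mirna", provenance = "tf_mirna"),
    tibble(from = consensus$mirna, to = consensus$gene,
           edge_type = "mirna_target", provenance = "consensus")
  )
  edges <- dplyr::distinct(edges, .data$from, .data$to, .data$edge_type,
                           .keep_all = TRUE)
  edges <- edges[lex_order(edges$from, edges$to, edges$edge_type), ]

  net <- structure(list(nodes = nodes, edges = edges,
                        source_ids = sources, target_ids = targets),
                   class = "reg_network")
  counts <- table(factor(edges$edge_type,
                         levels = c("ppi", "tf_mirna", "mirna_target")))
  inform(sprintf(
    "network: %d nodes (%d miRNA, %d TF, %d gene); %d directed edges (%d ppi, %d tf_mirna, %d mirna_target)",
    nrow(nodes), sum(node_type == "miRNA"), sum(node_type == "TF"),
    sum(node_type == "gene"), nrow(edges),
    counts[["ppi"]], counts[["tf_mirna"]], counts[["mirna_target"]]))
  net
}

normalize_two_cols <- function(x, names_out) {
  if (is.null(x) || nrow(as.data.frame(x)) == 0L) {
    return(stats::setNames(tibble(a = character(), b = character()), names_out))
  }
  x <- as_tibble(x)
  if (all(names_out %in% names(x))) x <- x[, names_out] else x <- x[, 1:2]
  names(x) <- names_out
  x[[1L]] <- as.character(x[[1L]])
  x[[2L]] <- as.character(x[[2L]])
  x
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("<reg_network> %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat("  node types:",
      paste(sprintf("%s=%d", names(table(x$nodes$node_type)),
                    table(x$nodes$node_type)), collapse = " "), "\n")
  cat("  edge types:",
      paste(sprintf("%s=%d", names(table(x$edges$edge_type)),
                    table(x$edges$edge_type)), collapse = " "), "\n")
  cat("  sources:", paste(x$source_ids, collapse = ", "),
      "| targets:", paste(x$target_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Check the structural invariants of a regulatory network
#'
#' Report-only validation: dangling edge endpoints, duplicate node ids or
#' edges, self-loops, illegal edge directions for the typed layers
#' (TF-to-miRNA edges must run TF to miRNA, miRNA-target edges miRNA to
#' gene, PPI arcs must connect gene/TF nodes), and missing source/target
#' declarations. The network is never mutated.
#'
#' @param net a `reg_network`.
#' @return A tibble with columns `violation` and `detail`; zero rows when
#'   the network is valid.
#' @export
validate_network <- function(net) {
  v <- list()
  add <- function(violation, detail) {
    v[[length(v) + 1L]] <<- tibble(violation = violation, detail = detail)
  }
  nodes <- net$nodes
  edges <- net$edges
  dup_nodes <- nodes$id[duplicated(nodes$id)]
  for (id in unique(dup_nodes)) add("duplicate_node", id)
  dangling <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  for (id in dangling) add("dangling_endpoint", id)
  loops <- edges$from == edges$to
  for (i in which(loops)) {
    add("self_loop", sprintf("%s->%s [%s]", edges$from[i], edges$to[i],
                             edges$edge_type[i]))
  }
  key <- paste(edges$from, edges$to, edges$edge_type)
  for (k in unique(key[duplicated(key)])) add("duplicate_edge", k)
  type_of <- stats::setNames(nodes$node_type, nodes$id)
  bad_type <- !edges$edge_type %in% c("ppi", "tf_mirna", "mirna_target")
  for (i in which(bad_type)) add("unknown_edge_type", edges$edge_type[i])
  ok_ends <- !(edges$from %in% dangling) & !(edges$to %in% dangling)
  for (i in which(ok_ends & edges$edge_type == "tf_mirna")) {
    if (type_of[[edges$from[i]]] != "TF" || type_of[[edges$to[i]]] != "miRNA") {
      add("bad_tf_mirna_direction",
          sprintf("%s(%s)->%s(%s)", edges$from[i], type_of[[edges$from[i]]],
                  edges$to[i], type_of[[edges$to[i]]]))
    }
  }
  for (i in which(ok_ends & edges$edge_type == "mirna_target")) {
    if (type_of[[edges$from[i]]] != "miRNA" || type_of[[edges$to[i]]] != "gene") {
      add("bad_mirna_target_direction",
          sprintf("%s(%s)->%s(%s)", edges$from[i], type_of[[edges$from[i]]],
                  edges$to[i], type_of[[edges$to[i]]]))
    }
  }
  for (i in which(ok_ends & edges$edge_type == "ppi")) {
    if (!type_of[[edges$from[i]]] %in% c("gene", "TF") ||
        !type_of[[edges$to[i]]] %in% c("gene", "TF")) {
      add("bad_ppi_endpoint",
          sprintf("%s(%s)-%s(%s)", edges$from[i], type_of[[edges$from[i]]],
                  edges$to[i], type_of[[edges$to[i]]]))
    }
  }
  for (id in setdiff(c(net$source_ids, net$target_ids), nodes$id)) {
    add("missing_source_or_target", id)
  }
  if (length(v) == 0L) {
    tibble(violation = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Convert a regulatory network to an igraph object
#'
#' Node and edge type attributes (`node_type`, `role`, `edge_type`,
#' `provenance`) are carried over; the result is a directed igraph graph
#' suitable for export or independent analysis.
#'
#' @param net a `reg_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Write a regulatory network to disk
#'
#' Writes the node and edge tables as TSV, plus GraphML and SIF exports
#' with `node_type` / `edge_type` attributes.
#'
#' @param net a `reg_network`.
#' @param dir output directory (created if needed).
#' @param basename file stem for the exports.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_network <- function(net, dir, basename = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    nodes = file.path(dir, paste0(basename, "_nodes.tsv")),
    edges = file.path(dir, paste0(basename, "_edges.tsv")),
    graphml = file.path(dir, paste0(basename, ".graphml")),
    sif = file.path(dir, paste0(basename, ".sif"))
  )
  readr::write_tsv(net$nodes, paths[["nodes"]], progress = FALSE)
  readr::write_tsv(net$edges, paths[["edges"]], progress = FALSE)
  igraph::write_graph(as_igraph(net), paths[["graphml"]], format = "graphml")
  writeLines(sprintf("%s\t%s\t%s", net$edges$from, net$edges$edge_type,
                     net$edges$to), paths[["sif"]])
  invisible(paths)
}

#' Read a regulatory network from node/edge TSV files
#'
#' @param nodes_path,edges_path TSV files as written by [write_network()].
#' @param sources,targets optional role declarations; default to the roles
#'   stored in the node table.
#' @return A `reg_network`.
#' @export
read_network <- function(nodes_path, edges_path,
                         sources = NULL, targets = NULL) {
  nodes <- readr::read_tsv(nodes_path, show_col_types = FALSE, progress = FALSE)
  edges <- readr::read_tsv(edges_path, show_col_types = FALSE, progress = FALSE)
  sources <- sources %||% nodes$id[nodes$role == "source"]
  targets <- targets %||% nodes$id[nodes$role == "target"]
  structure(list(nodes = as_tibble(nodes), edges = as_tibble(edges),
                 source_ids = as.character(sources),
                 target_ids = as.character(targets)),
            class = "reg_network")
}
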