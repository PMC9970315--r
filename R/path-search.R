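#' Configure the depth-first path search
#'
#' @param max_depth maximum number of edges per path (default 4: source and
#'   target plus one to three mediator layers).
#' @param edge_types optional subset of `c("ppi", "tf_mirna",
#'   "mirna_target")` to traverse; `NULL` traverses all layers.
#' @return A `search_config` object.
#' @export
search_config <- function(max_depth = 4, edge_types = NULL) {
  max_depth <- assert_scalar_count(max_depth, "max_depth", min = 1L)
  if (!is.null(edge_types)) {
    edge_types <- as.character(edge_types)
    bad <- setdiff(edge_types, c("ppi", "tf_mirna", "mirna_target"))
    if (length(bad) > 0L) {
      abort(sprintf("unknown edge type(s): %s", paste(bad, collapse = ", ")))
    }
  }
  structure(list(max_depth = max_depth, edge_types = edge_types),
            class = "search_config")
}

# Adjacency list keyed by node id; children sorted lexicographically by
# (to, edge_type) so every traversal is reproducible across platforms.
adjacency <- function(net, config) {
  edges <- net$edges
  if (!is.null(config$edge_types)) {
    edges <- edges[edges$edge_type %in% config$edge_types, ]
  }
  edges <- edges[lex_order(edges$from, edges$to, edges$edge_type), ]
  split(edges[, c("to", "edge_type")], factor(edges$from, levels = unique(edges$from)))
}

check_node <- function(net, id, what) {
  if (!id %in% net$nodes$id) {
    abort(sprintf("unknown %s node id: %s", what, id))
  }
}

#' Nodes reachable from a source within a depth bound
#'
#' Returns every node whose shortest directed distance from `source` is at
#' most `max_depth` edges (the source itself included), honouring the edge
#' type filter. Equivalent to the depth-truncated transitive closure row of
#' the source.
#'
#' @param net a `reg_network`.
#' @param source source node id.
#' @param config a [search_config()].
#' @return Character vector of reachable node ids, lexicographically sorted.
#' @export
reachable_nodes <- function(net, source, config = search_config()) {
  check_node(net, source, "source")
  adj <- adjacency(net, config)
  seen <- stats::setNames(TRUE, source)
  frontier <- source
  for (d in seq_len(config$max_depth)) {
    nxt <- character()
    for (v in frontier) {
      kids <- adj[[v]]
      if (!is.null(kids)) nxt <- c(nxt, kids$to)
    }
    nxt <- unique(nxt)
    nxt <- nxt[is.na(seen[nxt])]
    if (length(nxt) == 0L) break
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  lex_sort(names(seen))
}

#' Enumerate all simple source-to-target paths
#'
#' Depth-first enumeration of every simple directed path (no repeated
#' nodes) from `source` to `target` with at most `max_depth` edges. Each
#' path is reported exactly once; results are ordered by depth, then
#' lexicographically by node sequence. `source == target` returns an empty
#' list: the analysis concerns mediators between distinct molecules.
#'
#' @param net a `reg_network`.
#' @param source,target node ids.
#' @param config a [search_config()].
#' @return A list of `path_result` objects, each a list with `nodes`
#'   (ordered id vector), `edge_types` (one per edge) and `depth`
#'   (edge count).
#' @examples
#' net <- build_network(
#'   ppi = data.frame(a = "TGFB1", b = "SMAD3"),
#'   tf_mirna = data.frame(tf = "SMAD3", mirna = "miR-378a-3p"),
#'   consensus = data.frame(mirna = "miR-378a-3p", gene = "CTGF"),
#'   sources = "TGFB1", targets = "CTGF", tf_ids = "SMAD3")
#' enumerate_paths(net, "TGFB1", "CTGF")
#' @export
enumerate_paths <- function(net, source, target, config = search_config()) {
  check_node(net, source, "source")
  check_node(net, target, "target")
  if (identical(source, target)) return(list())
  adj <- adjacency(net, config)
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 64L)
  acc$n <- 0L
  on_path <- stats::setNames(TRUE, source)

  recurse <- function(node, nodes, types, depth) {
    if (depth >= config$max_depth) return(invisible())
    kids <- adj[[node]]
    if (is.null(kids) || nrow(kids) == 0L) return(invisible())
    for (i in seq_len(nrow(kids))) {
      child <- kids$to[i]
      if (identical(child, target)) {
        acc$n <- acc$n + 1L
        if (acc$n > length(acc$paths)) length(acc$paths) <- 2L * acc$n
        acc$paths[[acc$n]] <- structure(
          list(nodes = c(nodes, child),
               edge_types = c(types, kids$edge_type[i]),
               depth = depth + 1L),
          class = "path_result")
      } else if (is.na(on_path[child])) {
        on_path[child] <<- TRUE
        recurse(child, c(nodes, child), c(types, kids$edge_type[i]), depth + 1L)
        on_path[child] <<- NA
      }
    }
    invisible()
  }
  # depth 0 frame; target hits at depth >= 1
  recurse_guard <- function() {
    # allow paths up to max_depth edges: the recursion above tests
    # depth >= max_depth before expanding, so a hit at depth + 1 is in bound
    recurse(source, source, character(), 0L)
  }
  recurse_guard()
  paths <- acc$paths[seq_len(acc$n)]
  if (length(paths) == 0L) return(list())
  depth <- vapply(paths, `[[`, 0L, "depth")
  key <- vapply(paths, function(p) chain_key(p$nodes), "")
  paths[lex_order(depth, key)]
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("<path depth=%d> %s\n", x$depth, paste(x$nodes, collapse = " -> ")))
  cat("  edge types:", paste(x$edge_types, collapse = ", "), "\n")
  invisible(x)
}

#' Build the hierarchical DFS search tree from a source
#'
#' Expands every simple branch from the source up to `max_depth` edges,
#' children in lexicographic order. A node id may appear in several
#' branches but never twice on one root-to-leaf branch. Flattening the
#' branches that end at a target reproduces [enumerate_paths()] exactly.
#'
#' @param net a `reg_network`.
#' @param source source node id.
#' @param config a [search_config()].
#' @return A `search_tree`: a nested list of nodes, each with `id`, `depth`,
#'   `edge_type` (edge from its parent; `NA` at the root) and `children`.
#' @export
build_search_tree <- function(net, source, config = search_config()) {
  check_node(net, source, "source")
  adj <- adjacency(net, config)
  grow <- function(node, depth, edge_type, on_branch) {
    out <- list(id = node, depth = depth, edge_type = edge_type,
                children = list())
    if (depth < config$max_depth) {
      kids <- adj[[node]]
      if (!is.null(kids) && nrow(kids) > 0L) {
        for (i in seq_len(nrow(kids))) {
          child <- kids$to[i]
          if (!child %in% on_branch) {
            out$children[[length(out$children) + 1L]] <-
              grow(child, depth + 1L, kids$edge_type[i], c(on_branch, child))
          }
        }
      }
    }
    out
  }
  structure(grow(source, 0L, NA_character_, source),
            class = "search_tree", config = config)
}

#' Flatten the branches of a search tree that end at target nodes
#'
#' @param tree a [build_search_tree()] result.
#' @param targets character vector of target ids.
#' @return A list of `path_result` objects ordered by (depth, node
#'   sequence), identical to the corresponding [enumerate_paths()] output.
#' @export
flatten_tree_paths <- function(tree, targets) {
  acc <- list()
  walk <- function(node, nodes, types) {
    if (node$depth > 0L) {
      nodes <- c(nodes, node$id)
      types <- c(types, node$edge_type)
      if (node$id %in% targets) {
        acc[[length(acc) + 1L]] <<- structure(
          list(nodes = nodes, edge_types = types, depth = node$depth),
          class = "path_result")
      }
    } else {
      nodes <- node$id
      types <- character()
    }
    for (ch in node$children) walk(ch, nodes, types)
  }
  walk(tree, character(), character())
  acc <- acc[!vapply(acc, function(p) p$nodes[1L] %in% targets &&
                       length(p$nodes) == 1L, TRUE)]
  if (length(acc) == 0L) return(list())
  depth <- vapply(acc, `[[`, 0L, "depth")
  key <- vapply(acc, function(p) chain_key(p$nodes), "")
  acc[lex_order(depth, key)]
}

#' Render a search tree as indented text
#'
#' @param x a `search_tree`.
#' @param ... unused.
#' @return Character vector of lines, invisibly (also printed).
#' @export
format.search_tree <- function(x, ...) {
  lines <- character()
  walk <- function(node) {
    label <- if (is.na(node$edge_type)) node$id
             else sprintf("%s [%s]", node$id, node$edge_type)
    lines[[length(lines) + 1L]] <<- paste0(strrep("  ", node$depth), label)
    for (ch in node$children) walk(ch)
  }
  walk(x)
  unlist(lines)
}

#' @export
print.search_tree <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}

#' Export a search tree as JSON
#'
#' @param tree a `search_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_search_tree_json <- function(tree, path) {
  strip <- function(node) {
    list(id = node$id, depth = node$depth,
         edge_type = if (is.na(node$edge_type)) NULL else node$edge_type,
         children = lapply(node$children, strip))
  }
  jsonlite::write_json(strip(tree), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Tabulate path results
#'
#' One row per path: source, target, depth, the node chain joined with
#' `->` and the edge-type chain joined with `->`. [table_to_paths()] is the
#' lossless inverse (node ids must not contain the literal `->`).
#'
#' @param paths list of `path_result` objects.
#' @return A tibble with columns `source`, `target`, `depth`, `nodes`,
#'   `edge_types`.
#' @export
paths_to_table <- function(paths) {
  if (length(paths) == 0L) {
    return(tibble(source = character(), target = character(),
                  depth = integer(), nodes = character(),
                  edge_types = character()))
  }
  tibble(
    source = vapply(paths, function(p) p$nodes[1L], ""),
    target = vapply(paths, function(p) p$nodes[length(p$nodes)], ""),
    depth = vapply(paths, `[[`, 0L, "depth"),
    nodes = vapply(paths, function(p) paste(p$nodes, collapse = "->"), ""),
    edge_types = vapply(paths, function(p) paste(p$edge_types, collapse = "->"), "")
  )
}

#' @rdname paths_to_table
#' @param tab a table produced by [paths_to_table()].
#' @export
table_to_paths <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    structure(list(
      nodes = strsplit(tab$nodes[i], "->", fixed = TRUE)[[1L]],
      edge_types = if (nzchar(tab$edge_types[i])) {
        strsplit(tab$edge_types[i], "->", fixed = TRUE)[[1L]]
      } else character(),
      depth = as.integer(tab$depth[i])
    ), class = "path_result")
  })
}
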