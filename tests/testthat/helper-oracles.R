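# Independent oracles and fixture builders shared across test files.

# Minimal reg_network built directly from an edge table (bypasses
# build_network on purpose, so the search engine is tested on arbitrary
# digraphs, cyclic ones included).
raw_network <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  structure(list(
    nodes = tibble::tibble(id = nodes, node_type = "gene", role = "none"),
    edges = tibble::tibble(from = edges$from, to = edges$to,
                           edge_type = if ("edge_type" %in% names(edges))
                             edges$edge_type else "ppi",
                           provenance = "test"),
    source_ids = character(), target_ids = character()
  ), class = "reg_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random digraph on n nodes with independent arcs at probability p.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  grid <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  keep <- runif(nrow(grid)) < p
  edges <- grid[keep, ]
  types <- c("ppi", "tf_mirna", "mirna_target")
  edges$edge_type <- sample(types, nrow(edges), replace = TRUE)
  raw_network(edges, nodes = ids)
}

# Brute-force simple-path oracle: every permutation of <= max_depth - 1
# intermediate nodes between source and target, kept when each consecutive
# pair is an arc. Independent of the DFS implementation.
permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

brute_force_paths <- function(net, source, target, max_depth,
                              edge_types = NULL) {
  edges <- net$edges
  if (!is.null(edge_types)) edges <- edges[edges$edge_type %in% edge_types, ]
  arc <- paste(edges$from, edges$to)
  others <- setdiff(net$nodes$id, c(source, target))
  found <- character()
  for (k in 0:(max_depth - 1L)) {
    if (k > length(others)) break
    subsets <- if (k == 0L) list(character()) else
      utils::combn(others, k, simplify = FALSE)
    for (sub in subsets) {
      for (perm in permutations_of(sub)) {
        seq_ <- c(source, perm, target)
        pairs <- paste(seq_[-length(seq_)], seq_[-1L])
        if (all(pairs %in% arc)) {
          found <- c(found, paste(seq_, collapse = "->"))
        }
      }
    }
  }
  sort(found)
}

# Depth-truncated transitive closure by boolean adjacency-matrix powers.
matrix_power_reachable <- function(net, source, max_depth,
                                   edge_types = NULL) {
  ids <- net$nodes$id
  edges <- net$edges
  if (!is.null(edge_types)) edges <- edges[edges$edge_type %in% edge_types, ]
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  A[cbind(edges$from, edges$to)] <- TRUE
  reach <- stats::setNames(ids == source, ids)
  step <- reach
  for (d in seq_len(max_depth)) {
    step <- stats::setNames(as.logical(step %*% A), ids)
    new <- step & !reach
    if (!any(new)) break
    reach <- reach | step
  }
  sort(ids[reach])
}

# Exhaustive tool-vote oracle for the consensus rule.
vote_count_oracle <- function(records, min_tools) {
  pairs <- unique(records[, c("mirna", "gene")])
  keep <- list()
  for (i in seq_len(nrow(pairs))) {
    sub <- records[records$mirna == pairs$mirna[i] &
                     records$gene == pairs$gene[i], ]
    votes <- length(unique(sub$tool))
    if (votes >= min_tools) {
      keep[[length(keep) + 1L]] <-
        tibble::tibble(mirna = pairs$mirna[i], gene = pairs$gene[i],
                       vote_count = votes)
    }
  }
  out <- dplyr::bind_rows(keep)
  if (nrow(out) == 0L) {
    return(tibble::tibble(mirna = character(), gene = character(),
                          vote_count = integer()))
  }
  out[order(out$mirna, out$gene, method = "radix"), ]
}

# Random 5-tool prediction fixture over a miRNA x gene universe.
random_predictions <- function(n_mirnas, n_genes, p, seed,
                               tools = c("A", "B", "C", "D", "E")) {
  set.seed(seed)
  grid <- expand.grid(
    tool = tools,
    mirna = sprintf("mir-%d", seq_len(n_mirnas)),
    gene = sprintf("g%d", seq_len(n_genes)),
    stringsAsFactors = FALSE)
  tibble::as_tibble(grid[runif(nrow(grid)) < p, ])
}

path_chains <- function(paths) {
  vapply(paths, function(p) paste(p$nodes, collapse = "->"), "")
}

demo_config_path <- function() {
  system.file("extdata", "demo-config.yaml", package = "regpath")
}
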