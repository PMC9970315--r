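edges_net <- function(...) {
  pairs <- list(...)
  raw_network(tibble::tibble(
    from = vapply(pairs, `[`, "", 1),
    to = vapply(pairs, `[`, "", 2),
    edge_type = vapply(pairs, function(p) if (length(p) > 2) p[3] else "ppi", "")))
}

test_that("reachable_nodes respects the depth bound and isolates", {
  net <- edges_net(c("S", "A"), c("A", "B"))
  iso <- raw_network(tibble::tibble(from = "S", to = "A"),
                     nodes = c("S", "A", "Z"))
  expect_equal(reachable_nodes(net, "S", search_config(max_depth = 1)),
               c("A", "S"))
  expect_equal(reachable_nodes(net, "S", search_config(max_depth = 2)),
               c("A", "B", "S"))
  expect_equal(reachable_nodes(iso, "Z"), "Z")
  expect_error(reachable_nodes(net, "nope"), "unknown source")
})

test_that("simple two-route fixture enumerates in (depth, lexicographic) order", {
  net <- edges_net(c("S", "A"), c("A", "T"), c("S", "T"))
  paths <- enumerate_paths(net, "S", "T", search_config(max_depth = 3))
  expect_equal(path_chains(paths), c("S->T", "S->A->T"))
  expect_equal(vapply(paths, `[[`, 0L, "depth"), c(1L, 2L))
})

test_that("cycles terminate and unreachable targets give empty results", {
  net <- edges_net(c("S", "A"), c("A", "B"), c("B", "A")) # T unreachable
  net$nodes <- rbind(net$nodes,
                     tibble::tibble(id = "T", node_type = "gene", role = "none"))
  expect_equal(enumerate_paths(net, "S", "T", search_config(max_depth = 8)),
               list())
  expect_equal(enumerate_paths(net, "S", "S"), list())
  expect_error(enumerate_paths(net, "S", "nope"), "unknown target")
})

test_that("edge_type filters restrict traversal", {
  net <- edges_net(c("S", "A", "ppi"), c("A", "T", "tf_mirna"),
                   c("S", "T", "mirna_target"))
  all_paths <- enumerate_paths(net, "S", "T", search_config(max_depth = 3))
  expect_equal(length(all_paths), 2)
  no_direct <- enumerate_paths(net, "S", "T",
                               search_config(max_depth = 3,
                                             edge_types = c("ppi", "tf_mirna")))
  expect_equal(path_chains(no_direct), "S->A->T")
  expect_equal(no_direct[[1]]$edge_types, c("ppi", "tf_mirna"))
  expect_error(search_config(edge_types = "wat"), "unknown edge type")
})

test_that("enumeration matches the permutation brute force and igraph", {
  for (seed in 1:25) {
    n <- sample(4:8, 1)
    net <- random_digraph(n, p = 0.3, seed = seed)
    ids <- net$nodes$id
    st <- sample(ids, 2)
    d <- sample(2:4, 1)
    got <- path_chains(enumerate_paths(net, st[1], st[2],
                                       search_config(max_depth = d)))
    expect_equal(sort(got), brute_force_paths(net, st[1], st[2], d))

    g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                       vertices = ids)
    ig <- igraph::all_simple_paths(g, st[1], st[2], mode = "out", cutoff = d)
    ig <- vapply(ig, function(p) paste(names(p), collapse = "->"), "")
    expect_setequal(got, ig)
  }
})

test_that("reachability equals the boolean matrix-power oracle", {
  for (seed in 1:25) {
    net <- random_digraph(sample(4:10, 1), p = 0.3, seed = 100 + seed)
    src <- sample(net$nodes$id, 1)
    d <- sample(1:4, 1)
    expect_equal(reachable_nodes(net, src, search_config(max_depth = d)),
                 matrix_power_reachable(net, src, d))
  }
})

test_that("results are invariant to input edge order", {
  net <- random_digraph(8, p = 0.35, seed = 9)
  shuf <- net
  set.seed(1)
  shuf$edges <- shuf$edges[sample(nrow(shuf$edges)), ]
  cfg <- search_config(max_depth = 4)
  expect_identical(enumerate_paths(net, "n01", "n05", cfg),
                   enumerate_paths(shuf, "n01", "n05", cfg))
  expect_identical(reachable_nodes(net, "n01", cfg),
                   reachable_nodes(shuf, "n01", cfg))
})

test_that("the search tree is lexicographic, branch-simple, and flattens to the path set", {
  star <- edges_net(c("S", "C"), c("S", "A"), c("S", "B"))
  tree <- build_search_tree(star, "S", search_config(max_depth = 1))
  expect_equal(vapply(tree$children, `[[`, "", "id"), c("A", "B", "C"))

  diamond <- edges_net(c("S", "A"), c("A", "T"), c("S", "B"), c("B", "T"))
  tree <- build_search_tree(diamond, "S", search_config(max_depth = 2))
  flat <- flatten_tree_paths(tree, "T")
  expect_equal(path_chains(flat), c("S->A->T", "S->B->T"))

  for (seed in 1:10) {
    net <- random_digraph(7, p = 0.35, seed = 200 + seed)
    cfg <- search_config(max_depth = 4)
    tree <- build_search_tree(net, "n01", cfg)
    # no node repeats along any root-to-leaf branch
    check_branch <- function(node, seen) {
      expect_false(node$id %in% seen)
      for (ch in node$children) check_branch(ch, c(seen, node$id))
    }
    check_branch(tree, character())
    expect_identical(flatten_tree_paths(tree, "n06"),
                     enumerate_paths(net, "n01", "n06", cfg))
  }
})

test_that("search trees export to indented text and JSON", {
  net <- edges_net(c("S", "A"), c("A", "T"))
  tree <- build_search_tree(net, "S", search_config(max_depth = 2))
  txt <- format(tree)
  expect_equal(txt[1], "S")
  expect_match(txt[2], "^  A")
  expect_match(txt[3], "^    T")
  path <- withr::local_tempfile(fileext = ".json")
  write_search_tree_json(tree, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$id, "S")
  expect_equal(js$children[[1]]$id, "A")
})

test_that("paths_to_table round-trips losslessly", {
  expect_equal(nrow(paths_to_table(list())), 0)
  net <- random_digraph(8, p = 0.4, seed = 77)
  paths <- enumerate_paths(net, "n01", "n04", search_config(max_depth = 4))
  expect_gt(length(paths), 0)
  tab <- paths_to_table(paths)
  expect_identical(table_to_paths(tab), paths)
  expect_true(all(tab$source == "n01" & tab$target == "n04"))
})
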