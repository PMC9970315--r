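tiny_net <- function() {
  suppressMessages(build_network(
    ppi = tibble::tibble(a = c("TGFB1", "TGFB1", "GLI3"),
                         b = c("SMAD3", "GLI3", "SMAD3")),
    tf_mirna = tibble::tibble(tf = c("SMAD3", "SMAD3"),
                              mirna = c("miR-378a-3p", "mir-22")),
    consensus = tibble::tibble(mirna = c("miR-378a-3p", "miR-378a-3p"),
                               gene = c("CTGF", "GLI3")),
    sources = "TGFB1", targets = "CTGF", tf_ids = "SMAD3"))
}

test_that("undirected PPI pairs become two directed arcs, deduplicated", {
  net <- suppressMessages(build_network(
    ppi = tibble::tibble(a = c("A", "B"), b = c("B", "A")),
    sources = "A", targets = "B"))
  ppi_edges <- net$edges[net$edges$edge_type == "ppi", ]
  expect_equal(nrow(ppi_edges), 2)
  expect_setequal(paste(ppi_edges$from, ppi_edges$to), c("A B", "B A"))
})

test_that("a hand-enumerable fixture yields the expected nodes and edges", {
  net <- tiny_net()
  # 3 PPI pairs -> 6 arcs, 2 TF rows, 2 consensus targets = 10 edges;
  # nodes: TGFB1, SMAD3, GLI3, miR-378a-3p, mir-22, CTGF
  expect_equal(nrow(net$edges), 10)
  expect_equal(nrow(net$nodes), 6)
  expect_equal(sum(net$edges$edge_type == "ppi"), 6)
  expect_equal(sum(net$edges$edge_type == "tf_mirna"), 2)
  expect_equal(sum(net$edges$edge_type == "mirna_target"), 2)
  type <- setNames(net$nodes$node_type, net$nodes$id)
  expect_equal(type[["SMAD3"]], "TF")
  expect_equal(type[["miR-378a-3p"]], "miRNA")
  expect_equal(type[["TGFB1"]], "gene")
  role <- setNames(net$nodes$role, net$nodes$id)
  expect_equal(role[["TGFB1"]], "source")
  expect_equal(role[["CTGF"]], "target")
})

test_that("edge count conservation holds on random fixtures", {
  for (seed in 1:6) {
    set.seed(seed)
    genes <- sprintf("g%d", 1:8)
    ppi <- tibble::tibble(a = sample(genes, 12, TRUE),
                          b = sample(genes, 12, TRUE))
    ppi <- ppi[ppi$a != ppi$b, ]
    tfm <- tibble::tibble(tf = sample(c("tf1", "tf2"), 4, TRUE),
                          mirna = sample(c("m1", "m2"), 4, TRUE))
    cs <- tibble::tibble(mirna = sample(c("m1", "m2"), 5, TRUE),
                         gene = sample(genes, 5, TRUE))
    net <- suppressMessages(build_network(ppi, tfm, cs, sources = "g1",
                                          targets = "g2"))
    canon <- unique(paste(pmin(ppi$a, ppi$b), pmax(ppi$a, ppi$b)))
    expected <- 2 * length(canon) + nrow(unique(tfm)) + nrow(unique(cs))
    expect_equal(nrow(net$edges), expected)
  }
})

test_that("rebuilding from shuffled input rows gives an identical network", {
  net1 <- tiny_net()
  ppi <- tibble::tibble(a = c("GLI3", "TGFB1", "TGFB1"),
                        b = c("SMAD3", "GLI3", "SMAD3"))
  net2 <- suppressMessages(build_network(
    ppi,
    tf_mirna = tibble::tibble(tf = c("SMAD3", "SMAD3"),
                              mirna = c("mir-22", "miR-378a-3p")),
    consensus = tibble::tibble(mirna = c("miR-378a-3p", "miR-378a-3p"),
                               gene = c("GLI3", "CTGF")),
    sources = "TGFB1", targets = "CTGF", tf_ids = "SMAD3"))
  expect_identical(net1$nodes, net2$nodes)
  expect_identical(net1$edges, net2$edges)
})

test_that("contradictory node types and source/target overlap are rejected", {
  expect_error(suppressMessages(build_network(
    ppi = tibble::tibble(a = "m1", b = "B"),
    consensus = tibble::tibble(mirna = "m1", gene = "g"),
    sources = "B", targets = "g")), "contradictory.*m1")
  expect_error(suppressMessages(build_network(
    ppi = tibble::tibble(a = "A", b = "B"),
    sources = "A", targets = "A")), "both source and target")
})

test_that("self-loops are dropped with a warning", {
  expect_warning(
    net <- suppressMessages(build_network(
      ppi = tibble::tibble(a = c("A", "B"), b = c("A", "B2")),
      sources = "A", targets = "B2")),
    "self-loop")
  expect_false(any(net$edges$from == net$edges$to))
})

test_that("validate_network reports violations without mutating the network", {
  net <- tiny_net()
  expect_equal(nrow(validate_network(net)), 0)

  broken <- net
  broken$edges <- rbind(broken$edges,
                        tibble::tibble(from = "GHOST", to = "CTGF",
                                       edge_type = "ppi", provenance = "x"))
  report <- validate_network(broken)
  expect_true("dangling_endpoint" %in% report$violation)

  looped <- net
  looped$edges$to[1] <- looped$edges$from[1]
  report <- validate_network(looped)
  expect_true("self_loop" %in% report$violation)
  expect_match(report$detail[report$violation == "self_loop"][1],
               looped$edges$from[1])

  baddir <- net
  i <- which(net$edges$edge_type == "tf_mirna")[1]
  baddir$edges$from[i] <- "TGFB1" # a gene, not a TF
  report <- validate_network(baddir)
  expect_true("bad_tf_mirna_direction" %in% report$violation)
})

test_that("network TSV / GraphML / SIF exports round-trip and carry types", {
  dir <- withr::local_tempdir()
  net <- tiny_net()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(paths)))
  back <- read_network(paths[["nodes"]], paths[["edges"]])
  expect_equal(as.data.frame(back$nodes), as.data.frame(net$nodes))
  expect_equal(as.data.frame(back$edges), as.data.frame(net$edges))
  expect_setequal(back$source_ids, net$source_ids)

  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_setequal(unique(igraph::E(g)$edge_type), unique(net$edges$edge_type))

  sif <- read.delim(paths[["sif"]], header = FALSE)
  expect_equal(nrow(sif), nrow(net$edges))
  expect_setequal(unique(sif$V2), unique(net$edges$edge_type))
})
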