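one_path_cfg <- function(...) {
  network_sim_config(
    planted_paths = list(c("S", "TF1", "mir-a", "T")),
    mirnas = "mir-a", tfs = "TF1",
    n_decoy_genes = 0, n_tfs = 0, n_mirnas = 0, ...)
}

test_that("a zero-decoy database contains exactly the planted edges", {
  db <- gen_interaction_db(one_path_cfg(seed = 1))
  expect_equal(db$ppi, tibble::tibble(protein_a = "S", protein_b = "TF1"))
  expect_equal(db$tf_mirna, tibble::tibble(tf = "TF1", mirna = "mir-a"))
  all_preds <- dplyr::bind_rows(db$predictions)
  expect_equal(unique(all_preds[, c("mirna", "gene")]),
               tibble::tibble(mirna = "mir-a", gene = "T"))
  expect_length(db$truth, 1)
  expect_equal(db$truth[[1]]$nodes, c("S", "TF1", "mir-a", "T"))
  expect_equal(db$truth[[1]]$edge_types, c("ppi", "tf_mirna", "mirna_target"))
})

test_that("every true miRNA-target pair is emitted by at least min_tools tools", {
  for (seed in 1:20) {
    db <- gen_interaction_db(one_path_cfg(seed = seed))
    n_emitting <- sum(vapply(db$predictions, function(tb) {
      any(tb$mirna == "mir-a" & tb$gene == "T")
    }, TRUE))
    expect_gte(n_emitting, 3)
  }
})

test_that("planted edges land in the right table and truth matches a table scan", {
  cfg <- network_sim_config(
    planted_paths = list(c("S", "TF1", "mir-a", "T"),
                         c("S", "G1", "TF2", "mir-b", "T")),
    mirnas = c("mir-a", "mir-b"), tfs = c("TF1", "TF2"),
    n_decoy_genes = 10, n_tfs = 3, n_mirnas = 2,
    ppi_edge_prob = 0.3, seed = 1)
  db <- gen_interaction_db(cfg)
  ppi_key <- c(paste(db$ppi$protein_a, db$ppi$protein_b),
               paste(db$ppi$protein_b, db$ppi$protein_a))
  tfm_key <- paste(db$tf_mirna$tf, db$tf_mirna$mirna)
  pred_key <- unique(unlist(lapply(db$predictions, function(tb) {
    paste(tb$mirna, tb$gene)
  })))
  for (tr in db$truth) {
    n <- tr$nodes
    for (i in seq_along(tr$edge_types)) {
      key <- paste(n[i], n[i + 1])
      carrier <- switch(tr$edge_types[i],
                        ppi = ppi_key, tf_mirna = tfm_key,
                        mirna_target = pred_key)
      expect_true(key %in% carrier, label = sprintf("edge %s in its layer", key))
    }
  }
})

test_that("seed fixes all randomness; different seeds keep planted edges", {
  cfg1 <- network_sim_config(
    planted_paths = list(c("S", "TF1", "mir-a", "T")),
    mirnas = "mir-a", tfs = "TF1",
    n_decoy_genes = 8, n_tfs = 2, n_mirnas = 2,
    ppi_edge_prob = 0.4, seed = 11)
  cfg2 <- cfg1
  cfg2$seed <- 99L
  db1a <- gen_interaction_db(cfg1)
  db1b <- gen_interaction_db(cfg1)
  db2 <- gen_interaction_db(cfg2)
  expect_identical(db1a, db1b)
  expect_false(identical(db1a$ppi, db2$ppi))
  # planted edges survive any seed
  expect_true(all(paste("S", "TF1") %in%
                    paste(db2$ppi$protein_a, db2$ppi$protein_b)))
  expect_true(any(db2$tf_mirna$tf == "TF1" & db2$tf_mirna$mirna == "mir-a"))
})

test_that("illegal planted transitions are rejected naming the edge", {
  expect_error(
    network_sim_config(planted_paths = list(c("S", "mir-a", "mir-b")),
                       mirnas = c("mir-a", "mir-b")),
    "mir-a.*mir-b|no legal layer")
  expect_error(
    network_sim_config(planted_paths = list(c("S", "mir-a", "TF1")),
                       mirnas = "mir-a", tfs = "TF1"),
    "no legal layer")
})

test_that("decoy edges never create a new or shorter source-target path", {
  for (seed in 1:10) {
    cfg <- network_sim_config(
      planted_paths = list(c("S", "TF1", "mir-a", "T")),
      mirnas = "mir-a", tfs = "TF1",
      n_decoy_genes = 12, n_tfs = 3, n_mirnas = 3,
      ppi_edge_prob = 0.5, tf_mirna_decoy_prob = 0.5,
      p_decoy = 0.4, seed = seed)
    db <- gen_interaction_db(cfg)
    cs <- consensus_targets(predictions_to_records(db$predictions),
                            min_tools = 3)
    net <- suppressMessages(build_network(db$ppi, db$tf_mirna, cs,
                                          sources = db$sources,
                                          targets = db$targets,
                                          tf_ids = db$tf_ids))
    paths <- enumerate_paths(net, "S", "T", search_config(max_depth = 6))
    expect_equal(sort(path_chains(paths)), "S->TF1->mir-a->T")
  }
})

test_that("qPCR Ct values encode the planted folds", {
  cfg <- qpcr_sim_config(genes = c("g", "GAPDH"),
                         folds = list(OM = c(g = 0.5)),
                         ct_noise_sd = 0, n_replicates = 3, seed = 1)
  q <- gen_qpcr(cfg)
  ct_g_om <- q$ct[q$gene == "g" & q$group == "OM"]
  ct_g_ctl <- q$ct[q$gene == "g" & q$group == "control"]
  expect_equal(unique(ct_g_om - mean(ct_g_ctl)), 1) # fold 0.5 = +1 cycle
  expect_equal(unique(q$ct[q$gene == "GAPDH"]), cfg$baseline_ct)

  null_cfg <- qpcr_sim_config(genes = c("g", "GAPDH"),
                              folds = list(OM = c(g = 1)),
                              ct_noise_sd = 0, seed = 1)
  qn <- gen_qpcr(null_cfg)
  expect_equal(unique(qn$ct), null_cfg$baseline_ct)
})

test_that("qPCR config rejects bad inputs", {
  expect_error(qpcr_sim_config(genes = "g", folds = list(OM = c(g = 1))),
               "reference_gene")
  expect_error(qpcr_sim_config(genes = c("g", "GAPDH"),
                               folds = list(OM = c(g = -1))), "> 0")
  expect_error(qpcr_sim_config(genes = c("g", "GAPDH"),
                               folds = list(OM = c(g = 0.5)),
                               n_replicates = 0), "n_replicates")
})

test_that("cohort generator honours group sizes, SD = 0 and determinism", {
  cohort <- gen_cohort(aac_cohort_config(seed = 3))
  expect_equal(nrow(cohort), 35)
  expect_equal(as.vector(table(cohort$group)[c("non-AAC", "AAC")]), c(24, 11))
  expect_identical(cohort, gen_cohort(aac_cohort_config(seed = 3)))

  flat <- cohort_sim_config(group_specs = list(
    list(label = "a", n = 5, biomarkers = list(x = c(2.5, 0)),
         sex_ratio = 0.4, age_mean = 70, age_sd = 0)), seed = 1)
  fc <- gen_cohort(flat)
  expect_equal(fc$x, rep(2.5, 5))
  expect_equal(fc$age, rep(70, 5))
})

test_that("cohort sample means converge to the specified means", {
  big <- cohort_sim_config(group_specs = list(
    list(label = "a", n = 10000,
         biomarkers = list(x = c(9.62, 8.25)),
         sex_ratio = 0.5, age_mean = 75.8, age_sd = 6)),
    nonnegative_clip = FALSE, seed = 42)
  cohort <- gen_cohort(big)
  se <- 8.25 / sqrt(10000)
  expect_lt(abs(mean(cohort$x) - 9.62), 3 * se)
})

test_that("cohort config rejects missing or negative SDs", {
  expect_error(cohort_sim_config(group_specs = list(
    list(label = "a", n = 5, biomarkers = list(x = 2.5),
         sex_ratio = 0.4, age_mean = 70, age_sd = 1))), "mean, sd")
  expect_error(cohort_sim_config(group_specs = list(
    list(label = "a", n = 5, biomarkers = list(x = c(2.5, -1)),
         sex_ratio = 0.4, age_mean = 70, age_sd = 1))), "SD < 0")
})
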