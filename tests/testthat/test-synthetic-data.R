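test_that("config validation names the offending field", {
  expect_error(mega_sim_config(seed = NULL), "seed")
  expect_error(mega_sim_config(tau2 = -1, seed = 1), "tau2")
  expect_error(mega_sim_config(sigma2 = 0, seed = 1), "sigma2")
  expect_error(mega_sim_config(coverage_prob = 0, seed = 1), "coverage_prob")
  expect_error(mega_sim_config(coverage_prob = 1.5, seed = 1), "coverage_prob")
  expect_error(mega_sim_config(n_studies = 1, seed = 1), "n_studies")
  expect_error(mega_sim_config(n_case = 0, seed = 1), "n_case")
  expect_error(mega_sim_config(n_genes = 5, true_lfc = c(1, 2), seed = 1),
               "true_lfc")
})

test_that("defaults reproduce the 16-study registry conditions", {
  cfg <- mega_sim_config(n_genes = 5, seed = 1)
  expect_equal(cfg$n_studies, 16L)
  expect_equal(sum(cfg$n_case), 783L)
  expect_equal(sum(cfg$n_control), 439L)
  expect_equal(sort(unique(cfg$countries)),
               sort(c("Poland", "Belgium", "USA", "Portugal", "Singapore",
                      "France")))
})

test_that("noise-free limit recovers the planted doubling exactly", {
  cfg <- mega_sim_config(n_studies = 2, n_case = 4, n_control = 4,
                         n_genes = 3, true_lfc = c(1, 0, -2), tau2 = 0,
                         sigma2 = 1e-12, seed = 42)
  st <- generate_study(cfg, 1)
  eff <- study_effects(st)
  expect_equal(eff$lfc, c(1, 0, -2), tolerance = 1e-4)
  # case samples of a doubled gene sit at ~2x the control mean
  ctrl_mean <- mean(st$matrix[1, st$groups == "control"])
  expect_equal(unname(st$matrix[1, st$groups == "case"] / ctrl_mean),
               rep(2, 4), tolerance = 1e-4)
})

test_that("null per-study LFC estimates center on zero", {
  cfg <- mega_sim_config(n_studies = 2, n_case = 50, n_control = 50,
                         n_genes = 1000, true_lfc = 0, tau2 = 0,
                         sigma2 = 0.1, seed = 99)
  eff <- study_effects(generate_study(cfg, 1))
  se_mean <- stats::sd(eff$lfc) / sqrt(length(eff$lfc))
  expect_lt(abs(mean(eff$lfc)), 3 * se_mean)
})

test_that("full coverage puts every gene in every study", {
  cfg <- mega_sim_config(n_genes = 40, coverage_prob = 1, seed = 5)
  col <- generate_collection(cfg)
  expect_true(all(col$truth$membership))
  for (st in col$studies) expect_equal(nrow(st$matrix), 40L)
})

test_that("membership flags match the emitted matrices exactly", {
  cfg <- mega_sim_config(n_genes = 60, coverage_prob = 0.7, seed = 8)
  col <- generate_collection(cfg)
  for (j in seq_along(col$studies)) {
    flagged <- rownames(col$truth$membership)[col$truth$membership[, j]]
    expect_identical(rownames(col$studies[[j]]$matrix), flagged)
  }
})

test_that("same seed gives byte-identical output, and per-study draws match the collection", {
  cfg <- mega_sim_config(n_genes = 25, tau2 = 0.1, coverage_prob = 0.9,
                         seed = 17)
  col1 <- generate_collection(cfg)
  col2 <- generate_collection(cfg)
  expect_identical(col1, col2)
  expect_identical(generate_study(cfg, 7), col1$studies[[7]])
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_study_dataset(col1$studies[[1]], d1)
  write_study_dataset(col2$studies[[1]], d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("between-study variance of realized effects matches tau2", {
  cfg <- mega_sim_config(n_genes = 2000, true_lfc = 0, tau2 = 0.5, seed = 23)
  col <- generate_collection(cfg)
  v <- mean(apply(col$truth$realized, 1, stats::var))
  expect_lt(abs(v - 0.5) / 0.5, 0.15)
})

test_that("relation-table generator hits the designed set sizes after filtering", {
  rel <- generate_relation_tables(20000, 534, 1036, 176, seed = 5)
  sets <- gene_sets(filter_relations(rel$a), filter_relations(rel$b))
  expect_length(sets$a, 534)
  expect_length(sets$b, 1036)
  expect_length(sets$overlap, 176)
  ov <- overlap_analysis(sets$a, sets$b, 20000)
  expect_equal(ov$n_overlap, 176)
  expect_equal(round(ov$pct_of_a, 2), 32.96)
  # some generated records must fail the evidence/polarity filter
  expect_gt(nrow(rel$a), 534)
  expect_gt(nrow(rel$b), 1036)
})

test_that("degenerate relation designs are handled", {
  rel0 <- generate_relation_tables(200, 20, 30, 0, seed = 2)
  s0 <- gene_sets(filter_relations(rel0$a), filter_relations(rel0$b))
  expect_length(s0$overlap, 0)
  expect_gte(overlap_analysis(s0$a, s0$b, 200)$fisher_p, 0.5)
  # containment: A entirely inside B
  relc <- generate_relation_tables(200, 15, 40, 15, seed = 3)
  sc <- gene_sets(filter_relations(relc$a), filter_relations(relc$b))
  expect_length(sc$a_only, 0)
  expect_setequal(sc$overlap, sc$a)
  expect_error(generate_relation_tables(200, 10, 20, 15, seed = 1),
               "n_overlap")
  expect_error(generate_relation_tables(40, 30, 30, 5, seed = 1),
               "universe")
})
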