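test_that("hand-worked LFC examples hold for the arithmetic-reference estimator", {
  # exact doubling: controls all 2, cases all 4
  st <- make_study("S", "G", ctrl = rep(2, 4), case = rep(4, 3))
  expect_equal(gene_lfc(st, "G", control_mean = "arithmetic")$lfc, 1)
  # identity: equal groups
  st0 <- make_study("S", "G", ctrl = c(1, 1), case = c(1, 1))
  expect_equal(gene_lfc(st0, "G", control_mean = "arithmetic")$lfc, 0)
  # controls (2,4) -> mean 3; cases (3,6,12) -> per-case log2 ratios (0,1,2)
  st2 <- make_study("S", "G", ctrl = c(2, 4), case = c(3, 6, 12))
  eff <- gene_lfc(st2, "G", control_mean = "arithmetic")
  expect_equal(eff$lfc, 1)
  # case component of the variance is var(ratios)/n_case = 1/3
  ctrl_term <- var(c(2, 4)) / (2 * 3^2 * log(2)^2)
  expect_equal(eff$var, 1 / 3 + ctrl_term)
})

test_that("absent genes give a marker, undefined ratios an error", {
  st <- make_study("S", "G", ctrl = rep(2, 3), case = rep(4, 3))
  expect_null(gene_lfc(st, "NOPE"))
  stz <- make_study("S", "G", ctrl = c(0, 0, 6), case = c(1, 2, 3))
  expect_error(gene_lfc(stz, "G"), "undefined")
})

test_that("geometric-reference LFC equals the difference of log2 group means", {
  st <- make_study("S", c("G1", "G2"),
                   ctrl = matrix(c(2, 4, 8, 1, 3, 9), 2),
                   case = matrix(c(5, 7, 10, 2, 6, 11), 2))
  eff <- study_effects(st)
  lc <- log2(st$matrix[, st$groups == "case"])
  lk <- log2(st$matrix[, st$groups == "control"])
  expect_equal(eff$lfc, unname(rowMeans(lc) - rowMeans(lk)))
  expect_equal(eff$var,
               unname(apply(lc, 1, var) / 3 + apply(lk, 1, var) / 3))
})

test_that("Cochran's Q, I-squared and the combiners match hand arithmetic", {
  q <- cochran_q(c(0, 2), c(1, 1))
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1)
  expect_equal(cochran_q(c(1, 1, 1), c(0.5, 2, 7))$Q, 0)
  expect_equal(cochran_q(c(1, 1), c(1, 1))$q_p, 1)  # chi-sq upper tail at 0
  expect_error(cochran_q(1, 1), "2 studies")

  expect_equal(i_squared(0.5, 2), 0)   # clamped
  expect_equal(i_squared(2, 2), 0)     # boundary Q = df
  expect_equal(i_squared(20, 10), 50)

  fx <- combine_fixed(c(1, 3), c(1, 1))
  expect_equal(fx$effect, 2)
  expect_equal(fx$se, sqrt(1 / 2))
  one <- combine_fixed(5, 4)           # k = 1 passthrough
  expect_equal(one$effect, 5)
  expect_equal(one$se, 2)
  fx2 <- combine_fixed(c(0, 2), c(1, 3))
  expect_equal(fx2$effect, 0.5)
  expect_equal(fx2$se, sqrt(3) / 2)

  rd <- combine_random(c(0, 2), c(1, 1))  # Q=2, df=1, C=1 -> tau2=1
  expect_equal(rd$tau2, 1)
  expect_equal(rd$effect, 1)
  expect_equal(rd$se, 1)
  # degenerate heterogeneity: identical effects -> tau2 = 0, equals fixed
  rd0 <- combine_random(c(1.5, 1.5, 1.5), c(1, 2, 3))
  expect_equal(rd0$tau2, 0)
  expect_equal(rd0[c("effect", "se", "p")],
               combine_fixed(c(1.5, 1.5, 1.5), c(1, 2, 3)))
  # equal variances, no heterogeneity: se = sqrt(v / k)
  rdv <- combine_random(c(1, 1, 1, 1), rep(2, 4))
  expect_equal(rdv$se, sqrt(2 / 4))
})

test_that("meta statistics agree with an external random-effects implementation", {
  skip_if_not_installed("metafor")
  set.seed(31)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    y <- rnorm(k); v <- runif(k, 0.05, 2)
    rd <- combine_random(y, v)
    mf <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(rd$effect, as.numeric(mf$beta), tolerance = 1e-8)
    expect_equal(rd$se, mf$se, tolerance = 1e-8)
    expect_equal(rd$tau2, mf$tau2, tolerance = 1e-8)
    fx <- combine_fixed(y, v)
    me <- metafor::rma(yi = y, vi = v, method = "FE")
    expect_equal(fx$effect, as.numeric(me$beta), tolerance = 1e-8)
  }
})

test_that("study counting, model selection and audit fields are consistent", {
  cfg <- mega_sim_config(n_genes = 40, tau2 = 0.2, coverage_prob = 0.9,
                         seed = 12)
  col <- generate_collection(cfg)
  fit <- mega_analysis(col$studies)
  # k equals the number of studies actually carrying the gene
  expect_equal(fit$results$k,
               unname(rowSums(col$truth$membership))[
                 match(fit$results$gene, rownames(col$truth$membership))])
  # model selection rule: fixed <=> Q <= df <=> I2 == 0
  expect_identical(fit$results$model == "fixed",
                   fit$results$Q <= fit$results$df)
  expect_identical(fit$results$isq == 0, fit$results$model == "fixed")
  expect_true(all(fit$results$df == fit$results$k - 1))
  expect_true(all(fit$results$isq >= 0 & fit$results$isq < 100))
  expect_true(all(fit$results$tau2 >= 0))
  # the chosen-model columns match the retained audit columns
  fixed_rows <- fit$results$model == "fixed"
  expect_equal(fit$results$effect[fixed_rows],
               fit$results$fixed_effect[fixed_rows])
  expect_equal(fit$results$effect[!fixed_rows],
               fit$results$random_effect[!fixed_rows])
  # single-gene path agrees with the fit
  mr <- mega_analyze("GENE00007", col$studies)
  row <- fit$results[fit$results$gene == "GENE00007", ]
  expect_equal(mr$effect, row$effect)
  expect_equal(mr$Q, row$Q)
  expect_equal(mr$model, row$model)
})

test_that("a gene on 15 of 16 platforms is combined over k = 15", {
  cfg <- mega_sim_config(n_genes = 3, seed = 4)
  col <- generate_collection(cfg)
  # drop gene 1 from study 16's matrix
  st <- col$studies[[16]]
  m <- st$matrix[-1, , drop = FALSE]
  col$studies[[16]] <- study_dataset(st$study_id, m, st$groups,
                                     st$country, st$study_age)
  mr <- mega_analyze("GENE00001", col$studies)
  expect_equal(mr$k, 15)
  # below min_studies: skipped-marker, not an error
  few <- col$studies[1:3]
  expect_true(mega_analyze("GENE00001", few, min_studies = 4)$skipped)
})

test_that("study order does not change any combined result", {
  cfg <- mega_sim_config(n_genes = 15, tau2 = 0.1, coverage_prob = 0.8,
                         seed = 77)
  col <- generate_collection(cfg)
  fit1 <- mega_analysis(col$studies)
  set.seed(1); perm <- sample(length(col$studies))
  fit2 <- mega_analysis(col$studies[perm])
  r1 <- fit1$results[order(fit1$results$gene), ]
  r2 <- fit2$results[order(fit2$results$gene), ]
  rownames(r1) <- rownames(r2) <- NULL
  for (cl in c("k", "effect", "se", "p", "Q", "isq", "q_p", "tau2"))
    expect_equal(r1[[cl]], r2[[cl]])
  expect_identical(r1$model, r2$model)
})

test_that("significance filter uses strict thresholds and sorts by |LFC|", {
  res <- data.frame(
    gene = c("A", "B", "C", "D", "E"),
    effect = c(-1.5, -0.5, -2.0, 1.2, -1.5),
    p = c(1e-8, 1e-8, 1e-6, 1e-9, 1e-7),
    stringsAsFactors = FALSE)
  out <- select_significant(res)
  expect_identical(out$gene, c("A", "D"))  # strict p and strict |LFC| bounds
  expect_identical(select_significant(res[0, ])$gene, character(0))
  expect_true("p_bh" %in% names(select_significant(res, p_max = 1,
                                                   lfc_min_abs = 0,
                                                   add_bh = TRUE)))
})

test_that("the 95% CI of the combined effect covers a planted LFC", {
  hits <- 0L
  for (r in 1:200) {
    cfg <- mega_sim_config(n_genes = 1, true_lfc = -1.8, tau2 = 0.05,
                           seed = 5000 + r)
    fit <- mega_analysis(generate_collection(cfg)$studies)
    lo <- fit$results$effect - 1.96 * fit$results$se
    hi <- fit$results$effect + 1.96 * fit$results$se
    if (lo <= -1.8 && -1.8 <= hi) hits <- hits + 1L
  }
  expect_gte(hits, 180L)  # >= 90% coverage
})
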