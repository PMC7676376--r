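cov16 <- function() {
  reg <- default_study_registry()
  reg[, c("study_id", "n_case", "n_control", "country", "study_age")]
}

test_that("exact linear data is recovered perfectly", {
  eff <- data.frame(study_id = letters[1:5], lfc = c(1, 2, 3, 4, 5))
  cov <- data.frame(study_id = letters[1:5],
                    n_sample = c(10, 20, 30, 40, 50), country = "USA",
                    study_age = c(5, 5, 6, 6, 7))
  # one-country design drops the country block; slope on n_sample is 0.1
  # (a perfect fit makes lm's summary complain; the estimates are the point)
  res <- suppressWarnings(moderator_mlr(eff, cov))
  ns <- res$table[res$table$term == "n_sample", ]
  expect_equal(ns$estimate, 0.1)
  expect_equal(res$r2, 1)
  expect_false("country" %in% res$table$term)
})

test_that("a constant response yields the no-effect report", {
  eff <- data.frame(study_id = letters[1:6], lfc = rep(0.7, 6))
  cov <- data.frame(study_id = letters[1:6], n_sample = 1:6 * 10,
                    country = rep(c("USA", "Poland"), 3), study_age = 1:6)
  res <- moderator_mlr(eff, cov)
  expect_true(all(res$table$p == 1))
  expect_true(all(res$table$estimate[res$table$term != "country"] == 0))
  expect_equal(res$r2, 0)
})

test_that("adding a constant to all effects changes only the intercept", {
  set.seed(42)
  eff <- data.frame(study_id = cov16()$study_id, lfc = rnorm(16))
  res1 <- moderator_mlr(eff, cov16())
  eff2 <- eff; eff2$lfc <- eff2$lfc + 5
  res2 <- moderator_mlr(eff2, cov16())
  expect_equal(res1$table$estimate, res2$table$estimate)
  expect_equal(res1$table$p, res2$table$p)
})

test_that("OLS matches the closed-form normal equations and the slope t-test", {
  set.seed(9)
  cov <- cov16()
  eff <- data.frame(study_id = cov$study_id,
                    lfc = rnorm(16) + 0.01 * (cov$n_case + cov$n_control))
  res <- moderator_mlr(eff, cov)
  d <- merge(eff, cov)
  X <- model.matrix(~ I(n_case + n_control) + study_age + factor(country), d)
  beta <- solve(t(X) %*% X, t(X) %*% d$lfc)
  expect_equal(res$table$estimate[res$table$term == "n_sample"],
               as.numeric(beta["I(n_case + n_control)", 1]), tolerance = 1e-10)
  expect_equal(res$table$estimate[res$table$term == "study_age"],
               as.numeric(beta["study_age", 1]), tolerance = 1e-10)
  # single continuous predictor: reported p equals the classical slope t-test
  eff1 <- data.frame(study_id = letters[1:8], lfc = rnorm(8))
  cov1 <- data.frame(study_id = letters[1:8], n_sample = c(2, 5, 9, 4, 7, 8, 3, 6),
                     country = "USA", study_age = rnorm(8))
  res1 <- moderator_mlr(eff1, cov1)
  d1 <- merge(eff1, cov1)
  sm <- summary(lm(lfc ~ n_sample + study_age, d1))
  expect_equal(res1$table$p[res1$table$term == "n_sample"],
               sm$coefficients["n_sample", "Pr(>|t|)"])
  expect_equal(res1$table$p[res1$table$term == "study_age"],
               sm$coefficients["study_age", "Pr(>|t|)"])
})

test_that("confidence intervals bracket the estimates and errors are informative", {
  set.seed(11)
  eff <- data.frame(study_id = cov16()$study_id, lfc = rnorm(16))
  res <- moderator_mlr(eff, cov16())
  cont <- res$table[res$table$term != "country", ]
  expect_true(all(cont$ci_lo <= cont$estimate & cont$estimate <= cont$ci_hi))
  expect_true(all(res$table$p >= 0 & res$table$p <= 1))
  # collinear design: n_sample proportional to study_age
  covd <- data.frame(study_id = letters[1:8], n_sample = 1:8,
                     country = "USA", study_age = 2 * (1:8))
  effd <- data.frame(study_id = letters[1:8], lfc = rnorm(8))
  expect_error(moderator_mlr(effd, covd), "degenerate")
  expect_error(moderator_mlr(effd[1:3, ], cov16()), "too few studies")
})

test_that("the country partial F-test has power against a planted shift and is calibrated", {
  reg <- default_study_registry()
  country_rate <- function(shift, n_rep, base_seed) {
    detected <- 0L
    for (r in seq_len(n_rep)) {
      me <- if (shift != 0) list(country = c(USA = shift)) else list()
      cfg <- mega_sim_config(n_genes = 1, true_lfc = 0, tau2 = 0,
                             moderator_effects = me, seed = base_seed + r)
      col <- generate_collection(cfg)
      eff <- do.call(rbind, lapply(col$studies, study_effects))
      res <- moderator_mlr(eff[, c("study_id", "lfc")], reg,
                           gene = "GENE00001")
      if (res$table$p[res$table$term == "country"] < 0.05)
        detected <- detected + 1L
    }
    detected / n_rep
  }
  # power against a +0.5 log2 shift of the USA studies: the 5-numerator-df
  # partial F over 16 studies detects it far above the nominal 5% rate
  expect_gte(country_rate(0.5, 200L, 3000L), 0.25)
  # calibration: no shift -> rejections stay near the nominal level
  expect_lte(country_rate(0, 100L, 4000L), 0.15)
})

test_that("moderator_scan reports one row per gene and term", {
  cfg <- mega_sim_config(n_genes = 6, tau2 = 0.05, seed = 21)
  fit <- mega_analysis(generate_collection(cfg)$studies)
  tab <- moderator_scan(fit, genes = c("GENE00001", "GENE00002"))
  expect_setequal(unique(tab$gene), c("GENE00001", "GENE00002"))
  expect_setequal(unique(tab$term), c("n_sample", "study_age", "country"))
  expect_true(all(tab$n_obs == 16))
})
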