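#' Moderator regression of per-study effect sizes
#'
#' Ordinary least squares of one gene's per-study LFC on the study-level
#' moderators: total sample size (`n_sample = n_case + n_control`,
#' continuous), study age in years (continuous) and country (categorical,
#' reference-coded). Continuous moderators are reported with the
#' two-sided t-test p-value and 95% confidence interval of their slope;
#' the multi-level country factor is reported with a single partial-F
#' p-value comparing the models with and without the country block —
#' the only way a many-level factor yields one p-value per gene.
#'
#' @param effects Data frame with columns `study_id` and `lfc` (one row
#'   per study for a single gene), e.g. built from a `mega_fit`'s
#'   `study_lfc` matrix; a column `var` is used only when
#'   `weighted = TRUE`.
#' @param covariates Data frame with `study_id`, `country`, `study_age`
#'   and either `n_sample` or `n_case`/`n_control` (a registry works).
#' @param gene Optional gene label carried into the result.
#' @param weighted Use inverse-variance weights `1/var` instead of plain
#'   OLS (default FALSE).
#' @return A `moderator_result` list: `gene`, `n_obs`, `r2`, and `table`,
#'   a data frame with one row per reported term (`n_sample`,
#'   `study_age`, `country`) carrying `estimate`, `ci_lo`, `ci_hi`, `p`.
#'   The country row reports only the partial-F `p`.
#' @export
moderator_mlr <- function(effects, covariates, gene = NA_character_,
                          weighted = FALSE) {
  if (!all(c("study_id", "lfc") %in% names(effects)))
    .stopf("'effects' needs columns 'study_id' and 'lfc'")
  cov <- covariates
  if (!"n_sample" %in% names(cov)) {
    if (!all(c("n_case", "n_control") %in% names(cov)))
      .stopf("'covariates' needs 'n_sample' or 'n_case' + 'n_control'")
    cov$n_sample <- cov$n_case + cov$n_control
  }
  need <- c("study_id", "n_sample", "country", "study_age")
  if (!all(need %in% names(cov)))
    .stopf("'covariates' lacks column(s): %s",
           paste(setdiff(need, names(cov)), collapse = ", "))
  d <- merge(effects, cov[, need], by = "study_id")
  d <- d[is.finite(d$lfc), , drop = FALSE]
  if (anyNA(d[, c("n_sample", "country", "study_age")]))
    .stopf("missing covariate values for gene '%s'", gene)
  use_country <- length(unique(d$country)) >= 2L
  terms <- c("n_sample", "study_age", if (use_country) "country")
  p_cols <- 1L + 2L + if (use_country) length(unique(d$country)) - 1L else 0L
  if (nrow(d) < p_cols + 2L)
    .stopf("too few studies (%d) for %d regression columns", nrow(d), p_cols)

  empty_row <- function(term, est = NA_real_, lo = NA_real_, hi = NA_real_,
                        p = NA_real_)
    data.frame(term = term, estimate = est, ci_lo = lo, ci_hi = hi, p = p,
               stringsAsFactors = FALSE)

  # zero-variance response: no moderator can have an effect; report that
  # directly rather than dividing by a zero residual variance
  if (stats::var(d$lfc) == 0) {
    tab <- do.call(rbind, lapply(terms, function(tm) empty_row(tm, 0, 0, 0, 1)))
    return(structure(list(gene = gene, n_obs = nrow(d), r2 = 0, table = tab),
                     class = "moderator_result"))
  }

  d$country <- factor(d$country)
  w <- if (weighted) {
    if (!"var" %in% names(effects)) .stopf("weighted fit needs a 'var' column")
    1 / d$var
  } else NULL
  fml <- stats::as.formula(paste("lfc ~ n_sample + study_age",
                                 if (use_country) "+ country" else ""))
  X <- stats::model.matrix(fml, d)
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    aliased <- colnames(X)[dec$pivot[-seq_len(dec$rank)]]
    .stopf("degenerate design: factor '%s' is rank-deficient",
           if (any(grepl("^country", aliased))) "country" else aliased[1])
  }
  fit <- stats::lm(fml, data = d, weights = w)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  cont <- function(nm) {
    empty_row(nm, sm$coefficients[nm, "Estimate"],
              ci[nm, 1], ci[nm, 2], sm$coefficients[nm, "Pr(>|t|)"])
  }
  tab <- rbind(cont("n_sample"), cont("study_age"))
  if (use_country) {
    fit0 <- stats::lm(lfc ~ n_sample + study_age, data = d, weights = w)
    an <- stats::anova(fit0, fit)
    tab <- rbind(tab, empty_row("country", p = an[["Pr(>F)"]][2]))
  }
  structure(list(gene = gene, n_obs = nrow(d), r2 = sm$r.squared,
                 table = tab),
            class = "moderator_result")
}

#' @export
print.moderator_result <- function(x, ...) {
  cat(sprintf("<moderator_result> gene %s: n = %d studies, R2 = %.3f\n",
              x$gene, x$n_obs, x$r2))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Moderator regressions for the genes of a mega-analysis fit
#'
#' Runs [moderator_mlr()] per gene over the per-study LFCs stored in a
#' `mega_fit`.
#'
#' @param fit A `mega_fit`.
#' @param covariates Registry-like data frame (defaults to the fit's own
#'   study table).
#' @param genes Genes to regress (default: all analyzed genes).
#' @param weighted Passed to [moderator_mlr()].
#' @return Long data frame: one row per gene x term, with `n_obs` and
#'   `r2` repeated per gene.
#' @export
moderator_scan <- function(fit, covariates = NULL, genes = NULL,
                           weighted = FALSE) {
  if (!inherits(fit, "mega_fit")) .stopf("'fit' must be a mega_fit")
  if (is.null(covariates)) covariates <- fit$studies
  if (is.null(genes)) genes <- fit$results$gene
  genes <- canonical_genes(genes)
  out <- lapply(genes, function(g) {
    if (!g %in% rownames(fit$study_lfc)) return(NULL)
    eff <- data.frame(study_id = colnames(fit$study_lfc),
                      lfc = fit$study_lfc[g, ],
                      var = fit$study_var[g, ],
                      stringsAsFactors = FALSE)
    eff <- eff[is.finite(eff$lfc), , drop = FALSE]
    res <- moderator_mlr(eff, covariates, gene = g, weighted = weighted)
    cbind(gene = g, res$table, n_obs = res$n_obs, r2 = res$r2,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
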