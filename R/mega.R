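#' Per-study log2 fold-change effect sizes for all genes
#'
#' For each gene of one study, computes the log2 fold change (LFC) of
#' cases over the control reference together with its within-study
#' sampling variance — the per-study effect size entering the
#' mega-analysis.
#'
#' Two control references are available:
#' \describe{
#'   \item{`"geometric"` (default)}{per-case log2 ratio to the control
#'     geometric mean, averaged over cases; identical to the difference of
#'     group means of log2 expression. Variance:
#'     s2_case/n_case + s2_control/n_control on the log2 scale. This
#'     estimator is consistent for the log2-scale group difference under
#'     multiplicative noise.}
#'   \item{`"arithmetic"`}{per-case log2 ratio to the control arithmetic
#'     mean, averaged — the literal "expression over the mean of control
#'     expression, then log2" reading. Variance: s2 of the per-case log2
#'     ratios / n_case plus a delta-method term for the control-mean
#'     uncertainty, s2_control,linear / (n_control * mean_control^2 *
#'     ln(2)^2). Under multiplicative noise this reference carries an
#'     irreducible Jensen offset of about sigma2*ln(2)/2 (see the package
#'     vignette), which is why it is not the default.}
#' }
#'
#' Genes with fewer than 2 positive case or control values, or with any
#' non-positive value needed by the chosen reference, get `NA` effect and
#' variance (they are excluded from combining, with a warning, at the
#' [mega_analysis()] level).
#'
#' @param study A [study_dataset()].
#' @param control_mean Control reference, `"geometric"` or `"arithmetic"`.
#' @return Data frame with one row per gene of the study: `study_id`,
#'   `gene`, `lfc`, `var`, `n_case`, `n_control`.
#' @export
study_effects <- function(study, control_mean = c("geometric", "arithmetic")) {
  control_mean <- match.arg(control_mean)
  m <- study$matrix
  case <- m[, study$groups == "case", drop = FALSE]
  ctrl <- m[, study$groups == "control", drop = FALSE]
  nc <- ncol(case); nk <- ncol(ctrl)
  out <- data.frame(study_id = study$study_id, gene = rownames(m),
                    lfc = NA_real_, var = NA_real_,
                    n_case = nc, n_control = nk,
                    stringsAsFactors = FALSE)
  if (nc < 2L || nk < 2L) return(out)
  if (control_mean == "geometric") {
    ok <- rowSums(case <= 0) == 0 & rowSums(ctrl <= 0) == 0
    if (any(ok)) {
      lc <- log2(case[ok, , drop = FALSE])
      lk <- log2(ctrl[ok, , drop = FALSE])
      out$lfc[ok] <- rowMeans(lc) - rowMeans(lk)
      out$var[ok] <- .row_var(lc) / nc + .row_var(lk) / nk
    }
  } else {
    mk <- rowMeans(ctrl)
    ok <- mk > 0 & rowSums(case <= 0) == 0
    if (any(ok)) {
      ratios <- log2(case[ok, , drop = FALSE] / mk[ok])
      out$lfc[ok] <- rowMeans(ratios)
      out$var[ok] <- .row_var(ratios) / nc +
        .row_var(ctrl[ok, , drop = FALSE]) / (nk * mk[ok]^2 * log(2)^2)
    }
  }
  out
}

#' Log2 fold change of one gene in one study
#'
#' Single-gene wrapper around [study_effects()]. Returns `NULL` (an
#' absent-marker, not an error) when the gene is not on this study's
#' platform; raises an error when the gene is present but its ratio is
#' undefined (non-positive control reference or case values).
#'
#' @inheritParams study_effects
#' @param gene Gene symbol.
#' @return A `gene_effect` list (`study_id`, `gene`, `lfc`, `var`,
#'   `n_case`, `n_control`) or `NULL` if the gene is absent.
#' @export
gene_lfc <- function(study, gene, control_mean = c("geometric", "arithmetic")) {
  gene <- canonical_genes(gene)
  if (!gene %in% rownames(study$matrix)) return(NULL)
  eff <- study_effects(study, control_mean)
  row <- eff[eff$gene == gene, ]
  if (is.na(row$lfc))
    .stopf("undefined log ratio for gene '%s' in study '%s' (non-positive values or too few samples)",
           gene, study$study_id)
  structure(as.list(row), class = "gene_effect")
}

#' Cochran's Q heterogeneity statistic
#'
#' Q is the inverse-variance-weighted sum of squared deviations of the
#' study effects from the fixed-effect mean; under homogeneity it is
#' chi-square distributed with `df = k - 1` degrees of freedom. `q_p` is
#' the upper-tail probability that the observed total variance arises
#' from within-study sampling alone.
#'
#' @param effects Numeric vector of per-study effect sizes (k >= 2).
#' @param vars Numeric vector of their within-study variances (> 0).
#' @return List with `Q`, `df`, `q_p`.
#' @export
cochran_q <- function(effects, vars) {
  k <- length(effects)
  if (k < 2L) .stopf("heterogeneity needs at least 2 studies, got %d", k)
  if (length(vars) != k) .stopf("'effects' and 'vars' lengths differ")
  if (any(!is.finite(vars)) || any(vars <= 0))
    .stopf("all variances must be finite and > 0")
  w <- 1 / vars
  ybar <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - ybar)^2)
  df <- k - 1L
  list(Q = Q, df = df, q_p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' The I-squared heterogeneity percentage
#'
#' `100 * (Q - df) / Q`, clamped to 0 whenever the total variance Q does
#' not exceed its expectation df under homogeneity (including Q = df
#' exactly).
#'
#' @param Q Cochran's Q (>= 0).
#' @param df Degrees of freedom, k - 1 (>= 1).
#' @return I-squared in percent, in \[0, 100).
#' @export
i_squared <- function(Q, df) {
  if (Q < 0) .stopf("'Q' must be >= 0")
  if (df < 1) .stopf("'df' must be >= 1")
  if (Q <= df) 0 else 100 * (Q - df) / Q
}

#' Fixed-effect (inverse-variance) combination
#'
#' @param effects Numeric vector of per-study effect sizes (k >= 1).
#' @param vars Their within-study variances.
#' @return List with `effect` (weighted mean), `se` (`1/sqrt(sum w)`) and
#'   `p` (two-sided Wald test of effect/se against the standard Normal).
#' @export
combine_fixed <- function(effects, vars) {
  if (length(effects) < 1L) .stopf("need at least 1 study")
  if (length(vars) != length(effects)) .stopf("'effects' and 'vars' lengths differ")
  if (any(!is.finite(vars)) || any(vars <= 0))
    .stopf("all variances must be finite and > 0")
  w <- 1 / vars
  effect <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  list(effect = effect, se = se, p = 2 * stats::pnorm(-abs(effect / se)))
}

#' DerSimonian-Laird random-effects combination
#'
#' The between-study variance is the moment estimator
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)`,
#' after which studies are re-weighted by `1 / (var + tau2)` and combined
#' as in [combine_fixed()].
#'
#' @inheritParams cochran_q
#' @return List with `effect`, `se`, `p`, `tau2`.
#' @export
combine_random <- function(effects, vars) {
  k <- length(effects)
  if (k < 2L) .stopf("random-effects combination needs at least 2 studies, got %d", k)
  q <- cochran_q(effects, vars)
  w <- 1 / vars
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q$Q - q$df) / C)
  wr <- 1 / (vars + tau2)
  effect <- sum(wr * effects) / sum(wr)
  se <- sqrt(1 / sum(wr))
  list(effect = effect, se = se,
       p = 2 * stats::pnorm(-abs(effect / se)), tau2 = tau2)
}

# combine one gene's study effects into a MetaResult row (both models kept)
.meta_one <- function(effects, vars) {
  fx <- combine_fixed(effects, vars)
  q <- cochran_q(effects, vars)
  rd <- combine_random(effects, vars)
  isq <- i_squared(q$Q, q$df)
  model <- if (q$Q <= q$df) "fixed" else "random"
  sel <- if (model == "fixed") fx else rd
  list(k = length(effects), model = model,
       effect = sel$effect, se = sel$se, p = sel$p,
       Q = q$Q, df = q$df, isq = isq, q_p = q$q_p, tau2 = rd$tau2,
       fixed_effect = fx$effect, fixed_se = fx$se, fixed_p = fx$p,
       random_effect = rd$effect, random_se = rd$se, random_p = rd$p)
}

#' Combine one gene across studies
#'
#' Gathers the gene's per-study LFC effect sizes, computes Cochran's Q,
#' I-squared and the heterogeneity p-value, selects the fixed-effect
#' model when `Q <= df` and the DerSimonian-Laird random-effects model
#' otherwise, and reports the combined effect, standard error and
#' two-sided p-value from the selected model. Both models' results are
#' always retained for comparison.
#'
#' @param gene Gene symbol.
#' @param studies List of [study_dataset()] objects.
#' @param min_studies Minimum number of contributing studies (>= 2);
#'   genes below it return a skipped-marker.
#' @param control_mean Passed to [study_effects()].
#' @return A `meta_result` list (`gene`, `k`, `model`, `effect`, `se`,
#'   `p`, `Q`, `df`, `isq`, `q_p`, `tau2`, plus `fixed_*`/`random_*`
#'   audit fields), or — when fewer than `min_studies` studies carry the
#'   gene — a list with `skipped = TRUE` and the observed `k`.
#' @export
mega_analyze <- function(gene, studies, min_studies = 2,
                         control_mean = c("geometric", "arithmetic")) {
  if (min_studies < 2) .stopf("'min_studies' must be >= 2")
  control_mean <- match.arg(control_mean)
  gene <- canonical_genes(gene)
  eff <- var <- numeric(0)
  for (st in studies) {
    if (!gene %in% rownames(st$matrix)) next
    tab <- study_effects(st, control_mean)
    row <- tab[tab$gene == gene, ]
    if (is.na(row$lfc) || is.na(row$var) || row$var <= 0) {
      warning(sprintf("gene '%s' excluded from study '%s' (undefined ratio or zero variance)",
                      gene, st$study_id), call. = FALSE)
      next
    }
    eff <- c(eff, row$lfc); var <- c(var, row$var)
  }
  if (length(eff) < min_studies)
    return(structure(list(gene = gene, k = length(eff), skipped = TRUE),
                     class = "meta_result"))
  structure(c(list(gene = gene, skipped = FALSE), .meta_one(eff, var)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat(sprintf("<meta_result> %s: skipped (k = %d below the study minimum)\n",
                x$gene, x$k))
  } else {
    cat(sprintf("<meta_result> %s: %s-effect model over k=%d studies\n  LFC %.3f (se %.3f), p = %.3g; Q = %.3f (df %d, p = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
                x$gene, x$model, x$k, x$effect, x$se, x$p,
                x$Q, x$df, x$q_p, x$isq, x$tau2))
  }
  invisible(x)
}

#' Fit a gene-wise multi-study mega-analysis
#'
#' The main fitting function of the package: re-estimates every gene's
#' LFC from each study's expression matrix ([study_effects()]), then
#' combines the per-study effects gene by gene with the
#' heterogeneity-driven fixed/random-effects rule of [mega_analyze()].
#'
#' @param studies List of [study_dataset()] objects (>= 2).
#' @param genes Genes to analyze; default: all genes seen in any study.
#' @param min_studies Minimum contributing studies per gene (default 2);
#'   genes below it are reported in `skipped`, not in `results`.
#' @param control_mean Control reference for the LFC (see
#'   [study_effects()]).
#' @return An object of class `mega_fit` with components `results` (one
#'   row per analyzed gene: `gene`, `model`, `k`, `effect`, `se`, `p`,
#'   `Q`, `df`, `isq`, `q_p`, `tau2`, and `fixed_*`/`random_*` audit
#'   columns), `skipped` (genes with too few studies and their k),
#'   `study_lfc`/`study_var` (genes x studies matrices of the per-study
#'   inputs), `studies` (registry-like frame of the fitted studies),
#'   `params` and `call`.
#' @seealso [select_significant()], [moderator_mlr()]
#' @export
#' @examples
#' cfg <- mega_sim_config(n_genes = 50, true_lfc = c(-1.8, rep(0, 49)),
#'                        tau2 = 0.05, seed = 421)
#' fit <- mega_analysis(generate_collection(cfg)$studies)
#' fit
#' head(coef(fit))
mega_analysis <- function(studies, genes = NULL, min_studies = 2,
                          control_mean = c("geometric", "arithmetic")) {
  control_mean <- match.arg(control_mean)
  if (length(studies) < 2L) .stopf("need at least 2 studies")
  if (min_studies < 2) .stopf("'min_studies' must be >= 2")
  tabs <- lapply(studies, study_effects, control_mean = control_mean)
  all_genes <- unique(unlist(lapply(tabs, `[[`, "gene"), use.names = FALSE))
  if (!is.null(genes)) {
    genes <- canonical_genes(genes)
    all_genes <- all_genes[all_genes %in% genes]
  }
  study_ids <- vapply(studies, `[[`, character(1), "study_id")
  E <- V <- matrix(NA_real_, length(all_genes), length(studies),
                   dimnames = list(all_genes, study_ids))
  n_undef <- 0L
  for (j in seq_along(tabs)) {
    idx <- match(tabs[[j]]$gene, all_genes)
    keep <- !is.na(idx)
    n_undef <- n_undef + sum(keep & (is.na(tabs[[j]]$lfc) |
                                       is.na(tabs[[j]]$var) |
                                       tabs[[j]]$var <= 0))
    E[idx[keep], j] <- tabs[[j]]$lfc[keep]
    V[idx[keep], j] <- tabs[[j]]$var[keep]
  }
  if (n_undef > 0L)
    warning(sprintf("%d gene-study effect(s) excluded (undefined ratio or zero variance)",
                    n_undef), call. = FALSE)
  V[!is.na(V) & V <= 0] <- NA_real_
  usable <- !is.na(E) & !is.na(V)
  k <- rowSums(usable)

  analyzed <- which(k >= min_studies)
  rows <- vector("list", length(analyzed))
  for (i in seq_along(analyzed)) {
    g <- analyzed[i]
    u <- usable[g, ]
    rows[[i]] <- c(list(gene = all_genes[g]), .meta_one(E[g, u], V[g, u]))
  }
  results <- do.call(rbind, lapply(rows, as.data.frame))
  if (!length(analyzed))
    results <- data.frame(gene = character(0), k = integer(0),
                          model = character(0), effect = numeric(0),
                          se = numeric(0), p = numeric(0))
  structure(
    list(results = results,
         skipped = data.frame(gene = all_genes[k < min_studies],
                              k = k[k < min_studies], row.names = NULL,
                              stringsAsFactors = FALSE),
         study_lfc = E, study_var = V,
         studies = data.frame(
           study_id = study_ids,
           n_case = vapply(studies, `[[`, integer(1), "n_case"),
           n_control = vapply(studies, `[[`, integer(1), "n_control"),
           country = vapply(studies, `[[`, character(1), "country"),
           study_age = vapply(studies, `[[`, numeric(1), "study_age"),
           stringsAsFactors = FALSE),
         params = list(min_studies = min_studies, control_mean = control_mean),
         call = match.call()),
    class = "mega_fit")
}

#' @export
print.mega_fit <- function(x, ...) {
  cat(sprintf("Gene-wise mega-analysis: %d genes over %d studies (%s control reference)\n",
              nrow(x$results), nrow(x$studies), x$params$control_mean))
  if (nrow(x$results)) {
    cat(sprintf("  model selection: %d fixed, %d random; %d gene(s) skipped (k < %d)\n",
                sum(x$results$model == "fixed"),
                sum(x$results$model == "random"),
                nrow(x$skipped), x$params$min_studies))
  }
  invisible(x)
}

#' @export
summary.mega_fit <- function(object, p_max = 1e-7, lfc_min_abs = 1, ...) {
  hits <- select_significant(object, p_max = p_max, lfc_min_abs = lfc_min_abs)
  structure(list(fit = object, hits = hits, p_max = p_max,
                 lfc_min_abs = lfc_min_abs),
            class = "summary.mega_fit")
}

#' @export
print.summary.mega_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Significance filter: p < %g and |LFC| > %g -> %d gene(s)\n",
              x$p_max, x$lfc_min_abs, nrow(x$hits)))
  if (nrow(x$hits)) {
    show <- x$hits[, c("gene", "model", "k", "effect", "se", "p",
                       "Q", "isq", "tau2")]
    print(utils::head(show, 10), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
coef.mega_fit <- function(object, ...) {
  stats::setNames(object$results$effect, object$results$gene)
}

#' @export
as.data.frame.mega_fit <- function(x, ...) x$results

#' Volcano-style plot of a mega-analysis fit
#'
#' Combined LFC against -log10 p, with the significance filter drawn as
#' reference lines.
#'
#' @param x A `mega_fit`.
#' @param p_max,lfc_min_abs Filter thresholds to draw (defaults as in
#'   [select_significant()]).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mega_fit <- function(x, p_max = 1e-7, lfc_min_abs = 1, ...) {
  r <- x$results
  if (!nrow(r)) .stopf("nothing to plot: empty fit")
  sig <- r$p < p_max & abs(r$effect) > lfc_min_abs
  graphics::plot(r$effect, -log10(r$p),
                 xlab = "combined LFC (log2)", ylab = "-log10 p",
                 pch = 16, col = ifelse(sig, "firebrick", "grey40"), ...)
  graphics::abline(v = c(-lfc_min_abs, lfc_min_abs), lty = 2, col = "grey60")
  graphics::abline(h = -log10(p_max), lty = 2, col = "grey60")
  invisible(x)
}

#' Apply the significance filter to mega-analysis results
#'
#' Keeps genes with combined `p < p_max` and `|effect| > lfc_min_abs`
#' (both strict), sorted by |effect| descending. No multiplicity
#' adjustment is applied at this stage — the screen uses a raw-p
#' threshold; a BH-adjusted column can be added with `add_bh = TRUE`.
#'
#' @param results A `mega_fit` or its `results` data frame.
#' @param p_max Combined p-value threshold (default 1e-7).
#' @param lfc_min_abs Minimum |LFC| (default 1).
#' @param add_bh Add a `p_bh` Benjamini-Hochberg column (computed across
#'   all input genes before filtering)?
#' @return Filtered data frame sorted by |effect| descending.
#' @export
select_significant <- function(results, p_max = 1e-7, lfc_min_abs = 1,
                               add_bh = FALSE) {
  df <- if (inherits(results, "mega_fit")) results$results else results
  if (add_bh && nrow(df)) df$p_bh <- stats::p.adjust(df$p, method = "BH")
  keep <- df$p < p_max & abs(df$effect) > lfc_min_abs
  out <- df[keep & !is.na(keep), , drop = FALSE]
  out <- out[order(-abs(out$effect)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
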