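#' Read a disease-gene relation table
#'
#' Relation tables are TSVs with columns `disease`, `gene`, `polarity`
#' (one of `positive`, `negative`, `unknown`) and `ref_count` (number of
#' supporting references). Gene symbols are canonicalized
#' ([canonical_genes()]) on read.
#'
#' @param path TSV path.
#' @return Data frame of relation records, input order preserved.
#' @export
read_relation_table <- function(path) {
  if (!file.exists(path)) .stopf("relation table not found: %s", path)
  rel <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("disease", "gene", "polarity", "ref_count")
  if (!all(need %in% names(rel)))
    .stopf("relation table %s lacks column(s): %s", path,
           paste(setdiff(need, names(rel)), collapse = ", "))
  rel$gene <- canonical_genes(rel$gene)
  .check_relations(rel, path)
  rel
}

.check_relations <- function(rel, what = "relation records") {
  bad <- which(!rel$polarity %in% c("positive", "negative", "unknown"))
  if (length(bad))
    .stopf("unknown polarity '%s' in %s at row %d",
           rel$polarity[bad[1]], what, bad[1])
  if (any(!is.finite(rel$ref_count)) || any(rel$ref_count < 1))
    .stopf("ref_count must be >= 1 in %s", what)
  if (any(!nzchar(rel$gene)))
    .stopf("empty gene symbol in %s at row %d", what,
           which(!nzchar(rel$gene))[1])
  invisible(rel)
}

#' Filter relation records by evidence and polarity
#'
#' Keeps records with at least `min_refs` supporting references and, if
#' `require_polarity`, a specific positive/negative regulation polarity
#' (records with polarity `unknown` are dropped). Input order is
#' preserved.
#'
#' @param records Relation data frame (see [read_relation_table()]).
#' @param min_refs Minimum supporting-reference count (default 3).
#' @param require_polarity Drop `unknown`-polarity records (default TRUE).
#' @return The filtered data frame.
#' @export
filter_relations <- function(records, min_refs = 3, require_polarity = TRUE) {
  if (min_refs < 1) .stopf("'min_refs' must be >= 1")
  .check_relations(records)
  keep <- records$ref_count >= min_refs
  if (require_polarity)
    keep <- keep & records$polarity %in% c("positive", "negative")
  records[keep, , drop = FALSE]
}

#' Distinct gene sets of two diseases and their overlap
#'
#' @param records_a,records_b Filtered relation data frames (or character
#'   vectors of gene symbols).
#' @return List with `a`, `b` (distinct canonical gene sets, sorted),
#'   `overlap` (intersection) and `a_only` (genes of A not in B — e.g. the
#'   obesity-specific candidates screened by the mega-analysis).
#' @export
gene_sets <- function(records_a, records_b) {
  pull <- function(x) {
    g <- if (is.data.frame(x)) x$gene else x
    sort(unique(canonical_genes(g)))
  }
  a <- pull(records_a); b <- pull(records_b)
  list(a = a, b = b, overlap = intersect(a, b), a_only = setdiff(a, b))
}

#' Right-tail Fisher overlap test for two gene sets
#'
#' Tests whether two gene sets share more genes than expected when drawn
#' independently from a universe of `universe_size` genes. The p-value is
#' the hypergeometric right tail P(overlap >= observed); the odds ratio
#' comes from the 2x2 table (in/out of A x in/out of B over the universe)
#' with a Haldane 0.5 correction only when a cell is zero.
#'
#' @param set_a,set_b Character vectors of gene symbols (canonicalized
#'   internally).
#' @param universe_size Total number of genes both lists were drawn from.
#'   The published analyses never state this number, so it is an explicit
#'   required argument here.
#' @return An `overlap_result` list: `n_a`, `n_b`, `n_overlap`, `pct_of_a`
#'   (percentage of A shared with B), `fisher_p`, `odds_ratio`,
#'   `universe_size`.
#' @export
overlap_analysis <- function(set_a, set_b, universe_size) {
  a <- unique(canonical_genes(set_a)); b <- unique(canonical_genes(set_b))
  n_union <- length(union(a, b))
  if (universe_size < n_union)
    .stopf("universe_size (%d) smaller than |A union B| (%d)",
           universe_size, n_union)
  n11 <- length(intersect(a, b))
  n12 <- length(a) - n11
  n21 <- length(b) - n11
  n22 <- universe_size - n_union
  # right tail of Hypergeometric(N = universe, K = |A|, n = |B|)
  fisher_p <- stats::phyper(n11 - 1, length(a), universe_size - length(a),
                            length(b), lower.tail = FALSE)
  cells <- c(n11, n12, n21, n22)
  if (any(cells == 0)) cells <- cells + 0.5
  structure(
    list(n_a = length(a), n_b = length(b), n_overlap = n11,
         pct_of_a = if (length(a)) 100 * n11 / length(a) else NA_real_,
         fisher_p = fisher_p,
         odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
         universe_size = as.integer(universe_size)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0("<overlap_result> |A|=%d, |B|=%d, overlap=%d (%.2f%% of A), ",
                     "right-tail Fisher p=%.3g, OR=%.3g (universe %d)\n"),
              x$n_a, x$n_b, x$n_overlap, x$pct_of_a, x$fisher_p,
              x$odds_ratio, x$universe_size))
  invisible(x)
}
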