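#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per tab-separated line — set id, description,
#' then the member gene symbols. Members are canonicalized and
#' deduplicated.
#'
#' @param path GMT file path.
#' @return List of gene sets, each a list with `set_id`, `name`,
#'   `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      .stopf("GMT line %d of %s has %d field(s); need id, description and at least one member",
             i, path, length(f))
    j <- j + 1L
    out[[j]] <- list(set_id = f[1], name = f[2],
                     members = unique(canonical_genes(f[-(1:2)])))
  }
  out
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric right-tail test of a (unranked) query gene list against
#' each set of a collection, with Benjamini-Hochberg adjustment across
#' the collection. The raw p is P(overlap >= observed) when `|query|`
#' genes are drawn from a universe of `universe_size` genes of which
#' `set_size` belong to the set.
#'
#' @param query Character vector of query gene symbols.
#' @param collection Gene-set list (see [read_gmt()]).
#' @param universe_size Universe size; default: number of distinct genes
#'   in the collection.
#' @param q_threshold FDR significance threshold (default 0.005).
#' @return Data frame sorted by `fdr_p` then `set_id` (a deterministic
#'   tie-break): `set_id`, `name`, `set_size`, `n_overlap`,
#'   `overlap_genes` (semicolon-joined, query order), `raw_p`, `fdr_p`,
#'   `significant`.
#' @export
enrich <- function(query, collection, universe_size = NULL,
                   q_threshold = 0.005) {
  query <- unique(canonical_genes(query))
  if (!length(query)) .stopf("'query' must contain at least one gene")
  if (!length(collection)) .stopf("'collection' must contain at least one set")
  collection <- lapply(collection, function(s) {
    s$members <- unique(canonical_genes(s$members))
    s
  })
  all_members <- unique(unlist(lapply(collection, `[[`, "members"),
                               use.names = FALSE))
  if (is.null(universe_size)) universe_size <- length(all_members)
  n_known <- length(union(query, all_members))
  if (universe_size < n_known)
    .stopf("universe_size (%d) smaller than the %d distinct genes observed",
           universe_size, n_known)
  rows <- lapply(collection, function(s) {
    ov <- query[query %in% s$members]
    K <- length(s$members)
    raw_p <- stats::phyper(length(ov) - 1, K, universe_size - K,
                           length(query), lower.tail = FALSE)
    data.frame(set_id = s$set_id, name = s$name, set_size = K,
               n_overlap = length(ov),
               overlap_genes = paste(ov, collapse = ";"),
               raw_p = raw_p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr_p <- stats::p.adjust(res$raw_p, method = "BH")
  res$significant <- res$fdr_p < q_threshold
  res <- res[order(res$fdr_p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.split_overlaps <- function(results) {
  og <- as.character(results$overlap_genes)
  og[is.na(og)] <- ""
  strsplit(og, ";", fixed = TRUE)
}

#' Shared-pathway count matrix
#'
#' For the significant sets of an enrichment result, cell (i, j) counts
#' the sets whose overlap genes contain both gene i and gene j; the
#' diagonal counts the sets containing the gene at all. This is the
#' heat-map summary of how strongly the genes co-occur across enriched
#' pathways.
#'
#' @param results Enrichment data frame (rows with `significant == FALSE`
#'   are ignored when the column is present).
#' @param genes Ordered gene vector for the matrix; default: all genes
#'   appearing in the used rows' overlaps.
#' @return Symmetric integer matrix with `genes` as dimnames.
#' @export
shared_pathway_matrix <- function(results, genes = NULL) {
  if (!is.null(results$significant))
    results <- results[results$significant, , drop = FALSE]
  members <- lapply(.split_overlaps(results), canonical_genes)
  if (is.null(genes))
    genes <- unique(unlist(members, use.names = FALSE))
  genes <- canonical_genes(genes)
  M <- matrix(0L, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (mem in members) {
    idx <- match(intersect(genes, mem), genes)
    if (length(idx)) M[idx, idx] <- M[idx, idx] + 1L
  }
  M
}

#' Number of distinct genes covered by the top enriched sets
#'
#' @param results Enrichment data frame, already sorted (as returned by
#'   [enrich()]); the first `k` rows are used.
#' @param k Number of top rows (default 10).
#' @return Integer: size of the union of the top rows' overlap genes.
#' @export
distinct_overlap_genes <- function(results, k = 10) {
  if (k < 1) .stopf("'k' must be >= 1")
  top <- utils::head(results, k)
  length(unique(unlist(lapply(.split_overlaps(top), canonical_genes),
                       use.names = FALSE)))
}

#' Write an enrichment report as TSV
#'
#' @param results Enrichment data frame.
#' @param path Output path.
#' @param header Optional `#` comment line.
#' @export
write_enrichment <- function(results, path, header = NULL) {
  .write_atomic(path, function(p) {
    con <- file(p, "w"); on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(results, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(path)
}

#' Packaged thyroid-cancer network fixtures
#'
#' `tc_network_genes()` returns the 14 genes of the literature-derived
#' obesity/thyroid-cancer regulatory network (the five mega-analysis hits
#' FABP4, CFD, GHR, TNFRSF11B and LTF plus their nine network targets).
#' `tc_top_go_terms()` returns the published top-10 GO-term enrichment
#' rows for those genes, in the same shape as [enrich()] output.
#'
#' @return A character vector of 14 symbols, or a data frame of 10
#'   enrichment rows.
#' @export
tc_network_genes <- function() {
  canonical_genes(readLines(system.file("extdata", "tc_network_genes.txt",
                                        package = "megaexpr",
                                        mustWork = TRUE)))
}

#' @rdname tc_network_genes
#' @export
tc_top_go_terms <- function() {
  utils::read.delim(system.file("extdata", "tc_top_go_terms.tsv",
                                package = "megaexpr", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
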