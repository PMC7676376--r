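#' Construct a study dataset
#'
#' A `study_dataset` bundles one study's genes x samples expression matrix
#' (linear scale, non-negative) with its per-sample case/control labels and
#' the study-level covariates used downstream (country, study age).
#'
#' @param study_id Study label (e.g. a GEO accession).
#' @param matrix Numeric genes x samples matrix with gene ids as row names
#'   and sample ids as column names; linear-scale expression values.
#' @param groups Character vector, one of `"case"`/`"control"` per column.
#' @param country Study region label.
#' @param study_age Age of the study in years.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(study_id, matrix, groups, country = NA_character_,
                          study_age = NA_real_) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    .stopf("'matrix' must be a numeric matrix")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    .stopf("'matrix' must have unique gene ids as row names")
  if (length(groups) != ncol(matrix))
    .stopf("'groups' length (%d) does not match sample count (%d)",
           length(groups), ncol(matrix))
  if (!all(groups %in% c("case", "control")))
    .stopf("'groups' must be 'case' or 'control'; got: %s",
           paste(unique(setdiff(groups, c("case", "control"))), collapse = ", "))
  if (anyNA(matrix))
    .stopf("expression matrix for '%s' contains missing values", study_id)
  if (any(matrix < 0))
    .stopf("expression matrix for '%s' contains negative values", study_id)
  n_case <- sum(groups == "case")
  n_control <- sum(groups == "control")
  if (n_case < 1L || n_control < 1L)
    .stopf("study '%s' needs at least one case and one control", study_id)
  structure(
    list(study_id = as.character(study_id), matrix = matrix,
         groups = as.character(groups), country = as.character(country),
         study_age = as.numeric(study_age),
         n_case = n_case, n_control = n_control),
    class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %s: %d genes x %d samples (%d case / %d control), %s, study age %s y\n",
              x$study_id, nrow(x$matrix), ncol(x$matrix),
              x$n_case, x$n_control, x$country, format(x$study_age)))
  invisible(x)
}

#' Read one study's expression matrix and phenotype table
#'
#' Parses a series-matrix-style TSV (first column `gene_id`, one column per
#' sample) together with a phenotype TSV (`sample_id`, `group`). Duplicate
#' gene rows (e.g. multiple probes per gene) are collapsed; rows containing
#' missing values are dropped, so the gene is simply absent from this study.
#'
#' @param matrix_path Path to the expression TSV.
#' @param phenotype_path Path to the phenotype TSV (`sample_id`, `group`
#'   with group in `case`/`control`).
#' @param study_id Study label; defaults to the matrix file name.
#' @param country,study_age Study-level covariates.
#' @param collapse How duplicate gene rows are combined: `"mean"` (default)
#'   or `"max"`, applied per sample on the linear scale.
#' @param scale Either `"linear"` (default) or `"log2"`; in the latter case
#'   values are anti-logged on read. No scale auto-detection is attempted.
#' @return A [study_dataset()].
#' @export
read_expression_matrix <- function(matrix_path, phenotype_path,
                                   study_id = NULL, country = NA_character_,
                                   study_age = NA_real_,
                                   collapse = c("mean", "max"),
                                   scale = c("linear", "log2")) {
  collapse <- match.arg(collapse)
  scale <- match.arg(scale)
  if (!file.exists(matrix_path)) .stopf("matrix file not found: %s", matrix_path)
  if (!file.exists(phenotype_path)) .stopf("phenotype file not found: %s", phenotype_path)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (names(tab)[1] != "gene_id")
    .stopf("first column of %s must be 'gene_id', found '%s'",
           matrix_path, names(tab)[1])
  genes <- canonical_genes(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1]
      .stopf("non-numeric expression value in %s at row %d, column '%s'",
             matrix_path, if (is.na(bad)) 1L else bad, names(vals)[j])
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- genes

  ph <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!all(c("sample_id", "group") %in% names(ph)))
    .stopf("phenotype file %s must have columns 'sample_id' and 'group'",
           phenotype_path)
  miss_m <- setdiff(colnames(mat), ph$sample_id)
  miss_p <- setdiff(ph$sample_id, colnames(mat))
  if (length(miss_m) || length(miss_p))
    .stopf("sample mismatch between matrix and phenotype%s%s",
           if (length(miss_m)) paste0("; missing from phenotype: ",
                                      paste(miss_m, collapse = ", ")) else "",
           if (length(miss_p)) paste0("; missing from matrix: ",
                                      paste(miss_p, collapse = ", ")) else "")
  groups <- ph$group[match(colnames(mat), ph$sample_id)]

  if (scale == "log2") mat <- 2^mat
  drop <- rowSums(is.na(mat)) > 0
  if (any(drop)) {
    message(sprintf("dropping %d gene(s) with missing values in %s",
                    sum(drop), basename(matrix_path)))
    mat <- mat[!drop, , drop = FALSE]
  }
  if (anyDuplicated(rownames(mat))) {
    f <- factor(rownames(mat), levels = unique(rownames(mat)))
    agg <- if (collapse == "mean") {
      rowsum(mat, f) / as.vector(table(f))
    } else {
      do.call(rbind, lapply(split(seq_len(nrow(mat)), f), function(i)
        apply(mat[i, , drop = FALSE], 2, max)))
    }
    mat <- as.matrix(agg)[levels(f), , drop = FALSE]
    rownames(mat) <- levels(f)
  }
  if (is.null(study_id))
    study_id <- sub("_matrix\\.tsv$", "", basename(matrix_path))
  study_dataset(study_id, mat, groups, country, study_age)
}

#' Write a study dataset as matrix + phenotype TSVs
#'
#' Emits `<study_id>_matrix.tsv` and `<study_id>_phenotype.tsv` in `dir`.
#' Values are printed with enough digits that write/read/write round-trips
#' to byte-identical text.
#'
#' @param study A [study_dataset()].
#' @param dir Output directory (created if needed).
#' @param header Optional comment line (without the leading `#`) prepended
#'   to both files, e.g. a pipeline provenance stamp.
#' @return Invisibly, the two file paths.
#' @export
write_study_dataset <- function(study, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, paste0(study$study_id, "_matrix.tsv"))
  ppath <- file.path(dir, paste0(study$study_id, "_phenotype.tsv"))
  .write_atomic(mpath, function(p) {
    con <- file(p, "w"); on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    writeLines(paste(c("gene_id", colnames(study$matrix)), collapse = "\t"), con)
    body <- apply(study$matrix, 1, function(r) paste(.fmt_num(r), collapse = "\t"))
    writeLines(paste(rownames(study$matrix), body, sep = "\t"), con)
  })
  .write_atomic(ppath, function(p) {
    con <- file(p, "w"); on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    writeLines("sample_id\tgroup", con)
    writeLines(paste(colnames(study$matrix), study$groups, sep = "\t"), con)
  })
  invisible(c(matrix = mpath, phenotype = ppath))
}

#' Read / write a study registry
#'
#' The registry is one row per study: `study_id`, `n_case`, `n_control`,
#' `country`, `study_age`, and the selection fields `organism`,
#' `data_type`, `design`.
#'
#' @param path TSV path.
#' @return `read_study_registry()` returns a data frame.
#' @export
read_study_registry <- function(path) {
  if (!file.exists(path)) .stopf("registry file not found: %s", path)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("study_id", "n_case", "n_control", "country", "study_age")
  if (!all(need %in% names(reg)))
    .stopf("registry %s lacks column(s): %s", path,
           paste(setdiff(need, names(reg)), collapse = ", "))
  if (anyDuplicated(reg$study_id))
    .stopf("registry %s has duplicated study ids", path)
  reg
}

#' @rdname read_study_registry
#' @param registry Registry data frame.
#' @param header Optional `#` comment line prepended to the file.
#' @export
write_study_registry <- function(registry, path, header = NULL) {
  .write_atomic(path, function(p) {
    con <- file(p, "w"); on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(registry, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(path)
}

#' The packaged 16-study thyroid-cancer registry
#'
#' The registry of the 16 public thyroid-cancer case/control array studies
#' (783 cases, 439 controls) with country and study age, used as the
#' default set of study conditions by the simulator.
#'
#' @return Registry data frame (16 rows).
#' @export
default_study_registry <- function() {
  read_study_registry(system.file("extdata", "tc_study_registry.tsv",
                                  package = "megaexpr", mustWork = TRUE))
}

#' Apply the four dataset-selection criteria
#'
#' Keeps registry rows with (1) organism `Homo sapiens`, (2) data type
#' `RNA expression`, (3) total sample size `n_case + n_control >= min_n`,
#' and (4) a case vs healthy-control design (`design == "case_control"`).
#'
#' @param registry Registry data frame (see [read_study_registry()]).
#' @param min_n Minimum total sample size (default 10).
#' @return The filtered registry, original order preserved.
#' @export
select_datasets <- function(registry, min_n = 10) {
  keep <- registry$organism == "Homo sapiens" &
    registry$data_type == "RNA expression" &
    (registry$n_case + registry$n_control) >= min_n &
    registry$design == "case_control"
  registry[keep & !is.na(keep), , drop = FALSE]
}

#' Registry case/control totals
#'
#' @param registry Registry data frame.
#' @return List with `total_cases` and `total_controls`.
#' @export
registry_totals <- function(registry) {
  list(total_cases = sum(registry$n_case),
       total_controls = sum(registry$n_control))
}
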