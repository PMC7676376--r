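# internal helpers shared across modules

# sample variance of each row; n must be >= 2
.row_var <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

#' Canonicalize gene symbols
#'
#' Trims surrounding whitespace and upper-cases symbols so that relation
#' exports, GMT files and expression matrices that mix case (e.g. "FABP4"
#' vs "fabp4") refer to the same gene.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of the same length, trimmed and upper-cased.
#' @export
#' @examples
#' canonical_genes(c(" fabp4", "FABP4 "))
canonical_genes <- function(x) {
  toupper(trimws(as.character(x)))
}

# deterministic per-stream seed derivation; keeps results independent of
# how many draws an earlier stream consumed. Stays below 2^31 - 1.
.derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(as.character(stream))) %% 1000L
  as.integer((as.numeric(seed) + 104729 * as.numeric(index) + 7919 * h) %%
               2147483647)
}

# write a file atomically: writer(path) runs on a temp file which is then
# renamed into place, so a failed stage never leaves a truncated report
.write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# format doubles so that write -> read -> write round-trips to identical
# bytes (%.17g prints enough digits to reparse the exact double)
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
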