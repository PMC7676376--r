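#' Configuration for the multi-study expression simulator
#'
#' Describes a collection of case/control expression studies with known
#' per-gene true log2 fold changes (LFC), between-study heterogeneity and
#' study-level covariates. Defaults reproduce the conditions of the
#' packaged 16-study thyroid-cancer registry ([default_study_registry()]):
#' its case/control sizes, countries and study ages.
#'
#' The generative model: for gene g in study s, log2 expression of a
#' sample is Normal(baseline_log2\[g\] + delta\[g,s\] * is_case, sigma2)
#' and is anti-logged to the linear scale, where
#' delta\[g,s\] = true_lfc\[g\] + moderator shifts + Normal(0, tau2) is the
#' study's realized effect. Each gene is present on a study's platform
#' with probability `coverage_prob`, independently.
#'
#' @param n_studies Number of studies (>= 2).
#' @param n_case,n_control Per-study sample counts; scalars are recycled,
#'   vectors must have length `n_studies`. Defaults: the registry sizes.
#' @param n_genes Number of genes.
#' @param true_lfc True per-gene LFC in log2 units (scalar recycled).
#' @param tau2 Between-study variance of the realized LFC (log2^2 units).
#' @param sigma2 Within-sample log2-expression noise variance (> 0).
#' @param baseline_log2 Per-gene control-group mean log2 expression;
#'   default spans 4..12 evenly.
#' @param coverage_prob Probability a gene is measured on a study's
#'   platform, in (0, 1].
#' @param countries,study_age Per-study covariates; defaults from the
#'   registry, recycled round-robin if `n_studies` differs.
#' @param moderator_effects Optional list of study-level shifts added to
#'   every gene's realized LFC: `country` (named numeric vector of
#'   per-country shifts), `study_age` and `n_sample` (slopes).
#' @param study_ids,gene_ids Optional id vectors.
#' @param seed Mandatory integer RNG seed.
#' @return An object of class `mega_sim_config`.
#' @export
mega_sim_config <- function(n_studies = 16L, n_case = NULL, n_control = NULL,
                            n_genes = 2000L, true_lfc = 0, tau2 = 0,
                            sigma2 = 0.25, baseline_log2 = NULL,
                            coverage_prob = 1, countries = NULL,
                            study_age = NULL, moderator_effects = list(),
                            study_ids = NULL, gene_ids = NULL, seed) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    .stopf("invalid 'seed': an integer seed is mandatory")
  reg <- default_study_registry()
  recycle <- function(x, n, field) {
    if (length(x) == 1L) rep(x, n)
    else if (length(x) == n) x
    else .stopf("invalid '%s': length must be 1 or n_studies (%d)", field, n)
  }
  idx <- ((seq_len(n_studies) - 1L) %% nrow(reg)) + 1L
  if (is.null(n_case)) n_case <- reg$n_case[idx]
  if (is.null(n_control)) n_control <- reg$n_control[idx]
  if (is.null(countries)) countries <- reg$country[idx]
  if (is.null(study_age)) study_age <- reg$study_age[idx]
  if (is.null(study_ids))
    study_ids <- if (n_studies <= nrow(reg)) reg$study_id[idx]
                 else sprintf("STUDY%02d", seq_len(n_studies))

  n_studies <- as.integer(n_studies)
  if (is.na(n_studies) || n_studies < 2L)
    .stopf("invalid 'n_studies': must be an integer >= 2")
  n_case <- as.integer(recycle(n_case, n_studies, "n_case"))
  n_control <- as.integer(recycle(n_control, n_studies, "n_control"))
  if (any(is.na(n_case)) || any(n_case < 1L))
    .stopf("invalid 'n_case': all counts must be >= 1")
  if (any(is.na(n_control)) || any(n_control < 1L))
    .stopf("invalid 'n_control': all counts must be >= 1")
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L)
    .stopf("invalid 'n_genes': must be an integer >= 1")
  if (length(true_lfc) == 1L) true_lfc <- rep(true_lfc, n_genes)
  if (length(true_lfc) != n_genes)
    .stopf("invalid 'true_lfc': length must be 1 or n_genes (%d)", n_genes)
  if (!is.numeric(tau2) || length(tau2) != 1L || is.na(tau2) || tau2 < 0)
    .stopf("invalid 'tau2': must be a single number >= 0")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || is.na(sigma2) || sigma2 <= 0)
    .stopf("invalid 'sigma2': must be a single number > 0")
  if (is.null(baseline_log2))
    baseline_log2 <- if (n_genes == 1L) 8 else seq(4, 12, length.out = n_genes)
  if (length(baseline_log2) == 1L) baseline_log2 <- rep(baseline_log2, n_genes)
  if (length(baseline_log2) != n_genes)
    .stopf("invalid 'baseline_log2': length must be 1 or n_genes (%d)", n_genes)
  if (!is.numeric(coverage_prob) || length(coverage_prob) != 1L ||
      is.na(coverage_prob) || coverage_prob <= 0 || coverage_prob > 1)
    .stopf("invalid 'coverage_prob': must be in (0, 1]")
  countries <- as.character(recycle(countries, n_studies, "countries"))
  study_age <- as.numeric(recycle(study_age, n_studies, "study_age"))
  study_ids <- as.character(recycle(study_ids, n_studies, "study_ids"))
  if (anyDuplicated(study_ids)) .stopf("invalid 'study_ids': must be unique")
  if (is.null(gene_ids)) gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids))
    .stopf("invalid 'gene_ids': must be %d unique ids", n_genes)
  bad <- setdiff(names(moderator_effects), c("country", "study_age", "n_sample"))
  if (length(bad))
    .stopf("invalid 'moderator_effects': unknown component(s) %s",
           paste(bad, collapse = ", "))

  structure(
    list(n_studies = n_studies, n_case = n_case, n_control = n_control,
         n_genes = n_genes, true_lfc = as.numeric(true_lfc),
         tau2 = tau2, sigma2 = sigma2,
         baseline_log2 = as.numeric(baseline_log2),
         coverage_prob = coverage_prob, countries = countries,
         study_age = study_age, moderator_effects = moderator_effects,
         study_ids = study_ids, gene_ids = gene_ids,
         seed = as.integer(seed)),
    class = "mega_sim_config")
}

#' @export
print.mega_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<mega_sim_config> %d studies (%d cases / %d controls), ",
                     "%d genes, tau2=%g, sigma2=%g, coverage=%g, seed=%d\n"),
              x$n_studies, sum(x$n_case), sum(x$n_control), x$n_genes,
              x$tau2, x$sigma2, x$coverage_prob, x$seed))
  invisible(x)
}

# study-level moderator shift added to every gene's realized effect
.moderator_shift <- function(config, s) {
  me <- config$moderator_effects
  shift <- 0
  if (!is.null(me$country)) {
    eff <- me$country[config$countries[s]]
    if (!is.na(eff)) shift <- shift + unname(eff)
  }
  if (!is.null(me$study_age)) shift <- shift + me$study_age * config$study_age[s]
  if (!is.null(me$n_sample))
    shift <- shift + me$n_sample * (config$n_case[s] + config$n_control[s])
  shift
}

# draws one study; returns the dataset plus its slice of the truth
.generate_study_full <- function(config, study_index) {
  s <- as.integer(study_index)
  if (is.na(s) || s < 1L || s > config$n_studies)
    .stopf("invalid 'study_index': must be in 1..%d", config$n_studies)
  set.seed(.derive_seed(config$seed, "study", s))
  G <- config$n_genes
  covered <- stats::runif(G) <= config$coverage_prob
  realized <- config$true_lfc + .moderator_shift(config, s) +
    stats::rnorm(G, 0, sqrt(config$tau2))
  nc <- config$n_case[s]; nk <- config$n_control[s]
  n <- nc + nk
  log2mat <- matrix(stats::rnorm(G * n, sd = sqrt(config$sigma2)),
                    nrow = G, ncol = n) + config$baseline_log2
  case_cols <- nk + seq_len(nc)
  log2mat[, case_cols] <- log2mat[, case_cols] + realized
  mat <- 2^log2mat[covered, , drop = FALSE]
  rownames(mat) <- config$gene_ids[covered]
  colnames(mat) <- c(sprintf("%s_C%02d", config$study_ids[s], seq_len(nk)),
                     sprintf("%s_T%02d", config$study_ids[s], seq_len(nc)))
  ds <- study_dataset(config$study_ids[s], mat,
                      groups = c(rep("control", nk), rep("case", nc)),
                      country = config$countries[s],
                      study_age = config$study_age[s])
  list(dataset = ds, covered = covered, realized = realized)
}

#' Simulate one study of a multi-study collection
#'
#' Deterministic given `config$seed` and `study_index`: the study returned
#' here is identical to the corresponding element of
#' [generate_collection()].
#'
#' @param config A [mega_sim_config()].
#' @param study_index Study number in `1..n_studies`.
#' @return A [study_dataset()] on the linear expression scale; genes not
#'   covered by this study's platform are omitted from the matrix.
#' @export
generate_study <- function(config, study_index) {
  if (!inherits(config, "mega_sim_config"))
    .stopf("'config' must be a mega_sim_config")
  .generate_study_full(config, study_index)$dataset
}

#' Simulate a full multi-study collection with known truth
#'
#' @param config A [mega_sim_config()].
#' @return List with `studies` (list of [study_dataset()]) and `truth`, a
#'   `sim_truth` object holding the per-gene true LFC, the genes x studies
#'   matrix of realized study effects (true LFC + heterogeneity draw +
#'   moderator shifts) and the genes x studies platform-membership flags.
#' @export
generate_collection <- function(config) {
  if (!inherits(config, "mega_sim_config"))
    .stopf("'config' must be a mega_sim_config")
  full <- lapply(seq_len(config$n_studies), .generate_study_full,
                 config = config)
  realized <- matrix(vapply(full, `[[`, numeric(config$n_genes), "realized"),
                     nrow = config$n_genes)
  membership <- matrix(vapply(full, `[[`, logical(config$n_genes), "covered"),
                       nrow = config$n_genes)
  dimnames(realized) <- dimnames(membership) <-
    list(config$gene_ids, config$study_ids)
  truth <- structure(
    list(true_lfc = stats::setNames(config$true_lfc, config$gene_ids),
         realized = realized, membership = membership),
    class = "sim_truth")
  list(studies = lapply(full, `[[`, "dataset"), truth = truth)
}

#' Registry of a simulated collection
#'
#' Builds a selection-compliant registry data frame from simulated
#' studies, mirroring what [read_study_registry()] returns.
#'
#' @param studies List of [study_dataset()] objects.
#' @return Registry data frame.
#' @export
registry_from_studies <- function(studies) {
  data.frame(
    study_id = vapply(studies, `[[`, character(1), "study_id"),
    n_case = vapply(studies, `[[`, integer(1), "n_case"),
    n_control = vapply(studies, `[[`, integer(1), "n_control"),
    country = vapply(studies, `[[`, character(1), "country"),
    study_age = vapply(studies, `[[`, numeric(1), "study_age"),
    organism = "Homo sapiens", data_type = "RNA expression",
    design = "case_control", stringsAsFactors = FALSE)
}

#' Write the simulation truth as a long TSV
#'
#' One row per gene x study: membership flag and realized effect, plus the
#' gene's true LFC.
#'
#' @param truth A `sim_truth` (from [generate_collection()]).
#' @param path Output TSV path.
#' @param header Optional `#` comment line.
#' @export
write_sim_truth <- function(truth, path, header = NULL) {
  long <- data.frame(
    gene = rep(rownames(truth$membership), ncol(truth$membership)),
    study_id = rep(colnames(truth$membership),
                   each = nrow(truth$membership)),
    covered = as.vector(truth$membership),
    realized_lfc = .fmt_num(as.vector(truth$realized)),
    true_lfc = .fmt_num(rep(unname(truth$true_lfc), ncol(truth$membership))),
    stringsAsFactors = FALSE)
  .write_atomic(path, function(p) {
    con <- file(p, "w"); on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  invisible(path)
}

#' Simulate a pair of disease-gene relation tables
#'
#' Emulates a literature-mining export: two tables of
#' (disease, gene, polarity, ref_count) records whose *filter-passing*
#' gene sets (at least `min_refs` supporting references and a specific
#' positive/negative polarity) have the designed sizes and intersect in
#' exactly `n_overlap` genes. A configurable number of extra records that
#' fail the filter is added on decoy genes outside the designed sets.
#'
#' @param n_universe Size of the gene universe symbols are drawn from.
#' @param n_disease_a,n_disease_b Designed filter-passing set sizes.
#' @param n_overlap Designed intersection size.
#' @param seed Integer RNG seed.
#' @param frac_filtered_out Fraction (of each designed set size) of extra
#'   failing records to add (default 0.2).
#' @param diseases Length-2 character vector of disease labels.
#' @return List of two data frames `a` and `b` with columns
#'   `disease`, `gene`, `polarity`, `ref_count`.
#' @export
generate_relation_tables <- function(n_universe, n_disease_a, n_disease_b,
                                     n_overlap, seed,
                                     frac_filtered_out = 0.2,
                                     diseases = c("obesity",
                                                  "thyroid carcinoma")) {
  if (n_overlap > min(n_disease_a, n_disease_b))
    .stopf("n_overlap (%d) exceeds min(n_disease_a, n_disease_b)", n_overlap)
  extra_a <- round(frac_filtered_out * n_disease_a)
  extra_b <- round(frac_filtered_out * n_disease_b)
  need <- n_disease_a + n_disease_b - n_overlap + extra_a + extra_b
  if (need > n_universe)
    .stopf("universe too small: need %d distinct genes, have %d",
           need, n_universe)
  set.seed(.derive_seed(seed, "relations"))
  universe <- sprintf("GENE%05d", seq_len(n_universe))
  picked <- sample(universe, need)
  shared <- picked[seq_len(n_overlap)]
  a_only <- picked[n_overlap + seq_len(n_disease_a - n_overlap)]
  b_only <- picked[n_disease_a + seq_len(n_disease_b - n_overlap)]
  decoys <- picked[(n_disease_a + n_disease_b - n_overlap) +
                     seq_len(extra_a + extra_b)]

  passing <- function(genes, disease) {
    if (!length(genes)) return(NULL)
    data.frame(disease = disease, gene = genes,
               polarity = sample(c("positive", "negative"), length(genes),
                                 replace = TRUE),
               ref_count = sample(3:30, length(genes), replace = TRUE),
               stringsAsFactors = FALSE)
  }
  failing <- function(genes, disease) {
    if (!length(genes)) return(NULL)
    low_refs <- stats::runif(length(genes)) < 0.5
    data.frame(disease = disease, gene = genes,
               polarity = ifelse(low_refs,
                                 sample(c("positive", "negative"),
                                        length(genes), replace = TRUE),
                                 "unknown"),
               ref_count = ifelse(low_refs,
                                  sample(1:2, length(genes), replace = TRUE),
                                  sample(3:30, length(genes), replace = TRUE)),
               stringsAsFactors = FALSE)
  }
  a <- rbind(passing(c(shared, a_only), diseases[1]),
             failing(decoys[seq_len(extra_a)], diseases[1]))
  b <- rbind(passing(c(shared, b_only), diseases[2]),
             failing(decoys[extra_a + seq_len(extra_b)], diseases[2]))
  rownames(a) <- rownames(b) <- NULL
  list(a = a, b = b)
}

#' Simulate a gene-set collection over a gene universe
#'
#' Convenience generator of a GMT-style collection for exercising the
#' enrichment stage: random member draws, with optional seeding of one set
#' with a given gene list.
#'
#' @param gene_ids Character universe to draw members from.
#' @param n_sets Number of sets.
#' @param size_range Length-2 integer range of set sizes.
#' @param include Optional character vector of genes forced into the first
#'   set (e.g. planted targets).
#' @param seed Integer RNG seed.
#' @return List of lists with `set_id`, `name`, `members`.
#' @export
generate_gene_sets <- function(gene_ids, n_sets = 50,
                               size_range = c(10, 100), include = NULL,
                               seed) {
  set.seed(.derive_seed(seed, "genesets"))
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  sets <- lapply(seq_len(n_sets), function(i) {
    members <- sample(gene_ids, min(sizes[i], length(gene_ids)))
    if (i == 1L && !is.null(include))
      members <- unique(c(include, members))
    list(set_id = sprintf("SET%04d", i),
         name = sprintf("synthetic set %d", i),
         members = canonical_genes(members))
  })
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets List of gene sets (`set_id`, `name`, `members`).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  .write_atomic(path, function(p) {
    writeLines(vapply(sets, function(s)
      paste(c(s$set_id, s$name, s$members), collapse = "\t"),
      character(1)), p)
  })
  invisible(path)
}
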