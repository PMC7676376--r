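#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML (or JSON) mapping with blocks:
#' \describe{
#'   \item{`seed`}{integer; mandatory whenever simulation is enabled.}
#'   \item{`sim`}{simulator settings passed to [mega_sim_config()]:
#'     `n_genes`, `tau2`, `sigma2`, `coverage_prob`, plus `n_planted` /
#'     `planted_lfc` (that many leading genes get the planted true LFC).}
#'   \item{`relations`}{`n_universe`, `n_disease_a`, `n_disease_b`,
#'     `n_overlap`, `min_refs`, `overlap_universe`.}
#'   \item{`selection`}{`min_n`.}
#'   \item{`mega`}{`p_max`, `lfc_min_abs`, `min_studies`, `control_mean`.}
#'   \item{`enrichment`}{`n_sets`, `universe_size`, `q_threshold`,
#'     `top_k`.}
#' }
#' Unset values fall back to the defaults of the stage functions.
#'
#' @param path YAML/JSON config path.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config Raw config list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.null(config$seed))
    .stopf("config validation: 'seed' is mandatory when simulation is enabled")
  config$seed <- as.integer(config$seed)
  if (is.na(config$seed)) .stopf("config validation: 'seed' must be an integer")
  num_in <- function(x, lo, hi, name) {
    if (is.null(x)) return(invisible(NULL))
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
      .stopf("config validation: '%s' must be in [%g, %g]", name, lo, hi)
  }
  num_in(config$mega$p_max, 0, 1, "mega.p_max")
  num_in(config$mega$lfc_min_abs, 0, Inf, "mega.lfc_min_abs")
  num_in(config$mega$min_studies, 2, Inf, "mega.min_studies")
  num_in(config$selection$min_n, 0, Inf, "selection.min_n")
  num_in(config$relations$min_refs, 1, Inf, "relations.min_refs")
  num_in(config$enrichment$q_threshold, 0, 1, "enrichment.q_threshold")
  num_in(config$sim$coverage_prob, 1e-12, 1, "sim.coverage_prob")
  num_in(config$sim$tau2, 0, Inf, "sim.tau2")
  structure(config, class = "pipeline_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

.get <- function(x, name, default) {
  if (is.null(x[[name]])) default else x[[name]]
}

#' Run the full simulate/overlap/select/mega/moderators/enrich pipeline
#'
#' Executes the five analysis stages in order on a freshly simulated
#' collection, writing every report atomically under `out_dir` together
#' with a run manifest (config hash, seed, package version, file list).
#' Rerunning with the same config and seed reproduces identical bytes.
#'
#' @param config A `pipeline_config`, a raw list, or a YAML path.
#' @param out_dir Output directory.
#' @param verbose Log each stage to the console.
#' @return Invisibly, a named list of report paths.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  stamp <- sprintf("megaexpr pipeline; config=%s; seed=%d", hash, config$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  reports <- list()

  ## stage 1: simulate ------------------------------------------------
  say("stage simulate")
  sim <- config$sim
  collection <- relpair <- NULL
  stage("simulate", {
    n_genes <- .get(sim, "n_genes", 500L)
    true_lfc <- rep(0, n_genes)
    n_planted <- .get(sim, "n_planted", 0L)
    if (n_planted > 0)
      true_lfc[seq_len(n_planted)] <- .get(sim, "planted_lfc", -1.8)
    scfg <- mega_sim_config(
      n_genes = n_genes, true_lfc = true_lfc,
      tau2 = .get(sim, "tau2", 0), sigma2 = .get(sim, "sigma2", 0.25),
      coverage_prob = .get(sim, "coverage_prob", 1),
      seed = .derive_seed(config$seed, "simulate"))
    collection <- generate_collection(scfg)
    dat_dir <- file.path(out_dir, "data")
    for (st in collection$studies) write_study_dataset(st, dat_dir, stamp)
    reg <- registry_from_studies(collection$studies)
    reports$registry <- write_study_registry(
      reg, file.path(out_dir, "registry.tsv"), stamp)
    reports$truth <- write_sim_truth(
      collection$truth, file.path(out_dir, "truth.tsv"), stamp)
    rl <- config$relations
    relpair <- generate_relation_tables(
      n_universe = .get(rl, "n_universe", 20000L),
      n_disease_a = .get(rl, "n_disease_a", 534L),
      n_disease_b = .get(rl, "n_disease_b", 1036L),
      n_overlap = .get(rl, "n_overlap", 176L),
      seed = .derive_seed(config$seed, "relations"))
    for (side in c("a", "b")) {
      path <- file.path(out_dir, sprintf("relations_%s.tsv", side))
      .write_atomic(path, function(p) {
        con <- file(p, "w"); on.exit(close(con))
        writeLines(paste0("# ", stamp), con)
        utils::write.table(relpair[[side]], con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      })
      reports[[paste0("relations_", side)]] <- path
    }
  })

  ## stage 2: relations overlap --------------------------------------
  say("stage overlap")
  stage("overlap", {
    rl <- config$relations
    min_refs <- .get(rl, "min_refs", 3)
    fa <- filter_relations(relpair$a, min_refs = min_refs)
    fb <- filter_relations(relpair$b, min_refs = min_refs)
    sets <- gene_sets(fa, fb)
    ov <- overlap_analysis(sets$a, sets$b,
                           .get(rl, "overlap_universe",
                                .get(rl, "n_universe", 20000L)))
    reports$overlap <- file.path(out_dir, "overlap.json")
    .write_atomic(reports$overlap, function(p)
      jsonlite::write_json(c(unclass(ov),
                             list(n_a_only = length(sets$a_only),
                                  config = hash, seed = config$seed)),
                           p, auto_unbox = TRUE, digits = NA))
    say("  overlap %d of %d (%.2f%%), p = %.3g", ov$n_overlap, ov$n_a,
        ov$pct_of_a, ov$fisher_p)
  })

  ## stage 3: dataset selection --------------------------------------
  say("stage select")
  selected <- NULL
  stage("select", {
    reg <- read_study_registry(reports$registry)
    selected <- select_datasets(reg, min_n = .get(config$selection, "min_n", 10))
    reports$selected_registry <- write_study_registry(
      selected, file.path(out_dir, "selected_registry.tsv"), stamp)
  })

  ## stage 4: mega-analysis ------------------------------------------
  say("stage mega")
  fit <- targets <- NULL
  stage("mega", {
    mg <- config$mega
    studies <- collection$studies[
      vapply(collection$studies, `[[`, character(1), "study_id") %in%
        selected$study_id]
    fit <- mega_analysis(studies,
                          min_studies = .get(mg, "min_studies", 2),
                          control_mean = .get(mg, "control_mean", "geometric"))
    reports$mega <- file.path(out_dir, "mega_results.tsv")
    .write_atomic(reports$mega, function(p) {
      con <- file(p, "w"); on.exit(close(con))
      writeLines(paste0("# ", stamp), con)
      utils::write.table(fit$results, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    targets <- select_significant(fit, p_max = .get(mg, "p_max", 1e-7),
                                   lfc_min_abs = .get(mg, "lfc_min_abs", 1))
    reports$targets <- file.path(out_dir, "targets.tsv")
    .write_atomic(reports$targets, function(p) {
      con <- file(p, "w"); on.exit(close(con))
      writeLines(paste0("# ", stamp), con)
      utils::write.table(targets, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    say("  %d significant target(s)", nrow(targets))
  })

  ## stage 5: moderators ----------------------------------------------
  say("stage moderators")
  stage("moderators", {
    genes <- if (nrow(targets)) targets$gene else
      utils::head(fit$results$gene[order(fit$results$p)], 5)
    mod <- moderator_scan(fit, genes = genes)
    reports$moderators <- file.path(out_dir, "moderators.tsv")
    .write_atomic(reports$moderators, function(p) {
      con <- file(p, "w"); on.exit(close(con))
      writeLines(paste0("# ", stamp), con)
      utils::write.table(mod, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  })

  ## stage 6: enrichment ----------------------------------------------
  say("stage enrich")
  stage("enrich", {
    en <- config$enrichment
    gene_ids <- rownames(collection$truth$membership)
    sets <- generate_gene_sets(
      gene_ids, n_sets = .get(en, "n_sets", 50),
      include = if (nrow(targets)) targets$gene else NULL,
      seed = .derive_seed(config$seed, "enrich"))
    reports$gene_sets <- write_gmt(sets, file.path(out_dir, "gene_sets.gmt"))
    query <- if (nrow(targets)) targets$gene else
      utils::head(fit$results$gene[order(fit$results$p)], 5)
    res <- enrich(query, sets,
                  universe_size = .get(en, "universe_size", NULL),
                  q_threshold = .get(en, "q_threshold", 0.005))
    reports$enrichment <- write_enrichment(
      res, file.path(out_dir, "enrichment.tsv"), stamp)
    M <- shared_pathway_matrix(res, genes = query)
    reports$shared_matrix <- file.path(out_dir, "shared_pathways.tsv")
    .write_atomic(reports$shared_matrix, function(p) {
      con <- file(p, "w"); on.exit(close(con))
      writeLines(paste0("# ", stamp), con)
      utils::write.table(cbind(gene = rownames(M), as.data.frame(M)),
                         con, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  })

  ## manifest ----------------------------------------------------------
  manifest <- list(config_hash = hash, seed = config$seed,
                   package = "megaexpr",
                   version = as.character(utils::packageVersion("megaexpr")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   reports = lapply(reports, basename))
  reports$manifest <- file.path(out_dir, "manifest.json")
  .write_atomic(reports$manifest, function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE))
  say("pipeline complete: %d reports in %s", length(reports), out_dir)
  invisible(reports)
}
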