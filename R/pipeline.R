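## End-to-end orchestration: variance filter -> correlation -> soft
## threshold -> adjacency -> TOM -> tree -> cut/merge (+ sweep) -> eigengenes
## -> module-trait -> differential co-expression / preservation -> hub
## signatures -> validation scoring -> candidate table -> ORA, with a JSON
## manifest recording configuration, seeds and per-stage outputs.

#' Pipeline configuration
#'
#' Collects every stage's settings with the analysis defaults: top 20%
#' variance filter, biweight midcorrelation, soft power 8, dynamic hybrid
#' cut with deep split 2 / minimum module size 30 / merge threshold 0.15 /
#' PAM stage on, 200 permutations, top 120 hub genes per module signature,
#' module chosen by strongest |driver correlation|, 47 flagged candidates at
#' the p < 0.05 driver screen.
#'
#' @param expression path to the expression TSV (or a matrix).
#' @param traits path to the trait TSV (or a data.frame); needs `condition`
#'   and `pair` columns for the paired stages.
#' @param driver driver gene ID anchoring the prioritization.
#' @param output_dir directory for stage outputs.
#' @param validation optional path/matrix of a validation cohort.
#' @param test_expression optional path/matrix of a second dataset for
#'   cross-dataset preservation.
#' @param gene_sets optional GMT path (or named list) for ORA and the
#'   reference signature.
#' @param reference_signature optional gene set (or name of a `gene_sets`
#'   entry) for signature validation.
#' @param filter_fraction variance-filter fraction.
#' @param network a [network_config()].
#' @param cut a [cut_params()].
#' @param sweep_grid hyperparameter grid (`NULL` disables the sweep).
#' @param betas candidate soft powers for the threshold report.
#' @param n_perm permutations for preservation / differential co-expression.
#' @param top_k_hubs hub genes per module signature.
#' @param direction expected driver-correlation sign of candidates.
#' @param n_candidates candidates to flag.
#' @param alpha driver-screen p threshold.
#' @param seed master seed for all permutation stages.
#' @return list of class `cx_pipeline_config`.
#' @export
pipeline_config <- function(expression, traits, driver, output_dir,
                            validation = NULL, test_expression = NULL,
                            gene_sets = NULL, reference_signature = NULL,
                            filter_fraction = 0.20,
                            network = network_config(),
                            cut = cut_params(),
                            sweep_grid = default_sweep_grid(),
                            betas = c(1:10, 12, 14, 16, 18, 20),
                            n_perm = 200L, top_k_hubs = 120L,
                            direction = "negative", n_candidates = 47L,
                            alpha = 0.05, seed = 1L) {
  for (p in list(expression, traits, validation, test_expression, gene_sets)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      cx_stop("E_NO_FILE", paste("input path does not exist:", p))
    }
  }
  structure(as.list(environment()), class = "cx_pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar keys mirror the arguments of [pipeline_config()]; `network` and
#' `cut` may be given as nested maps.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a `cx_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) cx_stop("E_NO_FILE", paste("config not found:", path))
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$network)) raw$network <- do.call(network_config, raw$network)
  if (!is.null(raw$cut)) raw$cut <- do.call(cut_params, raw$cut)
  if (!is.null(raw$sweep_grid) && is.list(raw$sweep_grid)) {
    raw$sweep_grid <- as.data.frame(raw$sweep_grid)
  }
  do.call(pipeline_config, raw)
}

load_expr <- function(x, min_present = 0.8) {
  if (is.character(x)) read_expression(x, min_present = min_present) else
    validate_expression(x, min_present = min_present)
}

#' Run the full co-expression analysis pipeline
#'
#' Executes every stage on the configured inputs, writes per-stage
#' machine-readable outputs (TSV/JSON) into the output directory, and
#' returns a manifest describing what ran. Reruns with identical
#' configuration and seed reproduce identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  stages <- character(0)
  files <- list()
  note <- function(stage, ...) {
    stages <<- c(stages, stage)
    files[[stage]] <<- c(files[[stage]], unlist(list(...)))
    cx_log("info", "I_STAGE", paste("completed:", stage))
  }

  expr <- load_expr(cfg$expression)
  traits <- if (is.character(cfg$traits)) read_traits(cfg$traits) else cfg$traits
  if (!cfg$driver %in% rownames(expr)) {
    cx_stop("E_NO_DRIVER", sprintf("driver '%s' not in expression data", cfg$driver))
  }

  ## 1. variance filter (driver retained alongside for anchoring)
  filt <- filter_top_variable(expr, cfg$filter_fraction)
  if (!cfg$driver %in% rownames(filt)) {
    cx_log("info", "I_DRIVER_KEPT", "driver below variance cutoff; retained for anchoring")
    filt <- rbind(filt, expr[cfg$driver, , drop = FALSE])
    rownames(filt)[nrow(filt)] <- cfg$driver
  }
  write_expression(filt, out("filtered_expression.tsv"))
  note("filter", "filtered_expression.tsv")

  ## 2. correlation + soft-threshold report + adjacency + TOM
  cm <- correlation_matrix(filt, method = cfg$network$method,
                           min_pairs = cfg$network$min_pairs)
  pst <- pick_soft_threshold(cm, betas = cfg$betas, config = cfg$network)
  utils::write.table(pst$table, out("soft_threshold.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("soft_threshold", "soft_threshold.tsv")
  adj <- adjacency_matrix(cm, cfg$network)
  tom <- tom_similarity(adj)
  note("network")

  ## 3. tree + cut + merge (+ sweep)
  tree <- linkage_tree(tom$dissim)
  part0 <- cut_dynamic_hybrid(tree, tom$dissim, cfg$cut)
  merged <- if (part0$n_modules > 1L) {
    merge_close_modules(filt, part0, cfg$cut$merge_threshold)
  } else list(partition = part0,
              eigengenes = if (part0$n_modules > 0) module_eigengenes(filt, part0) else NULL)
  part <- merged$partition
  eg <- merged$eigengenes
  if (is.null(eg)) cx_stop("E_NO_MODULES", "no modules detected")
  utils::write.table(
    data.frame(gene_id = names(part$labels), label = unname(part$labels),
               color = unname(part$colors)),
    out("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(eg$me, out("eigengenes.tsv"), id_name = "sample_id")
  note("modules", "modules.tsv", "eigengenes.tsv")

  sweep <- NULL
  if (!is.null(cfg$sweep_grid) && nrow(cfg$sweep_grid)) {
    sweep <- hyperparameter_sweep(filt, tom$dissim, cfg$sweep_grid, tree = tree,
                                  cut_height = cfg$cut$cut_height)
    jsonlite::write_json(list(grid = sweep$grid, n_modules = sweep$n_modules,
                              sizes = sweep$sizes, ari = sweep$ari,
                              median_ari = sweep$median_ari),
                         out("sweep.json"), auto_unbox = TRUE, digits = NA)
    note("sweep", "sweep.json")
  }

  ## 4. module-trait / module-driver correlations
  tr_num <- traits
  tr_num$driver_expr <- as.numeric(expr[cfg$driver, match(traits$sample_id, colnames(expr))])
  case_samples <- if ("condition" %in% colnames(traits)) {
    traits$sample_id[traits$condition == 1L]
  } else traits$sample_id
  mt <- module_trait_correlation(eg, tr_num,
                                 sample_subset = if (length(case_samples) >= 4L)
                                   case_samples else NULL)
  mt_tab <- data.frame(module = rep(rownames(mt$r), ncol(mt$r)),
                       trait = rep(colnames(mt$r), each = nrow(mt$r)),
                       R = as.numeric(mt$r), p = as.numeric(mt$p), n = mt$n)
  utils::write.table(mt_tab, out("module_trait.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("module_trait", "module_trait.tsv")

  ## 5. differential co-expression across conditions (paired design)
  dc <- NULL
  if (all(c("condition", "pair") %in% colnames(traits)) && !anyNA(traits$pair)) {
    dc <- diff_coexpression(filt, traits, part, n_perm = cfg$n_perm,
                            seed = cfg$seed, paired = TRUE)
    jsonlite::write_json(list(D = as.list(dc$D), p = as.list(dc$p),
                              preserved = as.list(dc$preserved)),
                         out("diffcoex.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(dc$gene, out("diffcoex_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("diffcoex", "diffcoex.json", "diffcoex_genes.tsv")
  }

  ## 6. cross-dataset preservation
  pres <- NULL
  if (!is.null(cfg$test_expression)) {
    test_expr <- load_expr(cfg$test_expression)
    pres <- permutation_preservation(filt, test_expr, part, cfg$network,
                                     n_perm = cfg$n_perm, seed = cfg$seed)
    jsonlite::write_json(list(observed = as.data.frame(pres$observed),
                              z = as.data.frame(pres$z),
                              p = as.data.frame(pres$p),
                              zsummary = as.list(pres$zsummary),
                              preserved = as.list(pres$preserved)),
                         out("preservation.json"), auto_unbox = TRUE, digits = NA)
    note("preservation", "preservation.json")
  }

  ## 7. hub statistics and module selection by driver correlation
  gstats <- gene_module_stats(filt, part, adj, eg)
  utils::write.table(gstats, out("gene_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("gene_stats", "gene_stats.tsv")
  dr_col <- mt$r[, "driver_expr"]
  target_module <- as.integer(sub("^ME", "", names(dr_col)[which.max(abs(dr_col))]))
  if (cfg$direction == "negative") {
    neg <- dr_col[dr_col < 0]
    if (length(neg)) target_module <- as.integer(sub("^ME", "", names(neg)[which.max(abs(neg))]))
  }

  ## 8. hub signatures + validation scoring
  hub_sigs <- lapply(eg$modules, function(q)
    suppressWarnings(top_hub_genes(gstats, q, cfg$top_k_hubs)))
  names(hub_sigs) <- paste0("ME", eg$modules)
  val_tab <- NULL
  if (!is.null(cfg$validation)) {
    vexpr <- load_expr(cfg$validation)
    gene_sets <- if (is.character(cfg$gene_sets)) read_gmt(cfg$gene_sets) else cfg$gene_sets
    ref_sig <- cfg$reference_signature
    if (is.character(ref_sig) && length(ref_sig) == 1L && !is.null(gene_sets) &&
        ref_sig %in% names(gene_sets)) {
      ref_sig <- gene_sets[[ref_sig]]
    }
    if (!is.null(ref_sig)) {
      val_tab <- validate_signature(vexpr, hub_sigs, ref_sig)
      utils::write.table(val_tab, out("signature_validation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note("signature_validation", "signature_validation.tsv")
    }
  }

  ## 9. candidate ranking in the driver-anchored module
  cand <- rank_candidates(filt, part, gstats, target_module, cfg$driver,
                          direction = cfg$direction, N = cfg$n_candidates,
                          alpha = cfg$alpha,
                          sample_subset = if (length(case_samples) >= 4L)
                            case_samples else NULL)
  ## paired DE confirmation for the flagged candidates
  if (all(c("condition", "pair") %in% colnames(traits)) && !anyNA(traits$pair) &&
      any(cand$top_n)) {
    de <- paired_de_test(expr, traits, cand$gene_id[cand$top_n])
    cand$de_t <- de$t[match(cand$gene_id, de$gene_id)]
    cand$de_p <- de$p[match(cand$gene_id, de$gene_id)]
  }
  utils::write.table(cand, out("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("candidates", "candidates.tsv")

  ## 10. ORA of the flagged candidates
  if (!is.null(cfg$gene_sets)) {
    gene_sets <- if (is.character(cfg$gene_sets)) read_gmt(cfg$gene_sets) else cfg$gene_sets
    ora <- ora_hypergeometric(cand$gene_id[cand$top_n], gene_sets, rownames(filt))
    utils::write.table(ora, out("ora.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    note("ora", "ora.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("coexmod")),
    seed = cfg$seed,
    beta = cfg$network$beta,
    chosen_beta = pst$beta,
    n_genes_analyzed = nrow(filt),
    n_modules = part$n_modules,
    module_sizes = part$sizes,
    target_module = target_module,
    stages = stages,
    outputs = files,
    output_hashes = as.list(tools::md5sum(
      file.path(cfg$output_dir, unlist(files, use.names = FALSE))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
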