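#' Run the full multi-omic pipeline
#'
#' Orchestrates, from files on disk: methylation probe QC and beta values,
#' region and gene-level aggregation, differential methylation, the
#' co-expression and co-methylation networks with modules, a random-forest
#' GRN, regulator enrichment, and cross-layer integration statistics. Each
#' stage writes its table under `out_dir` and logs a line with its
#' parameters and row counts; failures abort naming the stage. A JSON
#' sidecar records the effective configuration and seed so a rerun with
#' the same inputs and seed reproduces every table byte for byte.
#'
#' Config sections (INI file, see [parse_config]) and their defaults mirror
#' the stage function defaults: `[inputs]` expression, design, tf_list,
#' gene_set, and optionally meth_m, meth_u, meth_annotation, detection_p,
#' bead_count; `[methylation]` offset, fail_fraction, min_beads,
#' detection_alpha, fdr_alpha, test_term; `[network]` power_expr,
#' power_meth, min_module_size, merge_height, edge_threshold; `[grn]`
#' n_trees, min_samples_expressed, fit_threshold; `[enrichment]`
#' top_fraction, alpha_e, alpha_d, log2fc_cutoff, mode.
#'
#' @param config nested list from [parse_config] (or equivalent).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; overrides `config$global$seed`.
#' @return invisibly, the list of artifact paths written.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  known <- c("global", "inputs", "methylation", "network", "grn",
             "enrichment")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(seed)) seed <- config$global$seed
  if (is.null(seed)) seed <- 1
  seed <- as.integer(seed)
  cfg <- function(section, key, default) {
    v <- config[[section]][[key]]
    if (is.null(v)) default else v
  }
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE))
  }
  artifacts <- character()
  emit <- function(name, df) {
    path <- file.path(out_dir, name)
    write_table_tsv(df, path)
    artifacts <<- c(artifacts, path)
    path
  }

  inputs <- config$inputs
  if (is.null(inputs$expression)) stop("config [inputs] expression is required")
  if (is.null(inputs$tf_list)) stop("config [inputs] tf_list is required")
  expr <- run_stage("read_expression", function()
    read_expression(inputs$expression, inputs$design))
  tf_list <- read_id_list(inputs$tf_list)
  gene_set <- if (!is.null(inputs$gene_set)) read_id_list(inputs$gene_set)
  logf("inputs", nrow(expr$values), " genes x ", ncol(expr$values),
       " samples; ", length(tf_list), " TFs")

  # ---- methylation layer (optional) --------------------------------------
  gene_beta <- NULL
  meth_design <- NULL
  if (!is.null(inputs$meth_m)) {
    meth <- run_stage("read_methylation", function()
      read_methylation(inputs$meth_m, inputs$meth_u, inputs$meth_annotation,
                       inputs$detection_p, inputs$bead_count))
    fail_fraction <- cfg("methylation", "fail_fraction", 0.05)
    detection_alpha <- cfg("methylation", "detection_alpha", 0.01)
    min_beads <- cfg("methylation", "min_beads", 3)
    offset <- cfg("methylation", "offset", 100)
    fdr_alpha <- cfg("methylation", "fdr_alpha", 0.05)
    test_term <- cfg("methylation", "test_term", "condition")
    meth_q <- run_stage("filter_probes", function()
      filter_probes(meth, fail_fraction, min_beads, detection_alpha))
    logf("filter_probes", "retained ", nrow(meth_q$M), "/", nrow(meth$M),
         " probes (fail_fraction=", fail_fraction, ", min_beads=", min_beads,
         ", detection_alpha=", detection_alpha, ")")
    beta <- run_stage("compute_beta", function()
      compute_beta(meth_q, offset = offset))
    region_beta <- run_stage("aggregate_regions", function()
      aggregate_regions(beta, meth_q$annotation))
    meth_design <- read_table_tsv(inputs$design)
    meth_design <- meth_design[match(colnames(region_beta$beta),
                                     meth_design$sample_id), , drop = FALSE]
    dm <- run_stage("differential_methylation", function()
      differential_linear_model(region_beta$beta, meth_design,
                                test_term = test_term,
                                fdr_alpha = fdr_alpha))
    dm <- cbind(dm, region_beta$feature_info[
      match(dm$feature_id, region_beta$feature_info$unit),
      c("gene", "region")])
    emit("differential_methylation.tsv", dm)
    dmg <- call_dmg(dm)
    emit("dmg.tsv", dmg)
    logf("differential_methylation", sum(dm$significant), " significant units; ",
         sum(dmg$dmg), " DMGs (test_term=", test_term, ")")
    gene_beta <- run_stage("assign_gene_beta", function()
      assign_gene_beta(region_beta, dm))
    if (nrow(gene_beta$beta) > 0) {
      write_matrix_tsv(gene_beta$beta, file.path(out_dir, "gene_beta.tsv"),
                       row_label = "gene")
      artifacts <- c(artifacts, file.path(out_dir, "gene_beta.tsv"))
    }
    logf("assign_gene_beta", nrow(gene_beta$beta), " genes with a DM region")
  }

  # ---- networks ----------------------------------------------------------
  power_expr <- cfg("network", "power_expr", 6)
  min_module_size <- cfg("network", "min_module_size", 30)
  merge_height <- cfg("network", "merge_height", 0.25)
  edge_threshold <- cfg("network", "edge_threshold", 0.02)
  coexpr <- run_stage("coexpression_network", function() {
    adj <- adjacency(expr, power = power_expr)
    tom <- topological_overlap(adj)
    det <- detect_modules(tom, min_size = min_module_size)
    dec <- merge_modules(expr, det$labels, merge_height = merge_height,
                         power = power_expr)
    list(tom = tom, decomp = dec)
  })
  logf("coexpression_network", length(setdiff(unique(coexpr$decomp$labels), 0)),
       " modules (power=", power_expr, ", min_size=", min_module_size,
       ", merge_height=", merge_height, ")")
  emit("coexpression_modules.tsv", .module_table(coexpr$decomp))
  emit("coexpression_edges.tsv",
       export_edges(coexpr$tom, threshold = edge_threshold,
                    labels = coexpr$decomp$labels))

  comet_decomp <- NULL
  if (!is.null(gene_beta) && nrow(gene_beta$beta) >= 2 * min_module_size) {
    power_meth <- cfg("network", "power_meth", 12)
    comet <- run_stage("comethylation_network", function() {
      adj <- adjacency(gene_beta$beta, power = power_meth)
      tom <- topological_overlap(adj)
      det <- detect_modules(tom, min_size = min_module_size)
      dec <- merge_modules(gene_beta$beta, det$labels,
                           merge_height = merge_height, power = power_meth)
      list(tom = tom, decomp = dec)
    })
    comet_decomp <- comet$decomp
    logf("comethylation_network",
         length(setdiff(unique(comet_decomp$labels), 0)), " modules (power=",
         power_meth, ")")
    emit("comethylation_modules.tsv", .module_table(comet_decomp))
    emit("comethylation_edges.tsv",
         export_edges(comet$tom, threshold = edge_threshold,
                      labels = comet_decomp$labels))
  }

  # ---- GRN + regulator enrichment ----------------------------------------
  mode <- cfg("enrichment", "mode", "grn")
  n_trees <- cfg("grn", "n_trees", 1000)
  fit_threshold <- cfg("grn", "fit_threshold", 0.5)
  min_samples_expressed <- cfg("grn", "min_samples_expressed", 10)
  top_fraction <- cfg("enrichment", "top_fraction", 0.05)
  alpha_e <- cfg("enrichment", "alpha_e", 0.05)
  alpha_d <- cfg("enrichment", "alpha_d", 0.05)
  log2fc_cutoff <- cfg("enrichment", "log2fc_cutoff", 0.6)
  if (is.null(gene_set))
    stop("config [inputs] gene_set is required for regulator enrichment")
  reg <- run_stage("regenrich", function()
    run_regenrich(expr, tf_list, gene_set, network_mode = mode,
                  top_fraction = top_fraction, power = power_expr,
                  edge_threshold = edge_threshold, alpha_e = alpha_e,
                  alpha_d = alpha_d, seed = seed, n_trees = n_trees,
                  fit_threshold = fit_threshold,
                  min_samples_expressed = min_samples_expressed))
  logf("regenrich", nrow(reg), " regulators scored; ", sum(reg$key_tf),
       " key TFs (mode=", mode, ", top_fraction=", top_fraction,
       ", n_trees=", n_trees, ", seed=", seed, ")")
  emit("regulator_table.tsv", as.data.frame(reg))
  tfnet <- tf_tf_network(reg, attr(attr(reg, "tf_targets"), "edges"),
                         log2fc_cutoff = log2fc_cutoff)
  emit("tf_tf_edges.tsv", tfnet$edges)
  emit("tf_tf_nodes.tsv", tfnet$nodes)

  # ---- integration --------------------------------------------------------
  if (!is.null(comet_decomp)) {
    xc <- eigengene_cross_correlation(coexpr$decomp$eigengenes,
                                      comet_decomp$eigengenes)
    emit("eigengene_cross_correlation.tsv",
         data.frame(expr_module = rep(rownames(xc$rho), ncol(xc$rho)),
                    meth_module = rep(colnames(xc$rho),
                                      each = nrow(xc$rho)),
                    spearman_r = as.vector(xc$rho), p = as.vector(xc$p)))
    shared_genes <- intersect(names(coexpr$decomp$labels),
                              names(comet_decomp$labels))
    if (length(shared_genes) > 0) {
      ov <- module_overlap(coexpr$decomp$labels[shared_genes],
                           comet_decomp$labels[shared_genes])
      emit("module_overlap.tsv", ov)
    }
    logf("integration", "eigengene cross-correlation and module overlap written")
  }
  if (!is.null(expr$design) &&
      all(c("condition", "day") %in% names(expr$design))) {
    traits <- expr$design[, intersect(c("condition", "day", "stim"),
                                      names(expr$design)), drop = FALSE]
    # drop degenerate traits (e.g. stim when no stimulation samples exist)
    traits <- traits[, vapply(traits, function(t) stats::sd(t) > 0,
                              logical(1)), drop = FALSE]
    tc <- trait_correlation(coexpr$decomp$eigengenes, traits)
    emit("trait_correlation.tsv",
         data.frame(module = rep(rownames(tc$r), ncol(tc$r)),
                    trait = rep(colnames(tc$r), each = nrow(tc$r)),
                    pearson_r = as.vector(tc$r), p = as.vector(tc$p)))
    mds <- classical_mds(t(expr$values), k = 2)
    emit("mds_coordinates.tsv",
         cbind(data.frame(sample_id = rownames(mds)), as.data.frame(mds),
               expr$design[rownames(mds),
                           setdiff(names(expr$design), "sample_id"),
                           drop = FALSE]))
    logf("integration", "trait correlations and MDS coordinates written")
  }

  meta <- list(seed = seed, config = config,
               package_version = as.character(utils::packageVersion("regenet")),
               metadata = attr(reg, "metadata"))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  artifacts <- c(artifacts, file.path(out_dir, "run_metadata.json"), log_path)
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.module_table <- function(decomp) {
  labels <- decomp$labels
  own <- ifelse(labels == 0, NA_real_, NA_real_)
  if (!is.null(decomp$membership)) {
    for (g in names(labels)) {
      if (labels[g] != 0)
        own[match(g, names(labels))] <-
          decomp$membership[g, paste0("M", labels[g])]
    }
  }
  data.frame(gene = names(labels), module = unname(labels),
             membership_in_own_module = unname(own),
             stringsAsFactors = FALSE)
}
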