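#' Specification for the synthetic multi-omic fixture
#'
#' Describes a desk-scale emulation of a longitudinal two-condition
#' monocyte-differentiation study: paired donors sampled over several days
#' with and without a differentiating stimulus, profiled on an expression
#' layer (variance-stabilized scale) and a methylation layer (array-style
#' M/U intensities). Planted structure — co-expression modules, TF-driven
#' targets, condition effects, differentially methylated regions, and
#' probes violating each QC rule — makes every pipeline stage's recovery
#' testable.
#'
#' @param n_donors number of donors (default 5).
#' @param timepoints day values; the default covers the full longitudinal
#'   design — differentiation days 0/2/4/6 plus post-stimulation
#'   timepoints 7, 7+4h and 8 (days >= 7 are marked as stimulation
#'   samples), giving 70 samples with 5 donors and 2 conditions.
#' @param n_genes total genes (default 300).
#' @param n_tfs number of genes designated transcription regulators
#'   (default 30).
#' @param n_modules planted co-expression modules (default 5).
#' @param module_size genes per module (default 40).
#' @param within_module_cor target within-module correlation in \[0, 1)
#'   (default 0.8).
#' @param planted_regulators named list TF index -> list(n_targets,
#'   effect); default two regulators with 50 and 20 targets.
#' @param noise_sd residual noise sd (default 0.3).
#' @param condition_effect additive shift on planted condition-responsive
#'   genes (default 1.0).
#' @param donor_sd sd of donor random intercepts (default 0.3).
#' @param dm_fraction fraction of (gene, region) units planted as
#'   differentially methylated (default 0.1).
#' @param dm_effect beta shift of planted DM units (default 0.2).
#' @param beta_modes low/high centers of the bimodal beta mixture
#'   (default c(0.1, 0.8)).
#' @param qc_fraction fraction of probes planted to violate each QC rule
#'   (default 0.02).
#' @param seed master seed (default 1).
#' @return `fixture_spec` list.
#' @export
fixture_spec <- function(n_donors = 5,
                         timepoints = c(0, 2, 4, 6, 7, 7 + 4 / 24, 8),
                         n_genes = 300, n_tfs = 30, n_modules = 5,
                         module_size = 40, within_module_cor = 0.8,
                         planted_regulators = list(
                           list(n_targets = 50, effect = 1.0),
                           list(n_targets = 20, effect = 0.8)),
                         noise_sd = 0.3, condition_effect = 1.0,
                         donor_sd = 0.3, dm_fraction = 0.1, dm_effect = 0.2,
                         beta_modes = c(0.1, 0.8), qc_fraction = 0.02,
                         seed = 1) {
  spec <- list(n_donors = n_donors, timepoints = timepoints,
               n_genes = n_genes, n_tfs = n_tfs, n_modules = n_modules,
               module_size = module_size,
               within_module_cor = within_module_cor,
               planted_regulators = planted_regulators,
               noise_sd = noise_sd, condition_effect = condition_effect,
               donor_sd = donor_sd, dm_fraction = dm_fraction,
               dm_effect = dm_effect, beta_modes = beta_modes,
               qc_fraction = qc_fraction, seed = seed)
  with(spec, {
    stopifnot(n_donors > 0, n_genes > 0, n_tfs > 1, n_modules > 0,
              module_size > 0, length(timepoints) > 0)
    if (within_module_cor < 0 || within_module_cor >= 1)
      stop("within_module_cor must lie in [0, 1)")
    # baselines are clamped to <= 1 - dm_effect - 0.02, so the shift stays
    # inside [0, 1) as long as that headroom exists at all
    if (dm_effect < 0 || dm_effect >= 0.96)
      stop("dm_effect would push beta outside [0, 1)")
    n_target_genes <- sum(vapply(planted_regulators, `[[`, numeric(1),
                                 "n_targets"))
    if (n_tfs + n_modules * module_size + n_target_genes > n_genes)
      stop("n_genes too small for the requested TFs, modules and targets")
    if (n_tfs < length(planted_regulators) + n_modules)
      stop("n_tfs must cover the planted regulators plus one TF per module")
  })
  structure(spec, class = "fixture_spec")
}

.fixture_design <- function(spec) {
  grid <- expand.grid(donor = seq_len(spec$n_donors), day = spec$timepoints,
                      condition = c(0, 1), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$condition, grid$day, grid$donor), , drop = FALSE]
  grid$stim <- as.integer(grid$day >= 7)
  grid$sample_id <- sprintf("S%03d", seq_len(nrow(grid)))
  grid$donor <- paste0("D", grid$donor)
  rownames(grid) <- grid$sample_id
  grid[, c("sample_id", "donor", "day", "condition", "stim")]
}

#' Generate a planted-structure expression matrix
#'
#' Builds a gene x sample matrix on a variance-stabilized-like scale with:
#' block-correlated module genes (shared latent factor, within-module
#' correlation `within_module_cor`), TF profiles, regulator-driven target
#' genes (weighted sum of planted TFs plus noise), donor random
#' intercepts, and an additive condition effect on the planted regulators
#' and their targets.
#'
#' @param spec a [fixture_spec].
#' @return list with `expr` (an [expression_matrix]) and `truth` (module
#'   labels, regulator edges, condition-responsive genes, TF list).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  design <- .fixture_design(spec)
  n_s <- nrow(design)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  tfs <- sprintf("TF%03d", seq_len(spec$n_tfs))
  genes[seq_len(spec$n_tfs)] <- tfs

  values <- matrix(stats::rnorm(spec$n_genes * n_s, sd = 1), spec$n_genes,
                   n_s, dimnames = list(genes, design$sample_id))
  labels <- stats::setNames(rep(0L, spec$n_genes), genes)

  # planted co-expression modules among non-TF genes; each module's latent
  # factor is the profile of a dedicated (non-regulator) TF, so module genes
  # are both block-correlated and genuinely TF-driven
  rho <- spec$within_module_cor
  n_reg <- length(spec$planted_regulators)
  if (spec$n_tfs < n_reg + spec$n_modules)
    stop("n_tfs must be at least n_modules + number of planted regulators")
  mod_pool <- setdiff(genes, tfs)
  pos <- 1
  module_tfs <- character(spec$n_modules)
  for (m in seq_len(spec$n_modules)) {
    members <- mod_pool[pos:(pos + spec$module_size - 1)]
    pos <- pos + spec$module_size
    module_tfs[m] <- tfs[n_reg + m]
    f <- as.numeric(scale(values[module_tfs[m], ]))
    eps <- matrix(stats::rnorm(length(members) * n_s), length(members), n_s)
    values[members, ] <- sqrt(rho) * matrix(f, length(members), n_s,
                                            byrow = TRUE) +
      sqrt(1 - rho) * eps
    labels[members] <- m
  }

  # regulator-driven targets from the remaining pool
  target_pool <- mod_pool[pos:length(mod_pool)]
  edges <- list(); tpos <- 1
  reg_tfs <- character(0)
  for (i in seq_along(spec$planted_regulators)) {
    reg <- spec$planted_regulators[[i]]
    tf <- tfs[i]
    reg_tfs <- c(reg_tfs, tf)
    tg <- target_pool[tpos:(tpos + reg$n_targets - 1)]
    tpos <- tpos + reg$n_targets
    values[tg, ] <- reg$effect *
      matrix(values[tf, ], length(tg), n_s, byrow = TRUE) +
      matrix(stats::rnorm(length(tg) * n_s, sd = spec$noise_sd),
             length(tg), n_s)
    edges[[i]] <- data.frame(source = tf, target = tg,
                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)

  # condition effect on regulators and their targets
  de_genes <- unique(c(reg_tfs, edges$target))
  shift <- spec$condition_effect * design$condition
  values[de_genes, ] <- values[de_genes, ] +
    matrix(shift, length(de_genes), n_s, byrow = TRUE)

  # donor random intercepts
  donors <- unique(design$donor)
  intercepts <- stats::setNames(stats::rnorm(length(donors),
                                             sd = spec$donor_sd), donors)
  values <- values + matrix(intercepts[design$donor], spec$n_genes, n_s,
                            byrow = TRUE)

  list(expr = expression_matrix(values, design),
       truth = list(module_labels = labels, regulator_edges = edges,
                    de_genes = de_genes, tf_list = tfs,
                    planted_regulators = reg_tfs, module_tfs = module_tfs))
}

#' Generate a planted linear TF-target network
#'
#' Benchmark fixture for edge-recovery: independent TF profiles, and
#' targets each equal to the sum of `tfs_per_target` randomly drawn TFs
#' plus Gaussian noise. Truth lists the planted edges so rankings of
#' candidate TF-target edges can be scored (e.g. by AUROC).
#'
#' @param n_tfs number of TFs (default 30).
#' @param n_targets number of target genes (default 200).
#' @param tfs_per_target planted regulators per target (default 2).
#' @param n_samples samples (default 40).
#' @param noise_sd residual noise sd (default 0.3).
#' @param seed seed.
#' @return list with `expr` (an [expression_matrix], no design),
#'   `tf_list`, and `truth$edges` (data.frame source, target).
#' @export
generate_linear_grn <- function(n_tfs = 30, n_targets = 200,
                                tfs_per_target = 2, n_samples = 40,
                                noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  targets <- sprintf("T%04d", seq_len(n_targets))
  samples <- sprintf("S%03d", seq_len(n_samples))
  tf_mat <- matrix(stats::rnorm(n_tfs * n_samples), n_tfs, n_samples,
                   dimnames = list(tfs, samples))
  edges <- list()
  tg_mat <- matrix(0, n_targets, n_samples, dimnames = list(targets, samples))
  for (i in seq_len(n_targets)) {
    parents <- sample(tfs, tfs_per_target)
    tg_mat[i, ] <- colSums(tf_mat[parents, , drop = FALSE]) +
      stats::rnorm(n_samples, sd = noise_sd)
    edges[[i]] <- data.frame(source = parents, target = targets[i],
                             stringsAsFactors = FALSE)
  }
  values <- rbind(tf_mat, tg_mat)
  list(expr = expression_matrix(values),
       tf_list = tfs,
       truth = list(edges = do.call(rbind, edges)))
}

#' Generate planted-structure methylation data
#'
#' Emits array-style methylated/unmethylated intensities whose implied
#' beta values follow a bimodal mixture (hypo- and hyper-methylated
#' modes), with 1-4 probes per (gene, region) unit. A `dm_fraction` of
#' units receive a condition-dependent beta shift of `dm_effect`. A
#' `qc_fraction` of probes each get an SNP flag, a multimapping flag, a
#' sex-chromosome location, failing detection p-values, or low bead
#' counts, so every probe-QC rule is exercised.
#'
#' @param spec a [fixture_spec]; `timepoints` and donors define the sample
#'   grid exactly as in [generate_expression].
#' @param n_genes_meth number of genes on the methylation layer (default
#'   `min(spec$n_genes, 120)` to keep probe counts desk-scale).
#' @return list with `meth` (a [methylation_data]) and `truth`
#'   (per-unit DM flags, per-probe QC plants, implied unit beta).
#' @export
generate_methylation <- function(spec, n_genes_meth = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 104729L)  # distinct stream from the expression layer
  design <- .fixture_design(spec)
  n_s <- nrow(design)
  if (is.null(n_genes_meth)) n_genes_meth <- min(spec$n_genes, 120L)
  genes <- sprintf("G%04d", seq_len(n_genes_meth))

  regions <- region_classes()
  units <- do.call(rbind, lapply(genes, function(g) {
    rg <- sample(regions, size = sample(2:4, 1))
    data.frame(gene = g, region = rg, stringsAsFactors = FALSE)
  }))
  units$unit <- paste(units$gene, units$region, sep = "|")
  n_units <- nrow(units)
  units$dm <- stats::runif(n_units) < spec$dm_fraction
  # bimodal baseline; DM units shifted by condition, headroom guaranteed
  base <- ifelse(stats::runif(n_units) < 0.5, spec$beta_modes[1],
                 spec$beta_modes[2])
  base <- pmin(pmax(base + stats::rnorm(n_units, sd = 0.03), 0.02),
               1 - spec$dm_effect - 0.02)
  unit_beta <- matrix(base, n_units, n_s,
                      dimnames = list(units$unit, design$sample_id))
  shift <- outer(ifelse(units$dm, spec$dm_effect, 0), design$condition)
  unit_beta <- unit_beta + shift

  probes_per_unit <- sample(1:4, n_units, replace = TRUE)
  probe_unit <- rep(seq_len(n_units), probes_per_unit)
  n_p <- length(probe_unit)
  probe_id <- sprintf("cg%06d", seq_len(n_p))
  beta_p <- unit_beta[probe_unit, , drop = FALSE] +
    matrix(stats::rnorm(n_p * n_s, sd = 0.02), n_p, n_s)
  # upper clamp keeps U = total - M positive at the lowest total intensity
  beta_p <- pmin(pmax(beta_p, 0.005), 0.95)
  rownames(beta_p) <- probe_id

  total <- matrix(stats::runif(n_p * n_s, 4000, 12000), n_p, n_s)
  M <- beta_p * (total + 100)
  U <- total - M
  dimnames(M) <- dimnames(U) <- list(probe_id, design$sample_id)

  detection_p <- matrix(stats::runif(n_p * n_s, 0, 0.005), n_p, n_s,
                        dimnames = dimnames(M))
  bead_count <- matrix(stats::rpois(n_p * n_s, 12) + 3L, n_p, n_s,
                       dimnames = dimnames(M))
  n_bad <- max(1L, round(spec$qc_fraction * n_p))
  bad <- sample(n_p, 5 * n_bad)
  bad_snp <- bad[seq_len(n_bad)]
  bad_multi <- bad[n_bad + seq_len(n_bad)]
  bad_sex <- bad[2 * n_bad + seq_len(n_bad)]
  bad_det <- bad[3 * n_bad + seq_len(n_bad)]
  bad_bead <- bad[4 * n_bad + seq_len(n_bad)]
  n_fail <- max(1L, ceiling(0.05 * n_s))
  detection_p[bad_det, seq_len(n_fail)] <- 0.5
  bead_count[bad_bead, seq_len(n_fail)] <- 1L

  annotation <- data.frame(
    probe_id = probe_id,
    gene = units$gene[probe_unit],
    region = units$region[probe_unit],
    chrom = "chr1",
    snp = FALSE, multimap = FALSE, stringsAsFactors = FALSE)
  annotation$snp[bad_snp] <- TRUE
  annotation$multimap[bad_multi] <- TRUE
  annotation$chrom[bad_sex] <- "chrX"

  meth <- methylation_data(M, U, annotation, detection_p = detection_p,
                           bead_count = bead_count)
  list(meth = meth,
       truth = list(units = units, unit_beta = unit_beta,
                    qc = list(snp = probe_id[bad_snp],
                              multimap = probe_id[bad_multi],
                              sex = probe_id[bad_sex],
                              detection = probe_id[bad_det],
                              bead = probe_id[bad_bead]),
                    design = design))
}

#' Differential table for the generated expression fixture
#'
#' Computes per-gene condition p-values with the package's own per-feature
#' OLS test on the generated matrix, and log2 fold changes as
#' condition-group mean differences on the variance-stabilized scale.
#'
#' @param gen result of [generate_expression].
#' @return data.frame `gene`, `p`, `fdr`, `log2fc`.
#' @export
generate_differential_table <- function(gen) {
  expr <- gen$expr
  dt <- differential_linear_model(expr$values, expr$design,
                                  test_term = "condition")
  cond <- expr$design$condition
  lfc <- rowMeans(expr$values[, cond == 1, drop = FALSE]) -
    rowMeans(expr$values[, cond == 0, drop = FALSE])
  data.frame(gene = dt$feature_id, p = dt$p, fdr = dt$fdr,
             log2fc = unname(lfc[dt$feature_id]), stringsAsFactors = FALSE)
}
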