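#' Construct a methylation data set
#'
#' Bundles methylated/unmethylated signal intensity matrices with per-probe
#' annotation and optional QC matrices (detection p-values, bead counts) into
#' a validated container used by the probe-QC and beta-value functions.
#'
#' @param M numeric probe x sample matrix of methylated signal (>= 0).
#' @param U numeric probe x sample matrix of unmethylated signal (>= 0),
#'   with row and column names identical to `M`.
#' @param annotation data.frame with columns `probe_id`, `gene`, `region`
#'   (one of TSS1500, TSS200, 5'UTR, 1stExon, ExonBnd, 3'UTR), `chrom`,
#'   `snp` (logical), `multimap` (logical). Every probe in `M` must appear.
#' @param detection_p optional probe x sample matrix of detection p-values
#'   in \[0,1\], same dimnames as `M`.
#' @param bead_count optional probe x sample matrix of non-negative integer
#'   bead counts, same dimnames as `M`.
#' @return An object of class `methylation_data`.
#' @export
methylation_data <- function(M, U, annotation, detection_p = NULL,
                             bead_count = NULL) {
  M <- as.matrix(M); U <- as.matrix(U)
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop("signal matrices must carry probe (row) and sample (column) names")
  if (!identical(dimnames(M), dimnames(U)))
    stop("M and U must share identical probe and sample index sets")
  .check_no_missing(M, "M"); .check_no_missing(U, "U")
  .check_nonnegative(M, "M"); .check_nonnegative(U, "U")
  annotation <- as.data.frame(annotation)
  needed <- c("probe_id", "gene", "region", "chrom", "snp", "multimap")
  missing_cols <- setdiff(needed, names(annotation))
  if (length(missing_cols))
    stop("annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  absent <- setdiff(rownames(M), annotation$probe_id)
  if (length(absent))
    stop("probes missing from annotation: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) " ...")
  bad_region <- setdiff(unique(annotation$region), region_classes())
  if (length(bad_region))
    stop("unknown region class(es): ", paste(bad_region, collapse = ", "))
  for (nm in c("detection_p", "bead_count")) {
    mat <- get(nm)
    if (!is.null(mat)) {
      mat <- as.matrix(mat)
      if (!identical(dimnames(mat), dimnames(M)))
        stop(nm, " must share dimnames with M")
      assign(nm, mat)
    }
  }
  ann <- annotation[match(rownames(M), annotation$probe_id), , drop = FALSE]
  rownames(ann) <- ann$probe_id
  structure(list(M = M, U = U, annotation = ann,
                 detection_p = detection_p, bead_count = bead_count),
            class = "methylation_data")
}

#' The six Illumina manifest gene sub-region classes
#' @return Character vector of the region vocabulary.
#' @export
region_classes <- function() {
  c("TSS1500", "TSS200", "5'UTR", "1stExon", "ExonBnd", "3'UTR")
}

#' Priority chain used to pick a gene-level beta profile
#' @return Character vector, highest priority first.
#' @export
region_priority <- function() c("TSS200", "TSS1500", "5'UTR", "1stExon")

.check_no_missing <- function(mat, name) {
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value in %s at probe '%s', sample '%s'",
                 name, rownames(mat)[idx[1]], colnames(mat)[idx[2]]))
  }
}

.check_nonnegative <- function(mat, name) {
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative signal in %s at probe '%s', sample '%s'",
                 name, rownames(mat)[idx[1]], colnames(mat)[idx[2]]))
  }
}

#' @export
print.methylation_data <- function(x, ...) {
  cat("methylation_data:", nrow(x$M), "probes x", ncol(x$M), "samples\n")
  cat("  detection_p:", if (is.null(x$detection_p)) "absent" else "present",
      " bead_count:", if (is.null(x$bead_count)) "absent" else "present", "\n")
  invisible(x)
}

#' Beta-value matrix container
#'
#' @param beta numeric matrix of methylation fractions in \[0,1).
#' @param level aggregation level: "probe", "region" or "gene".
#' @param feature_info optional data.frame describing rows (e.g. gene and
#'   region per row at region level).
#' @return `beta_matrix` object (list with `beta`, `level`, `feature_info`).
#' @export
beta_matrix <- function(beta, level = c("probe", "region", "gene"),
                        feature_info = NULL) {
  level <- match.arg(level)
  beta <- as.matrix(beta)
  if (anyNA(beta)) stop("beta matrix contains missing values")
  if (any(beta < 0) || any(beta >= 1)) stop("beta values must lie in [0, 1)")
  structure(list(beta = beta, level = level, feature_info = feature_info),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix (%s level): %d features x %d samples\n",
              x$level, nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

#' Compute beta values from signal intensities
#'
#' The methylation level of each probe is the methylated signal over the
#' total signal plus a stabilizing offset: beta = M / (M + U + offset).
#' The offset bounds beta strictly below 1 and damps noise at low total
#' intensity.
#'
#' @param data a [methylation_data] object.
#' @param offset non-negative stabilizing constant (default 100, the
#'   Illumina array convention).
#' @return A probe-level [beta_matrix].
#' @examples
#' ann <- data.frame(probe_id = "p1", gene = "G1", region = "TSS200",
#'                   chrom = "chr1", snp = FALSE, multimap = FALSE)
#' M <- matrix(100, 1, 1, dimnames = list("p1", "s1"))
#' U <- matrix(0, 1, 1, dimnames = list("p1", "s1"))
#' compute_beta(methylation_data(M, U, ann))$beta  # 0.5
#' @export
compute_beta <- function(data, offset = 100) {
  stopifnot(inherits(data, "methylation_data"))
  if (length(offset) != 1 || offset < 0) stop("offset must be a non-negative scalar")
  beta <- data$M / (data$M + data$U + offset)
  beta[data$M == 0] <- 0  # guard 0/0 when offset = 0
  beta_matrix(beta, level = "probe")
}

#' Quality-filter methylation probes
#'
#' Removes probes that (i) fail detection (detection p >= `detection_alpha`)
#' in at least `fail_fraction` of samples, (ii) have bead count below
#' `min_beads` in at least `fail_fraction` of samples, (iii) target SNP
#' sites, (iv) align to multiple genomic locations, or (v) lie on the sex
#' chromosomes. Thresholds on the sample fraction are inclusive. When the
#' detection-p or bead-count matrix is absent the corresponding criterion is
#' skipped with a warning.
#'
#' @param data a [methylation_data] object.
#' @param fail_fraction fraction of samples at which a probe is discarded
#'   (inclusive; default 0.05).
#' @param min_beads minimum bead count (default 3).
#' @param detection_alpha detection p-value at or above which a measurement
#'   counts as failed (default 0.01).
#' @return The retained `methylation_data` subset; attribute `removed` holds
#'   the per-criterion removal counts (a probe may count under several).
#' @export
filter_probes <- function(data, fail_fraction = 0.05, min_beads = 3,
                          detection_alpha = 0.01) {
  stopifnot(inherits(data, "methylation_data"))
  n_samples <- ncol(data$M)
  ann <- data$annotation
  fail_det <- fail_bead <- rep(FALSE, nrow(data$M))
  if (is.null(data$detection_p)) {
    warning("detection_p matrix absent; detection-failure criterion skipped")
  } else {
    fail_det <- rowMeans(data$detection_p >= detection_alpha) >= fail_fraction
  }
  if (is.null(data$bead_count)) {
    warning("bead_count matrix absent; bead-count criterion skipped")
  } else {
    fail_bead <- rowMeans(data$bead_count < min_beads) >= fail_fraction
  }
  is_snp <- as.logical(ann$snp)
  is_multi <- as.logical(ann$multimap)
  is_sex <- ann$chrom %in% c("chrX", "chrY", "X", "Y")
  drop <- fail_det | fail_bead | is_snp | is_multi | is_sex
  keep <- which(!drop)
  out <- methylation_data(
    data$M[keep, , drop = FALSE], data$U[keep, , drop = FALSE],
    ann[keep, , drop = FALSE],
    detection_p = if (!is.null(data$detection_p)) data$detection_p[keep, , drop = FALSE],
    bead_count = if (!is.null(data$bead_count)) data$bead_count[keep, , drop = FALSE])
  attr(out, "removed") <- c(detection = sum(fail_det), bead = sum(fail_bead),
                            snp = sum(is_snp), multimap = sum(is_multi),
                            sex_chromosome = sum(is_sex),
                            total = sum(drop), retained = length(keep))
  out
}

#' Aggregate probe-level beta values to (gene, region) units
#'
#' Each (gene, region-class) unit gets, per sample, the arithmetic mean of
#' the beta values of its member probes. Units with no surviving probes are
#' absent from the output rather than zero-filled.
#'
#' @param beta a probe-level [beta_matrix].
#' @param annotation probe annotation data.frame (`probe_id`, `gene`,
#'   `region`) covering every row of `beta`.
#' @return A region-level [beta_matrix]; rows are named `gene|region` and
#'   `feature_info` maps rows to gene and region.
#' @export
aggregate_regions <- function(beta, annotation) {
  stopifnot(inherits(beta, "beta_matrix"), beta$level == "probe")
  annotation <- as.data.frame(annotation)
  ann <- annotation[match(rownames(beta$beta), annotation$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id)) stop("annotation does not cover all probes")
  unit <- paste(ann$gene, ann$region, sep = "|")
  agg <- rowsum(beta$beta, group = unit, reorder = TRUE)
  counts <- as.vector(table(unit)[rownames(agg)])
  agg <- agg / counts
  info_idx <- !duplicated(unit)
  info <- data.frame(unit = unit[info_idx], gene = ann$gene[info_idx],
                     region = ann$region[info_idx], stringsAsFactors = FALSE)
  info <- info[match(rownames(agg), info$unit), , drop = FALSE]
  rownames(info) <- NULL
  beta_matrix(agg, level = "region", feature_info = info)
}

#' Per-feature ordinary-least-squares differential test
#'
#' Fits, at every feature, the linear model value ~ donor + time
#' (+ condition when present in the design), and reports a two-sided t-test
#' on the coefficient of `test_term`, with Benjamini-Hochberg FDR across
#' features. Donor enters as categorical dummies, time as numeric day,
#' condition as a binary indicator.
#'
#' Degenerate fits are flagged rather than dropped: a feature constant
#' across samples gets coefficient 0 and p = 1; a feature fitted exactly
#' (zero residual variance but non-zero effect) gets p = 0.
#'
#' @param values numeric feature x sample matrix.
#' @param design data.frame with one row per sample (in column order of
#'   `values`); must contain the covariates of `covariates`.
#' @param test_term name of the tested covariate ("time" or "condition").
#' @param fdr_alpha significance threshold on the BH-adjusted p (default 0.05).
#' @param covariates model covariates in order; default uses donor and time
#'   plus condition if present.
#' @return data.frame with `feature_id`, `coefficient`, `p`, `fdr`,
#'   `significant`, `degenerate`.
#' @export
differential_linear_model <- function(values, design, test_term = "time",
                                      fdr_alpha = 0.05, covariates = NULL) {
  values <- as.matrix(values)
  design <- as.data.frame(design)
  if (nrow(design) != ncol(values))
    stop("design rows must match sample columns of `values`")
  if (is.null(covariates)) {
    covariates <- intersect(c("donor", "time", "condition"), names(design))
  }
  if (!test_term %in% covariates)
    stop("test_term '", test_term, "' is not among the model covariates")
  dd <- design[, covariates, drop = FALSE]
  if ("donor" %in% names(dd)) dd$donor <- factor(dd$donor)
  X <- stats::model.matrix(~ ., data = dd)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df_resid <- nrow(X) - ncol(X)
  if (df_resid < 2) stop("fewer than 2 residual degrees of freedom")
  term_col <- .match_term_column(colnames(X), test_term, dd)

  coefs <- qr.coef(qrX, t(values))            # p x features
  fitted <- X %*% coefs
  resid <- t(values) - fitted
  sigma2 <- colSums(resid^2) / df_resid
  xtx_inv <- chol2inv(qr.R(qrX))
  v_jj <- xtx_inv[term_col, term_col]
  beta_hat <- coefs[term_col, ]
  feature_var <- apply(values, 1, stats::var)
  constant <- feature_var < 1e-12
  degenerate <- !constant & (sigma2 < pmax(feature_var, 1) * 1e-10)

  se <- sqrt(sigma2 * v_jj)
  tstat <- beta_hat / se
  p <- 2 * stats::pt(-abs(tstat), df = df_resid)
  beta_hat[constant] <- 0
  p[constant] <- 1
  p[degenerate] <- 0
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(feature_id = rownames(values), coefficient = unname(beta_hat),
             p = unname(p), fdr = unname(fdr),
             significant = unname(fdr < fdr_alpha),
             degenerate = unname(degenerate),
             stringsAsFactors = FALSE)
}

.match_term_column <- function(xnames, test_term, dd) {
  if (test_term %in% xnames) return(match(test_term, xnames))
  hits <- which(startsWith(xnames, test_term))
  if (length(hits) == 0)
    stop("no design-matrix column for test_term '", test_term, "'")
  if (length(hits) > 1)
    stop("test_term '", test_term,
         "' expands to several columns; it must be numeric or binary")
  hits
}

#' Call differentially methylated genes from region-level results
#'
#' A gene is differentially methylated when at least one of its (gene,
#' region) units is significant.
#'
#' @param region_results data.frame with columns `gene` and `significant`
#'   (one row per (gene, region) unit), e.g. a [differential_linear_model]
#'   result joined with region `feature_info`.
#' @return data.frame with `gene` and logical `dmg`.
#' @export
call_dmg <- function(region_results) {
  region_results <- as.data.frame(region_results)
  stopifnot(all(c("gene", "significant") %in% names(region_results)))
  agg <- tapply(region_results$significant, region_results$gene, any)
  data.frame(gene = names(agg), dmg = unname(as.logical(agg)),
             stringsAsFactors = FALSE)
}

#' Assign one beta profile per gene by region priority
#'
#' For every gene with at least one differentially methylated (DM) region,
#' picks the beta profile of the highest-priority DM region along the chain
#' TSS200 > TSS1500 > 5'UTR > 1stExon. Genes whose only DM regions fall
#' outside the chain (ExonBnd, 3'UTR) are excluded unless the chain is
#' extended.
#'
#' @param region_beta a region-level [beta_matrix] (rows `gene|region`).
#' @param region_dm data.frame with `gene`, `region`, `significant` flags.
#' @param priority region priority chain, highest first; default
#'   [region_priority()]. Pass `c(region_priority(), "ExonBnd", "3'UTR")`
#'   to extend it.
#' @return A gene-level [beta_matrix]; `feature_info` records the region
#'   chosen per gene.
#' @export
assign_gene_beta <- function(region_beta, region_dm,
                             priority = region_priority()) {
  stopifnot(inherits(region_beta, "beta_matrix"), region_beta$level == "region")
  region_dm <- as.data.frame(region_dm)
  stopifnot(all(c("gene", "region", "significant") %in% names(region_dm)))
  dm <- region_dm[region_dm$significant & region_dm$region %in% priority, ,
                  drop = FALSE]
  if (nrow(dm) == 0) {
    return(beta_matrix(region_beta$beta[0, , drop = FALSE], level = "gene",
                       feature_info = data.frame(gene = character(),
                                                 region = character())))
  }
  dm$rank <- match(dm$region, priority)
  dm <- dm[order(dm$gene, dm$rank), , drop = FALSE]
  pick <- dm[!duplicated(dm$gene), , drop = FALSE]
  rows <- paste(pick$gene, pick$region, sep = "|")
  present <- rows %in% rownames(region_beta$beta)
  if (!all(present))
    stop("region beta rows missing for: ",
         paste(utils::head(rows[!present], 5), collapse = ", "))
  out <- region_beta$beta[rows, , drop = FALSE]
  rownames(out) <- pick$gene
  beta_matrix(out, level = "gene",
              feature_info = data.frame(gene = pick$gene, region = pick$region,
                                        stringsAsFactors = FALSE))
}
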