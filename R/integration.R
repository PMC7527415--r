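#' Critical correlation magnitude at a given sample size
#'
#' Returns the two-sided critical |r| solving
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) with t the upper alpha/2 Student
#' quantile on n - 2 degrees of freedom. Valid for Pearson correlations
#' and, to a good approximation, for Spearman. At n = 64 and alpha = 0.01
#' this is the familiar |r| ~ 0.32 cutoff.
#'
#' @param n number of sample pairs (>= 4).
#' @param alpha two-sided significance level in (0, 1).
#' @return positive scalar critical correlation.
#' @export
critical_correlation <- function(n, alpha) {
  if (n < 4) stop("n must be at least 4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  tq <- stats::qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(n - 2 + tq^2)
}

# Spearman rho with a two-sided p from the t approximation; exact
# permutation enumeration available for very small n.
.spearman_test <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  if (method == "exact") {
    if (n > 8) stop("exact permutation p available only for n <= 8")
    perms <- .all_permutations(n)
    rx <- rank(x); ry <- rank(y)
    obs <- abs(stats::cor(rx, ry))
    rhos <- apply(perms, 1, function(pm) abs(stats::cor(rx, ry[pm])))
    p <- mean(rhos >= obs - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    out[row, ] <- append(sub[i, ], n, after = pos - 1)
    row <- row + 1
  }
  out
}

#' Expression-methylation concordance per gene/region pair
#'
#' Spearman correlation between a gene's expression profile and a beta
#' profile (region- or gene-level), across the shared samples, with a
#' two-sided p from the t approximation. Pairs whose beta (or expression)
#' profile is constant have undefined ranks and are flagged `degenerate`;
#' they should be excluded from summaries.
#'
#' @param expr gene x sample expression matrix (or [expression_matrix]).
#' @param beta a [beta_matrix] (region or gene level) or plain matrix.
#' @param pairing data.frame with `expr_id` (row of `expr`) and `meth_id`
#'   (row of the beta matrix); optional extra columns (e.g. `region`) are
#'   carried through.
#' @param alpha significance level for the `significant` flag (default 0.01).
#' @param method "t" (default) or "exact" (n <= 8).
#' @return data.frame with the pairing columns plus `spearman_r`, `p`,
#'   `significant`, `degenerate`, and attribute `critical_r`.
#' @export
expr_meth_correlation <- function(expr, beta, pairing, alpha = 0.01,
                                  method = c("t", "exact")) {
  method <- match.arg(method)
  ev <- .values_of(expr)
  bv <- if (inherits(beta, "beta_matrix")) beta$beta else as.matrix(beta)
  shared <- intersect(colnames(ev), colnames(bv))
  if (length(shared) < 4) stop("fewer than 4 shared samples between layers")
  ev <- ev[, shared, drop = FALSE]; bv <- bv[, shared, drop = FALSE]
  pairing <- as.data.frame(pairing)
  stopifnot(all(c("expr_id", "meth_id") %in% names(pairing)))
  res <- lapply(seq_len(nrow(pairing)), function(i) {
    e_id <- pairing$expr_id[i]; m_id <- pairing$meth_id[i]
    if (!e_id %in% rownames(ev) || !m_id %in% rownames(bv))
      stop("pairing row ", i, " references unknown feature IDs")
    .spearman_test(ev[e_id, ], bv[m_id, ], method = method)
  })
  out <- cbind(pairing,
               spearman_r = vapply(res, `[[`, numeric(1), "rho"),
               p = vapply(res, `[[`, numeric(1), "p"),
               degenerate = vapply(res, `[[`, logical(1), "degenerate"))
  out$significant <- !out$degenerate & out$p < alpha
  attr(out, "critical_r") <- critical_correlation(length(shared), alpha)
  attr(out, "n_samples") <- length(shared)
  out
}

#' Cross-correlation of two eigengene sets
#'
#' Spearman correlations (with t-approximation p-values) between every
#' expression-module eigengene and every methylation-module eigengene over
#' the shared samples.
#'
#' @param eig_a,eig_b module x sample eigengene matrices.
#' @return list with matrices `rho` and `p` (rows = modules of `eig_a`).
#' @export
eigengene_cross_correlation <- function(eig_a, eig_b) {
  shared <- intersect(colnames(eig_a), colnames(eig_b))
  if (length(shared) < 4) stop("no (or too few) shared samples")
  A <- eig_a[, shared, drop = FALSE]; B <- eig_b[, shared, drop = FALSE]
  rho <- stats::cor(t(A), t(B), method = "spearman")
  n <- length(shared)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p, n = n)
}

#' Module-overlap significance between two labelings
#'
#' For every pair of modules (one from each labeling over the same gene
#' universe), counts shared genes and tests the 2x2 contingency table
#' (in/out of each module) with a two-tailed Fisher exact test (sum of
#' table probabilities at most that of the observed table).
#'
#' @param labels_a,labels_b named integer module labels over the same
#'   genes; label 0 (unassigned) is skipped unless `include_unassigned`.
#' @param include_unassigned treat label 0 as a module (default FALSE).
#' @return data.frame `module_a`, `module_b`, `overlap`, `size_a`,
#'   `size_b`, `p`.
#' @export
module_overlap <- function(labels_a, labels_b, include_unassigned = FALSE) {
  genes <- names(labels_a)
  if (is.null(genes) || is.null(names(labels_b)) ||
      !setequal(genes, names(labels_b)))
    stop("labelings must cover the same gene universe")
  labels_b <- labels_b[genes]
  mods_a <- sort(unique(labels_a)); mods_b <- sort(unique(labels_b))
  if (!include_unassigned) {
    mods_a <- setdiff(mods_a, 0); mods_b <- setdiff(mods_b, 0)
  }
  N <- length(genes)
  rows <- list(); idx <- 1
  for (a in mods_a) for (b in mods_b) {
    in_a <- labels_a == a; in_b <- labels_b == b
    k <- sum(in_a & in_b)
    tab <- matrix(c(k, sum(in_a & !in_b), sum(!in_a & in_b),
                    sum(!in_a & !in_b)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    rows[[idx]] <- data.frame(module_a = a, module_b = b, overlap = k,
                              size_a = sum(in_a), size_b = sum(in_b), p = p)
    idx <- idx + 1
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Module-trait Pearson correlations
#'
#' Relates module eigengenes to numeric-coded sample traits (e.g. CXCL4
#' exposure and polyI:C stimulation as 0/1, time as day number).
#'
#' @param eigengenes module x sample matrix.
#' @param traits data.frame of numeric traits, one row per sample in the
#'   column order of `eigengenes`.
#' @return list with matrices `r` and `p` (modules x traits); constant
#'   traits yield NA with a warning.
#' @export
trait_correlation <- function(eigengenes, traits) {
  traits <- as.data.frame(traits)
  if (nrow(traits) != ncol(eigengenes))
    stop("traits must have one row per eigengene sample")
  if (!all(vapply(traits, is.numeric, logical(1))))
    stop("all traits must be numeric-coded")
  n <- ncol(eigengenes)
  const <- vapply(traits, function(t) stats::sd(t) == 0, logical(1))
  if (any(const))
    warning("constant trait(s) flagged undefined: ",
            paste(names(traits)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(eigengenes), as.matrix(traits)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-15] <- 0
  r[, const] <- NA; p[, const] <- NA
  list(r = r, p = p)
}

#' Compare module membership of TFs vs non-TFs
#'
#' For every module containing at least one TF and one non-TF, computes the
#' mean absolute own-module membership (|kME|) separately for TFs and
#' non-TFs, then runs a paired two-sided t-test across modules. Regulators
#' sitting at module cores show systematically higher |kME|.
#'
#' @param decomp a [module_decomposition] with labels and membership.
#' @param tf_list character vector of TF gene IDs.
#' @return list with `per_module` (module, n_tf, n_nontf, mean_abs_kme_tf,
#'   mean_abs_kme_nontf) and `test` (htest from [stats::t.test]).
#' @export
compare_tf_membership <- function(decomp, tf_list) {
  stopifnot(inherits(decomp, "module_decomposition"))
  labels <- decomp$labels
  kme <- decomp$membership
  if (is.null(kme)) stop("decomposition lacks a membership matrix")
  mods <- sort(setdiff(unique(labels), 0))
  rows <- list()
  for (m in mods) {
    members <- names(labels)[labels == m]
    tfs <- intersect(members, tf_list)
    non <- setdiff(members, tf_list)
    if (length(tfs) == 0 || length(non) == 0) next  # modules w/o TFs excluded
    own <- paste0("M", m)
    rows[[length(rows) + 1]] <- data.frame(
      module = m, n_tf = length(tfs), n_nontf = length(non),
      mean_abs_kme_tf = mean(abs(kme[tfs, own])),
      mean_abs_kme_nontf = mean(abs(kme[non, own])))
  }
  per_module <- do.call(rbind, rows)
  if (is.null(per_module) || nrow(per_module) < 2)
    stop("fewer than 2 modules contain both TFs and non-TFs")
  test <- stats::t.test(per_module$mean_abs_kme_tf,
                        per_module$mean_abs_kme_nontf, paired = TRUE)
  list(per_module = per_module, test = test)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Projects samples into k dimensions from their Euclidean distances by
#' double-centering -D^2/2 and taking the top-k eigenvectors scaled by the
#' square roots of their eigenvalues. When fewer than k positive
#' eigenvalues exist the trailing coordinates are zero-filled with a
#' warning. Deterministic up to sign and rotation.
#'
#' @param x samples x features matrix (Euclidean distances computed
#'   row-wise), or a distance matrix / `dist` when `use_distance = TRUE`.
#' @param k number of output dimensions (default 2).
#' @param use_distance interpret `x` as distances (default FALSE).
#' @return samples x k coordinate matrix (columns `MDS1..MDSk`);
#'   attribute `eig` holds the eigenvalues.
#' @export
classical_mds <- function(x, k = 2, use_distance = FALSE) {
  if (use_distance || inherits(x, "dist")) {
    d <- stats::as.dist(x)
  } else {
    d <- stats::dist(as.matrix(x))
  }
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = min(k, n - 1), eig = TRUE)
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {
    warning("fewer than ", k, " positive eigenvalues; ",
            "trailing dimensions zero-filled")
    pad <- matrix(0, n, k - if (is.null(pts)) 0 else ncol(pts))
    pts <- cbind(pts, pad)
  }
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  rownames(pts) <- attr(d, "Labels")
  attr(pts, "eig") <- fit$eig
  pts
}
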