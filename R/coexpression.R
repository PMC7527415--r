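#' Expression matrix container
#'
#' @param values numeric gene x sample matrix (variance-stabilized
#'   expression, or beta values for the methylation layer).
#' @param design data.frame with one row per sample; typically columns
#'   `sample_id`, `donor`, `day`, `condition`, `stim`.
#' @return `expression_matrix` object.
#' @export
expression_matrix <- function(values, design = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("expression values contain missing entries")
  if (ncol(values) < 4) stop("at least 4 samples are required")
  if (is.null(rownames(values))) stop("gene (row) names are required")
  if (anyDuplicated(rownames(values))) stop("gene IDs must be unique")
  if (!is.null(design)) {
    design <- as.data.frame(design)
    if (nrow(design) != ncol(values))
      stop("design must have one row per sample column")
  }
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  invisible(x)
}

.values_of <- function(x) {
  if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
}

#' Unsigned weighted correlation adjacency
#'
#' a_ij = |cor(x_i, x_j)|^power with unit diagonal. Raising the absolute
#' Pearson correlation to a soft-thresholding power suppresses weak
#' correlations continuously instead of hard-thresholding them, yielding an
#' approximately scale-free weighted network.
#'
#' @param expr an [expression_matrix] or gene x sample matrix.
#' @param power positive soft-thresholding exponent (6 is the usual
#'   expression default, 12 the methylation default).
#' @param mode only "unsigned" is implemented.
#' @return symmetric gene x gene adjacency matrix in \[0,1\].
#' @export
adjacency <- function(expr, power = 6, mode = "unsigned") {
  mode <- match.arg(mode, "unsigned")
  if (length(power) != 1 || power <= 0) stop("power must be a positive scalar")
  values <- .values_of(expr)
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(values)[sds == 0], 5), collapse = ", "))
  a <- abs(stats::cor(t(values)))^power
  diag(a) <- 1
  # enforce exact symmetry against floating-point asymmetry
  (a + t(a)) / 2
}

#' Evaluate candidate soft-thresholding powers
#'
#' For each candidate power, computes node connectivities k_i = sum_j a_ij
#' (j != i), bins them, and fits log10 p(k) against log10 k. The scale-free
#' fit index is the R-squared of that line, signed by the slope direction
#' (positive when the degree distribution decays, as scale-free topology
#' requires).
#'
#' @param expr an [expression_matrix] or gene x sample matrix.
#' @param powers candidate powers (default 1:20).
#' @param n_bins number of connectivity bins (default 10).
#' @return data.frame with `power`, `sft_r_squared` (signed), `slope`,
#'   `mean_connectivity`. `sft_r_squared` is NA when the fit is undefined
#'   (e.g. all connectivities equal).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, n_bins = 10) {
  if (any(powers <= 0)) stop("candidate powers must be positive")
  values <- .values_of(expr)
  cors <- abs(stats::cor(t(values)))
  diag(cors) <- 0
  out <- lapply(powers, function(p) {
    a <- cors^p
    k <- rowSums(a)
    fit <- .scale_free_fit(k, n_bins)
    data.frame(power = p, sft_r_squared = fit$r2, slope = fit$slope,
               mean_connectivity = mean(k))
  })
  do.call(rbind, out)
}

.scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(list(r2 = NA_real_, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  ok <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(ok) < 2) return(list(r2 = NA_real_, slope = NA_real_))
  x <- log10(dk[ok]); y <- log10(pk[ok])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  # signed scale-free index: positive when the degree distribution decays
  list(r2 = -sign(slope) * r2, slope = slope)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) for
#' i != j, where k_i excludes the diagonal; TOM_ii = 1. Two nodes overlap
#' strongly when they are directly connected and share neighbors.
#'
#' @param adj symmetric adjacency with unit diagonal and values in \[0,1\].
#' @return symmetric TOM matrix with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  adj <- as.matrix(adj)
  if (!isSymmetric(unname(adj), tol = 1e-8)) stop("adjacency must be symmetric")
  if (any(adj < 0) || any(adj > 1 + 1e-12))
    stop("adjacency values must lie in [0,1]")
  a0 <- adj
  diag(a0) <- 0
  shared <- a0 %*% a0                 # sum_u a_iu a_uj, u free of diagonal
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a0) / (kmin + 1 - a0)
  tom[kmin + 1 - a0 == 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  (tom + t(tom)) / 2
}

#' Module decomposition container
#' @param labels integer vector named by gene; 0 = unassigned.
#' @param eigengenes module x sample matrix or NULL.
#' @param membership gene x module correlation matrix or NULL.
#' @param power soft threshold used (metadata).
#' @param variant tree-cut variant string (metadata).
#' @return `module_decomposition` object.
#' @export
module_decomposition <- function(labels, eigengenes = NULL, membership = NULL,
                                 power = NA_real_, variant = "tree") {
  structure(list(labels = labels, eigengenes = eigengenes,
                 membership = membership, power = power, variant = variant),
            class = "module_decomposition")
}

#' @export
print.module_decomposition <- function(x, ...) {
  k <- setdiff(unique(x$labels), 0)
  cat("module_decomposition:", length(k), "modules over", length(x$labels),
      "genes (", sum(x$labels == 0), "unassigned )\n")
  invisible(x)
}

#' Detect co-expression modules by adaptive tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' followed by an adaptive height cut: candidate cut heights spanning the
#' dendrogram are scanned and the cut yielding the most clusters of size >=
#' `min_size` is kept (ties resolved toward the higher cut). Each cluster
#' is then pruned of weakly attached members — genes whose mean
#' topological overlap with the rest of the cluster falls below
#' `attach_frac` of the cluster's median attachment — so scattered genes
#' that merge into a cluster only near the dendrogram top are left
#' unassigned. Clusters below `min_size` (after pruning) are unassigned
#' (label 0). Labels are ordered by decreasing module size.
#'
#' @param tom TOM (or any symmetric similarity in \[0,1\] with unit diagonal).
#' @param min_size minimum module size (default 30).
#' @param cut_quantiles candidate cut heights as fractions of the maximum
#'   merge height (default `seq(0.99, 0.40, by = -0.01)`).
#' @param attach_frac fraction of the median within-cluster attachment
#'   below which a member is pruned (default 0.5; 0 disables pruning).
#' @return a [module_decomposition] with labels only.
#' @export
detect_modules <- function(tom, min_size = 30,
                           cut_quantiles = seq(0.99, 0.40, by = -0.01),
                           attach_frac = 0.5) {
  tom <- as.matrix(tom)
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  if (n < min_size) {
    warning("fewer genes than min_size; all genes left unassigned")
    labels <- stats::setNames(rep(0L, n), genes)
    return(module_decomposition(labels, variant = "tree"))
  }
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  hmax <- max(tree$height)
  best <- NULL; best_n <- -1L; best_h <- NA_real_
  for (q in cut_quantiles) {
    cl <- stats::cutree(tree, h = q * hmax)
    sizes <- table(cl)
    n_big <- sum(sizes >= min_size)
    if (n_big > best_n) {
      best_n <- n_big; best <- cl; best_h <- q * hmax
    }
  }
  if (attach_frac > 0) best <- .prune_weak_members(best, tom, min_size,
                                                   attach_frac)
  labels <- .relabel_by_size(best, min_size)
  names(labels) <- genes
  out <- module_decomposition(labels, variant = "tree")
  attr(out, "cut_height") <- best_h
  out
}

# Drop cluster members whose mean within-cluster similarity is an outlier
# below the cluster's median attachment; pruned genes become singletons.
.prune_weak_members <- function(cl, tom, min_size, attach_frac) {
  next_label <- max(cl) + 1L
  for (m in names(which(table(cl) >= min_size))) {
    members <- which(cl == as.integer(m))
    attach <- vapply(members, function(g)
      mean(tom[g, setdiff(members, g)]), numeric(1))
    weak <- members[attach < attach_frac * stats::median(attach)]
    for (g in weak) {
      cl[g] <- next_label
      next_label <- next_label + 1L
    }
  }
  cl
}

.relabel_by_size <- function(cl, min_size) {
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  big <- big[order(-sizes[big], as.numeric(big))]
  labels <- integer(length(cl))
  for (i in seq_along(big)) labels[cl == big[i]] <- i
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized member-gene profiles: the single sample profile explaining
#' the largest share of member variance. It is sign-oriented so that its
#' correlation with the module mean profile is non-negative, and scaled to
#' unit variance. Unassigned genes (label 0) are ignored.
#'
#' @param expr an [expression_matrix] or gene x sample matrix.
#' @param labels named integer module labels (from [detect_modules]).
#' @return module x sample matrix; rows named `M<label>`.
#' @export
module_eigengenes <- function(expr, labels) {
  values <- .values_of(expr)
  mods <- sort(setdiff(unique(labels), 0))
  if (length(mods) == 0) stop("no assigned modules")
  E <- matrix(NA_real_, length(mods), ncol(values),
              dimnames = list(paste0("M", mods), colnames(values)))
  for (i in seq_along(mods)) {
    members <- names(labels)[labels == mods[i]]
    X <- values[members, , drop = FALSE]
    Xs <- t(scale(t(X)))                       # standardize each gene profile
    if (nrow(Xs) == 1) {
      e <- as.numeric(Xs)
    } else {
      sv <- svd(Xs, nu = 0, nv = 1)
      e <- sv$v[, 1]
    }
    if (stats::sd(e) == 0) stop("degenerate eigengene for module ", mods[i])
    if (sum(e * colMeans(Xs)) < 0) e <- -e     # orient toward mean profile
    E[i, ] <- e / stats::sd(e)
  }
  E
}

#' Merge correlated modules via their eigengenes
#'
#' Iteratively merges the pair of modules with the smallest eigengene
#' dissimilarity 1 - cor while that dissimilarity is below `merge_height`
#' (i.e. eigengene correlation above 1 - merge_height), recomputing
#' eigengenes after each merge. `literal_rule = TRUE` instead merges pairs
#' whose eigengene correlation is below `merge_height` (the strict-literal
#' reading of a common phrasing of the rule; not recommended).
#'
#' @param expr an [expression_matrix] or gene x sample matrix.
#' @param labels named integer module labels.
#' @param merge_height dissimilarity threshold (default 0.25).
#' @param literal_rule merge on low correlation instead of low
#'   dissimilarity (default FALSE).
#' @param power soft-threshold metadata carried into the result.
#' @return a [module_decomposition] with relabeled modules, eigengenes and
#'   gene x module membership.
#' @export
merge_modules <- function(expr, labels, merge_height = 0.25,
                          literal_rule = FALSE, power = NA_real_) {
  values <- .values_of(expr)
  labels <- labels[rownames(values)]
  repeat {
    mods <- sort(setdiff(unique(labels), 0))
    if (length(mods) < 2) break
    E <- module_eigengenes(values, labels)
    cc <- stats::cor(t(E))
    diag(cc) <- NA
    if (literal_rule) {
      crit <- cc          # merge the most correlated pair below threshold?
      pair <- which(crit == min(crit, na.rm = TRUE), arr.ind = TRUE)[1, ]
      if (min(crit, na.rm = TRUE) >= merge_height) break
    } else {
      diss <- 1 - cc
      pair <- which(diss == min(diss, na.rm = TRUE), arr.ind = TRUE)[1, ]
      if (min(diss, na.rm = TRUE) >= merge_height) break
    }
    keep <- mods[min(pair)]; absorb <- mods[max(pair)]
    labels[labels == absorb] <- keep
  }
  # relabel by decreasing size, preserving unassigned 0
  mods <- setdiff(unique(labels), 0)
  sizes <- table(factor(labels[labels != 0], levels = mods))
  ord <- mods[order(-sizes, mods)]
  new <- labels
  for (i in seq_along(ord)) new[labels == ord[i]] <- i
  labels <- new
  E <- module_eigengenes(values, labels)
  M <- module_membership(values, E)
  module_decomposition(labels, eigengenes = E, membership = M, power = power)
}

#' Gene-by-module membership (kME)
#'
#' membership(g, m) = Pearson correlation between gene g's profile and
#' module m's eigengene; a measure of how central the gene is to the module.
#'
#' @param expr an [expression_matrix] or gene x sample matrix.
#' @param eigengenes module x sample matrix from [module_eigengenes].
#' @return gene x module matrix of correlations in \[-1, 1\].
#' @export
module_membership <- function(expr, eigengenes) {
  values <- .values_of(expr)
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(values)[sds == 0], 5), collapse = ", "))
  stats::cor(t(values), t(eigengenes))
}

#' Export thresholded network edges
#'
#' Returns all unordered gene pairs whose TOM weight reaches `threshold`,
#' annotated with the endpoints' module labels when given.
#'
#' @param tom symmetric weight matrix.
#' @param threshold minimum edge weight (inclusive; default 0.02).
#' @param labels optional named module labels for endpoint annotation.
#' @return data.frame `source`, `target`, `weight`, `source_module`,
#'   `target_module`, in deterministic (source, target) order.
#' @export
export_edges <- function(tom, threshold = 0.02, labels = NULL) {
  tom <- as.matrix(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  idx <- which(upper.tri(tom) & tom >= threshold, arr.ind = TRUE)
  out <- data.frame(source = genes[idx[, 1]], target = genes[idx[, 2]],
                    weight = tom[idx], stringsAsFactors = FALSE)
  lab <- function(g) {
    if (is.null(labels)) rep(NA_integer_, length(g)) else unname(labels[g])
  }
  out$source_module <- lab(out$source)
  out$target_module <- lab(out$target)
  out[order(out$source, out$target), , drop = FALSE]
}
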