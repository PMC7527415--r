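#' Weighted network container
#'
#' Shared container for directed TF-target regulatory networks and
#' undirected co-expression/co-methylation networks.
#'
#' @param edges data.frame with `source`, `target`, `weight` (>= 0 finite);
#'   for directed GRNs also `target_fit`.
#' @param directed logical.
#' @param node_roles named character vector mapping gene -> "TF"/"nonTF".
#' @param model_fit optional named numeric of per-target fit metrics.
#' @return `weighted_network` object.
#' @export
weighted_network <- function(edges, directed, node_roles = NULL,
                             model_fit = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and non-negative")
  if (any(edges$source == edges$target)) stop("self-edges are not allowed")
  if (directed && !is.null(node_roles)) {
    src_roles <- node_roles[edges$source]
    if (any(is.na(src_roles)) || any(src_roles != "TF"))
      stop("in a directed GRN every edge source must be a TF")
  }
  structure(list(edges = edges, directed = directed, node_roles = node_roles,
                 model_fit = model_fit),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network (%s): %d edges, %d nodes\n",
              if (x$directed) "directed" else "undirected", nrow(x$edges),
              length(unique(c(x$edges$source, x$edges$target)))))
  invisible(x)
}

# Deterministic 31-adic string hash into [0, 2^31 - 2]; used to derive
# per-target RF seeds that are stable under changes to the target set.
.string_seed <- function(s, master) {
  h <- as.numeric(master %% 2147483647L)
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Infer a TF-target gene regulatory network with random forests
#'
#' For every eligible target gene, fits a random-forest regression of the
#' target's standardized profile on all transcription-factor profiles
#' (excluding the target itself when it is a TF), with sqrt-of-#TF
#' candidate features per split. The weight of edge TF -> target is the
#' TF's total impurity-decrease importance in that forest. Targets
#' expressed in fewer than `min_samples_expressed` samples are dropped
#' up front, and targets whose out-of-bag variance explained falls below
#' `fit_threshold` are discarded afterwards, keeping only well-modelled
#' targets in the network.
#'
#' Samples are put in canonical (sorted sample-ID) order and each target
#' gets a seed derived deterministically from `seed` and its own ID, so
#' results do not depend on input sample or target order.
#'
#' @param expr an [expression_matrix] or gene x sample matrix
#'   (variance-stabilized scale).
#' @param tf_list character vector of TF gene IDs, all present in `expr`.
#' @param n_trees trees per forest (default 1000).
#' @param min_samples_expressed minimum number of samples in which a target
#'   must be expressed (default 10).
#' @param fit_threshold minimum out-of-bag variance explained (default 0.5).
#' @param seed master seed.
#' @param counts optional gene x sample raw count matrix; when supplied,
#'   "expressed" means count > 0, otherwise value > row minimum.
#' @param expressed_predicate optional function(row_values) -> logical
#'   vector overriding the default expressed test.
#' @param literal_fit_filter if TRUE, apply the inverted reading of the fit
#'   filter (keep targets with OOB variance explained <= `fit_threshold`).
#' @param normalize_importance if TRUE, scale each target's importances to
#'   sum to 1 before reporting.
#' @return a directed [weighted_network]; `model_fit` holds OOB variance
#'   explained for every fitted target (including discarded ones).
#' @export
infer_grn <- function(expr, tf_list, n_trees = 1000,
                      min_samples_expressed = 10, fit_threshold = 0.5,
                      seed = 1, counts = NULL, expressed_predicate = NULL,
                      literal_fit_filter = FALSE,
                      normalize_importance = FALSE) {
  values <- .values_of(expr)
  if (n_trees < 1) stop("n_trees must be >= 1")
  absent <- setdiff(tf_list, rownames(values))
  if (length(absent))
    stop("TF(s) absent from the expression matrix: ",
         paste(utils::head(absent, 5), collapse = ", "))
  if (length(tf_list) < 2) stop("at least 2 TFs are required")
  values <- values[, order(colnames(values)), drop = FALSE]  # canonical order
  if (!is.null(counts)) counts <- counts[, colnames(values), drop = FALSE]

  expressed_in <- function(g) {
    row <- values[g, ]
    if (!is.null(expressed_predicate)) return(sum(expressed_predicate(row)))
    if (!is.null(counts)) return(sum(counts[g, ] > 0))
    sum(row > min(row))
  }
  genes <- rownames(values)
  n_expr <- vapply(genes, expressed_in, numeric(1))
  targets <- genes[n_expr >= min_samples_expressed]
  targets <- targets[apply(values[targets, , drop = FALSE], 1, stats::sd) > 0]

  edge_list <- vector("list", length(targets))
  fits <- stats::setNames(rep(NA_real_, length(targets)), targets)
  for (i in seq_along(targets)) {
    g <- targets[i]
    preds <- setdiff(tf_list, g)
    x <- t(values[preds, , drop = FALSE])
    y <- as.numeric(scale(values[g, ]))
    rf <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                         mtry = ceiling(sqrt(length(preds))),
                         importance = "impurity", num.threads = 1,
                         seed = .string_seed(g, seed))
    fits[g] <- rf$r.squared
    imp <- rf$variable.importance
    if (normalize_importance && sum(imp) > 0) imp <- imp / sum(imp)
    edge_list[[i]] <- data.frame(source = names(imp), target = g,
                                 weight = unname(imp),
                                 stringsAsFactors = FALSE)
  }
  keep <- if (literal_fit_filter) fits <= fit_threshold else fits >= fit_threshold
  kept_targets <- names(fits)[keep]
  edges <- do.call(rbind, edge_list)
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric())
  edges <- edges[edges$target %in% kept_targets, , drop = FALSE]
  edges$target_fit <- unname(fits[edges$target])
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  roles <- stats::setNames(ifelse(genes %in% tf_list, "TF", "nonTF"), genes)
  out <- weighted_network(edges, directed = TRUE, node_roles = roles,
                          model_fit = fits)
  attr(out, "params") <- list(n_trees = n_trees,
                              min_samples_expressed = min_samples_expressed,
                              fit_threshold = fit_threshold, seed = seed,
                              literal_fit_filter = literal_fit_filter,
                              normalize_importance = normalize_importance)
  out
}
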