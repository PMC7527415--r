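#' Select the top fraction of TF-incident network edges
#'
#' For an undirected co-expression network, edges with at least one TF
#' endpoint are oriented TF -> partner (a TF-TF edge contributes both
#' directions); a directed GRN is used as-is. All candidate directed edges
#' are ranked by weight (ties broken lexicographically by source then
#' target, for reproducibility) and the top `ceiling(fraction * N)` are
#' kept.
#'
#' @param network a [weighted_network].
#' @param fraction fraction of candidate edges to keep, in (0, 1\]
#'   (default 0.05).
#' @return named list mapping each TF to its retained target set;
#'   attribute `edges` holds the retained directed edges.
#' @export
top_edges <- function(network, fraction = 0.05) {
  stopifnot(inherits(network, "weighted_network"))
  if (length(fraction) != 1 || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  edges <- network$edges
  if (!network$directed) {
    roles <- network$node_roles
    if (is.null(roles)) stop("undirected network needs node_roles")
    is_tf <- function(g) !is.na(roles[g]) & roles[g] == "TF"
    src_tf <- is_tf(edges$source); tgt_tf <- is_tf(edges$target)
    fwd <- edges[src_tf, c("source", "target", "weight"), drop = FALSE]
    rev <- edges[tgt_tf, , drop = FALSE]
    rev <- data.frame(source = rev$target, target = rev$source,
                      weight = rev$weight, stringsAsFactors = FALSE)
    cand <- rbind(fwd, rev)
  } else {
    cand <- edges[, c("source", "target", "weight"), drop = FALSE]
  }
  if (nrow(cand) == 0) stop("network has no TF-incident edges")
  ord <- order(-cand$weight, cand$source, cand$target)
  cand <- cand[ord, , drop = FALSE]
  n_keep <- ceiling(fraction * nrow(cand))
  kept <- cand[seq_len(n_keep), , drop = FALSE]
  rownames(kept) <- NULL
  out <- split(kept$target, kept$source)
  out <- lapply(out, unique)
  attr(out, "edges") <- kept
  out
}

#' One-tailed hypergeometric TF-target enrichment
#'
#' For a TF with K targets in a universe of N genes of which n belong to
#' the gene set, and k of the TF's targets in the set, the enrichment
#' p-value is the upper tail P(X >= k) with X ~ Hypergeometric(N, K, n)
#' (the observed count included). A TF with no targets gets p_E = 1 and a
#' flag.
#'
#' @param tf_targets named list TF -> character vector of targets, all
#'   within `universe`.
#' @param gene_set character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector of all target-eligible genes.
#' @return data.frame `tf_id`, `n_targets`, `n_targets_in_set`, `p_e`,
#'   `no_targets`.
#' @export
tf_enrichment <- function(tf_targets, gene_set, universe) {
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, universe)
  if (length(outside))
    stop("gene_set members outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  bad <- names(tf_targets)[vapply(tf_targets, function(t)
    length(setdiff(t, universe)) > 0, logical(1))]
  if (length(bad))
    stop("target sets outside the universe for TF(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  N <- length(universe); n <- length(gene_set)
  res <- lapply(names(tf_targets), function(tf) {
    tg <- unique(tf_targets[[tf]])
    K <- length(tg); k <- length(intersect(tg, gene_set))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
    data.frame(tf_id = tf, n_targets = K, n_targets_in_set = k, p_e = p,
               no_targets = K == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Score and rank regulators
#'
#' Combines each TF's target-set enrichment p-value with its own
#' differential-expression evidence:
#' score = norm(-log p_E) + norm(-log p_D), where norm(x) =
#' (x - min x) / (max x - min x) is taken per column across TFs. A TF is a
#' key TF when p_E < `alpha_e` and p_D < `alpha_d`. When a column is
#' constant its normalized values are defined as all zeros.
#'
#' @param enrich result of [tf_enrichment] (columns `tf_id`, `p_e`, and
#'   optionally `n_targets`, `n_targets_in_set`).
#' @param diff_table data.frame with `gene`, `p`, `log2fc` giving per-TF
#'   differential statistics; TFs absent from it get p_D = 1, log2fc = 0.
#' @param alpha_e,alpha_d significance cutoffs (default 0.05 each).
#' @return a `regulator_table` data.frame sorted by score descending:
#'   `tf_id`, `p_e`, `p_d`, `log2fc`, `n_targets`, `n_targets_in_set`,
#'   `score`, `key_tf`.
#' @export
score_regulators <- function(enrich, diff_table, alpha_e = 0.05,
                             alpha_d = 0.05) {
  enrich <- as.data.frame(enrich)
  diff_table <- as.data.frame(diff_table)
  stopifnot(all(c("tf_id", "p_e") %in% names(enrich)),
            all(c("gene", "p") %in% names(diff_table)))
  m <- match(enrich$tf_id, diff_table$gene)
  p_d <- ifelse(is.na(m), 1, diff_table$p[m])
  log2fc <- if ("log2fc" %in% names(diff_table))
    ifelse(is.na(m), 0, diff_table$log2fc[m]) else rep(NA_real_, nrow(enrich))
  clamp <- function(p, label) {
    if (any(p <= 0)) {
      warning(label, " p-values of 0 clamped to the smallest positive double")
      p[p <= 0] <- .Machine$double.xmin
    }
    p
  }
  p_e <- clamp(enrich$p_e, "enrichment")
  p_d <- clamp(p_d, "differential")
  norm01 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) {
      message("constant -log(p) column; normalized scores set to 0")
      return(rep(0, length(x)))
    }
    (x - rng[1]) / diff(rng)
  }
  score <- norm01(-log(p_e)) + norm01(-log(p_d))
  out <- data.frame(
    tf_id = enrich$tf_id, p_e = p_e, p_d = p_d, log2fc = log2fc,
    n_targets = if ("n_targets" %in% names(enrich)) enrich$n_targets else NA,
    n_targets_in_set = if ("n_targets_in_set" %in% names(enrich))
      enrich$n_targets_in_set else NA,
    score = score,
    key_tf = p_e < alpha_e & p_d < alpha_d,
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$tf_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regulator_table", "data.frame")
  out
}

#' TF-TF subnetwork among key regulators
#'
#' Keeps only edges whose both endpoints are key TFs, and marks each key TF
#' with a display flag for |log2FC| above `log2fc_cutoff` (a visualization
#' filter only: it does not remove nodes).
#'
#' @param reg a `regulator_table` from [score_regulators].
#' @param edges directed edge data.frame (`source`, `target`, `weight`),
#'   e.g. `attr(top_edges(net), "edges")`.
#' @param log2fc_cutoff display threshold on |log2FC| (default 0.6).
#' @return list with `edges` (both endpoints key TFs) and `nodes`
#'   (`tf_id`, `log2fc`, `display`).
#' @export
tf_tf_network <- function(reg, edges, log2fc_cutoff = 0.6) {
  reg <- as.data.frame(reg)
  key <- reg$tf_id[reg$key_tf]
  edges <- as.data.frame(edges)
  kept <- edges[edges$source %in% key & edges$target %in% key, , drop = FALSE]
  rownames(kept) <- NULL
  nodes <- data.frame(tf_id = key,
                      log2fc = reg$log2fc[match(key, reg$tf_id)],
                      stringsAsFactors = FALSE)
  nodes$display <- !is.na(nodes$log2fc) & abs(nodes$log2fc) > log2fc_cutoff
  list(edges = kept, nodes = nodes)
}

#' Run the full regulator-enrichment pipeline
#'
#' Three steps: (1) build a data-driven network from expression — either an
#' undirected co-expression network (unsigned adjacency, TOM, edge export)
#' or a directed random-forest GRN; (2) keep the top fraction of TF-target
#' edges; (3) test each TF's target set for enrichment in `gene_set`
#' (one-tailed hypergeometric, universe = all target-eligible genes of the
#' network) and combine with differential evidence into a ranked regulator
#' table.
#'
#' @param expr an [expression_matrix].
#' @param tf_list character vector of TF IDs present in `expr`.
#' @param gene_set genes of interest (e.g. the differential signature).
#' @param diff_table optional data.frame (`gene`, `p`, `log2fc`); when NULL
#'   the package's own per-feature OLS test on the `condition` design
#'   column supplies p_D and group-mean log2fc is computed from the design
#'   (flagged in metadata).
#' @param network_mode "grn" (default) or "coexpression".
#' @param top_fraction fraction of edges kept (default 0.05).
#' @param power soft-thresholding power for coexpression mode (default 6).
#' @param edge_threshold TOM export threshold for coexpression mode
#'   (default 0.02).
#' @param alpha_e,alpha_d key-TF cutoffs (default 0.05).
#' @param seed master seed for the GRN forests.
#' @param ... further arguments passed to [infer_grn].
#' @return a `regulator_table`; attributes `metadata` (mode, parameters,
#'   seed, p_D source), `network`, and `tf_targets`.
#' @export
run_regenrich <- function(expr, tf_list, gene_set, diff_table = NULL,
                          network_mode = c("grn", "coexpression"),
                          top_fraction = 0.05, power = 6,
                          edge_threshold = 0.02, alpha_e = 0.05,
                          alpha_d = 0.05, seed = 1, ...) {
  network_mode <- match.arg(network_mode)
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(gene_set) == 0) stop("stage gene_set: gene_set is empty")
  p_d_source <- "user-supplied differential table"
  if (is.null(diff_table)) {
    if (is.null(expr$design) || !"condition" %in% names(expr$design))
      stop("stage differential: no diff_table and no 'condition' design column")
    dt <- differential_linear_model(expr$values, expr$design,
                                    test_term = "condition")
    cond <- expr$design$condition
    lfc <- rowMeans(expr$values[, cond == max(cond), drop = FALSE]) -
      rowMeans(expr$values[, cond == min(cond), drop = FALSE])
    diff_table <- data.frame(gene = dt$feature_id, p = dt$p,
                             log2fc = unname(lfc[dt$feature_id]))
    p_d_source <- "built-in linear-model stand-in on the condition term"
  }
  net <- switch(network_mode,
    grn = tryCatch(infer_grn(expr, tf_list, seed = seed, ...),
                   error = function(e) stop("stage grn: ", conditionMessage(e))),
    coexpression = tryCatch({
      adj <- adjacency(expr, power = power)
      tom <- topological_overlap(adj)
      edges <- export_edges(tom, threshold = edge_threshold)
      roles <- stats::setNames(
        ifelse(rownames(expr$values) %in% tf_list, "TF", "nonTF"),
        rownames(expr$values))
      weighted_network(edges, directed = FALSE, node_roles = roles)
    }, error = function(e) stop("stage coexpression: ", conditionMessage(e))))
  tf_targets <- tryCatch(top_edges(net, fraction = top_fraction),
                         error = function(e) stop("stage top_edges: ",
                                                  conditionMessage(e)))
  universe <- unique(net$edges$target)
  if (!net$directed)
    universe <- unique(c(net$edges$source, net$edges$target))
  gene_set_used <- intersect(gene_set, universe)
  if (length(gene_set_used) == 0)
    stop("stage enrichment: gene_set has no overlap with the network universe")
  enrich <- tf_enrichment(tf_targets, gene_set_used, universe)
  reg <- score_regulators(enrich, diff_table, alpha_e = alpha_e,
                          alpha_d = alpha_d)
  attr(reg, "metadata") <- list(
    mode = network_mode, top_fraction = top_fraction, power = power,
    edge_threshold = edge_threshold, alpha_e = alpha_e, alpha_d = alpha_d,
    seed = seed, universe_size = length(universe),
    gene_set_size = length(gene_set_used), p_d_source = p_d_source)
  attr(reg, "network") <- net
  attr(reg, "tf_targets") <- tf_targets
  reg
}
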