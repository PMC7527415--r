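test_that("top-edge selection counts, orients and tie-breaks deterministically", {
  set.seed(1)
  edges <- data.frame(source = paste0("TF", rep(1:5, each = 20)),
                      target = paste0("g", 1:100),
                      weight = runif(100))
  net <- weighted_network(edges, directed = TRUE,
                          node_roles = setNames(
                            c(rep("TF", 5), rep("nonTF", 100)),
                            c(paste0("TF", 1:5), paste0("g", 1:100))))
  tt <- top_edges(net, fraction = 0.05)
  kept <- attr(tt, "edges")
  expect_equal(nrow(kept), 5)  # ceiling(0.05 * 100)
  expect_equal(kept$weight, sort(edges$weight, decreasing = TRUE)[1:5])

  # all weights equal: lexicographic (source, target) tie-break, exact count
  edges$weight <- 1
  net2 <- weighted_network(edges, directed = TRUE, node_roles = net$node_roles)
  tt2 <- top_edges(net2, fraction = 0.05)
  kept2 <- attr(tt2, "edges")
  expect_equal(nrow(kept2), 5)
  expect_equal(kept2$source, rep("TF1", 5))
  expect_equal(kept2$target, sort(kept2$target))
  expect_error(top_edges(net, fraction = 0), "fraction")
  expect_error(top_edges(net, fraction = 1.5), "fraction")
})

test_that("undirected networks are restricted to TF-incident edges and oriented", {
  edges <- data.frame(source = c("TF1", "g1", "TF1", "g2"),
                      target = c("g1", "g2", "TF2", "g3"),
                      weight = c(0.9, 0.8, 0.7, 0.6))
  roles <- setNames(c("TF", "TF", "nonTF", "nonTF", "nonTF"),
                    c("TF1", "TF2", "g1", "g2", "g3"))
  net <- weighted_network(edges, directed = FALSE, node_roles = roles)
  tt <- top_edges(net, fraction = 1)
  kept <- attr(tt, "edges")
  # g1-g2 and g2-g3 have no TF endpoint; TF1-TF2 contributes both directions
  expect_equal(nrow(kept), 3)
  expect_setequal(unique(kept$source), c("TF1", "TF2"))
  expect_true(all(c("g1", "TF2") %in% tt$TF1))
  expect_equal(tt$TF2, "TF1")
})

test_that("hypergeometric enrichment equals exhaustive enumeration up to N = 12", {
  # spec hand case: N=10, K=4, n=5, k=4
  universe <- paste0("g", 1:10)
  res <- tf_enrichment(list(A = universe[1:4]), universe[c(1:4, 7)], universe)
  expect_equal(res$p_e, 6 / 252, tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:40) {
    N <- sample(4:12, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    universe <- paste0("u", seq_len(N))
    targets <- universe[seq_len(K)]
    gene_set <- sample(universe, n)
    k <- length(intersect(targets, gene_set))
    got <- tf_enrichment(setNames(list(targets), "TF"), gene_set,
                         universe)$p_e
    expect_equal(got, enumerate_hypergeom_upper(N, K, n, k),
                 tolerance = 1e-10)
  }
})

test_that("degenerate enrichment cases behave as contracts state", {
  universe <- paste0("g", 1:10)
  # TF with no targets: p_E = 1 with a flag
  res <- tf_enrichment(list(Z = character(0)), universe[1:5], universe)
  expect_equal(res$p_e, 1)
  expect_true(res$no_targets)
  # gene_set = universe saturates: p_E = 1 for every TF
  res2 <- tf_enrichment(list(A = universe[1:4], B = universe[7:10]),
                        universe, universe)
  expect_equal(res2$p_e, c(1, 1))
  expect_error(tf_enrichment(list(A = universe[1:2]), c("g1", "nope"),
                             universe), "outside the universe")
})

test_that("regulator scores follow the min-max normalized -log p sum", {
  enrich <- data.frame(tf_id = c("A", "B"), p_e = c(0.01, 0.1))
  diff <- data.frame(gene = c("A", "B"), p = c(0.05, 0.5), log2fc = c(1, 0.2))
  reg <- score_regulators(enrich, diff)
  expect_equal(reg$score[reg$tf_id == "A"], 2)
  expect_equal(reg$score[reg$tf_id == "B"], 0)
  # both conditions needed for key status: p_d = 0.05 is not < 0.05
  expect_false(any(reg$key_tf))
  reg2 <- score_regulators(enrich,
                           data.frame(gene = c("A", "B"), p = c(0.04, 0.06),
                                      log2fc = 0))
  expect_true(reg2$key_tf[reg2$tf_id == "A"])
  expect_false(reg2$key_tf[reg2$tf_id == "B"])  # p_e 0.1 and p_d 0.06

  # identical p-values in both columns: all scores 0 (degenerate norm rule)
  same <- data.frame(tf_id = c("A", "B", "C"), p_e = 0.2)
  dsame <- data.frame(gene = c("A", "B", "C"), p = 0.3, log2fc = 0)
  expect_message(reg3 <- score_regulators(same, dsame), "constant")
  expect_equal(reg3$score, rep(0, 3))
})

test_that("scores are bounded in [0,2], base-invariant and order-invariant", {
  set.seed(7)
  n <- 20
  enrich <- data.frame(tf_id = paste0("TF", 1:n), p_e = runif(n))
  diff <- data.frame(gene = paste0("TF", 1:n), p = runif(n), log2fc = rnorm(n))
  reg <- score_regulators(enrich, diff)
  expect_true(all(reg$score >= 0 & reg$score <= 2))
  # min-max normalization makes the log base irrelevant: recompute in log10
  norm01 <- function(x) (x - min(x)) / (max(x) - min(x))
  alt <- norm01(-log10(enrich$p_e)) + norm01(-log10(diff$p))
  expect_equal(sort(reg$score), sort(alt), tolerance = 1e-12)
  # permuting TF input order leaves the ranking unchanged
  perm <- sample(n)
  reg_p <- score_regulators(enrich[perm, ], diff)
  expect_equal(reg_p$tf_id, reg$tf_id)
  expect_equal(reg_p$score, reg$score)
})

test_that("p-values of zero are clamped with a warning", {
  enrich <- data.frame(tf_id = c("A", "B"), p_e = c(0, 0.5))
  diff <- data.frame(gene = c("A", "B"), p = c(0.2, 0.4), log2fc = 0)
  expect_warning(reg <- score_regulators(enrich, diff), "clamped")
  expect_true(all(reg$p_e > 0))
})

test_that("TF-TF networks keep only key-TF edges; log2fc is a display filter", {
  reg <- data.frame(tf_id = c("A", "B", "C"),
                    log2fc = c(0.5, 1.2, 2),
                    key_tf = c(TRUE, TRUE, FALSE))
  edges <- data.frame(source = c("A", "A", "B", "C"),
                      target = c("B", "C", "C", "A"),
                      weight = 1:4)
  net <- tf_tf_network(reg, edges, log2fc_cutoff = 0.6)
  expect_equal(nrow(net$edges), 1)  # only A -> B has two key endpoints
  expect_equal(net$edges$source, "A")
  # A is a key TF below the display cutoff: present but not displayed
  expect_true("A" %in% net$nodes$tf_id)
  expect_false(net$nodes$display[net$nodes$tf_id == "A"])
  expect_true(net$nodes$display[net$nodes$tf_id == "B"])
  # no key TFs: empty network
  reg$key_tf <- FALSE
  expect_equal(nrow(tf_tf_network(reg, edges)$edges), 0)
})

test_that("the end-to-end pipeline is deterministic and finds the planted master", {
  spec <- fixture_spec(seed = 5)
  gen <- generate_expression(spec)
  dt <- generate_differential_table(gen)
  reg1 <- run_regenrich(gen$expr, gen$truth$tf_list, gen$truth$de_genes,
                        diff_table = dt, network_mode = "grn", seed = 5)
  reg2 <- run_regenrich(gen$expr, gen$truth$tf_list, gen$truth$de_genes,
                        diff_table = dt, network_mode = "grn", seed = 5)
  expect_equal(as.data.frame(reg1), as.data.frame(reg2))
  master <- gen$truth$planted_regulators[1]
  expect_lte(match(master, reg1$tf_id), 3)
  meta <- attr(reg1, "metadata")
  expect_equal(meta$mode, "grn")
  expect_equal(meta$seed, 5)
})

test_that("coexpression-mode enrichment runs and respects the mode contract", {
  spec <- fixture_spec(n_donors = 3, seed = 2)
  gen <- generate_expression(spec)
  dt <- generate_differential_table(gen)
  reg <- run_regenrich(gen$expr, gen$truth$tf_list, gen$truth$de_genes,
                       diff_table = dt, network_mode = "coexpression",
                       power = 6, seed = 2)
  expect_s3_class(reg, "regulator_table")
  expect_true(all(reg$score >= 0 & reg$score <= 2))
  net <- attr(reg, "network")
  expect_false(net$directed)
})
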