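# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# triple-loop TOM evaluation straight from the definition
brute_force_tom <- function(a) {
  n <- nrow(a)
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a0[i, u] * a0[u, j]
    tom[i, j] <- (s + a0[i, j]) / (min(k[i], k[j]) + 1 - a0[i, j])
  }
  tom
}

random_symmetric_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) draws of the gene set, counting how many hit >= k of the targets
enumerate_hypergeom_upper <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  targets <- seq_len(K)
  hits <- apply(sets, 2, function(s) sum(s %in% targets))
  mean(hits >= k)
}

# two-tailed Fisher exact p by enumerating all 2x2 tables with the
# observed margins and summing probabilities <= that of the observed table
enumerate_fisher_two_tail <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  p_of <- function(a) stats::dhyper(a, c1, N - c1, r1)
  p_obs <- p_of(tab[1, 1])
  a_range <- max(0, r1 + c1 - N):min(r1, c1)
  sum(vapply(a_range, p_of, numeric(1))[
    vapply(a_range, p_of, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# rank-based AUROC (Wilcoxon identity); scores higher = more confident
rank_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# adjusted Rand index from the pair-counting contingency formula
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(sum(tab))
  expected <- sum_i * sum_j / total
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# minimal methylation fixture: explicit matrices, no generator involved
tiny_methylation <- function(n_probes = 4, n_samples = 4, genes = "G1",
                             regions = "TSS200") {
  probes <- paste0("p", seq_len(n_probes))
  samples <- paste0("s", seq_len(n_samples))
  M <- matrix(100, n_probes, n_samples, dimnames = list(probes, samples))
  U <- matrix(100, n_probes, n_samples, dimnames = list(probes, samples))
  ann <- data.frame(probe_id = probes,
                    gene = rep_len(genes, n_probes),
                    region = rep_len(regions, n_probes),
                    chrom = "chr1", snp = FALSE, multimap = FALSE,
                    stringsAsFactors = FALSE)
  list(M = M, U = U, ann = ann, probes = probes, samples = samples)
}

# samples x 2 coordinates with a planted exactly-embeddable geometry
embeddable_distances <- function(n, seed = 1) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(n * 2), n, 2)
  list(points = pts, d = as.matrix(stats::dist(pts)))
}
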