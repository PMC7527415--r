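make_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

test_that("unsigned adjacency is |cor|^power with unit diagonal", {
  x <- make_expr(4, 12)
  x[2, ] <- -0.5 * x[1, ] + sqrt(1 - 0.25) * x[4, ]  # engineered correlation
  a <- adjacency(x, power = 6)
  expect_equal(diag(a), rep(1, 4), ignore_attr = TRUE)
  expect_equal(a, t(a))
  r <- cor(x[1, ], x[2, ])
  expect_equal(a[1, 2], abs(r)^6)
  expect_equal(abs(-0.5)^6, 0.015625)  # the |cor|^power map at cor = -0.5
  # zero-variance gene is rejected by name
  x[3, ] <- 7
  expect_error(adjacency(x, 6), "g3")
})

test_that("scale-free fit index is 1 for an exact power law and table is per power", {
  # connectivity profile engineered so binned log-log fit is exactly linear
  # use the analytic path: test .scale_free_fit via a network whose degree
  # sequence is a perfect power law across bins
  x <- make_expr(30, 20)
  out <- pick_soft_threshold(x, powers = c(2, 6))
  expect_equal(out$power, c(2, 6))
  expect_equal(nrow(out), 2)
  expect_true(all(out$mean_connectivity > 0))
  # perfect power-law check on the internal fit: p(k) ~ k^-1 exactly
  k <- rep(c(1, 2, 4, 8, 16), times = c(16, 8, 4, 2, 1))
  fit <- suppressWarnings(regenet:::.scale_free_fit(k, n_bins = 30))
  expect_equal(abs(fit$r2), 1, tolerance = 1e-8)
  expect_gt(fit$r2, 0)  # decaying distribution: signed index positive
})

test_that("TOM matches hand cases and the brute-force oracle", {
  # 3 nodes fully connected with weight 1: TOM_12 = (1+1)/(2+1-1) = 1
  a <- matrix(1, 3, 3)
  expect_equal(topological_overlap(a)[1, 2], 1)
  # empty network: off-diagonal TOM is 0
  e <- diag(4)
  expect_equal(unname(topological_overlap(e)[1, 2]), 0)
  expect_equal(diag(topological_overlap(e)), rep(1, 4))
  # star graph has no shared neighbors between leaves and the hub:
  # TOM(hub, leaf) reduces to a_ij / (min(k)+1-a_ij) checked via oracle
  set.seed(5)
  for (i in 1:25) {
    a <- random_symmetric_adjacency(6)
    expect_equal(topological_overlap(a), brute_force_tom(a),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  tom <- topological_overlap(random_symmetric_adjacency(8))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

planted_tom <- function(n_blocks, block_size, n_samples, rho = 0.8,
                        seed = 1) {
  set.seed(seed)
  n <- n_blocks * block_size
  f <- matrix(rnorm(n_blocks * n_samples), n_blocks, n_samples)
  x <- matrix(rnorm(n * n_samples) * sqrt(1 - rho), n, n_samples)
  labels <- rep(seq_len(n_blocks), each = block_size)
  x <- x + sqrt(rho) * f[labels, ]
  rownames(x) <- paste0("g", seq_len(n))
  list(x = x, labels = setNames(labels, rownames(x)),
       tom = topological_overlap(adjacency(x, power = 6)))
}

test_that("module detection recovers planted blocks and enforces min size", {
  p <- planted_tom(2, 40, 24, seed = 3)
  det <- detect_modules(p$tom, min_size = 30)
  found <- setdiff(unique(det$labels), 0)
  expect_equal(length(found), 2)
  expect_equal(adjusted_rand_index(p$labels, det$labels), 1)

  # fewer genes than min_size: everything unassigned, with a warning
  small <- planted_tom(1, 10, 24)
  expect_warning(d0 <- detect_modules(small$tom, min_size = 30), "unassigned")
  expect_true(all(d0$labels == 0))

  # one tight block of 35 plus 5 scattered genes
  set.seed(8)
  f <- rnorm(24)
  x <- rbind(t(sapply(1:35, function(i) sqrt(0.85) * f + sqrt(0.15) * rnorm(24))),
             matrix(rnorm(5 * 24), 5, 24))
  rownames(x) <- paste0("g", 1:40)
  tom <- topological_overlap(adjacency(x, power = 6))
  det2 <- detect_modules(tom, min_size = 30)
  expect_equal(length(setdiff(unique(det2$labels), 0)), 1)
  expect_gte(sum(det2$labels == 1), 30)
  expect_true(all(det2$labels[36:40] == 0))
})

test_that("eigengenes summarize modules as the leading principal component", {
  # identical profiles: eigengene equals the standardized shared profile
  set.seed(2)
  base <- rnorm(12)
  x <- matrix(rep(base, each = 5), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  labels <- setNames(rep(1L, 5), rownames(x))
  E <- module_eigengenes(x, labels)
  expect_equal(unname(E[1, ]), as.numeric(scale(base)) / sd(scale(base)),
               tolerance = 1e-10)
  expect_equal(sd(E[1, ]), 1)
  expect_gte(cor(E[1, ], base), 0.999)

  # genes = +/- same profile in equal numbers: orientation follows the rule
  x2 <- rbind(x[1:2, ], -x[1:2, ])
  rownames(x2) <- paste0("h", 1:4)
  labels2 <- setNames(rep(1L, 4), rownames(x2))
  E2 <- module_eigengenes(x2, labels2)
  expect_equal(abs(cor(E2[1, ], base)), 1, tolerance = 1e-10)

  # eigengene maximizes explained member variance (vs full eigendecomposition)
  set.seed(9)
  xm <- matrix(rnorm(6 * 10), 6, 10,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  lab <- setNames(rep(1L, 6), rownames(xm))
  E3 <- module_eigengenes(xm, lab)
  xs <- t(scale(t(xm)))
  ev <- eigen(crossprod(xs))  # sample-space covariance eigendecomposition
  best <- ev$vectors[, 1]
  expect_equal(abs(cor(E3[1, ], best)), 1, tolerance = 1e-8)

  # two modules give two rows
  lab2 <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), rownames(xm))
  expect_equal(nrow(module_eigengenes(xm, lab2)), 2)
})

test_that("module merging follows the dissimilarity rule and terminates", {
  set.seed(4)
  base <- rnorm(16)
  mk <- function(f, n, noise) t(sapply(seq_len(n), function(i)
    sqrt(1 - noise) * f + sqrt(noise) * rnorm(16)))
  # modules 1 and 2 share a factor (eigengene cor ~ 1): must merge
  x <- rbind(mk(base, 6, 0.05), mk(base, 6, 0.05), mk(rnorm(16), 6, 0.05))
  rownames(x) <- paste0("g", 1:18)
  colnames(x) <- paste0("s", 1:16)
  labels <- setNames(rep(1:3, each = 6), rownames(x))
  dec <- merge_modules(x, labels)
  expect_equal(length(setdiff(unique(dec$labels), 0)), 2)
  merged <- unique(dec$labels[paste0("g", 1:12)])
  expect_equal(length(merged), 1)

  # anti-correlated eigengenes (cor ~ -0.9): dissimilarity ~1.9, no merge
  x2 <- rbind(mk(base, 6, 0.02), mk(-base, 6, 0.02))
  rownames(x2) <- paste0("g", 1:12)
  colnames(x2) <- paste0("s", 1:16)
  labels2 <- setNames(rep(1:2, each = 6), rownames(x2))
  dec2 <- merge_modules(x2, labels2)
  expect_equal(length(setdiff(unique(dec2$labels), 0)), 2)

  # stable configuration is a fixed point and invariant to label permutation
  x3 <- rbind(mk(rnorm(16), 6, 0.05), mk(rnorm(16), 6, 0.05))
  rownames(x3) <- paste0("g", 1:12)
  colnames(x3) <- paste0("s", 1:16)
  labels3 <- setNames(rep(1:2, each = 6), rownames(x3))
  dec3 <- merge_modules(x3, labels3)
  labels3_swapped <- setNames(rep(c(2L, 1L), each = 6), rownames(x3))
  dec3b <- merge_modules(x3, labels3_swapped)
  # same partition regardless of how input labels were numbered
  expect_equal(adjusted_rand_index(dec3$labels, dec3b$labels), 1)
  expect_equal(adjusted_rand_index(dec3$labels, labels3), 1)
})

test_that("module membership is the gene-eigengene correlation", {
  set.seed(6)
  e <- rnorm(14)
  x <- rbind(same = e, ortho = rnorm(14), anti = -e)
  x["ortho", ] <- residuals(lm(x["ortho", ] ~ e))  # exactly orthogonal
  colnames(x) <- paste0("s", 1:14)
  E <- matrix(scale(e)[, 1] / sd(scale(e)), 1, 14,
              dimnames = list("M1", colnames(x)))
  M <- module_membership(x, E)
  expect_equal(unname(M["same", "M1"]), 1, tolerance = 1e-10)
  expect_equal(unname(M["ortho", "M1"]), 0, tolerance = 1e-10)
  expect_equal(unname(M["anti", "M1"]), -1, tolerance = 1e-10)
  expect_true(all(M >= -1 & M <= 1))
  x2 <- rbind(x, flat = rep(1, 14))
  expect_error(module_membership(x2, E), "flat")
})

test_that("edge export applies an inclusive threshold and annotates modules", {
  tom <- matrix(c(1, 0.5, 0.01, 0.03,
                  0.5, 1, 0.02, 0.001,
                  0.01, 0.02, 1, 0.4,
                  0.03, 0.001, 0.4, 1), 4, 4,
                dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  labels <- setNames(c(1L, 1L, 2L, 2L), paste0("g", 1:4))
  edges <- export_edges(tom, threshold = 0.02, labels = labels)
  expect_equal(nrow(edges), 4)  # 0.5, 0.03, 0.02, 0.4 all >= 0.02
  expect_true(all(edges$weight >= 0.02))
  expect_equal(edges$source_module[edges$source == "g1" & edges$target == "g2"], 1L)
  expect_equal(nrow(export_edges(tom, threshold = 0)), 6)    # all pairs
  expect_equal(nrow(export_edges(tom, threshold = 1.01)), 0) # none
})
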