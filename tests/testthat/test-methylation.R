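test_that("beta values follow M/(M+U+offset) on hand cases and bounds", {
  fx <- tiny_methylation(3, 2)
  fx$M[] <- c(0, 100, 400, 0, 100, 400)
  fx$U[] <- c(0, 0, 100, 0, 0, 100)
  md <- methylation_data(fx$M, fx$U, fx$ann)
  b <- compute_beta(md)
  expect_equal(unname(b$beta[, 1]), c(0, 0.5, 400 / 600))
  expect_equal(b$level, "probe")
  # monotonicity and upper bound beta <= M/(M+offset) < 1
  m_grid <- seq(0, 5000, by = 250)
  betas <- m_grid / (m_grid + 50 + 100)
  expect_true(all(diff(betas) > 0))
  expect_true(all(betas <= m_grid / (m_grid + 100)))
})

test_that("negative signal is rejected naming the offending cell", {
  fx <- tiny_methylation(2, 2)
  fx$U["p2", "s1"] <- -5
  expect_error(methylation_data(fx$M, fx$U, fx$ann), "p2.*s1")
})

test_that("probe QC applies all five criteria with inclusive thresholds", {
  # 10 probes, 20 samples: 2 snp-flagged, 1 multimapping, 7 clean
  fx <- tiny_methylation(10, 20)
  fx$ann$snp[c(1, 2)] <- TRUE
  fx$ann$multimap[3] <- TRUE
  md <- methylation_data(fx$M, fx$U, fx$ann)
  out <- suppressWarnings(filter_probes(md))
  expect_equal(nrow(out$M), 7)
  removed <- attr(out, "removed")
  expect_equal(unname(removed["snp"]), 2)
  expect_equal(unname(removed["multimap"]), 1)

  # detection failure in exactly 1 of 20 samples (5%) is removed (inclusive)
  fx <- tiny_methylation(2, 20)
  det <- matrix(0, 2, 20, dimnames = dimnames(fx$M))
  det["p1", 1] <- 0.5
  md <- methylation_data(fx$M, fx$U, fx$ann, detection_p = det)
  out <- suppressWarnings(filter_probes(md))
  expect_false("p1" %in% rownames(out$M))
  expect_true("p2" %in% rownames(out$M))

  # sex-chromosome probes removed even when otherwise perfect
  fx <- tiny_methylation(2, 4)
  fx$ann$chrom[2] <- "chrX"
  md <- methylation_data(fx$M, fx$U, fx$ann)
  out <- suppressWarnings(filter_probes(md))
  expect_identical(rownames(out$M), "p1")

  # bead-count criterion
  fx <- tiny_methylation(2, 20)
  bc <- matrix(10, 2, 20, dimnames = dimnames(fx$M))
  bc["p2", 1] <- 2
  md <- methylation_data(fx$M, fx$U, fx$ann, bead_count = bc)
  out <- suppressWarnings(filter_probes(md))
  expect_false("p2" %in% rownames(out$M))
})

test_that("probe QC warns when optional matrices are absent and is idempotent", {
  fx <- tiny_methylation(5, 4)
  fx$ann$snp[1] <- TRUE
  md <- methylation_data(fx$M, fx$U, fx$ann)
  expect_warning(expect_warning(filter_probes(md), "detection_p"),
                 "bead_count")
  once <- suppressWarnings(filter_probes(md))
  twice <- suppressWarnings(filter_probes(once))
  expect_identical(rownames(once$M), rownames(twice$M))
  expect_identical(once$M, twice$M)
})

test_that("region aggregation averages member probes per sample", {
  fx <- tiny_methylation(3, 2, genes = c("G1", "G1", "G2"),
                         regions = c("TSS200", "TSS200", "5'UTR"))
  md <- methylation_data(fx$M, fx$U, fx$ann)
  b <- compute_beta(md)
  b$beta["p1", ] <- 0.2; b$beta["p2", ] <- 0.4; b$beta["p3", ] <- 0.7
  rb <- aggregate_regions(b, fx$ann)
  expect_equal(unname(rb$beta["G1|TSS200", ]), c(0.3, 0.3))
  expect_equal(unname(rb$beta["G2|5'UTR", ]), c(0.7, 0.7))  # single probe
  expect_equal(rb$level, "region")
  # commutes with sample permutation; values within member range
  perm <- c(2, 1)
  rb_perm <- aggregate_regions(
    beta_matrix(b$beta[, perm], level = "probe"), fx$ann)
  expect_equal(rb_perm$beta, rb$beta[, perm])
  expect_true(all(rb$beta >= 0.2 & rb$beta <= 0.7))
})

test_that("per-feature OLS handles degenerate features and matches BH by hand", {
  design <- data.frame(donor = rep(c("a", "b"), each = 4),
                       time = rep(c(0, 2, 4, 6), 2))
  set.seed(42)
  vals <- rbind(const = rep(1, 8),
                exact = 0.5 * design$time + ifelse(design$donor == "a", 1, 0),
                noise = rnorm(8))
  res <- differential_linear_model(vals, design, test_term = "time")
  expect_equal(res$coefficient[res$feature_id == "const"], 0)
  expect_equal(res$p[res$feature_id == "const"], 1)
  expect_true(res$degenerate[res$feature_id == "exact"])
  expect_equal(res$p[res$feature_id == "exact"], 0)
  expect_false(res$degenerate[res$feature_id == "noise"])

  # BH hand computation for m = 4: p {.01,.02,.03,.04} -> fdr all .04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(1)
  many <- matrix(rnorm(40 * 8), 40, 8,
                 dimnames = list(paste0("f", 1:40), NULL))
  r2 <- differential_linear_model(many, design, test_term = "time")
  ord <- order(r2$p)
  expect_true(all(diff(r2$fdr[ord]) >= -1e-12))  # BH monotone in p order
  expect_true(all(r2$fdr >= r2$p - 1e-12))
})

test_that("rank-deficient designs are rejected naming collinear columns", {
  design <- data.frame(donor = rep(c("a", "b"), 4),
                       time = rep(1, 8))  # constant time column
  vals <- matrix(rnorm(8), 1, 8, dimnames = list("f1", NULL))
  expect_error(differential_linear_model(vals, design, test_term = "time"),
               "collinear.*time")
})

test_that("a gene is a DMG when any region is significant", {
  rr <- data.frame(
    gene = c("G1", "G1", "G2", "G3"),
    region = c("TSS200", "3'UTR", "TSS1500", "3'UTR"),
    significant = c(TRUE, FALSE, FALSE, TRUE))
  out <- call_dmg(rr)
  expect_true(out$dmg[out$gene == "G1"])   # TSS200 only
  expect_false(out$dmg[out$gene == "G2"])  # nothing significant
  expect_true(out$dmg[out$gene == "G3"])   # 3'UTR alone counts
})

test_that("gene beta follows the TSS200 > TSS1500 > 5'UTR > 1stExon priority", {
  regions <- c("TSS200", "5'UTR", "1stExon", "ExonBnd")
  units <- paste("G1", regions, sep = "|")
  beta <- matrix(seq(0.1, 0.4, by = 0.1), 4, 3,
                 dimnames = list(units, paste0("s", 1:3)))
  info <- data.frame(unit = units, gene = "G1", region = regions)
  rb <- beta_matrix(beta, level = "region", feature_info = info)

  dm <- data.frame(gene = "G1", region = regions,
                   significant = c(TRUE, TRUE, FALSE, FALSE))
  out <- assign_gene_beta(rb, dm)
  expect_equal(out$feature_info$region, "TSS200")
  expect_equal(unname(out$beta["G1", ]), rep(0.1, 3))

  dm2 <- data.frame(gene = "G1", region = regions,
                    significant = c(FALSE, FALSE, TRUE, FALSE))
  out2 <- assign_gene_beta(rb, dm2)
  expect_equal(out2$feature_info$region, "1stExon")

  # only ExonBnd differentially methylated: excluded by default ...
  dm3 <- data.frame(gene = "G1", region = regions,
                    significant = c(FALSE, FALSE, FALSE, TRUE))
  out3 <- assign_gene_beta(rb, dm3)
  expect_equal(nrow(out3$beta), 0)
  # ... but included when the chain is extended
  out4 <- assign_gene_beta(rb, dm3,
                           priority = c(region_priority(), "ExonBnd", "3'UTR"))
  expect_equal(out4$feature_info$region, "ExonBnd")
})

test_that("null features show calibrated raw type-I error", {
  set.seed(99)
  design <- data.frame(donor = rep(paste0("d", 1:5), each = 6),
                       time = rep(c(0, 2, 4), 10),
                       condition = rep(c(0, 1), each = 15))
  vals <- matrix(rnorm(2000 * 30), 2000, 30,
                 dimnames = list(paste0("f", 1:2000), NULL))
  res <- differential_linear_model(vals, design, test_term = "condition")
  alpha <- 0.05
  se3 <- 3 * sqrt(alpha * (1 - alpha) / 2000)
  expect_lt(abs(mean(res$p < alpha) - alpha), se3)
})
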