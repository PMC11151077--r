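# Correlation, signal strength, annotation, activity scores, variance models.

test_that("correlation handles both methods and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlation(x, 2 * x + 1)$r, 1)
  expect_equal(correlation(c(1, 2, 3), c(3, 1, 2), "spearman")$r, -0.5)
  expect_error(correlation(x, rep(1, 5)),
               class = "cometh_undefined_correlation")
  expect_error(correlation(x, x[1:4]), class = "cometh_parameter_error")
  expect_error(correlation(c(1, 2, NA), c(1, 2, 3)),
               class = "cometh_parameter_error")  # < 3 complete pairs
  # symmetry, affine invariance, monotone invariance of Spearman
  set.seed(31)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(correlation(a, b)$r, correlation(b, a)$r)
  expect_equal(correlation(3 * a + 2, b)$r, correlation(a, b)$r)
  expect_equal(correlation(exp(a), b, "spearman")$r,
               correlation(a, b, "spearman")$r)
  # p matches the t reference implementation
  ct <- cor.test(a, b)
  got <- correlation(a, b)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p, ct$p.value)
})

test_that("signal_strength follows log2(count/len*1000 + 1)", {
  expect_equal(signal_strength(0, 500), 0)
  expect_equal(signal_strength(1000, 2000), log2(501))
  expect_equal(signal_strength(2, 1000), log2(3))
  expect_error(signal_strength(5, 0), class = "cometh_parameter_error")
  expect_error(signal_strength(-1, 10), class = "cometh_parameter_error")
})

test_that("promoter windows are symmetric and clipped", {
  g <- gene_model("g1", "chr1", "+", tss = 10000L, start = 9000L, end = 20000L)
  expect_equal(promoter_of(g), list(start = 8000L, end = 12000L))
  g2 <- gene_model("g2", "chr1", "-", tss = 10000L, start = 5000L, end = 10500L)
  expect_equal(promoter_of(g2), promoter_of(g))  # strand-symmetric
  g3 <- gene_model("g3", "chr1", "+", tss = 500L, start = 0L, end = 3000L)
  expect_equal(promoter_of(g3), list(start = 0L, end = 2500L))
  expect_error(gene_model("g", "chr1", "+", 99L, 100L, 200L),
               class = "cometh_parameter_error")
})

mk_dmr <- function(start, end, dir = "hyper", chrom = "chr1") {
  data.table::data.table(chrom = chrom, start = start, end = end,
                         n_cpg = 5L, mean_diff = 0.3, W = 1, p = 1e-4,
                         q = 1e-3, direction = dir)
}

test_that("DMR-gene assignment uses strict distance and deterministic ties", {
  genes <- rbind(gene_model("gB", "chr1", "+", 5000L, 4000L, 8000L),
                 gene_model("gA", "chr1", "+", 12000L, 11500L, 15000L))
  # inside a gene body
  p0 <- assign_dmrs_to_genes(mk_dmr(4500L, 4600L), genes)
  expect_equal(p0$gene_id, "gB")
  expect_equal(p0$distance_bp, 0L)
  # 1500 bp away: assigned; exactly 2000 bp: NOT (strict less-than)
  expect_equal(assign_dmrs_to_genes(mk_dmr(2400L, 2500L), genes)$gene_id, "gB")
  expect_equal(nrow(assign_dmrs_to_genes(mk_dmr(1900L, 2000L), genes)), 0L)
  expect_equal(assign_dmrs_to_genes(mk_dmr(1901L, 2001L), genes)$distance_bp,
               1999L)
  # equidistant between gB(end 8000) and gA(start 11500): smaller gene_id wins
  tie <- assign_dmrs_to_genes(mk_dmr(9250L, 10250L), genes)
  expect_equal(tie$distance_bp, 1250L)
  expect_equal(tie$gene_id, "gA")
  # tss anchor variant
  near_tss <- assign_dmrs_to_genes(mk_dmr(13000L, 13100L), genes,
                                   anchor = "tss")
  expect_equal(near_tss$gene_id, "gA")
  expect_equal(near_tss$distance_bp, 1000L)
})

test_that("classify_pairs applies the five-way rule and partitions", {
  pairs <- rbind(
    cbind(mk_dmr(1L, 10L, "hyper"), gene_id = "g1", distance_bp = 0L),
    cbind(mk_dmr(20L, 30L, "hypo"), gene_id = "g2", distance_bp = 0L),
    cbind(mk_dmr(40L, 50L, "hypo"), gene_id = "g3", distance_bp = 0L),
    cbind(mk_dmr(60L, 70L, "hyper"), gene_id = "g4", distance_bp = 0L),
    cbind(mk_dmr(80L, 90L, "hyper"), gene_id = "missing", distance_bp = 0L))
  deg <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    log2FC = c(-1.2, 0.8, 2.0, 1.5),
                    FDR = c(0.001, 0.2, 1e-6, 0.01))
  out <- classify_pairs(pairs, deg)
  expect_equal(out$category,
               c("Hyper-Down", "NS", "Hypo-Up", "Hyper-Up", "NS"))
  expect_true(all(out$category %in%
                    c("Hyper-Down", "Hyper-Up", "Hypo-Down", "Hypo-Up", "NS")))
  expect_error(classify_pairs(pairs, deg[, 1:2]), class = "cometh_input_error")
})

test_that("cgi_context bands distances from the island border", {
  cgis <- data.frame(start = c(10000L, 50000L), end = c(11000L, 51000L))
  expect_equal(cgi_context(10500L, cgis), "CGI")
  expect_equal(cgi_context(11000L + 1999L, cgis), "shore")
  expect_equal(cgi_context(11000L + 2000L, cgis), "shelf")
  expect_equal(cgi_context(11000L + 4000L, cgis), "shelf")  # inclusive band
  expect_equal(cgi_context(11000L + 4001L, cgis), "inteCGI")
  expect_equal(cgi_context(30000L, cgis), "inteCGI")
  expect_equal(cgi_context(10500L, cgis[0L, ]), "inteCGI")
  # upstream side mirrors
  expect_equal(cgi_context(10000L - 1500L, cgis), "shore")
})

test_that("nearest_feature_distance measures end-to-start gaps", {
  feats <- data.frame(start = c(100L, 500L), end = c(200L, 600L))
  expect_equal(nearest_feature_distance(list(start = 150L, end = 260L), feats), 0L)
  expect_equal(nearest_feature_distance(list(start = 201L, end = 250L), feats), 1L)
  expect_equal(nearest_feature_distance(list(start = 200L, end = 250L), feats), 0L)
  expect_true(is.na(nearest_feature_distance(list(start = 1L, end = 2L),
                                             feats[0L, ])))
})

test_that("merge_motifs unions overlapping sites and preserves coverage", {
  # 19 overlapping sites collapsing into 3 clusters
  mk_cluster <- function(origin, n) {
    s <- origin + (seq_len(n) - 1L) * 8L   # 12 bp motifs tiled every 8 bp
    data.frame(start = s, end = s + 12L)
  }
  motifs <- rbind(mk_cluster(1000L, 7L), mk_cluster(5000L, 6L),
                  mk_cluster(9000L, 6L))
  motifs <- motifs[sample(nrow(motifs)), ]
  merged <- merge_motifs(motifs)
  expect_equal(nrow(merged), 3L)
  expect_true(all(merged$start[-1L] > merged$end[-nrow(merged)]))
  covered <- function(df) unique(unlist(Map(seq, df$start, df$end - 1L)))
  expect_setequal(covered(merged), covered(motifs))
  disjoint <- data.frame(start = c(1L, 100L), end = c(10L, 120L))
  expect_equal(merge_motifs(disjoint), data.table::as.data.table(disjoint))
  nested <- data.frame(start = c(1L, 3L), end = c(50L, 10L))
  expect_equal(merge_motifs(nested),
               data.table::data.table(start = 1L, end = 50L))
})

test_that("motif_occupancy follows the extended-window literal-sum rule", {
  dmr <- list(start = 1000L, end = 1100L)  # 100 bp -> 500 bp extended
  one <- data.frame(start = 1020L, end = 1045L)  # 25 bp inside
  expect_equal(motif_occupancy(dmr, one), 25 / 500)
  expect_equal(motif_occupancy(dmr, one[0L, ]), 0)
  two <- data.frame(start = c(900L, 900L), end = c(1150L, 1150L))
  expect_equal(motif_occupancy(dmr, two), 1.0)  # identical motifs both counted
  # motif partially outside the extended window is clipped
  hang <- data.frame(start = 700L, end = 900L)
  expect_equal(motif_occupancy(dmr, hang), 100 / 500)
})

test_that("activity_score drops non-inverse motifs and averages the rest", {
  expect_equal(activity_value(-0.5, 4), -1)
  n <- 12L
  tumor_mask <- rep(c(TRUE, FALSE), each = n / 2)
  lin <- c(rep(15, n / 2), rep(3, n / 2))          # fold change 5
  expr <- log2(lin + 1)
  inv <- rank(-lin) / n                              # perfectly inverse motif
  pos <- rank(lin) / n                               # positively correlated
  rec <- activity_score(rbind(inv, pos), expr, tumor_mask)
  expect_length(rec$motif_activities, 1L)
  expect_equal(unname(rec$r_spearman), -1, tolerance = 1e-12)
  expect_equal(rec$log2_fold_change, log2(5))
  expect_equal(rec$activity, -log2(5))
  expect_true(rec$reportable)  # |activity| = log2(5) > 1.2
  # two motifs: mean of their activities
  inv2 <- (rank(-lin) / n)^2
  rec2 <- activity_score(rbind(inv, inv2), expr, tumor_mask)
  expect_equal(rec2$activity, mean(rec2$motif_activities))
  # all motifs non-inverse -> NULL activity
  rec3 <- activity_score(pos, expr, tumor_mask)
  expect_null(rec3$activity)
  expect_false(rec3$reportable)
  # undefined fold change on zero normal expression
  expect_error(activity_score(inv, log2(c(rep(4, 6), rep(0, 6)) + 1),
                              tumor_mask),
               class = "cometh_undefined_foldchange")
  expect_error(activity_score(inv, expr, rep(TRUE, n)),
               class = "cometh_parameter_error")
})

test_that("variance_explained fits the four nested OLS models", {
  set.seed(33)
  n <- 40L
  meth <- runif(n); tf <- rnorm(n)
  y <- 1 + 2 * meth - 1.5 * tf + 0.8 * meth * tf
  vm <- suppressWarnings(variance_explained(y, meth, tf))  # perfect fit
  expect_equal(vm$adj_r2_interaction, 1, tolerance = 1e-10)
  # raw R2 monotone over the nested sequence
  expect_lte(vm$r2_meth, vm$r2_joint + 1e-12)
  expect_lte(vm$r2_tf, vm$r2_joint + 1e-12)
  expect_lte(vm$r2_joint, vm$r2_interaction + 1e-12)
  # independence: adjusted R2 near zero
  y0 <- rnorm(500)
  vm0 <- variance_explained(y0, runif(500), rnorm(500))
  expect_lt(abs(vm0$adj_r2_joint), 0.05)
  expect_error(variance_explained(y[1:4], meth[1:4], tf[1:4]),
               class = "cometh_parameter_error")
  expect_error(variance_explained(y, rep(0.5, n), tf),
               class = "cometh_model_error")
})

test_that("OLS coefficients match a normal-equations oracle", {
  set.seed(34)
  n <- 10L
  meth <- runif(n); tf <- rnorm(n)
  y <- 0.5 + 1.2 * meth - 0.7 * tf + 0.3 * meth * tf + rnorm(n, 0, 0.1)
  vm <- variance_explained(y, meth, tf)
  X <- cbind(1, meth, tf, meth * tf)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(vm$coefficients), as.vector(beta), tolerance = 1e-10)
  # adjusted R2 formula: 1 - (1 - R2)(n-1)/(n-p-1)
  fitted <- X %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  expect_equal(vm$adj_r2_interaction, 1 - (1 - r2) * (n - 1) / (n - 3 - 1),
               tolerance = 1e-10)
})
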