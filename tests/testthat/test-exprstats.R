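toy_design <- function(n_per_group = 2) {
  g <- expand.grid(line = c("CTRL1", "CTRL2"), protocol = c("LSF", "SSC"),
                   replicate = seq_len(n_per_group))
  data.frame(sample = paste0("s", seq_len(nrow(g))), g,
             stringsAsFactors = FALSE)
}

test_that("low-expression filtering applies the CPM rule exactly", {
  design <- toy_design(1)   # 4 samples, groups of size 1 -> k = 1
  counts <- rbind(zero = c(0, 0, 0, 0),
                  high = c(500, 600, 700, 800),
                  lowish = c(1, 0, 0, 0),
                  mid = c(0, 0, 90, 80),
                  tiny = c(0, 1, 0, 1))
  colnames(counts) <- design$sample
  # library sizes ~ hundreds: CPM cutoff 1 is passed by any positive count
  kept <- filter_low_expression(counts, design, cpm_cutoff = 1,
                                min_samples = "auto")
  # oracle: brute-force evaluation of the stated rule with k = 1
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  oracle <- rownames(counts)[rowSums(cpm >= 1) >= 1]
  expect_identical(rownames(kept), oracle)
  expect_false("zero" %in% rownames(kept))
  expect_true("high" %in% rownames(kept))
  # explicit k = 2 on the same toy matrix
  kept2 <- filter_low_expression(counts, design, 1, min_samples = 2)
  oracle2 <- rownames(counts)[rowSums(cpm >= 1) >= 2]
  expect_identical(rownames(kept2), oracle2)
  # gene order is preserved
  expect_identical(rownames(kept2),
                   intersect(rownames(counts), rownames(kept2)))
  # zero library size names the sample
  bad <- counts; bad[, 2] <- 0
  expect_error(filter_low_expression(bad, design), "s2")
})

test_that("a gene above the cutoff in every sample is never removed", {
  design <- toy_design(2)
  set.seed(3)
  for (i in 1:20) {
    counts <- matrix(rpois(40 * 8, 5), 40, 8,
                     dimnames = list(paste0("g", 1:40), design$sample))
    counts[1, ] <- 1000   # far above cutoff everywhere
    kept <- filter_low_expression(counts, design, 1, "auto")
    lib <- colSums(counts)
    cpm1 <- min(counts[1, ] / lib * 1e6)
    expect_true(cpm1 > 1 && "g1" %in% rownames(kept))
  }
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:60, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    # monotone in the raw p ordering
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("row Z-scores are centred, scaled and zero for constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(10, 0, 20))
  z <- row_zscore(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(rowMeans(z), c(a = 0, b = 0, c = 0))
  expect_equal(apply(z[c("a", "c"), ], 1, sd), c(a = 1, c = 1))
  expect_error(row_zscore(m[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("marker-panel scores are signed means of row Z-scores", {
  m <- matrix(c(1, 2, 3, 4,
                4, 3, 2, 1,
                1, 1, 2, 2), 3, 4, byrow = TRUE,
              dimnames = list(c("GFAP", "VIM", "AQP4"),
                              paste0("s", 1:4)))
  # single up-gene: score equals that gene's z-row
  one <- marker_panel_score(m, data.frame(gene = "GFAP"))
  expect_equal(unname(one$scores), unname(row_zscore(m)["GFAP", ]))
  # hand-computed oracle: mean of z rows with VIM flipped
  panel <- data.frame(gene = c("GFAP", "VIM", "AQP4"),
                      direction = c("up", "down", "up"))
  sc <- marker_panel_score(m, panel)
  z <- row_zscore(m)
  oracle <- colMeans(rbind(z["GFAP", ], -z["VIM", ], z["AQP4", ]))
  expect_equal(sc$scores, oracle)
  # identical samples -> all-zero scores
  mm <- matrix(5, 3, 4, dimnames = dimnames(m))
  expect_equal(unname(marker_panel_score(mm, panel)$scores), rep(0, 4))
  # missing genes reported; all-missing errors
  sc2 <- marker_panel_score(m, data.frame(gene = c("GFAP", "S100B")))
  expect_identical(sc2$missing_genes, "S100B")
  expect_error(marker_panel_score(m, data.frame(gene = "S100B")),
               "no panel gene")
})

test_that("two-way ANOVA matches the sums-of-squares oracle", {
  # fixed toy 2x2 design, n = 3 per cell
  v <- c(3.1, 2.9, 3.4, 5.0, 5.2, 4.7, 3.6, 3.8, 3.5, 6.1, 6.4, 5.8)
  a <- rep(c("L1", "L2"), each = 6)
  b <- rep(rep(c("LSF", "SSC"), each = 3), 2)
  fit <- two_way_anova(v, a, b)
  oracle <- anova_ss_oracle(v, a, b)
  expect_equal(fit$factor_a$F, oracle$F_a, tolerance = 1e-10)
  expect_equal(fit$factor_b$F, oracle$F_b, tolerance = 1e-10)
  expect_equal(fit$interaction$F, oracle$F_ab, tolerance = 1e-10)
  expect_equal(fit$factor_a$p, oracle$p_a, tolerance = 1e-10)
  expect_equal(fit$residual_df, 8)
  # symmetry in factor A: swapping A-levels leaves the data unchanged
  vs <- c(1, 2, 3, 4, 1, 2, 3, 4)
  as_ <- rep(c("x", "y"), each = 4)
  bs <- rep(rep(c("p", "q"), each = 2), 2)
  fs <- two_way_anova(vs, as_, bs)
  expect_lt(fs$factor_a$F, 1e-20)
  # errors: n = 1 cells, unbalanced design, zero residual variance
  expect_error(two_way_anova(1:4, c("x", "x", "y", "y"), c("p", "q", "p", "q")),
               "at least 2 observations")
  expect_error(two_way_anova(1:10, rep(c("x", "y"), c(6, 4)),
                             rep(c("p", "q"), 5)), "unbalanced")
  expect_error(two_way_anova(rep(1, 8), rep(c("x", "y"), each = 4),
                             rep(c("p", "q"), 4)), "residual variance")
})

test_that("two-way ANOVA equals the oracle on random balanced designs", {
  set.seed(29)
  worst <- 0
  for (i in 1:100) {
    a_lv <- sample(2:3, 1); b_lv <- sample(2:3, 1); n <- sample(2:4, 1)
    g <- expand.grid(A = paste0("a", 1:a_lv), B = paste0("b", 1:b_lv),
                     r = 1:n)
    v <- rnorm(nrow(g))
    fit <- two_way_anova(v, g$A, g$B)
    oracle <- anova_ss_oracle(v, g$A, g$B)
    worst <- max(worst,
                 abs(fit$factor_a$F - oracle$F_a),
                 abs(fit$factor_b$F - oracle$F_b),
                 abs(fit$interaction$F - oracle$F_ab))
  }
  expect_lt(worst, 1e-10)
})

test_that("delta-delta-Ct relative expression follows the housekeeping convention", {
  design <- data.frame(sample = c("r1", "r2", "t1"),
                       line = "CTRL1",
                       protocol = c("LSF", "LSF", "SSC"),
                       replicate = c(1, 2, 1))
  ct <- rbind(
    data.frame(sample = "r1", gene = c("GFAP", "ACTB", "L27"),
               ct = c(21, 18, 20)),   # hk mean 19 -> dCt 2
    data.frame(sample = "r2", gene = c("GFAP", "ACTB", "L27"),
               ct = c(21, 19, 19)),   # dCt 2  (reference mean dCt = 2)
    data.frame(sample = "t1", gene = c("GFAP", "ACTB", "L27"),
               ct = c(20, 18, 20)))   # dCt 1 -> ddCt -1 -> RQ 2
  rq <- qpcr_relative_expression(ct, targets = "GFAP",
                                 reference_group = "LSF", design = design)
  expect_equal(rq$delta_ct[rq$sample == "t1"], 1)  # mean(18,20)=19; 20-19
  expect_equal(rq$rq[rq$sample == "t1"], 2)        # 2^-(1-2)
  # reference samples at the reference mean give RQ = 1
  expect_equal(rq$rq[rq$sample %in% c("r1", "r2")], c(1, 1))
  # missing housekeeping Ct names sample and gene
  expect_error(qpcr_relative_expression(ct[-2, ], "GFAP",
                                        reference_group = "LSF",
                                        design = design),
               "r1.*ACTB")
})
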