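test_that("rank-sum p matches full enumeration on small samples", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(rank_sum_test(x, y)$p.value, 0.1)  # 2 of C(6,3)=20 orderings
  expect_equal(rank_sum_test(x, y)$p.value, oracle_ranksum_p(x, y))
  # identical multisets: exact path returns 1
  expect_gte(rank_sum_test(c(2, 7, 7, 1), c(7, 1, 2, 7))$p.value, 0.99)
  # random small cases, with ties, against the enumeration oracle
  for (i in 1:15) {
    n1 <- withr::with_seed(400 + i, sample(2:5, 1))
    n2 <- withr::with_seed(420 + i, sample(2:5, 1))
    x <- withr::with_seed(i, sample(1:6, n1, replace = TRUE))
    y <- withr::with_seed(50 + i, sample(1:6, n2, replace = TRUE))
    expect_equal(rank_sum_test(x, y)$p.value, oracle_ranksum_p(x, y))
  }
})

test_that("large-sample path agrees with the classical tie-corrected statistic", {
  x <- withr::with_seed(1, rpois(40, 4))
  y <- withr::with_seed(2, rpois(35, 5))
  ours <- rank_sum_test(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(ours$p.value, ref$p.value)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
})

test_that("constant genes get p = 1 and per-gene tests run columnwise", {
  v <- cbind(a = c(1, 2, 3, 4, 5, 6), b = rep(2, 6), c = c(9, 9, 9, 1, 1, 1))
  grp <- rep(c("CON", "DSS"), each = 3)
  p <- per_gene_test(v, grp)
  expect_equal(unname(p["b"]), 1)
  expect_equal(unname(p["c"]), oracle_ranksum_p(v[1:3, "c"], v[4:6, "c"]))
  expect_error(per_gene_test(v, rep("CON", 6)), "2 groups")
})

test_that("BH adjustment matches its step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  for (i in 1:10) {
    p <- withr::with_seed(i, runif(sample(3:30, 1))^2)  # length drawn under the same seed
    expect_equal(bh_adjust(p), oracle_bh(p))
    # order invariance
    perm <- withr::with_seed(99 + i, sample(length(p)))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
})

test_that("fold change works on de-logged means with the pseudocount", {
  # build log values whose de-logged group means are exactly 20 and 10
  v <- rbind(log1p(20), log1p(20), log1p(10), log1p(10))
  colnames(v) <- "g"
  grp <- c("DSS", "DSS", "CON", "CON")
  fc <- fold_change(v, grp, "DSS", pseudocount = 0)
  expect_equal(fc$fc, 2.0)
  expect_identical(fc$direction, "up")
  v2 <- rbind(log1p(7), log1p(7), log1p(10), log1p(10)); colnames(v2) <- "g"
  fc2 <- fold_change(v2, grp, "DSS", pseudocount = 0)
  expect_equal(fc2$fc, 0.7)
  expect_equal(fc2$abs_fc, 1 / 0.7)
  expect_identical(fc2$direction, "down")
  # equal means: abs_fc exactly 1 regardless of pseudocount
  v3 <- rbind(log1p(5), log1p(5), log1p(5), log1p(5)); colnames(v3) <- "g"
  fc3 <- fold_change(v3, grp, "DSS")
  expect_equal(fc3$abs_fc, 1)
})

test_that("abs fold change is invariant to swapping group labels", {
  v <- withr::with_seed(3, matrix(rexp(60), 10, 6))
  colnames(v) <- paste0("g", 1:6)
  grp <- rep(c("A", "B"), 5)
  a <- fold_change(v, grp, "A")
  b <- fold_change(v, grp, "B")
  expect_equal(a$abs_fc, b$abs_fc)
  expect_equal(a$fc, 1 / b$fc)
})

test_that("the DE gates apply the fold-change and FDR thresholds jointly", {
  # two clearly separated genes with different effect sizes and one null
  withr::with_seed(8, {
    n <- 30
    g_big <- c(rnorm(n, 5, 0.2), rnorm(n, 6.2, 0.2))    # huge fc on delog scale
    g_mid <- c(rnorm(n, 5, 0.1), rnorm(n, 5.1, 0.1))    # small fc, tiny p
    g_null <- rnorm(2 * n, 5, 0.2)
    v <- cbind(big = g_big, mid = g_mid, null = g_null)
  })
  grp <- rep(c("CON", "DSS"), each = 30)
  de <- de_table(v, grp, "DSS")
  expect_true(de$pass_de[de$gene == "big"])
  expect_true(de$top_tier[de$gene == "big"])
  row_mid <- de[de$gene == "mid", ]
  expect_lt(row_mid$padj, 0.01)
  expect_lt(row_mid$abs_fc, 1.25)   # FC gate blocks it despite the p-value
  expect_false(row_mid$pass_de)
  expect_false(de$pass_de[de$gene == "null"])
  expect_true(all(de$padj >= de$p))
  expect_identical(de$gene[1], "big")  # sorted by padj then abs_fc
})

test_that("spatial similarity is Spearman correlation with conventions", {
  sc <- cbind(glutamatergic = c(0.1, 0.9, 0.4, 0.7, 0.2))
  v <- cbind(follow = c(1, 9, 4, 7, 2), anti = c(9, 1, 6, 3, 8),
             flat = rep(2, 5))
  expect_equal(unname(spatial_similarity(v, sc, "glutamatergic", "follow")), 1)
  expect_equal(unname(spatial_similarity(v, sc, "glutamatergic", "anti")), -1)
  expect_warning(
    s0 <- spatial_similarity(v, sc, "glutamatergic", "flat"), "constant")
  expect_equal(unname(s0), 0)
  expect_warning(
    sc0 <- spatial_similarity(v, cbind(glutamatergic = rep(1, 5)), "glutamatergic"),
    "constant score")
  expect_equal(unname(sc0), rep(0, 3))
  expect_error(spatial_similarity(v[1:2, ], sc[1:2, , drop = FALSE],
                                  "glutamatergic"), ">= 3 spots")
})

test_that("candidate ranking is similarity-major, fold-change-minor", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   abs_fc = c(2, 3, 1.6, 5),
                   top_tier = c(TRUE, TRUE, TRUE, FALSE),
                   similarity = c(0.9, 0.4, 0.9, 0.99),
                   stringsAsFactors = FALSE)
  gs <- gene_sets(list(glutamatergic = c("a", "b", "c", "d")))
  ranked <- prioritize_candidates(de, gs)
  expect_identical(ranked$gene, c("a", "c", "b"))  # d excluded: not top tier
  empty <- prioritize_candidates(de[de$gene == "d", ], gs)
  expect_identical(nrow(empty), 0L)
})
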