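test_that("ECDF statistic equals averaged-tie ranks over spots", {
  m <- matrix(c(3, 1, 2), ncol = 1)
  expect_equal(ecdf_transform(m)[, 1], c(1, 1 / 3, 2 / 3))
  m <- matrix(c(5, 5, 2), ncol = 1)
  expect_equal(ecdf_transform(m)[, 1], c(5 / 6, 5 / 6, 1 / 3))
  m <- matrix(c(4, 4, 4), ncol = 1)
  expect_equal(ecdf_transform(m)[, 1], c(2 / 3, 2 / 3, 2 / 3))
  expect_error(ecdf_transform(matrix(1, 1, 2)), ">= 2 spots")
})

test_that("kernel-mode statistic is monotone in expression and handles sd 0", {
  m <- cbind(c(1, 5, 2, 8), c(3, 3, 3, 3))
  e <- ecdf_transform(m, "gaussian-kernel")
  expect_identical(order(e[, 1]), order(m[, 1]))
  expect_true(all(e > 0 & e < 1))
  expect_equal(e[, 2], rep(0.5, 4))
})

test_that("per-spot ranking weights are |N/2 - R| with index tie-break", {
  e <- matrix(c(0.9, 0.7, 0.5, 0.1), nrow = 1)  # one spot, ranks 1..4
  rs <- spot_rank_stat(e)
  expect_identical(rs$order[1, ], 1:4)
  expect_equal(rs$weight[1, ], c(1, 0, 1, 2))
  # exact tie: lower gene index takes the better rank
  e2 <- matrix(c(0.5, 0.8, 0.8), nrow = 1)
  expect_identical(spot_rank_stat(e2)$order[1, ], c(2L, 3L, 1L))
  # kernel statistics are tie-free across genes: permutation only relabels
  v <- random_notie_matrix(4, 6, seed = 8)
  perm <- c(3, 1, 6, 2, 5, 4)
  a <- spot_rank_stat(ecdf_transform(v, "gaussian-kernel"))
  b <- spot_rank_stat(ecdf_transform(v[, perm], "gaussian-kernel"))
  expect_equal(b$rank, a$rank[, perm])
})

test_that("the four-step walk reproduces its hand-enumerated trace", {
  es <- random_walk_es(gene_order = 1:4, weights = c(1, 0, 1, 2),
                       set_mask = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(attr(es, "walk"), c(0.5, 0.0, 0.5, 0.0))
  expect_equal(as.numeric(es), 0.5)
})

test_that("walk edge behavior: concentration, zero-weight sets, degenerate sets", {
  # set occupying the top ranks with positive weights -> ES > 0
  es <- random_walk_es(1:6, weights = c(3, 2, 1, 1, 2, 3),
                       set_mask = c(TRUE, TRUE, rep(FALSE, 4)))
  expect_gt(as.numeric(es), 0)
  expect_equal(max(attr(es, "walk")), 1)  # all in-set weight seen at l = m
  # all in-set weight zero: in-set term contributes nothing
  es0 <- random_walk_es(1:4, weights = c(1, 0, 1, 2),
                        set_mask = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(attr(es0, "walk"), c(-1 / 3, -1 / 3, -2 / 3, -1))
  expect_error(random_walk_es(1:3, rep(1, 3), rep(FALSE, 3), set_name = "GLUT"),
               "GLUT")
  expect_error(random_walk_es(1:3, rep(1, 3), rep(TRUE, 3)), "every gene")
})

test_that("scores match the independent brute-force oracle exactly", {
  params <- list(set_score_params(es_mode = "diff"),
                 set_score_params(es_mode = "maxabs"),
                 set_score_params(tau = 0.75))
  n_checked <- 0
  for (i in 1:60) {
    S <- withr::with_seed(i, sample(2:5, 1))
    G <- withr::with_seed(60 + i, sample(3:8, 1))
    v <- random_notie_matrix(S, G, seed = 1000 + i)
    set_genes <- withr::with_seed(120 + i,
      sample(colnames(v), sample(seq_len(G - 1), 1)))
    p <- params[[1 + i %% length(params)]]
    got <- score_sets(v, gene_sets(list(X = set_genes)), p)
    want <- oracle_setscore(v, set_genes, p$tau, p$es_mode)
    expect_equal(unname(got[, "X"]), want)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("enrichment scores respect their mode-specific bounds", {
  for (i in 1:25) {
    v <- random_notie_matrix(4, 7, seed = 2000 + i)
    gs <- gene_sets(list(X = withr::with_seed(i, sample(colnames(v), 3))))
    expect_lte(max(abs(score_sets(v, gs))), 2)
    expect_lte(max(abs(score_sets(v, gs, set_score_params(es_mode = "maxabs")))), 1)
  }
})

test_that("for the unweighted walk, the complement's walk is the exact negation", {
  # with tau = 0 both CDFs are count-based, so nu_complement = -nu identically
  pp <- set_score_params(tau = 0, es_mode = "maxabs")
  v <- random_notie_matrix(3, 5, seed = 77)
  e <- ecdf_transform(v, "gaussian-kernel")  # tie-free shared ordering
  rs <- spot_rank_stat(e)
  genes <- colnames(v)
  for (pair in asplit(utils::combn(genes, 2), 2)) {
    for (s in seq_len(nrow(v))) {
      es1 <- random_walk_es(rs$order[s, ], rs$weight[s, ], genes %in% pair, pp)
      es2 <- random_walk_es(rs$order[s, ], rs$weight[s, ],
                            !(genes %in% pair), pp)
      expect_equal(attr(es2, "walk"), -attr(es1, "walk"))
      # scores agree in magnitude; signs are opposite unless the walk is
      # magnitude-symmetric, where the extraction rule prefers the maximum
      expect_equal(abs(as.numeric(es2)), abs(as.numeric(es1)))
    }
  }
})

test_that("identical spots and relabeled genes give identical scores", {
  v <- random_notie_matrix(4, 6, seed = 3)
  v2 <- rbind(v, v[2, , drop = FALSE])
  rownames(v2) <- c(rownames(v), "copy")
  gs <- gene_sets(list(X = colnames(v)[c(1, 4)]))
  sc <- score_sets(v2, gs)
  expect_equal(sc["copy", ], sc[rownames(v)[2], ])
  perm <- withr::with_seed(4, sample(ncol(v)))
  pk <- set_score_params(ecdf_mode = "gaussian-kernel")  # tie-free ordering
  expect_equal(unname(score_sets(v[, perm], gs, pk)),
               unname(score_sets(v, gs, pk)))
})

test_that("set sizes actually used are recorded", {
  v <- random_notie_matrix(3, 5, seed = 6)
  gs <- gene_sets(list(X = c(colnames(v)[1:2], "NotHere")))
  expect_identical(attr(score_sets(v, gs), "set_sizes_used"), c(X = 2L))
})

test_that("permutation null is seeded, centered, and tightens with set size", {
  ds <- default_hipp_norm()
  sub <- eispot:::subset_spots(ds$nm, rownames(ds$nm$values)[seq(1, 700, by = 4)])
  a <- permutation_null(sub, set_size = 30, n_perm = 120, seed = 5)
  b <- permutation_null(sub, set_size = 30, n_perm = 120, seed = 5)
  expect_identical(a, b)
  per_perm <- rowMeans(a)
  se <- stats::sd(per_perm) / sqrt(length(per_perm))
  expect_lt(abs(mean(per_perm)), 3 * se)
  small <- permutation_null(sub, set_size = 5, n_perm = 80, seed = 6)
  big <- permutation_null(sub, set_size = 50, n_perm = 80, seed = 6)
  expect_lt(stats::sd(big), stats::sd(small))
})

test_that("raising in-set expression raises those spots' scores", {
  for (f in c(1.2, 1.5, 2)) {
    v <- random_notie_matrix(30, 40, seed = 50 + round(10 * f))
    gs <- gene_sets(list(X = colnames(v)[1:8]))
    base <- score_sets(v, gs)
    boosted <- v; boosted[1:10, 1:8] <- boosted[1:10, 1:8] * f
    up <- score_sets(boosted, gs)
    expect_gte(mean(up[1:10, ]), mean(base[1:10, ]))
  }
})
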