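make_norm <- function(values, barcodes, genes) {
  dimnames(values) <- list(barcodes, genes)
  structure(list(values = values, scale_factor = 1e4, provenance = list()),
            class = "norm_matrix")
}

test_that("marker scores are mean z-scores with the zero-variance rule", {
  v <- rbind(c(0, 0, 5), c(2, 0, 5), c(4, 0, 5))
  nm <- make_norm(v, c("a", "b", "c"), c("g1", "g2", "g3"))
  gs <- gene_sets(list(markers_CA1 = c("g1", "g2"), markers_CA3 = c("g3")))
  ms <- marker_score(nm, gs)
  # g2 and g3 are constant -> contribute 0; CA1 score is z(g1)/2
  expect_equal(ms$CA1, scale(v[, 1])[, 1] / 2)
  expect_equal(ms$CA3, c(0, 0, 0))
  # spot "a" is at/below the mean for every gene
  expect_true(all(ms[ms$barcode == "a", c("CA1", "CA3")] <= 0))
  expect_error(marker_score(nm, gene_sets(list(markers_DG = "absent"))),
               "absent")
})

test_that("region assignment is argmax with threshold and fixed tie order", {
  sc <- data.frame(barcode = c("s1", "s2", "s3"),
                   CA1 = c(2.0, 0.1, 1.0), CA3 = c(0.1, 0.2, 1.0),
                   DG = c(-0.3, 0.15, 0.4))
  spots <- spot_table(barcode = c("s1", "s2", "s3"), row = 1:3, col = 1)
  out <- assign_regions(sc, spots, threshold = 0.5)
  expect_identical(out$region, c("CA1", "other", "CA1"))  # tie CA1 > CA3
  expect_identical(assign_regions(sc, spots, threshold = 1.5)$region,
                   c("CA1", "other", "other"))
  expect_setequal(hippocampal_spots(out), c("s1", "s3"))
})

test_that("in-band marker scores exceed out-of-band scores on the default data", {
  ds <- default_fixture()
  cm <- qc_genes(qc_spots(ds$counts), 3)
  nm <- lognormalize(cm)
  mk <- ds$sets[grepl("^markers_", names(ds$sets))]
  class(mk) <- "gene_sets"
  ms <- marker_score(nm, mk)
  truth <- ds$truth$spots$region[match(ms$barcode, ds$truth$spots$barcode)]
  for (r in c("CA1", "CA3", "DG")) {
    expect_gt(mean(ms[[r]][truth == r]), mean(ms[[r]][truth != r]))
  }
})

test_that("assignment is invariant to gene reordering and non-marker duplication", {
  ds <- generate_dataset(sim_config(n_spots_per_sample = 150, n_genes = 300,
                                    n_markers_per_region = 15, seed = 5))
  cm <- qc_genes(qc_spots(ds$counts, 10, 0.5), 1)
  nm <- lognormalize(cm)
  mk <- ds$sets[grepl("^markers_", names(ds$sets))]
  class(mk) <- "gene_sets"
  base <- assign_regions(marker_score(nm, mk), ds$spots[match(cm$barcodes, ds$spots$barcode), ])

  perm <- withr::with_seed(2, sample(ncol(nm$values)))
  nm_perm <- nm; nm_perm$values <- nm$values[, perm]
  out_perm <- assign_regions(marker_score(nm_perm, mk),
                             ds$spots[match(cm$barcodes, ds$spots$barcode), ])
  expect_identical(out_perm$region, base$region)

  nm_dup <- nm
  dup <- nm$values[, "Gene0001", drop = FALSE]; colnames(dup) <- "Gene0001copy"
  nm_dup$values <- cbind(nm$values, dup)
  out_dup <- assign_regions(marker_score(nm_dup, mk),
                            ds$spots[match(cm$barcodes, ds$spots$barcode), ])
  expect_identical(out_dup$region, base$region)
})

test_that("without marker signal, accuracy drops to the no-information rate", {
  accs <- vapply(1:3, function(seed) {
    ds <- generate_dataset(sim_config(n_spots_per_sample = 300, n_genes = 300,
                                      n_markers_per_region = 15,
                                      marker_fold = 1, seed = seed))
    cm <- qc_genes(qc_spots(ds$counts, 10, 0.5), 1)
    nm <- lognormalize(cm)
    mk <- ds$sets[grepl("^markers_", names(ds$sets))]
    class(mk) <- "gene_sets"
    st <- assign_regions(marker_score(nm, mk),
                         ds$spots[match(cm$barcodes, ds$spots$barcode), ])
    truth <- ds$truth$spots$region[match(st$barcode, ds$truth$spots$barcode)]
    mean(st$region == truth)
  }, numeric(1))
  # no-information: guessing "other" everywhere would score the other-fraction
  ds <- generate_dataset(sim_config(n_spots_per_sample = 300, n_genes = 300,
                                    n_markers_per_region = 15, seed = 1))
  nir <- mean(ds$truth$spots$region == "other")
  expect_lt(mean(accs), nir + 0.1)
})
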