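# Shared fixtures; expensive ones are computed once per test run.

random_count_matrix <- function(S, G, seed = 1, max_count = 10) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(S * G, lambda = 2), S, G)
    count_matrix(counts,
                 sprintf("BC%03d", seq_len(S)),
                 sprintf("G%03d", seq_len(G)))
  })
}

# small dense no-tie expression matrix (spots x genes)
random_notie_matrix <- function(S, G, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(sample(seq_len(S * G * 10), S * G), S, G)
    dimnames(m) <- list(sprintf("BC%03d", seq_len(S)),
                        sprintf("G%03d", seq_len(G)))
    m / 7  # non-integral, still tie-free
  })
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

default_fixture <- function() memo("default_fixture", generate_dataset(default_config()))

default_run <- function() memo("default_run", {
  cfg <- modifyList(default_pipeline_config(),
                    list(outdir = file.path(tempdir(), "eispot-default-run")))
  run_pipeline(cfg)
})

# normalized hippocampal-spot matrix of the default fixture (ground truth)
default_hipp_norm <- function() memo("default_hipp_norm", {
  ds <- default_fixture()
  cm <- qc_genes(qc_spots(ds$counts), 3)
  nm <- lognormalize(cm)
  truth <- ds$truth$spots
  hipp <- intersect(truth$barcode[truth$region != "other"], cm$barcodes)
  list(nm = eispot:::subset_spots(nm, hipp),
       group = truth$sample[match(hipp, truth$barcode)],
       truth = ds$truth)
})
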