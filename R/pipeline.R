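#' Default end-to-end pipeline configuration
#'
#' Nested list of every knob the pipeline reads, schema-validated by
#' [validate_pipeline_config()]: simulation (or input paths), QC,
#' normalization, region assignment, set scoring, and the DE screen.
#'
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 7,
    simulate = TRUE,
    outdir = "results",
    input = list(counts_dir = NULL, positions = NULL, gmt = NULL),
    sim = unclass(sim_config()),
    qc = list(min_features = 100, max_mito = 0.2, min_spots = 3),
    norm = list(scale_factor = 1e4),
    regions = list(threshold = 0.25),
    score = list(tau = 1, es_mode = "diff", ecdf_mode = "ecdf"),
    de = list(fc_min = 1.25, padj_max = 0.05, top_fc = 1.5,
              pseudocount = 0.01),
    sets = list(glut = "glutamatergic", gaba = "GABAergic")
  )
}

check_keys <- function(cfg, ref, prefix = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  }
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]])) stop("config key ", prefix, k, " must be a mapping")
      check_keys(cfg[[k]], ref[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(cfg)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]])
    } else override[[k]]
  }
  base
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys (at any nesting level) are rejected before any computation;
#' missing keys are filled from [default_pipeline_config()].
#'
#' @param cfg A partial configuration list, or a path to a YAML file.
#' @return The completed configuration.
#' @export
validate_pipeline_config <- function(cfg = list()) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) stop("config file not found: ", cfg)
    cfg <- yaml::read_yaml(cfg)
  }
  ref <- default_pipeline_config()
  check_keys(cfg, ref)
  cfg <- merge_config(ref, cfg)
  if (!cfg$simulate && is.null(cfg$input$counts_dir)) {
    stop("either simulate: true or input.counts_dir must be given")
  }
  cfg
}

#' Run the full spot-level E/I analysis pipeline
#'
#' simulate (or load) -> QC + log-normalize -> marker-based region
#' assignment -> glutamatergic/GABAergic set scores on hippocampal spots ->
#' median-split E/I classification and group statistics -> rank-sum DE
#' screen within the hippocampus -> similarity-ranked candidate table.
#' All result tables are written as TSV under `outdir` together with a JSON
#' run manifest; two runs with the same config are byte-identical.
#'
#' @param cfg Configuration list or YAML path (see
#'   [validate_pipeline_config()]).
#' @return Invisibly, a list with all intermediate objects: `counts`,
#'   `spots`, `norm`, `scores`, `classification` (`cls`), `summary`, `de`,
#'   `candidates`, `manifest`.
#' @export
run_pipeline <- function(cfg = default_pipeline_config()) {
  cfg <- validate_pipeline_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  if (cfg$simulate) {
    sim <- do.call(sim_config, cfg$sim[setdiff(names(cfg$sim), "seed")])
    sim$seed <- cfg$seed
    ds <- generate_dataset(sim)
    cm <- ds$counts; spots <- ds$spots; sets <- ds$sets; truth <- ds$truth
  } else {
    cm <- read_count_matrix(cfg$input$counts_dir)
    spots <- read_positions(cfg$input$positions)
    sets <- read_gmt(cfg$input$gmt)
    truth <- NULL
  }
  n_spots_in <- length(cm$barcodes); n_genes_in <- length(cm$genes)

  cm <- qc_spots(cm, cfg$qc$min_features, cfg$qc$max_mito)
  cm <- qc_genes(cm, cfg$qc$min_spots)
  spots <- spots[match(cm$barcodes, spots$barcode), , drop = FALSE]
  nm <- lognormalize(cm, cfg$norm$scale_factor)

  marker_sets <- sets[grepl("^markers_", names(sets))]
  class(marker_sets) <- "gene_sets"
  ms <- marker_score(nm, marker_sets)
  spots <- assign_regions(ms, spots, cfg$regions$threshold)
  hipp <- hippocampal_spots(spots)
  if (length(hipp) < 4) stop("fewer than 4 hippocampal spots assigned")
  nm_h <- subset_spots(nm, hipp)
  spots_h <- spots[match(hipp, spots$barcode), , drop = FALSE]

  params <- set_score_params(cfg$score$tau, cfg$score$es_mode,
                             cfg$score$ecdf_mode)
  sig_sets <- sets[c(cfg$sets$glut, cfg$sets$gaba)]
  class(sig_sets) <- "gene_sets"
  scores <- score_sets(nm_h, sig_sets, params)

  glut_lv <- dichotomize(scores, cfg$sets$glut)
  gaba_lv <- dichotomize(scores, cfg$sets$gaba)
  cls <- classify_ei(glut_lv, gaba_lv)
  summ <- group_summary(cls, spots_h, scores)

  affected <- if (cfg$simulate) sim$affected else utils::tail(unique(spots_h$group), 1)
  de <- de_table(nm_h, spots_h$group, affected,
                 cfg$de$fc_min, cfg$de$padj_max, cfg$de$top_fc,
                 cfg$de$pseudocount)
  de$similarity <- spatial_similarity(nm_h, scores, cfg$sets$glut,
                                      de$gene)[de$gene]
  cand <- prioritize_candidates(de, sig_sets, cfg$sets$glut)

  hipp_by_sample <- table(spots_h$sample)
  manifest <- list(
    package = "eispot",
    version = as.character(utils::packageVersion("eispot")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "outdir")],
    n_spots_input = n_spots_in, n_genes_input = n_genes_in,
    n_spots_qc = length(cm$barcodes), n_genes_qc = length(cm$genes),
    hippocampal_spots = as.list(hipp_by_sample),
    n_pass_de = sum(de$pass_de), n_top_tier = sum(de$top_tier),
    n_candidates = nrow(cand))

  cls_out <- data.frame(barcode = spots_h$barcode, sample = spots_h$sample,
                        group = spots_h$group, region = spots_h$region,
                        glut_score = scores[, cfg$sets$glut],
                        gaba_score = scores[, cfg$sets$gaba],
                        cls$levels, stringsAsFactors = FALSE, row.names = NULL)
  write_tsv(cls_out, file.path(cfg$outdir, "ei_classification.tsv"))
  write_tsv(summ$category_table, file.path(cfg$outdir, "ei_category_table.tsv"))
  write_tsv(summ$score_tests, file.path(cfg$outdir, "score_tests.tsv"))
  write_tsv(summ$prop_tests, file.path(cfg$outdir, "proportion_tests.tsv"))
  write_tsv(de, file.path(cfg$outdir, "de_table.tsv"))
  write_tsv(cand, file.path(cfg$outdir, "candidates.tsv"))
  write_tsv(spots, file.path(cfg$outdir, "spots_assigned.tsv"))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(counts = cm, spots = spots, norm = nm, spots_hipp = spots_h,
                 scores = scores, cls = cls, summary = summ, de = de,
                 candidates = cand, truth = truth, manifest = manifest))
}
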