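#' Configuration for the Visium-like hippocampus simulator
#'
#' Defaults emulate the study design the pipeline targets: two samples
#' (control-like `CON` and colitis-like `DSS`) of 1000 in-tissue spots each
#' on a 40 x 25 array, with a contiguous band of rows forming the
#' hippocampus (~350 spots per sample, split into CA1/CA3/DG sub-bands),
#' negative-binomial UMI counts, region marker genes elevated within their
#' band, and a condition effect that multiplies glutamatergic-synapse genes
#' in hippocampal spots of the affected group while leaving the GABAergic
#' set untouched.
#'
#' @param n_spots_per_sample Spots per sample (filled row-major on the grid).
#' @param n_genes Total genes, including markers, signature sets, `mt-`
#'   genes and spiked DE genes.
#' @param n_cols,n_rows Array grid dimensions; `n_cols * n_rows` must be at
#'   least `n_spots_per_sample`.
#' @param hippocampal_fraction Fraction of grid rows forming the hippocampal
#'   band (split into three equal CA1/CA3/DG sub-bands).
#' @param marker_fold Multiplicative elevation of each region's marker genes
#'   inside its own band (>= 1).
#' @param marker_base_mean Baseline NB mean of marker genes; markers emulate
#'   the top, highly expressed cluster markers, so their baseline is above
#'   the genome-wide `baseline_mean`.
#' @param n_markers_per_region Marker genes per subregion; the first three
#'   of each set are the field's canonical CA1/CA3/DG markers.
#' @param glut_set_size,gaba_set_size Sizes of the glutamatergic and
#'   GABAergic signature sets.
#' @param effect_glut Multiplicative condition effect on glutamatergic-set
#'   genes in hippocampal spots of the affected group.
#' @param effect_gaba Same for the GABAergic set (default 1 = no effect).
#' @param baseline_mean Negative-binomial mean per gene per spot before
#'   multipliers.
#' @param dispersion NB dispersion alpha (variance mu + alpha * mu^2); 0
#'   gives Poisson counts.
#' @param libsize_cv Coefficient of variation of the per-spot library-size
#'   factor (lognormal, mean 1).
#' @param mito_fraction_mean Expected fraction of counts from `mt-` genes.
#' @param n_mito Number of `mt-` prefixed mitochondrial genes.
#' @param n_de_spike Number of extra spiked DE genes (outside the signature
#'   sets) elevated in affected hippocampal spots.
#' @param de_spike_fold Fold applied to the spiked genes.
#' @param glut_activity_sd Lognormal sd of a per-spot glutamatergic activity
#'   factor shared by glut-set genes in hippocampal spots of both groups;
#'   gives the glutamatergic score genuine spot-to-spot spatial variation.
#' @param gaba_activity_sd Same for the GABAergic set: per-spot pathway
#'   activity shared by its genes in hippocampal spots of both groups.
#' @param receptor_gene Name of the receptor-like candidate gene (a member
#'   of the glutamatergic set).
#' @param receptor_loading Exponent of the activity factor for the receptor
#'   gene (stronger coupling to the pathway than the other set genes).
#' @param receptor_fold Extra condition fold on the receptor gene, on top of
#'   `effect_glut`.
#' @param groups Character vector of the two sample/group labels,
#'   control first.
#' @param affected Which group carries the condition effects.
#' @param seed RNG seed; generation is deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_spots_per_sample = 1000, n_genes = 1000,
                       n_cols = 40, n_rows = 25,
                       hippocampal_fraction = 0.35,
                       marker_fold = 4, n_markers_per_region = 50,
                       marker_base_mean = 2.0,
                       glut_set_size = 30, gaba_set_size = 30,
                       effect_glut = 1.5, effect_gaba = 1.0,
                       baseline_mean = 0.5, dispersion = 0.3,
                       libsize_cv = 0.3,
                       mito_fraction_mean = 0.05, n_mito = 13,
                       n_de_spike = 0, de_spike_fold = 2.0,
                       glut_activity_sd = 0.3, gaba_activity_sd = 0.3,
                       receptor_gene = "Grm1",
                       receptor_loading = 2, receptor_fold = 1.4,
                       groups = c("CON", "DSS"), affected = "DSS",
                       seed = 7) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_cols * n_rows < n_spots_per_sample) {
      stop("grid too small: ", n_cols, " x ", n_rows, " < ", n_spots_per_sample)
    }
    if (hippocampal_fraction <= 0 || hippocampal_fraction >= 1) {
      stop("hippocampal_fraction must be in (0, 1)")
    }
    if (effect_glut <= 0 || effect_gaba <= 0 || de_spike_fold <= 0 ||
        receptor_fold <= 0) {
      stop("effect sizes must be > 0")
    }
    if (marker_fold < 1) stop("marker_fold must be >= 1")
    n_named <- 3 * n_markers_per_region + glut_set_size + gaba_set_size +
      n_mito + n_de_spike
    if (n_named > n_genes) {
      stop("set sizes (", n_named, " named genes) exceed n_genes (", n_genes, ")")
    }
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (length(groups) != 2 || !(affected %in% groups)) {
      stop("groups must be two labels with affected among them")
    }
  })
  invisible(cfg)
}

#' The packaged default simulator configuration
#'
#' @return The [sim_config()] defaults: 2 samples x 1000 spots, ~350
#'   hippocampal spots each, 1000 genes, 30-gene glutamatergic and GABAergic
#'   sets, `effect_glut` 1.5, `effect_gaba` 1.0, dispersion 0.3, seed 7.
#' @export
default_config <- function() sim_config()

#' Null study conditions: no condition effect anywhere
#'
#' All condition multipliers at 1 (glutamatergic, GABAergic, receptor,
#' spikes); used to check test calibration.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
null_config <- function(...) {
  sim_config(effect_glut = 1, effect_gaba = 1, receptor_fold = 1,
             n_de_spike = 0, ...)
}

#' Spike-in DE recovery conditions
#'
#' 30 genes spiked at fold 2 in affected hippocampal spots as the only true
#' differential signal (signature effects off), for measuring recall and
#' false discovery of the DE screen against ground truth.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
de_spike_config <- function(...) {
  sim_config(effect_glut = 1, effect_gaba = 1, receptor_fold = 1,
             n_de_spike = 30, de_spike_fold = 2.0, ...)
}

# hippocampal row bands: a centered block of rows split into three equal
# CA1/CA3/DG sub-bands
region_layout <- function(cfg) {
  k <- round(cfg$n_rows * cfg$hippocampal_fraction)
  k <- max(3, k - (k %% 3))
  start <- floor((cfg$n_rows - k) / 2) + 1
  w <- k / 3
  list(CA1 = start:(start + w - 1),
       CA3 = (start + w):(start + 2 * w - 1),
       DG = (start + 2 * w):(start + k - 1))
}

sim_gene_names <- function(cfg) {
  nm <- cfg$n_markers_per_region
  mk <- function(paper, prefix) c(paper, sprintf("%sm%d", prefix, seq_len(nm))[-(1:3)])
  markers <- list(CA1 = mk(c("Itpka", "Fibcd1", "Spink8"), "Ca1"),
                  CA3 = mk(c("Cabp7", "Homer3", "Hs3st4"), "Ca3"),
                  DG = mk(c("C1ql2", "Fam163b", "Dsp"), "Dg"))
  glut <- c("Grm1", "Shank3", "Grik4",
            sprintf("Glut%02d", seq_len(cfg$glut_set_size))[-(1:3)])
  gaba <- c("Gabra1", "Gad1", "Slc32a1",
            sprintf("Gaba%02d", seq_len(cfg$gaba_set_size))[-(1:3)])
  mito <- c("mt-Nd1", "mt-Nd2", "mt-Nd3", "mt-Nd4", "mt-Nd4l", "mt-Nd5",
            "mt-Nd6", "mt-Co1", "mt-Co2", "mt-Co3", "mt-Atp6", "mt-Atp8",
            "mt-Cytb", sprintf("mt-X%d", seq_len(max(0, cfg$n_mito - 13))))
  mito <- mito[seq_len(cfg$n_mito)]
  spike <- sprintf("Spike%02d", seq_len(cfg$n_de_spike))
  named <- c(unlist(markers, use.names = FALSE), glut, gaba, mito, spike)
  fill <- sprintf("Gene%04d", seq_len(cfg$n_genes - length(named)))
  list(all = c(named, fill), markers = markers, glut = glut, gaba = gaba,
       mito = mito, spike = spike)
}

#' Generate a two-condition Visium-like dataset with ground truth
#'
#' Draws UMI counts for two samples from a negative binomial whose mean is
#' `baseline_mean` x per-spot library factor x region-marker, signature and
#' condition multipliers (see [sim_config()]). Deterministic given the
#' config seed; the global RNG state is left untouched.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` ([count_matrix()], both samples stacked;
#'   barcodes prefixed by sample), `spots` (spot table with true `sample`
#'   and `group`, `region` unassigned), `sets` ([gene_sets()]:
#'   `glutamatergic`, `GABAergic`, and `markers_CA1/CA3/DG`), and `truth`
#'   (list: `spots` with the true region per spot, `genes` with set
#'   membership and true condition fold, `receptor_gene`, `config`).
#' @export
generate_dataset <- function(cfg = default_config()) {
  validate_sim_config(cfg)
  gn <- sim_gene_names(cfg)
  layout <- region_layout(cfg)

  grid <- expand.grid(col = seq_len(cfg$n_cols), row = seq_len(cfg$n_rows))
  grid <- grid[seq_len(cfg$n_spots_per_sample), , drop = FALSE]
  true_region <- rep("other", nrow(grid))
  for (r in names(layout)) true_region[grid$row %in% layout[[r]]] <- r

  N <- cfg$n_genes
  base <- rep(cfg$baseline_mean, N)
  names(base) <- gn$all
  all_marker_idx <- match(unlist(gn$markers, use.names = FALSE), gn$all)
  base[all_marker_idx] <- cfg$marker_base_mean
  mito_idx <- match(gn$mito, gn$all)
  f <- cfg$mito_fraction_mean
  base[mito_idx] <- f / (1 - f) * sum(base[-mito_idx]) / cfg$n_mito

  glut_idx <- match(gn$glut, gn$all)
  gaba_idx <- match(gn$gaba, gn$all)
  spike_idx <- match(gn$spike, gn$all)
  receptor_idx <- match(cfg$receptor_gene, gn$all)
  sdlog <- sqrt(log(1 + cfg$libsize_cv^2))

  sample_counts <- withr::with_seed(cfg$seed, lapply(cfg$groups, function(g) {
    S <- nrow(grid)
    hipp <- true_region != "other"
    mu <- matrix(base, nrow = S, ncol = N, byrow = TRUE)
    for (r in names(gn$markers)) {
      midx <- match(gn$markers[[r]], gn$all)
      mu[true_region == r, midx] <- mu[true_region == r, midx] * cfg$marker_fold
    }
    # shared glutamatergic activity across hippocampal spots of both groups
    act <- rep(1, S)
    act[hipp] <- exp(stats::rnorm(sum(hipp), -cfg$glut_activity_sd^2 / 2,
                                  cfg$glut_activity_sd))
    mu[, glut_idx] <- mu[, glut_idx] * act
    mu[, receptor_idx] <- mu[, receptor_idx] * act^(cfg$receptor_loading - 1)
    act_g <- rep(1, S)
    act_g[hipp] <- exp(stats::rnorm(sum(hipp), -cfg$gaba_activity_sd^2 / 2,
                                    cfg$gaba_activity_sd))
    mu[, gaba_idx] <- mu[, gaba_idx] * act_g
    if (g == cfg$affected) {
      mu[hipp, glut_idx] <- mu[hipp, glut_idx] * cfg$effect_glut
      mu[hipp, gaba_idx] <- mu[hipp, gaba_idx] * cfg$effect_gaba
      if (length(spike_idx)) {
        mu[hipp, spike_idx] <- mu[hipp, spike_idx] * cfg$de_spike_fold
      }
      mu[hipp, receptor_idx] <- mu[hipp, receptor_idx] * cfg$receptor_fold
    }
    lib <- exp(stats::rnorm(S, -sdlog^2 / 2, sdlog))
    mu <- mu * lib
    size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
    matrix(stats::rnbinom(S * N, mu = mu, size = size), nrow = S, ncol = N)
  }))

  barcodes <- unlist(lapply(cfg$groups, function(g) {
    sprintf("%s_%04d-1", g, seq_len(nrow(grid)))
  }))
  cm <- count_matrix(do.call(rbind, sample_counts), barcodes, gn$all)
  spots <- spot_table(
    barcode = barcodes,
    row = rep(grid$row, 2), col = rep(grid$col, 2),
    in_tissue = TRUE,
    sample = rep(cfg$groups, each = nrow(grid)),
    group = rep(cfg$groups, each = nrow(grid)),
    region = "unassigned")

  sets <- gene_sets(
    c(list(glutamatergic = gn$glut, GABAergic = gn$gaba),
      stats::setNames(gn$markers, paste0("markers_", names(gn$markers)))),
    descriptions = c(
      glutamatergic = "glutamatergic synapse signature",
      GABAergic = "GABAergic synapse signature",
      markers_CA1 = "CA1 subregion markers",
      markers_CA3 = "CA3 subregion markers",
      markers_DG = "DG subregion markers"))

  true_fold <- rep(1, N)
  true_fold[glut_idx] <- cfg$effect_glut
  true_fold[gaba_idx] <- cfg$effect_gaba
  if (length(spike_idx)) true_fold[spike_idx] <- cfg$de_spike_fold
  true_fold[receptor_idx] <- cfg$effect_glut * cfg$receptor_fold
  membership <- rep("none", N)
  membership[glut_idx] <- "glut"
  membership[gaba_idx] <- "gaba"
  membership[mito_idx] <- "mito"
  if (length(spike_idx)) membership[spike_idx] <- "spike"
  for (r in names(gn$markers)) {
    membership[match(gn$markers[[r]], gn$all)] <- paste0("marker_", r)
  }

  truth <- list(
    spots = data.frame(barcode = barcodes,
                       sample = rep(cfg$groups, each = nrow(grid)),
                       region = rep(true_region, 2),
                       stringsAsFactors = FALSE),
    genes = data.frame(gene = gn$all, membership = membership,
                       true_fold = true_fold, stringsAsFactors = FALSE),
    receptor_gene = cfg$receptor_gene,
    config = cfg)
  list(counts = cm, spots = spots, sets = sets, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits the 10x-style triplet directory, a positions CSV, the signature and
#' marker GMT, and a tab-separated ground-truth sidecar.
#'
#' @param ds Output of [generate_dataset()].
#' @param outdir Output directory.
#' @export
write_dataset <- function(ds, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(ds$counts, file.path(outdir, "counts"))
  write_positions(ds$spots, file.path(outdir, "positions.csv"))
  write_gmt(ds$sets, file.path(outdir, "gene_sets.gmt"))
  write_tsv(ds$truth$spots, file.path(outdir, "truth_spots.tsv"))
  write_tsv(ds$truth$genes, file.path(outdir, "truth_genes.tsv"))
  invisible(NULL)
}
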