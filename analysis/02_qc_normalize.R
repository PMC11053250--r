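#!/usr/bin/env Rscript
# Step 2 — quality control and normalization.
#
# Reads the simulated dataset back from disk (exercising the 10x triplet
# readers), removes low-quality spots (< 100 detected genes or > 20%
# mitochondrial counts) and rarely detected genes (< 3 spots), and
# log-normalizes to counts-per-10k. Writes a per-spot QC table.

suppressPackageStartupMessages(library(eispot))

cm <- read_count_matrix("results/simulated/counts")
spots <- read_positions("results/simulated/positions.csv")
n0 <- length(cm$barcodes)

qc <- data.frame(
  barcode = cm$barcodes,
  total_counts = Matrix::rowSums(cm$counts),
  detected_genes = Matrix::rowSums(cm$counts > 0),
  mito_fraction = Matrix::rowSums(
    cm$counts[, grepl("^mt-", cm$genes), drop = FALSE]) /
    pmax(Matrix::rowSums(cm$counts), 1))

cm <- qc_spots(cm, min_features = 100, max_mito = 0.2)
cm <- qc_genes(cm, min_spots = 3)
nm <- lognormalize(cm, scale_factor = 1e4)

qc$kept <- qc$barcode %in% cm$barcodes
write_tsv(qc, "results/spot_qc.tsv")

cat(sprintf("Spots: %d -> %d after QC (%.1f%% retained)\n",
            n0, length(cm$barcodes), 100 * length(cm$barcodes) / n0))
cat(sprintf("Genes: %d retained\n", length(cm$genes)))
cat(sprintf("Median library size: %d counts; median detected genes: %d\n",
            round(median(qc$total_counts[qc$kept])),
            round(median(qc$detected_genes[qc$kept]))))
cat("Normalized matrix:", nrow(nm$values), "spots x", ncol(nm$values), "genes\n")
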