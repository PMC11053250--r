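#!/usr/bin/env Rscript
# Step 1 — simulate the two-condition Visium-like study.
#
# Generates the default study conditions: a control-like (CON) and a
# colitis-like (DSS) sample of 1000 spots each, a three-band hippocampus
# (~360 spots/sample), and a 1.5x glutamatergic-synapse effect confined to
# hippocampal spots of the DSS sample. Writes the 10x-style triplet matrix,
# positions CSV, signature/marker GMT and ground-truth sidecars.

suppressPackageStartupMessages(library(eispot))

outdir <- "results/simulated"
ds <- generate_dataset(default_config())
write_dataset(ds, outdir)

tab <- table(ds$truth$spots$sample, ds$truth$spots$region)
cat("Simulated", length(ds$counts$barcodes), "spots x",
    length(ds$counts$genes), "genes ->", outdir, "\n")
cat("True region counts per sample:\n")
print(tab)
cat("Signature sets:",
    paste(sprintf("%s (%d genes)", names(ds$sets), lengths(ds$sets)),
          collapse = ", "), "\n")
cat("Receptor-like candidate gene:", ds$truth$receptor_gene, "\n")
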