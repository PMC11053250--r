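#!/usr/bin/env Rscript
# Step 5 — hippocampal DE screen and candidate prioritization.
#
# Rank-sum test per gene between DSS and CON hippocampal spots, BH-adjusted,
# gated at |FC| >= 1.25 & Padj < 0.05 with a top tier at |FC| >= 1.5; each
# gene's spatial similarity to the glutamatergic score (Spearman) ranks the
# top-tier glutamatergic-set candidates (the Grm1/Shank3 logic).

suppressPackageStartupMessages(library(eispot))

cm <- read_count_matrix("results/simulated/counts")
spots <- read.delim("results/spots_assigned.tsv")
sets <- read_gmt("results/simulated/gene_sets.gmt")

cm <- qc_genes(qc_spots(cm, 100, 0.2), 3)
nm <- lognormalize(cm)
hipp <- spots$barcode[spots$region %in% c("CA1", "CA3", "DG")]
nm_h <- structure(list(values = nm$values[hipp, ], scale_factor = nm$scale_factor,
                       provenance = nm$provenance), class = "norm_matrix")
spots_h <- spots[match(hipp, spots$barcode), ]

de <- de_table(nm_h, spots_h$group, affected = "DSS")
sig <- sets[c("glutamatergic", "GABAergic")]
class(sig) <- "gene_sets"
scores <- score_sets(nm_h, sig)
de$similarity <- spatial_similarity(nm_h, scores, "glutamatergic",
                                    de$gene)[de$gene]
cand <- prioritize_candidates(de, sig, "glutamatergic")

write_tsv(de, "results/de_table.tsv")
write_tsv(cand, "results/candidates.tsv")

cat(sprintf("DE genes passing |FC|>=1.25 & Padj<0.05: %d (%d up, %d down)\n",
            sum(de$pass_de), sum(de$pass_de & de$direction == "up"),
            sum(de$pass_de & de$direction == "down")))
cat(sprintf("Top tier (|FC|>=1.5): %d\n", sum(de$top_tier)))
cat("\nTop candidates (top-tier glutamatergic-set genes by similarity):\n")
print(head(cand[, c("gene", "fc", "abs_fc", "padj", "similarity")], 5),
      digits = 3, row.names = FALSE)
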