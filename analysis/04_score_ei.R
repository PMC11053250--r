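#!/usr/bin/env Rscript
# Step 4 — per-spot synapse-signature scores and E/I classification.
#
# Computes the glutamatergic and GABAergic synapse scores for every
# hippocampal spot (ECDF -> symmetric rank weights -> weighted KS random
# walk), splits each signature at its pooled median into high/low, crosses
# the two levels into the four E/I categories, and compares the groups:
# Mann-Whitney on the scores, two-proportion chi-square on the
# high-glutamatergic and excitatory fractions.

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

sig <- sets[c("glutamatergic", "GABAergic")]
class(sig) <- "gene_sets"
scores <- score_sets(nm_h, sig)

glut <- dichotomize(scores, "glutamatergic")
gaba <- dichotomize(scores, "GABAergic")
cls <- classify_ei(glut, gaba)
summ <- group_summary(cls, spots_h, scores)

out <- data.frame(barcode = spots_h$barcode, group = spots_h$group,
                  region = spots_h$region,
                  glut_score = scores[, "glutamatergic"],
                  gaba_score = scores[, "GABAergic"], cls$levels)
write_tsv(out, "results/ei_classification.tsv")
write_tsv(summ$category_table, "results/ei_category_table.tsv")
write_tsv(summ$score_tests, "results/score_tests.tsv")
write_tsv(summ$prop_tests, "results/proportion_tests.tsv")

cat("Mann-Whitney on per-spot scores (CON vs DSS):\n")
print(summ$score_tests, digits = 3)
cat("\nFour-category proportions per group:\n")
print(reshape(summ$category_table[, c("group", "category", "proportion")],
              idvar = "group", timevar = "category", direction = "wide"),
      digits = 3)
cat("\nProportion tests (chi-square, continuity-corrected):\n")
print(summ$prop_tests, digits = 3)
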