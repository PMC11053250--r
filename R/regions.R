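#' Per-spot marker scores for each subregion
#'
#' For each region's marker set, the score of a spot is the mean across the
#' set's genes (those present in the matrix) of the gene-wise z-score, where
#' each gene is centered and scaled across spots. Genes with zero variance
#' contribute 0. This is an automated stand-in for the manual, image-guided
#' spot curation the scores emulate.
#'
#' @param nm A `norm_matrix` from [lognormalize()].
#' @param markers A [gene_sets()] collection of marker sets; names become
#'   the score columns (a `markers_` prefix is stripped).
#' @return A data.frame: `barcode` plus one numeric score column per region.
#' @export
marker_score <- function(nm, markers) {
  z <- scale(nm$values)          # genes centered/scaled across spots
  z[, attr(z, "scaled:scale") == 0] <- 0
  out <- data.frame(barcode = rownames(nm$values), stringsAsFactors = FALSE)
  for (set_name in names(markers)) {
    present <- intersect(markers[[set_name]], colnames(nm$values))
    if (length(present) == 0) {
      stop("marker set '", set_name, "' has no gene in the matrix; missing: ",
           paste(markers[[set_name]], collapse = ", "))
    }
    region <- sub("^markers_", "", set_name)
    out[[region]] <- rowMeans(z[, present, drop = FALSE])
  }
  out
}

#' Assign spots to subregions by marker-score argmax
#'
#' A spot is assigned to the region with the highest marker score if that
#' score reaches `threshold`, otherwise to `"other"`. Ties are broken by the
#' fixed order CA1 > CA3 > DG (column order of the score table). The
#' hippocampus is the union of the three subregions.
#'
#' @param scores Score table from [marker_score()].
#' @param spots A spot table; its `region` column is replaced.
#' @param threshold Minimum winning score for an assignment.
#' @return The spot table with `region` filled in.
#' @export
assign_regions <- function(scores, spots, threshold = 0.25) {
  stopifnot(all(spots$barcode %in% scores$barcode))
  s <- as.matrix(scores[match(spots$barcode, scores$barcode), -1, drop = FALSE])
  regions <- colnames(s)
  best <- apply(s, 1, which.max)   # first maximum = fixed-order tie-break
  win <- s[cbind(seq_len(nrow(s)), best)]
  spots$region <- ifelse(win >= threshold, regions[best], "other")
  spots
}

#' Hippocampal spot barcodes of an assigned spot table
#'
#' @param spots Spot table with assigned regions.
#' @return Character vector of barcodes in CA1, CA3 or DG.
#' @export
hippocampal_spots <- function(spots) {
  spots$barcode[spots$region %in% c("CA1", "CA3", "DG")]
}
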