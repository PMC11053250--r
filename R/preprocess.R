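#' Filter low-quality spots
#'
#' Keeps spots with at least `min_features` detected genes (count > 0) and a
#' mitochondrial count fraction of at most `max_mito`. Mitochondrial genes
#' are identified by a case-insensitive `mt-` symbol prefix; a matrix with
#' no such genes has mito fraction 0 everywhere. Spot order is preserved.
#'
#' @param cm A [count_matrix()].
#' @param min_features Minimum detected genes per spot.
#' @param max_mito Maximum mitochondrial fraction in `[0, 1]`.
#' @return The filtered [count_matrix()].
#' @export
qc_spots <- function(cm, min_features = 100, max_mito = 0.2) {
  stopifnot(inherits(cm, "count_matrix"), min_features >= 0,
            max_mito >= 0, max_mito <= 1)
  detected <- Matrix::rowSums(cm$counts > 0)
  mito <- grepl("^mt-", cm$genes, ignore.case = TRUE)
  total <- Matrix::rowSums(cm$counts)
  mito_frac <- ifelse(total > 0, Matrix::rowSums(cm$counts[, mito, drop = FALSE]) / total, 0)
  keep <- detected >= min_features & mito_frac <= max_mito
  if (!any(keep)) {
    stop("qc_spots removed every spot; relax min_features (", min_features,
         ") or max_mito (", max_mito, ")")
  }
  count_matrix(cm$counts[keep, , drop = FALSE], cm$barcodes[keep], cm$genes)
}

#' Filter rarely detected genes
#'
#' Keeps genes detected (count > 0) in at least `min_spots` spots.
#'
#' @param cm A [count_matrix()].
#' @param min_spots Minimum number of spots with a non-zero count.
#' @return The filtered [count_matrix()].
#' @export
qc_genes <- function(cm, min_spots = 3) {
  stopifnot(inherits(cm, "count_matrix"), min_spots >= 0)
  keep <- Matrix::colSums(cm$counts > 0) >= min_spots
  count_matrix(cm$counts[, keep, drop = FALSE], cm$barcodes, cm$genes[keep])
}

#' Library-size log-normalization
#'
#' Removes the capture-size preference between spots:
#' `value = ln(1 + count * scale_factor / spot_total)`. Exactly invariant to
#' multiplying any spot's counts by a positive constant.
#'
#' @param cm A [count_matrix()] with no all-zero spots (run [qc_spots()]
#'   first).
#' @param scale_factor Counts-per-`scale_factor` target library size.
#' @return A `norm_matrix`: list with `values` (dense spots x genes matrix),
#'   `scale_factor`, and `provenance`.
#' @export
lognormalize <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "count_matrix"), scale_factor > 0)
  total <- Matrix::rowSums(cm$counts)
  if (any(total == 0)) {
    stop("all-zero spot(s): ",
         paste(utils::head(cm$barcodes[total == 0], 5), collapse = ", "),
         "; run qc_spots first")
  }
  values <- log1p(as.matrix(cm$counts) * (scale_factor / total))
  dimnames(values) <- list(cm$barcodes, cm$genes)
  structure(list(values = values, scale_factor = scale_factor,
                 provenance = list()),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d spots x %d genes (scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

# subset a norm_matrix by spot barcodes, preserving attributes
subset_spots <- function(nm, barcodes) {
  structure(list(values = nm$values[barcodes, , drop = FALSE],
                 scale_factor = nm$scale_factor, provenance = nm$provenance),
            class = "norm_matrix")
}
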