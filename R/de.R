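#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact when `n1 + n2 <= 12` (full enumeration of all group assignments,
#' valid under ties); otherwise a tie-corrected normal approximation of the
#' U statistic, without continuity correction. A comparison in which the
#' pooled values are constant returns p = 1 by convention.
#'
#' @param x,y Numeric samples for the two groups.
#' @return A list with `statistic` (U of the first sample) and `p.value`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  v <- c(x, y)
  if (length(unique(v)) == 1) {
    return(list(statistic = n1 * n2 / 2, p.value = 1))
  }
  r <- rank(v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= 12) {
    idx <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  } else {
    ties <- table(v)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = u_obs, p.value = p)
}

#' Per-gene two-group rank-sum p-values
#'
#' Applies [rank_sum_test()] to each gene of a normalized matrix, comparing
#' the spots of the two groups. A gene constant across all spots gets p = 1.
#'
#' @param nm A `norm_matrix` (or spots x genes matrix).
#' @param groups Group label per spot (exactly two distinct labels, each
#'   with >= 2 spots).
#' @return Named numeric vector of two-sided p-values per gene.
#' @export
per_gene_test <- function(nm, groups) {
  v <- if (inherits(nm, "norm_matrix")) nm$values else as.matrix(nm)
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly 2 groups, got: ",
                             paste(lev, collapse = ", "))
  if (min(table(groups)) < 2) stop("both groups need >= 2 spots")
  i1 <- groups == lev[1]
  apply(v, 2, function(g) rank_sum_test(g[i1], g[!i1])$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and names as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene fold change between groups
#'
#' Computed on de-logged normalized expression: the log-normalized values
#' are mapped back through `expm1` to the counts-per-scale-factor scale,
#' averaged per group, and the affected/control ratio is taken with a small
#' pseudocount: `fc = (mean_affected + c) / (mean_control + c)`.
#' `abs_fc = max(fc, 1/fc)` is direction-free.
#'
#' @param nm A `norm_matrix` (or spots x genes matrix of log-normalized
#'   values).
#' @param groups Group label per spot.
#' @param affected Label of the affected (numerator) group.
#' @param pseudocount Stabilizer `c` (default 0.01).
#' @return data.frame per gene: `gene`, group means (de-logged), `fc`,
#'   `abs_fc`, `direction` (`up`/`down`).
#' @export
fold_change <- function(nm, groups, affected, pseudocount = 0.01) {
  v <- if (inherits(nm, "norm_matrix")) nm$values else as.matrix(nm)
  stopifnot(affected %in% groups)
  expr <- expm1(v)
  m_aff <- colMeans(expr[groups == affected, , drop = FALSE])
  m_con <- colMeans(expr[groups != affected, , drop = FALSE])
  fc <- (m_aff + pseudocount) / (m_con + pseudocount)
  data.frame(gene = colnames(v), mean_control = m_con, mean_affected = m_aff,
             fc = fc, abs_fc = pmax(fc, 1 / fc),
             direction = ifelse(fc >= 1, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential-expression table with the fold-change / FDR gates
#'
#' Rank-sum p-values with BH adjustment and de-logged fold changes,
#' gated at `|FC| >= fc_min` with `padj < padj_max` (`pass_de`), and a top
#' tier at `|FC| >= top_fc` among the passing genes. Sorted by `padj`, ties
#' by `abs_fc` descending.
#'
#' @param nm A `norm_matrix` of the spots to compare.
#' @param groups Group label per spot.
#' @param affected Label of the affected group.
#' @param fc_min,padj_max,top_fc DE gates (defaults 1.25, 0.05, 1.5).
#' @param pseudocount Fold-change pseudocount.
#' @return data.frame per gene: fold-change columns plus `p`, `padj`,
#'   `pass_de`, `top_tier`, and a `similarity` column initialized to `NA`
#'   (filled by [spatial_similarity()]).
#' @export
de_table <- function(nm, groups, affected, fc_min = 1.25, padj_max = 0.05,
                     top_fc = 1.5, pseudocount = 0.01) {
  de <- fold_change(nm, groups, affected, pseudocount)
  de$p <- unname(per_gene_test(nm, groups))
  de$padj <- bh_adjust(de$p)
  de$pass_de <- de$abs_fc >= fc_min & de$padj < padj_max
  de$top_tier <- de$pass_de & de$abs_fc >= top_fc
  de$similarity <- NA_real_
  de[order(de$padj, -de$abs_fc), , drop = FALSE]
}

#' Spatial similarity of genes to a gene-set score
#'
#' Spearman rank correlation between each gene's per-spot normalized
#' expression and one column of the score matrix, over the spots of both
#' groups. A constant gene (or constant score) yields 0 with a warning.
#'
#' @param nm A `norm_matrix` over the spots of interest (>= 3 spots).
#' @param scores A `score_matrix` aligned to the same spots.
#' @param set_name Score column to correlate against.
#' @param genes Genes to evaluate (default: all in `nm`).
#' @return Named numeric vector of similarities per gene.
#' @export
spatial_similarity <- function(nm, scores, set_name, genes = NULL) {
  v <- if (inherits(nm, "norm_matrix")) nm$values else as.matrix(nm)
  if (nrow(v) < 3) stop("spatial_similarity needs >= 3 spots")
  if (!set_name %in% colnames(scores)) stop("unknown set name: ", set_name)
  if (is.null(genes)) genes <- colnames(v)
  miss <- setdiff(genes, colnames(v))
  if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
  sc <- scores[, set_name]
  if (stats::sd(sc) == 0) {
    warning("constant score column '", set_name, "'; similarities set to 0")
    return(stats::setNames(rep(0, length(genes)), genes))
  }
  out <- suppressWarnings(
    as.vector(stats::cor(v[, genes, drop = FALSE], sc, method = "spearman")))
  if (anyNA(out)) {
    warning(sum(is.na(out)), " constant gene(s); similarity set to 0")
    out[is.na(out)] <- 0
  }
  stats::setNames(out, genes)
}

#' Rank candidate genes by similarity to the pathway score
#'
#' Candidates are the top-tier DE genes that belong to the named signature
#' set, ranked by spatial similarity descending, ties by `abs_fc`
#' descending. An empty candidate set returns an empty table.
#'
#' @param de A [de_table()] with the `similarity` column filled.
#' @param sets A [gene_sets()] collection.
#' @param set_name Signature set defining the candidate pool.
#' @return The candidate rows of `de`, ranked.
#' @export
prioritize_candidates <- function(de, sets, set_name = "glutamatergic") {
  pool <- de[de$top_tier & de$gene %in% sets[[set_name]], , drop = FALSE]
  pool[order(-pool$similarity, -pool$abs_fc), , drop = FALSE]
}
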