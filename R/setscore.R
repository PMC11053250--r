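#' Parameters for the per-spot gene-set variation score
#'
#' @param tau Weight exponent of the random walk (default 1).
#' @param es_mode `"diff"`: enrichment score = maximum of the walk plus its
#'   minimum (the walk's zero starting state counts as a minimum candidate);
#'   `"maxabs"`: the walk extremum of largest magnitude (the positive one
#'   when the two magnitudes tie exactly).
#' @param ecdf_mode `"ecdf"` (default): expression statistic from
#'   averaged-tie ranks across spots; `"gaussian-kernel"`: smoothed CDF with
#'   per-gene bandwidth `sd / 4`.
#' @return A `set_score_params` list.
#' @export
set_score_params <- function(tau = 1, es_mode = c("diff", "maxabs"),
                             ecdf_mode = c("ecdf", "gaussian-kernel")) {
  stopifnot(tau >= 0)
  structure(list(tau = tau, es_mode = match.arg(es_mode),
                 ecdf_mode = match.arg(ecdf_mode)),
            class = "set_score_params")
}

#' Expression-level statistic: per-gene ECDF across spots
#'
#' Stage 1 of the scorer. In `"ecdf"` mode, `e[spot, gene]` is the
#' averaged-tie rank of the spot among all spots for that gene, divided by
#' the number of spots (values in (0, 1]). In `"gaussian-kernel"` mode it is
#' the mean Gaussian CDF of the spot's value against all spots, bandwidth
#' `sd(gene) / 4`; a zero-variance gene gets 0.5 everywhere.
#'
#' @param nm A `norm_matrix` (or plain spots x genes matrix) with >= 2 spots.
#' @param ecdf_mode See [set_score_params()].
#' @return A spots x genes matrix of expression statistics.
#' @export
ecdf_transform <- function(nm, ecdf_mode = "ecdf") {
  v <- if (inherits(nm, "norm_matrix")) nm$values else as.matrix(nm)
  S <- nrow(v)
  if (S < 2) stop("ecdf_transform needs >= 2 spots")
  if (ecdf_mode == "ecdf") {
    e <- apply(v, 2, rank, ties.method = "average") / S
  } else {
    e <- apply(v, 2, function(x) {
      h <- stats::sd(x) / 4
      if (h == 0) return(rep(0.5, S))
      rowMeans(stats::pnorm(outer(x, x, "-") / h))
    })
  }
  dimnames(e) <- dimnames(v)
  e
}

#' Per-spot gene ranking and rank weights
#'
#' Stage 2. Within each spot, genes are ordered by decreasing expression
#' statistic, ties broken by ascending gene index; a gene at rank `R` of `N`
#' gets the symmetric weight `|N/2 - R|`, largest at both extremes of the
#' ranking.
#'
#' @param e Spots x genes matrix from [ecdf_transform()].
#' @return A list: `order` (spots x genes matrix of gene indices, best rank
#'   first), `rank` (spots x genes matrix, rank of each gene column), and
#'   `weight` (spots x genes matrix, `|N/2 - rank|` aligned to gene columns).
#' @export
spot_rank_stat <- function(e) {
  e <- as.matrix(e)
  S <- nrow(e); N <- ncol(e)
  ord <- matrix(0L, S, N)
  rk <- matrix(0L, S, N)
  for (s in seq_len(S)) {
    o <- order(-e[s, ], seq_len(N))
    ord[s, ] <- o
    rk[s, o] <- seq_len(N)
  }
  list(order = ord, rank = rk, weight = abs(N / 2 - rk))
}

#' Weighted Kolmogorov-Smirnov random walk enrichment score
#'
#' Stage 3. Walking down one spot's gene ranking, the walk at position `l`
#' is the tau-weighted fraction of in-set weight seen so far minus the
#' fraction of out-of-set genes seen so far:
#' `nu(l) = sum_{i<=l, in set} w_i^tau / sum_{in set} w^tau -
#'  (#out-of-set <= l) / (N - m)`.
#'
#' @param gene_order Integer vector: gene indices from best to worst rank
#'   for one spot.
#' @param weights Numeric vector of per-gene weights (aligned to gene
#'   index, not to rank).
#' @param set_mask Logical vector: set membership per gene index; the set
#'   must contain at least one but not all genes.
#' @param params A [set_score_params()].
#' @param set_name Used in error messages.
#' @return The enrichment score (scalar), with the full walk in attribute
#'   `walk`.
#' @export
random_walk_es <- function(gene_order, weights, set_mask,
                           params = set_score_params(), set_name = "set") {
  N <- length(gene_order)
  m <- sum(set_mask)
  if (m == 0) stop("no gene of set '", set_name, "' is in the matrix")
  if (m == N) stop("set '", set_name, "' covers every gene; walk undefined")
  ins <- set_mask[gene_order]
  w <- weights[gene_order]^params$tau
  win <- w * ins
  tot <- sum(win)
  num <- if (tot > 0) cumsum(win) / tot else rep(0, N)
  nu <- num - cumsum(!ins) / (N - m)
  es <- if (params$es_mode == "diff") {
    max(nu) + min(0, nu)
  } else {
    # larger-magnitude extremum; the positive one on a magnitude tie
    if (max(nu) >= -min(nu) - 1e-12) max(nu) else min(nu)
  }
  attr(es, "walk") <- nu
  es
}

#' Score gene sets per spot
#'
#' Composition of the three stages: ECDF expression statistic, per-spot
#' symmetric rank weights, and the weighted KS random walk, giving one
#' enrichment score per spot per set. Only set genes present in the matrix
#' are used; the sizes actually used are recorded.
#'
#' @param nm A `norm_matrix` (or plain spots x genes matrix).
#' @param sets A [gene_sets()] collection.
#' @param params A [set_score_params()].
#' @return A spots x sets numeric matrix of class `score_matrix`, with
#'   attributes `params` and `set_sizes_used`.
#' @export
score_sets <- function(nm, sets, params = set_score_params()) {
  e <- ecdf_transform(nm, params$ecdf_mode)
  rs <- spot_rank_stat(e)
  S <- nrow(e); N <- ncol(e)
  genes <- colnames(e)
  out <- matrix(NA_real_, S, length(sets),
                dimnames = list(rownames(e), names(sets)))
  sizes <- integer(length(sets)); names(sizes) <- names(sets)
  for (k in seq_along(sets)) {
    mask <- genes %in% sets[[k]]
    sizes[k] <- sum(mask)
    for (s in seq_len(S)) {
      out[s, k] <- as.numeric(random_walk_es(rs$order[s, ], rs$weight[s, ],
                                             mask, params, names(sets)[k]))
    }
  }
  structure(out, params = params, set_sizes_used = sizes,
            class = c("score_matrix", class(out)))
}

#' Null enrichment-score sample from random gene sets
#'
#' Scores `n_perm` random gene sets of a given size on the same matrix, a
#' calibration utility for judging observed scores against a
#' no-association null.
#'
#' @param nm A `norm_matrix` (or plain matrix).
#' @param set_size Genes per random set.
#' @param n_perm Number of random sets.
#' @param seed RNG seed (sampling is deterministic given it).
#' @param params A [set_score_params()].
#' @return An `n_perm` x spots matrix of null enrichment scores.
#' @export
permutation_null <- function(nm, set_size, n_perm, seed = 1,
                             params = set_score_params()) {
  stopifnot(n_perm >= 1)
  e <- ecdf_transform(nm, params$ecdf_mode)
  rs <- spot_rank_stat(e)
  S <- nrow(e); N <- ncol(e)
  stopifnot(set_size >= 1, set_size < N)
  out <- matrix(NA_real_, n_perm, S)
  withr::with_seed(seed, {
    for (p in seq_len(n_perm)) {
      mask <- logical(N)
      mask[sample.int(N, set_size)] <- TRUE
      for (s in seq_len(S)) {
        out[p, s] <- as.numeric(random_walk_es(rs$order[s, ], rs$weight[s, ],
                                               mask, params))
      }
    }
  })
  out
}
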