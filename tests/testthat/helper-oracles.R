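# Independent brute-force oracles. These re-derive the scoring and testing
# definitions from first principles with naive loops, sharing no code with
# the package implementations they check.

# averaged-tie rank ECDF by explicit counting
oracle_ecdf <- function(values) {
  S <- nrow(values); G <- ncol(values)
  e <- matrix(0, S, G)
  for (j in seq_len(G)) {
    for (s in seq_len(S)) {
      less <- sum(values[, j] < values[s, j])
      eq <- sum(values[, j] == values[s, j])
      e[s, j] <- (less + (eq + 1) / 2) / S
    }
  }
  e
}

# per-spot enrichment score by stepwise walk enumeration
oracle_walk <- function(e_row, set_idx, tau = 1, es_mode = "diff") {
  G <- length(e_row)
  # selection-sort style ordering: larger e first, ties by lower gene index
  remaining <- seq_len(G)
  ord <- integer(0)
  while (length(remaining)) {
    best <- remaining[1]
    for (g in remaining) if (e_row[g] > e_row[best]) best <- g
    ord <- c(ord, best)
    remaining <- setdiff(remaining, best)
  }
  m <- length(set_idx)
  w_tot <- 0
  for (pos in seq_len(G)) {
    if (ord[pos] %in% set_idx) w_tot <- w_tot + abs(G / 2 - pos)^tau
  }
  walk <- numeric(G)
  in_acc <- 0; out_acc <- 0
  for (pos in seq_len(G)) {
    if (ord[pos] %in% set_idx) {
      in_acc <- in_acc + (if (w_tot > 0) abs(G / 2 - pos)^tau / w_tot else 0)
    } else {
      out_acc <- out_acc + 1 / (G - m)
    }
    walk[pos] <- in_acc - out_acc
  }
  if (es_mode == "diff") {
    max(walk) + min(c(0, walk))
  } else if (max(walk) >= -min(walk) - 1e-12) max(walk) else min(walk)
}

oracle_setscore <- function(values, set_genes, tau = 1, es_mode = "diff") {
  e <- oracle_ecdf(values)
  set_idx <- which(colnames(values) %in% set_genes)
  vapply(seq_len(nrow(values)),
         function(s) oracle_walk(e[s, ], set_idx, tau, es_mode), numeric(1))
}

# two-sided rank-sum p by full enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  v <- c(x, y)
  r <- rank(v)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  hits <- 0; total <- 0
  for (idx in asplit(utils::combn(n, n1), 2)) {
    total <- total + 1
    if (abs(u_of(idx) - mu) >= obs - 1e-12) hits <- hits + 1
  }
  hits / total
}

# BH step-up from the min-over-tail definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  padj <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(o == i)
    padj[i] <- min(1, min(p[o][rank_i:n] * n / (rank_i:n)))
  }
  padj
}
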