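# Brute-force reference implementations used as independent oracles.
# Deliberately naive: plain loops and first-principles formulas only.

bf_raw_score <- function(set_a, set_b, tc_cutoff = 0.28) {
  total <- 0
  for (fa in set_a$ligands$fingerprint) {
    for (fb in set_b$ligands$fingerprint) {
      tc <- length(intersect(fa, fb)) / length(union(fa, fb))
      if (tc >= tc_cutoff) total <- total + tc
    }
  }
  total
}

bf_auroc <- function(scores, pos, neg) {
  wins <- 0
  for (p in pos) {
    for (n in neg) {
      if (scores[p] > scores[n]) wins <- wins + 1
      else if (scores[p] == scores[n]) wins <- wins + 0.5
    }
  }
  wins / (length(pos) * length(neg))
}

bf_neighbor_voting <- function(W, A) {
  n <- nrow(W); t <- ncol(A)
  P <- matrix(0, n, t)
  for (i in seq_len(n)) {
    deg <- sum(W[i, ])
    for (j in seq_len(t)) {
      s <- 0
      for (k in seq_len(n)) s <- s + W[i, k] * A[k, j]
      P[i, j] <- if (deg > 0) s / deg else 0
    }
  }
  P
}

# all-pairs minimum path length by repeated boolean matrix products
bf_extend_ppi <- function(adj, max_path = 6L) {
  n <- nrow(adj)
  w <- matrix(0, n, n)
  reach <- diag(n)
  seen <- diag(n) > 0
  for (L in seq_len(max_path)) {
    reach <- (reach %*% adj > 0) * 1
    new_pair <- reach > 0 & !seen
    w[new_pair] <- 1 / L
    seen <- seen | new_pair
  }
  diag(w) <- 1
  w
}

bf_average_precision <- function(ranks_of_positives) {
  r <- sort(ranks_of_positives)
  mean(seq_along(r) / r)
}

# random small fingerprint as integer set
random_fp <- function(n_bits = 64L, n_on = 8L) {
  sort(sample.int(n_bits, n_on))
}

toy_ligand_set <- function(id, fps) {
  ligand_set(id, ligand_frame(paste0(id, "_", seq_along(fps)), fps))
}
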