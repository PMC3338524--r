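# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by brute force, without calling
# the package's vectorised implementations.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Brute-force divergence score for one column: enumerate all clade x
# outgroup non-gap pairs explicitly.
oracle_fd_score <- function(column, clade_a, clade_b, outgroup,
                            B = blosum62(), se_floor = 1e-6) {
  pair_scores <- function(members) {
    v <- numeric(0)
    for (a in column[members]) {
      for (o in column[outgroup]) {
        if (a != "-" && o != "-") v <- c(v, B[a, o])
      }
    }
    v
  }
  v1 <- pair_scores(clade_a)
  v2 <- pair_scores(clade_b)
  if (length(v1) == 0 || length(v2) == 0) return(NA_real_)
  m1 <- mean(v1); m2 <- mean(v2)
  if (m1 == m2) return(0)
  s1 <- if (length(v1) > 1) stats::var(v1) else 0
  s2 <- if (length(v2) > 1) stats::var(v2) else 0
  se <- sqrt(s1 / length(v1) + s2 / length(v2))
  abs(m1 - m2) / max(se, se_floor)
}

# Step-up FDR oracle, written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# A small in-memory group with uniform tag and one species per sequence.
toy_group <- function(seqs, tag = "J", group_id = "toy",
                      species = NULL) {
  ids <- names(seqs)
  if (is.null(species)) {
    species <- stats::setNames(paste0("sp_", ids), ids)
  }
  alignment_group(seqs, species = species,
                  category = stats::setNames(rep(tag, length(ids)), ids),
                  group_id = group_id)
}

# Random tree with strictly positive branch lengths; its patristic
# distances are additive by construction.
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  tr
}

# Partition built directly from label sets (bypasses tree enumeration).
manual_partition <- function(clade_a, clade_b, outgroup, node_id = 0L) {
  structure(list(node_id = node_id, clade_a = clade_a, clade_b = clade_b,
                 outgroup = outgroup), class = "node_partition")
}
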