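# Independent brute-force oracles, deliberately not sharing code with the
# package's igraph-based shortest-path machinery.

# all-pairs shortest paths by vectorized Floyd-Warshall over an adjacency
# matrix rebuilt directly from the surface nodes' voxel indices
oracle_all_pairs <- function(surface) {
  nd <- surface$nodes
  n <- nrow(nd)
  s <- surface$spacing
  dx <- outer(nd$ix, nd$ix, "-")
  dy <- outer(nd$iy, nd$iy, "-")
  dz <- outer(nd$iz, nd$iz, "-")
  adjacent <- pmax(abs(dx), abs(dy), abs(dz)) == 1
  W <- matrix(Inf, n, n)
  W[adjacent] <- s * sqrt(dx[adjacent]^2 + dy[adjacent]^2 + dz[adjacent]^2)
  diag(W) <- 0
  for (k in seq_len(n)) {
    via <- outer(W[, k], W[k, ], "+")
    W <- pmin(W, via)
  }
  W
}

# O(n^2) nearest-neighbor distances from an oracle distance matrix
oracle_nnd <- function(D_oracle, idx) {
  sub <- D_oracle[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  apply(sub, 1, min)
}
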