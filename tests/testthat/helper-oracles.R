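# Independent oracles used across the suite. These deliberately use naive,
# brute-force formulations so they share no code with the implementation.

# Riemann-sum overlap of the two Beta posteriors on a fine midpoint grid.
riemann_overlap <- function(k1, n1, k0, n0, n_grid = 2e5) {
  x <- seq(0.5 / n_grid, 1 - 0.5 / n_grid, length.out = n_grid)
  mean(pmin(
    dbeta(x, k1 + 1, n1 - k1 + 1),
    dbeta(x, k0 + 1, n0 - k0 + 1)
  ))
}

# Truth-table variant classification: plain loops over an evidence matrix
# (rows = variants, columns = samples, entries in {"called","supported","absent"}).
classify_oracle <- function(evidence) {
  out <- character(nrow(evidence))
  for (i in seq_len(nrow(evidence))) {
    n_called <- 0
    for (j in seq_len(ncol(evidence))) {
      if (evidence[i, j] == "called") n_called <- n_called + 1
    }
    out[i] <- if (n_called == 0) {
      NA_character_
    } else if (n_called == ncol(evidence)) {
      "ubiquitous"
    } else if (n_called >= 2) {
      "shared"
    } else {
      "private"
    }
  }
  out
}

# Exhaustive nearest-positive-pixel scan, mirroring the distance contract:
# zero for centroids inside a positive pixel, else the minimum Euclidean
# distance to a positive pixel centre.
distance_oracle <- function(cells, mask, pixel_size) {
  out <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cx <- cells$centroid_x[i]
    cy <- cells$centroid_y[i]
    col <- floor(cx / pixel_size) + 1
    row <- floor(cy / pixel_size) + 1
    if (row >= 1 && row <= nrow(mask) && col >= 1 && col <= ncol(mask) &&
      mask[row, col] != 0) {
      out[i] <- 0
      next
    }
    best <- Inf
    for (r in seq_len(nrow(mask))) {
      for (cc in seq_len(ncol(mask))) {
        if (mask[r, cc] != 0) {
          d <- sqrt((cx - (cc - 0.5) * pixel_size)^2 +
            (cy - (r - 0.5) * pixel_size)^2)
          if (d < best) best <- d
        }
      }
    }
    out[i] <- best
  }
  out
}

# Random additive (tree-realizable) distance matrix plus its generating tree.
random_additive_distances <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa)
    tr$edge.length <- runif(nrow(tr$edge), 0.3, 2)
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}

# Column-by-column Hamming scan for binary matrices.
hamming_oracle <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      diff <- 0
      for (k in seq_len(ncol(mat))) {
        if (mat[i, k] != mat[j, k]) diff <- diff + 1
      }
      d[i, j] <- diff
    }
  }
  d
}

# Small five-biopsy clonal tree used by several tests.
demo_clonal_tree <- function(branch_n = c(
                               trunk = 30, anc1 = 10, anc2 = 8,
                               PT = 12, Bx1 = 15, Bx2 = 15, Bx3 = 25, Bx4 = 18
                             ),
                             purity = 0.6) {
  clonal_tree(
    parent = c(
      trunk = NA, anc1 = "trunk", anc2 = "anc1",
      PT = "anc1", Bx1 = "anc2", Bx2 = "anc2",
      Bx3 = "trunk", Bx4 = "anc1"
    ),
    branch_mutations = branch_n,
    sample_map = c(PT = "PT", Bx1 = "Bx1", Bx2 = "Bx2", Bx3 = "Bx3", Bx4 = "Bx4"),
    purity = purity
  )
}
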