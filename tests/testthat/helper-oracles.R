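# Independent oracles. These share no code with the package implementation:
# the segmentation oracle is a straight-line per-pixel recomputation, and the
# island census uses igraph connected components over an explicitly built
# pixel-adjacency graph (the package uses its own flood fill).

oracle_segment <- function(image, myo, roi, n, remove_spurious = FALSE,
                           min_island = 10L, connectivity = 8L) {
  v <- image[roi]
  mu <- sum(v) / length(v)
  sigma <- sqrt(sum((v - mu)^2) / (length(v) - 1))
  thr <- mu + n * sigma
  mask <- matrix(FALSE, nrow(image), ncol(image))
  for (r in seq_len(nrow(image))) {
    for (c in seq_len(ncol(image))) {
      if (myo[r, c] && image[r, c] > thr) mask[r, c] <- TRUE
    }
  }
  removed <- 0L
  if (remove_spurious && any(mask)) {
    census <- oracle_components(mask, connectivity)
    drop_ids <- which(census$sizes < min_island)
    if (length(drop_ids)) {
      drop <- census$index[census$membership %in% drop_ids]
      mask[drop] <- FALSE
      removed <- length(drop)
    }
  }
  list(mask = mask, threshold = thr, removed = removed,
       fraction = 100 * sum(mask) / sum(myo))
}

# igraph-based connected-component census of a logical matrix.
oracle_components <- function(mask, connectivity = 8L) {
  idx <- which(mask)
  np <- length(idx)
  rr <- ((idx - 1L) %% nrow(mask)) + 1L
  cc <- ((idx - 1L) %/% nrow(mask)) + 1L
  dr <- abs(outer(rr, rr, "-"))
  dc <- abs(outer(cc, cc, "-"))
  adj <- if (connectivity == 8L) pmax(dr, dc) == 1L else (dr + dc) == 1L
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (nrow(pairs)) g <- igraph::add_edges(g, as.vector(t(pairs)))
  comp <- igraph::components(g)
  list(index = idx, membership = comp$membership, sizes = as.integer(comp$csize))
}

# Brute-force count of pixel centers inside an annulus given analytic circles.
oracle_annulus_count <- function(grid, center, r_endo, r_epi) {
  count <- 0L
  for (x in 0:(grid - 1)) {
    for (y in 0:(grid - 1)) {
      d <- sqrt((x - center[1])^2 + (y - center[2])^2)
      if (d < r_epi && d >= r_endo) count <- count + 1L
    }
  }
  count
}
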