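# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementation.

# Brute-force clustering oracle: all-pairs adjacency + union-find.
bf_cluster_oracle <- function(pos, threshold = 1000) {
  pos <- sort(pos)
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- numeric(0)
  for (i in seq_len(max(n - 1, 0))) {
    js <- which(abs(pos - pos[i]) < threshold)
    js <- js[js > i]
    for (j in js) {
      edges <- c(edges, pos[j] - pos[i])
      ri <- find(i)
      rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(pos, roots)
  comps <- comps[lengths(comps) >= 2]
  comps <- unname(lapply(comps, sort))
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  list(components = comps, edge_distances = sort(edges))
}

# canonical form of the package's components for one clone/chromosome
pkg_cluster_form <- function(pos, threshold = 1000) {
  cl <- find_clusters(
    tibble::tibble(clone_id = "c", chrom = "chr", pos = pos),
    threshold = threshold)
  comps <- unname(lapply(cl$components$positions, sort))
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  d <- intermutation_distances(cl)$distance
  list(components = comps, edge_distances = sort(d))
}

# Exhaustive permutation oracle for a two-group comparison: enumerates all
# subsets of the values taken by group A (global label shuffles weight all
# subsets of a given size equally).
exhaustive_perm_oracle <- function(values, n_a) {
  n <- length(values)
  subsets <- utils::combn(n, n_a)
  apply(subsets, 2, function(idx) {
    mean(values[idx]) - mean(values[-idx])
  })
}

# Closed-form BH step-up, written independently of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
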