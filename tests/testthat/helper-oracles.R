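# Independent brute-force oracles. These deliberately avoid the package's
# computation paths: PD by explicit root-path edge unions, MPD/MNTD by
# explicit double loops.

tree4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# map each node to its parent edge (row of tree$edge), then take the union of
# edges on all root-to-tip paths for the sampled tips
oracle_pd <- function(tree, tips, include_root = TRUE) {
  idx <- match(tips, tree$tip.label)
  stopifnot(!anyNA(idx))
  parent_edge <- integer(length(tree$tip.label) + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  paths <- lapply(idx, function(i) {
    es <- integer(0)
    node <- i
    while (parent_edge[node] != 0L) {
      e <- parent_edge[node]
      es <- c(es, e)
      node <- tree$edge[e, 1]
    }
    es
  })
  edges <- unique(unlist(paths))
  if (!include_root) {
    shared <- Reduce(intersect, paths)  # edges above the sample's MRCA
    edges <- setdiff(edges, shared)
  }
  sum(tree$edge.length[edges])
}

oracle_mpd_within <- function(d, s) {
  tot <- 0; np <- 0
  for (i in seq_along(s)) for (j in seq_along(s)) {
    if (i < j) { tot <- tot + d[s[i], s[j]]; np <- np + 1 }
  }
  tot / np
}

oracle_mntd_within <- function(d, s) {
  mins <- numeric(length(s))
  for (i in seq_along(s)) {
    best <- Inf
    for (j in seq_along(s)) if (i != j) best <- min(best, d[s[i], s[j]])
    mins[i] <- best
  }
  mean(mins)
}

oracle_mpd_between <- function(d, a, b) {
  tot <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) tot <- tot + d[a[i], b[j]]
  tot / (length(a) * length(b))
}

oracle_mntd_between <- function(d, a, b) {
  vals <- numeric(0)
  for (i in seq_along(a)) {
    best <- Inf
    for (j in seq_along(b)) best <- min(best, d[a[i], b[j]])
    vals <- c(vals, best)
  }
  for (j in seq_along(b)) {
    best <- Inf
    for (i in seq_along(a)) best <- min(best, d[b[j], a[i]])
    vals <- c(vals, best)
  }
  mean(vals)
}

# random non-ultrametric tree with unique labels (uniform branch lengths)
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

write_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
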