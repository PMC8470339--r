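#' Faith's phylogenetic diversity of an assemblage
#'
#' Sum of branch lengths of the minimal subtree spanning the sampled tips.
#' With `include_root = TRUE` (the default, the common convention in
#' community-phylogenetics software) the path connecting that subtree to the
#' root is counted too, so a single-species assemblage has PD equal to its
#' root-to-tip distance rather than zero; set `include_root = FALSE` for the
#' rootless variant.
#'
#' @param tree A `"phylo"` object.
#' @param sample Character vector of tip labels (non-empty, all on the tree).
#' @param include_root Include the root-connecting path? Default `TRUE`.
#' @return Branch-length sum (numeric scalar).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' faith_pd(tr, c("A", "B"))                       # 3
#' faith_pd(tr, c("A", "B", "C", "D"))             # 6, the whole tree
#' faith_pd(tr, "A", include_root = FALSE)         # 0
#' @export
faith_pd <- function(tree, sample, include_root = TRUE) {
  cache <- pd_cache(tree)
  idx <- match_sample(sample, cache$tips)
  pd_from_cache(cache, idx, include_root)
}

# Per-tree edge structure for fast PD: for each edge, which tips descend
# from it. `inc` is a tips x edges 0/1 matrix (dense double so that null-model
# replicates can be batched through BLAS).
pd_cache <- function(tree) {
  validate_phylo(tree)
  n_tip <- length(tree$tip.label)
  tr <- if (n_tip >= 2L) stats::reorder(tree, "postorder") else tree
  n_edge <- nrow(tr$edge)
  n_node <- n_tip + tr$Nnode
  # postorder: children visited before parents, so descendant sets accumulate
  desc <- matrix(FALSE, n_node, n_tip)
  desc[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (e in seq_len(n_edge)) {
    p <- tr$edge[e, 1L]; k <- tr$edge[e, 2L]
    desc[p, ] <- desc[p, ] | desc[k, ]
  }
  inc <- t(desc[tr$edge[, 2L], , drop = FALSE]) + 0  # tips x edges
  list(tips = tree$tip.label, inc = inc, edge_length = tr$edge.length)
}

pd_from_cache <- function(cache, idx, include_root) {
  k <- length(idx)
  cs <- colSums(cache$inc[idx, , drop = FALSE])
  keep <- if (include_root) cs > 0 else (cs > 0 & cs < k)
  sum(cache$edge_length[keep])
}

#' Mean pairwise phylogenetic distance within an assemblage
#'
#' Mean of the patristic distance d(i, j) over all unordered pairs of distinct
#' taxa in the sample.
#'
#' @param dist A patristic distance matrix (see [cophenetic_matrix()]).
#' @param sample Character vector of at least 2 taxon labels.
#' @return Numeric scalar.
#' @export
mpd_within <- function(dist, sample) {
  idx <- match_sample(sample, rownames(dist))
  k <- length(idx)
  if (k < 2L) stop("MPD is undefined for fewer than 2 taxa", call. = FALSE)
  sub <- dist[idx, idx, drop = FALSE]
  sum(sub) / (k * (k - 1))
}

#' Mean nearest-taxon distance within an assemblage
#'
#' For each taxon, the patristic distance to its closest relative in the same
#' assemblage; the statistic is the mean of these minima. Always less than or
#' equal to [mpd_within()] on the same sample.
#'
#' @inheritParams mpd_within
#' @return Numeric scalar.
#' @export
mntd_within <- function(dist, sample) {
  idx <- match_sample(sample, rownames(dist))
  if (length(idx) < 2L) stop("MNTD is undefined for fewer than 2 taxa", call. = FALSE)
  sub <- dist[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  mean(row_mins(sub))
}

#' Between-community mean pairwise distance (comdist-style)
#'
#' Mean of d(i, j) over all ordered pairs with i in `a` and j in `b`. Species
#' shared between the two communities contribute zero-distance pairs; set
#' `exclude_shared = TRUE` to drop shared species from both sides first.
#'
#' @param dist A patristic distance matrix.
#' @param a,b Character vectors of taxon labels (non-empty).
#' @param exclude_shared Drop the intersection of `a` and `b` before
#'   averaging? Default `FALSE`.
#' @return Numeric scalar; symmetric in `a` and `b`.
#' @export
mpd_between <- function(dist, a, b, exclude_shared = FALSE) {
  ab <- resolve_pair(dist, a, b, exclude_shared)
  mean(dist[ab$a, ab$b, drop = FALSE])
}

#' Between-community mean nearest-taxon distance (comdistnt-style)
#'
#' For each taxon of `a` the distance to its nearest taxon in `b`, and for
#' each taxon of `b` the distance to its nearest taxon in `a`; the statistic
#' is the mean of all `|a| + |b|` values, each taxon weighted equally. Two
#' identical communities have distance 0.
#'
#' @inheritParams mpd_between
#' @return Numeric scalar; symmetric in `a` and `b`.
#' @export
mntd_between <- function(dist, a, b, exclude_shared = FALSE) {
  ab <- resolve_pair(dist, a, b, exclude_shared)
  cross <- dist[ab$a, ab$b, drop = FALSE]
  mean(c(row_mins(cross), row_mins(t(cross))))
}

resolve_pair <- function(dist, a, b, exclude_shared) {
  ia <- match_sample(a, rownames(dist), "a")
  ib <- match_sample(b, rownames(dist), "b")
  if (exclude_shared) {
    shared <- intersect(ia, ib)
    ia <- setdiff(ia, shared)
    ib <- setdiff(ib, shared)
    if (!length(ia) || !length(ib)) {
      stop("a community is empty after excluding shared species", call. = FALSE)
    }
  }
  list(a = ia, b = ib)
}

match_sample <- function(sample, labels, what = "sample") {
  sample <- as.character(sample)
  if (!length(sample)) stop("'", what, "' must be non-empty", call. = FALSE)
  if (anyDuplicated(sample)) sample <- unique(sample)
  idx <- match(sample, labels)
  if (anyNA(idx)) {
    stop("taxa not found: ", paste(sample[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

# row minima of a numeric matrix without apply(); ties need no breaking
# because only the minimum value is used
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}
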