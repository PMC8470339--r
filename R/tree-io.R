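#' Parse a Newick string into a validated phylogeny
#'
#' Reads a single rooted tree in Newick format and validates it for use in
#' downstream phylogenetic-diversity calculations. Branch lengths may be in
#' decimal or scientific notation; internal node labels are allowed (they are
#' ignored by all distance computations); zero-length branches and polytomies
#' are permitted, as both occur routinely in published mega-trees.
#'
#' Square-bracket comments (including NHX annotations) are not supported and
#' are rejected with an explicit error rather than silently stripped.
#'
#' @param text A length-1 character string containing one Newick tree,
#'   terminated by a semicolon.
#' @return An object of class `"phylo"` (as used by the \pkg{ape} package)
#'   satisfying the package's tree invariants: a single root, unique non-empty
#'   tip labels, and finite non-negative branch lengths on every edge.
#' @seealso [read_newick()], [write_newick()], [prune_tree()],
#'   [cophenetic_matrix()]
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' sum(tr$edge.length)  # total branch length = 6
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("[", text, fixed = TRUE) || grepl("]", text, fixed = TRUE)) {
    stop("Newick comments in square brackets (e.g. NHX annotations) are not supported; ",
         "offending text: ", substr(text, regexpr("[", text, fixed = TRUE),
                                    min(nchar(text), regexpr("[", text, fixed = TRUE) + 20L)),
         call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick string must be terminated by a semicolon", call. = FALSE)
  }
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tr)) stop("malformed Newick: parser returned no tree", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    stop("exactly one tree per Newick string/file is required; found ",
         length(tr), call. = FALSE)
  }
  validate_phylo(tr)
  tr
}

#' Read a single Newick tree from a file
#'
#' @param path Path to a Newick file (`.nwk`/`.tre`) containing exactly one
#'   tree with a trailing semicolon.
#' @return A validated `"phylo"` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parse_newick(txt)
}

#' Write a phylogeny to Newick
#'
#' @param tree A `"phylo"` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @param digits Number of significant digits used for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  validate_phylo(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Validate the package's phylogeny invariants
#'
#' Checks that `tree` is a rooted `"phylo"` object with unique, non-empty tip
#' labels and finite, non-negative branch lengths on every edge. Called by all
#' entry points that accept a tree; exported so users can validate trees built
#' elsewhere.
#'
#' @param tree A `"phylo"` object.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object", call. = FALSE)
  tips <- tree$tip.label
  if (length(tips) < 1L) stop("tree has no tips", call. = FALSE)
  if (any(!nzchar(tips)) || anyNA(tips)) {
    stop("empty or missing tip labels", call. = FALSE)
  }
  dup <- unique(tips[duplicated(tips)])
  if (length(dup)) {
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  el <- tree$edge.length
  if (is.null(el)) stop("tree has no branch lengths", call. = FALSE)
  if (length(el) != nrow(tree$edge)) {
    stop("branch length missing on ", nrow(tree$edge) - length(el),
         " edge(s)", call. = FALSE)
  }
  if (anyNA(el) || any(!is.finite(el))) {
    stop("missing or non-finite branch length(s)", call. = FALSE)
  }
  if (any(el < 0)) {
    bad <- which(el < 0)[1L]
    stop("negative branch length ", format(el[bad]), " on edge ", bad, call. = FALSE)
  }
  # single root: exactly one node that never appears as a child
  if (length(tips) >= 2L) {
    kids <- tree$edge[, 2L]
    parents <- tree$edge[, 1L]
    roots <- setdiff(unique(parents), kids)
    if (length(roots) != 1L) {
      stop("tree must have exactly one root; found ", length(roots), call. = FALSE)
    }
    if (anyDuplicated(kids)) {
      stop("a node has more than one parent", call. = FALSE)
    }
  }
  invisible(tree)
}

#' Patristic (cophenetic) distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the path between tips i and j,
#' in the tree's branch-length units. Rows and columns follow the order of
#' `tree$tip.label`.
#'
#' @param tree A `"phylo"` object with at least 2 tips.
#' @return A symmetric numeric matrix with zero diagonal and tip labels as
#'   dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  validate_phylo(tree)
  if (length(tree$tip.label) < 2L) {
    stop("cophenetic distances require at least 2 tips", call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Prune a phylogeny to a set of tips
#'
#' Retains only the tips in `keep`; unbranched internal nodes created by the
#' pruning are collapsed, with their branch lengths summed, so that patristic
#' distances among the kept tips are unchanged. Mirrors the mega-tree pruning
#' step used when matching a species list against a reference phylogeny.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least one; all
#'   must be present on the tree).
#' @return The pruned `"phylo"` object. When a single tip is kept, the result
#'   is a one-tip tree whose sole edge length is the original root-to-tip
#'   distance.
#' @export
prune_tree <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  if (length(keep) < 1L) stop("'keep' must contain at least one tip", call. = FALSE)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("tip label(s) not on tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(keep) == 1L) {
    depth <- node_depths(tree)[match(keep, tree$tip.label)]
    out <- structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L), edge.length = depth,
           tip.label = keep, Nnode = 1L),
      class = "phylo", order = "cladewise")
    return(out)
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# root-to-tip path lengths, one per tip, in tip.label order
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  depth <- numeric(n_node)
  tr <- if (n_tip >= 2L) stats::reorder(tree, "cladewise") else tree
  # cladewise order guarantees parents are visited before children
  for (e in seq_len(nrow(tr$edge))) {
    depth[tr$edge[e, 2L]] <- depth[tr$edge[e, 1L]] + tr$edge.length[e]
  }
  depth[seq_len(n_tip)]
}

#' Total branch length of a tree
#'
#' @param tree A `"phylo"` object.
#' @return Sum of all edge lengths.
#' @export
total_branch_length <- function(tree) {
  validate_phylo(tree)
  sum(tree$edge.length)
}
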