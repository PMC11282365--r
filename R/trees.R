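#' Parse a newick string into a rooted tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Chronogram databases
#' store binomial species names, so by default underscores in unquoted labels
#' are decoded to spaces (`"Emberiza_citrinella"` becomes
#' `"Emberiza citrinella"`); set `underscores_to_spaces = FALSE` to keep them.
#'
#' @param text A single newick string, `;`-terminated. Branch lengths and
#'   quoted labels are optional.
#' @param underscores_to_spaces Decode `_` to space in labels (default `TRUE`).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text, underscores_to_spaces = TRUE) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    stop("newick parse error: input must be a single non-empty string")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf(
      "newick parse error: unbalanced parentheses (%d '(' vs %d ')')",
      n_open, n_close
    ))
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("newick parse error: ", conditionMessage(w))
  )
  if (is.null(phy)) stop("newick parse error: could not read a tree from input")
  if (underscores_to_spaces) {
    phy$tip.label <- gsub("_", " ", phy$tip.label, fixed = TRUE)
    if (!is.null(phy$node.label)) {
      phy$node.label <- gsub("_", " ", phy$node.label, fixed = TRUE)
    }
  }
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup)) {
    stop("newick parse error: duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(phy$tip.label))) stop("newick parse error: empty tip label")
  phy
}

#' Serialize a tree to newick
#'
#' @param tree A `phylo` object.
#' @param include_lengths Emit `:length` fields when present (default `TRUE`).
#' @param canonical Reorder children so that each node's first child leads to
#'   the alphabetically smallest descendant tip label, giving a bit-stable
#'   output for topologically identical trees. Default `FALSE`.
#' @return A newick string (spaces in labels written as underscores).
#' @export
write_newick <- function(tree, include_lengths = TRUE, canonical = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (canonical) tree <- canonical_order(tree)
  if (!include_lengths) tree$edge.length <- NULL
  ape::write.tree(tree)
}

# rotate children so each node's children sort by smallest descendant label
canonical_order <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  # smallest descendant label per node, computed tip-up
  min_lab <- character(ntip + tree$Nnode)
  min_lab[seq_len(ntip)] <- tree$tip.label
  po <- rev(unique(tree$edge[, 1])) # parents in postorder-ish (cladewise reversed)
  for (nd in po) {
    ch <- tree$edge[kids[[as.character(nd)]], 2]
    min_lab[nd] <- min(min_lab[ch])
  }
  new_edge_rows <- integer(0)
  visit <- function(nd) {
    rows <- kids[[as.character(nd)]]
    if (is.null(rows)) return(invisible())
    ch <- tree$edge[rows, 2]
    ord <- order(min_lab[ch])
    for (i in ord) {
      new_edge_rows <<- c(new_edge_rows, rows[i])
      if (tree$edge[rows[i], 2] > ntip) visit(tree$edge[rows[i], 2])
    }
  }
  visit(ntip + 1L)
  tree$edge <- tree$edge[new_edge_rows, , drop = FALSE]
  if (!is.null(tree$edge.length)) tree$edge.length <- tree$edge.length[new_edge_rows]
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels (length >= 1). A single tip is
#'   its own MRCA.
#' @return The node index (tip index for a single tip).
#' @export
tree_mrca <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) >= 1)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", "))
  }
  if (length(unique(idx)) == 1) return(idx[1])
  ape::getMRCA(tree, unique(idx))
}

#' Prune a tree to a set of tips
#'
#' Produces the induced subtree: unbranched internal nodes are suppressed and
#' their branch lengths summed, so patristic distances (and hence MRCA ages in
#' a chronogram) between retained tips are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain; at least two must be
#'   present in the tree.
#' @return The pruned `phylo`.
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- intersect(keep, tree$tip.label)
  if (length(keep) < 2) {
    stop("pruning requires at least 2 retained tips, got ", length(keep))
  }
  ape::keep.tip(tree, keep)
}

#' Node ages of a chronogram
#'
#' Ages in Myr before present: tips at 0, each internal node at the sum of
#' branch lengths down to any descendant tip.
#'
#' @param tree An ultrametric `phylo` with branch lengths.
#' @return Numeric vector indexed by node number (tips then internal nodes).
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  # tips of an ultrametric tree sit at the present
  ages[seq_len(ape::Ntip(tree))] <- 0
  ages
}

#' Test ultrametricity within a relative tolerance
#'
#' All root-to-tip path sums must agree to relative tolerance `tol`
#' (default 1e-6), absorbing the rounding noise published newick files carry.
#'
#' @param tree A `phylo` with branch lengths.
#' @param tol Relative tolerance on root-to-tip sums.
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) return(FALSE)
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(depth)
  if (h == 0) return(TRUE)
  (max(depth) - min(depth)) / h <= tol
}

#' Validate a tree as a chronogram
#'
#' A chronogram is a rooted tree with all branch lengths present (Myr) that is
#' ultrametric within tolerance. Trees failing the check are rejected with an
#' informative error rather than rescaled.
#'
#' @inheritParams is_ultrametric_tree
#' @return The tree, invisibly classed as before (a valid `phylo`).
#' @export
as_chronogram <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("not a chronogram: branch lengths missing")
  }
  if (any(tree$edge.length < 0)) stop("not a chronogram: negative branch length")
  if (!is_ultrametric_tree(tree, tol)) {
    stop("not a chronogram: tree is not ultrametric within relative tolerance ", tol)
  }
  tree
}

#' Patristic distance matrix of a chronogram
#'
#' Total tip-to-tip path distance in Myr. For an ultrametric tree the entry
#' for tips `a`, `b` equals twice the age of their MRCA, so node ages are half
#' the stored values.
#'
#' @param chronogram An ultrametric `phylo` with branch lengths.
#' @param tol Ultrametricity tolerance (see [as_chronogram()]).
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(chronogram, tol = 1e-6) {
  chronogram <- as_chronogram(chronogram, tol)
  m <- stats::cophenetic(chronogram)
  # stable order: as in the tree
  m[chronogram$tip.label, chronogram$tip.label]
}
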