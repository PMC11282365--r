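#' Detect groves among tree tip sets
#'
#' Two trees overlap at level `n` when they share at least `n` taxa. Groves
#' are the connected components of the pairwise n-overlap graph: sets of
#' trees sufficiently interlinked to be combinable into one supertree.
#'
#' @param tip_sets Named list of character vectors (tip labels per tree).
#' @param n Minimum pairwise taxon overlap for an edge (default 2).
#' @return A list of groves, each a list with `members` (names/indices),
#'   `n_trees`, and `n_taxa` (distinct taxa across members). Ordered by
#'   smallest member.
#' @export
find_groves <- function(tip_sets, n = 2) {
  stopifnot(n >= 1, length(tip_sets) >= 1)
  if (is.null(names(tip_sets))) names(tip_sets) <- as.character(seq_along(tip_sets))
  k <- length(tip_sets)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (k > 1) {
    pairs <- utils::combn(k, 2)
    keep <- apply(pairs, 2, function(p) {
      length(intersect(tip_sets[[p[1]]], tip_sets[[p[2]]])) >= n
    })
    if (any(keep)) g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
  }
  comp <- igraph::components(g)$membership
  lapply(sort(unique(comp)), function(cc) {
    members <- names(tip_sets)[comp == cc]
    list(members = members,
         n_trees = length(members),
         n_taxa = length(unique(unlist(tip_sets[members]))))
  })
}

#' Pick a grove
#'
#' By default the grove with the most distinct taxa wins; with
#' `criterion = "trees"` the grove with the most member trees wins. Ties go
#' to the larger value of the other criterion, then the smallest member id.
#'
#' @param groves A list of groves from [find_groves()].
#' @param criterion `"taxa"` (default) or `"trees"`.
#' @return A single grove.
#' @export
pick_grove <- function(groves, criterion = c("taxa", "trees")) {
  criterion <- match.arg(criterion)
  if (!length(groves)) stop("pick_grove: empty grove list")
  key1 <- vapply(groves, `[[`, 0, if (criterion == "taxa") "n_taxa" else "n_trees")
  key2 <- vapply(groves, `[[`, 0, if (criterion == "taxa") "n_trees" else "n_taxa")
  key3 <- vapply(groves, function(g) sort(g$members)[1], "")
  groves[[order(-key1, -key2, key3)[1]]]
}

# average-linkage agglomerative clustering on a (possibly incomplete)
# distance matrix, pairwise-available averaging; returns a rooted phylo
agglomerate_topology <- function(d) {
  labs <- rownames(d)
  k <- length(labs)
  if (k < 2) stop("agglomerate_topology: need >= 2 tips")
  # cluster members by current cluster index
  members <- as.list(seq_len(k))
  active <- seq_len(k)
  subtrees <- paste0(gsub(" ", "_", labs)) # build newick bottom-up
  while (length(active) > 1) {
    # average distance between clusters over available cells
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        a <- members[[active[ii]]]
        b <- members[[active[jj]]]
        cells <- d[a, b, drop = FALSE]
        if (all(is.na(cells))) next
        avg <- mean(cells, na.rm = TRUE)
        if (avg < best_d) {
          best_d <- avg
          best <- c(ii, jj)
        }
      }
    }
    if (is.null(best)) {
      stop("agglomerate_topology: disconnected distance matrix (no shared cells)")
    }
    i <- active[best[1]]
    j <- active[best[2]]
    members[[i]] <- c(members[[i]], members[[j]])
    subtrees[i] <- paste0("(", subtrees[i], ",", subtrees[j], ")")
    active <- setdiff(active, j)
  }
  parse_newick(paste0(subtrees[active], ";"))
}

#' Summary supertree topology from a grove of chronogram records
#'
#' Checks that the records form a single grove under 2-overlap, summarizes
#' their patristic matrices with [sdm_summary()], and clusters the summary
#' matrix with average-linkage agglomeration (pairwise-available averaging
#' over missing cells). Branch lengths are discarded: the result is a
#' topology.
#'
#' @param records A list of chronogram records (each with `tree`), e.g.
#'   `db$records`, or a `chronogram_db`.
#' @return A `phylo` topology.
#' @export
build_supertree <- function(records) {
  if (inherits(records, "chronogram_db")) records <- records$records
  stopifnot(length(records) >= 1)
  if (length(records) == 1) {
    topo <- records[[1]]$tree
    topo$edge.length <- NULL
    return(topo)
  }
  matrices <- lapply(records, function(r) patristic_matrix(r$tree))
  names(matrices) <- vapply(records, function(r) as.character(r$id), "")
  groves <- find_groves(lapply(matrices, rownames), n = 2)
  if (length(groves) > 1) {
    stop("build_supertree: source chronograms do not form a grove; ",
         "the supertree reconstruction will fail (see find_groves())")
  }
  m <- sdm_summary(matrices)
  agglomerate_topology(m)
}
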