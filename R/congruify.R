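# descendant tip labels per node, indexed by node number (tips included)
descendant_tips <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  out <- vector("list", ntip + tree$Nnode)
  out[seq_len(ntip)] <- as.list(tree$tip.label)
  for (i in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[i, 1]
    ch <- tree$edge[i, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Stable node names for a topology
#'
#' Internal nodes are named `n1`, `n2`, ... with `n1` the root, then preorder
#' following the tree's own child ordering, so the deepest node is `n1` and
#' names are stable for a given input tree.
#'
#' @param tree A `phylo`.
#' @return Tibble with `node` (node number) and `node_name`.
#' @export
node_names <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  internal <- unique(tree$edge[, 1]) # preorder of internal nodes
  tibble::tibble(node = internal,
                 node_name = paste0("n", seq_along(internal)))
}

#' Congruify one source matrix onto a target topology
#'
#' Maps node ages from a source patristic matrix onto congruent nodes of the
#' target. A target internal node `v` receives a calibration when (i) `v` is
#' the target MRCA of the shared tips below it, and (ii) the source MRCA of
#' those shared tips has no other shared descendants — the clades agree on the
#' shared taxa. The calibration age is half the patristic entry of a witness
#' pair spanning the source MRCA (the lexicographically smallest such pair).
#' Incongruent nodes simply yield no row.
#'
#' @param target A `phylo` topology (branch lengths not required).
#' @param source A patristic matrix (see [patristic_matrix()]).
#' @param tol Relative tolerance when comparing source distances.
#' @return Tibble with columns `node`, `node_name`, `taxon_a`, `taxon_b`,
#'   `age`.
#' @export
congruify_one <- function(target, source, tol = 1e-6) {
  stopifnot(inherits(target, "phylo"), is.matrix(source))
  target <- ape::reorder.phylo(target, "cladewise")
  shared <- intersect(target$tip.label, rownames(source))
  nn <- node_names(target)
  empty <- tibble::tibble(node = integer(), node_name = character(),
                          taxon_a = character(), taxon_b = character(),
                          age = numeric())
  if (length(shared) < 2) return(empty)
  desc <- descendant_tips(target)
  rows <- purrr::map_dfr(seq_len(nrow(nn)), function(i) {
    v <- nn$node[i]
    S <- intersect(shared, desc[[v]])
    if (length(S) < 2) return(empty)
    # v must itself be the target MRCA of its shared tips
    if (tree_mrca(target, S) != v) return(empty)
    sub <- source[S, S, drop = FALSE]
    mx <- max(sub)
    age <- mx / 2
    # congruence: no other shared tip descends from the source MRCA
    others <- setdiff(shared, S)
    if (length(others)) {
      mins <- apply(source[others, S, drop = FALSE], 1, min)
      if (any(mins <= mx * (1 + tol))) return(empty)
    }
    # witness pair: lexicographically smallest pair spanning the source MRCA
    idx <- which(sub >= mx * (1 - tol) & upper.tri(sub), arr.ind = TRUE)
    pairs <- cbind(rownames(sub)[idx[, 1]], colnames(sub)[idx[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    tibble::tibble(node = v, node_name = nn$node_name[i],
                   taxon_a = pairs[1, 1], taxon_b = pairs[1, 2], age = age)
  })
  rows
}

#' Build a calibration table from a search result
#'
#' Concatenates [congruify_one()] over every record of a search result,
#' attaching record ids and citations. Row order is by node name then age.
#'
#' @param target A `phylo` topology.
#' @param result A `chrono_search` (see [search_chronograms()]).
#' @return A `calibration_table`: tibble with columns `node_name`, `taxon_a`,
#'   `taxon_b`, `age`, `record_id`, `citation`, carrying the target topology
#'   as attribute `target`. Empty (with a message attribute) when no record
#'   overlaps the target on two or more tips.
#' @export
build_calibration_table <- function(target, result, tol = 1e-6) {
  stopifnot(inherits(target, "phylo"), inherits(result, "chrono_search"))
  rows <- purrr::map_dfr(names(result$matrices), function(id) {
    one <- congruify_one(target, result$matrices[[id]], tol = tol)
    if (!nrow(one)) return(one)
    one$record_id <- id
    one$citation <- result$records$citation[match(id, result$records$id)]
    one
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(node_name = character(), taxon_a = character(),
                           taxon_b = character(), age = numeric(),
                           record_id = character(), citation = character())
    out <- structure(rows, class = c("calibration_table", class(rows)),
                     target = target,
                     message = "no source chronogram is congruent with the target on 2+ shared taxa")
    return(out)
  }
  rows <- dplyr::arrange(
    dplyr::distinct(rows, .data$node_name, .data$age, .data$record_id,
                    .data$taxon_a, .data$taxon_b, .keep_all = TRUE),
    as.integer(sub("^n", "", .data$node_name)), .data$age
  )
  rows <- rows[, c("node_name", "taxon_a", "taxon_b", "age", "record_id",
                   "citation", "node")]
  structure(rows, class = c("calibration_table", class(rows)),
            target = target, message = NULL)
}

#' @export
print.calibration_table <- function(x, ...) {
  msg <- attr(x, "message")
  if (!is.null(msg)) cat("<calibration_table>", msg, "\n")
  else cat("<calibration_table>", nrow(x), "calibration point(s) on",
           length(unique(x$node_name)), "node(s)\n")
  NextMethod()
}

#' Write / read a calibration table as CSV
#'
#' Columns follow the conventional calibration-table layout: node name, the
#' two witness taxa, the node age in Myr, and the study reference.
#'
#' @param table A `calibration_table`.
#' @param path CSV file path.
#' @export
write_calibration_csv <- function(table, path) {
  out <- data.frame(
    node_name = table$node_name, taxon_a = table$taxon_a,
    taxon_b = table$taxon_b, node_age = table$age,
    study_reference = table$citation
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  names(tab) <- c("node_name", "taxon_a", "taxon_b", "age", "citation")
  tab
}
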