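#' Filter node-age summaries into a consistent calibration set
#'
#' Secondary calibrations must decrease strictly from root to tips. The
#' filter traverses root-down, discarding a node's age when it is at least as
#' old as its nearest retained ancestor's age, then tip-up, discarding ages
#' no older than any retained descendant's. Provenance (used /
#' discarded:older-than-ancestor / discarded:younger-than-descendant) is
#' recorded per node.
#'
#' @param summaries A `node_age_summary` (see [summarize_node_ages()]).
#' @param target The `phylo` topology the node names refer to (defaults to
#'   the summary's stored target).
#' @param stat Which summary age to calibrate with: `"median"` (default) or
#'   `"mean"`.
#' @return A `calibration_set` tibble: `node_name`, `node`, `age`, `status`;
#'   attributes `target`, `stat`.
#' @export
filter_calibrations <- function(summaries, target = attr(summaries, "target"),
                                stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(inherits(target, "phylo"))
  target <- ape::reorder.phylo(target, "cladewise")
  nn <- node_names(target)
  age_of <- stats::setNames(summaries[[stat]], summaries$node_name)
  unknown <- setdiff(names(age_of), nn$node_name)
  if (length(unknown)) {
    stop("filter_calibrations: node name(s) not on target: ",
         paste(unknown, collapse = ", "))
  }
  node_id <- stats::setNames(nn$node, nn$node_name)
  parent <- integer(max(target$edge))
  parent[target$edge[, 2]] <- target$edge[, 1]
  root <- ape::Ntip(target) + 1L
  status <- stats::setNames(rep("used", length(age_of)), names(age_of))
  by_node <- stats::setNames(age_of, node_id[names(age_of)])

  retained_age <- function(nd) {
    # age of nearest retained calibrated ancestor, NA above the root
    while (nd != root) {
      nd <- parent[nd]
      key <- as.character(nd)
      if (!is.null(by_node[key]) && !is.na(by_node[key]) &&
          status[names(age_of)[match(key, as.character(node_id[names(age_of)]))]] == "used") {
        return(by_node[[key]])
      }
    }
    NA_real_
  }

  # root-down pass: preorder over calibrated nodes
  pre <- nn$node_name[nn$node_name %in% names(age_of)]
  for (nm in pre) {
    anc_age <- retained_age(node_id[[nm]])
    if (!is.na(anc_age) && age_of[[nm]] >= anc_age) {
      status[nm] <- "discarded:older-than-ancestor"
    }
  }
  # tip-up pass: discard ages not older than any retained descendant age
  desc <- descendant_tips(target)
  post <- rev(pre)
  for (nm in post) {
    if (status[nm] != "used") next
    below <- desc[[node_id[[nm]]]]
    for (other in pre) {
      if (other == nm || status[other] != "used") next
      if (all(desc[[node_id[[other]]]] %in% below) &&
          length(desc[[node_id[[other]]]]) < length(below) &&
          age_of[[nm]] <= age_of[[other]]) {
        status[nm] <- "discarded:younger-than-descendant"
        break
      }
    }
  }
  if (!any(status == "used")) {
    stop("filter_calibrations: all candidate calibrations discarded")
  }
  out <- tibble::tibble(
    node_name = names(age_of),
    node = unname(node_id[names(age_of)]),
    age = unname(age_of),
    status = unname(status[names(age_of)])
  )
  structure(out, class = c("calibration_set", class(out)),
            target = target, stat = stat)
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("<calibration_set>", sum(x$status == "used"), "of", nrow(x),
      "summary age(s) retained as calibrations (", attr(x, "stat"), ")\n")
  NextMethod()
}

#' Resolve the root age for dating
#'
#' The even-spacing dater needs a fixed root age. A user-provided value wins;
#' otherwise the root's own retained summary age is used; otherwise the
#' default is 1.1 x the oldest retained calibration, with a conspicuous
#' warning. Set `randomize = TRUE` (with a seed) to instead draw the fallback
#' uniformly between the oldest calibration and 1.5 x it.
#'
#' @param set A `calibration_set`.
#' @param user_root Optional root age in Myr.
#' @param randomize Draw the fallback root age at random (default `FALSE`).
#' @param seed Optional integer seed for the randomized fallback.
#' @return Root age in Myr.
#' @export
resolve_root_age <- function(set, user_root = NULL, randomize = FALSE,
                             seed = NULL) {
  if (!is.null(user_root)) {
    stopifnot(is.numeric(user_root), user_root > 0)
    return(user_root)
  }
  used <- set[set$status == "used", ]
  if (!nrow(used)) stop("resolve_root_age: no calibrations and no user root age")
  target <- attr(set, "target")
  root <- ape::Ntip(target) + 1L
  if (root %in% used$node) return(used$age[match(root, used$node)])
  oldest <- max(used$age)
  if (randomize) {
    if (!is.null(seed)) set.seed(seed)
    root_age <- stats::runif(1, oldest, 1.5 * oldest)
  } else {
    root_age <- 1.1 * oldest
  }
  warning(
    "No age information for the root: root age set to ",
    signif(root_age, 6), " Myr (",
    if (randomize) "drawn at random above" else "1.1 x",
    " the oldest retained calibration, ", signif(oldest, 6),
    " Myr). Provide a root age from the literature for a defensible chronogram.",
    call. = FALSE
  )
  root_age
}

#' Date a topology by even spacing between calibrated nodes (BLADJ)
#'
#' Fixes calibrated node ages on the topology and assigns every uncalibrated
#' internal node an age by distributing time evenly along the path between
#' its nearest fixed ancestor and a fixed descendant (tips count as fixed at
#' age 0), minimizing age variance. The fixed descendant is the one reachable
#' through the fewest unfixed nodes; ties go to the oldest such descendant,
#' then the smallest label. The result is exactly ultrametric with parent
#' ages strictly above child ages.
#'
#' @param target A `phylo` topology.
#' @param set A `calibration_set` with retained ages (see
#'   [filter_calibrations()]).
#' @param root_age Root age in Myr (see [resolve_root_age()]); defaults to
#'   the set's own root calibration when present.
#' @return An ultrametric `phylo` chronogram with attribute `ages` (per-node
#'   ages, Myr).
#' @export
bladj <- function(target, set, root_age = NULL) {
  stopifnot(inherits(target, "phylo"))
  target <- ape::reorder.phylo(target, "cladewise")
  ntip <- ape::Ntip(target)
  nnode <- target$Nnode
  root <- ntip + 1L
  used <- set[set$status == "used", ]
  fixed_age <- rep(NA_real_, ntip + nnode)
  fixed_age[seq_len(ntip)] <- 0
  fixed_age[used$node] <- used$age
  if (is.null(root_age)) root_age <- resolve_root_age(set)
  fixed_age[root] <- root_age
  # sanity: fixed ages must decrease root-to-tip
  parent <- integer(ntip + nnode)
  parent[target$edge[, 2]] <- target$edge[, 1]
  for (nd in which(!is.na(fixed_age))) {
    if (nd == root) next
    anc <- parent[nd]
    while (is.na(fixed_age[anc]) && anc != root) anc <- parent[anc]
    if (!is.na(fixed_age[anc]) && fixed_age[anc] <= fixed_age[nd] && nd > ntip) {
      stop("bladj: inconsistent fixed ages (node ", nd, " vs ancestor ", anc, ")")
    }
  }
  kids <- split(target$edge[, 2], target$edge[, 1])
  min_lab <- character(ntip + nnode)
  min_lab[seq_len(ntip)] <- target$tip.label
  for (nd in rev(unique(target$edge[, 1]))) {
    min_lab[nd] <- min(min_lab[kids[[as.character(nd)]]])
  }
  # nearest fixed descendant of each node through unfixed nodes only:
  # (steps to it, its age, its smallest label), computed tip-up
  ndesc_steps <- rep(NA_real_, ntip + nnode)
  ndesc_age <- rep(NA_real_, ntip + nnode)
  ndesc_lab <- character(ntip + nnode)
  order_nodes <- c(seq_len(ntip), rev(unique(target$edge[, 1])))
  for (nd in order_nodes) {
    if (!is.na(fixed_age[nd])) {
      ndesc_steps[nd] <- 0
      ndesc_age[nd] <- fixed_age[nd]
      ndesc_lab[nd] <- min_lab[nd]
      next
    }
    ch <- kids[[as.character(nd)]]
    # stepping into a fixed child crosses no unfixed node; into an unfixed one,
    # the child itself plus whatever lies below it
    cand_steps <- ifelse(is.na(fixed_age[ch]), ndesc_steps[ch] + 1, 0)
    best <- which(cand_steps == min(cand_steps))
    if (length(best) > 1) {
      ages <- ifelse(is.na(fixed_age[ch[best]]), ndesc_age[ch[best]],
                     fixed_age[ch[best]])
      best <- best[ages == max(ages)]
      if (length(best) > 1) {
        labs <- ifelse(is.na(fixed_age[ch[best]]), ndesc_lab[ch[best]],
                       min_lab[ch[best]])
        best <- best[order(labs)[1]]
      }
    }
    b <- ch[best[1]]
    ndesc_steps[nd] <- cand_steps[best[1]]
    ndesc_age[nd] <- if (is.na(fixed_age[b])) ndesc_age[b] else fixed_age[b]
    ndesc_lab[nd] <- if (is.na(fixed_age[b])) ndesc_lab[b] else min_lab[b]
  }
  # interpolate unfixed nodes: k-th of m unfixed nodes on the A -> D chain
  ages <- fixed_age
  internal_pre <- unique(target$edge[, 1])
  for (nd in internal_pre) {
    if (!is.na(ages[nd])) next
    # nearest fixed ancestor and position k below it
    anc <- parent[nd]
    k <- 1L
    while (is.na(fixed_age[anc])) {
      anc <- parent[anc]
      k <- k + 1L
    }
    a <- fixed_age[anc]
    d <- ndesc_age[nd]
    m <- k - 1L + ndesc_steps[nd] + 1L # unfixed nodes on the whole A -> D path
    ages[nd] <- a - (a - d) * k / (m + 1L)
  }
  out <- target
  out$edge.length <- ages[out$edge[, 1]] - ages[out$edge[, 2]]
  if (any(out$edge.length < 0)) stop("bladj: produced a negative branch length")
  attr(out, "ages") <- ages
  out
}
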