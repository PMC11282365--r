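#' Leave-one-study-out cross-validation of dated node ages
#'
#' Treats every chronogram of the held-out study as an undated topology,
#' congruifies ages from all other studies onto it, applies mean summary ages
#' as secondary calibrations (average ages, as in the cross-validation
#' design), filters conflicts and re-dates with [bladj()]. Each row pairs a
#' node's original age with its cross-validated estimate.
#'
#' Exclusion is at study (citation) granularity: when a study contributed
#' several chronograms, none of them informs the calibrations.
#'
#' @param db A `chronogram_db` with at least 2 studies.
#' @param study A record id or citation identifying the held-out study.
#' @param stat Summary statistic for calibration ages (default `"mean"`).
#' @return A tibble: `study`, `record_id`, `node_name`, `original_age`,
#'   `estimated_age`, `depth` (descendant-tip count). Empty with a `message`
#'   attribute when overlap is insufficient.
#' @export
cross_validate_study <- function(db, study, stat = "mean") {
  stopifnot(inherits(db, "chronogram_db"))
  citations <- vapply(db$records, `[[`, "", "citation")
  held_ids <- names(db$records)[citations == study | names(db$records) == study]
  if (!length(held_ids)) stop("cross_validate_study: unknown study '", study, "'")
  held_cit <- unique(citations[held_ids])
  rest_ids <- names(db$records)[!citations %in% held_cit]
  if (!length(rest_ids)) {
    stop("cross_validate_study: database has no other study to calibrate from")
  }
  rest_db <- chronogram_db(unname(db$records[rest_ids]), version = db$version)
  empty <- tibble::tibble(study = character(), record_id = character(),
                          node_name = character(), original_age = numeric(),
                          estimated_age = numeric(), depth = integer())
  out <- purrr::map_dfr(held_ids, function(id) {
    rec <- db$records[[id]]
    target <- rec$tree
    orig_ages <- node_ages(target)
    target_topo <- target
    target_topo$edge.length <- NULL
    pool_names <- unique(unlist(lapply(rest_db$records, `[[`, "tips")))
    shared <- intersect(rec$tips, pool_names)
    if (length(shared) < 2) return(empty)
    query <- structure(
      tibble::tibble(input = rec$tips, name = rec$tips,
                     id = NA_integer_, match = "exact"),
      class = c("resolved_query", "tbl_df", "tbl", "data.frame"),
      topology = target_topo, taxonomy_version = db$taxonomy_version
    )
    res <- search_chronograms(query, rest_db)
    if (!length(res$matrices)) return(empty)
    calib <- build_calibration_table(target_topo, res)
    if (!nrow(calib)) return(empty)
    summ <- summarize_node_ages(calib)
    set <- tryCatch(filter_calibrations(summ, target_topo, stat = stat),
                    error = function(e) NULL)
    if (is.null(set)) return(empty)
    root_age <- suppressWarnings(resolve_root_age(set))
    chrono <- bladj(target_topo, set, root_age = root_age)
    est <- attr(chrono, "ages")
    nn <- node_names(target_topo)
    desc <- descendant_tips(target_topo)
    # report nodes that had congruent data (calibrated or filtered out)
    nodes <- nn[nn$node_name %in% summ$node_name, ]
    # original ages indexed on the same (cladewise) node numbering
    orig <- node_ages(ape::reorder.phylo(target, "cladewise"))
    tibble::tibble(
      study = rec$citation, record_id = id,
      node_name = nodes$node_name,
      original_age = orig[nodes$node],
      estimated_age = est[nodes$node],
      depth = lengths(desc[nodes$node])
    )
  })
  if (!nrow(out)) {
    attr(out, "message") <- "insufficient taxon overlap with the remaining studies"
  }
  out
}

#' Summarize cross-validation rows
#'
#' Per-study Pearson correlation of original vs cross-validated ages and
#' per-depth-bin mean signed error (estimated minus original), to expose
#' systematic under- or over-estimation by node depth.
#'
#' @param rows Output of [cross_validate_study()] (rows from one or more
#'   studies may be bound together); at least 3 rows.
#' @param depth_bins Number of node-depth bins (default 3).
#' @return A list with `by_study` (tibble: `study`, `n`, `correlation` -
#'   `NA` when a column is constant) and `by_depth` (tibble: `depth_bin`,
#'   `n`, `mean_signed_error`).
#' @export
crossval_report <- function(rows, depth_bins = 3) {
  if (nrow(rows) < 3) stop("crossval_report: need at least 3 rows")
  by_study <- dplyr::summarise(
    dplyr::group_by(rows, .data$study),
    n = dplyr::n(),
    correlation = if (stats::sd(.data$original_age) == 0 ||
                      stats::sd(.data$estimated_age) == 0) NA_real_
                  else stats::cor(.data$original_age, .data$estimated_age),
    .groups = "drop"
  )
  rows$depth_bin <- cut(rows$depth, breaks = depth_bins, labels = FALSE)
  by_depth <- dplyr::summarise(
    dplyr::group_by(rows, .data$depth_bin),
    n = dplyr::n(),
    mean_signed_error = mean(.data$estimated_age - .data$original_age),
    .groups = "drop"
  )
  list(by_study = by_study, by_depth = by_depth)
}
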