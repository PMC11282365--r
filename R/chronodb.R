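#' Construct a chronogram database
#'
#' A versioned collection of published chronograms, each a record carrying a
#' citation. Tip labels are canonicalized against the taxonomy at construction
#' time (exact + synonym matches only; synonym-bearing studies then match
#' standardized queries), mirroring a curated, versioned chronogram store.
#'
#' @param records A list; each element a list with `id` (unique string),
#'   `citation` (non-empty string), and `tree` (ultrametric `phylo`, branch
#'   lengths in Myr).
#' @param version Database version string (mandatory).
#' @param tax Optional `taxonomy` used to canonicalize tip labels.
#' @return An object of class `chronogram_db`.
#' @export
chronogram_db <- function(records, version, tax = NULL) {
  if (missing(version) || !nzchar(version)) stop("chronogram_db: version string is mandatory")
  ids <- vapply(records, function(r) as.character(r$id), "")
  if (anyDuplicated(ids)) stop("chronogram_db: duplicate record ids")
  records <- lapply(records, function(r) {
    if (is.null(r$citation) || !nzchar(r$citation)) {
      stop("chronogram_db: record ", r$id, " has no citation")
    }
    r$tree <- as_chronogram(r$tree)
    if (ape::Ntip(r$tree) < 2) stop("chronogram_db: record ", r$id, " has < 2 tips")
    if (!is.null(tax)) {
      res <- resolve_names(r$tree$tip.label, tax, use_tnrs = TRUE)
      # canonicalize only exact/synonym hits; never fuzzy against DB tips
      hit <- res$match %in% c("exact", "synonym")
      r$tree$tip.label[hit] <- res$name[hit]
    }
    r$tips <- r$tree$tip.label
    r
  })
  names(records) <- ids
  structure(
    list(records = records, version = version,
         taxonomy_version = if (!is.null(tax)) attr(tax, "version") else NA_character_),
    class = "chronogram_db"
  )
}

#' @export
print.chronogram_db <- function(x, ...) {
  cat("<chronogram_db> version", x$version, "-", length(x$records), "record(s),",
      length(unique(unlist(lapply(x$records, `[[`, "tips")))), "distinct taxa\n")
  invisible(x)
}

#' Save / load a chronogram database
#'
#' On-disk layout: a directory with one newick file per record plus a
#' `manifest.json` holding ids, citations, file names, tip counts and the
#' database and taxonomy version strings. Round-trips losslessly.
#'
#' @param db A `chronogram_db`.
#' @param path Directory path (created if needed).
#' @return [save_db()] the path invisibly; [load_db()] a `chronogram_db`.
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "chronogram_db"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    version = db$version,
    taxonomy_version = db$taxonomy_version,
    records = lapply(db$records, function(r) {
      file <- paste0(gsub("[^A-Za-z0-9_.-]", "_", r$id), ".nwk")
      writeLines(write_newick(r$tree), file.path(path, file))
      list(id = r$id, citation = r$citation, file = file,
           n_tips = ape::Ntip(r$tree))
    })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_db
#' @export
load_db <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("load_db: no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf)
  if (is.null(manifest$version)) stop("load_db: manifest has no version string")
  records <- lapply(manifest$records, function(r) {
    if (is.null(r$citation) || !nzchar(r$citation)) {
      stop("load_db: record ", r$id, " has no citation")
    }
    list(id = r$id, citation = r$citation,
         tree = parse_newick(readLines(file.path(path, r$file))))
  })
  db <- chronogram_db(records, version = manifest$version)
  db$taxonomy_version <- manifest$taxonomy_version %||% NA_character_
  db
}

#' Search a chronogram database
#'
#' Records whose tip labels share at least two resolved query names are pruned
#' to the matched taxa and converted to patristic distance matrices. An empty
#' result is valid and carries an explicit lack-of-data message.
#'
#' @param query A `resolved_query` (see [resolve_names()], [make_query()]).
#' @param db A `chronogram_db`.
#' @return A `chrono_search`: list with `matrices` (named list of patristic
#'   matrices), `records` (tibble: `id`, `citation`, `n_matched`,
#'   `matched` list-column), `query`, `db_version`, and `message` (non-`NULL`
#'   when nothing matched).
#' @export
search_chronograms <- function(query, db) {
  stopifnot(inherits(query, "resolved_query"), inherits(db, "chronogram_db"))
  qnames <- unique(stats::na.omit(query$name))
  if (!length(qnames)) stop("search_chronograms: query has no resolved names")
  hits <- purrr::keep(db$records, function(r) length(intersect(qnames, r$tips)) >= 2)
  if (!length(hits)) {
    return(structure(
      list(matrices = list(),
           records = tibble::tibble(id = character(), citation = character(),
                                    n_matched = integer(), matched = list()),
           query = query, db_version = db$version,
           message = "no age data found for the queried taxa in the database"),
      class = "chrono_search"
    ))
  }
  matrices <- lapply(hits, function(r) {
    patristic_matrix(prune_tree(r$tree, intersect(qnames, r$tips)))
  })
  records <- purrr::map_dfr(hits, function(r) {
    m <- intersect(qnames, r$tips)
    tibble::tibble(id = r$id, citation = r$citation, n_matched = length(m),
                   matched = list(m))
  })
  structure(
    list(matrices = matrices, records = records, query = query,
         db_version = db$version, message = NULL),
    class = "chrono_search"
  )
}

#' @export
print.chrono_search <- function(x, ...) {
  if (!is.null(x$message)) {
    cat("<chrono_search>", x$message, "\n")
  } else {
    cat("<chrono_search>", length(x$matrices), "source chronogram(s) from",
        length(unique(x$records$citation)), "study citation(s), db version",
        x$db_version, "\n")
  }
  invisible(x)
}

#' Summarize a search result
#'
#' Per-record root ages (half the largest patristic entry), citations, a
#' matched-name report, and the record(s) matching the most query names.
#'
#' @param result A `chrono_search`.
#' @return A list with `summary` (tibble: `id`, `citation`, `root_age`,
#'   `n_matched`), `match_report` (tibble: query name x record matched flag),
#'   `best_records` (ids maximizing matched names), and `message`.
#' @export
summary_report <- function(result) {
  stopifnot(inherits(result, "chrono_search"))
  if (!length(result$matrices)) {
    return(list(summary = tibble::tibble(), match_report = tibble::tibble(),
                best_records = character(),
                message = result$message %||% "empty search result"))
  }
  summary <- dplyr::mutate(
    result$records,
    root_age = unname(vapply(result$matrices[result$records$id],
                             function(m) max(m) / 2, 0))
  )[, c("id", "citation", "root_age", "n_matched")]
  qnames <- unique(stats::na.omit(result$query$name))
  match_report <- purrr::map_dfr(seq_len(nrow(result$records)), function(i) {
    tibble::tibble(id = result$records$id[i], name = qnames,
                   matched = qnames %in% result$records$matched[[i]])
  })
  best <- summary$id[summary$n_matched == max(summary$n_matched)]
  list(summary = summary, match_report = match_report,
       best_records = best, message = NULL)
}

#' Export a search result as a flat table
#'
#' One row per record and taxon pair: `id`, `citation`, `taxon_a`, `taxon_b`,
#' `distance_myr` (total tip-to-tip time).
#'
#' @param result A `chrono_search`.
#' @return A tibble.
#' @export
search_result_table <- function(result) {
  stopifnot(inherits(result, "chrono_search"))
  if (!length(result$matrices)) {
    return(tibble::tibble(id = character(), citation = character(),
                          taxon_a = character(), taxon_b = character(),
                          distance_myr = numeric()))
  }
  purrr::map_dfr(names(result$matrices), function(id) {
    m <- result$matrices[[id]]
    cmb <- utils::combn(rownames(m), 2)
    tibble::tibble(
      id = id,
      citation = result$records$citation[match(id, result$records$id)],
      taxon_a = cmb[1, ], taxon_b = cmb[2, ],
      distance_myr = m[cbind(cmb[1, ], cmb[2, ])]
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
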