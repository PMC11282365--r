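#' Construct a taxonomy table
#'
#' A taxonomy is a tibble of records (`id`, `parent_id`, `name`, `rank`,
#' `synonyms`) with a version string attribute. Canonical names must be
#' unique, parent links must form a tree rooted at a single top record
#' (`parent_id = NA`), and every synonym must resolve to exactly one id.
#'
#' @param records A data frame with columns `id` (integer), `parent_id`
#'   (integer, `NA` for the root record), `name` (canonical name), `rank`
#'   (e.g. `"species"`, `"genus"`, `"family"`, `"subspecies"`), and
#'   `synonyms` (list-column of character vectors, or a pipe-separated
#'   character column).
#' @param version Taxonomy version string.
#' @return A tibble of class `taxonomy` with a `version` attribute.
#' @export
taxonomy <- function(records, version = "unversioned") {
  tab <- tibble::as_tibble(records)
  req <- c("id", "parent_id", "name", "rank", "synonyms")
  if (!all(req %in% names(tab))) {
    stop("taxonomy needs columns: ", paste(setdiff(req, names(tab)), collapse = ", "))
  }
  if (is.character(tab$synonyms)) {
    tab$synonyms <- lapply(tab$synonyms, function(s) {
      if (is.na(s) || !nzchar(s)) character(0) else trimws(strsplit(s, "|", fixed = TRUE)[[1]])
    })
  }
  if (anyDuplicated(tab$name)) {
    stop("taxonomy: duplicate canonical name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  }
  if (anyDuplicated(tab$id)) stop("taxonomy: duplicate ids")
  if (sum(is.na(tab$parent_id)) != 1) {
    stop("taxonomy: parent links must be rooted at exactly one top record")
  }
  syn <- unlist(tab$synonyms)
  if (anyDuplicated(syn)) {
    stop("taxonomy: synonym(s) mapping to more than one record: ",
         paste(unique(syn[duplicated(syn)]), collapse = ", "))
  }
  # cycle check: every record must reach the root
  parent <- stats::setNames(tab$parent_id, tab$id)
  for (id in tab$id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(parent[[as.character(cur)]])) {
      if (cur %in% seen) stop("taxonomy: cycle in parent links at id ", id)
      seen <- c(seen, cur)
      cur <- parent[[as.character(cur)]]
      if (!as.character(cur) %in% names(parent)) {
        stop("taxonomy: parent id ", cur, " not found")
      }
    }
  }
  structure(tab, class = c("taxonomy", class(tab)), version = version)
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> version", attr(x, "version"), "-", nrow(x), "records\n")
  NextMethod()
}

#' Read / write a taxonomy TSV
#'
#' Plain-text tabular format: a header line `# taxonomy-version: <string>`
#' followed by tab-separated columns `id`, `parent_id`, `name`, `rank`,
#' `synonyms` (pipe-separated).
#'
#' @param path File path.
#' @return [read_taxonomy()] returns a `taxonomy`; [write_taxonomy()] the path,
#'   invisibly.
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# taxonomy-version:", lines[1])) {
    stop("taxonomy file must start with '# taxonomy-version: <string>'")
  }
  version <- trimws(sub("^# taxonomy-version:", "", lines[1]))
  tab <- utils::read.delim(
    text = paste(lines[-1], collapse = "\n"),
    stringsAsFactors = FALSE, na.strings = "NA"
  )
  tab$parent_id <- suppressWarnings(as.integer(tab$parent_id))
  if (!"synonyms" %in% names(tab)) tab$synonyms <- ""
  tab$synonyms[is.na(tab$synonyms)] <- ""
  taxonomy(tab, version = version)
}

#' @rdname read_taxonomy
#' @param tax A `taxonomy` object.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  out <- as.data.frame(tax)
  out$synonyms <- vapply(tax$synonyms, paste, "", collapse = "|")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# taxonomy-version:", attr(tax, "version")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# normalized similarity in [0,1]: 1 - levenshtein/nchar(longer)
name_similarity <- function(a, b) {
  d <- utils::adist(tolower(a), tolower(b))[1, 1]
  1 - d / max(nchar(a), nchar(b))
}

#' Resolve taxon names against a taxonomy
#'
#' Local taxonomic name resolution: an exact -> synonym -> fuzzy cascade over
#' the taxonomy's canonical names and synonym lists. Synonym hits are replaced
#' by the canonical name; fuzzy matching uses normalized edit-distance
#' similarity with threshold `fuzzy_threshold`, ties broken by preferring a
#' candidate in the same genus as the input, then lexicographically. With
#' `use_tnrs = FALSE` only exact canonical matches are attempted. Unmatched
#' names are reported, not fatal.
#'
#' @param names Character vector of input names (non-empty).
#' @param tax A `taxonomy`.
#' @param use_tnrs Enable the synonym + fuzzy cascade (default `TRUE`).
#' @param fuzzy_threshold Minimum normalized similarity for a fuzzy match.
#' @param topology Optional `phylo` retained alongside the resolution (used
#'   when the query came from a tree).
#' @return A `resolved_query`: a tibble (`input`, `name`, `id`, `match`)
#'   with `match` one of `"exact"`, `"synonym"`, `"fuzzy"`, `"unmatched"`,
#'   plus attributes `topology` and `taxonomy_version`.
#' @export
resolve_names <- function(names, tax, use_tnrs = TRUE, fuzzy_threshold = 0.90,
                          topology = NULL) {
  stopifnot(inherits(tax, "taxonomy"))
  names <- trimws(names)
  names <- names[nzchar(names)]
  if (!length(names)) stop("resolve_names: empty name list")
  syn_map <- tibble::tibble(
    synonym = unlist(tax$synonyms),
    id = rep(tax$id, lengths(tax$synonyms))
  )
  resolve_one <- function(nm) {
    hit <- match(nm, tax$name)
    if (!is.na(hit)) {
      return(tibble::tibble(input = nm, name = tax$name[hit], id = tax$id[hit],
                            match = "exact"))
    }
    if (!use_tnrs) {
      return(tibble::tibble(input = nm, name = NA_character_, id = NA_integer_,
                            match = "unmatched"))
    }
    shit <- match(nm, syn_map$synonym)
    if (!is.na(shit)) {
      id <- syn_map$id[shit]
      return(tibble::tibble(input = nm, name = tax$name[match(id, tax$id)],
                            id = id, match = "synonym"))
    }
    cand <- c(tax$name, syn_map$synonym)
    sims <- vapply(cand, name_similarity, 0, b = nm)
    ok <- which(sims >= fuzzy_threshold)
    if (length(ok)) {
      best <- ok[sims[ok] == max(sims[ok])]
      if (length(best) > 1) {
        genus <- strsplit(nm, " ")[[1]][1]
        same_genus <- startsWith(cand[best], paste0(genus, " "))
        if (any(same_genus)) best <- best[same_genus]
        best <- best[order(cand[best])]
      }
      pick <- cand[best[1]]
      id <- if (best[1] <= nrow(tax)) tax$id[best[1]] else
        syn_map$id[best[1] - nrow(tax)]
      return(tibble::tibble(input = nm, name = tax$name[match(id, tax$id)],
                            id = id, match = "fuzzy"))
    }
    tibble::tibble(input = nm, name = NA_character_, id = NA_integer_,
                   match = "unmatched")
  }
  res <- purrr::map_dfr(names, resolve_one)
  structure(res, class = c("resolved_query", class(res)),
            topology = topology, taxonomy_version = attr(tax, "version"))
}

#' @export
print.resolved_query <- function(x, ...) {
  cat("<resolved_query>", nrow(x), "name(s), taxonomy",
      attr(x, "taxonomy_version"),
      if (!is.null(attr(x, "topology"))) "(with input topology)" else "", "\n")
  NextMethod()
}

#' Expand an inclusive taxon name to its species
#'
#' For a name above species rank with `get_species = TRUE`, returns every
#' species-rank descendant (subspecific variants excluded). With
#' `get_species = FALSE`, inclusive names are excluded from the query with a
#' notice and an empty expansion. Species and subspecies inputs pass through
#' as provided.
#'
#' @param name A single taxon name resolvable in `tax`.
#' @param tax A `taxonomy`.
#' @param get_species Expand inclusive names to species (default `TRUE`).
#' @return Character vector of species names (possibly empty), with attribute
#'   `notice` when an inclusive name was excluded.
#' @export
expand_taxon <- function(name, tax, get_species = TRUE) {
  stopifnot(inherits(tax, "taxonomy"))
  res <- resolve_names(name, tax)
  if (res$match[1] == "unmatched") stop("expand_taxon: cannot resolve '", name, "'")
  rec <- tax[match(res$id[1], tax$id), ]
  sub_ranks <- c("subspecies", "variety", "strain", "subspecies-variant", "form")
  if (rec$rank %in% c("species", sub_ranks)) return(res$name[1])
  if (!get_species) {
    out <- character(0)
    attr(out, "notice") <- paste0(
      "inclusive taxon '", rec$name, "' (rank ", rec$rank,
      ") excluded from query; set get_species = TRUE to expand it"
    )
    return(out)
  }
  # collect species-rank descendants by walking parent links
  kids <- split(tax$id, tax$parent_id)
  out_ids <- integer(0)
  frontier <- rec$id
  while (length(frontier)) {
    nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
    out_ids <- c(out_ids, nxt)
    frontier <- nxt
  }
  desc <- tax[match(out_ids, tax$id), ]
  sort(unique(desc$name[desc$rank == "species"]))
}

#' Build a query from a name string or a newick topology
#'
#' Accepts either a comma-separated string of scientific names or a newick
#' string; tip labels are harvested and the topology retained in the latter
#' case.
#'
#' @param input A single string: `"name1, name2, ..."` or `"(...);"` newick.
#' @param tax A `taxonomy`.
#' @inheritParams resolve_names
#' @return A `resolved_query` (see [resolve_names()]).
#' @export
make_query <- function(input, tax, use_tnrs = TRUE, fuzzy_threshold = 0.90) {
  stopifnot(is.character(input), length(input) == 1)
  looks_newick <- grepl("\\(", input) || grepl(";\\s*$", input)
  if (looks_newick) {
    topo <- parse_newick(input) # parse errors propagate
    resolve_names(topo$tip.label, tax, use_tnrs = use_tnrs,
                  fuzzy_threshold = fuzzy_threshold, topology = topo)
  } else {
    nms <- trimws(strsplit(input, ",", fixed = TRUE)[[1]])
    nms <- nms[nzchar(nms)]
    if (!length(nms)) stop("make_query: no names in input")
    resolve_names(nms, tax, use_tnrs = use_tnrs, fuzzy_threshold = fuzzy_threshold)
  }
}
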