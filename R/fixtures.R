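#' Build a chronogram from node ages on a topology
#'
#' Inverse of age extraction: branch lengths are parent-child age
#' differences, tips sit at the present. Ages must strictly decrease
#' root-to-tip and cover every internal node.
#'
#' @param topology A `phylo`.
#' @param ages Numeric vector of ages (Myr) named by node name (see
#'   [node_names()]), one per internal node.
#' @return An ultrametric `phylo`.
#' @export
chronogram_from_node_ages <- function(topology, ages) {
  stopifnot(inherits(topology, "phylo"))
  topology <- ape::reorder.phylo(topology, "cladewise")
  nn <- node_names(topology)
  missing <- setdiff(nn$node_name, names(ages))
  if (length(missing)) {
    stop("chronogram_from_node_ages: no age for node(s) ",
         paste(missing, collapse = ", "))
  }
  ntip <- ape::Ntip(topology)
  full <- numeric(ntip + topology$Nnode)
  full[nn$node] <- ages[nn$node_name]
  out <- topology
  out$edge.length <- full[out$edge[, 1]] - full[out$edge[, 2]]
  if (any(out$edge.length <= 0)) {
    stop("chronogram_from_node_ages: ages must strictly decrease root-to-tip")
  }
  out
}

# chronogram on a subset of a target's tips, with ages given per target node
# name; every internal node of the induced subtree must map to a named node
record_tree_from_target <- function(target, tips, age_map) {
  sub <- prune_tree(target, tips)
  sub$edge.length <- NULL
  nn_target <- node_names(target)
  nn_sub <- node_names(sub)
  desc <- descendant_tips(sub)
  ages <- vapply(nn_sub$node, function(v) {
    tgt_node <- tree_mrca(target, desc[[v]])
    nm <- nn_target$node_name[match(tgt_node, nn_target$node)]
    if (!nm %in% names(age_map)) {
      stop("record_tree_from_target: no age witnessed for target node ", nm)
    }
    age_map[[nm]]
  }, 0)
  chronogram_from_node_ages(sub, stats::setNames(ages, nn_sub$node_name))
}

#' The six-species worked example
#'
#' Reconstructs the package's small worked example: six passeriform species
#' (two grosbeaks, three buntings, one Darwin's finch), a taxonomy carrying
#' the *Emberiza elegans* = *Schoeniclus elegans* synonym, a target topology
#' with stable node names `n1`..`n5`, and a database of nine synthetic source
#' chronograms across six study citations, built so that each record's node
#' ages equal its published congruified ages. All components are synthetic
#' reconstructions from the published age table, not the original newick
#' files.
#'
#' @return A list: `db` (`chronogram_db`), `tax` (`taxonomy`), `query`
#'   (`resolved_query` for the six input names, synonym applied), `target`
#'   (`phylo` topology), and `table1` (tibble of the published calibration
#'   ages used to build the records).
#' @export
small_example_db <- function() {
  tax <- small_example_taxonomy()
  target <- parse_newick(paste0(
    "((Platyspiza_crassirostris,(Pheucticus_tibialis,Rhodothraupis_celaeno)),",
    "((Emberiza_citrinella,Emberiza_leucocephalos),Schoeniclus_elegans));"
  ))
  # per-record congruified node ages (Myr) on the target's named nodes
  spec <- list(
    list(id = "A1", citation = "Study A",
         tips = c("Emberiza citrinella", "Emberiza leucocephalos",
                  "Schoeniclus elegans", "Platyspiza crassirostris",
                  "Rhodothraupis celaeno"),
         ages = c(n1 = 9.651, n2 = 7.969, n4 = 5.324, n5 = 0.141)),
    list(id = "A2", citation = "Study A",
         tips = c("Emberiza citrinella", "Emberiza leucocephalos",
                  "Schoeniclus elegans", "Platyspiza crassirostris",
                  "Rhodothraupis celaeno"),
         ages = c(n1 = 21.514, n2 = 19.709, n4 = 10.339, n5 = 0.273)),
    list(id = "B1", citation = "Study B",
         tips = c("Emberiza citrinella", "Emberiza leucocephalos",
                  "Schoeniclus elegans", "Pheucticus tibialis",
                  "Rhodothraupis celaeno"),
         ages = c(n1 = 14.334, n3 = 10.530, n4 = 9.862, n5 = 0.201)),
    list(id = "B2", citation = "Study B",
         tips = c("Emberiza citrinella", "Emberiza leucocephalos",
                  "Schoeniclus elegans", "Pheucticus tibialis",
                  "Rhodothraupis celaeno"),
         ages = c(n1 = 16.298, n3 = 11.210, n4 = 11.732, n5 = 0.241)),
    list(id = "C1", citation = "Study C",
         tips = c("Emberiza citrinella", "Emberiza leucocephalos",
                  "Platyspiza crassirostris", "Pheucticus tibialis",
                  "Rhodothraupis celaeno"),
         ages = c(n1 = 22.376, n2 = 19.713, n3 = 18.157, n5 = 0.576)),
    list(id = "C2", citation = "Study C",
         tips = c("Emberiza citrinella", "Emberiza leucocephalos",
                  "Platyspiza crassirostris", "Rhodothraupis celaeno"),
         ages = c(n1 = 22.000, n2 = 19.709, n5 = 0.152)),
    list(id = "D1", citation = "Study D",
         tips = c("Emberiza citrinella", "Emberiza leucocephalos",
                  "Schoeniclus elegans", "Platyspiza crassirostris"),
         ages = c(n1 = 16.950, n4 = 12.513, n5 = 2.290)),
    list(id = "E1", citation = "Study E",
         tips = c("Pheucticus tibialis", "Platyspiza crassirostris"),
         ages = c(n2 = 44.296)),
    list(id = "F1", citation = "Study F",
         tips = c("Pheucticus tibialis", "Rhodothraupis celaeno"),
         ages = c(n3 = 10.538))
  )
  records <- lapply(spec, function(s) {
    list(id = s$id, citation = s$citation,
         tree = record_tree_from_target(target, s$tips, as.list(s$ages)))
  })
  db <- chronogram_db(records, version = "small-example-1.0", tax = tax)
  query <- resolve_names(
    c("Pheucticus tibialis", "Rhodothraupis celaeno", "Emberiza citrinella",
      "Emberiza leucocephalos", "Emberiza elegans", "Platyspiza crassirostris"),
    tax
  )
  table1 <- purrr::map_dfr(spec, function(s) {
    tibble::tibble(record_id = s$id, citation = s$citation,
                   node_name = names(s$ages), age = unname(s$ages))
  })
  list(db = db, tax = tax, query = query, target = target, table1 = table1)
}

# minimal taxonomy for the six-species example, with the key synonym
small_example_taxonomy <- function() {
  records <- tibble::tibble(
    id = 1:12,
    parent_id = c(NA, 1L, 1L, 1L, 1L, 1L, 2L, 3L, 4L, 5L, 6L, 6L),
    name = c(
      "Passeriformes",
      "Pheucticus", "Rhodothraupis", "Platyspiza", "Schoeniclus", "Emberiza",
      "Pheucticus tibialis", "Rhodothraupis celaeno",
      "Platyspiza crassirostris", "Schoeniclus elegans",
      "Emberiza citrinella", "Emberiza leucocephalos"
    ),
    rank = c("order", rep("genus", 5), rep("species", 6)),
    synonyms = list(
      character(0), character(0), character(0), character(0), character(0),
      character(0), character(0), character(0), character(0),
      "Emberiza elegans", character(0), character(0)
    )
  )
  taxonomy(records, version = "small-example-taxonomy-1.0")
}

#' Random chronogram database generator
#'
#' Reproducible synthetic databases for property tests: each record is an
#' ultrametric pure-birth tree over a random subset of a taxon pool, rescaled
#' to a root age drawn uniformly on `root_age_range` (Myr).
#'
#' @param n_studies Number of records (0 gives an empty database).
#' @param tips_per_study Tips per record (>= 2, at most the pool size).
#' @param taxon_pool Character vector of available taxon names.
#' @param seed Integer seed.
#' @param root_age_range Range of root ages, Myr (default 10-50, typical of
#'   family-level chronograms).
#' @return A `chronogram_db`.
#' @export
random_db <- function(n_studies, tips_per_study, taxon_pool, seed,
                      root_age_range = c(10, 50)) {
  stopifnot(n_studies >= 0, tips_per_study >= 2)
  if (length(taxon_pool) < tips_per_study) {
    stop("random_db: taxon pool smaller than tips_per_study")
  }
  set.seed(seed)
  records <- lapply(seq_len(n_studies), function(i) {
    tips <- sample(taxon_pool, tips_per_study)
    tr <- ape::rphylo(tips_per_study, birth = 1, death = 0)
    tr$tip.label <- tips
    root_age <- stats::runif(1, root_age_range[1], root_age_range[2])
    tr$edge.length <- tr$edge.length * root_age /
      max(ape::node.depth.edgelength(tr))
    list(id = sprintf("rand-%03d", i), citation = sprintf("Random study %d", i),
         tree = tr)
  })
  chronogram_db(records, version = sprintf("random-seed-%d", seed))
}

#' Synthetic finch-like taxonomy
#'
#' Generates a synthetic taxonomy emulating the shape of a large passerine
#' family in a reference taxonomy: a family record (default name
#' `"Fringillidae"`) with `n_genera` genera, `n_species` species spread
#' round-robin across them, and `n_subspecies` subspecific variants (used to
#' exercise their exclusion from species expansion). Names are invented
#' (`Fgenus01 species0001`, ...), not real taxa.
#'
#' @param n_species Number of species records (default 289).
#' @param n_genera Number of genera (default 25).
#' @param n_subspecies Number of subspecies records (default 10).
#' @param family_name Name of the family record.
#' @return A `taxonomy`.
#' @export
finch_like_taxonomy <- function(n_species = 289, n_genera = 25,
                                n_subspecies = 10,
                                family_name = "Fringillidae") {
  n_genera <- min(n_genera, n_species)
  n_subspecies <- min(n_subspecies, n_species)
  genera <- sprintf("Fgenus%02d", seq_len(n_genera))
  gen_of <- rep(seq_len(n_genera), length.out = n_species)
  species <- sprintf("%s species%04d", genera[gen_of], seq_len(n_species))
  fam_id <- 1L
  gen_ids <- fam_id + seq_len(n_genera)
  sp_ids <- max(gen_ids) + seq_len(n_species)
  ssp_ids <- max(sp_ids) + seq_len(n_subspecies)
  records <- tibble::tibble(
    id = c(fam_id, gen_ids, sp_ids, ssp_ids),
    parent_id = c(NA, rep(fam_id, n_genera), gen_ids[gen_of],
                  sp_ids[seq_len(n_subspecies)]),
    name = c(family_name, genera, species,
             paste(species[seq_len(n_subspecies)],
                   sprintf("var%02d", seq_len(n_subspecies)))),
    rank = c("family", rep("genus", n_genera), rep("species", n_species),
             rep("subspecies", n_subspecies)),
    synonyms = rep(list(character(0)), 1 + n_genera + n_species + n_subspecies)
  )
  taxonomy(records, version = "finch-like-synthetic-1.0")
}

#' Synthetic finch-like chronogram database
#'
#' A scaled stand-in for a real curated database over a large family:
#' `n_studies` random chronograms drawn over the species pool of a
#' [finch_like_taxonomy()], for stress-testing search, congruification and
#' dating at larger sizes.
#'
#' @inheritParams random_db
#' @param tax A taxonomy from [finch_like_taxonomy()] (one is generated if
#'   omitted).
#' @return A list with `db` and `tax`.
#' @export
finch_like_db <- function(n_studies = 5, tips_per_study = 20, seed = 1,
                          tax = finch_like_taxonomy()) {
  pool <- tax$name[tax$rank == "species"]
  db <- random_db(n_studies, tips_per_study, pool, seed = seed)
  list(db = db, tax = tax)
}
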