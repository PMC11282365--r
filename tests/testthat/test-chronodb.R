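ex <- small_example_db()

test_that("search returns records with >= 2 matched tips, pruned to the query", {
  res <- search_chronograms(ex$query, ex$db)
  expect_length(res$matrices, 9)
  expect_equal(length(unique(res$records$citation)), 6)
  qnames <- stats::na.omit(ex$query$name)
  for (m in res$matrices) {
    expect_gte(nrow(m), 2)
    expect_true(all(rownames(m) %in% qnames))
  }
  # per-record coverage; at study level: three studies reach 5 matched names,
  # one reaches 4, two reach 2
  expect_equal(sort(res$records$n_matched), c(2, 2, 4, 4, 5, 5, 5, 5, 5))
  by_study <- tapply(res$records$n_matched, res$records$citation, max)
  expect_equal(sort(as.vector(by_study)), c(2, 2, 4, 5, 5, 5))
})

test_that("a record sharing a single query tip is excluded", {
  q <- resolve_names(c("Pheucticus tibialis", "Platyspiza crassirostris"), ex$tax)
  res <- search_chronograms(q, ex$db)
  # D1 contains Platyspiza but not Pheucticus of this 2-name query: kept only
  # if it has both; C2 has Platyspiza only -> excluded
  expect_false("C2" %in% res$records$id)
  expect_true("E1" %in% res$records$id)
})

test_that("a query with no database overlap yields a messaged empty result", {
  ft <- finch_like_taxonomy(n_species = 5)
  q <- resolve_names(c("Fgenus01 species0001", "Fgenus02 species0002"), ft)
  res <- search_chronograms(q, ex$db)
  expect_length(res$matrices, 0)
  expect_match(res$message, "no age data")
  rep <- summary_report(res)
  expect_match(rep$message, "no age data")
})

test_that("search matrices equal prune-then-patristic on each record", {
  res <- search_chronograms(ex$query, ex$db)
  qnames <- stats::na.omit(ex$query$name)
  for (id in res$records$id) {
    rec <- ex$db$records[[id]]
    expected <- patristic_matrix(prune_tree(rec$tree, intersect(qnames, rec$tips)))
    got <- res$matrices[[id]]
    expect_equal(got[rownames(expected), colnames(expected)], expected,
                 tolerance = 1e-10)
  }
})

test_that("enlarging the query never removes a record (monotonicity)", {
  small_q <- resolve_names(c("Emberiza citrinella", "Emberiza leucocephalos"),
                           ex$tax)
  big_q <- ex$query
  small_ids <- search_chronograms(small_q, ex$db)$records$id
  big_ids <- search_chronograms(big_q, ex$db)$records$id
  expect_true(all(small_ids %in% big_ids))
})

test_that("summary report carries root ages (half max entry) and best records", {
  res <- search_chronograms(ex$query, ex$db)
  rep <- summary_report(res)
  for (i in seq_len(nrow(rep$summary))) {
    id <- rep$summary$id[i]
    expect_equal(rep$summary$root_age[i], max(res$matrices[[id]]) / 2)
  }
  expect_setequal(
    unique(res$records$citation[match(rep$best_records, res$records$id)]),
    c("Study A", "Study B", "Study C")
  )
  expect_true(all(res$records$n_matched[match(rep$best_records, res$records$id)] == 5))
})

test_that("database save/load round-trips records, citations and versions", {
  dir <- withr::local_tempdir()
  save_db(ex$db, dir)
  back <- load_db(dir)
  expect_equal(back$version, ex$db$version)
  expect_setequal(names(back$records), names(ex$db$records))
  for (id in names(ex$db$records)) {
    expect_equal(back$records[[id]]$citation, ex$db$records[[id]]$citation)
    expect_equal(
      patristic_matrix(back$records[[id]]$tree),
      patristic_matrix(ex$db$records[[id]]$tree),
      tolerance = 1e-8
    )
  }
  # validation errors
  expect_error(load_db(withr::local_tempdir()), "manifest")
  expect_error(
    chronogram_db(list(list(id = "x", citation = "",
                            tree = parse_newick("(A:1,B:1);"))),
                  version = "v"),
    "citation"
  )
  expect_error(
    chronogram_db(list(
      list(id = "x", citation = "c", tree = parse_newick("(A:1,B:1);")),
      list(id = "x", citation = "c", tree = parse_newick("(A:1,C:1);"))
    ), version = "v"),
    "duplicate"
  )
})

test_that("database tip canonicalization lets synonym-bearing studies match", {
  # a record published under the synonym still matches the standardized query
  rec <- list(list(
    id = "syn1", citation = "Synonym study",
    tree = parse_newick("(Emberiza_elegans:4,Emberiza_citrinella:4);")
  ))
  db2 <- chronogram_db(rec, version = "v-syn", tax = ex$tax)
  expect_true("Schoeniclus elegans" %in% db2$records[["syn1"]]$tips)
  q <- resolve_names(c("Emberiza elegans", "Emberiza citrinella"), ex$tax)
  res <- search_chronograms(q, db2)
  expect_length(res$matrices, 1)
})
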