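ex <- small_example_db()

test_that("congruifying a chronogram's own matrix recovers its node ages", {
  set.seed(3)
  for (i in 1:20) {
    tr <- random_chronogram(sample(4:15, 1))
    topo <- tr
    topo$edge.length <- NULL
    rows <- congruify_one(topo, patristic_matrix(tr))
    truth <- named_node_ages(tr)
    expect_equal(nrow(rows), tr$Nnode)
    expect_equal(stats::setNames(rows$age, rows$node_name), truth[rows$node_name],
                 tolerance = 1e-9)
  }
})

test_that("topological conflict on shared tips suppresses the calibration", {
  target <- parse_newick("((A,B),C);")
  source <- patristic_matrix(parse_newick("((A:1,C:1):1,B:2);"))
  rows <- congruify_one(target, source)
  # the A,B cherry conflicts with the source's (A,C) grouping; root survives
  expect_false(any(vapply(seq_len(nrow(rows)), function(i) {
    setequal(c(rows$taxon_a[i], rows$taxon_b[i]), c("A", "B")) & rows$age[i] < 2
  }, TRUE)))
  expect_equal(nrow(rows), 1)
  expect_equal(rows$age, 2) # root age = 4/2
  expect_equal(rows$node_name, "n1")
})

test_that("every emitted age is half a source matrix entry", {
  res <- search_chronograms(ex$query, ex$db)
  calib <- build_calibration_table(ex$target, res)
  for (i in seq_len(nrow(calib))) {
    m <- res$matrices[[calib$record_id[i]]]
    expect_equal(calib$age[i], m[calib$taxon_a[i], calib$taxon_b[i]] / 2,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("the six-species pipeline reproduces the published age table", {
  res <- search_chronograms(ex$query, ex$db)
  calib <- build_calibration_table(ex$target, res)
  expect_equal(nrow(calib), 28)
  # per-record, per-node ages match the table the fixtures encode
  got <- dplyr::arrange(
    dplyr::select(tibble::as_tibble(calib), "record_id", "node_name", "age"),
    .data$record_id, .data$node_name
  )
  want <- dplyr::arrange(
    dplyr::select(ex$table1, "record_id", "node_name", "age"),
    .data$record_id, .data$node_name
  )
  expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the deepest node's smallest age comes from record A1
  expect_equal(calib$age[calib$node_name == "n1" & calib$record_id == "A1"],
               9.651, tolerance = 1e-9)
})

test_that("synonym resolution is what admits the bunting-parent calibrations", {
  res <- search_chronograms(ex$query, ex$db)
  calib <- build_calibration_table(ex$target, res)
  expect_equal(sum(calib$node_name == "n4"), 5)
  # without TNRS the synonym input name stays unmatched and the node gets none
  q_raw <- resolve_names(ex$query$input, ex$tax, use_tnrs = FALSE)
  res_raw <- search_chronograms(q_raw, ex$db)
  calib_raw <- build_calibration_table(ex$target, res_raw)
  expect_equal(sum(calib_raw$node_name == "n4"), 0)
})

test_that("pruning the target creates no calibrations absent from the full run", {
  set.seed(5)
  res <- search_chronograms(ex$query, ex$db)
  full <- build_calibration_table(ex$target, res)
  keep <- c("Emberiza citrinella", "Emberiza leucocephalos",
            "Schoeniclus elegans", "Platyspiza crassirostris")
  sub_target <- prune_tree(ex$target, keep)
  sub <- build_calibration_table(sub_target, res)
  # ages on surviving nodes must be a subset of the full run's ages
  expect_true(all(sub$age %in% full$age))
})

test_that("an empty search yields an empty calibration table with a message", {
  ft <- finch_like_taxonomy(n_species = 5)
  q <- resolve_names(c("Fgenus01 species0001", "Fgenus02 species0002"), ft)
  res <- search_chronograms(q, ex$db)
  calib <- build_calibration_table(ex$target, res)
  expect_equal(nrow(calib), 0)
  expect_match(attr(calib, "message"), "no source chronogram")
})

test_that("node naming is stable: root first, then preorder", {
  nn <- node_names(ex$target)
  expect_equal(nn$node_name, paste0("n", 1:5))
  desc <- lapply(nn$node, descendant_tips_of, tree = ex$target)
  expect_length(desc[[1]], 6) # n1 = root
  expect_setequal(desc[[4]], c("Emberiza citrinella", "Emberiza leucocephalos",
                               "Schoeniclus elegans")) # n4: bunting clade
  expect_setequal(desc[[5]], c("Emberiza citrinella", "Emberiza leucocephalos"))
})

test_that("calibration tables round-trip as CSV with the standard columns", {
  res <- search_chronograms(ex$query, ex$db)
  calib <- build_calibration_table(ex$target, res)
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(calib, path)
  back <- read_calibration_csv(path)
  expect_equal(nrow(back), 28)
  expect_equal(back$age, calib$age, tolerance = 1e-9)
})
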