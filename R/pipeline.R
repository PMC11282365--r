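#' Date a topology end to end
#'
#' Composes the whole workflow: search the chronogram database with a
#' resolved query, congruify matched matrices onto the target topology,
#' summarize ages per node, filter conflicting calibrations, and date with
#' [bladj()]. Returns the dated chronogram together with full provenance.
#'
#' @param query A `resolved_query` (see [make_query()]).
#' @param db A `chronogram_db`.
#' @param target A `phylo` topology; defaults to the query's own input
#'   topology when one was provided.
#' @param stat Summary age used for calibrations: `"median"` (default) or
#'   `"mean"`.
#' @param root_age Optional user root age (Myr); see [resolve_root_age()].
#' @return A `dated_chronogram`: list with `chronogram` (ultrametric
#'   `phylo`), `calibrations` (a `calibration_table`), `summaries`
#'   (`node_age_summary`), `set` (`calibration_set` with provenance),
#'   `search` (the `chrono_search`), `root_age`, and version strings.
#'   When the search finds nothing, a list with a `message` instead.
#' @export
date_topology <- function(query, db, target = attr(query, "topology"),
                          stat = c("median", "mean"), root_age = NULL) {
  stat <- match.arg(stat)
  if (is.null(target)) {
    stop("date_topology: no target topology (provide one or query with a tree)")
  }
  res <- search_chronograms(query, db)
  if (!length(res$matrices)) {
    return(structure(list(message = res$message, search = res),
                     class = "dated_chronogram"))
  }
  calib <- build_calibration_table(target, res)
  if (!nrow(calib)) {
    return(structure(list(message = attr(calib, "message"), search = res),
                     class = "dated_chronogram"))
  }
  summ <- summarize_node_ages(calib)
  set <- filter_calibrations(summ, target, stat = stat)
  ra <- resolve_root_age(set, user_root = root_age)
  chrono <- bladj(target, set, root_age = ra)
  structure(
    list(chronogram = chrono, calibrations = calib, summaries = summ,
         set = set, search = res, root_age = ra,
         db_version = db$version,
         taxonomy_version = attr(query, "taxonomy_version"),
         message = NULL),
    class = "dated_chronogram"
  )
}

#' @export
print.dated_chronogram <- function(x, ...) {
  if (!is.null(x$message)) {
    cat("<dated_chronogram>", x$message, "\n")
    return(invisible(x))
  }
  cat("<dated_chronogram>", ape::Ntip(x$chronogram), "tips, root age",
      signif(x$root_age, 6), "Myr;", sum(x$set$status == "used"),
      "calibration(s) used,", sum(x$set$status != "used"), "discarded\n")
  invisible(x)
}

#' Tidy a dated chronogram into per-node rows
#'
#' One row per internal node: node name, dated age, whether it was calibrated
#' and with what summary age, and its provenance status.
#'
#' @param x A `dated_chronogram`.
#' @param ... Unused.
#' @return A tibble (`node_name`, `node`, `age`, `calibrated`, `summary_age`,
#'   `status`).
#' @export
tidy.dated_chronogram <- function(x, ...) {
  if (!is.null(x$message)) return(tibble::tibble())
  nn <- node_names(x$chronogram)
  ages <- attr(x$chronogram, "ages")
  out <- dplyr::mutate(
    nn,
    age = ages[.data$node],
    calibrated = .data$node_name %in% x$set$node_name[x$set$status == "used"]
  )
  dplyr::left_join(out, x$set[, c("node_name", "age", "status")],
                   by = "node_name", suffix = c("", "_summary")) |>
    dplyr::rename(summary_age = "age_summary")
}

#' One-row summary of a dated chronogram
#'
#' @inheritParams tidy.dated_chronogram
#' @return A one-row tibble: tip and node counts, root age, numbers of
#'   calibrations used and discarded, and data-provenance versions.
#' @export
glance.dated_chronogram <- function(x, ...) {
  if (!is.null(x$message)) {
    return(tibble::tibble(n_tips = 0L, n_nodes = 0L, root_age = NA_real_,
                          n_calibrations = 0L, n_discarded = 0L,
                          db_version = NA_character_))
  }
  tibble::tibble(
    n_tips = ape::Ntip(x$chronogram),
    n_nodes = x$chronogram$Nnode,
    root_age = x$root_age,
    n_calibrations = sum(x$set$status == "used"),
    n_discarded = sum(x$set$status != "used"),
    db_version = x$db_version
  )
}

#' Generic tidy/glance (broom-style)
#'
#' @param x Object to tidy or glance.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot calibration ages per node
#'
#' Dot plot of congruified ages by node, overlaid with the per-node median —
#' a quick view of between-study age disparity.
#'
#' @param object A `calibration_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_table <- function(object, ...) {
  med <- dplyr::summarise(dplyr::group_by(object, .data$node_name),
                          median = stats::median(.data$age), .groups = "drop")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$node_name, y = .data$age)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = med,
                        ggplot2::aes(y = .data$median),
                        shape = 3, size = 4, colour = "firebrick") +
    ggplot2::labs(x = "node", y = "age (Myr)",
                  title = "Congruified node ages by target node",
                  subtitle = "crosses: per-node median") +
    ggplot2::theme_minimal()
}

#' Plot a dated chronogram's node ages
#'
#' Node ages against node names, distinguishing calibrated from interpolated
#' nodes.
#'
#' @param object A `dated_chronogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dated_chronogram <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$node_name, y = .data$age,
                                   colour = .data$calibrated)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "node", y = "age (Myr)",
                  title = "Dated node ages",
                  colour = "calibrated") +
    ggplot2::theme_minimal()
}
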