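#' Per-node summary statistics of calibration ages
#'
#' For every target node in a calibration table, summarizes its congruified
#' ages: min, first quartile, median, mean, third quartile, max (Myr),
#' sample variance (Myr^2, `n - 1` denominator) and standard deviation.
#' Quartiles use the linear-interpolation convention `h = (n - 1) p + 1`
#' ([stats::quantile()] type 7). A node with a single age reports all location
#' statistics at that age and `NA` variance.
#'
#' @param table A `calibration_table` (or any tibble with `node_name`, `age`).
#' @return A `node_age_summary` tibble: `node_name`, `n`, `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`, `variance`, `sd`; ordered by node name.
#' @export
summarize_node_ages <- function(table) {
  if (!nrow(table)) stop("summarize_node_ages: empty calibration table")
  out <- dplyr::summarise(
    dplyr::group_by(table, .data$node_name),
    n = dplyr::n(),
    min = min(.data$age),
    q1 = stats::quantile(.data$age, 0.25, names = FALSE, type = 7),
    median = stats::median(.data$age),
    mean = mean(.data$age),
    q3 = stats::quantile(.data$age, 0.75, names = FALSE, type = 7),
    max = max(.data$age),
    variance = if (dplyr::n() > 1) stats::var(.data$age) else NA_real_,
    sd = if (dplyr::n() > 1) stats::sd(.data$age) else NA_real_,
    .groups = "drop"
  )
  out <- dplyr::arrange(out, as.integer(sub("^n", "", .data$node_name)))
  structure(out, class = c("node_age_summary", class(out)),
            target = attr(table, "target"))
}

#' Write a node-age summary as CSV
#'
#' @param summary A `node_age_summary`.
#' @param path CSV file path.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}

# align a list of patristic matrices onto the union of their tips;
# returns a 3-d array tips x tips x matrix with NA where a pair is absent
align_matrices <- function(matrices) {
  tips <- sort(unique(unlist(lapply(matrices, rownames))))
  arr <- array(NA_real_, dim = c(length(tips), length(tips), length(matrices)),
               dimnames = list(tips, tips, names(matrices)))
  for (p in seq_along(matrices)) {
    m <- matrices[[p]]
    arr[rownames(m), colnames(m), p] <- m
  }
  arr
}

#' Cellwise summary of patristic matrices
#'
#' Summarizes a set of patristic matrices over the union of their tips with a
#' classic statistic, applied cellwise over the matrices containing both tips
#' of a cell. Cells with no data stay missing (`NA`); no imputation is done.
#'
#' @param matrices Named list of patristic matrices.
#' @param stat One of `"mean"`, `"median"`, `"min"`, `"max"`.
#' @return A symmetric matrix over the tip union with attribute
#'   `method = stat`.
#' @export
summary_matrix <- function(matrices, stat = c("mean", "median", "min", "max")) {
  stat <- match.arg(stat)
  if (!length(matrices)) stop("summary_matrix: no matrices")
  arr <- align_matrices(matrices)
  f <- switch(stat, mean = mean, median = stats::median, min = min, max = max)
  out <- apply(arr, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else f(x[!is.na(x)])
  })
  diag(out) <- 0
  attr(out, "method") <- stat
  out
}

#' Super-distance-matrix (SDM) summary
#'
#' Deforms patristic matrices by a positive scale factor each, chosen to
#' minimize the variance of scaled entries around their cellwise mean,
#' subject to the scales summing to the number of matrices, then averages the
#' scaled matrices cellwise. The objective
#' \deqn{\sum_p \sum_{(i,j)\ shared} (\alpha_p d_p(i,j) - \mu_{ij})^2,\quad
#'   \mu_{ij} = \mathrm{mean}_q\, \alpha_q d_q(i,j)}
#' is quadratic in the scales, so the constrained minimizer is obtained from
#' the KKT linear system exactly (no iteration needed).
#'
#' @param matrices Named list of >= 2 patristic matrices whose tip sets form
#'   a single grove under 2-overlap (checked; see [find_groves()]).
#' @return A symmetric summary matrix over the tip union, with attributes
#'   `method = "sdm"` and `alpha` (the scale factors).
#' @export
sdm_summary <- function(matrices) {
  P <- length(matrices)
  if (P < 2) stop("sdm_summary: need at least 2 matrices")
  tip_sets <- lapply(matrices, rownames)
  groves <- find_groves(tip_sets, n = 2)
  if (length(groves) > 1) {
    stop("sdm_summary: matrices do not form a single grove under 2-overlap; ",
         "the supertree reconstruction will fail. Run find_groves() and ",
         "summarize one grove at a time.")
  }
  arr <- align_matrices(matrices)
  ntip <- dim(arr)[1]
  # quadratic form: objective = alpha' A alpha with
  # A = sum over cells of D (I - 11'/k) D, D = diag of that cell's entries
  A <- matrix(0, P, P)
  for (i in seq_len(ntip - 1)) {
    for (j in (i + 1):ntip) {
      v <- arr[i, j, ]
      have <- which(!is.na(v))
      k <- length(have)
      if (k < 1) next
      d <- v[have]
      M <- diag(k) - matrix(1 / k, k, k)
      A[have, have] <- A[have, have] + d * M * rep(d, each = k)
    }
  }
  # KKT: minimize alpha' A alpha  s.t.  sum(alpha) = P
  K <- rbind(cbind(2 * A, rep(1, P)), c(rep(1, P), 0))
  sol <- tryCatch(solve(K, c(rep(0, P), P)), error = function(e) NULL)
  if (is.null(sol)) {
    # singular when the objective is flat in some direction; fall back to the
    # minimum-norm solution around equal weights
    sol <- c(qr.coef(qr(K), c(rep(0, P), P)))
    sol[is.na(sol)] <- 0
  }
  alpha <- sol[seq_len(P)]
  if (any(alpha <= 0)) {
    warning("sdm_summary: non-positive scale factor(s); inputs are strongly discordant")
  }
  scaled <- arr
  for (p in seq_len(P)) scaled[, , p] <- arr[, , p] * alpha[p]
  out <- apply(scaled, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x[!is.na(x)])
  })
  diag(out) <- 0
  attr(out, "method") <- "sdm"
  attr(out, "alpha") <- stats::setNames(alpha, names(matrices))
  out
}

# objective value of the SDM criterion at given scales (used by tests too)
sdm_objective <- function(matrices, alpha) {
  arr <- align_matrices(matrices)
  tot <- 0
  ntip <- dim(arr)[1]
  for (i in seq_len(ntip - 1)) {
    for (j in (i + 1):ntip) {
      v <- arr[i, j, ]
      have <- which(!is.na(v))
      if (!length(have)) next
      s <- v[have] * alpha[have]
      tot <- tot + sum((s - mean(s))^2)
    }
  }
  tot
}

#' Write a summary matrix as CSV
#'
#' Square CSV with a header row and first column of tip names.
#'
#' @param m A summary matrix.
#' @param path CSV file path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
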