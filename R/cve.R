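#' Build a coverage-vs-error-per-query curve at one rank
#'
#' Orders the scored reads from best to worst score (descending for
#' `higher_better` scores, ascending for E-value-like `lower_better`
#' scores) and accumulates, prefix by prefix, the error per query
#' (cumulative FP over the fixed total number of queries) against the
#' coverage (cumulative TP over the number of reads with an expected taxon
#' at the rank). Only reads carrying a score and a TP-or-FP label at the
#' rank enter the ranking; FN/TN/NA reads and unscored assignments
#' contribute to the denominators only. Ties on score are processed as one
#' block, so the curve is invariant to the input order of equal-scored
#' reads.
#'
#' @param labels Per-read labels from [label_reads()] (the `score` column
#'   is used for the ranking) or from a `tax_eval`'s `$labels`.
#' @param rank One of [tax_ranks()].
#' @param score_direction `"higher_better"` or `"lower_better"`.
#' @param method Method label for plots and cut-off tables.
#' @param total_queries,total_expected Overridable denominators; default to
#'   the truth-derived values (all reads, and reads with an expected taxon
#'   at the rank).
#' @return A `cve_curve` object: block-wise points tibble (`score`,
#'   `n_reads`, `cum_tp`, `cum_fp`, `cum_epq`, `cum_coverage`) plus the
#'   denominators and metadata.
#' @export
build_cve <- function(labels, rank, score_direction = "higher_better",
                      method = "method",
                      total_queries = NULL, total_expected = NULL) {
  rank <- match.arg(rank, tax_ranks())
  score_direction <- match.arg(score_direction, c("higher_better", "lower_better"))
  l <- labels[[rank]]
  total_queries <- total_queries %||% nrow(labels)
  total_expected <- total_expected %||% sum(!labels$is_shuffled & !is.na(l))

  in_rank <- !is.na(labels$score) & !is.na(l) & l %in% c("TP", "FP")
  if (!any(in_rank)) {
    warn(sprintf("no scored TP/FP reads at rank '%s': empty curve", rank))
    points <- tibble(score = numeric(), n_reads = integer(),
                     cum_tp = numeric(), cum_fp = numeric(),
                     cum_epq = numeric(), cum_coverage = numeric())
    return(new_cve_curve(points, rank, total_queries, total_expected,
                         score_direction, method))
  }
  sc <- labels$score[in_rank]
  is_tp <- l[in_rank] == "TP"

  blocks <- tibble(score = sc, tp = as.integer(is_tp), fp = as.integer(!is_tp)) |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(n_reads = dplyr::n(), tp = sum(.data$tp), fp = sum(.data$fp),
                     .groups = "drop")
  blocks <- if (score_direction == "higher_better") {
    dplyr::arrange(blocks, dplyr::desc(.data$score))
  } else {
    dplyr::arrange(blocks, .data$score)
  }
  points <- dplyr::mutate(
    blocks,
    cum_tp = cumsum(.data$tp),
    cum_fp = cumsum(.data$fp),
    cum_epq = .data$cum_fp / total_queries,
    cum_coverage = if (total_expected > 0) .data$cum_tp / total_expected else NA_real_
  ) |>
    dplyr::select("score", "n_reads", "cum_tp", "cum_fp", "cum_epq", "cum_coverage")
  new_cve_curve(points, rank, total_queries, total_expected,
                score_direction, method)
}

new_cve_curve <- function(points, rank, total_queries, total_expected,
                          score_direction, method) {
  structure(
    list(points = points, rank = rank,
         total_queries = total_queries, total_expected = total_expected,
         score_direction = score_direction, method = method),
    class = "cve_curve"
  )
}

#' @export
print.cve_curve <- function(x, ...) {
  cat(sprintf(
    "<cve_curve> %s, rank %s, %d score blocks, final EPQ %.4g, final coverage %.4g\n",
    x$method, x$rank, nrow(x$points),
    if (nrow(x$points)) tail(x$points$cum_epq, 1) else NA,
    if (nrow(x$points)) tail(x$points$cum_coverage, 1) else NA
  ))
  invisible(x)
}

#' @rdname build_cve
#' @param x A `cve_curve`.
#' @param ... Unused.
#' @method tidy cve_curve
#' @export
tidy.cve_curve <- function(x, ...) {
  dplyr::mutate(x$points, method = x$method, rank = x$rank, .before = 1)
}

#' Score cut-off at a target error rate
#'
#' Finds the longest best-score-first prefix of the curve (aligned to
#' tie blocks) whose cumulative error per query stays at or below
#' `target_error`. The cut-off is the worst score admitted by that prefix
#' and the coverage is the prefix's cumulative coverage. If even the
#' best-scored block exceeds the target, `reached` is `FALSE` and coverage
#' is 0.
#'
#' @param curve A `cve_curve`.
#' @param target_error Target error-per-query rate in (0, 1), e.g. 0.01,
#'   0.05, 0.10.
#' @return A one-row tibble: `method`, `rank`, `target_error`,
#'   `score_cutoff`, `coverage`, `reached`.
#' @export
cutoff_at_error <- function(curve, target_error) {
  stopifnot(inherits(curve, "cve_curve"),
            length(target_error) == 1L, target_error > 0, target_error < 1)
  p <- curve$points
  admissible <- which(p$cum_epq <= target_error)
  if (nrow(p) == 0L || length(admissible) == 0L) {
    return(tibble(method = curve$method, rank = curve$rank,
                  target_error = target_error,
                  score_cutoff = NA_real_, coverage = 0, reached = FALSE))
  }
  # cum_epq is non-decreasing, so the admissible prefix is contiguous
  k <- max(admissible)
  tibble(
    method = curve$method, rank = curve$rank, target_error = target_error,
    score_cutoff = p$score[k], coverage = p$cum_coverage[k], reached = TRUE
  )
}

#' Cut-off table over several curves and error targets
#'
#' The machine-readable cut-off table: one row per curve and target error
#' rate (defaults 1%, 5% and 10%).
#'
#' @param curves A `cve_curve` or list of them.
#' @param targets Numeric vector of target error rates.
#' @return A tibble as in [cutoff_at_error()].
#' @export
cve_cutoffs <- function(curves, targets = c(0.01, 0.05, 0.10)) {
  if (inherits(curves, "cve_curve")) curves <- list(curves)
  purrr::map_dfr(curves, function(cv)
    purrr::map_dfr(targets, function(t) cutoff_at_error(cv, t)))
}

#' @rdname build_cve
#' @param object A `cve_curve`.
#' @param targets Error rates to mark with vertical guides.
#' @method autoplot cve_curve
#' @export
autoplot.cve_curve <- function(object, targets = c(0.01, 0.05, 0.10), ...) {
  plot_cve(list(object), targets = targets)
}

#' Plot coverage-vs-error curves
#'
#' Error per query on the x axis, coverage on the y axis, one line per
#' method, with vertical guides at the target error rates.
#'
#' @param curves A `cve_curve` or list of them (same rank).
#' @param targets Error rates marked with vertical dashed guides.
#' @return A ggplot object.
#' @export
plot_cve <- function(curves, targets = c(0.01, 0.05, 0.10)) {
  if (inherits(curves, "cve_curve")) curves <- list(curves)
  if (length(curves) == 0L) abort("at least one curve is required")
  df <- purrr::map_dfr(curves, tidy)
  rank <- curves[[1]]$rank
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cum_epq, y = .data$cum_coverage,
                                   colour = .data$method)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_vline(xintercept = targets, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Error per query (EPQ)", y = "Coverage",
                  title = sprintf("Coverage vs error per query (%s)", rank),
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Export a CVE plot to file
#'
#' @inheritParams plot_cve
#' @param path Output path; format chosen by extension (`.png`, `.svg`,
#'   `.pdf`).
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
export_cve_plot <- function(curves, path, targets = c(0.01, 0.05, 0.10),
                            width = 7, height = 5) {
  g <- plot_cve(curves, targets = targets)
  ggplot2::ggsave(path, plot = g, width = width, height = height, dpi = 150)
  invisible(path)
}
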