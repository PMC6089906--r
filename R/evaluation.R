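#' Label one read at the eight ranks
#'
#' Compares an expected eight-rank lineage against an assigned one, rank by
#' rank from domain to subspecies, producing one of `TP`, `FP`, `FN`, `TN`
#' or `NA` per rank:
#'
#' * real (non-shuffled) read — expected slot empty: `NA` (that rank simply
#'   does not exist for the read); expected filled and assigned equal: `TP`;
#'   expected filled, assigned empty: `FN` (non-classification); expected
#'   filled, assigned different: `FP` (misclassification). Once a rank is
#'   `FP`, every deeper evaluated rank is `FP` as well — a wrong genus makes
#'   the species call wrong no matter what it says.
#' * shuffled read — any assigned slot is `FP`; an empty one is `TN`.
#'
#' So a read correctly classified down to family but unclassified below
#' yields `TP,TP,TP,TP,TP,FN,FN,FN`, while a wrong genus under a correct
#' family yields `TP,TP,TP,TP,TP,FP,FP,FP`.
#'
#' @param expected Integer vector of length 8 (the expected lineage slots,
#'   `NA` = empty); ignored for shuffled reads.
#' @param assigned Integer vector of length 8, or `NULL` for an unclassified
#'   read.
#' @param is_shuffled Is the read a shuffled true-negative sequence?
#' @return Character vector of length 8 over `TP`/`FP`/`FN`/`TN`/`NA`.
#' @export
label_read <- function(expected, assigned = NULL, is_shuffled = FALSE) {
  if (is.null(assigned)) assigned <- rep(NA_integer_, 8L)
  stopifnot(length(expected) == 8L, length(assigned) == 8L)
  E <- matrix(as.integer(expected), nrow = 1)
  A <- matrix(as.integer(assigned), nrow = 1)
  lab <- label_matrix(E, A, shuffled = is_shuffled, unresolved = FALSE)
  stats::setNames(lab[1, ], tax_ranks())
}

# Vectorized labeling over n reads. E, A: n x 8 integer matrices (NA =
# empty slot); shuffled, unresolved: logical n-vectors. An unresolved
# assignment is a classification with unknown lineage: FP wherever a label
# can be wrong.
label_matrix <- function(E, A, shuffled, unresolved) {
  n <- nrow(E)
  shuffled <- rep_len(shuffled, n)
  unresolved <- rep_len(unresolved, n)
  lab <- matrix(NA_character_, n, 8L, dimnames = list(NULL, tax_ranks()))

  seen_fp <- rep(FALSE, n)
  for (j in seq_len(8L)) {
    e <- E[, j]
    a <- A[, j]
    col <- rep(NA_character_, n)

    real <- !shuffled
    has_e <- real & !is.na(e)
    col[has_e & !unresolved & is.na(a)] <- "FN"
    col[has_e & !is.na(a) & a == e] <- "TP"
    col[has_e & ((!is.na(a) & a != e) | unresolved)] <- "FP"
    # FP propagates leaf-ward over every evaluated rank
    col[has_e & seen_fp] <- "FP"

    shuf <- shuffled
    col[shuf & (!is.na(a) | unresolved)] <- "FP"
    col[shuf & is.na(a) & !unresolved] <- "TN"

    seen_fp <- seen_fp | (!is.na(col) & col == "FP")
    lab[, j] <- col
  }
  lab
}

#' Label every read of a truth set at the eight ranks
#'
#' Joins a truth set with an assignment set on `read_id` (reads absent from
#' the assignments are unclassified), homogenizes both sides onto the eight
#' canonical ranks and applies [label_read()]'s rules to every read.
#'
#' @param truth Truth tibble from [read_truth()] or a library builder.
#' @param assignments A `tax_assignments` tibble.
#' @param db The `tax_db` both lineages are resolved against.
#' @param strain_as_subspecies Passed to [homogenize()].
#' @return A tibble with `read_id`, `is_shuffled`, `score`, and one
#'   character label column per rank.
#' @export
label_reads <- function(truth, assignments, db, strain_as_subspecies = FALSE) {
  stopifnot(inherits(db, "tax_db"))
  policy <- attr(assignments, "unresolved_policy") %||% "fp"
  idx <- match(truth$read_id, assignments$read_id)
  assigned_taxid <- assignments$taxid[idx]
  unresolved <- !is.na(idx) & assignments$unresolved[idx]
  if (policy == "unclassified") unresolved[] <- FALSE
  score <- assignments$score[idx]

  E <- lineage_rows(db, ifelse(truth$is_shuffled, NA_integer_, truth$expected_taxid),
                    strain_as_subspecies = strain_as_subspecies)
  A <- lineage_rows(db, assigned_taxid, strain_as_subspecies = strain_as_subspecies)
  lab <- label_matrix(E, A, shuffled = truth$is_shuffled, unresolved = unresolved)
  dplyr::bind_cols(
    tibble(read_id = truth$read_id, is_shuffled = truth$is_shuffled, score = score),
    as_tibble(as.data.frame(lab, stringsAsFactors = FALSE))
  )
}

#' Aggregate per-read labels into per-rank confusion counts
#'
#' @param labels Tibble from [label_reads()] (or rows with the eight rank
#'   label columns).
#' @param na_as_tn Count ranks where the expected lineage has no taxon as
#'   true negatives instead of excluding them. Off by default: the
#'   true-negative class is defined by shuffled sequences, and counting
#'   structural lineage gaps as TN would inflate specificity.
#' @return A tibble with one row per rank: `rank`, `tp`, `fp`, `fn`, `tn`,
#'   `na`, `total_queries`, `total_expected`.
#' @export
aggregate_labels <- function(labels, na_as_tn = FALSE) {
  n <- nrow(labels)
  purrr::map_dfr(tax_ranks(), function(rk) {
    l <- labels[[rk]]
    na_n <- sum(is.na(l))
    tn <- sum(l == "TN", na.rm = TRUE)
    if (na_as_tn) {
      tn <- tn + na_n
      na_n <- 0L
    }
    tibble(
      rank = rk,
      tp = sum(l == "TP", na.rm = TRUE),
      fp = sum(l == "FP", na.rm = TRUE),
      fn = sum(l == "FN", na.rm = TRUE),
      tn = tn,
      na = na_n,
      total_queries = n,
      # reads whose expected lineage has a taxon at this rank: every
      # non-shuffled read not labeled NA there
      total_expected = sum(!labels$is_shuffled & !is.na(l))
    )
  })
}

#' Classification metrics from per-rank confusion counts
#'
#' Computes, per rank:
#' \deqn{EPQ = FP / total\ queries}
#' \deqn{Coverage = TP / total\ expected}
#' \deqn{Sensitivity = TP / (TP + FN)}
#' \deqn{Specificity = TN / (TN + FP)}
#' \deqn{Accuracy = (TP + TN) / (TP + FP + FN + TN)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#'
#' `NA`-labeled ranks are excluded from every formula. A metric whose
#' denominator is zero is reported as `NA` (undefined), except MCC with a
#' zero factor, which follows the common convention of 0 with
#' `mcc_degenerate = TRUE`.
#'
#' @param conf Confusion tibble from [aggregate_labels()], or any tibble
#'   with columns `tp`, `fp`, `fn`, `tn`, `total_queries`, `total_expected`.
#' @return `conf` with columns `epq`, `coverage`, `sensitivity`,
#'   `specificity`, `accuracy`, `mcc`, `mcc_degenerate` appended.
#' @export
rank_metrics <- function(conf) {
  tp <- as.numeric(conf$tp); fp <- as.numeric(conf$fp)
  fn <- as.numeric(conf$fn); tn <- as.numeric(conf$tn)
  tq <- as.numeric(conf$total_queries)
  te <- as.numeric(conf$total_expected)

  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)

  mcc_den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- mcc_den2 == 0
  mcc <- ifelse(degenerate, 0, (tp * tn - fp * fn) / sqrt(mcc_den2))

  dplyr::mutate(
    conf,
    epq = safe_div(fp, tq),
    coverage = safe_div(tp, te),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = safe_div(tp + tn, tp + fp + fn + tn),
    mcc = mcc,
    mcc_degenerate = degenerate
  )
}

#' Evaluate an assignment set against a truth set
#'
#' One-call wrapper: labels every read ([label_reads()]), aggregates
#' confusion counts ([aggregate_labels()]) and computes metrics
#' ([rank_metrics()]). The result supports [tidy()] (per-rank metric
#' tibble), [glance()] (one-row summary) and keeps the per-read labels for
#' curve building.
#'
#' @inheritParams label_reads
#' @param na_as_tn See [aggregate_labels()].
#' @param replicate Optional replicate label carried into tidy output.
#' @return A `tax_eval` object.
#' @export
evaluate_assignments <- function(truth, assignments, db, na_as_tn = FALSE,
                                 strain_as_subspecies = FALSE,
                                 replicate = NA_character_) {
  labels <- label_reads(truth, assignments, db,
                        strain_as_subspecies = strain_as_subspecies)
  conf <- aggregate_labels(labels, na_as_tn = na_as_tn)
  structure(
    list(
      labels = labels,
      metrics = rank_metrics(conf),
      method = attr(assignments, "method_name") %||% "method",
      score_direction = attr(assignments, "score_direction") %||% "higher_better",
      replicate = replicate
    ),
    class = "tax_eval"
  )
}

#' @export
print.tax_eval <- function(x, ...) {
  cat(sprintf("<tax_eval> method '%s', %d reads\n", x$method, nrow(x$labels)))
  print(dplyr::select(x$metrics, "rank", "tp", "fp", "fn", "tn", "na",
                      "epq", "coverage", "mcc"))
  invisible(x)
}

#' @rdname evaluate_assignments
#' @param x A `tax_eval` object.
#' @param ... Unused.
#' @method tidy tax_eval
#' @export
tidy.tax_eval <- function(x, ...) {
  dplyr::mutate(x$metrics, method = x$method, replicate = x$replicate,
                .before = 1)
}

#' @rdname evaluate_assignments
#' @method glance tax_eval
#' @export
glance.tax_eval <- function(x, ...) {
  m <- x$metrics
  tibble(
    method = x$method,
    n_reads = m$total_queries[1],
    n_shuffled = sum(x$labels$is_shuffled),
    mean_mcc = mean(m$mcc, na.rm = TRUE),
    mean_epq = mean(m$epq, na.rm = TRUE),
    genus_mcc = m$mcc[m$rank == "genus"],
    species_mcc = m$mcc[m$rank == "species"]
  )
}

#' Mean and standard deviation of metrics across replicate libraries
#'
#' @param records A list of per-replicate metric tibbles (from
#'   [rank_metrics()] or `tidy()` on a `tax_eval`), all covering the same
#'   ranks. At least two replicates are required; the spread uses the sample
#'   (n - 1) standard deviation, treating the replicates as draws of a
#'   stochastic library generator. Undefined (`NA`) metric values are
#'   excluded pairwise.
#' @param metrics Which metric columns to summarise.
#' @return A tibble: `rank`, `metric`, `n`, `mean`, `sd`.
#' @export
summarize_replicates <- function(records,
                                 metrics = c("epq", "coverage", "sensitivity",
                                             "specificity", "accuracy", "mcc")) {
  if (!is.list(records) || inherits(records, "data.frame")) {
    abort("`records` must be a list of per-replicate metric tables")
  }
  if (length(records) < 2L) abort(">=2 replicates required")
  ranks <- lapply(records, function(r) sort(unique(r$rank)))
  if (length(unique(ranks)) != 1L) abort("replicates cover different rank sets")
  long <- purrr::imap_dfr(records, function(r, i) {
    tidyr::pivot_longer(
      dplyr::select(r, "rank", dplyr::all_of(metrics)),
      -"rank", names_to = "metric", values_to = "value"
    ) |> dplyr::mutate(replicate = i)
  })
  long |>
    dplyr::group_by(.data$rank, .data$metric) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(rank = factor(.data$rank, levels = tax_ranks())) |>
    dplyr::arrange(.data$rank, .data$metric) |>
    dplyr::mutate(rank = as.character(.data$rank))
}

#' Observed vs expected taxon abundance at one rank
#'
#' Relative abundance profile of the classifications at a given rank,
#' compared against the truth. The observed abundance of a taxon is the
#' fraction of classified reads whose homogenized assigned lineage carries
#' it at that rank; the expected abundance is computed identically from the
#' truth (shuffled reads are excluded from the expectation but enter the
#' observation if a classifier annotated them). Taxa observed but absent
#' from the expected set are flagged `is_other` — the "not expected"
#' category — with per-taxon detail retained.
#'
#' @inheritParams label_reads
#' @param rank One of [tax_ranks()].
#' @return A tibble: `rank`, `taxid`, `taxon`, `observed`, `expected`,
#'   `bias` (= observed - expected), `is_other`.
#' @export
abundance_profile <- function(assignments, truth, db, rank = "phylum") {
  rank <- match.arg(rank, tax_ranks())
  slot <- rank_slot(rank)

  A <- lineage_rows(db, assignments$taxid)[, slot]
  classified <- !is.na(assignments$taxid)
  obs_tab <- table(A[classified & !is.na(A)])
  n_classified <- sum(classified)
  observed <- if (n_classified > 0) as.numeric(obs_tab) / n_classified else numeric()

  real <- !truth$is_shuffled
  E <- lineage_rows(db, truth$expected_taxid)[, slot]
  exp_tab <- table(E[real & !is.na(E)])
  n_real <- sum(real)
  expected <- if (n_real > 0) as.numeric(exp_tab) / n_real else numeric()

  all_ids <- sort(unique(c(as.integer(names(obs_tab)), as.integer(names(exp_tab)))))
  obs_v <- stats::setNames(rep(0, length(all_ids)), all_ids)
  exp_v <- obs_v
  obs_v[names(obs_tab)] <- observed
  exp_v[names(exp_tab)] <- expected

  names_v <- db$nodes$name[db$index[as.character(all_ids)]]
  tibble(
    rank = rank,
    taxid = all_ids,
    taxon = ifelse(is.na(names_v), as.character(all_ids), names_v),
    observed = unname(obs_v),
    expected = unname(exp_v),
    bias = unname(obs_v - exp_v),
    is_other = !(all_ids %in% as.integer(names(exp_tab)))
  )
}

#' Plot an abundance-bias profile
#'
#' Bar chart of observed relative abundance per taxon at one rank with the
#' expected abundance overlaid, the usual way per-rank annotation biases
#' are displayed.
#'
#' @param profile Tibble from [abundance_profile()].
#' @return A ggplot object.
#' @export
plot_abundance_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = stats::reorder(.data$taxon, -.data$expected))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed, fill = .data$is_other)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), shape = 95, size = 8,
                        colour = "black") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"),
                               name = "not expected") +
    ggplot2::labs(x = NULL, y = "relative abundance",
                  title = sprintf("Observed vs expected abundance (%s)",
                                  profile$rank[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write tidy metric and abundance tables
#'
#' @param x A `tax_eval`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  stopifnot(inherits(x, "tax_eval"))
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
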