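test_that("per-read labeling distinguishes non-classification from misclassification", {
  db <- fixture_db()
  expected <- fixture_lineage(22L) # full 8-slot lineage

  # correct down to family, unclassified below
  fam <- label_read(expected, fixture_lineage(10L))
  expect_equal(unname(fam), c(rep("TP", 5), rep("FN", 3)))

  # correct family but wrong genus: FP propagates to every deeper rank
  wrong_genus <- fixture_lineage(14L)
  fp <- label_read(expected, wrong_genus)
  expect_equal(unname(fp), c(rep("TP", 5), rep("FP", 3)))

  # shuffled read left unclassified is all TN
  expect_equal(unname(label_read(rep(NA_integer_, 8), NULL, is_shuffled = TRUE)),
               rep("TN", 8))
  # shuffled read annotated at phylum level only
  shuf <- label_read(rep(NA_integer_, 8), fixture_lineage(4L), is_shuffled = TRUE)
  expect_equal(unname(shuf), c("FP", "FP", rep("TN", 6)))

  # ranks absent from the expected lineage are NA, not TN
  sp_only <- label_read(fixture_lineage(17L), fixture_lineage(17L))
  expect_equal(unname(sp_only), c(rep("TP", 7), NA))
})

test_that("aggregation counts the worked examples by hand", {
  db <- fixture_db()
  truth <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    expected_taxid = c(22L, 22L, NA),
    is_shuffled = c(FALSE, FALSE, TRUE)
  )
  asn <- assignment_set(c("r1", "r2", "r3"),
                        taxid = c(10L, 14L, NA), score = c(0.9, 0.8, NA))
  labels <- label_reads(truth, asn, db)
  conf <- aggregate_labels(labels)
  genus <- conf[conf$rank == "genus", ]
  expect_equal(unlist(genus[c("tp", "fp", "fn", "tn", "na")]),
               c(tp = 0L, fp = 1L, fn = 1L, tn = 1L, na = 0L))
  expect_equal(genus$total_queries, 3L)
  expect_equal(genus$total_expected, 2L)

  # empty input gives all-zero matrices
  empty <- aggregate_labels(label_reads(truth[0, ], assignment_set(character()), db))
  expect_true(all(empty[c("tp", "fp", "fn", "tn", "na")] == 0))

  # closure under repetition: identical correct reads are pure TP
  n <- 100L
  truth_n <- tibble::tibble(read_id = sprintf("x%03d", 1:n),
                            expected_taxid = 22L, is_shuffled = FALSE)
  asn_n <- assignment_set(truth_n$read_id, taxid = 22L, score = 1)
  conf_n <- aggregate_labels(label_reads(truth_n, asn_n, db))
  expect_true(all(conf_n$tp == n))
})

test_that("reads missing from assignments and unresolved labels follow policy", {
  db <- fixture_db()
  truth <- tibble::tibble(read_id = c("a", "b"), expected_taxid = c(17L, NA),
                          is_shuffled = c(FALSE, TRUE))
  # nothing assigned at all: FN for the real read, TN for the shuffled one
  labels <- label_reads(truth, assignment_set(character()), db)
  expect_equal(labels$genus, c("FN", "TN"))
  expect_equal(labels$domain, c("FN", "TN"))
  expect_equal(labels[labels$is_shuffled, ][["phylum"]], "TN")

  # unresolved labels count as classifications (false positives) by default
  tbl <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tunidentified_bacterioplankton\t0.9",
               "b\tunidentified_bacterioplankton\t0.9"), tbl)
  asn_fp <- read_assignments(tbl, dialect(label_kind = "name"), db)
  lab_fp <- label_reads(truth, asn_fp, db)
  expect_equal(lab_fp$species[1], "FP")
  expect_true(all(unlist(lab_fp[2, tax_ranks()]) == "FP"))

  asn_un <- read_assignments(tbl, dialect(label_kind = "name",
                                          unresolved = "unclassified"), db)
  lab_un <- label_reads(truth, asn_un, db)
  expect_equal(lab_un$species[1], "FN")
  expect_true(all(unlist(lab_un[2, tax_ranks()]) == "TN"))
})

test_that("metrics match their defining formulas, with explicit degenerate flags", {
  # balanced counts: MCC exactly zero
  bal <- rank_metrics(tibble::tibble(rank = "genus", tp = 25, fp = 25, fn = 25,
                                     tn = 25, na = 0, total_queries = 100,
                                     total_expected = 50))
  expect_equal(bal$mcc, 0)
  expect_false(bal$mcc_degenerate)

  # perfect classifier
  perf <- rank_metrics(tibble::tibble(rank = "genus", tp = 10, fp = 0, fn = 0,
                                      tn = 5, na = 0, total_queries = 15,
                                      total_expected = 10))
  expect_equal(perf$mcc, 1)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$epq, 0)
  expect_equal(perf$coverage, 1)

  # independently hand-computed mixed case
  mix <- rank_metrics(tibble::tibble(rank = "genus", tp = 90, fp = 10, fn = 20,
                                     tn = 80, na = 0, total_queries = 200,
                                     total_expected = 110))
  expect_equal(mix$epq, 0.05)
  expect_equal(mix$coverage, 90 / 110, tolerance = 1e-12)
  expect_equal(mix$mcc, 7000 / sqrt(100 * 110 * 90 * 100), tolerance = 1e-12)
  expect_equal(round(mix$mcc, 4), 0.7035)

  # zero denominators are undefined, not zero; degenerate MCC flagged
  deg <- rank_metrics(tibble::tibble(rank = "genus", tp = 0, fp = 0, fn = 0,
                                     tn = 5, na = 3, total_queries = 8,
                                     total_expected = 0))
  expect_true(is.na(deg$coverage))
  expect_true(is.na(deg$sensitivity))
  expect_equal(deg$mcc, 0)
  expect_true(deg$mcc_degenerate)
})

test_that("every metric agrees with an independent confusion oracle on random label sets", {
  db <- fixture_db()
  withr::local_seed(421)
  for (rep in 1:25) {
    pair <- random_pair(db, n = 60)
    labels <- label_reads(pair$truth, pair$assignments, db)
    metrics <- rank_metrics(aggregate_labels(labels))
    for (rk in tax_ranks()) {
      row <- metrics[metrics$rank == rk, ]
      orc <- oracle_metrics(labels[[rk]], row$total_queries, row$total_expected)
      for (m in names(orc)) {
        if (is.na(orc[[m]])) expect_true(is.na(row[[m]]))
        else expect_equal(row[[m]], orc[[m]], tolerance = 1e-12)
      }
    }
  }
})

test_that("the label-pattern invariant holds over randomized truth/assignment pairs", {
  db <- fixture_db()
  withr::local_seed(99)
  for (rep in 1:20) {
    pair <- random_pair(db, n = 50)
    labels <- label_reads(pair$truth, pair$assignments, db)
    mat <- as.matrix(labels[, tax_ranks()])
    for (i in seq_len(nrow(mat))) {
      expect_true(label_pattern_ok(mat[i, ], labels$is_shuffled[i]))
    }
  }
})

test_that("EPQ and coverage recover integer counts exactly", {
  db <- fixture_db()
  withr::local_seed(7)
  pair <- random_pair(db, n = 200)
  metrics <- rank_metrics(aggregate_labels(label_reads(pair$truth, pair$assignments, db)))
  expect_equal(metrics$epq * metrics$total_queries, as.numeric(metrics$fp),
               tolerance = 1e-9)
  cov_tp <- metrics$coverage * metrics$total_expected
  expect_equal(cov_tp[!is.na(cov_tp)], as.numeric(metrics$tp[!is.na(cov_tp)]),
               tolerance = 1e-9)
})

test_that("replicate summaries use the sample standard deviation", {
  base <- tibble::tibble(rank = tax_ranks(), tp = 1, fp = 0, fn = 0, tn = 1,
                         na = 0, total_queries = 2, total_expected = 1)
  m1 <- rank_metrics(dplyr::mutate(base))
  reps <- list(m1, m1, m1)
  s <- summarize_replicates(reps)
  expect_true(all(s$sd == 0))

  covs <- c(0.8, 0.9, 1.0)
  recs <- lapply(covs, function(cv) dplyr::mutate(m1, coverage = cv))
  s2 <- summarize_replicates(recs)
  cov_rows <- s2[s2$metric == "coverage", ]
  expect_equal(unique(cov_rows$mean), 0.9, tolerance = 1e-12)
  expect_equal(unique(cov_rows$sd), 0.1, tolerance = 1e-12)

  expect_error(summarize_replicates(list(m1)), "2 replicates")
  m_bad <- m1[m1$rank != "genus", ]
  expect_error(summarize_replicates(list(m1, m_bad)), "rank")
})

test_that("abundance profiles compare observed and expected fractions", {
  db <- fixture_db()
  # identical assignments: zero bias everywhere, nothing unexpected
  truth <- tibble::tibble(read_id = sprintf("r%02d", 1:20),
                          expected_taxid = rep(c(17L, 21L), each = 10),
                          is_shuffled = FALSE)
  same <- assignment_set(truth$read_id, taxid = truth$expected_taxid, score = 1)
  p0 <- abundance_profile(same, truth, db, rank = "phylum")
  expect_true(all(p0$bias == 0))
  expect_false(any(p0$is_other))

  # 12 vs 8 reads assigned across two 10/10 phyla: bias +0.10 / -0.10
  shifted <- assignment_set(truth$read_id,
                            taxid = c(rep(17L, 12), rep(21L, 8)), score = 1)
  p1 <- abundance_profile(shifted, truth, db, rank = "phylum")
  expect_equal(p1$bias[p1$taxid == 4L], 0.10, tolerance = 1e-12)
  expect_equal(p1$bias[p1$taxid == 5L], -0.10, tolerance = 1e-12)

  # a shuffled read classified into an unexpected phylum lands under "other"
  truth2 <- dplyr::bind_rows(truth,
    tibble::tibble(read_id = "shuf1", expected_taxid = NA_integer_,
                   is_shuffled = TRUE))
  asn2 <- assignment_set(truth2$read_id,
                         taxid = c(truth$expected_taxid, 35L), score = 1)
  p2 <- abundance_profile(asn2, truth2, db, rank = "phylum")
  other <- p2[p2$is_other, ]
  expect_equal(other$taxid, 30L)
  expect_gt(other$observed, 0)
  expect_equal(other$expected, 0)
})

test_that("tax_eval objects expose tidy and glance summaries", {
  db <- fixture_db()
  truth <- tibble::tibble(read_id = c("a", "b", "c"),
                          expected_taxid = c(22L, 22L, NA),
                          is_shuffled = c(FALSE, FALSE, TRUE))
  asn <- assignment_set(truth$read_id, taxid = c(22L, 22L, NA),
                        score = c(0.9, 0.8, NA), method_name = "demo")
  ev <- evaluate_assignments(truth, asn, db)
  td <- tidy(ev)
  expect_equal(nrow(td), 8L)
  expect_equal(unique(td$method), "demo")
  gl <- glance(ev)
  expect_equal(gl$n_reads, 3L)
  expect_equal(gl$genus_mcc, 1)
})
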