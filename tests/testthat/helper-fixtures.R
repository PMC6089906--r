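# Shared fixtures and independent oracles for the suite.

fixture_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      db <<- load_taxdump(
        system.file("extdata/mini_taxonomy_nodes.tsv", package = "taxabench"),
        system.file("extdata/mini_taxonomy_names.tsv", package = "taxabench")
      )
    }
    db
  }
})

# eight-slot lineage of one taxid as a plain integer vector
fixture_lineage <- function(taxid, db = fixture_db()) {
  unlist(homogenize(db, taxid)[1, tax_ranks()])
}

# Independent confusion-matrix oracle: counts a flat label vector by
# explicit looping and evaluates the metric formulas directly, sharing no
# code with rank_metrics().
oracle_metrics <- function(labels, total_queries, total_expected) {
  tp <- fp <- fn <- tn <- 0
  for (l in labels) {
    if (is.na(l)) next
    if (l == "TP") tp <- tp + 1
    if (l == "FP") fp <- fp + 1
    if (l == "FN") fn <- fn + 1
    if (l == "TN") tn <- tn + 1
  }
  den <- function(x) if (x > 0) x else NA_real_
  mccd <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(
    epq = fp / den(total_queries),
    coverage = tp / den(total_expected),
    sensitivity = tp / den(tp + fn),
    specificity = tn / den(tn + fp),
    accuracy = (tp + tn) / den(tp + fp + fn + tn),
    mcc = if (mccd == 0) 0 else (tp * tn - fp * fn) / sqrt(mccd)
  )
}

# Brute-force cut-off oracle: enumerate every block-aligned prefix.
oracle_cutoff <- function(curve, target) {
  p <- curve$points
  best <- NULL
  for (k in seq_len(nrow(p))) {
    if (p$cum_epq[k] <= target) best <- k
  }
  if (is.null(best)) {
    list(reached = FALSE, coverage = 0, score_cutoff = NA_real_)
  } else {
    list(reached = TRUE, coverage = p$cum_coverage[best],
         score_cutoff = p$score[best])
  }
}

# label-pattern invariant: real reads are TP* then (FP* | FN*) over the
# evaluated (non-NA) ranks; shuffled reads carry only FP and TN
label_pattern_ok <- function(labels_row, is_shuffled) {
  l <- labels_row[!is.na(labels_row)]
  if (is_shuffled) return(all(l %in% c("FP", "TN")))
  collapsed <- paste(l, collapse = "")
  grepl("^(TP)*((FP)*|(FN)*)$", collapsed)
}

# small randomized truth/assignment pair over a taxonomy's nodes
random_pair <- function(db, n, p_shuffled = 0.2, p_unclassified = 0.2) {
  leafish <- db$nodes$taxid[!is.na(db$lineage[, "species"])]
  shuf <- runif(n) < p_shuffled
  truth <- tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    expected_taxid = ifelse(shuf, NA_integer_,
                            sample(leafish, n, replace = TRUE)),
    is_shuffled = shuf
  )
  assigned <- sample(db$nodes$taxid[db$nodes$taxid != db$root_id], n, replace = TRUE)
  assigned[runif(n) < p_unclassified] <- NA_integer_
  asn <- assignment_set(truth$read_id, taxid = assigned,
                        score = round(runif(n), 2))
  list(truth = truth, assignments = asn)
}
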