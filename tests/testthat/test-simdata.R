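# small branching used throughout to keep runtimes low
small_branching <- c(1L, 2L, 1L, 1L, 1L, 2L, 2L, 1L)

test_that("mock taxonomies are balanced, complete and deterministic", {
  mt <- make_mock_taxonomy(small_branching, dir = withr::local_tempdir())
  expect_equal(nrow(mt$leaves), prod(small_branching))
  expect_equal(mt$db$root_id, 1L)
  # every leaf homogenizes to a full 8-slot lineage
  h <- homogenize(mt$db, mt$leaves$taxid)
  expect_false(anyNA(as.matrix(h[, tax_ranks()])))

  chain <- make_mock_taxonomy(rep(1L, 8), dir = withr::local_tempdir())
  expect_equal(nrow(chain$db$nodes), 9L) # root + one node per rank
  expect_equal(nrow(chain$leaves), 1L)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_mock_taxonomy(small_branching, dir = d1)
  make_mock_taxonomy(small_branching, dir = d2)
  expect_identical(readLines(file.path(d1, "nodes.tsv")),
                   readLines(file.path(d2, "nodes.tsv")))
  expect_identical(readLines(file.path(d1, "names.tsv")),
                   readLines(file.path(d2, "names.tsv")))
})

test_that("templates embed primer sites and amplify within the configured bounds", {
  mt <- make_mock_taxonomy(small_branching, dir = withr::local_tempdir())
  primers <- primer_pair()
  tmpl <- make_templates(mt$db, primers, insert_range = c(400L, 460L), seed = 3)
  expect_equal(length(tmpl$sequences), nrow(mt$leaves))

  footprints <- nchar(primers$forward) + nchar(primers$reverse)
  for (s in tmpl$sequences) {
    hits <- insilico_pcr(s, primers)
    expect_gte(nrow(hits), 1L)
    len <- nchar(hits$sequence[1])
    expect_gte(len, 400L + footprints)
    expect_lte(len, 460L + footprints)
    expect_equal(hits$end[1] - hits$start[1], len)
  }

  again <- make_templates(mt$db, primers, insert_range = c(400L, 460L), seed = 3)
  expect_identical(tmpl$sequences, again$sequences)
})

test_that("in-silico PCR honours IUPAC degeneracy, orientation and coordinates", {
  p <- primer_pair("CCTACGGGAGGC", "GGATTAGATACCC", max_mismatch = 0L)
  # no sites at all
  expect_equal(nrow(insilico_pcr(strrep("AT", 200), p)), 0L)

  # constructed site: forward at 1-based 51, reverse-complement site ending at 500
  fwd_site <- "CCTACGGGAGGC"
  rev_site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("GGATTAGATACCC")))
  withr::local_seed(8)
  left <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  mid_len <- 500 - 50 - nchar(fwd_site) - nchar(rev_site)
  mid <- paste(sample(c("A", "G", "T"), mid_len, TRUE), collapse = "") # no C: no spurious sites
  right <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  template <- paste0(left, fwd_site, mid, rev_site, right)
  hits <- insilico_pcr(template, p)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 50L)
  expect_equal(hits$end, 500L)
  expect_equal(hits$sequence, substring(template, 51, 500))

  # N matches any base with zero mismatches allowed
  pn <- primer_pair("CCNACGGGAGGC", "GGATTAGATACCC", max_mismatch = 0L)
  expect_equal(nrow(insilico_pcr(template, pn)), 1L)
})

test_that("largest-remainder apportionment conserves totals", {
  w <- c(5, 3, 2)
  expect_equal(sum(largest_remainder(w, 1000)), 1000L)
  expect_equal(largest_remainder(w, 10), c(5L, 3L, 2L))
  # uniform model: counts differ by at most one
  u <- largest_remainder(rep(1, 7), 100)
  expect_equal(sum(u), 100L)
  expect_lte(diff(range(u)), 1L)
  withr::local_seed(13)
  for (i in 1:20) {
    w <- runif(sample(2:30, 1))
    n <- sample(1:10000, 1)
    expect_equal(sum(largest_remainder(w, n)), n)
  }
})

test_that("library plans share a common pool and apportion reads exactly", {
  spec <- library_spec(n_read_pairs = 10000L, n_shuffled = 500L,
                       shared_fraction = 0.9, n_replicates = 3L, seed = 5)
  plan <- library_plan(spec, 100L)
  expect_length(plan$shared, 90L) # ceiling(0.9 * 100)
  per_rep <- split(plan$allocation$ref, plan$allocation$replicate)
  # the shared pool is in every replicate; private picks are disjoint
  common <- Reduce(intersect, per_rep)
  expect_setequal(common, plan$shared)
  privates <- lapply(per_rep, setdiff, plan$shared)
  expect_equal(length(unlist(privates)), length(unique(unlist(privates))))
  # read totals are exact per replicate
  totals <- tapply(plan$allocation$n_reads, plan$allocation$replicate, sum)
  expect_true(all(totals == 10000L))
  # linear model: counts non-increasing in abundance rank
  a1 <- plan$allocation[plan$allocation$replicate == 1, ]
  expect_true(all(diff(a1$n_reads[order(a1$abundance_rank)]) <= 0))

  # full sharing: identical reference sets
  full <- library_plan(library_spec(shared_fraction = 1, seed = 5), 50L)
  expect_length(unique(lapply(split(full$allocation$ref, full$allocation$replicate),
                              sort)), 1L)
})

test_that("shuffling preserves per-sequence base composition deterministically", {
  src <- c("ACGTACGTGG", "TTTTAAACCC")
  sh <- shuffle_sequences(src, 6, seed = 2)
  expect_length(sh, 6L)
  base_hist <- function(x) sort(table(strsplit(x, "")[[1]]))
  for (s in sh) {
    expect_true(any(vapply(src, function(o)
      identical(base_hist(o), base_hist(s)), logical(1))))
  }
  expect_identical(sh, shuffle_sequences(src, 6, seed = 2))
  expect_length(shuffle_sequences(src, 0, seed = 2), 0L)
})

test_that("replicate libraries emit coherent FASTA/FASTQ/truth files", {
  mt <- make_mock_taxonomy(small_branching, dir = withr::local_tempdir())
  tmpl <- make_templates(mt$db, seed = 11, insert_range = c(360L, 420L))
  spec <- library_spec(n_read_pairs = 500L, read_length = 300L, phred = 30L,
                       n_shuffled = 25L, n_replicates = 2L,
                       shared_fraction = 0.75, seed = 9)
  out <- withr::local_tempdir()
  man <- build_libraries(tmpl, spec, out_dir = out)
  expect_equal(nrow(man), 2L)
  expect_true(all(man$n_read_pairs == 500L))
  expect_true(all(man$n_shuffled == 25L))

  truth <- read_truth(man$truth[1])
  expect_equal(nrow(truth), 525L)
  expect_equal(sum(truth$is_shuffled), 25L)

  fasta <- Biostrings::readDNAStringSet(man$fasta[1])
  expect_length(fasta, 525L)

  r1 <- readLines(man$r1[1])
  expect_equal(length(r1), 500L * 4L)
  quals <- unique(unlist(strsplit(r1[seq(4, length(r1), by = 4)], "")))
  expect_equal(quals, "?") # chr(30 + 33)
  # R1 is the amplicon prefix; R2 the reverse complement of its suffix
  amp <- as.character(fasta[[1]])
  seq1 <- r1[2]
  expect_equal(seq1, substring(amp, 1, 300))
  r2 <- readLines(man$r2[1])
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r2[2]))),
    substring(amp, nchar(amp) - 299, nchar(amp)))

  # every non-shuffled merged amplicon re-amplifies to itself (round trip)
  for (i in c(1L, 250L, 500L)) {
    hit <- insilico_pcr(as.character(fasta[[i]]), primer_pair())
    expect_equal(hit$sequence[1], as.character(fasta[[i]]))
  }

  # identical spec and seed: byte-identical outputs
  out2 <- withr::local_tempdir()
  build_libraries(tmpl, spec, out_dir = out2)
  for (f in c("amplicons.fasta", "reads_R1.fastq", "reads_R2.fastq", "truth.tsv")) {
    expect_identical(readLines(file.path(out, "replicate_1", f)),
                     readLines(file.path(out2, "replicate_1", f)))
  }
})

test_that("the mock annotator reproduces its configured behaviour", {
  mt <- make_mock_taxonomy(c(1L, 2L, 1L, 1L, 2L, 3L, 3L, 1L),
                           dir = withr::local_tempdir())
  withr::local_seed(31)
  leaves <- mt$leaves$taxid
  truth <- tibble::tibble(
    read_id = sprintf("r%05d", 1:2000),
    expected_taxid = c(sample(leaves, 1800, replace = TRUE), rep(NA_integer_, 200)),
    is_shuffled = c(rep(FALSE, 1800), rep(TRUE, 200))
  )

  # a perfect profile gives MCC 1 and EPQ 0 at every rank
  perfect <- mock_annotator(truth, mt$db, error_profile(), seed = 4)
  mp <- rank_metrics(aggregate_labels(label_reads(truth, perfect, mt$db)))
  expect_true(all(mp$mcc == 1))
  expect_true(all(mp$epq == 0))
  expect_true(all(mp$coverage == 1))

  # unclassifiable shuffled reads stay true negatives when p_classify_shuffled = 0
  labs <- label_reads(truth, perfect, mt$db)
  shuf_labels <- unlist(labs[labs$is_shuffled, tax_ranks()])
  expect_true(all(shuf_labels == "TN"))

  # a profile that annotates shuffled reads generates FPs on them
  sloppy <- mock_annotator(truth, mt$db,
                           error_profile(p_classify_shuffled = 0.5), seed = 4)
  labs2 <- label_reads(truth, sloppy, mt$db)
  expect_gt(sum(unlist(labs2[labs2$is_shuffled, tax_ranks()]) == "FP"), 0)

  # determinism
  expect_identical(
    mock_annotator(truth, mt$db, error_profile(), seed = 4)$taxid,
    perfect$taxid
  )

  expect_error(error_profile(p_correct = rep(0.2, 8)), "at most 1")
  expect_error(error_profile(p_classify_shuffled = 1.5), "\\[0, 1\\]")
})
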