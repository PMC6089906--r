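#' Degenerate primer pair
#'
#' A pair of IUPAC primers, the reverse primer given 5'->3' on the reverse
#' strand (as primers are ordered). The shipped defaults are the widely
#' used 341F/805R V3-V4 bacterial 16S primers under their standard IUPAC
#' degeneracies; any pair can be supplied.
#'
#' @param forward,reverse IUPAC nucleotide strings, length >= 10.
#' @param max_mismatch Mismatches tolerated per primer site.
#' @return A `primer_pair` list.
#' @export
primer_pair <- function(forward = "CCTACGGGNGGCWGCAG",
                        reverse = "GACTACHVGGGTATCTAATCC",
                        max_mismatch = 0L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  ok <- function(x) nchar(x) >= 10L &&
    grepl(sprintf("^[%s]+$", paste(names(Biostrings::IUPAC_CODE_MAP), collapse = "")), x)
  if (!ok(forward) || !ok(reverse)) {
    abort("primers must be IUPAC nucleotide strings of length >= 10")
  }
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' Simulated-library specification
#'
#' Parameters of one benchmark amplicon experiment. The defaults reproduce
#' the reference construction: 750,000 read pairs of 300 bp per replicate
#' at a fixed Phred 30 base quality, a linear rank-abundance model, 37,500
#' shuffled true-negative sequences per library, and three replicate
#' libraries drawing 90% of their reference sequences from a common pool.
#'
#' @param n_read_pairs Read pairs per replicate.
#' @param read_length Read length in bp.
#' @param phred Fixed per-base quality (Sanger/Phred+33 encoding).
#' @param n_shuffled Shuffled true-negative sequences per replicate.
#' @param abundance_model `"linear"` (abundance of the i-th of k references
#'   proportional to k - i + 1) or `"uniform"`.
#' @param shared_fraction Fraction of the reference set placed in the pool
#'   common to all replicates.
#' @param n_replicates Number of replicate libraries.
#' @param seed Seed driving every random choice of the builder.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_read_pairs = 750000L, read_length = 300L,
                         phred = 30L, n_shuffled = 37500L,
                         abundance_model = c("linear", "uniform"),
                         shared_fraction = 0.9, n_replicates = 3L,
                         seed = 1234L) {
  abundance_model <- match.arg(abundance_model)
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("shared_fraction must be in [0, 1]")
  }
  if (any(c(n_read_pairs, read_length, phred, n_shuffled, n_replicates) < 0)) {
    abort("library_spec counts must be non-negative")
  }
  structure(list(
    n_read_pairs = as.integer(n_read_pairs), read_length = as.integer(read_length),
    phred = as.integer(phred), n_shuffled = as.integer(n_shuffled),
    abundance_model = abundance_model, shared_fraction = shared_fraction,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  ), class = "library_spec")
}

#' Generate a balanced mock taxonomy
#'
#' Builds a fully balanced taxonomy tree carrying exactly the eight
#' canonical ranks below the root, with unique synthetic names, and writes
#' it in the simplified taxdump TSV dialect. The default branching yields
#' 864 subspecies leaves, on the order of the ~840 reference genomes behind
#' the reference amplicon libraries. Output is deterministic.
#'
#' @param branching Integer vector of length 8: children per node at each
#'   rank, domain to subspecies.
#' @param dir Directory the `nodes.tsv` / `names.tsv` files are written to.
#' @return A list: `db` (the `tax_db`), `nodes_path`, `names_path`,
#'   `leaves` (tibble of leaf taxids and names).
#' @export
make_mock_taxonomy <- function(branching = c(2L, 3L, 2L, 2L, 3L, 3L, 2L, 2L),
                               dir = tempfile("mocktax")) {
  stopifnot(length(branching) == 8L, all(branching >= 1L))
  abbr <- c("d", "p", "c", "o", "f", "g", "s", "t")

  taxid <- 1L; parent <- 1L; rank <- "no rank"; name <- "root"
  prev_ids <- 1L; prev_names <- ""
  next_id <- 2L
  for (lvl in seq_len(8L)) {
    k <- branching[lvl]
    n_new <- length(prev_ids) * k
    ids <- seq.int(next_id, length.out = n_new)
    pars <- rep(prev_ids, each = k)
    stem <- rep(prev_names, each = k)
    nm <- paste0(ifelse(stem == "", "", paste0(stem, "_")),
                 abbr[lvl], sprintf("%02d", rep(seq_len(k), length(prev_ids))))
    taxid <- c(taxid, ids); parent <- c(parent, pars)
    rank <- c(rank, rep(tax_ranks()[lvl], n_new)); name <- c(name, nm)
    prev_ids <- ids; prev_names <- nm
    next_id <- next_id + n_new
  }

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes_path <- file.path(dir, "nodes.tsv")
  names_path <- file.path(dir, "names.tsv")
  readr::write_tsv(tibble(taxid = taxid, parent = parent, rank = rank), nodes_path)
  readr::write_tsv(tibble(taxid = taxid, name = name,
                          class = "scientific name"), names_path)
  db <- load_taxdump(nodes_path, names_path)
  leaves <- tibble(taxid = prev_ids, name = prev_names)
  list(db = db, nodes_path = nodes_path, names_path = names_path, leaves = leaves)
}

# expand one IUPAC code to concrete bases
iupac_bases <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
}

# instantiate a degenerate primer into a concrete sequence (random choice
# at each degenerate position)
instantiate_primer <- function(primer) {
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(c) {
    b <- iupac_bases(c)
    if (length(b) == 1L) b else sample(b, 1L)
  }, character(1)), collapse = "")
}

random_dna <- function(n_seqs, len) {
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate amplifiable template sequences
#'
#' One template per species-or-deeper leaf of the taxonomy: a random
#' flank, an exact forward-primer site (degenerate positions instantiated
#' at random), a random insert of length uniform in `insert_range`, the
#' reverse complement of the reverse-primer site, and a random trailing
#' flank. Every template therefore yields exactly one amplicon under
#' [insilico_pcr()] with the same primers. A truth mapping records each
#' template's source taxid.
#'
#' @param db A `tax_db` (typically from [make_mock_taxonomy()]).
#' @param primers A [primer_pair()].
#' @param insert_range Length range (bp) of the inter-primer insert; the
#'   default emulates a V3-V4-sized product.
#' @param flank_range Length range of the flanks outside the primer sites.
#' @param seed Seed; identical seeds give identical templates.
#' @return A list: `sequences` (named character vector), `truth`
#'   (tibble `template_id`, `taxid`).
#' @export
make_templates <- function(db, primers = primer_pair(),
                           insert_range = c(400L, 460L),
                           flank_range = c(30L, 80L), seed = 1L) {
  stopifnot(inherits(db, "tax_db"), inherits(primers, "primer_pair"))
  kids <- table(db$nodes$parent[db$nodes$parent != db$nodes$taxid])
  has_child <- db$nodes$taxid %in% as.integer(names(kids))
  sp_slot <- db$lineage[, "species"]
  leaf_ids <- db$nodes$taxid[!has_child & !is.na(sp_slot)]
  if (length(leaf_ids) == 0L) abort("taxonomy has no species-or-deeper leaves")

  withr::with_seed(seed, {
    inserts <- sample.int(insert_range[2] - insert_range[1] + 1L,
                          length(leaf_ids), replace = TRUE) + insert_range[1] - 1L
    flank5 <- sample.int(flank_range[2] - flank_range[1] + 1L,
                         length(leaf_ids), replace = TRUE) + flank_range[1] - 1L
    flank3 <- sample.int(flank_range[2] - flank_range[1] + 1L,
                         length(leaf_ids), replace = TRUE) + flank_range[1] - 1L
    seqs <- vapply(seq_along(leaf_ids), function(i) {
      paste0(
        random_dna(1, flank5[i]),
        instantiate_primer(primers$forward),
        random_dna(1, inserts[i]),
        revcomp(instantiate_primer(primers$reverse)),
        random_dna(1, flank3[i])
      )
    }, character(1))
  })
  ids <- sprintf("tmpl_%d", leaf_ids)
  names(seqs) <- ids
  list(sequences = seqs,
       truth = tibble(template_id = ids, taxid = leaf_ids))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' In-silico PCR on one template
#'
#' Scans a template for forward-primer matches and, downstream of each, for
#' reverse-primer matches on the reverse strand (i.e. matches of the
#' reverse complement of the reverse primer on the plus strand). Degenerate
#' IUPAC codes match their expansion sets and up to `max_mismatch`
#' mismatches are tolerated per site. Every properly oriented pair whose
#' product length falls in `product_range` is emitted; the amplicon
#' includes both primer footprints.
#'
#' @param template A single DNA sequence (character or `DNAString`) over
#'   A/C/G/T/N.
#' @param primers A [primer_pair()].
#' @param product_range Admissible product length window (bp).
#' @return A tibble with 0-based half-open coordinates: `start`, `end`,
#'   `sequence`; zero rows when no site pair is found.
#' @export
insilico_pcr <- function(template, primers = primer_pair(),
                         product_range = c(50L, 5000L)) {
  stopifnot(inherits(primers, "primer_pair"))
  subj <- Biostrings::DNAString(as.character(template))
  fwd_hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primers$forward), subj,
    max.mismatch = primers$max_mismatch, fixed = FALSE)
  rev_site <- Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse))
  rev_hits <- Biostrings::matchPattern(
    rev_site, subj, max.mismatch = primers$max_mismatch, fixed = FALSE)
  if (length(fwd_hits) == 0L || length(rev_hits) == 0L) {
    return(tibble(start = integer(), end = integer(), sequence = character()))
  }
  fs <- Biostrings::start(fwd_hits); fe <- Biostrings::end(fwd_hits)
  rs <- Biostrings::start(rev_hits); re <- Biostrings::end(rev_hits)
  out <- purrr::map_dfr(seq_along(fs), function(i) {
    j <- which(rs > fe[i])
    if (!length(j)) return(NULL)
    len <- re[j] - fs[i] + 1L
    ok <- len >= product_range[1] & len <= product_range[2]
    if (!any(ok)) return(NULL)
    tibble(start = fs[i] - 1L, end = re[j][ok])
  })
  if (nrow(out) == 0L) {
    return(tibble(start = integer(), end = integer(), sequence = character()))
  }
  tpl <- as.character(subj)
  dplyr::mutate(out, sequence = substring(tpl, .data$start + 1L, .data$end))
}

#' Largest-remainder apportionment of read counts
#'
#' Rounds fractional per-reference read quotas to integers whose sum equals
#' the configured total exactly: each reference gets the floor of its
#' quota, and the remaining reads go to the largest fractional remainders
#' (ties broken by position).
#'
#' @param weights Non-negative abundance weights.
#' @param total Total count to apportion.
#' @return Integer vector summing exactly to `total`.
#' @export
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), sum(weights) > 0, total >= 0)
  quota <- weights / sum(weights) * total
  counts <- floor(quota)
  left <- total - sum(counts)
  if (left > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Per-replicate reference pools and read allocation
#'
#' The deterministic planning stage of [build_libraries()]: selects the
#' common reference pool (`ceiling(shared_fraction * n)` references used by
#' every replicate), gives each replicate a disjoint private sample of the
#' remainder, assigns abundance ranks by a seeded permutation per
#' replicate, and apportions the configured read total over references by
#' largest-remainder rounding of the abundance model.
#'
#' @param spec A [library_spec()].
#' @param n_templates Number of available reference templates.
#' @return A list: `shared` (indices of the common pool), `allocation`
#'   (tibble `replicate`, `ref`, `abundance_rank`, `n_reads`).
#' @export
library_plan <- function(spec, n_templates) {
  stopifnot(inherits(spec, "library_spec"), n_templates >= 1L)
  n_shared <- ceiling(spec$shared_fraction * n_templates)
  if (n_shared > n_templates) abort("shared pool exceeds the available references")
  withr::with_seed(spec$seed, {
    perm <- sample.int(n_templates)
    shared <- sort(perm[seq_len(n_shared)])
    rest <- perm[-seq_len(n_shared)]
    n_private <- if (spec$n_replicates > 0) length(rest) %/% spec$n_replicates else 0L
    alloc <- purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
      priv <- if (n_private > 0) {
        sort(rest[seq.int((r - 1L) * n_private + 1L, length.out = n_private)])
      } else integer()
      refs <- c(shared, priv)
      k <- length(refs)
      ranks <- sample.int(k)
      w <- if (spec$abundance_model == "linear") (k - ranks + 1) else rep(1, k)
      tibble(replicate = r, ref = refs, abundance_rank = ranks,
             n_reads = largest_remainder(w, spec$n_read_pairs))
    })
  })
  list(shared = shared, allocation = alloc)
}

#' Shuffle sequences into unclassifiable true negatives
#'
#' Each output sequence is a seeded Fisher-Yates permutation of the bases
#' of a randomly chosen source sequence, so the mononucleotide composition
#' of every sequence is preserved while all positional signal is destroyed.
#'
#' @param source Character vector of source sequences.
#' @param n Number of shuffled sequences.
#' @param seed Seed.
#' @param prefix Identifier prefix for the output names.
#' @return Named character vector of `n` shuffled sequences.
#' @export
shuffle_sequences <- function(source, n, seed = 1L, prefix = "SHUFFLED") {
  if (length(source) == 0L) abort("source must be non-empty")
  if (n == 0L) return(stats::setNames(character(), character()))
  withr::with_seed(seed, {
    pick <- sample.int(length(source), n, replace = TRUE)
    out <- vapply(source[pick], function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  stats::setNames(out, sprintf("%s_%06d", prefix, seq_len(n)))
}

#' Build replicate benchmark libraries
#'
#' The full construction: amplifies every template with the primers,
#' selects per-replicate reference pools and read counts via
#' [library_plan()], emits for each replicate the merged-amplicon FASTA
#' (the unit classifiers annotate; shuffled true negatives appended), the
#' paired R1/R2 FASTQ (R1 = first `read_length` bases of the amplicon,
#' R2 = reverse complement of the last `read_length` bases, every base at
#' the fixed Phred quality) and the ground-truth TSV. With the default
#' [library_spec()] each replicate's truth table has exactly
#' 750,000 + 37,500 rows.
#'
#' @param templates Output of [make_templates()] (or a compatible list with
#'   `sequences` and `truth`).
#' @param spec A [library_spec()].
#' @param primers The [primer_pair()] used for amplification.
#' @param out_dir Output directory; one `replicate_<r>/` subdirectory per
#'   replicate.
#' @return A manifest tibble (one row per replicate: paths and counts),
#'   with the [library_plan()] attached as attribute `plan`.
#' @export
build_libraries <- function(templates, spec = library_spec(),
                            primers = primer_pair(),
                            out_dir = tempfile("library")) {
  stopifnot(inherits(spec, "library_spec"))
  amp <- vapply(templates$sequences, function(s) {
    hits <- insilico_pcr(s, primers)
    if (nrow(hits) == 0L) NA_character_ else hits$sequence[1]
  }, character(1))
  ok <- !is.na(amp)
  if (!any(ok)) abort("no template yields an amplicon with these primers")
  amp <- amp[ok]
  taxids <- templates$truth$taxid[ok]

  plan <- library_plan(spec, length(amp))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qual_char <- intToUtf8(spec$phred + 33L)

  manifest <- purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
    rep_dir <- file.path(out_dir, sprintf("replicate_%d", r))
    dir.create(rep_dir, showWarnings = FALSE)
    alloc <- dplyr::filter(plan$allocation, .data$replicate == r)

    ref_amp <- amp[alloc$ref]
    ref_tax <- taxids[alloc$ref]
    reads_seq <- rep(ref_amp, alloc$n_reads)
    reads_tax <- rep(ref_tax, alloc$n_reads)
    n_reads <- length(reads_seq)
    read_ids <- sprintf("rep%d_read%07d", r, seq_len(n_reads))

    shuf <- shuffle_sequences(unique(ref_amp), spec$n_shuffled,
                              seed = spec$seed + r,
                              prefix = sprintf("rep%d_shuffled", r))

    # merged amplicons: real reads then shuffled true negatives
    fasta_path <- file.path(rep_dir, "amplicons.fasta")
    writeLines(as.vector(rbind(paste0(">", c(read_ids, names(shuf))),
                               c(reads_seq, unname(shuf)))),
               fasta_path)

    lens <- nchar(reads_seq)
    L <- spec$read_length
    r1 <- substring(reads_seq, 1L, pmin(lens, L))
    r2 <- revcomp(substring(reads_seq, pmax(1L, lens - L + 1L), lens))
    q1 <- strrep(qual_char, nchar(r1))
    q2 <- strrep(qual_char, nchar(r2))
    r1_path <- file.path(rep_dir, "reads_R1.fastq")
    r2_path <- file.path(rep_dir, "reads_R2.fastq")
    writeLines(as.vector(rbind(paste0("@", read_ids, "/1"), r1, "+", q1)), r1_path)
    writeLines(as.vector(rbind(paste0("@", read_ids, "/2"), r2, "+", q2)), r2_path)

    truth <- tibble(
      read_id = c(read_ids, names(shuf)),
      expected_taxid = c(reads_tax, rep(NA_integer_, length(shuf))),
      is_shuffled = c(rep(FALSE, n_reads), rep(TRUE, length(shuf)))
    )
    truth_path <- file.path(rep_dir, "truth.tsv")
    write_truth(truth, truth_path)

    tibble(replicate = r, dir = rep_dir,
           fasta = fasta_path, r1 = r1_path, r2 = r2_path, truth = truth_path,
           n_read_pairs = n_reads, n_shuffled = length(shuf),
           n_references = nrow(alloc))
  })
  attr(manifest, "plan") <- plan
  manifest
}

#' Mock-annotator error profile
#'
#' Per-rank behaviour of the configurable mock annotator used for
#' closed-loop testing. For each real read, the annotator picks one
#' outcome: "correct to rank r" (assigned lineage is the expected one
#' truncated at r) with probability `p_correct[r]`, "misclassified at rank
#' r" (correct above r, a random sibling taxon at r) with probability
#' `p_misclassify[r]`, or unclassified with the remaining mass. A shuffled
#' read is annotated (to a random species) with probability
#' `p_classify_shuffled`. Scores are Beta-distributed, higher-is-better,
#' with separate shapes for correct and erroneous calls so the two
#' populations overlap realistically.
#'
#' @param p_correct,p_misclassify Numeric vectors of length 8 (domain to
#'   subspecies); their total must not exceed 1.
#' @param p_classify_shuffled Probability a shuffled read is annotated.
#' @param score_correct,score_error Beta shape pairs for the score of
#'   correct and erroneous calls.
#' @return An `error_profile` list.
#' @export
error_profile <- function(p_correct = c(rep(0, 7), 1),
                          p_misclassify = rep(0, 8),
                          p_classify_shuffled = 0,
                          score_correct = c(8, 2),
                          score_error = c(2, 5)) {
  stopifnot(length(p_correct) == 8L, length(p_misclassify) == 8L)
  probs <- c(p_correct, p_misclassify, p_classify_shuffled)
  if (any(probs < 0) || any(probs > 1)) {
    abort("error-profile probabilities must lie in [0, 1]")
  }
  if (sum(p_correct) + sum(p_misclassify) > 1 + 1e-12) {
    abort("p_correct and p_misclassify must sum to at most 1")
  }
  structure(list(p_correct = p_correct, p_misclassify = p_misclassify,
                 p_classify_shuffled = p_classify_shuffled,
                 score_correct = score_correct, score_error = score_error),
            class = "error_profile")
}

#' Annotate a truth set with a configurable mock classifier
#'
#' Samples one assignment per truth read according to an [error_profile()],
#' deterministically for a given seed. The result plugs straight into
#' [evaluate_assignments()] and [build_cve()], closing the loop between the
#' simulator and the evaluation machinery: configured error rates should be
#' recovered by the measured metrics.
#'
#' @param truth Truth tibble.
#' @param db The `tax_db` the truth taxids live in.
#' @param profile An [error_profile()].
#' @param seed Seed.
#' @param method_name Label carried into outputs.
#' @return A `tax_assignments` tibble.
#' @export
mock_annotator <- function(truth, db, profile = error_profile(), seed = 1L,
                           method_name = "mock") {
  stopifnot(inherits(db, "tax_db"), inherits(profile, "error_profile"))
  n <- nrow(truth)
  E <- lineage_rows(db, ifelse(truth$is_shuffled, NA_integer_, truth$expected_taxid))

  # sibling pools: nodes sharing parent and rank; fallback pool per rank
  nodes <- db$nodes
  rank_pool <- split(nodes$taxid, nodes$rank)

  taxid <- rep(NA_integer_, n)
  score <- rep(NA_real_, n)
  correct_call <- rep(NA, n)

  withr::with_seed(seed, {
    real <- which(!truth$is_shuffled)
    if (length(real)) {
      p <- c(profile$p_correct, profile$p_misclassify,
             max(0, 1 - sum(profile$p_correct) - sum(profile$p_misclassify)))
      cat17 <- sample.int(17L, length(real), replace = TRUE, prob = p)
      # correct-to-rank-k outcomes, vectorized: deepest non-empty slot <= k
      for (k in 1:8) {
        idx <- real[cat17 == k]
        if (!length(idx)) next
        sub <- E[idx, seq_len(k), drop = FALSE]
        filled <- !is.na(sub)
        has_any <- rowSums(filled) > 0
        deepest <- max.col(filled, ties.method = "last")
        hit <- idx[has_any]
        taxid[hit] <- sub[cbind(which(has_any), deepest[has_any])]
        correct_call[hit] <- TRUE
      }
      # sibling-swap misclassification at rank k (rare: per-read loop)
      for (k in 1:8) {
        idx <- real[cat17 == k + 8L]
        if (!length(idx)) next
        for (ri in idx) {
          target <- E[ri, k]
          if (!is.na(target)) {
            par <- nodes$parent[db$index[[as.character(target)]]]
            pool <- nodes$taxid[nodes$parent == par &
                                  rank_slot(nodes$rank) %in% k &
                                  nodes$taxid != target]
            sib <- if (length(pool)) pool else
              setdiff(rank_pool[[tax_ranks()[k]]], target)
          } else {
            sib <- rank_pool[[tax_ranks()[k]]]
          }
          if (length(sib)) {
            taxid[ri] <- if (length(sib) == 1L) sib else sample(sib, 1L)
            correct_call[ri] <- FALSE
          }
        }
      }
    }
    shuf <- which(truth$is_shuffled)
    if (length(shuf) && profile$p_classify_shuffled > 0) {
      hit <- runif(length(shuf)) < profile$p_classify_shuffled
      sp_pool <- rank_pool[["species"]]
      taxid[shuf[hit]] <- sample(sp_pool, sum(hit), replace = TRUE)
      correct_call[shuf[hit]] <- FALSE
    }
    called <- !is.na(taxid)
    ncall <- sum(called)
    if (ncall) {
      sc <- rep(NA_real_, ncall)
      corr <- correct_call[called]
      sc[corr] <- rbeta(sum(corr), profile$score_correct[1], profile$score_correct[2])
      sc[!corr] <- rbeta(sum(!corr), profile$score_error[1], profile$score_error[2])
      score[called] <- sc
    }
  })
  assignment_set(truth$read_id, taxid = taxid, score = score,
                 score_direction = "higher_better", method_name = method_name)
}
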