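#' Read a pipeline run configuration
#'
#' Configuration is a YAML (or flat `key: value`) file mirroring the
#' [library_spec()] and [make_mock_taxonomy()] parameters; values passed in
#' `overrides` win over file values. Defaults are fixed and documented —
#' including the seed, since reproducibility is the product.
#'
#' @param path Optional YAML config path.
#' @param overrides Named list of values overriding the file.
#' @return A validated config list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1234L,
    n_read_pairs = 750000L, read_length = 300L, phred = 30L,
    n_shuffled = 37500L, abundance_model = "linear",
    shared_fraction = 0.9, n_replicates = 3L,
    branching = c(2L, 3L, 2L, 2L, 3L, 3L, 2L, 2L),
    insert_range = c(400L, 460L),
    forward_primer = "CCTACGGGNGGCWGCAG",
    reverse_primer = "GACTACHVGGGTATCTAATCC",
    max_mismatch = 0L,
    targets = c(0.01, 0.05, 0.10)
  )
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: '%s'", path))
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown)) {
      abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    }
    cfg[names(file_cfg)] <- file_cfg
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1) {
    abort("shared_fraction must be in [0, 1]")
  }
  cfg
}

config_spec <- function(cfg) {
  library_spec(
    n_read_pairs = cfg$n_read_pairs, read_length = cfg$read_length,
    phred = cfg$phred, n_shuffled = cfg$n_shuffled,
    abundance_model = cfg$abundance_model,
    shared_fraction = cfg$shared_fraction,
    n_replicates = cfg$n_replicates, seed = cfg$seed
  )
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[taxabench] %s", sprintf(fmt, ...)))
}

#' Simulate a complete benchmark run directory
#'
#' Generates the mock taxonomy, the amplifiable templates and the replicate
#' libraries into `out_dir`, echoing the effective configuration to
#' `config_used.yaml`. All inputs are validated before anything is
#' written.
#'
#' @param out_dir Output directory.
#' @param config A config list from [read_run_config()] (or `NULL` for the
#'   defaults).
#' @return The library manifest tibble, invisibly; the taxonomy lives under
#'   `<out_dir>/taxonomy/`, replicate libraries under
#'   `<out_dir>/replicate_<r>/`.
#' @export
run_simulate <- function(out_dir, config = NULL) {
  cfg <- if (is.null(config)) read_run_config() else config
  spec <- config_spec(cfg)
  primers <- primer_pair(cfg$forward_primer, cfg$reverse_primer, cfg$max_mismatch)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "config_used.yaml"))

  pipeline_log("building mock taxonomy (branching %s)",
               paste(cfg$branching, collapse = "x"))
  tax <- make_mock_taxonomy(cfg$branching, dir = file.path(out_dir, "taxonomy"))
  pipeline_log("generating templates for %d leaves", nrow(tax$leaves))
  tmpl <- make_templates(tax$db, primers, insert_range = cfg$insert_range,
                         seed = cfg$seed)
  write_fasta(tmpl$sequences, file.path(out_dir, "templates.fasta"))
  readr::write_tsv(tmpl$truth, file.path(out_dir, "templates_truth.tsv"))
  pipeline_log("building %d replicate libraries (%d read pairs, %d shuffled each)",
               spec$n_replicates, spec$n_read_pairs, spec$n_shuffled)
  manifest <- build_libraries(tmpl, spec, primers, out_dir = out_dir)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Annotate every replicate of a run with the mock classifier
#'
#' @param run_dir A directory produced by [run_simulate()].
#' @param profile An [error_profile()].
#' @param seed Seed (one stream per replicate, derived from it).
#' @return Tibble of written assignment paths, invisibly.
#' @export
run_annotate_mock <- function(run_dir, profile = error_profile(), seed = 1L) {
  db <- run_db(run_dir)
  rep_dirs <- sort(list.dirs(run_dir, recursive = FALSE))
  rep_dirs <- rep_dirs[grepl("replicate_\\d+$", rep_dirs)]
  if (!length(rep_dirs)) abort(sprintf("no replicate directories under '%s'", run_dir))
  out <- purrr::imap_dfr(rep_dirs, function(d, i) {
    truth <- read_truth(file.path(d, "truth.tsv"))
    asn <- mock_annotator(truth, db, profile, seed = seed + i,
                          method_name = "mock")
    path <- file.path(d, "assignments_mock.tsv")
    write_assignments(asn, path)
    pipeline_log("annotated %s (%d reads)", basename(d), nrow(truth))
    tibble(replicate = i, path = path)
  })
  invisible(out)
}

run_db <- function(run_dir) {
  nodes <- file.path(run_dir, "taxonomy", "nodes.tsv")
  names_ <- file.path(run_dir, "taxonomy", "names.tsv")
  if (!file.exists(nodes)) abort(sprintf("no taxonomy under '%s'", run_dir))
  load_taxdump(nodes, names_)
}

#' Evaluate assignment tables against their truth tables
#'
#' Runs the full per-rank evaluation for one or more replicates and writes
#' tidy TSVs: per-replicate metrics, a mean +/- sd summary when there are
#' at least two replicates, and a phylum abundance-bias profile per
#' replicate.
#'
#' @param truth_paths,assignment_paths Parallel vectors of truth and
#'   (native-dialect) assignment TSV paths. For a non-native classifier
#'   table pass `dialect`.
#' @param db A `tax_db`, or a length-2 character vector of
#'   nodes/names paths.
#' @param out_dir Output directory.
#' @param dialect Optional [dialect()] (or config path) used to parse the
#'   assignment tables; default expects the native dialect.
#' @param abundance_rank Rank of the abundance-bias profile.
#' @return A list: `evals` (per-replicate `tax_eval`s), `summary` (or
#'   `NULL` for a single replicate), invisibly.
#' @export
run_evaluate <- function(truth_paths, assignment_paths, db, out_dir,
                         dialect = NULL, abundance_rank = "phylum") {
  if (is.character(db)) db <- load_taxdump(db[1], db[2])
  if (length(truth_paths) != length(assignment_paths)) {
    abort("truth_paths and assignment_paths must be parallel")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  evals <- purrr::map(seq_along(truth_paths), function(i) {
    truth <- read_truth(truth_paths[i])
    asn <- if (is.null(dialect)) {
      read_native_assignments(assignment_paths[i], db)
    } else {
      read_assignments(assignment_paths[i], dialect, db)
    }
    ev <- evaluate_assignments(truth, asn, db, replicate = as.character(i))
    readr::write_tsv(tidy(ev), file.path(out_dir, sprintf("metrics_rep%d.tsv", i)))
    prof <- abundance_profile(asn, truth, db, rank = abundance_rank)
    readr::write_tsv(prof, file.path(out_dir, sprintf("abundance_rep%d.tsv", i)))
    pipeline_log("evaluated replicate %d: genus MCC %.3f", i,
                 ev$metrics$mcc[ev$metrics$rank == "genus"])
    ev
  })
  summary <- NULL
  if (length(evals) >= 2L) {
    summary <- summarize_replicates(purrr::map(evals, ~.x$metrics))
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  }
  invisible(list(evals = evals, summary = summary))
}

#' Build CVE curves and cut-off tables for evaluated replicates
#'
#' @param evals List of `tax_eval` objects (e.g. from [run_evaluate()]).
#' @param out_dir Output directory for the cut-off TSV and per-rank plots.
#' @param targets Target error rates.
#' @param plot_ranks Ranks to render as plot files (PNG if a png device is
#'   available, otherwise PDF).
#' @return The cut-off tibble, invisibly.
#' @export
run_cve <- function(evals, out_dir, targets = c(0.01, 0.05, 0.10),
                    plot_ranks = c("phylum", "genus", "species")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cutoffs <- purrr::imap_dfr(evals, function(ev, i) {
    purrr::map_dfr(tax_ranks(), function(rk) {
      curve <- suppressWarnings(
        build_cve(ev$labels, rk, score_direction = ev$score_direction,
                  method = ev$method))
      dplyr::mutate(cve_cutoffs(curve, targets), replicate = i, .after = "method")
    })
  })
  readr::write_tsv(cutoffs, file.path(out_dir, "cutoffs.tsv"))
  ext <- if (capabilities("png")) "png" else "pdf"
  for (rk in plot_ranks) {
    curves <- purrr::map(evals, function(ev) suppressWarnings(
      build_cve(ev$labels, rk, score_direction = ev$score_direction,
                method = ev$method)))
    curves <- purrr::keep(curves, ~nrow(.x$points) > 0)
    if (length(curves)) {
      export_cve_plot(curves, file.path(out_dir, sprintf("cve_%s.%s", rk, ext)),
                      targets = targets)
    }
  }
  invisible(cutoffs)
}

#' Write a markdown summary report for a completed run
#'
#' Collects the metric, summary, cut-off and abundance tables written by
#' [run_evaluate()]/[run_cve()] into a single markdown document with an
#' MCC-by-rank matrix and, when several methods were evaluated, a per-rank
#' ranking of methods by MCC.
#'
#' @param eval_dir Directory holding the evaluation TSVs.
#' @param path Output markdown path (defaults to `report.md` inside
#'   `eval_dir`).
#' @return `path`, invisibly.
#' @export
run_report <- function(eval_dir, path = file.path(eval_dir, "report.md")) {
  metric_files <- sort(list.files(eval_dir, "^metrics_rep\\d+\\.tsv$",
                                  full.names = TRUE))
  if (!length(metric_files)) {
    abort(sprintf("no metrics tables under '%s' - run the evaluation first", eval_dir))
  }
  metrics <- purrr::map_dfr(metric_files, readr::read_tsv,
                            col_types = readr::cols())
  lines <- c("# Benchmark report", "")

  mcc <- metrics |>
    dplyr::group_by(.data$method, .data$rank) |>
    dplyr::summarise(mcc = mean(.data$mcc, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "method", values_from = "mcc") |>
    dplyr::mutate(rank = factor(.data$rank, levels = tax_ranks())) |>
    dplyr::arrange(.data$rank)
  lines <- c(lines, "## MCC by taxonomic rank", "", md_table(mcc), "")

  ranking <- metrics |>
    dplyr::group_by(.data$rank, .data$method) |>
    dplyr::summarise(mcc = mean(.data$mcc, na.rm = TRUE), .groups = "drop") |>
    dplyr::group_by(.data$rank) |>
    dplyr::arrange(dplyr::desc(.data$mcc), .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(rank = factor(.data$rank, levels = tax_ranks())) |>
    dplyr::arrange(.data$rank)
  lines <- c(lines, "## Best method per rank (by MCC)", "", md_table(ranking), "")

  summary_path <- file.path(eval_dir, "summary.tsv")
  if (file.exists(summary_path)) {
    summ <- readr::read_tsv(summary_path, col_types = readr::cols())
    lines <- c(lines, "## Replicate mean +/- sd", "", md_table(summ), "")
  }
  cutoff_path <- file.path(eval_dir, "cutoffs.tsv")
  if (file.exists(cutoff_path)) {
    cuts <- readr::read_tsv(cutoff_path, col_types = readr::cols())
    lines <- c(lines, "## Score cut-offs at target error rates", "",
               md_table(cuts), "")
  }
  abundance_files <- sort(list.files(eval_dir, "^abundance_rep\\d+\\.tsv$",
                                     full.names = TRUE))
  if (length(abundance_files)) {
    ab <- readr::read_tsv(abundance_files[1], col_types = readr::cols())
    lines <- c(lines, "## Abundance bias (replicate 1)", "", md_table(ab), "")
  }
  writeLines(lines, path)
  pipeline_log("report written to %s", path)
  invisible(path)
}

# minimal markdown table renderer
md_table <- function(df) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                        ~round(.x, 4)))
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
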