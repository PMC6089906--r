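#' Read a ground-truth table
#'
#' A truth table is a TSV with columns `read_id` and `expected_taxid`; the
#' taxid is either an integer or the literal `SHUFFLED`, marking a
#' base-permuted true-negative sequence that no classifier should annotate.
#'
#' @param path Path to the truth TSV.
#' @return A tibble with columns `read_id` (character), `expected_taxid`
#'   (integer, `NA` for shuffled reads) and `is_shuffled` (logical).
#' @export
read_truth <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("read_id", "expected_taxid") %in% names(raw))) {
    abort(sprintf("truth table '%s' must have columns read_id and expected_taxid", path))
  }
  if (anyDuplicated(raw$read_id)) {
    dup <- raw$read_id[duplicated(raw$read_id)][1]
    abort(sprintf("duplicated read_id '%s' in truth table", dup))
  }
  shuf <- toupper(trimws(raw$expected_taxid)) == "SHUFFLED"
  taxid <- rep(NA_integer_, nrow(raw))
  taxid[!shuf] <- suppressWarnings(as.integer(raw$expected_taxid[!shuf]))
  if (any(is.na(taxid) & !shuf)) {
    bad <- which(is.na(taxid) & !shuf)[1]
    abort(sprintf("malformed expected_taxid '%s' on line %d of '%s'",
                  raw$expected_taxid[bad], bad + 1L, path))
  }
  tibble(read_id = raw$read_id, expected_taxid = taxid, is_shuffled = shuf)
}

#' Write a ground-truth table
#'
#' @param truth A truth tibble as returned by [read_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- tibble(
    read_id = truth$read_id,
    expected_taxid = ifelse(truth$is_shuffled, "SHUFFLED",
                            as.character(truth$expected_taxid))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

dialect_keys <- c(
  "read_id_col", "label_col", "score_col", "label_kind", "score_direction",
  "ambiguity", "ambig_marker", "ambig_sep", "lineage_sep", "unresolved",
  "header", "method_name"
)

#' Declare a classifier output dialect
#'
#' Taxonomic classifiers emit heterogeneous tables: some report taxids,
#' some taxon names, some full semicolon-separated name lineages; scores may
#' be similarities or confidences (higher is better) or E-values (lower is
#' better); some tools flag multi-taxon calls with a marker word such as
#' `AMBIGUOUS`. A dialect captures those conventions so any such table can
#' be normalized into one assignment format.
#'
#' @param read_id_col,label_col,score_col Column names or 1-based positions
#'   in the classifier table. `score_col = NA` means the tool reports no
#'   score (such assignments are excluded from coverage-vs-error curves but
#'   still enter the confusion counts).
#' @param label_kind One of `"taxid"`, `"name"`, `"lineage"` (semicolon-
#'   separated names, deepest resolvable name wins).
#' @param score_direction `"higher_better"` (similarity, confidence, k-mer
#'   fraction) or `"lower_better"` (E-value).
#' @param ambiguity `"none"` or `"list"`: with `"list"`, labels of the form
#'   `MARKER(a<sep>b<sep>...)` are collapsed to the lowest common ancestor of
#'   the listed taxa.
#' @param ambig_marker Marker word introducing an ambiguous list.
#' @param ambig_sep Separator inside an ambiguous list.
#' @param lineage_sep Separator of a name-lineage label.
#' @param unresolved `"fp"` (an unresolvable label still counts as a
#'   classification, hence a false positive wherever a taxon was expected) or
#'   `"unclassified"` (treated as no call).
#' @param header Does the table carry a header line?
#' @param method_name Label used in outputs and plots.
#' @return A `tax_dialect` list.
#' @export
dialect <- function(read_id_col = 1L, label_col = 2L, score_col = 3L,
                    label_kind = c("taxid", "name", "lineage"),
                    score_direction = c("higher_better", "lower_better"),
                    ambiguity = c("none", "list"),
                    ambig_marker = "AMBIGUOUS", ambig_sep = ";",
                    lineage_sep = ";",
                    unresolved = c("fp", "unclassified"),
                    header = FALSE, method_name = "method") {
  d <- list(
    read_id_col = read_id_col, label_col = label_col, score_col = score_col,
    label_kind = match.arg(label_kind),
    score_direction = match.arg(score_direction),
    ambiguity = match.arg(ambiguity),
    ambig_marker = ambig_marker, ambig_sep = ambig_sep,
    lineage_sep = lineage_sep,
    unresolved = match.arg(unresolved),
    header = isTRUE(header) || identical(header, "true"),
    method_name = method_name
  )
  structure(d, class = "tax_dialect")
}

#' Read a dialect from a key = value config file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are a
#' configuration error. See [dialect()] for the keys and their meaning.
#'
#' @param path Path to the config file.
#' @return A `tax_dialect`.
#' @export
read_dialect <- function(path) {
  if (!file.exists(path)) abort(sprintf("dialect file not found: '%s'", path))
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  unknown <- setdiff(keys, dialect_keys)
  if (length(unknown)) {
    abort(sprintf("unknown dialect key(s): %s", paste(unknown, collapse = ", ")))
  }
  args <- as.list(vals)
  names(args) <- keys
  for (k in c("read_id_col", "label_col", "score_col")) {
    if (!is.null(args[[k]])) {
      v <- suppressWarnings(as.integer(args[[k]]))
      args[[k]] <- if (is.na(v)) {
        if (toupper(args[[k]]) %in% c("NA", "NONE")) NA else args[[k]]
      } else v
    }
  }
  if (!is.null(args$header)) args$header <- tolower(args$header) %in% c("true", "1", "yes")
  do.call(dialect, args)
}

#' Read classifier assignments under a declared dialect
#'
#' Parses a classifier output table and normalizes every row to a single
#' assignment: a taxid (name and lineage labels are resolved against the
#' taxonomy, ambiguous multi-taxon lists collapsed to their lowest common
#' ancestor via [lca()]) plus the reported score. Labels that resolve to
#' nothing keep their raw text, get `taxid = NA` and are flagged
#' `unresolved`; how they are scored is governed by the dialect's
#' `unresolved` policy. A homonym name resolving to several taxids is
#' collapsed to their LCA.
#'
#' @param path Path to the classifier table (TSV).
#' @param dialect A [dialect()] or path to a dialect config.
#' @param db A `tax_db`.
#' @return A `tax_assignments` tibble with columns `read_id`, `taxid`,
#'   `raw_label`, `score`, `ambiguous` (list of member taxids or `NULL`),
#'   `unresolved`; attributes `score_direction`, `method_name`,
#'   `unresolved_policy` and `n_unresolved`.
#' @export
read_assignments <- function(path, dialect, db) {
  if (is.character(dialect)) dialect <- read_dialect(dialect)
  stopifnot(inherits(dialect, "tax_dialect"), inherits(db, "tax_db"))
  raw <- readr::read_tsv(path, col_names = dialect$header == TRUE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!dialect$header) names(raw) <- paste0("X", seq_along(raw))
  pick <- function(col) {
    if (length(col) == 1L && is.na(col)) return(NULL)
    if (is.numeric(col)) raw[[as.integer(col)]] else raw[[col]]
  }
  read_id <- pick(dialect$read_id_col)
  label <- trimws(pick(dialect$label_col))
  score_raw <- pick(dialect$score_col)
  score <- if (is.null(score_raw)) rep(NA_real_, nrow(raw)) else
    suppressWarnings(as.numeric(score_raw))
  if (is.null(read_id) || is.null(label)) {
    abort("dialect read_id_col/label_col do not match the table")
  }
  if (anyDuplicated(read_id)) {
    abort(sprintf("duplicate read_id '%s' in assignment table",
                  read_id[duplicated(read_id)][1]))
  }

  n <- length(read_id)
  taxid <- rep(NA_integer_, n)
  members <- vector("list", n)
  unresolved <- logical(n)

  ambig_re <- NULL
  if (dialect$ambiguity == "list") {
    ambig_re <- paste0("^", dialect$ambig_marker, "\\s*\\((.*)\\)$")
  }
  for (i in seq_len(n)) {
    lab <- label[i]
    if (is.na(lab) || lab == "" || toupper(lab) %in% c("UNCLASSIFIED", "NA")) next
    if (!is.null(ambig_re) && grepl(ambig_re, lab)) {
      inner <- sub(ambig_re, "\\1", lab)
      parts <- trimws(strsplit(inner, dialect$ambig_sep, fixed = TRUE)[[1]])
      ids <- resolve_labels(db, parts, dialect$label_kind)
      if (length(ids)) {
        members[[i]] <- ids
        taxid[i] <- lca(db, ids)
      } else {
        unresolved[i] <- TRUE
      }
      next
    }
    id <- resolve_labels(db, lab, dialect$label_kind,
                         lineage_sep = dialect$lineage_sep)
    if (length(id) == 1L) taxid[i] <- id
    else if (length(id) > 1L) taxid[i] <- lca(db, id)
    else unresolved[i] <- TRUE
  }

  out <- tibble(
    read_id = read_id, taxid = taxid, raw_label = label,
    score = score, ambiguous = members, unresolved = unresolved
  )
  new_assignments(out,
                  score_direction = dialect$score_direction,
                  method_name = dialect$method_name,
                  unresolved_policy = dialect$unresolved)
}

# resolve a vector of labels of one kind into taxids (possibly several for
# a homonym name; empty when unresolvable)
resolve_labels <- function(db, labels, kind, lineage_sep = ";") {
  if (kind == "taxid") {
    ids <- suppressWarnings(as.integer(labels))
    ids <- ids[!is.na(ids) & as.character(ids) %in% names(db$index)]
    return(unique(ids))
  }
  if (kind == "name") {
    ids <- unlist(lapply(labels, function(l) resolve_name(db, strip_rank_prefix(l))))
    return(unique(ids))
  }
  # semicolon lineage: deepest resolvable name wins, scanned leaf-ward first
  out <- integer()
  for (lab in labels) {
    parts <- rev(trimws(strsplit(lab, lineage_sep, fixed = TRUE)[[1]]))
    parts <- strip_rank_prefix(parts)
    parts <- parts[nzchar(parts)]
    for (p in parts) {
      ids <- resolve_name(db, p)
      if (length(ids)) { out <- c(out, ids); break }
    }
  }
  unique(out)
}

# drop greengenes-style "g__" / "s__" rank prefixes and underscores-for-spaces
strip_rank_prefix <- function(x) {
  trimws(sub("^[a-zA-Z]__", "", x))
}

new_assignments <- function(tbl, score_direction, method_name,
                            unresolved_policy = "fp") {
  structure(
    tbl,
    score_direction = score_direction,
    method_name = method_name,
    unresolved_policy = unresolved_policy,
    n_unresolved = sum(tbl$unresolved),
    class = c("tax_assignments", class(tibble())))
}

#' Construct an assignment set from vectors
#'
#' Programmatic counterpart of [read_assignments()], used by the mock
#' annotator and in tests.
#'
#' @param read_id,taxid,score Per-read vectors (taxid/score may be `NA`).
#' @param score_direction,method_name,unresolved_policy See
#'   [read_assignments()].
#' @return A `tax_assignments` tibble.
#' @export
assignment_set <- function(read_id, taxid = NA_integer_, score = NA_real_,
                           score_direction = "higher_better",
                           method_name = "method",
                           unresolved_policy = "fp") {
  if (anyDuplicated(read_id)) abort("duplicate read_id in assignment set")
  tbl <- tibble(
    read_id = as.character(read_id),
    taxid = as.integer(rep_len(taxid, length(read_id))),
    raw_label = as.character(rep_len(taxid, length(read_id))),
    score = as.numeric(rep_len(score, length(read_id))),
    ambiguous = vector("list", length(read_id)),
    unresolved = FALSE
  )
  new_assignments(tbl, score_direction, method_name, unresolved_policy)
}

#' Write an assignment set in the native dialect
#'
#' The native dialect is a headered TSV (`read_id`, `taxid`, `score`,
#' `members`, `raw_label`, `unresolved`) that round-trips an assignment set
#' exactly; re-read it with [read_native_assignments()].
#'
#' @param x A `tax_assignments` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(x, path) {
  out <- tibble(
    read_id = x$read_id,
    taxid = ifelse(is.na(x$taxid), "", as.character(x$taxid)),
    score = ifelse(is.na(x$score), "", sprintf("%.17g", x$score)),
    members = vapply(x$ambiguous, function(m)
      if (is.null(m)) "" else paste(m, collapse = ";"), character(1)),
    raw_label = x$raw_label,
    unresolved = ifelse(x$unresolved, "1", "0")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an assignment set written by [write_assignments()]
#'
#' @param path Path to a native-dialect TSV.
#' @param db A `tax_db` (used only for validation).
#' @param score_direction,method_name,unresolved_policy Metadata to attach;
#'   see [read_assignments()].
#' @return A `tax_assignments` tibble.
#' @export
read_native_assignments <- function(path, db,
                                    score_direction = "higher_better",
                                    method_name = "method",
                                    unresolved_policy = "fp") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  tbl <- tibble(
    read_id = raw$read_id,
    taxid = suppressWarnings(as.integer(raw$taxid)),
    raw_label = ifelse(is.na(raw$raw_label), "", raw$raw_label),
    score = suppressWarnings(as.numeric(raw$score)),
    ambiguous = lapply(raw$members, function(m)
      if (is.na(m) || m == "") NULL else as.integer(strsplit(m, ";", fixed = TRUE)[[1]])),
    unresolved = raw$unresolved == "1"
  )
  check_taxids(db, tbl$taxid, arg = "assigned taxid")
  new_assignments(tbl, score_direction, method_name, unresolved_policy)
}

#' Collapse an ambiguous multi-taxon call to one taxid
#'
#' Thin wrapper over [lca()]: an ambiguous list of candidate taxa is
#' replaced by their lowest common ancestor.
#'
#' @inheritParams lca
#' @param members Non-empty integer vector of candidate taxids.
#' @return A single taxid.
#' @export
collapse_ambiguous <- function(db, members) {
  lca(db, members)
}
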