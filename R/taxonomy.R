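#' The eight canonical taxonomic ranks
#'
#' The fixed rank ladder every lineage is projected onto, ordered from the
#' most inclusive (domain) to the least (subspecies). "superkingdom" in a
#' taxonomy dump is treated as a synonym of "domain".
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' tax_ranks()
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family",
    "genus", "species", "subspecies")
}

# rank label -> slot index (1..8), with the superkingdom synonym folded in
rank_slot <- function(rank_label) {
  slots <- stats::setNames(seq_len(8L), tax_ranks())
  slots[["superkingdom"]] <- 1L
  out <- slots[rank_label]
  unname(out)
}

#' Load a taxonomy from dump files
#'
#' Reads a taxonomy tree from an NCBI-style `nodes.dmp` / `names.dmp` pair
#' (fields separated by `"\t|\t"`, lines terminated by `"\t|"`) or from the
#' simplified plain-TSV dialect (`nodes`: taxid, parent, rank; `names`:
#' taxid, name, and optionally a name class column). The dialect is
#' auto-detected from the first line of each file.
#'
#' The root is the node that is its own parent. Every other node must have a
#' parent present in the file; an orphan reference is an error naming the
#' offending node.
#'
#' @param nodes_path Path to the nodes table.
#' @param names_path Path to the names table.
#' @param name_classes Name classes loaded into the name index. Defaults to
#'   `"scientific name"` only; pass additional classes (e.g. `"synonym"`) to
#'   make them resolvable. Rows in the simplified dialect without a class
#'   column are treated as scientific names.
#' @return A `tax_db` object: a list with `nodes` (tibble of taxid, parent,
#'   rank, name), `name_index`, `root_id`, and a precomputed eight-rank
#'   lineage matrix used by [homogenize()].
#' @export
load_taxdump <- function(nodes_path, names_path,
                         name_classes = "scientific name") {
  node_rows <- read_dmp_table(nodes_path)
  if (nrow(node_rows) == 0L) {
    abort(sprintf("no nodes in '%s'", nodes_path))
  }
  if (ncol(node_rows) < 3L) {
    abort(sprintf("nodes table '%s' needs at least 3 columns (taxid, parent, rank)",
                  nodes_path))
  }
  taxid <- suppressWarnings(as.integer(node_rows[[1]]))
  parent <- suppressWarnings(as.integer(node_rows[[2]]))
  rank <- trimws(node_rows[[3]])
  if (anyNA(taxid) || anyNA(parent)) {
    bad <- which(is.na(taxid) | is.na(parent))[1]
    abort(sprintf("malformed taxid/parent on row %d of '%s'", bad, nodes_path))
  }
  if (anyDuplicated(taxid)) {
    dup <- taxid[duplicated(taxid)][1]
    abort(sprintf("duplicate node id %d in '%s'", dup, nodes_path))
  }

  name_rows <- read_dmp_table(names_path)
  if (nrow(name_rows) > 0L) {
    name_taxid <- suppressWarnings(as.integer(name_rows[[1]]))
    name_txt <- trimws(name_rows[[2]])
    # NCBI names.dmp order is taxid | name | unique name | class; the
    # simplified dialect is taxid, name[, class]
    last_col <- trimws(name_rows[[ncol(name_rows)]])
    name_class <- if (ncol(name_rows) >= 3L && any(last_col != "")) {
      last_col
    } else {
      rep("scientific name", nrow(name_rows))
    }
    keep <- name_class %in% name_classes
    name_taxid <- name_taxid[keep]
    name_txt <- name_txt[keep]
  } else {
    name_taxid <- integer()
    name_txt <- character()
  }

  build_tax_db(taxid, parent, rank, name_taxid, name_txt)
}

# Split a dump table into a character matrix-ish list of columns, accepting
# both the "\t|\t"-separated NCBI dialect and plain TSV.
read_dmp_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(as.data.frame(matrix(character(), nrow = 0, ncol = 3)))
  }
  ncbi <- grepl("\t|\t", lines[1], fixed = TRUE) || grepl("\\t\\|$", lines[1])
  if (ncbi) {
    lines <- sub("\t\\|$", "", lines)
    parts <- strsplit(lines, "\t|\t", fixed = TRUE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    # a simplified dialect may carry a header; drop it if col 1 is not numeric
    if (length(parts) > 0 && is.na(suppressWarnings(as.integer(parts[[1]][1])))) {
      parts <- parts[-1]
    }
  }
  if (length(parts) == 0L) {
    return(as.data.frame(matrix(character(), nrow = 0, ncol = 3)))
  }
  ncols <- max(lengths(parts))
  mat <- vapply(parts, function(p) c(p, rep("", ncols - length(p)))[seq_len(ncols)],
                character(ncols))
  as.data.frame(t(matrix(mat, nrow = ncols)), stringsAsFactors = FALSE)
}

build_tax_db <- function(taxid, parent, rank, name_taxid, name_txt) {
  n <- length(taxid)
  idx <- stats::setNames(seq_len(n), taxid)

  root <- taxid[taxid == parent]
  if (length(root) == 0L) abort("no root node (a node that is its own parent)")
  if (length(root) > 1L) {
    abort(sprintf("multiple root nodes: %s", paste(root, collapse = ", ")))
  }
  missing_parent <- !(parent %in% taxid)
  if (any(missing_parent)) {
    orphan <- taxid[missing_parent][1]
    abort(sprintf(
      "orphan node %d: parent %d is not present in the nodes table",
      orphan, parent[missing_parent][1]
    ))
  }

  name <- rep(NA_character_, n)
  known <- !is.na(name_taxid) & as.character(name_taxid) %in% names(idx)
  first <- !duplicated(name_taxid) & known
  name[idx[as.character(name_taxid[first])]] <- name_txt[first]

  lineage <- lineage_matrix(taxid, parent, rank, idx, root)

  nodes <- tibble(
    taxid = taxid, parent = parent, rank = rank, name = name
  )
  keep_names <- known
  name_index <- tibble(
    name_norm = normalize_name(name_txt[keep_names]),
    taxid = name_taxid[keep_names]
  )
  name_index <- dplyr::arrange(dplyr::distinct(name_index), .data$name_norm, .data$taxid)

  structure(
    list(
      nodes = nodes,
      name_index = name_index,
      root_id = root,
      lineage = lineage,
      index = idx
    ),
    class = "tax_db"
  )
}

# Walk the tree root-ward once, topologically, so each node inherits its
# parent's eight-rank projection before overlaying its own rank. The
# nearest-to-root occupant of a slot wins; a deeper duplicate of an already
# filled rank is ignored with a warning.
lineage_matrix <- function(taxid, parent, rank, idx, root) {
  n <- length(taxid)
  mat <- matrix(NA_integer_, nrow = n, ncol = 8L,
                dimnames = list(taxid, tax_ranks()))
  children <- split(seq_len(n), parent)
  visited <- logical(n)
  queue <- idx[[as.character(root)]]
  visited[queue] <- TRUE
  dup_warned <- FALSE
  while (length(queue) > 0L) {
    i <- queue[1]
    queue <- queue[-1]
    pi <- idx[[as.character(parent[i])]]
    if (pi != i) mat[i, ] <- mat[pi, ]
    slot <- rank_slot(rank[i])
    if (!is.na(slot)) {
      if (is.na(mat[i, slot])) {
        mat[i, slot] <- taxid[i]
      } else if (!dup_warned) {
        warn(sprintf(
          "node %d repeats rank '%s' already filled by ancestor %d; keeping the ancestor",
          taxid[i], rank[i], mat[i, slot]
        ))
        dup_warned <- TRUE
      }
    }
    kids <- children[[as.character(taxid[i])]]
    kids <- kids[!visited[kids]]
    if (length(kids)) {
      visited[kids] <- TRUE
      queue <- c(queue, kids)
    }
  }
  if (!all(visited)) {
    bad <- taxid[!visited][1]
    abort(sprintf("node %d is not reachable from the root (cycle or detached subtree)", bad))
  }
  mat
}

normalize_name <- function(x) {
  stringr::str_squish(tolower(x))
}

#' @export
print.tax_db <- function(x, ...) {
  cat(sprintf(
    "<tax_db> %d nodes, root id %d, %d indexed names\n",
    nrow(x$nodes), x$root_id, nrow(x$name_index)
  ))
  invisible(x)
}

check_taxids <- function(db, taxids, arg = "taxid") {
  known <- as.character(taxids) %in% names(db$index)
  if (!all(known | is.na(taxids))) {
    abort(sprintf("unknown %s: %s", arg,
                  paste(unique(taxids[!known & !is.na(taxids)]), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Project taxids onto the eight canonical ranks
#'
#' Walks each taxid's ancestor path and places every ancestor whose rank is
#' one of the eight canonical labels into the matching slot ("superkingdom"
#' counts as domain). Non-canonical ranks ("no rank", "strain", ...) never
#' fill a slot, so a lineage may have gaps (e.g. an order with no ranked
#' class above it); gaps are preserved as `NA`.
#'
#' @param db A `tax_db` from [load_taxdump()] or [make_mock_taxonomy()].
#' @param taxids Integer vector of taxids present in `db`.
#' @param strain_as_subspecies If `TRUE`, a queried node of rank
#'   `"strain"`/`"no rank"` whose parent is a species fills the otherwise
#'   empty subspecies slot with its own taxid. Off by default.
#' @return A tibble with one row per input taxid: `taxid` plus one integer
#'   column per rank (`NA` = no taxon at that rank).
#' @export
homogenize <- function(db, taxids, strain_as_subspecies = FALSE) {
  stopifnot(inherits(db, "tax_db"))
  taxids <- as.integer(taxids)
  check_taxids(db, taxids)
  rows <- db$index[as.character(taxids)]
  mat <- db$lineage[rows, , drop = FALSE]
  if (strain_as_subspecies && length(taxids) > 0L) {
    rk <- db$nodes$rank[rows]
    parent_rank <- db$nodes$rank[db$index[as.character(db$nodes$parent[rows])]]
    fill <- rk %in% c("strain", "no rank") & parent_rank == "species" &
      is.na(mat[, 8L])
    mat[fill, 8L] <- taxids[fill]
  }
  out <- as_tibble(as.data.frame(mat, row.names = NULL))
  dplyr::bind_cols(tibble(taxid = taxids), out)
}

# internal: lineage matrix (n x 8) for a taxid vector, NA rows for NA taxids
lineage_rows <- function(db, taxids, strain_as_subspecies = FALSE) {
  mat <- matrix(NA_integer_, nrow = length(taxids), ncol = 8L,
                dimnames = list(NULL, tax_ranks()))
  ok <- !is.na(taxids)
  if (any(ok)) {
    h <- homogenize(db, taxids[ok], strain_as_subspecies = strain_as_subspecies)
    mat[ok, ] <- as.matrix(h[, tax_ranks()])
  }
  mat
}

# path from root down to taxid (inclusive), as a taxid vector
root_path <- function(db, taxid) {
  path <- integer()
  cur <- taxid
  repeat {
    path <- c(cur, path)
    nxt <- db$nodes$parent[db$index[[as.character(cur)]]]
    if (nxt == cur) break
    cur <- nxt
  }
  path
}

#' Lowest common ancestor of a set of taxids
#'
#' The deepest node lying on every input taxid's path to the root. Used to
#' collapse ambiguous multi-taxon classifier calls to a single conservative
#' assignment. `lca(db, x)` of a single taxid is `x` itself.
#'
#' @inheritParams homogenize
#' @param taxids Non-empty integer vector of taxids present in `db`.
#' @return A single taxid.
#' @export
lca <- function(db, taxids) {
  stopifnot(inherits(db, "tax_db"))
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L || all(is.na(taxids))) {
    abort("lca() needs at least one taxid")
  }
  if (anyNA(taxids)) abort("lca() taxids must not be NA")
  check_taxids(db, taxids)
  if (length(taxids) == 1L) return(taxids)
  paths <- lapply(taxids, function(t) root_path(db, t))
  depth <- min(lengths(paths))
  common <- 0L
  for (d in seq_len(depth)) {
    step <- vapply(paths, `[[`, integer(1), d)
    if (all(step == step[1])) common <- d else break
  }
  if (common == 0L) abort("taxids share no common ancestor (disconnected tree?)")
  paths[[1]][common]
}

#' Resolve a taxon name to taxids
#'
#' Case-insensitive, whitespace-normalized exact lookup against the name
#' index. Homonyms return every matching taxid in increasing id order; an
#' unknown name returns an empty vector (not an error), leaving the caller
#' to decide how an unresolvable label is scored.
#'
#' @inheritParams homogenize
#' @param name A single taxon name.
#' @return Integer vector of matching taxids (possibly empty).
#' @export
resolve_name <- function(db, name) {
  stopifnot(inherits(db, "tax_db"), length(name) == 1L)
  hits <- db$name_index$taxid[db$name_index$name_norm == normalize_name(name)]
  sort(unique(hits))
}

#' Write homogenized lineages as TSV
#'
#' Serializes the eight-rank projection of `taxids` as an 8 + 1 column TSV
#' (taxid then one column per rank, empty string for an empty slot).
#'
#' @inheritParams homogenize
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(db, taxids, path) {
  h <- homogenize(db, taxids)
  h <- dplyr::mutate(h, dplyr::across(dplyr::all_of(tax_ranks()),
                                      ~ifelse(is.na(.x), "", as.character(.x))))
  readr::write_tsv(h, path)
  invisible(path)
}
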