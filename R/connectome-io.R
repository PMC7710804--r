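#' @title Connectome data model and file I/O
#'
#' @description Readers, writers and validating constructors for the three
#'   on-disk inputs of a connectome study: a node (parcellation) table, one
#'   weighted connectivity matrix per subject, and a cohort manifest.
#'   All text I/O is UTF-8 with a decimal point; node order is defined by
#'   the node table and every matrix in a study must follow it.
#' @name connectome-io
NULL

REQUIRED_NODE_COLUMNS <- c("node_id", "label", "community", "hemisphere",
                           "x", "y", "z")

#' Construct a parcellation from a node metadata data frame
#'
#' A parcellation is the ordered node template shared by every connectivity
#' matrix in a study: one row per cortical area, with an integer `node_id`,
#' a free-text `label`, a functional `community` (e.g. "ventral attention"),
#' a `hemisphere` code (`"L"` or `"R"`) and centroid coordinates `x`, `y`,
#' `z` in millimetres of the template space. Row order is canonical: row k
#' of the table is row/column k of every matrix.
#'
#' @param nodes data frame with columns `node_id`, `label`, `community`,
#'   `hemisphere`, `x`, `y`, `z`.
#' @return An object of class `parcellation` (a validated data frame).
#' @export
parcellation <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  missing_cols <- setdiff(REQUIRED_NODE_COLUMNS, names(nodes))
  if (length(missing_cols) > 0L)
    stop("node table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  nodes <- as.data.frame(nodes)[, REQUIRED_NODE_COLUMNS]
  nodes$node_id <- as.integer(nodes$node_id)
  if (nrow(nodes) < 2L)
    stop("a parcellation needs at least 2 nodes", call. = FALSE)
  if (anyNA(nodes$node_id) || any(nodes$node_id < 1L))
    stop("node_id must be a positive integer", call. = FALSE)
  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup) > 0L)
    stop("duplicate node_id ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (!all(nodes$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  for (col in c("x", "y", "z")) {
    nodes[[col]] <- as.numeric(nodes[[col]])
    if (any(!is.finite(nodes[[col]])))
      stop("non-finite centroid coordinate in column ", col, call. = FALSE)
  }
  rownames(nodes) <- NULL
  class(nodes) <- c("parcellation", "data.frame")
  nodes
}

#' Number of nodes in a parcellation
#' @param x a `parcellation`
#' @return integer node count
#' @export
n_nodes <- function(x) {
  stopifnot(inherits(x, "parcellation"))
  nrow(x)
}

#' Read a node (parcellation) table
#'
#' Reads a delimited text table (tab or comma separated, header required,
#' UTF-8 with optional BOM) with columns `node_id`, `label`, `community`,
#' `hemisphere`, `x`, `y`, `z` and returns the parcellation in file order.
#'
#' @param path path to the node table.
#' @return A [parcellation()].
#' @export
read_node_table <- function(path) {
  sep <- detect_sep(path)
  nodes <- read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, strip.white = TRUE,
                      fileEncoding = "UTF-8-BOM", comment.char = "")
  parcellation(nodes)
}

#' Write a node table
#' @param parc a [parcellation()]
#' @param path output path; tab-separated with header.
#' @return `invisible(path)`
#' @export
write_node_table <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  write.table(as.data.frame(parc), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a connectome from a weight matrix
#'
#' A connectome is one subject's weighted undirected graph over the
#' parcellation nodes; weights are streamline counts (non-negative,
#' unitless). The matrix must be symmetric to within `tol` (asymmetries
#' below `tol` are averaged away; anything larger is treated as a wrong
#' file, not noise), with a zero diagonal (a non-zero diagonal is zeroed
#' with a warning) and no negative or non-finite entries.
#'
#' @param weights N x N numeric matrix of streamline counts.
#' @param parc the [parcellation()] defining node order; N must equal
#'   `n_nodes(parc)`.
#' @param tol symmetry tolerance (default `1e-9`).
#' @return An object of class `connectome`: a list with elements `weights`
#'   and `parcellation`.
#' @export
connectome <- function(weights, parc, tol = 1e-9) {
  stopifnot(inherits(parc, "parcellation"))
  weights <- as.matrix(weights)
  N <- n_nodes(parc)
  if (nrow(weights) != N || ncol(weights) != N)
    stop(sprintf("matrix is %d x %d but the parcellation has %d nodes",
                 nrow(weights), ncol(weights), N), call. = FALSE)
  bad <- which(!is.finite(weights), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite weight at (%d,%d)", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  neg <- which(weights < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative weight at (%d,%d)", neg[1, 1], neg[1, 2]),
         call. = FALSE)
  asym <- max(abs(weights - t(weights)))
  if (asym > tol)
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.1g", asym, tol),
         call. = FALSE)
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warning("non-zero diagonal entries set to 0", call. = FALSE)
    diag(weights) <- 0
  }
  dimnames(weights) <- NULL
  structure(list(weights = weights, parcellation = parc),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  W <- x$weights
  ne <- sum(W[upper.tri(W)] > 0)
  cat(sprintf("connectome: %d nodes, %d edges, total weight %.6g\n",
              nrow(W), ne, sum(W) / 2))
  invisible(x)
}

#' Read a connectivity matrix
#'
#' Reads a whitespace- or comma-delimited N x N numeric matrix (optionally
#' gzip-compressed) and validates it against the parcellation via
#' [connectome()].
#'
#' @inheritParams connectome
#' @param path path to the matrix file.
#' @param normalize if `TRUE`, divide all weights by the matrix total so
#'   that weights sum to 1 over the upper triangle. Raw counts are the
#'   default; normalization is provided for studies that want to remove
#'   between-subject differences in total streamline count.
#' @return A `connectome`.
#' @export
read_connectivity_matrix <- function(path, parc, tol = 1e-9,
                                     normalize = FALSE) {
  if (!file.exists(path))
    stop("matrix file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  vals <- scan(path, what = numeric(), sep = if (sep == ",") "," else "",
               quiet = TRUE)
  N <- n_nodes(parc)
  if (length(vals) != N * N)
    stop(sprintf("matrix has %d values, expected %d x %d", length(vals),
                 N, N), call. = FALSE)
  W <- matrix(vals, nrow = N, byrow = TRUE)
  cn <- connectome(W, parc, tol = tol)
  if (normalize) {
    tot <- sum(cn$weights) / 2
    if (tot > 0) cn$weights <- cn$weights / tot
  }
  cn
}

#' Write a connectivity matrix
#' @param cn a `connectome`
#' @param path output path; tab-delimited plain text, one row per line.
#' @return `invisible(path)`
#' @export
write_connectivity_matrix <- function(cn, path) {
  stopifnot(inherits(cn, "connectome"))
  write.table(cn$weights, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a subject record
#'
#' @param subject_id character scalar.
#' @param group one of `"MSNI"`, `"MSCI"`, `"borderline"`, `"excluded"`,
#'   `"unknown"`.
#' @param ci_index cognitive-impairment index in `[0, 1]`, or `NA`.
#' @param connectome a `connectome` or `NULL`.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group = "unknown", ci_index = NA_real_,
                           connectome = NULL) {
  group <- match.arg(group,
                     c("MSNI", "MSCI", "borderline", "excluded", "unknown"))
  if (!is.na(ci_index) && (ci_index < 0 || ci_index > 1))
    stop("ci_index must lie in [0, 1]", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), group = group,
                 ci_index = as.numeric(ci_index), connectome = connectome),
            class = "subject_record")
}

#' Construct a cohort dataset
#'
#' The unit the comparison pipeline consumes: a shared parcellation plus a
#' list of subject records whose connectomes are all defined on it.
#'
#' @param parc shared [parcellation()].
#' @param subjects list of [subject_record()]s with unique subject ids.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(parc, subjects) {
  stopifnot(inherits(parc, "parcellation"))
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject_id ", ids[duplicated(ids)][1], call. = FALSE)
  for (s in subjects) {
    if (!is.null(s$connectome) &&
        nrow(s$connectome$weights) != n_nodes(parc))
      stop("subject ", s$subject_id,
           " has a connectome on a different parcellation", call. = FALSE)
  }
  structure(list(parcellation = parc, subjects = subjects),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$group, character(1))
  cat(sprintf("cohort_dataset: %d nodes, %d subjects (%s)\n",
              n_nodes(x$parcellation), length(x$subjects),
              paste(sprintf("%s: %d", names(table(groups)), table(groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Group labels of a cohort
#' @param dataset a `cohort_dataset`
#' @return character vector of group labels, one per subject.
#' @export
cohort_groups <- function(dataset) {
  vapply(dataset$subjects, function(s) s$group, character(1))
}

#' Drop borderline / excluded subjects
#'
#' Subjects whose impairment index falls between the two classification
#' thresholds are labelled borderline and must be excluded before any
#' between-group statistic is computed.
#'
#' @param dataset a `cohort_dataset`
#' @return the dataset restricted to subjects with group `MSNI` or `MSCI`.
#' @export
included_subjects <- function(dataset) {
  keep <- cohort_groups(dataset) %in% c("MSNI", "MSCI")
  cohort_dataset(dataset$parcellation, dataset$subjects[keep])
}

#' Read a cohort manifest
#'
#' The manifest is a delimited table with one row per subject:
#' `subject_id`, `matrix_path` (relative paths are resolved against the
#' manifest's directory) and either a `group` column, a `ci_index` column,
#' or both. When `group` is absent it is derived from `ci_index` via
#' [classify_ci()]; borderline subjects are retained in the dataset but
#' flagged so that [included_subjects()] drops them.
#'
#' @param path manifest path (TSV or CSV with header).
#' @param parc the study [parcellation()].
#' @param thresholds passed to [classify_ci()] when groups are derived.
#' @return A [cohort_dataset()] with eagerly loaded connectomes.
#' @export
read_cohort_manifest <- function(path, parc,
                                 thresholds = ci_thresholds()) {
  sep <- detect_sep(path)
  man <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, strip.white = TRUE,
                    fileEncoding = "UTF-8-BOM", comment.char = "")
  if (!"subject_id" %in% names(man))
    stop("manifest is missing column subject_id", call. = FALSE)
  if (!"matrix_path" %in% names(man))
    stop("manifest is missing column matrix_path", call. = FALSE)
  if (!("group" %in% names(man)) && !("ci_index" %in% names(man)))
    stop("manifest needs a group or a ci_index column", call. = FALSE)
  base <- dirname(path)
  subjects <- lapply(seq_len(nrow(man)), function(k) {
    row <- man[k, ]
    mp <- row$matrix_path
    if (!file.exists(mp)) mp <- file.path(base, row$matrix_path)
    if (!file.exists(mp))
      stop("matrix file for subject ", row$subject_id, " not found: ",
           row$matrix_path, call. = FALSE)
    cn <- read_connectivity_matrix(mp, parc)
    ci <- if ("ci_index" %in% names(man)) as.numeric(row$ci_index)
          else NA_real_
    grp <- if ("group" %in% names(man)) as.character(row$group)
           else classify_ci(ci, thresholds)
    subject_record(row$subject_id, group = grp, ci_index = ci,
                   connectome = cn)
  })
  cohort_dataset(parc, subjects)
}

#' Write a results table
#'
#' Tab-separated output with header, stable column order and deterministic
#' float formatting: numeric columns are written with 6 significant digits.
#'
#' @param table a data frame.
#' @param path output path.
#' @return `invisible(path)`
#' @export
write_results_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- out[[col]]
      s <- trimws(formatC(signif(v, 6), format = "g", digits = 6))
      s[is.na(v)] <- NA_character_
      out[[col]] <- s
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path path to a TSV results table.
#' @return data frame.
#' @export
read_results_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8-BOM", comment.char = "")
}

# Guess the field separator of a delimited text file from its first line:
# tab wins over comma; otherwise whitespace.
detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}
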