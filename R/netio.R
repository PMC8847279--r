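#' Read a connectivity matrix from delimited text
#'
#' Reads a square numeric table (comma-, tab- or whitespace-delimited,
#' autodetected, no header) holding one subject's symmetric weighted
#' adjacency matrix of FA-based interregional connection weights, and
#' validates it: entries in \[0, 1\] scale is not enforced beyond
#' non-negativity, the diagonal must be exactly zero, and near-symmetric
#' input (maximum asymmetry below \code{1e-8}) is symmetrized by averaging.
#'
#' @param path Path to a delimited text file containing a square numeric
#'   table.
#' @param expected_n Optional integer; if given, the matrix must be
#'   \code{expected_n} x \code{expected_n}.
#' @return A validated symmetric numeric matrix with zero diagonal.
#' @export
read_matrix <- function(path, expected_n = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "numeric", strip.white = TRUE)
  m <- as.matrix(tab)
  dimnames(m) <- NULL
  if (!is.null(expected_n) && nrow(m) != expected_n)
    stop("matrix has ", nrow(m), " rows, expected ", expected_n)
  validate_matrix(m)
}

#' Validate (and symmetrize) a connectivity matrix
#'
#' @param m Numeric square matrix.
#' @param asym_tol Maximum absolute asymmetry tolerated; below this the
#'   matrix is symmetrized by averaging \code{(m + t(m)) / 2}, above it the
#'   function errors. Tractography-derived matrices are near-symmetric by
#'   construction, so genuine asymmetry indicates a corrupt file.
#' @return The validated symmetric matrix.
#' @export
validate_matrix <- function(m, asym_tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) stop("not a numeric matrix")
  if (nrow(m) != ncol(m)) stop("matrix is not square: ", nrow(m), " x ", ncol(m))
  if (anyNA(m)) stop("matrix contains NaN/NA entries")
  if (any(m < 0)) stop("negative weight in connectivity matrix")
  asym <- max(abs(m - t(m)))
  if (asym > asym_tol)
    stop("matrix asymmetry ", format(asym), " exceeds tolerance ", asym_tol)
  m <- (m + t(m)) / 2
  if (any(diag(m) != 0)) stop("diagonal entries must be exactly zero")
  m
}

#' Write a connectivity matrix as whitespace-delimited text
#'
#' Full-precision round-trip companion of \code{\link{read_matrix}}.
#'
#' @param m Symmetric numeric matrix.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = TRUE),
                                          collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a node (region) table
#'
#' CSV with header \code{node_id,label,network}: region identifiers on the
#' 1-based atlas convention, region names, and an intrinsic-connectivity
#' network tag per node (\code{"other"} allowed).
#'
#' @param path CSV path.
#' @param n_nodes Optional; node_ids must then be exactly \code{1:n_nodes}.
#' @return data.frame with columns node_id, label, network.
#' @export
read_node_table <- function(path, n_nodes = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_id", "label", "network")
  if (!all(need %in% names(tab))) stop("node table must have columns ",
                                       paste(need, collapse = ","))
  ids <- sort(tab$node_id)
  if (any(duplicated(ids))) stop("duplicate node_id in node table")
  if (!identical(ids, seq_along(ids))) stop("node_ids must be contiguous 1..n")
  if (!is.null(n_nodes) && length(ids) != n_nodes)
    stop("node table has ", length(ids), " nodes, expected ", n_nodes)
  if (any(is.na(tab$network) | tab$network == ""))
    stop("every node needs a network tag (use 'other')")
  tab[order(tab$node_id), , drop = FALSE]
}

#' Read a subject table into a cohort skeleton
#'
#' CSV with header
#' \code{subject_id,group,age,sex,behavior_score,matrix_file}. Groups must
#' be \code{patient}/\code{control}; every patient needs a behavior score
#' (the speech-intelligibility scale is measured in patients only), controls
#' may have it missing. Rows are sorted by subject_id so the cohort is
#' invariant to input row order.
#'
#' @param path CSV path.
#' @return A cohort skeleton: data.frame of subjects without matrices.
#' @export
read_subject_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex", "matrix_file")
  if (!all(need %in% names(tab)))
    stop("subject table must have columns ", paste(need, collapse = ","))
  if (is.null(tab$behavior_score)) tab$behavior_score <- NA_real_
  validate_subjects(tab)
}

validate_subjects <- function(tab) {
  if (any(duplicated(tab$subject_id)))
    stop("duplicate subject_id: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(tab$group), c("patient", "control"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  if (!all(table(factor(tab$group, c("patient", "control"))) > 0L))
    stop("both groups must be non-empty")
  if (!all(tab$sex %in% c("M", "F"))) stop("sex must be M or F")
  miss <- tab$group == "patient" & is.na(tab$behavior_score)
  if (any(miss))
    stop("patients require a behavior score: ",
         paste(tab$subject_id[miss], collapse = ", "))
  tab <- tab[order(tab$subject_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Attach connectivity matrices to a cohort skeleton
#'
#' @param skeleton Output of \code{\link{read_subject_table}}.
#' @param directory Directory holding the files named in
#'   \code{matrix_file}.
#' @return A \code{cohort} object: list with \code{$subjects} (data.frame)
#'   and \code{$matrices} (list of matrices in subject order).
#' @export
attach_matrices <- function(skeleton, directory) {
  paths <- file.path(directory, skeleton$matrix_file)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing matrix file: ", paste(paths[missing], collapse = ", "))
  mats <- lapply(paths, read_matrix)
  new_cohort(skeleton, mats)
}

#' Construct a validated cohort
#'
#' @param subjects Subject data.frame (see \code{\link{read_subject_table}}).
#' @param matrices List of connectivity matrices, one per subject row.
#' @return A \code{cohort} object.
#' @export
new_cohort <- function(subjects, matrices) {
  if (length(matrices) != nrow(subjects))
    stop("need one matrix per subject")
  matrices <- matrices[order(subjects$subject_id)]
  subjects <- validate_subjects(subjects)
  ns <- vapply(matrices, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("all matrices must share n_nodes; got ", paste(unique(ns), collapse = ", "))
  matrices <- lapply(matrices, validate_matrix)
  structure(list(subjects = subjects, matrices = matrices,
                 n_nodes = ns[[1L]]),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "patient"), "patients /",
      sum(x$subjects$group == "control"), "controls ),",
      x$n_nodes, "nodes\n")
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Writes one matrix file per subject plus \code{subjects.csv}, in the
#' exchange layout \code{\link{attach_matrices}} reads back.
#'
#' @param cohort A \code{cohort}.
#' @param directory Output directory (created if needed).
#' @return \code{directory}, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  sub <- cohort$subjects
  if (is.null(sub$matrix_file) || anyNA(sub$matrix_file))
    sub$matrix_file <- paste0(sub$subject_id, ".txt")
  for (i in seq_len(nrow(sub)))
    write_matrix(cohort$matrices[[i]], file.path(directory, sub$matrix_file[i]))
  utils::write.csv(sub, file.path(directory, "subjects.csv"), row.names = FALSE)
  invisible(directory)
}

#' Read a cohort back from a directory written by \code{write_cohort}
#' @param directory Cohort directory.
#' @return A \code{cohort}.
#' @export
read_cohort <- function(directory) {
  skel <- read_subject_table(file.path(directory, "subjects.csv"))
  attach_matrices(skel, directory)
}
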