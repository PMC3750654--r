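# Gene x GO-class binary membership matrix: rows are genes in input order,
# columns are the union of all closed terms sorted by numeric key. Cells are
# kept as 1-based (row, col) triplets; the sparse three-column layout is the
# primary on-disk form, with a full 0/1 grid and MatrixMarket as options.

new_membership_matrix <- function(row_names, col_names, i, j) {
  o <- order(i, j)
  structure(list(
    row_names = row_names,
    col_names = col_names,
    i = as.integer(i)[o],
    j = as.integer(j)[o]
  ), class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("<membership_matrix: %d gene(s) x %d GO class(es), %d cell(s)>\n",
              length(x$row_names), length(x$col_names), length(x$i)))
  invisible(x)
}

#' @export
dim.membership_matrix <- function(x) {
  c(length(x$row_names), length(x$col_names))
}

#' Build the binary membership matrix from a closed annotation set
#'
#' Reported GO classes are exactly those occurring in the closed input —
#' direct annotations plus their parents; columns are sorted by numeric key,
#' rows follow input gene order. Genes whose closure is empty keep their row
#' (all zero), so the row registry always matches the input gene list.
#'
#' @param closed a closed `annotation_set`.
#' @return a `membership_matrix`.
#' @export
build_matrix <- function(closed) {
  stopifnot(inherits(closed, "annotation_set"))
  if (all(lengths(closed$terms) == 0L)) {
    stop("no gene has a non-empty closed term set; nothing to build",
         call. = FALSE)
  }
  col_names <- unique(unlist(closed$terms, use.names = FALSE))
  col_names <- col_names[order(accession_key(col_names))]
  i <- rep.int(seq_along(closed$gene_id), lengths(closed$terms))
  j <- match(unlist(closed$terms, use.names = FALSE), col_names)
  new_membership_matrix(closed$gene_id, col_names, i, j)
}

#' Convert a membership matrix to a Matrix sparse matrix
#'
#' @param m a `membership_matrix`.
#' @return a `Matrix::sparseMatrix` (dgCMatrix) with dimnames.
#' @export
as_sparse_matrix <- function(m) {
  Matrix::sparseMatrix(
    i = m$i, j = m$j, x = 1,
    dims = dim(m), dimnames = list(m$row_names, m$col_names)
  )
}

#' @export
as.matrix.membership_matrix <- function(x, ...) {
  out <- matrix(0L, nrow = length(x$row_names), ncol = length(x$col_names),
                dimnames = list(x$row_names, x$col_names))
  if (length(x$i)) out[cbind(x$i, x$j)] <- 1L
  out
}

#' Write a membership matrix as sparse triplets plus name registries
#'
#' The triplet file holds one `row<TAB>col<TAB>1` line per non-zero cell,
#' sorted by (row, col); the row-name and column-name files hold one name
#' per line, the line number being the 1-based index used in the triplets.
#' This three-file layout imports directly into R (`Matrix::sparseMatrix`),
#' Matlab (`sparse`) and Python (`scipy.sparse.coo_matrix`).
#'
#' @param m a `membership_matrix`.
#' @param triplet_path,rownames_path,colnames_path output file paths.
#' @return invisibly, the number of triplets written.
#' @export
write_sparse <- function(m, triplet_path, rownames_path, colnames_path) {
  data.table::fwrite(
    list(m$i, m$j, rep.int(1L, length(m$i))),
    file = triplet_path, sep = "\t", col.names = FALSE, eol = "\n"
  )
  writeLines(m$row_names, rownames_path, useBytes = TRUE)
  writeLines(m$col_names, colnames_path, useBytes = TRUE)
  invisible(length(m$i))
}

#' Read a sparse-triplet membership matrix back
#'
#' Inverse of [write_sparse()]: rejects indices outside the name registries,
#' values other than 1, and duplicate cells.
#'
#' @param triplet_path,rownames_path,colnames_path files as written by
#'   [write_sparse()].
#' @return a `membership_matrix`.
#' @export
read_sparse <- function(triplet_path, rownames_path, colnames_path) {
  row_names <- readLines(rownames_path, warn = FALSE)
  col_names <- readLines(colnames_path, warn = FALSE)
  if (!length(row_names) || !length(col_names)) {
    stop("empty row or column name registry", call. = FALSE)
  }
  if (file.size(triplet_path) == 0) {
    return(new_membership_matrix(row_names, col_names, integer(), integer()))
  }
  tr <- data.table::fread(triplet_path, sep = "\t", header = FALSE,
                          colClasses = "integer")
  if (ncol(tr) != 3L) stop("triplet file must have 3 columns", call. = FALSE)
  i <- tr[[1L]]
  j <- tr[[2L]]
  v <- tr[[3L]]
  if (any(v != 1L)) stop("triplet values must all be 1", call. = FALSE)
  if (any(i < 1L | i > length(row_names)) ||
      any(j < 1L | j > length(col_names))) {
    stop("triplet index out of range of the name registries", call. = FALSE)
  }
  if (anyDuplicated(cbind(i, j))) {
    stop("duplicate cell in triplet file", call. = FALSE)
  }
  new_membership_matrix(row_names, col_names, i, j)
}

#' Write a membership matrix as a full 0/1 grid
#'
#' Tab-separated; the header row is an empty corner cell followed by the
#' column names, then one row per gene: the gene id and `|col_names|` 0/1
#' fields. Densification of the sparse triplets cell-by-cell.
#'
#' @param m a `membership_matrix`.
#' @param path output file path.
#' @return invisibly, the number of data rows written.
#' @export
write_full <- function(m, path) {
  dense <- as.matrix(m)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("", m$col_names), collapse = "\t"), con, useBytes = TRUE)
  body <- apply(dense, 1L, paste, collapse = "\t")
  writeLines(paste0(m$row_names, "\t", body), con, useBytes = TRUE)
  invisible(length(m$row_names))
}

#' Write a membership matrix in MatrixMarket coordinate format
#'
#' Optional alternative to the native triplet layout, for direct
#' `scipy.io.mmread` / `Matrix::readMM` import; name registries are written
#' alongside as in [write_sparse()].
#'
#' @param m a `membership_matrix`.
#' @param mtx_path,rownames_path,colnames_path output file paths.
#' @return invisibly, the number of non-zero entries.
#' @export
write_mtx <- function(m, mtx_path, rownames_path, colnames_path) {
  Matrix::writeMM(as_sparse_matrix(m), mtx_path)
  writeLines(m$row_names, rownames_path, useBytes = TRUE)
  writeLines(m$col_names, colnames_path, useBytes = TRUE)
  invisible(length(m$i))
}
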