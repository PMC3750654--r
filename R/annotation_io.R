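# Readers for the two supported annotation dialects (generic tab-separated
# text and GAF 2.x) into a normalized, ordered gene -> term-set mapping, and
# the writer for the augmented per-gene listing with parents added.

new_annotation_set <- function(gene_id, terms, source_dialect,
                               counts = list(), closed = FALSE) {
  structure(list(
    gene_id = gene_id,
    terms = terms,
    source_dialect = source_dialect,
    counts = counts,
    closed = closed,
    summary = NULL
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d gene(s), %d term assignment(s), %s%s>\n",
              length(x$gene_id), sum(lengths(x$terms)), x$source_dialect,
              if (x$closed) ", closed" else ""))
  invisible(x)
}

# merge duplicate gene rows: union of term vectors, first position kept
merge_gene_records <- function(gene, terms_list) {
  first <- !duplicated(gene)
  ug <- gene[first]
  gi <- match(gene, ug)
  merged <- vector("list", length(ug))
  sp <- split(seq_along(gene), gi)
  for (k in seq_along(sp)) {
    merged[[k]] <- unique(unlist(terms_list[sp[[k]]], use.names = FALSE))
  }
  list(gene_id = ug, terms = merged)
}

#' Read a generic tab-separated annotation file
#'
#' Each row carries a gene name in column `gene_col` and accessions in one or
#' more `go_cols`; multi-valued cells are split on `go_separator`. Tokens are
#' whitespace-trimmed and kept when they match `prefix:digits`; anything else
#' is counted as malformed. Rows too short for the requested columns are
#' skipped with a count. Duplicate gene rows merge by term-set union at the
#' first row's position; genes with no valid token are dropped with a count.
#'
#' @param source path, connection, or character vector of lines.
#' @param gene_col 1-based column index of the gene name.
#' @param go_cols integer vector of 1-based accession column indices
#'   (must not contain `gene_col`).
#' @param go_separator separator inside a multi-valued accession cell
#'   (`";"` by default; `","` and `"|"` are common alternatives).
#' @param header `"auto"` skips a first row in which no `go_col` holds a
#'   valid accession; `TRUE`/`FALSE` force the behaviour.
#' @return an `annotation_set` with dialect `generic_tsv`; its `counts`
#'   report skipped/malformed/dropped bookkeeping.
#' @export
parse_generic <- function(source, gene_col, go_cols, go_separator = ";",
                          header = "auto") {
  gene_col <- as.integer(gene_col)
  go_cols <- as.integer(go_cols)
  if (gene_col < 1L || any(go_cols < 1L)) {
    stop("column indices are 1-based; got a value below 1", call. = FALSE)
  }
  if (gene_col %in% go_cols) {
    stop("gene_col must not appear in go_cols", call. = FALSE)
  }
  lines <- read_text_lines(source)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty annotation file", call. = FALSE)

  cells <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(gene_col, go_cols)

  extract_row <- function(row) {
    toks <- unlist(strsplit(row[go_cols], go_separator, fixed = TRUE),
                   use.names = FALSE)
    trimws(toks)
  }

  header_skipped <- FALSE
  if (length(cells)) {
    first <- cells[[1L]]
    skip1 <- if (identical(header, "auto")) {
      length(first) >= need && !any(is_valid_accession(extract_row(first)))
    } else {
      isTRUE(header)
    }
    if (skip1 && length(cells) >= 1L) {
      cells <- cells[-1L]
      header_skipped <- TRUE
    }
  }
  if (!length(cells)) stop("no data rows in annotation file", call. = FALSE)

  ok_len <- lengths(cells) >= need
  n_short <- sum(!ok_len)
  if (n_short) {
    warning(n_short, " row(s) shorter than required column count skipped",
            call. = FALSE)
  }
  if (all(lengths(cells) < gene_col)) {
    stop("gene_col=", gene_col, " out of range on every row", call. = FALSE)
  }
  cells <- cells[ok_len]
  if (!length(cells)) stop("zero valid rows in annotation file", call. = FALSE)

  gene <- vapply(cells, `[[`, character(1L), gene_col)
  toks <- lapply(cells, extract_row)
  valid <- lapply(toks, function(t) t[is_valid_accession(t)])
  n_malformed <- sum(lengths(toks)) - sum(lengths(valid)) -
    sum(vapply(toks, function(t) sum(!nzchar(t)), integer(1L)))

  if (any(!nzchar(gene))) {
    keep <- nzchar(gene)
    warning(sum(!keep), " row(s) with empty gene name skipped", call. = FALSE)
    gene <- gene[keep]
    valid <- valid[keep]
  }

  merged <- merge_gene_records(gene, valid)
  empty <- lengths(merged$terms) == 0L
  n_dropped <- sum(empty)
  if (n_dropped) {
    warning(n_dropped, " gene(s) with no valid accession dropped", call. = FALSE)
  }
  if (all(empty)) stop("zero genes with a valid accession", call. = FALSE)

  new_annotation_set(
    gene_id = merged$gene_id[!empty],
    terms = merged$terms[!empty],
    source_dialect = "generic_tsv",
    counts = list(
      n_rows = length(lines) - header_skipped,
      n_short_rows_skipped = n_short,
      n_malformed_tokens = n_malformed,
      n_empty_genes_dropped = n_dropped,
      header_skipped = header_skipped
    )
  )
}

#' Read a GAF 2.x gene association file
#'
#' Comment lines start with `!`. Column 2 is the DB object id (the gene),
#' column 5 the GO accession, column 4 the qualifier: associations qualified
#' with `NOT` are excluded and counted. One term is appended per association
#' line; duplicate gene/term pairs merge as in [parse_generic()].
#'
#' @param source path, connection, or character vector of lines.
#' @return an `annotation_set` with dialect `gaf`.
#' @export
parse_gaf <- function(source) {
  lines <- read_text_lines(source)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) {
    stop("no non-comment lines in GAF input", call. = FALSE)
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ok_len <- lengths(cells) >= 15L
  n_short <- sum(!ok_len)
  if (n_short) {
    warning(n_short, " GAF line(s) with fewer than 15 columns skipped",
            call. = FALSE)
  }
  cells <- cells[ok_len]
  if (!length(cells)) stop("zero well-formed GAF lines", call. = FALSE)

  gene <- vapply(cells, `[[`, character(1L), 2L)
  qual <- vapply(cells, `[[`, character(1L), 4L)
  term <- vapply(cells, `[[`, character(1L), 5L)

  is_not <- vapply(strsplit(qual, "|", fixed = TRUE),
                   function(q) "NOT" %in% q, logical(1L))
  n_not <- sum(is_not)

  keep <- !is_not & is_valid_accession(term) & nzchar(gene)
  n_malformed <- sum(!is_not & !is_valid_accession(term))
  if (!any(keep)) stop("zero usable GAF associations", call. = FALSE)

  merged <- merge_gene_records(gene[keep], as.list(term[keep]))
  new_annotation_set(
    gene_id = merged$gene_id,
    terms = merged$terms,
    source_dialect = "gaf",
    counts = list(
      n_lines = length(lines),
      n_short_rows_skipped = n_short,
      n_not_excluded = n_not,
      n_malformed_tokens = n_malformed
    )
  )
}

#' Write the augmented (parent-added) per-gene listing
#'
#' One tab-separated row per gene: the gene id, then all closed accessions
#' joined with `";"` in a single second column, in the stored order (closed
#' sets are sorted by numeric key). Genes whose closure came out empty keep
#' their row with an empty second field. Output is byte-identical across
#' runs on identical input.
#'
#' @param closed a closed `annotation_set` (see [close_annotation_set()]).
#' @param path file path or writable connection.
#' @return invisibly, the number of rows written.
#' @export
write_augmented <- function(closed, path) {
  stopifnot(inherits(closed, "annotation_set"))
  joined <- vapply(closed$terms, paste, character(1L), collapse = ";")
  writeLines(paste0(closed$gene_id, "\t", joined), path, useBytes = TRUE)
  invisible(length(closed$gene_id))
}
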