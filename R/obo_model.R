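# OBO 1.2 flat-file model: parse [Term] stanzas into an in-memory DAG keyed by
# the numeric part of the accession, resolve any incoming accession (primary,
# alt_id, obsolete) to live term(s), and serialize back to OBO text.

VALID_ACCESSION <- "^[A-Za-z_][A-Za-z0-9_]*:[0-9]+$"

#' Test whether a token is a syntactically valid ontology accession
#'
#' Accessions have the shape `prefix:digits`, e.g. `GO:0008150` or
#' `PO:0000001`. The numeric part (ignoring zero padding) is the term key.
#'
#' @param x character vector of tokens.
#' @return logical vector.
#' @export
is_valid_accession <- function(x) {
  grepl(VALID_ACCESSION, x)
}

#' Numeric key of an accession
#'
#' @param x character vector of accessions (`prefix:digits`).
#' @return integer vector of numeric keys (digits parsed as integer).
#' @export
accession_key <- function(x) {
  as.integer(sub("^[^:]*:", "", x))
}

accession_prefix <- function(x) sub(":.*$", "", x)

# strip a trailing "! comment" from a tag value (OBO comment syntax)
strip_obo_comment <- function(x) trimws(sub("\\s*!.*$", "", x))

#' @export
format.ontology <- function(x, ...) {
  live <- sum(!x$is_obsolete)
  sprintf(
    "<ontology: %d terms (%d live, %d obsolete), %d parent edges, %d alt ids%s>",
    n_terms(x), live, n_terms(x) - live, x$n_edges, length(x$alt_index),
    if (!is.na(x$source_date)) paste0(", dated ", format(x$source_date)) else ""
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Number of terms in an ontology
#' @param ontology an `ontology` object.
#' @return integer count of `[Term]` stanzas parsed (live and obsolete).
#' @export
n_terms <- function(ontology) length(ontology$numeric_key)

#' Keys of namespace roots (live terms with no parent edges)
#' @param ontology an `ontology` object.
#' @return integer vector of numeric keys.
#' @export
root_keys <- function(ontology) {
  has_parent <- lengths(ontology$is_a_parents) + lengths(ontology$part_of_parents) > 0L
  ontology$numeric_key[!ontology$is_obsolete & !has_parent]
}

# Internal constructor shared by parse_obo() and the fixture generator.
# Validates the DAG invariants: unique keys, no dangling parent references,
# acyclicity over is_a + part_of, alt ids disjoint from primary ids.
new_ontology <- function(numeric_key, go_id, prefix, name, namespace,
                         definition, is_obsolete, is_a_parents,
                         part_of_parents, consider_targets, replaced_by,
                         alt_ids, format_version = "1.2",
                         source_date = as.Date(NA)) {
  n <- length(numeric_key)
  if (anyDuplicated(numeric_key)) {
    dup <- go_id[duplicated(numeric_key)][1L]
    stop("duplicate primary id in ontology: ", dup, call. = FALSE)
  }

  all_parents <- c(unlist(is_a_parents, use.names = FALSE),
                   unlist(part_of_parents, use.names = FALSE))
  missing <- setdiff(all_parents, numeric_key)
  if (length(missing)) {
    stop("dangling parent reference(s): key ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }

  # non-obsolete terms carrying obsolete-only tags: keep, warn, never traverse
  stray <- !is_obsolete & (lengths(consider_targets) > 0L | !is.na(replaced_by))
  if (any(stray)) {
    warning(sum(stray), " non-obsolete term(s) carry replaced_by/consider ",
            "tags; retained but never used for resolution of live terms",
            call. = FALSE)
  }

  # traversal index: row indices of is_a + part_of parents, obsolete parents
  # excluded so closures never contain obsolete terms
  key2row <- seq_len(n)
  names(key2row) <- as.character(numeric_key)
  row_of <- function(keys) unname(key2row[as.character(keys)])
  parent_idx <- vector("list", n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    pk <- c(is_a_parents[[i]], part_of_parents[[i]])
    if (!length(pk)) {
      parent_idx[[i]] <- integer()
      next
    }
    ri <- row_of(unique(pk))
    keep <- !is_obsolete[ri]
    n_skipped <- n_skipped + sum(!keep)
    parent_idx[[i]] <- ri[keep]
  }
  n_edges <- sum(lengths(parent_idx))

  # acyclicity over the traversed edge set
  if (n_edges > 0L) {
    child <- rep.int(seq_len(n), lengths(parent_idx))
    par <- unlist(parent_idx, use.names = FALSE)
    g <- igraph::make_graph(c(rbind(child, par)), n = n, directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- find_one_cycle(parent_idx)
      stop("cycle detected over is_a/part_of edges: ",
           paste(go_id[cyc], collapse = " -> "), call. = FALSE)
    }
  }

  # alt id registry: first claim wins, ids colliding with a primary id dropped
  alt_owner <- rep.int(seq_len(n), lengths(alt_ids))
  alt_acc <- unlist(alt_ids, use.names = FALSE)
  if (length(alt_acc)) {
    clash <- alt_acc %in% go_id
    if (any(clash)) {
      warning("alt_id(s) colliding with a primary id dropped: ",
              paste(unique(alt_acc[clash]), collapse = ", "), call. = FALSE)
      alt_acc <- alt_acc[!clash]
      alt_owner <- alt_owner[!clash]
    }
    dup <- duplicated(alt_acc)
    if (any(dup)) {
      warning("alt_id(s) claimed by more than one term; first claim kept: ",
              paste(unique(alt_acc[dup]), collapse = ", "), call. = FALSE)
      alt_acc <- alt_acc[!dup]
      alt_owner <- alt_owner[!dup]
    }
  }
  alt_index <- structure(numeric_key[alt_owner], names = alt_acc)

  structure(list(
    format_version = format_version,
    source_date = source_date,
    numeric_key = as.integer(numeric_key),
    go_id = go_id,
    prefix = prefix,
    name = name,
    namespace = namespace,
    definition = definition,
    is_obsolete = is_obsolete,
    is_a_parents = is_a_parents,
    part_of_parents = part_of_parents,
    consider_targets = consider_targets,
    replaced_by = as.integer(replaced_by),
    alt_ids = alt_ids,
    alt_index = alt_index,
    parent_idx = parent_idx,
    n_edges = n_edges,
    n_obsolete_parent_edges_skipped = n_skipped
  ), class = "ontology")
}

# DFS for one explicit cycle; only reached when igraph::is_dag() is FALSE
find_one_cycle <- function(parent_idx) {
  n <- length(parent_idx)
  color <- integer(n) # 0 white, 1 on path, 2 done
  path <- integer(0)
  dfs <- function(v) {
    color[v] <<- 1L
    path <<- c(path, v)
    for (p in parent_idx[[v]]) {
      if (color[p] == 1L) {
        i <- match(p, path)
        return(c(path[i:length(path)], p))
      }
      if (color[p] == 0L) {
        r <- dfs(p)
        if (!is.null(r)) return(r)
      }
    }
    color[v] <<- 2L
    path <<- path[-length(path)]
    NULL
  }
  for (v in seq_len(n)) {
    if (color[v] == 0L) {
      r <- dfs(v)
      if (!is.null(r)) return(r)
    }
  }
  integer()
}

#' Parse an OBO 1.2 flat file into an ontology DAG
#'
#' Reads `[Term]` stanzas (other stanza types are skipped), storing for each
#' term its accession, name, namespace, definition, obsolete flag, `is_a` and
#' `relationship: part_of` parent edges, and the obsolete-resolution hints
#' `replaced_by`, `consider` and `alt_id`. Terms are keyed by the numeric
#' part of the accession, so non-GO prefixes (e.g. Plant Ontology `PO:`)
#' parse identically. Unix and Windows line endings are both accepted.
#'
#' Only `is_a` and `part_of` are stored as parent edges; all other
#' relationship types (`regulates`, `has_part`, ...) are ignored. `consider`
#' is a resolution hint for obsolete terms, never a DAG edge.
#'
#' Parse-time validation: duplicate primary ids, parent references to absent
#' terms, and cycles over the `is_a`/`part_of` edge set are errors; a stanza
#' with no `id` line is an error reporting its byte offset.
#'
#' @param source path to an OBO file, a connection, or a character vector of
#'   lines (length > 1, or containing newlines).
#' @return an `ontology` object.
#' @seealso [resolve_term()], [serialize_obo()], [ancestors()]
#' @export
parse_obo <- function(source) {
  lines <- read_text_lines(source)
  lines <- sub("\r$", "", lines)

  byte_off <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))

  stanza_start <- startsWith(lines, "[")
  sid <- cumsum(stanza_start)
  start_line <- which(stanza_start)
  stype <- lines[start_line] # one per stanza

  skipped <- unique(stype[stype != "[Term]"])
  if (length(skipped)) {
    message("skipping non-Term stanza type(s): ", paste(skipped, collapse = " "))
  }

  # header
  fv <- "1.2"
  sd <- as.Date(NA)
  hdr <- if (length(start_line)) lines[seq_len(start_line[1L] - 1L)] else lines
  m <- grep("^format-version:", hdr, value = TRUE)
  if (length(m)) fv <- trimws(sub("^format-version:", "", m[1L]))
  m <- grep("^date:", hdr, value = TRUE)
  if (length(m)) {
    d <- try(as.Date(substr(trimws(sub("^date:", "", m[1L])), 1L, 10L),
                     format = "%d:%m:%Y"), silent = TRUE)
    if (!inherits(d, "try-error") && !is.na(d)) sd <- d
  }

  term_sids <- which(stype == "[Term]")
  if (!length(term_sids)) {
    stop("no [Term] stanzas found in OBO input", call. = FALSE)
  }
  in_term <- sid > 0L & !stanza_start
  in_term[in_term] <- stype[sid[in_term]] == "[Term]"

  colon <- regexpr(":", lines, fixed = TRUE)
  tagline <- in_term & colon > 0L & !startsWith(lines, "!")
  li <- which(tagline)
  tag <- substr(lines[li], 1L, colon[li] - 1L)
  val <- trimws(substr(lines[li], colon[li] + 1L, nchar(lines[li])))
  tsid <- sid[li]

  n <- length(term_sids)
  row_of_sid <- integer(length(stype))
  row_of_sid[term_sids] <- seq_len(n)
  trow <- row_of_sid[tsid]

  # --- id (required, unique per stanza) ---
  is_id <- tag == "id"
  id_rows <- trow[is_id]
  id_vals <- strip_obo_comment(val[is_id])
  no_id <- setdiff(seq_len(n), id_rows)
  if (length(no_id)) {
    bad <- term_sids[no_id[1L]]
    stop(sprintf("[Term] stanza with no id line at byte offset %d",
                 byte_off[start_line[bad]]), call. = FALSE)
  }
  if (anyDuplicated(id_rows)) {
    stop("stanza with multiple id lines: ",
         id_vals[duplicated(id_rows)][1L], call. = FALSE)
  }
  go_raw <- character(n)
  go_raw[id_rows] <- id_vals
  bad_id <- !is_valid_accession(go_raw)
  if (any(bad_id)) {
    stop("malformed term id: '", go_raw[bad_id][1L], "'", call. = FALSE)
  }
  key <- accession_key(go_raw)
  if (anyDuplicated(key)) {
    stop("duplicate primary id: ", go_raw[duplicated(key)][1L], call. = FALSE)
  }
  prefix <- accession_prefix(go_raw)
  pad <- max(7L, max(nchar(sub("^[^:]*:", "", go_raw))))
  go_id <- sprintf("%s:%0*d", prefix, pad, key)

  scalar_tag <- function(tagname, default = "") {
    out <- rep.int(default, n)
    sel <- tag == tagname
    out[trow[sel]] <- val[sel] # last occurrence wins
    out
  }
  list_tag <- function(sel, values) {
    out <- rep.int(list(character()), n)
    if (any(sel)) {
      sp <- split(values[sel], trow[sel])
      out[as.integer(names(sp))] <- sp
    }
    out
  }

  name <- scalar_tag("name")
  namespace <- scalar_tag("namespace")

  defv <- scalar_tag("def", NA_character_)
  definition <- character(n)
  has_def <- !is.na(defv)
  definition[has_def] <- extract_quoted(defv[has_def])

  is_obsolete <- startsWith(tolower(scalar_tag("is_obsolete", "false")), "true")

  acc_or_stop <- function(a, what) {
    bad <- !is_valid_accession(a)
    if (any(bad)) {
      stop("malformed ", what, " value: '", a[bad][1L], "'", call. = FALSE)
    }
    a
  }

  clean <- strip_obo_comment(val)

  sel <- tag == "is_a"
  if (any(sel)) acc_or_stop(clean[sel], "is_a")
  is_a_acc <- list_tag(sel, clean)

  rel_type <- sub("\\s.*$", "", clean)
  rel_target <- trimws(sub("^\\S+\\s*", "", clean))
  sel_po <- tag == "relationship" & rel_type == "part_of"
  if (any(sel_po)) acc_or_stop(rel_target[sel_po], "part_of")
  part_of_acc <- list_tag(sel_po, rel_target)

  sel_con <- tag == "consider"
  if (any(sel_con)) acc_or_stop(clean[sel_con], "consider")
  consider_acc <- list_tag(sel_con, clean)

  sel_alt <- tag == "alt_id"
  if (any(sel_alt)) acc_or_stop(clean[sel_alt], "alt_id")
  alt_ids <- list_tag(sel_alt, clean)

  repl <- strip_obo_comment(scalar_tag("replaced_by", NA_character_))
  has_repl <- !is.na(repl)
  if (any(has_repl)) acc_or_stop(repl[has_repl], "replaced_by")
  replaced_by <- rep(NA_integer_, n)
  replaced_by[has_repl] <- accession_key(repl[has_repl])

  new_ontology(
    numeric_key = key, go_id = go_id, prefix = prefix, name = name,
    namespace = namespace, definition = definition,
    is_obsolete = is_obsolete,
    is_a_parents = lapply(is_a_acc, accession_key),
    part_of_parents = lapply(part_of_acc, accession_key),
    consider_targets = lapply(consider_acc, accession_key),
    replaced_by = replaced_by,
    alt_ids = alt_ids,
    format_version = fv, source_date = sd
  )
}

# first double-quoted string of a def line, backslash escapes honoured;
# the raw value is returned when no quoted section exists
extract_quoted <- function(x) {
  m <- regexpr('"(\\\\.|[^"\\\\])*"', x)
  out <- x
  hit <- m > 0L
  q <- regmatches(x, m)
  if (length(q)) {
    q <- substr(q, 2L, nchar(q) - 1L)
    q <- gsub('\\\\(["\\\\])', "\\1", q)
    out[hit] <- q
  }
  out
}

read_text_lines <- function(source) {
  if (inherits(source, "connection")) {
    return(readLines(source, warn = FALSE))
  }
  if (is.character(source)) {
    # several strings (or none), or embedded newlines/tabs: content, not a path
    if (length(source) != 1L || any(grepl("[\n\t]", source))) {
      return(unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE))
    }
    if (!file.exists(source)) {
      stop("file not found: ", source, call. = FALSE)
    }
    return(readLines(source, warn = FALSE))
  }
  stop("source must be a path, connection, or character vector of lines",
       call. = FALSE)
}

#' Serialize an ontology back to OBO 1.2 text
#'
#' Tags are emitted in a fixed order (id, name, namespace, alt_id, def, is_a,
#' relationship, is_obsolete, replaced_by, consider) so output is
#' byte-deterministic, and `parse_obo(serialize_obo(x))` reproduces `x`
#' field-by-field.
#'
#' @param ontology an `ontology` object.
#' @param path optional file path; when given, lines are written there.
#' @return character vector of OBO lines, invisibly when `path` is given.
#' @export
serialize_obo <- function(ontology, path = NULL) {
  o <- ontology
  acc_of <- function(keys) {
    o$go_id[match(keys, o$numeric_key)]
  }
  hdr <- c(paste0("format-version: ", o$format_version))
  if (!is.na(o$source_date)) {
    hdr <- c(hdr, paste0("date: ", format(o$source_date, "%d:%m:%Y"), " 00:00"))
  }
  out <- vector("list", n_terms(o) + 1L)
  out[[1L]] <- c(hdr, "")
  for (i in seq_len(n_terms(o))) {
    s <- c("[Term]", paste0("id: ", o$go_id[i]))
    if (nzchar(o$name[i])) s <- c(s, paste0("name: ", o$name[i]))
    if (nzchar(o$namespace[i])) s <- c(s, paste0("namespace: ", o$namespace[i]))
    if (length(o$alt_ids[[i]])) s <- c(s, paste0("alt_id: ", o$alt_ids[[i]]))
    if (nzchar(o$definition[i])) {
      esc <- gsub('(["\\\\])', "\\\\\\1", o$definition[i])
      s <- c(s, paste0('def: "', esc, '" []'))
    }
    if (length(o$is_a_parents[[i]])) {
      s <- c(s, paste0("is_a: ", acc_of(o$is_a_parents[[i]])))
    }
    if (length(o$part_of_parents[[i]])) {
      s <- c(s, paste0("relationship: part_of ", acc_of(o$part_of_parents[[i]])))
    }
    if (o$is_obsolete[i]) s <- c(s, "is_obsolete: true")
    if (!is.na(o$replaced_by[i])) {
      s <- c(s, paste0("replaced_by: ", acc_of(o$replaced_by[i])))
    }
    if (length(o$consider_targets[[i]])) {
      s <- c(s, paste0("consider: ", acc_of(o$consider_targets[[i]])))
    }
    out[[i + 1L]] <- c(s, "")
  }
  lines <- unlist(out, use.names = FALSE)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Resolve an accession to usable live term(s)
#'
#' Lookup order: (1) primary id; (2) registered alt_id; (3) for obsolete
#' primaries, `replaced_by` (chains followed up to `max_chain` hops), else
#' `consider` targets (each themselves resolved to live terms); (4) unknown.
#' A returned target is never obsolete. With `resolve_obsolete = FALSE`,
#' anything that resolves only through an obsolete term is `unknown`.
#'
#' @param ontology an `ontology` object.
#' @param accession a single accession string, `prefix:digits`.
#' @param resolve_obsolete follow `replaced_by`/`consider` of obsolete terms
#'   (the obsolete-id rescue is optional in the workflow).
#' @param max_chain maximum `replaced_by` chain length followed before giving
#'   up (guards malformed files).
#' @return a `resolution`: list with `status` (one of `primary`, `alt_id`,
#'   `obsolete_replaced`, `obsolete_consider`, `unknown`) and `targets`
#'   (integer numeric keys; empty iff unknown).
#' @export
resolve_term <- function(ontology, accession, resolve_obsolete = TRUE,
                         max_chain = 5L) {
  if (length(accession) != 1L || !is_valid_accession(accession)) {
    stop(errorCondition(
      paste0("syntactically invalid accession: '", accession, "'"),
      class = c("ontomatrix_bad_accession", "error", "condition")
    ))
  }
  o <- ontology
  res <- function(status, targets) {
    structure(list(status = status, targets = as.integer(targets)),
              class = "resolution")
  }
  unknown <- res("unknown", integer())

  # follow replaced_by chains of an obsolete row to a live key, or NA
  chase_replacement <- function(row, hops) {
    while (hops > 0L) {
      k <- o$replaced_by[row]
      if (is.na(k)) return(NA_integer_)
      row <- match(k, o$numeric_key)
      if (is.na(row)) return(NA_integer_)
      if (!o$is_obsolete[row]) return(o$numeric_key[row])
      hops <- hops - 1L
    }
    NA_integer_
  }
  # resolve an obsolete row to live keys via replaced_by then consider
  obsolete_targets <- function(row) {
    k <- chase_replacement(row, max_chain)
    if (!is.na(k)) return(list(status = "obsolete_replaced", keys = k))
    cons <- o$consider_targets[[row]]
    keys <- integer()
    for (ck in cons) {
      cr <- match(ck, o$numeric_key)
      if (is.na(cr)) next
      if (!o$is_obsolete[cr]) {
        keys <- c(keys, ck)
      } else {
        rk <- chase_replacement(cr, max_chain)
        if (!is.na(rk)) keys <- c(keys, rk)
      }
    }
    if (length(keys)) {
      return(list(status = "obsolete_consider", keys = unique(keys)))
    }
    NULL
  }

  key <- accession_key(accession)
  row <- match(key, o$numeric_key)
  if (!is.na(row)) {
    if (!o$is_obsolete[row]) return(res("primary", o$numeric_key[row]))
    if (!resolve_obsolete) return(unknown)
    hit <- obsolete_targets(row)
    if (is.null(hit)) return(unknown)
    return(res(hit$status, hit$keys))
  }
  # alt index lookup is by full accession string
  alt <- unname(o$alt_index[accession])
  if (!length(alt)) alt <- NA_integer_
  if (!is.na(alt)) {
    arow <- match(alt, o$numeric_key)
    if (!o$is_obsolete[arow]) return(res("alt_id", alt))
    if (!resolve_obsolete) return(unknown)
    hit <- obsolete_targets(arow)
    if (is.null(hit)) return(unknown)
    return(res(hit$status, hit$keys))
  }
  unknown
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.resolution <- function(x, ...) {
  cat(sprintf("<resolution: %s -> [%s]>\n", x$status,
              paste(x$targets, collapse = ", ")))
  invisible(x)
}
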