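# Ancestor closure with a dynamically grown memo table. The memo maps each
# term to the frozen set {term} + all is_a/part_of ancestors, so once every
# distinct annotated term has been seen, processing further genes does no
# graph traversal at all: total work is bounded by ontology size, not by the
# number of annotated genes.

#' Create an empty ancestor-closure cache for an ontology
#'
#' The cache is an environment holding one frozen ancestor set per term
#' (grown on demand, so its size never exceeds the term count) and a
#' traversal counter: an edge is counted once, when it is consumed into a
#' memoized union. Cache hits touch no edges.
#'
#' @param ontology an `ontology` object.
#' @return a `closure_cache` environment.
#' @export
closure_cache <- function(ontology) {
  e <- new.env(parent = emptyenv())
  e$sets <- vector("list", n_terms(ontology)) # row index -> row-index set
  e$n_cached <- 0L
  e$traversals <- 0L
  class(e) <- c("closure_cache", "environment")
  e
}

#' @export
print.closure_cache <- function(x, ...) {
  cat(sprintf("<closure_cache: %d term(s) cached, %d edge traversal(s)>\n",
              x$n_cached, x$traversals))
  invisible(x)
}

# Fill cache$sets for every row index in `need` (and, necessarily, all their
# ancestors), iteratively so ontology depth cannot overflow the call stack.
warm_closure <- function(ontology, cache, need) {
  sets <- cache$sets
  parent_idx <- ontology$parent_idx
  n_cached <- cache$n_cached
  traversals <- cache$traversals
  for (start in need) {
    if (!is.null(sets[[start]])) next
    stack <- start
    while (length(stack)) {
      t <- stack[length(stack)]
      if (!is.null(sets[[t]])) {
        stack <- stack[-length(stack)]
        next
      }
      ps <- parent_idx[[t]]
      if (length(ps)) {
        ready <- !vapply(sets[ps], is.null, logical(1L))
        if (!all(ready)) {
          stack <- c(stack, ps[!ready])
          next
        }
        sets[[t]] <- unique(c(t, unlist(sets[ps], use.names = FALSE)))
      } else {
        sets[[t]] <- t
      }
      n_cached <- n_cached + 1L
      traversals <- traversals + length(ps)
      stack <- stack[-length(stack)]
    }
  }
  cache$sets <- sets
  cache$n_cached <- n_cached
  cache$traversals <- traversals
  invisible(cache)
}

#' Ancestor set of a term (the term itself plus all ancestors)
#'
#' Walks `is_a` and `part_of` edges transitively to the namespace root(s).
#' With a shared cache, each term's set is computed once; later queries for
#' the term or any of its ancestors are pure lookups.
#'
#' @param ontology an `ontology` object.
#' @param key numeric key of a live primary term (resolve obsolete or alt
#'   accessions first with [resolve_term()]).
#' @param cache optional shared [closure_cache()]; a transient one is used
#'   when omitted.
#' @return sorted integer vector of numeric keys, always containing `key`.
#' @export
ancestors <- function(ontology, key, cache = NULL) {
  row <- match(key, ontology$numeric_key)
  if (is.na(row)) {
    stop("term key ", key, " not present in ontology", call. = FALSE)
  }
  if (ontology$is_obsolete[row]) {
    stop("term ", ontology$go_id[row],
         " is obsolete; resolve it before asking for ancestors",
         call. = FALSE)
  }
  if (is.null(cache)) cache <- closure_cache(ontology)
  if (is.null(cache$sets[[row]])) warm_closure(ontology, cache, row)
  sort(ontology$numeric_key[cache$sets[[row]]])
}

#' Close an annotation set over the ontology
#'
#' Replaces each gene's direct terms with the union of the ancestor sets of
#' all its resolvable terms, the up-propagation step that makes a gene
#' annotated to a specific class a member of every broader parent class.
#' Direct terms that fail resolution are dropped from the gene and counted;
#' genes whose every term fails stay in the set with an empty term vector.
#' Gene order is preserved and each closed set is sorted by numeric key.
#'
#' @param ontology an `ontology` object.
#' @param annotations an `annotation_set` from [parse_generic()] or
#'   [parse_gaf()] (closing an already-closed set is the identity).
#' @param resolve_obsolete passed to [resolve_term()]; when `FALSE`,
#'   obsolete accessions are dropped rather than rescued.
#' @param cache optional shared [closure_cache()] reused across calls.
#' @return the closed `annotation_set`; its `summary` field reports
#'   `n_genes`, `n_direct_terms`, `n_unresolved`, `n_obsolete_resolved` and
#'   `n_genes_emptied`.
#' @export
close_annotation_set <- function(ontology, annotations,
                                 resolve_obsolete = TRUE, cache = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (is.null(cache)) cache <- closure_cache(ontology)

  terms <- annotations$terms
  uniq_acc <- unique(unlist(terms, use.names = FALSE))

  # resolve each distinct accession once; live primaries (the vast majority)
  # are resolved in one vectorized lookup, the rest go through resolve_term
  target_keys <- vector("list", length(uniq_acc))
  status <- character(length(uniq_acc))
  uk <- suppressWarnings(accession_key(uniq_acc))
  ur <- match(uk, ontology$numeric_key)
  fast <- !is.na(ur) & !ontology$is_obsolete[ifelse(is.na(ur), 1L, ur)]
  status[fast] <- "primary"
  target_keys[fast] <- as.list(uk[fast])
  for (i in which(!fast)) {
    r <- tryCatch(
      resolve_term(ontology, uniq_acc[i], resolve_obsolete = resolve_obsolete),
      ontomatrix_bad_accession = function(e) {
        list(status = "unknown", targets = integer())
      }
    )
    status[i] <- r$status
    target_keys[[i]] <- r$targets
  }
  names(target_keys) <- uniq_acc
  names(status) <- uniq_acc

  rows_needed <- match(unique(unlist(target_keys, use.names = FALSE)),
                       ontology$numeric_key)
  warm_closure(ontology, cache, rows_needed)

  # per distinct accession: closed set as ontology row indices
  closed_rows <- lapply(target_keys, function(ks) {
    if (!length(ks)) return(integer())
    rows <- match(ks, ontology$numeric_key)
    unique(unlist(cache$sets[rows], use.names = FALSE))
  })

  n_direct <- sum(lengths(terms))
  acc_unresolved <- status == "unknown"
  obs_status <- status %in% c("obsolete_replaced", "obsolete_consider")

  # one vectorized accession lookup over the whole file, then a per-gene
  # union by integer position (keeps the per-gene pass O(closed set size))
  gene_of <- rep.int(seq_along(terms), lengths(terms))
  ai <- match(unlist(terms, use.names = FALSE), uniq_acc)
  n_unresolved <- sum(acc_unresolved[ai])
  n_obs_resolved <- sum(obs_status[ai])
  ai_by_gene <- split(ai, factor(gene_of, levels = seq_along(terms)))

  go_id <- ontology$go_id
  numeric_key <- ontology$numeric_key
  closed_terms <- vector("list", length(terms))
  for (g in seq_along(terms)) {
    rows <- unique(unlist(closed_rows[ai_by_gene[[g]]], use.names = FALSE))
    if (!length(rows)) {
      closed_terms[[g]] <- character()
      next
    }
    closed_terms[[g]] <- go_id[rows[order(numeric_key[rows])]]
  }

  out <- annotations
  out$terms <- closed_terms
  out$closed <- TRUE
  out$summary <- list(
    n_genes = length(terms),
    n_direct_terms = n_direct,
    n_unresolved = n_unresolved,
    n_obsolete_resolved = n_obs_resolved,
    n_genes_emptied = sum(lengths(closed_terms) == 0L)
  )
  out
}
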