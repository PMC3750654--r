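# Seeded synthetic fixtures: valid OBO ontologies, generic-TSV and GAF
# annotation files, all with exact recorded ground truth (per-term reachable
# sets by an implementation-independent BFS over the raw edge list, per-gene
# closed sets, malformed/NOT counts, per-release deltas). Everything other
# module does is testable against these with no download.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# sample() that never falls into the 1:x trap on length-1 pools
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# reachable-set oracle: plain breadth-first expansion over an edge list
# keyed by numeric key; deliberately independent of the closure module
bfs_reachable <- function(parents_by_key, key) {
  seen <- integer()
  frontier <- key
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(parents_by_key[as.character(frontier)],
                         use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  sort(unique(seen))
}

#' Generate a random ontology DAG with recorded ground truth
#'
#' Terms are created in topological order — each new term draws its parents
#' from already-created live terms — so the result is acyclic by
#' construction. Roots are live and parentless; every live non-root gets at
#' least one parent (`is_a` with probability 0.8, else `part_of`) plus
#' extra parents governed by `edge_density`. Obsolete terms carry no parent
#' edges and receive `replaced_by` (45%), `consider` targets (45%) or
#' nothing (10%, unresolvable) among live terms. A fraction `p_alt` of live
#' terms is granted one alt_id drawn from an unused key range.
#'
#' @param n_terms,n_roots total terms and number of roots
#'   (`n_terms >= n_roots >= 1`).
#' @param edge_density probability weight for extra parents per live term
#'   (0 gives a forest/tree).
#' @param p_obsolete probability that a non-root term is obsolete.
#' @param seed integer seed; identical seeds give byte-identical OBO text.
#' @param p_alt fraction of live terms granted an alt_id.
#' @param prefix accession prefix (`"GO"`; use `"PO"` to exercise the
#'   non-GO-prefix path).
#' @param reachable compute the per-term BFS reachable sets (disable for
#'   very large smoke fixtures).
#' @return a `fixture_truth` list: `ontology`, `per_term_reachable` (named
#'   by key), `live_keys`, `leaf_keys`, `alt_map`, `obsolete_resolution`,
#'   `max_key_used`, `counts`.
#' @export
generate_dag <- function(n_terms, n_roots = 1L, edge_density = 0.15,
                         p_obsolete = 0, seed = 1L, p_alt = 0,
                         prefix = "GO", reachable = TRUE) {
  n_terms <- as.integer(n_terms)
  n_roots <- as.integer(n_roots)
  if (n_terms < 1L || n_roots < 1L || n_roots > n_terms) {
    stop("need n_terms >= n_roots >= 1", call. = FALSE)
  }
  if (edge_density < 0 || edge_density > 1 || p_obsolete < 0 || p_obsolete > 1) {
    stop("edge_density and p_obsolete must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    key <- seq_len(n_terms)
    go_id <- sprintf("%s:%07d", prefix, key)
    ns_pool <- c("biological_process", "molecular_function",
                 "cellular_component")
    namespace <- character(n_terms)
    namespace[seq_len(n_roots)] <- ns_pool[(seq_len(n_roots) - 1L) %% 3L + 1L]
    is_obsolete <- logical(n_terms)
    is_a <- rep.int(list(integer()), n_terms)
    part_of <- rep.int(list(integer()), n_terms)
    consider <- rep.int(list(integer()), n_terms)
    replaced_by <- rep.int(NA_integer_, n_terms)

    live <- seq_len(n_roots)
    if (n_terms > n_roots) {
      for (t in (n_roots + 1L):n_terms) {
        if (stats::runif(1) < p_obsolete) {
          is_obsolete[t] <- TRUE
          namespace[t] <- ns_pool[1L]
          u <- stats::runif(1)
          if (u < 0.45) {
            replaced_by[t] <- resample(live, 1L)
          } else if (u < 0.90) {
            consider[[t]] <- sort(resample(live, min(length(live),
                                                     sample(1:2, 1L))))
          } # else: unresolvable obsolete
          next
        }
        n_par <- 1L + stats::rbinom(1L, 2L, edge_density)
        par <- resample(live, min(n_par, length(live)))
        kind <- stats::runif(length(par)) < 0.8
        is_a[[t]] <- sort(par[kind])
        part_of[[t]] <- sort(par[!kind])
        namespace[t] <- namespace[par[1L]]
        live <- c(live, t)
      }
    }

    alt_ids <- rep.int(list(character()), n_terms)
    alt_map <- integer()
    next_free <- n_terms
    if (p_alt > 0) {
      granted <- live[stats::runif(length(live)) < p_alt]
      if (length(granted)) {
        alt_keys <- next_free + seq_along(granted)
        next_free <- next_free + length(granted)
        acc <- sprintf("%s:%07d", prefix, alt_keys)
        for (k in seq_along(granted)) alt_ids[[granted[k]]] <- acc[k]
        alt_map <- structure(as.integer(granted), names = acc)
      }
    }

    ont <- new_ontology(
      numeric_key = key, go_id = go_id, prefix = rep.int(prefix, n_terms),
      name = sprintf("synthetic term %d", key),
      namespace = namespace,
      definition = sprintf("Synthetic class %s.", go_id),
      is_obsolete = is_obsolete,
      is_a_parents = is_a, part_of_parents = part_of,
      consider_targets = consider, replaced_by = replaced_by,
      alt_ids = alt_ids,
      source_date = as.Date("2026-01-01")
    )

    parents_by_key <- stats::setNames(
      lapply(seq_len(n_terms), function(i) c(is_a[[i]], part_of[[i]])),
      as.character(key)
    )
    per_term_reachable <- NULL
    if (reachable) {
      per_term_reachable <- stats::setNames(
        lapply(live, function(k) bfs_reachable(parents_by_key, k)),
        as.character(live)
      )
    }

    has_child <- unique(unlist(parents_by_key, use.names = FALSE))
    leaf_keys <- setdiff(live, has_child)

    obs_keys <- key[is_obsolete]
    obsolete_resolution <- stats::setNames(lapply(obs_keys, function(k) {
      if (!is.na(replaced_by[k])) {
        list(status = "obsolete_replaced", targets = replaced_by[k])
      } else if (length(consider[[k]])) {
        list(status = "obsolete_consider", targets = consider[[k]])
      } else {
        list(status = "unknown", targets = integer())
      }
    }), as.character(obs_keys))

    structure(list(
      ontology = ont,
      per_term_reachable = per_term_reachable,
      parents_by_key = parents_by_key,
      live_keys = as.integer(live),
      leaf_keys = as.integer(leaf_keys),
      alt_map = alt_map,
      obsolete_resolution = obsolete_resolution,
      max_key_used = next_free,
      seed = seed,
      counts = list(
        n_terms = n_terms,
        n_roots = n_roots,
        n_obsolete = sum(is_obsolete),
        n_alt_ids = length(alt_map),
        n_edges = sum(lengths(is_a)) + sum(lengths(part_of))
      )
    ), class = "fixture_truth")
  })
}

#' @export
print.fixture_truth <- function(x, ...) {
  cat(sprintf("<fixture_truth: %d term(s), %d live, seed %d%s>\n",
              x$counts$n_terms, length(x$live_keys), x$seed,
              if (!is.null(x$annotations))
                sprintf(", %d gene(s)", length(x$annotations$gene_id))
              else ""))
  invisible(x)
}

#' Annotate synthetic genes over a fixture ontology
#'
#' Genes draw direct terms from the live set with a leaf bias (default 80%
#' of draws from leaves, mimicking the specificity profile of curated
#' annotation). Optional injections, all exactly counted: alt_id accessions
#' standing in for their primary (`p_alt_accession`), resolvable or
#' unresolvable obsolete accessions appended to a gene
#' (`p_obsolete_accession`), malformed tokens appended inside TSV cells
#' (`p_malformed`; never a gene's only token), and `NOT`-qualified GAF
#' lines (`n_not`). Ground-truth per-gene closed sets come from the
#' generator's own BFS reachable sets and recorded resolution targets.
#'
#' @param truth a `fixture_truth` from [generate_dag()] (with reachable
#'   sets).
#' @param n_genes number of genes.
#' @param terms_per_gene_range integer range of direct terms per gene.
#' @param p_malformed probability of appending a malformed token per cell
#'   token (TSV rendition only).
#' @param seed integer seed.
#' @param leaf_bias fraction of draws taken from leaf terms.
#' @param p_alt_accession probability a drawn term is written as its alt_id
#'   (only terms owning one).
#' @param p_obsolete_accession probability a gene gets one extra obsolete
#'   accession.
#' @param n_not number of NOT-qualified GAF lines appended.
#' @return the `fixture_truth` extended with `annotations` (gene ids +
#'   written token vectors), `per_gene_closed` (accession vectors sorted by
#'   key), `tsv_lines`, `gaf_lines`, and an `ann_counts` bookkeeping list.
#' @export
generate_annotations <- function(truth, n_genes, terms_per_gene_range = c(1L, 4L),
                                 p_malformed = 0, seed = 1L, leaf_bias = 0.8,
                                 p_alt_accession = 0, p_obsolete_accession = 0,
                                 n_not = 0L) {
  stopifnot(inherits(truth, "fixture_truth"))
  if (is.null(truth$per_term_reachable)) {
    stop("truth has no reachable sets; regenerate with reachable = TRUE",
         call. = FALSE)
  }
  ont <- truth$ontology
  lo <- as.integer(terms_per_gene_range[1L])
  hi <- as.integer(terms_per_gene_range[length(terms_per_gene_range)])
  obs_keys <- as.integer(names(truth$obsolete_resolution))
  alt_by_owner <- if (length(truth$alt_map)) {
    stats::setNames(names(truth$alt_map), truth$alt_map)
  } else {
    character()
  }

  with_seed(seed, {
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    tokens <- vector("list", n_genes)
    closed <- vector("list", n_genes)
    n_malformed <- 0L
    n_obs_tok <- 0L
    n_unresolvable_tok <- 0L
    n_alt_tok <- 0L
    mal_counter <- 0L

    acc_of <- function(keys) ont$go_id[match(keys, ont$numeric_key)]

    for (g in seq_len(n_genes)) {
      k <- if (hi > lo) sample(lo:hi, 1L) else lo
      pool_leaf <- stats::runif(k) < leaf_bias & length(truth$leaf_keys) > 0L
      draws <- integer(k)
      n_leaf <- sum(pool_leaf)
      if (n_leaf) {
        draws[pool_leaf] <- resample(truth$leaf_keys, n_leaf, replace = TRUE)
      }
      if (k - n_leaf) {
        draws[!pool_leaf] <- resample(truth$live_keys, k - n_leaf,
                                      replace = TRUE)
      }
      draws <- unique(draws)

      toks <- acc_of(draws)
      if (p_alt_accession > 0) {
        for (d in seq_along(draws)) {
          a <- alt_by_owner[as.character(draws[d])]
          if (!is.na(a) && stats::runif(1) < p_alt_accession) {
            toks[d] <- a
            n_alt_tok <- n_alt_tok + 1L
          }
        }
      }

      target_keys <- draws
      if (p_obsolete_accession > 0 && length(obs_keys) &&
          stats::runif(1) < p_obsolete_accession) {
        ok <- resample(obs_keys, 1L)
        toks <- c(toks, acc_of(ok))
        n_obs_tok <- n_obs_tok + 1L
        res <- truth$obsolete_resolution[[as.character(ok)]]
        if (length(res$targets)) {
          target_keys <- c(target_keys, res$targets)
        } else {
          n_unresolvable_tok <- n_unresolvable_tok + 1L
        }
      }

      if (p_malformed > 0) {
        add <- stats::runif(length(toks)) < p_malformed
        if (any(add)) {
          bad <- sprintf("BAD_%05d", mal_counter + seq_len(sum(add)))
          mal_counter <- mal_counter + sum(add)
          n_malformed <- n_malformed + sum(add)
          toks <- c(toks, bad)
        }
      }

      tokens[[g]] <- toks
      ck <- sort(unique(unlist(
        truth$per_term_reachable[as.character(unique(target_keys))],
        use.names = FALSE
      )))
      closed[[g]] <- acc_of(ck)
    }

    tsv_lines <- paste0(gene_id, "\t",
                        vapply(tokens, paste, character(1L), collapse = ";"))

    valid <- lapply(tokens, function(t) t[is_valid_accession(t)])
    gaf_assoc <- function(gene, acc, qualifier = "") {
      paste(c("SYNTH", gene, gene, qualifier, acc, "SYNTH:ref", "IEA", "",
              "P", "", "", "protein", "taxon:0000", "20260101", "SYNTH",
              "", ""), collapse = "\t")
    }
    gaf_lines <- c("!gaf-version: 2.1")
    for (g in seq_len(n_genes)) {
      for (a in valid[[g]]) {
        gaf_lines <- c(gaf_lines, gaf_assoc(gene_id[g], a))
      }
    }
    if (n_not > 0L) {
      for (z in seq_len(n_not)) {
        gaf_lines <- c(gaf_lines, gaf_assoc(
          resample(gene_id, 1L),
          acc_of(resample(truth$live_keys, 1L)), "NOT"
        ))
      }
    }

    out <- truth
    out$annotations <- list(gene_id = gene_id, tokens = tokens,
                            valid_tokens = valid)
    out$per_gene_closed <- stats::setNames(closed, gene_id)
    out$tsv_lines <- tsv_lines
    out$gaf_lines <- gaf_lines
    out$ann_counts <- list(
      n_genes = n_genes,
      n_direct_valid = sum(lengths(valid)),
      n_malformed = n_malformed,
      n_not = as.integer(n_not),
      n_alt_tokens = n_alt_tok,
      n_obsolete_tokens = n_obs_tok,
      n_unresolvable_tokens = n_unresolvable_tok
    )
    out
  })
}

#' Evolve a fixture ontology into a new release with recorded deltas
#'
#' Obsoletes `n_obsolete` live leaf terms (cleared of parent edges and given
#' a `replaced_by` pointing at a surviving live term), renames `n_rename`
#' surviving live terms (altering their definition fingerprint), and appends
#' `n_add` new live terms parented among survivors. The recorded deltas are
#' exact ground truth for [compare_ontologies()].
#'
#' @param truth a `fixture_truth`.
#' @param n_obsolete,n_rename,n_add delta sizes.
#' @param seed integer seed.
#' @return list with `truth` (the new release as a `fixture_truth`, without
#'   reachable sets) and `deltas` (`obsoleted`, `renamed`, `added` key
#'   vectors).
#' @export
evolve_release <- function(truth, n_obsolete = 0L, n_rename = 0L,
                           n_add = 0L, seed = 1L) {
  stopifnot(inherits(truth, "fixture_truth"))
  o <- truth$ontology
  with_seed(seed, {
    leaf_pool <- setdiff(truth$leaf_keys, o$numeric_key[
      lengths(o$is_a_parents) + lengths(o$part_of_parents) == 0L
    ]) # never obsolete a root
    if (n_obsolete > length(leaf_pool)) {
      stop("not enough non-root leaf terms to obsolete", call. = FALSE)
    }
    obsoleted <- sort(resample(leaf_pool, n_obsolete))

    key <- o$numeric_key
    name <- o$name
    namespace <- o$namespace
    definition <- o$definition
    is_obsolete <- o$is_obsolete
    is_a <- o$is_a_parents
    part_of <- o$part_of_parents
    consider <- o$consider_targets
    replaced_by <- o$replaced_by
    alt_ids <- o$alt_ids

    survivors <- setdiff(truth$live_keys, obsoleted)
    for (k in obsoleted) {
      r <- match(k, key)
      is_obsolete[r] <- TRUE
      is_a[[r]] <- integer()
      part_of[[r]] <- integer()
      replaced_by[r] <- resample(survivors, 1L)
    }

    rename_pool <- survivors
    if (n_rename > length(rename_pool)) {
      stop("not enough live terms to rename", call. = FALSE)
    }
    renamed <- sort(resample(rename_pool, n_rename))
    for (k in renamed) {
      r <- match(k, key)
      name[r] <- paste0(name[r], " (revised)")
    }

    added <- integer()
    if (n_add > 0L) {
      added <- truth$max_key_used + seq_len(n_add)
      for (k in added) {
        par <- resample(survivors, 1L)
        key <- c(key, k)
        go_new <- sprintf("%s:%07d", o$prefix[1L], k)
        name <- c(name, sprintf("synthetic term %d", k))
        namespace <- c(namespace, namespace[match(par, key)])
        definition <- c(definition, sprintf("Synthetic class %s.", go_new))
        is_obsolete <- c(is_obsolete, FALSE)
        is_a <- c(is_a, list(par))
        part_of <- c(part_of, list(integer()))
        consider <- c(consider, list(integer()))
        replaced_by <- c(replaced_by, NA_integer_)
        alt_ids <- c(alt_ids, list(character()))
        survivors <- c(survivors, k)
      }
    }

    n <- length(key)
    pad_prefix <- rep.int(o$prefix[1L], n)
    ont2 <- new_ontology(
      numeric_key = key,
      go_id = sprintf("%s:%07d", pad_prefix, key),
      prefix = pad_prefix,
      name = name, namespace = namespace, definition = definition,
      is_obsolete = is_obsolete,
      is_a_parents = is_a, part_of_parents = part_of,
      consider_targets = consider, replaced_by = replaced_by,
      alt_ids = alt_ids,
      source_date = if (is.na(o$source_date)) as.Date(NA)
                    else o$source_date + 180L
    )

    parents_by_key <- stats::setNames(
      lapply(seq_len(n), function(i) c(is_a[[i]], part_of[[i]])),
      as.character(key)
    )
    has_child <- unique(unlist(parents_by_key, use.names = FALSE))
    new_truth <- structure(list(
      ontology = ont2,
      per_term_reachable = NULL,
      parents_by_key = parents_by_key,
      live_keys = as.integer(sort(survivors)),
      leaf_keys = as.integer(setdiff(sort(survivors), has_child)),
      alt_map = truth$alt_map,
      obsolete_resolution = NULL,
      max_key_used = max(truth$max_key_used, key),
      seed = seed,
      counts = list(
        n_terms = n,
        n_roots = truth$counts$n_roots,
        n_obsolete = sum(is_obsolete),
        n_alt_ids = length(truth$alt_map),
        n_edges = sum(lengths(is_a)) + sum(lengths(part_of))
      )
    ), class = "fixture_truth")

    list(truth = new_truth,
         deltas = list(obsoleted = obsoleted, renamed = renamed,
                       added = added))
  })
}

#' Write a fixture bundle (OBO + TSV + GAF) to a directory
#'
#' @param truth an annotated `fixture_truth`.
#' @param dir target directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_fixture_bundle <- function(truth, dir) {
  stopifnot(inherits(truth, "fixture_truth"))
  if (is.null(truth$tsv_lines)) {
    stop("truth carries no annotations; call generate_annotations() first",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    obo = file.path(dir, "synthetic.obo"),
    tsv = file.path(dir, "synthetic_annotations.tsv"),
    gaf = file.path(dir, "synthetic_annotations.gaf")
  )
  serialize_obo(truth$ontology, paths[["obo"]])
  writeLines(truth$tsv_lines, paths[["tsv"]], useBytes = TRUE)
  writeLines(truth$gaf_lines, paths[["gaf"]], useBytes = TRUE)
  paths
}
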