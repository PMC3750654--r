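# Ontology-version diffing: GO classes turn over quickly between OBO
# releases, so analyses pinned to an old structure miss or mis-define a
# substantial slice of current classes. These utilities quantify that
# turnover: per-pair set algebra and a multi-release per-year table.

#' Compare two OBO releases class-by-class
#'
#' Class identity is the numeric key. A shared live class counts as
#' *altered* when its definition fingerprint — the (name, namespace,
#' definition) tuple — differs between releases, *unaltered* otherwise.
#' Classes live in the old release count as *obsoleted* when obsolete in the
#' new one and *removed* when physically absent from it. *Added* classes are
#' live in the new release with no live counterpart in the old. Classes
#' obsolete in both releases are ignored entirely. Edge-set changes among
#' shared live classes are reported separately (`edges_changed`) and never
#' inflate `altered`.
#'
#' Two partition identities always hold:
#' `shared_unaltered + altered + obsoleted + removed = n_old_live` and
#' `shared_unaltered + altered + added = n_new_live`.
#'
#' @param old,new `ontology` objects, older release first.
#' @return a `diff_report` list of counts, including
#'   `altered_or_added = added + altered` and
#'   `percent_altered = 100 * altered_or_added / n_new_live` (the share of
#'   current classes missing or stale in the old release).
#' @export
compare_ontologies <- function(old, new) {
  stopifnot(inherits(old, "ontology"), inherits(new, "ontology"))
  fingerprint <- function(o, rows) {
    paste(o$name[rows], o$namespace[rows], o$definition[rows], sep = "\r")
  }
  edge_sig <- function(o, rows) {
    vapply(rows, function(r) {
      paste(sort(c(o$is_a_parents[[r]], 1e9 + o$part_of_parents[[r]])),
            collapse = ",")
    }, character(1L))
  }

  old_live <- old$numeric_key[!old$is_obsolete]
  new_live <- new$numeric_key[!new$is_obsolete]

  shared <- intersect(old_live, new_live)
  ro <- match(shared, old$numeric_key)
  rn <- match(shared, new$numeric_key)
  same <- fingerprint(old, ro) == fingerprint(new, rn)

  obsoleted <- sum(old_live %in% new$numeric_key[new$is_obsolete])
  removed <- sum(!(old_live %in% new$numeric_key))
  added <- sum(!(new_live %in% old_live))
  altered <- sum(!same)
  shared_unaltered <- sum(same)

  structure(list(
    n_old_live = length(old_live),
    n_new_live = length(new_live),
    shared_unaltered = shared_unaltered,
    altered = altered,
    obsoleted = obsoleted,
    added = added,
    removed = removed,
    altered_or_added = added + altered,
    percent_altered = 100 * (added + altered) / length(new_live),
    edges_changed = sum(edge_sig(old, ro) != edge_sig(new, rn))
  ), class = "diff_report")
}

#' @export
print.diff_report <- function(x, ...) {
  cat("Ontology release comparison\n")
  cat(sprintf("  live classes: %d (old) -> %d (new)\n",
              x$n_old_live, x$n_new_live))
  cat(sprintf("  shared unaltered : %d\n", x$shared_unaltered))
  cat(sprintf("  altered          : %d\n", x$altered))
  cat(sprintf("  obsoleted        : %d\n", x$obsoleted))
  cat(sprintf("  removed          : %d\n", x$removed))
  cat(sprintf("  added            : %d\n", x$added))
  cat(sprintf("  edges changed    : %d (informational)\n", x$edges_changed))
  cat(sprintf("  added or altered : %d (%.2f%% of current classes)\n",
              x$altered_or_added, x$percent_altered))
  invisible(x)
}

#' Write a diff report as a two-column TSV
#'
#' @param report a `diff_report`.
#' @param path output file path.
#' @return invisibly, the report.
#' @export
write_diff_report <- function(report, path) {
  fields <- names(unclass(report))
  vals <- vapply(fields, function(f) format(report[[f]], digits = 10),
                 character(1L))
  writeLines(paste0(fields, "\t", vals), path, useBytes = TRUE)
  invisible(report)
}

#' Per-release class totals and year-on-year change
#'
#' Given a date-ordered series of OBO releases, tabulates the live-class
#' total of each, the difference from the previous release, and the
#' arithmetic mean of those differences — the average number of GO classes
#' added per interval.
#'
#' @param ontologies list of two or more `ontology` objects in release
#'   order, or a numeric vector of live-class totals.
#' @param labels optional labels (defaults to the source dates, or
#'   positions).
#' @return a `turnover_table`: data frame with columns `label`,
#'   `total_live`, `change`, plus attribute `mean_change`.
#' @export
turnover_table <- function(ontologies, labels = NULL) {
  if (is.numeric(ontologies)) {
    totals <- as.numeric(ontologies)
    if (is.null(labels)) labels <- as.character(seq_along(totals))
  } else {
    if (!is.list(ontologies) ||
        !all(vapply(ontologies, inherits, logical(1L), "ontology"))) {
      stop("ontologies must be a list of ontology objects or numeric totals",
           call. = FALSE)
    }
    totals <- vapply(ontologies, function(o) sum(!o$is_obsolete), numeric(1L))
    if (is.null(labels)) {
      dates <- vapply(ontologies, function(o) format(o$source_date),
                      character(1L))
      labels <- ifelse(is.na(dates) | dates == "NA",
                       as.character(seq_along(totals)), dates)
    }
  }
  if (length(totals) < 2L) {
    stop("turnover requires at least two releases", call. = FALSE)
  }
  change <- c(NA_real_, diff(totals))
  out <- data.frame(
    label = as.character(labels),
    total_live = totals,
    change = change,
    stringsAsFactors = FALSE
  )
  attr(out, "mean_change") <- mean(change[-1L])
  class(out) <- c("turnover_table", "data.frame")
  out
}

#' @export
print.turnover_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("mean change per interval: %.4g\n", attr(x, "mean_change")))
  invisible(x)
}
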