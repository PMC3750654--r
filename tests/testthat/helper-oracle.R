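# Test-side reachability oracle, written against the ontology's raw
# is_a/part_of key lists (not the traversal index the closure engine uses):
# a plain worklist expansion, kept independent of both the closure module
# and the generator's own BFS.
oracle_reachable <- function(ontology, key) {
  parents_of <- function(k) {
    r <- match(k, ontology$numeric_key)
    c(ontology$is_a_parents[[r]], ontology$part_of_parents[[r]])
  }
  seen <- integer()
  todo <- key
  while (length(todo)) {
    k <- todo[1L]
    todo <- todo[-1L]
    if (k %in% seen) next
    seen <- c(seen, k)
    todo <- c(todo, parents_of(k))
  }
  sort(seen)
}

# hand-written six-term fixture covering every resolution path:
# two roots A,B; C live child of A with alt_id; X obsolete replaced_by C;
# Y obsolete with consider A,B; Z obsolete with nothing (unresolvable);
# W obsolete replaced_by Y (chain through a dead term must reach live A/B? no
# -- replaced_by chain: W -> Y, Y has no replaced_by => chain dead-ends)
resolution_fixture_obo <- function() {
  c(
    "format-version: 1.2",
    "date: 01:02:2012 00:00",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root A",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: root B",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: child C",
    "namespace: biological_process",
    "alt_id: GO:0000103",
    "is_a: GO:0000001 ! root A",
    "",
    "[Term]",
    "id: GO:0000010",
    "name: gone X",
    "is_obsolete: true",
    "replaced_by: GO:0000003",
    "",
    "[Term]",
    "id: GO:0000011",
    "name: gone Y",
    "is_obsolete: true",
    "consider: GO:0000001",
    "consider: GO:0000002",
    "",
    "[Term]",
    "id: GO:0000012",
    "name: gone Z",
    "is_obsolete: true",
    ""
  )
}
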