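---
title: "Building GO membership matrices: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building GO membership matrices: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontomatrix)
```

## The procedure

Gene Ontology annotation follows the true-path rule: a gene annotated to a
class is implicitly annotated to every ancestor of that class. `ontomatrix`
materializes that implication. Given an OBO 1.2 structure file and a
gene→term annotation table, it computes for each gene the union of the
ancestor closures of its terms and lays the result out as a binary
genes × classes matrix.

The ancestor closure `anc(t)` is `{t}` plus everything reachable from `t`
over `is_a` and `relationship: part_of` edges. Only those two edge types
propagate; `regulates`, `has_part` and other relationship types are ignored
because annotation transfer along them is not implied by the true-path
rule. `consider` never acts as a graph edge: in OBO semantics it annotates
obsolete stanzas, so treating it as a parent link would create paths out of
dead terms. It is used purely as a resolution hint (below).

Closures are memoized in a cache that grows on demand, one frozen set per
distinct term. The cache can never grow past the number of classes in the
ontology, and an edge is consumed into a union exactly once per cache
lifetime, so total traversal work over an entire annotation file is bounded
by the ontology's edge count — after the distinct terms of the input have
been seen once, adding more genes adds only set-union work. This is what
makes 100,000-gene inputs unremarkable: the graph work is the same as for
100 genes.

Traversal is iterative (an explicit stack), so ontology depth cannot
overflow the R call stack.

## Resolving incoming accessions

Annotation files routinely contain accessions that are not live primary
ids. Lookups therefore go through a fixed order: primary id; registered
`alt_id`; for obsolete primaries `replaced_by` (chains followed up to 5
hops, a guard against malformed files), then `consider` targets, each
themselves chased to a live term; otherwise unknown. A resolved target is
never obsolete. The obsolete rescue is optional (`resolve_obsolete`,
default on); with it off, anything that resolves only through an obsolete
term is dropped and counted. Unresolvable terms are dropped per gene; a
gene whose every term fails stays in the output with an empty set, so row
registries always match the input gene list.

Namespace roots are kept as matrix columns by default — they are real,
if uninformative, memberships, and dropping them is a one-flag decision
(`drop_roots`) better left to the analyst. `part_of` edges are followed
wherever they lead, with no namespace firewall, since the three
sub-ontologies are processed as one structure.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `gene_col`, `go_cols` | `parse_generic()` | 1, 2 | 1-based, matching the "column number" convention of spreadsheet-adjacent bioinformatics; validated with a clear error on 0 |
| `go_separator` | `parse_generic()` | `";"` | the common multi-valued cell delimiter; `","` and `"|"` accepted |
| `header` | `parse_generic()` | `"auto"` | a first row whose annotation columns hold no valid accession is taken for a header; force with TRUE/FALSE |
| `resolve_obsolete` | closure/resolution | `TRUE` | obsolete-id rescue recovers usable signal from stale annotation files |
| `max_chain` | `resolve_term()` | 5 | replacement chains longer than this indicate a broken file, not a resolvable id |
| `matrix_format` | `run_matrix()` | `"sparse"` | GO membership matrices are overwhelmingly zero; the triplet form is the format intended for large inputs |
| `drop_roots` | `run_matrix()` | `FALSE` | roots are genuine memberships; exclusion is an analysis choice |

Triplet files are written sorted by (row, column) with 1-based indices and
a literal value column of 1, and the row/column name registries go to
separate one-name-per-line files whose line numbers are the indices. The
sort order is a determinism choice (outputs are byte-identical across
runs); the 1-based indexing matches the R and Matlab import targets.

## The synthetic-fixture generator

Every test runs against generated data with exact recorded ground truth,
so the suite needs no downloads. `generate_dag()` builds terms in
topological order — each new term draws parents from already-created live
terms — which gives acyclicity by construction. Defaults and choices:

- edges are `is_a` with probability 0.8, else `part_of`, roughly the
  proportion in real GO releases;
- annotation draws are 80% leaf-biased (`leaf_bias`), mimicking the
  specificity profile of curated annotation so that deep propagation paths
  are actually exercised;
- obsolete fixture terms get `replaced_by` (45%), `consider` (45%) or
  nothing (10%, deliberately unresolvable);
- malformed tokens are injected as *extra* cell tokens, never replacing a
  gene's only valid term, so the generator's bookkeeping stays exact under
  the parser's drop-empty-genes rule;
- ground-truth reachable sets come from a plain breadth-first expansion
  over the raw edge list — an implementation deliberately independent of
  the memoized closure engine it validates.

What the generator does not emulate: the power-law fan-in of real GO
topology, evidence codes, inter-ontology `regulates` structure, or
realistic annotation depth distributions. Passing tests demonstrate
correctness of parsing, propagation, bookkeeping and serialization — not
that any biological conclusion drawn from a real matrix is sound.

`evolve_release()` obsoletes only leaf terms so surviving terms never gain
obsolete parents mid-lineage, keeping recorded deltas exact for the diff
tests.

## Release diffing

`compare_ontologies()` keys classes on the numeric accession and calls a
shared live class *altered* when its (name, namespace, definition) tuple
changed — the minimal attribute set the parser itself stores. Edge rewires
are counted separately (`edges_changed`) and never inflate `altered`.
`added` means live-in-new with no live counterpart in old (so a
resurrected class counts as added); this is what makes the two partition
identities — old live = unaltered + altered + obsoleted + removed, and
new live = unaltered + altered + added — hold simultaneously.
`percent_altered` is taken against the *newer* release's live count: the
share of current classes missing or stale in the old structure. Classes
obsolete in both releases are ignored entirely.

## Numerical and degenerate-input choices

- Term keys are the integer value of the accession digits; 7-digit
  zero-padding is restored on output, and non-GO prefixes are preserved.
- All comparisons are exact set/string operations; there are no floating
  tolerances anywhere in the pipeline.
- Duplicate annotation rows merge by union at the first row's position;
  duplicate `alt_id` claims keep the first owner with a warning; duplicate
  primary ids are an error.
- Empty files, rows shorter than the requested columns, dangling parent
  references and `is_a`/`part_of` cycles all fail loudly at parse time
  rather than propagating silently.
- Output is atomic: files are written to temporaries in the target
  directory and renamed only after the whole run succeeded.

## Problem sizes used in the checks

The test suite and the acceptance script exercise: 200 random DAGs of
30–300 terms against the brute-force oracle; 1,000-gene end-to-end truth
recovery through the on-disk formats; 50 random matrices for sparse/full
round trips; a 2,000-term, 10,000-gene run for the cache work bound; and a
100,000-gene × 20,000-term smoke run that completes in ordinary memory.
These sizes were chosen to cover the tool's design range — inputs well
beyond 20,000 annotated genes — while keeping a full check run fast enough
to be part of routine development.

## Known limitations

- OBO 1.2 flat files only; no OWL/RDF, no typedef semantics, no
  cross-ontology imports.
- Propagation is all-or-nothing binary membership: no evidence-code
  weighting, no information-content computation, no partial propagation.
- GAF support covers the association columns (object id, qualifier, GO
  id); GPAD/GPI are out of scope.
- The diff utility reports counts, not per-class listings or graphics;
  plotting is left to downstream tools.
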