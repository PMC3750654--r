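test_that("a minimal three-stanza file parses into the written DAG", {
  obo <- c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: R",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: A",
    "is_a: GO:0000001 ! R", "",
    "[Term]", "id: GO:0000003", "name: B",
    "relationship: part_of GO:0000002", ""
  )
  ont <- parse_obo(obo)
  expect_equal(n_terms(ont), 3L)
  expect_equal(ont$numeric_key, 1:3)
  expect_equal(ont$is_a_parents[[2L]], 1L)
  expect_equal(ont$part_of_parents[[3L]], 2L)
  expect_equal(root_keys(ont), 1L)
})

test_that("trailing '! comment' is stripped from edge values", {
  obo <- c(
    "[Term]", "id: GO:0008150", "name: biological_process", "",
    "[Term]", "id: GO:0000001", "name: x",
    "is_a: GO:0008150 ! biological_process", ""
  )
  ont <- parse_obo(obo)
  expect_equal(ont$is_a_parents[[match(1L, ont$numeric_key)]], 8150L)
})

test_that("parse handles Windows line endings, skipped stanzas, def quoting", {
  obo <- paste0(c(
    "format-version: 1.2",
    "[Typedef]", "id: part_of",
    "[Term]", "id: GO:0000001", "name: r",
    'def: "a \\"quoted\\" def" [PMID:1]', ""
  ), "\r")
  expect_message(ont <- parse_obo(obo), "Typedef")
  expect_equal(n_terms(ont), 1L)
  expect_equal(ont$definition, 'a "quoted" def')
})

test_that("parse rejects duplicate ids, dangling parents, cycles, missing id", {
  base <- c("[Term]", "id: GO:0000001", "name: r", "")
  expect_error(parse_obo(c(base, base)), "duplicate primary id")
  expect_error(
    parse_obo(c("[Term]", "id: GO:0000001", "is_a: GO:0000009", "")),
    "dangling"
  )
  expect_error(
    parse_obo(c(
      "[Term]", "id: GO:0000001", "is_a: GO:0000002", "",
      "[Term]", "id: GO:0000002", "is_a: GO:0000001", ""
    )),
    "cycle"
  )
  expect_error(
    parse_obo(c("header: x", "", "[Term]", "name: no id here", "")),
    "byte offset"
  )
})

test_that("serialize -> parse round-trips generated ontologies field-by-field", {
  fields <- c("numeric_key", "go_id", "prefix", "name", "namespace",
              "definition", "is_obsolete", "is_a_parents", "part_of_parents",
              "consider_targets", "replaced_by", "alt_ids", "alt_index",
              "source_date")
  for (case in list(
    list(n = 500L, roots = 3L, dens = 0.2, pobs = 0.08, palt = 0.1,
         prefix = "GO", seed = 11L),
    list(n = 120L, roots = 1L, dens = 0.4, pobs = 0, palt = 0,
         prefix = "PO", seed = 12L)
  )) {
    ont <- generate_dag(case$n, case$roots, case$dens, case$pobs,
                        seed = case$seed, p_alt = case$palt,
                        prefix = case$prefix)$ontology
    ont2 <- parse_obo(serialize_obo(ont))
    for (f in fields) {
      expect_identical(ont2[[f]], ont[[f]],
                       label = sprintf("%s (prefix %s)", f, case$prefix))
    }
  }
})

test_that("term count equals the number of [Term] stanzas", {
  tr <- generate_dag(200L, 2L, 0.2, 0.1, seed = 21L)
  lines <- serialize_obo(tr$ontology)
  expect_equal(n_terms(parse_obo(lines)), sum(lines == "[Term]"))
})

test_that("resolution covers primary, alt_id, replaced_by, consider, unknown", {
  ont <- parse_obo(resolution_fixture_obo())

  r <- resolve_term(ont, "GO:0000003")
  expect_equal(r$status, "primary")
  expect_equal(r$targets, 3L)

  r <- resolve_term(ont, "GO:0000103")
  expect_equal(r$status, "alt_id")
  expect_equal(r$targets, 3L)

  r <- resolve_term(ont, "GO:0000010")
  expect_equal(r$status, "obsolete_replaced")
  expect_equal(r$targets, 3L)

  r <- resolve_term(ont, "GO:0000011")
  expect_equal(r$status, "obsolete_consider")
  expect_equal(sort(r$targets), c(1L, 2L))

  r <- resolve_term(ont, "GO:0000012") # obsolete, no hints
  expect_equal(r$status, "unknown")
  expect_length(r$targets, 0L)

  r <- resolve_term(ont, "GO:0999999") # absent everywhere
  expect_equal(r$status, "unknown")
})

test_that("resolution of obsolete terms can be switched off", {
  ont <- parse_obo(resolution_fixture_obo())
  expect_equal(resolve_term(ont, "GO:0000010", resolve_obsolete = FALSE)$status,
               "unknown")
  expect_equal(resolve_term(ont, "GO:0000011", resolve_obsolete = FALSE)$status,
               "unknown")
  # live lookups unaffected
  expect_equal(resolve_term(ont, "GO:0000001", resolve_obsolete = FALSE)$status,
               "primary")
})

test_that("replaced_by chains resolve through dead terms, capped in depth", {
  chain <- c(
    "[Term]", "id: GO:0000001", "name: live", "",
    "[Term]", "id: GO:0000002", "is_obsolete: true",
    "replaced_by: GO:0000001", "",
    "[Term]", "id: GO:0000003", "is_obsolete: true",
    "replaced_by: GO:0000002", ""
  )
  ont <- parse_obo(chain)
  r <- resolve_term(ont, "GO:0000003")
  expect_equal(r$status, "obsolete_replaced")
  expect_equal(r$targets, 1L) # chained through GO:0000002 to the live term
  expect_equal(resolve_term(ont, "GO:0000003", max_chain = 1L)$status,
               "unknown")
})

test_that("resolved targets are never obsolete", {
  tr <- generate_dag(300L, 3L, 0.2, 0.15, seed = 31L, p_alt = 0.1)
  ont <- tr$ontology
  for (acc in ont$go_id) {
    r <- resolve_term(ont, acc)
    if (length(r$targets)) {
      expect_false(any(ont$is_obsolete[match(r$targets, ont$numeric_key)]),
                   label = acc)
    }
  }
})

test_that("syntactically invalid accessions raise a distinct error", {
  ont <- parse_obo(resolution_fixture_obo())
  expect_error(resolve_term(ont, "not-an-accession"),
               class = "ontomatrix_bad_accession")
  expect_error(resolve_term(ont, "GO:12ab"),
               class = "ontomatrix_bad_accession")
})

test_that("duplicate alt_id claims warn and keep the first owner", {
  obo <- c(
    "[Term]", "id: GO:0000001", "alt_id: GO:0000100", "",
    "[Term]", "id: GO:0000002", "alt_id: GO:0000100", ""
  )
  expect_warning(ont <- parse_obo(obo), "first claim kept")
  expect_equal(unname(ont$alt_index["GO:0000100"]), 1L)
})
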