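# small helper: a closed annotation set straight from fixture truth
closed_fixture <- function(n_terms = 200L, n_genes = 100L, seed = 141L) {
  tr <- generate_dag(n_terms, 2L, 0.25, 0, seed = seed)
  tr <- generate_annotations(tr, n_genes = n_genes, seed = seed + 1L)
  list(truth = tr,
       closed = close_annotation_set(tr$ontology,
                                     parse_generic(tr$tsv_lines, 1L, 2L)))
}

test_that("single-gene, single-term input gives the 1x1 matrix", {
  ont <- parse_obo(c("[Term]", "id: GO:0008150", "name: bp", ""))
  closed <- close_annotation_set(ont, parse_generic("g1\tGO:0008150", 1L, 2L))
  m <- build_matrix(closed)
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(m$row_names, "g1")
  expect_equal(m$col_names, "GO:0008150")
  expect_equal(cbind(m$i, m$j), cbind(1L, 1L))
})

test_that("disjoint closed sets force dimensions and row sums", {
  ont <- parse_obo(unlist(lapply(1:5, function(k) {
    c("[Term]", sprintf("id: GO:%07d", k), "")
  })))
  ann <- parse_generic(c(
    "g1\tGO:0000001;GO:0000002",
    "g2\tGO:0000003;GO:0000004;GO:0000005"
  ), 1L, 2L)
  m <- build_matrix(close_annotation_set(ont, ann))
  expect_equal(dim(m), c(2L, 5L))
  expect_equal(length(m$i), 5L)
  expect_equal(unname(rowSums(as.matrix(m))), c(2, 3))
})

test_that("row and column sums match an independent tally of the closed set", {
  cf <- closed_fixture(n_genes = 300L)
  m <- build_matrix(cf$closed)
  expect_equal(unname(rowSums(as.matrix(m))),
               as.numeric(lengths(cf$closed$terms)))
  # independent per-term membership tally over the annotation set
  tally <- table(unlist(cf$closed$terms, use.names = FALSE))
  expect_equal(unname(colSums(as.matrix(m))),
               as.numeric(tally[m$col_names]))
  # conservation: triplet count is the sum of closed-set sizes
  expect_equal(length(m$i), sum(lengths(cf$closed$terms)))
  # columns sorted by numeric key
  expect_false(is.unsorted(accession_key(m$col_names), strictly = TRUE))
})

test_that("membership counts never shrink from child to is_a parent", {
  cf <- closed_fixture(seed = 151L)
  m <- build_matrix(cf$closed)
  ont <- cf$truth$ontology
  counts <- colSums(as.matrix(m))
  key_of <- accession_key(m$col_names)
  for (ci in seq_along(m$col_names)) {
    r <- match(key_of[ci], ont$numeric_key)
    for (p in ont$is_a_parents[[r]]) {
      pi <- match(p, key_of)
      if (!is.na(pi)) expect_gte(counts[pi], counts[ci])
    }
  }
})

test_that("sparse triplet files round-trip exactly on random matrices", {
  for (seed in 161:172) {
    tr <- generate_dag(sample(30:120, 1L), sample(1:2, 1L), 0.3, 0,
                       seed = seed)
    tr <- generate_annotations(tr, n_genes = sample(10:60, 1L),
                               seed = seed + 500L)
    m <- build_matrix(close_annotation_set(
      tr$ontology, parse_generic(tr$tsv_lines, 1L, 2L)
    ))
    f <- replicate(3L, tempfile())
    on.exit(unlink(f), add = TRUE)
    write_sparse(m, f[1L], f[2L], f[3L])
    m2 <- read_sparse(f[1L], f[2L], f[3L])
    expect_identical(m2, m, label = paste("seed", seed))
  }
})

test_that("triplet layout is the documented row<TAB>col<TAB>1, (row,col) sorted", {
  ont <- parse_obo(c("[Term]", "id: GO:0008150", "name: bp", ""))
  closed <- close_annotation_set(ont, parse_generic("g1\tGO:0008150", 1L, 2L))
  m <- build_matrix(closed)
  f <- replicate(3L, tempfile())
  write_sparse(m, f[1L], f[2L], f[3L])
  expect_identical(readLines(f[1L]), "1\t1\t1")
  expect_identical(readLines(f[2L]), "g1")
  expect_identical(readLines(f[3L]), "GO:0008150")
})

test_that("an emptied gene keeps its rowname but contributes no triplets", {
  cf <- closed_fixture(n_genes = 20L, seed = 181L)
  closed <- cf$closed
  closed$terms[[5L]] <- character()
  m <- build_matrix(closed)
  f <- replicate(3L, tempfile())
  write_sparse(m, f[1L], f[2L], f[3L])
  expect_equal(length(readLines(f[2L])), 20L)
  tr <- read.table(f[1L], sep = "\t")
  expect_false(5L %in% tr$V1)
})

test_that("full grid densifies identically to the sparse triplets", {
  cf <- closed_fixture(n_genes = 40L, seed = 191L)
  m <- build_matrix(cf$closed)
  f <- withr::local_tempfile()
  write_full(m, f)
  lines <- readLines(f)
  hdr <- strsplit(lines[1L], "\t")[[1L]]
  expect_equal(hdr[1L], "")
  expect_equal(hdr[-1L], m$col_names)
  body <- strsplit(lines[-1L], "\t")
  expect_equal(vapply(body, `[[`, character(1L), 1L), m$row_names)
  dense <- t(vapply(body, function(r) as.integer(r[-1L]),
                    integer(length(m$col_names))))
  expect_equal(unname(dense), unname(as.matrix(m)))
})

test_that("read_sparse rejects malformed triplet inputs", {
  rn <- withr::local_tempfile(lines = c("g1", "g2"))
  cn <- withr::local_tempfile(lines = c("GO:0000001"))
  bad_val <- withr::local_tempfile(lines = "1\t1\t2")
  expect_error(read_sparse(bad_val, rn, cn), "must all be 1")
  oob <- withr::local_tempfile(lines = "3\t1\t1")
  expect_error(read_sparse(oob, rn, cn), "out of range")
  dup <- withr::local_tempfile(lines = c("1\t1\t1", "1\t1\t1"))
  expect_error(read_sparse(dup, rn, cn), "duplicate")
  empty_names <- withr::local_tempfile(lines = character())
  expect_error(read_sparse(dup, empty_names, cn), "empty row or column")
})

test_that("the MatrixMarket export matches the native sparse form", {
  cf <- closed_fixture(n_genes = 25L, seed = 201L)
  m <- build_matrix(cf$closed)
  f <- replicate(3L, tempfile())
  write_mtx(m, f[1L], f[2L], f[3L])
  mm <- Matrix::readMM(f[1L])
  expect_equal(unname(as.matrix(mm)) * 1, unname(as.matrix(m)) * 1,
               ignore_attr = TRUE)
})
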