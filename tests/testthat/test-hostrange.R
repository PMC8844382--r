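test_that("read_host_range parses delimited matrices in both orientations", {
  cells <- matrix(c(1, 0, 0, 0, 1, 1), 2, 3, byrow = TRUE,
                  dimnames = list(c("b1", "b2"), c("p1", "p2", "p3")))
  path <- write_matrix_file(cells)
  hrm <- read_host_range(path)
  expect_s3_class(hrm, "host_range_matrix")
  expect_identical(dim(hrm$binary), c(2L, 3L))
  expect_identical(n_lytic(hrm), 3L)
  expect_identical(hrm$binary, matrix(as.integer(cells), 2, 3,
                                      dimnames = dimnames(cells)))

  # transposed source: rows are phages, canonical form is still 2x3
  tpath <- write_matrix_file(t(cells))
  hrm_t <- read_host_range(tpath, orientation = "rows_are_phages")
  expect_identical(hrm_t$binary, hrm$binary)
})

test_that("quantitative cells binarize strictly above the threshold", {
  cells <- matrix(c(0.5, 0.0, 0.2, 0.9), 2, 2, byrow = TRUE,
                  dimnames = list(c("b1", "b2"), c("p1", "p2")))
  hrm <- read_host_range(write_matrix_file(cells), threshold = 0.3)
  expect_identical(hrm$binary, matrix(c(1L, 0L, 0L, 1L), 2, 2, byrow = TRUE,
                                      dimnames = dimnames(cells)))
  expect_identical(hrm$cells, cells)  # raw values retained
  # threshold is strict: a cell equal to the threshold is non-lytic
  expect_identical(host_range_matrix(cells, threshold = 0.5)$binary["b1", "p1"], 0L)
})

test_that("delimiter auto-detection covers tab, comma and semicolon", {
  cells <- matrix(c(1, 0, 1, 1), 2, 2,
                  dimnames = list(c("b1", "b2"), c("p1", "p2")))
  for (d in c("\t", ",", ";")) {
    hrm <- read_host_range(write_matrix_file(cells, delim = d))
    expect_identical(hrm$binary, matrix(as.integer(cells), 2, 2,
                                        dimnames = dimnames(cells)))
  }
})

test_that("malformed matrices raise labelled errors", {
  cells <- matrix(1, 2, 2, dimnames = list(c("b1", "b1"), c("p1", "p2")))
  expect_error(read_host_range(write_matrix_file(cells)), "duplicate bacterium.*b1")
  cells2 <- matrix(1, 2, 2, dimnames = list(c("b1", "b2"), c("p1", "p1")))
  expect_error(read_host_range(write_matrix_file(cells2)), "duplicate phage.*p1")

  ragged <- tempfile()
  writeLines(c("\tp1\tp2", "b1\t1\t0", "b2\t1"), ragged)
  expect_error(read_host_range(ragged), "ragged")

  bad <- tempfile()
  writeLines(c("\tp1\tp2", "b1\t1\tx", "b2\t0\t1"), bad)
  expect_error(read_host_range(bad), 'non-numeric cell at row "b1", column "p2"')

  expect_error(host_range_matrix(matrix(-1, 1, 1,
    dimnames = list("b1", "p1"))), "non-negative")
})

test_that("edge lists count lytic cells and round-trip the binarized matrix", {
  id2 <- host_range_matrix(structure(diag(2),
    dimnames = list(c("b1", "b2"), c("p1", "p2"))))
  path <- tempfile()
  expect_identical(write_edge_list(id2, path), 2L)

  zero <- host_range_matrix(matrix(0, 2, 2,
    dimnames = list(c("b1", "b2"), c("p1", "p2"))))
  path0 <- tempfile()
  expect_identical(write_edge_list(zero, path0), 0L)
  expect_identical(readLines(path0), "phage\tbacterium")  # header only

  cells <- matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1), 3, 3)[, 1:2]
  dimnames(cells) <- list(c("b1", "b2", "b3"), c("p1", "p2"))
  hrm <- host_range_matrix(cells)
  p5 <- tempfile()
  expect_identical(write_edge_list(hrm, p5), sum(cells == 1))

  edges <- utils::read.delim(p5, stringsAsFactors = FALSE)
  back <- matrix_from_edges(edges, bacteria_ids(hrm), phage_ids(hrm))
  expect_identical(back$binary, hrm$binary)
})

test_that("binarization is idempotent", {
  hrm <- random_matrix(8, 5, fill = 0.4, seed = 7)
  again <- host_range_matrix(hrm$binary * 1)
  expect_identical(again$binary, hrm$binary)
})

test_that("corpus metadata fixture satisfies its structural invariants", {
  meta <- load_table1_metadata()
  expect_identical(nrow(meta), 50L)
  expect_true(all(meta$matrix_size == meta$n_hosts * meta$n_phages))
  expect_identical(meta$n_hosts[1], 7L)
  expect_identical(meta$n_phages[1], 3L)
  expect_identical(meta$matrix_size[1], 21L)
  expect_identical(max(meta$matrix_size), 12450L)
})
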