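test_that("read_mtx reads coordinate files, sums duplicates, drops zeros", {
  dir <- write_mtx_text(tempfile("mtx"), n_genes = 3, n_cells = 2,
                        triplets = data.frame(i = c(1, 3), j = c(1, 2),
                                              x = c(2, 1)))
  sc <- read_fixture(dir)
  expect_s4_class(sc, "SparseCounts")
  expect_equal(dim(sc), c(2L, 3L))            # cells x genes
  expect_equal(length(sc@x), 2L)
  expect_equal(unname(Matrix::colSums(sc)), c(2, 0, 1))

  # duplicate triplets are accumulated
  dup <- write_mtx_text(tempfile("dup"), 2, 2,
                        data.frame(i = c(1, 1), j = c(1, 1), x = c(1, 2)))
  sd <- read_fixture(dup)
  expect_equal(length(sd@x), 1L)
  expect_equal(as.matrix(sd)["c1", "g1"], 3)

  # degenerate: empty entry list is a valid all-zero matrix
  z <- write_mtx_text(tempfile("z"), 5, 4, data.frame(i = integer(), j = integer(),
                                                      x = numeric()))
  sz <- read_fixture(z)
  expect_equal(dim(sz), c(4L, 5L))
  expect_equal(length(sz@x), 0L)
})

test_that("read_mtx rejects dimension mismatches and bad values", {
  dir <- write_mtx_text(tempfile("bad"), 3, 2,
                        data.frame(i = 1, j = 1, x = 1))
  writeLines(c("g1", "g2"), file.path(dir, "genes.tsv"))   # wrong length
  expect_error(read_fixture(dir), "format error")

  neg <- write_mtx_text(tempfile("neg"), 2, 2,
                        data.frame(i = 1, j = 1, x = -3))
  expect_error(read_fixture(neg), "data error")

  frac <- write_mtx_text(tempfile("frac"), 2, 2,
                         data.frame(i = 1, j = 1, x = 1.5), field = "real")
  expect_error(read_fixture(frac), "data error")
})

test_that("write_mtx / read_mtx round trip preserves the triplet multiset", {
  rs <- generate_random_sparse(20, 30, density = 0.1, seed = 7)
  dir <- tempfile("rt")
  write_mtx(rs$counts, dir)
  back <- read_fixture(dir)
  expect_identical(as.matrix(back), as.matrix(rs$counts))
  expect_identical(gene_ids(back), gene_ids(rs$counts))
  expect_identical(cell_ids(back), cell_ids(rs$counts))
})

test_that("orient_gene_major is an involution that preserves per-gene sums", {
  set.seed(42)
  dense <- matrix(rpois(20 * 30, 0.3), nrow = 20)  # genes x cells
  rownames(dense) <- paste0("g", 1:20); colnames(dense) <- paste0("c", 1:30)
  sc <- orient_gene_major(Matrix::Matrix(dense, sparse = TRUE))
  expect_equal(as.matrix(sc), t(dense))
  expect_equal(unname(Matrix::colSums(sc)), unname(rowSums(dense)))
  back <- Matrix::t(as(sc, "dgCMatrix"))
  expect_equal(as.matrix(back), dense)
})

test_that("qc_filter applies each threshold and reports removal counts", {
  cells <- data.frame(
    n_genes_detected = c(400, 3000, 5500, 2000, 1000, 1500),
    total_umi        = c(900, 45000, 20000, 8000, 5000, 6000),
    pct_mito         = c(2, 2, 3, 25, 2, 5))
  mask <- qc_filter(cells, qc_thresholds())
  expect_identical(as.logical(mask), c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  rc <- attr(mask, "removal_counts")
  expect_equal(unname(rc["low_genes"]), 1)
  expect_equal(unname(rc["high_genes"]), 1)
  expect_equal(unname(rc["high_umi"]), 1)
  expect_equal(unname(rc["high_mito"]), 1)
  # boundary values are retained (bounds are inclusive)
  edge <- data.frame(n_genes_detected = c(500, 5000), total_umi = c(40000, 100),
                     pct_mito = c(20, 0))
  expect_true(all(qc_filter(edge)))
  expect_length(qc_filter(cells[0, ]), 0)
})

test_that("qc_filter is monotone under threshold loosening", {
  set.seed(5)
  cells <- data.frame(n_genes_detected = sample(0:8000, 300, TRUE),
                      total_umi = sample(0:60000, 300, TRUE),
                      pct_mito = runif(300, 0, 40))
  base <- qc_filter(cells, qc_thresholds(500, 5000, 40000, 20))
  looser <- list(qc_thresholds(400, 5000, 40000, 20),
                 qc_thresholds(500, 6000, 40000, 20),
                 qc_thresholds(500, 5000, 50000, 20),
                 qc_thresholds(500, 5000, 40000, 30))
  for (thr in looser) {
    m <- qc_filter(cells, thr)
    expect_true(all(m[base]))   # no previously retained cell is removed
  }
})

test_that("log_normalize matches ln(1 + v*sf/T) and preserves structure", {
  dense <- rbind(c(10, 0, 9990), c(4, 4, 0))   # cells x genes, totals 10000, 8
  sc <- counts_from_dense(dense)
  ln <- log_normalize(sc, scale_factor = 10000)
  expect_equal(counts_layer(ln), "lognorm")
  expect_equal(as.matrix(ln)[1, 1], log(11))
  expect_equal(as.matrix(ln)[1, 2], 0)          # implicit zero preserved
  # scale invariance: doubling a cell's counts leaves its profile unchanged
  ln2 <- log_normalize(counts_from_dense(2 * dense))
  expect_equal(as.matrix(ln2), as.matrix(ln))
  # nonzero pattern and within-cell ordering survive
  rs <- generate_random_sparse(40, 60, 0.2, seed = 2)
  raw <- bump_empty_cells(rs$counts)
  lnr <- log_normalize(raw)
  expect_identical(lnr@i, as(raw, "dgCMatrix")@i)
  expect_identical(lnr@p, as(raw, "dgCMatrix")@p)
  for (cell in c(1, 17)) {
    o_raw <- order(as.matrix(raw)[cell, ])
    o_ln <- order(as.matrix(lnr)[cell, ])
    expect_identical(o_ln, o_raw)
  }
  # zero-total cell is an error naming the cell
  bad <- counts_from_dense(rbind(c(1, 0), c(0, 0)))
  expect_error(log_normalize(bad), "cell2")
})

test_that("annotations join by cell id in barcode order with QC stats", {
  rs <- generate_random_sparse(10, 4, 0.5, seed = 3)
  ann <- data.frame(cell_id = rev(cell_ids(rs$counts)),
                    donor_id = "d1", cell_type = "T",
                    age_years = 30, sex = "F", pct_mito = 1)
  path <- tempfile(fileext = ".tsv")
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  joined <- read_cell_annotations(path, rs$counts)
  expect_identical(joined$cell_id, cell_ids(rs$counts))
  expect_identical(joined$n_genes_detected,
                   unname(as.integer(Matrix::rowSums(as.matrix(rs$counts) > 0))))
  ann_miss <- ann[-1, ]
  write.table(ann_miss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cell_annotations(path, rs$counts), "missing")
})

test_that("pct_mito_from_prefix computes per-cell mitochondrial percentage", {
  dense <- rbind(c(2, 8), c(0, 5))
  sc <- sparse_counts(Matrix::Matrix(dense, sparse = TRUE),
                      gene_ids = c("MT-CO1", "ACTB"),
                      cell_ids = c("a", "b"))
  expect_equal(pct_mito_from_prefix(sc), c(20, 0))
})
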