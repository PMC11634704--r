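#' Read a Matrix Market sparse count matrix with gene and barcode files
#'
#' Reads the CellRanger-style triplet layout: a coordinate-format `.mtx` with
#' genes in rows and cells in columns, plus one-identifier-per-line gene and
#' barcode files. Duplicate (gene, cell) triplets are summed and explicit
#' zeros dropped; the result is reoriented to the package's gene-major
#' (cells x genes) layout.
#'
#' @param matrix_path Path to a Matrix Market coordinate file (genes x cells).
#' @param genes_path Path to a text file of gene identifiers, one per line
#'   (first tab-separated field is used, so CellRanger `genes.tsv` works).
#' @param barcodes_path Path to a text file of cell barcodes, one per line.
#' @param layer Layer of the stored values; raw integer counts by default.
#' @return A [SparseCounts-class] object.
#' @export
read_mtx <- function(matrix_path, genes_path, barcodes_path,
                     layer = c("raw", "lognorm")) {
  layer <- match.arg(layer)
  for (p in c(matrix_path, genes_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  genes <- read_id_column(genes_path)
  barcodes <- read_id_column(barcodes_path)
  if (nrow(m) != length(genes))
    stop(sprintf("format error: matrix has %d rows but %d gene ids", nrow(m), length(genes)))
  if (ncol(m) != length(barcodes))
    stop(sprintf("format error: matrix has %d columns but %d barcodes", ncol(m), length(barcodes)))
  # readMM returns dgTMatrix; coercion to CsparseMatrix sums duplicate triplets
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  if (length(m@x)) {
    if (anyNA(m@x) || any(m@x < 0))
      stop("data error: negative or missing count in ", matrix_path)
    if (layer == "raw" && any(m@x != floor(m@x)))
      stop("data error: non-integer count in raw matrix ", matrix_path)
  }
  orient_gene_major(m, gene_ids = genes, cell_ids = barcodes, layer = layer)
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a SparseCounts object as Matrix Market + gene/barcode files
#'
#' Inverse of [read_mtx()]: writes `matrix.mtx` (genes x cells, coordinate
#' format; the `real` field is used for the lognorm layer), `genes.tsv` and
#' `barcodes.tsv` into `dir`.
#'
#' @param counts A [SparseCounts-class] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_mtx <- function(counts, dir) {
  stopifnot(is(counts, "SparseCounts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  m <- Matrix::t(as_dgc(counts))   # genes x cells on disk
  Matrix::writeMM(m, paths[1])
  writeLines(gene_ids(counts), paths[2])
  writeLines(cell_ids(counts), paths[3])
  invisible(paths)
}

#' Read a per-cell annotation table
#'
#' Expects a tab-separated file with a header including at least
#' `cell_id`, `donor_id`, `cell_type`, `age_years`, `sex` and optionally
#' `pct_mito`. Rows are joined to the matrix cell axis by `cell_id` and
#' reordered so the barcode file order is authoritative.
#'
#' @param path Path to the TSV file.
#' @param counts Optional [SparseCounts-class]; when given, the table is
#'   reordered to match `cell_ids(counts)` and QC statistics
#'   (`n_genes_detected`, `total_umi`) are computed from the raw matrix.
#' @return A `data.frame` with one row per cell, in matrix order when
#'   `counts` is supplied.
#' @export
read_cell_annotations <- function(path, counts = NULL) {
  # read everything as character first: type.convert would turn an all-female
  # sex column ("F", "F", ...) into logicals
  ann <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  for (col in intersect(c("age_years", "pct_mito", "n_genes_detected",
                          "total_umi", "decile"), names(ann)))
    ann[[col]] <- as.numeric(ann[[col]])
  required <- c("cell_id", "donor_id", "cell_type", "age_years", "sex")
  missing <- setdiff(required, names(ann))
  if (length(missing))
    stop("annotation file missing columns: ", paste(missing, collapse = ", "))
  if (!all(ann$sex %in% c("F", "M")))
    stop("sex must be coded F/M")
  if (is.null(counts)) return(ann)
  idx <- match(cell_ids(counts), ann$cell_id)
  if (anyNA(idx))
    stop("annotation table is missing ", sum(is.na(idx)), " cell ids present in the matrix")
  ann <- ann[idx, , drop = FALSE]
  rownames(ann) <- NULL
  cbind(ann, cell_qc_stats(counts)[setdiff(c("n_genes_detected", "total_umi"), names(ann))])
}

#' Per-cell QC statistics from a raw count matrix
#'
#' @param counts A raw-layer [SparseCounts-class] object.
#' @return A `data.frame` with `n_genes_detected` (nonzero genes per cell) and
#'   `total_umi` (column sum of raw counts), in matrix cell order.
#' @export
cell_qc_stats <- function(counts) {
  stopifnot(is(counts, "SparseCounts"))
  m <- as_dgc(counts)
  data.frame(
    n_genes_detected = as.integer(Matrix::rowSums(m > 0)),
    total_umi = as.integer(round(Matrix::rowSums(m)))
  )
}

#' Mitochondrial UMI percentage from a gene-name prefix
#'
#' @param counts A raw-layer [SparseCounts-class] object.
#' @param prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return Numeric vector, percent of each cell's UMIs on prefix-matching
#'   genes (0 for cells with no UMIs).
#' @export
pct_mito_from_prefix <- function(counts, prefix = "MT-") {
  m <- as_dgc(counts)
  mito <- startsWith(gene_ids(counts), prefix)
  tot <- Matrix::rowSums(m)
  mt <- if (any(mito)) Matrix::rowSums(m[, mito, drop = FALSE]) else numeric(nrow(m))
  unname(ifelse(tot > 0, 100 * mt / tot, 0))
}

#' QC thresholds for cell filtering
#'
#' Defaults follow common droplet-data practice for PBMCs: cells with fewer
#' than 500 detected genes are dropped as low quality; cells with more than
#' 5000 detected genes or more than 40,000 UMIs are dropped as likely
#' doublets; the mitochondrial cutoff defaults to the permissive end (20%) of
#' the usual 5--20% range and should be tuned per dataset.
#'
#' @param min_genes,max_genes Bounds on detected genes per cell.
#' @param max_umi Upper bound on total UMI per cell.
#' @param max_pct_mito Upper bound on mitochondrial percentage.
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(min_genes = 500, max_genes = 5000,
                          max_umi = 40000, max_pct_mito = 20) {
  stopifnot(min_genes > 0, max_genes > 0, max_umi > 0, max_pct_mito > 0,
            min_genes < max_genes)
  list(min_genes = min_genes, max_genes = max_genes,
       max_umi = max_umi, max_pct_mito = max_pct_mito)
}

#' Filter cells on QC thresholds
#'
#' A cell is retained iff `min_genes <= n_genes_detected <= max_genes`,
#' `total_umi <= max_umi` and `pct_mito <= max_pct_mito`.
#'
#' @param cells A per-cell `data.frame` with columns `n_genes_detected`,
#'   `total_umi` and `pct_mito` (see [read_cell_annotations()],
#'   [pct_mito_from_prefix()]).
#' @param thresholds A list from [qc_thresholds()].
#' @return A logical mask over cells (`TRUE` = retained) with attribute
#'   `removal_counts`, the number of cells failing each criterion (a cell may
#'   count against several).
#' @export
qc_filter <- function(cells, thresholds = qc_thresholds()) {
  need <- c("n_genes_detected", "total_umi", "pct_mito")
  missing <- setdiff(need, names(cells))
  if (length(missing)) stop("cells table missing columns: ", paste(missing, collapse = ", "))
  too_few  <- cells$n_genes_detected < thresholds$min_genes
  too_many <- cells$n_genes_detected > thresholds$max_genes
  high_umi <- cells$total_umi > thresholds$max_umi
  high_mt  <- cells$pct_mito > thresholds$max_pct_mito
  mask <- !(too_few | too_many | high_umi | high_mt)
  attr(mask, "removal_counts") <- c(
    low_genes = sum(too_few), high_genes = sum(too_many),
    high_umi = sum(high_umi), high_mito = sum(high_mt))
  mask
}

#' Log-normalize raw counts
#'
#' Per cell, each raw count `v` with cell total `T` maps to
#' `log(1 + v * scale_factor / T)`; the sparsity pattern is unchanged.
#' `scale_factor = 10000` is the convention for UMI data.
#'
#' @param counts A raw-layer [SparseCounts-class] object; every cell must
#'   have at least one UMI.
#' @param scale_factor Library-size target after rescaling.
#' @return A lognorm-layer [SparseCounts-class] object.
#' @export
log_normalize <- function(counts, scale_factor = 10000) {
  stopifnot(is(counts, "SparseCounts"))
  if (counts@layer != "raw") stop("log_normalize expects the raw layer")
  m <- as_dgc(counts)
  tot <- Matrix::rowSums(m)
  if (any(tot <= 0)) {
    bad <- cell_ids(counts)[tot <= 0][1]
    stop("cell with zero total UMI: ", bad)
  }
  # scale each stored value by its cell's total: values are column-compressed
  # by gene, so expand cell totals over the row-index slot
  m@x <- log1p(m@x * scale_factor / tot[m@i + 1L])
  sparse_counts(m, layer = "lognorm")
}
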