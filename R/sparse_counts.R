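#' @importClassesFrom Matrix dgCMatrix
NULL

#' Sparse gene-major count container
#'
#' `SparseCounts` extends [Matrix::dgCMatrix-class] with a `layer` slot and
#' fixes the orientation used throughout the package: cells in rows, genes in
#' columns, so each compressed column is one gene -- the layout the rank
#' engine consumes. Stored values are strictly positive (zeros are implicit);
#' the `raw` layer holds integer UMI counts, the `lognorm` layer holds
#' log-normalized expression.
#'
#' @slot layer Either `"raw"` or `"lognorm"`.
#' @export
setClass("SparseCounts", contains = "dgCMatrix",
         representation(layer = "character"),
         prototype(layer = "raw"))

setValidity("SparseCounts", function(object) {
  if (length(object@layer) != 1L || !object@layer %in% c("raw", "lognorm"))
    return("layer must be 'raw' or 'lognorm'")
  x <- object@x
  if (anyNA(x) || any(!is.finite(x)))
    return("stored values must be finite and non-missing")
  if (any(x <= 0))
    return("stored values must be strictly positive (zeros are implicit)")
  if (object@layer == "raw" && any(x != floor(x)))
    return("raw layer requires integer counts")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("cell and gene identifiers are required")
  if (anyDuplicated(rownames(object))) return("cell_ids must be unique")
  if (anyDuplicated(colnames(object))) return("gene_ids must be unique")
  TRUE
})

#' Construct a SparseCounts object
#'
#' @param mat A matrix coercible to `dgCMatrix`, cells in rows and genes in
#'   columns. Explicit zeros are dropped.
#' @param gene_ids Character vector of unique gene identifiers (one per
#'   column); defaults to `colnames(mat)` or `gene1..geneG`.
#' @param cell_ids Character vector of unique cell barcodes (one per row);
#'   defaults to `rownames(mat)` or `cell1..cellN`.
#' @param layer `"raw"` (positive integer counts) or `"lognorm"`.
#'
#' @return A [SparseCounts-class] object.
#' @examples
#' m <- Matrix::rsparsematrix(20, 10, density = 0.2,
#'                            rand.x = function(n) rpois(n, 3) + 1)
#' sc <- sparse_counts(m)
#' counts_layer(sc)
#' @export
sparse_counts <- function(mat, gene_ids = NULL, cell_ids = NULL,
                          layer = c("raw", "lognorm")) {
  layer <- match.arg(layer)
  m <- as(as(as(mat, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  m <- Matrix::drop0(m)
  if (is.null(gene_ids)) gene_ids <- colnames(m) %||% paste0("gene", seq_len(ncol(m)))
  if (is.null(cell_ids)) cell_ids <- rownames(m) %||% paste0("cell", seq_len(nrow(m)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(m))
    stop("length(gene_ids) must equal the number of matrix columns (genes)")
  if (length(cell_ids) != nrow(m))
    stop("length(cell_ids) must equal the number of matrix rows (cells)")
  dimnames(m) <- list(cell_ids, gene_ids)
  new("SparseCounts", m, layer = layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accessors for SparseCounts metadata
#'
#' @param x A `SparseCounts` object.
#' @return `counts_layer()` returns `"raw"` or `"lognorm"`; `gene_ids()` and
#'   `cell_ids()` return the axis identifiers; `n_genes()`/`n_cells()` the
#'   axis extents.
#' @export
counts_layer <- function(x) x@layer

#' @rdname counts_layer
#' @export
gene_ids <- function(x) colnames(x)

#' @rdname counts_layer
#' @export
cell_ids <- function(x) rownames(x)

#' @rdname counts_layer
#' @export
n_genes <- function(x) ncol(x)

#' @rdname counts_layer
#' @export
n_cells <- function(x) nrow(x)

setMethod("show", "SparseCounts", function(object) {
  cat(sprintf("SparseCounts: %d cells x %d genes, layer=%s, %d stored values (%.1f%% dense)\n",
              nrow(object), ncol(object), object@layer, length(object@x),
              if (prod(dim(object)) > 0) 100 * length(object@x) / prod(dim(object)) else 0))
  invisible(object)
})

#' Reorient a gene-by-cell sparse matrix to the package's gene-major layout
#'
#' Matrix Market files conventionally store genes in rows and cells in
#' columns; the package works on the transpose (cells x genes) so that each
#' compressed column is one gene. The multiset of (gene, cell, value)
#' triplets is preserved exactly.
#'
#' @param mat A sparse matrix with genes in rows and cells in columns.
#' @inheritParams sparse_counts
#' @return A [SparseCounts-class] object (cells x genes).
#' @export
orient_gene_major <- function(mat, gene_ids = rownames(mat), cell_ids = colnames(mat),
                              layer = c("raw", "lognorm")) {
  sparse_counts(Matrix::t(mat), gene_ids = gene_ids, cell_ids = cell_ids,
                layer = match.arg(layer))
}

# Plain dgCMatrix view (drops the subclass for Matrix operations).
as_dgc <- function(x) as(x, "dgCMatrix")

#' Subset a SparseCounts object by cells and/or genes
#'
#' @param x A `SparseCounts` object.
#' @param cells,genes Index vectors (integer, logical or character) into the
#'   cell and gene axes; `NULL` keeps the axis unchanged.
#' @return A `SparseCounts` object with the original layer.
#' @export
subset_counts <- function(x, cells = NULL, genes = NULL) {
  m <- as_dgc(x)
  if (!is.null(cells)) m <- m[cells, , drop = FALSE]
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  sparse_counts(m, layer = x@layer)
}
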