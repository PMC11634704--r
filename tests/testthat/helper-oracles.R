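# Independent dense oracles and small fixture builders. The oracles work on
# dense matrices and stats::wilcox.test only, so they share no code path with
# the sparse engine they check.

# classes x genes matrix of two-sided tie-corrected normal-approximation
# rank-sum p-values, one wilcox.test per (gene, class).
dense_wilcox_oracle <- function(counts, labels, continuity = TRUE) {
  dm <- as.matrix(counts)
  labels <- as.character(labels)
  classes <- unique(labels)
  p <- matrix(NA_real_, length(classes), ncol(dm),
              dimnames = list(classes, colnames(dm)))
  for (cl in classes) {
    in_cl <- labels == cl
    for (g in seq_len(ncol(dm))) {
      pv <- suppressWarnings(
        stats::wilcox.test(dm[in_cl, g], dm[!in_cl, g],
                           exact = FALSE, correct = continuity)$p.value)
      # wilcox.test yields NaN when every value ties (zero variance); the
      # degenerate-variance convention is "no evidence": p = 1
      p[cl, g] <- if (is.nan(pv)) 1 else pv
    }
  }
  p
}

# End-to-end dense marker pipeline: fold changes and detection fractions from
# the dense matrix, wilcox.test p-values, Bonferroni over the gene panel,
# then the marker criteria. Mirrors the published filter definitions only.
brute_force_markers <- function(lognorm, labels, logfc_threshold = 0.5,
                                alpha = 0.05, min_pct = 0.1) {
  dm <- as.matrix(lognorm)
  labels <- as.character(labels)
  classes <- unique(labels)
  G <- ncol(dm)
  p <- dense_wilcox_oracle(lognorm, labels)
  out <- list()
  for (cl in classes) {
    in_cl <- labels == cl
    m1 <- colMeans(expm1(dm[in_cl, , drop = FALSE]))
    m2 <- colMeans(expm1(dm[!in_cl, , drop = FALSE]))
    log_fc <- log2((m1 + 1) / (m2 + 1))
    pct1 <- colMeans(dm[in_cl, , drop = FALSE] > 0)
    pct2 <- colMeans(dm[!in_cl, , drop = FALSE] > 0)
    p_adj <- pmin(1, p[cl, ] * G)
    out[[cl]] <- data.frame(
      class = cl, gene = colnames(dm), log_fc = log_fc,
      pct_1 = pct1, pct_2 = pct2, p = p[cl, ], p_adj = p_adj,
      is_marker = (log_fc > logfc_threshold) & (p_adj < alpha) &
        (pmax(pct1, pct2) > min_pct),
      row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# SparseCounts from a dense matrix (cells x genes).
counts_from_dense <- function(mat, layer = "raw") {
  sparse_counts(Matrix::Matrix(mat, sparse = TRUE), layer = layer)
}

# Write a Matrix Market fixture by hand (so reading is tested against an
# independently constructed file, not against write_mtx()).
write_mtx_text <- function(dir, n_genes, n_cells, triplets,
                           field = "integer") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  lines <- c(sprintf("%%%%MatrixMarket matrix coordinate %s general", field),
             sprintf("%d %d %d", n_genes, n_cells, nrow(triplets)))
  if (nrow(triplets) > 0)
    lines <- c(lines, sprintf("%d %d %s", triplets[[1]], triplets[[2]],
                              format(triplets[[3]], trim = TRUE)))
  writeLines(lines, mtx)
  writeLines(sprintf("g%d", seq_len(n_genes)), file.path(dir, "genes.tsv"))
  writeLines(sprintf("c%d", seq_len(n_cells)), file.path(dir, "barcodes.tsv"))
  dir
}

read_fixture <- function(dir, ...) {
  read_mtx(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
           file.path(dir, "barcodes.tsv"), ...)
}

# Small annotated random matrix for label-based tests.
random_labelled <- function(n_genes = 60, n_cells = 150, density = 0.15,
                            n_classes = 3, seed = 1) {
  rs <- generate_random_sparse(n_genes, n_cells, density, n_classes,
                               seed = seed)
  rs$lognorm <- log_normalize(bump_empty_cells(rs$counts))
  rs
}

# Guarantee every cell has at least one UMI so log_normalize is defined.
bump_empty_cells <- function(counts) {
  m <- as(counts, "dgCMatrix")
  tot <- Matrix::rowSums(m)
  if (any(tot == 0)) m[which(tot == 0), 1] <- 1
  sparse_counts(m, layer = "raw")
}
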