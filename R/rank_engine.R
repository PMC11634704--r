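#' Rank one sparse gene column with a shared zero-block midrank
#'
#' Zeros are the smallest values of a sparse expression column: they occupy
#' ranks `1..n_zero` and collapse to the single midrank `(n_zero + 1) / 2`.
#' Nonzero values are ranked above the zero block with average (midrank) tie
#' handling. The tie-group sizes include the zero block, so the tie
#' correction `T = sum(t^3 - t)` can be formed directly.
#'
#' @param values Stored (strictly positive) values of the column.
#' @param n Total number of cells in the column (stored + implicit zeros).
#' @param cells Optional cell indices (1-based) of the stored values, carried
#'   through for rank-sum accumulation.
#' @return A list of class `ranked_column`: `n`, `n_zero`, `zero_rank`,
#'   `nz_ranks` (midranks of the stored values within the full column),
#'   `tie_sizes`, `tie_term` (`sum(t^3 - t)`), and `cells`.
#' @examples
#' rc <- rank_column(c(5, 3), n = 6, cells = c(3, 5))
#' rc$zero_rank   # 2.5: zeros occupy ranks 1..4
#' rc$nz_ranks    # 6, 5
#' @export
rank_column <- function(values, n, cells = seq_along(values)) {
  values <- as.numeric(values)
  if (length(values) > n) stop("more stored values than cells")
  if (anyNA(values) || any(values <= 0))
    stop("data error: stored values must be strictly positive")
  n_zero <- n - length(values)
  zero_rank <- (n_zero + 1) / 2
  nz_ranks <- if (length(values)) n_zero + rank(values, ties.method = "average") else numeric(0)
  tie_sizes <- c(if (n_zero >= 1) n_zero,
                 if (length(values)) as.integer(table(values)))
  structure(list(n = n, n_zero = n_zero, zero_rank = zero_rank,
                 nz_ranks = nz_ranks, tie_sizes = tie_sizes,
                 tie_term = sum(tie_sizes^3 - tie_sizes),
                 cells = cells),
            class = "ranked_column")
}

#' Accumulate per-class rank sums from a ranked column
#'
#' Each class's rank sum is the sum of its cells' ranks; cells in the zero
#' block contribute the shared zero midrank. Only the stored values are
#' visited -- the zero contribution is `n_zero_c * zero_rank` by bookkeeping
#' -- so the cost per gene is `O(nnz + C)` regardless of the number of
#' classes.
#'
#' @param ranked A `ranked_column` from [rank_column()].
#' @param labels Class label per cell (factor or character), length `n`.
#' @return A list of class `class_rank_sums`: `rank_sum` and `class_size`
#'   (named per class), `tie_term`, `n`.
#' @export
accumulate_rank_sums <- function(ranked, labels) {
  stopifnot(inherits(ranked, "ranked_column"))
  if (length(labels) != ranked$n)
    stop("labels must have length n = ", ranked$n)
  f <- as.factor(labels)
  codes <- as.integer(f)
  C <- nlevels(f)
  n_c <- tabulate(codes, C)
  nz_codes <- codes[ranked$cells]
  # rank sum of stored values per class, then add the zero-block contribution
  r_nz <- vapply(seq_len(C), function(c)
    sum(ranked$nz_ranks[nz_codes == c]), numeric(1))
  nz_per_class <- tabulate(nz_codes, C)
  rank_sum <- r_nz + (n_c - nz_per_class) * ranked$zero_rank
  structure(list(rank_sum = setNames(rank_sum, levels(f)),
                 class_size = setNames(n_c, levels(f)),
                 tie_term = ranked$tie_term, n = ranked$n),
            class = "class_rank_sums")
}

#' Convert a rank sum to U, z and a two-sided p-value
#'
#' Mann-Whitney form `U = R - n_c (n_c + 1) / 2`, normal approximation with
#' tie-corrected variance
#' `sigma^2 = n_c (n - n_c) / 12 * ((n + 1) - T / (n (n - 1)))` and an
#' optional 0.5 continuity correction toward the mean. When all values tie
#' (`sigma^2 = 0`) there is no evidence against the null and `p = 1`,
#' `z = 0`. Vectorized over its arguments.
#'
#' @param rank_sum Rank sum(s) `R_c` of the tested class.
#' @param class_size Class size(s) `n_c` (`1 <= n_c <= n - 1`).
#' @param n Total number of cells.
#' @param tie_term Tie correction `T = sum(t^3 - t)` over all tie groups.
#' @param continuity Apply the 0.5 continuity correction (default `TRUE`,
#'   matching the standard normal-approximation rank-sum test).
#' @return A data.frame with columns `U`, `z`, `p`.
#' @examples
#' # sizes 3 vs 3, no ties, U at its minimum
#' u_to_p(rank_sum = 6, class_size = 3, n = 6, tie_term = 0)$p  # 0.0809
#' @export
u_to_p <- function(rank_sum, class_size, n, tie_term = 0, continuity = TRUE) {
  if (any(class_size < 1) || any(class_size > n - 1))
    stop("class_size must be in 1..(n-1): one-vs-rest split undefined")
  n1 <- as.numeric(class_size)
  n2 <- n - n1
  U <- rank_sum - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  sigma2 <- pmax(sigma2, 0)
  d <- U - mu
  cc <- if (continuity) 0.5 * sign(d) else 0
  z <- ifelse(sigma2 > 0, (d - cc) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, pmin(1, 2 * pnorm(-abs(z))), 1)
  data.frame(U = U, z = z, p = p)
}

#' One-vs-all-others Wilcoxon rank-sum test for every gene and class
#'
#' For each gene column the stored values are ranked once (zero block
#' collapsed to a shared midrank, midrank ties) and the ranks are summed by
#' class in a single pass over the stored entries; the per-class U statistics
#' are then converted to two-sided p-values with the tie-corrected normal
#' approximation of [u_to_p()]. Every gene column is sorted exactly once and
#' reused for all classes, and each stored value is visited once per gene
#' regardless of the number of classes.
#'
#' Rank statistics are invariant under strictly increasing transforms applied
#' to a gene's values, so any shared rescaling (e.g. `log1p` at a fixed
#' scale) gives identical p-values. Per-cell library-size normalization is
#' not such a transform -- it can reorder values within a gene when totals
#' differ -- so run the test on the layer you mean to compare (the lognorm
#' layer, conventionally).
#'
#' @param counts A [SparseCounts-class] object (either layer).
#' @param labels Class label per cell (factor or character), length
#'   `n_cells(counts)`; at least two classes must be present.
#' @param continuity Apply the 0.5 continuity correction (default `TRUE`).
#' @return A list of class `ovr_test` with `classes x genes` matrices `U`,
#'   `z`, `p`, `rank_sum`, plus `class_size` (per class), `tie_term` (per
#'   gene), `n`, `classes`, `genes`. Class order is by first appearance in
#'   `labels` (factor level order for factors).
#' @export
wilcoxon_one_vs_rest <- function(counts, labels, continuity = TRUE) {
  stopifnot(is(counts, "SparseCounts"))
  n <- n_cells(counts)
  if (length(labels) != n) stop("labels must have length n_cells(counts)")
  f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  if (any(tabulate(as.integer(f), nlevels(f)) == 0)) {
    warning("dropping class levels with 0 cells: ",
            paste(setdiff(levels(f), unique(as.character(f))), collapse = ", "))
    f <- droplevels(f)
  }
  if (nlevels(f) < 2) stop("at least two classes are required")

  acc <- ovr_accumulate(counts, f)
  res <- u_to_p(as.vector(acc$rank_sum),
                rep(acc$class_size, times = ncol(acc$rank_sum)),
                n = n,
                tie_term = rep(acc$tie_term, each = nrow(acc$rank_sum)),
                continuity = continuity)
  shape <- function(v) matrix(v, nrow = nlevels(f),
                              dimnames = list(levels(f), gene_ids(counts)))
  structure(list(U = shape(res$U), z = shape(res$z), p = shape(res$p),
                 rank_sum = acc$rank_sum,
                 class_size = acc$class_size, tie_term = acc$tie_term,
                 n = n, classes = levels(f), genes = gene_ids(counts)),
            class = "ovr_test")
}

# Vectorized one-pass accumulation over all genes: per-class rank sums,
# per-class nonzero counts and de-logged sums (reused by fold_change), and
# per-gene tie terms. Works on the dgCMatrix slots directly.
ovr_accumulate <- function(counts, f, expm1_sums = FALSE) {
  m <- as_dgc(counts)
  n <- nrow(m); G <- ncol(m)
  C <- nlevels(f)
  codes <- as.integer(f)
  n_c <- tabulate(codes, C)
  nnz_per_gene <- diff(m@p)
  n_zero <- n - nnz_per_gene
  zero_rank <- (n_zero + 1) / 2

  dn <- list(levels(f), colnames(m))
  if (length(m@x) == 0L) {
    rank_sum <- outer(n_c, zero_rank)
    dimnames(rank_sum) <- dn
    return(list(rank_sum = rank_sum,
                nz_count = matrix(0, C, G, dimnames = dn),
                expm1_sum = if (expm1_sums) matrix(0, C, G, dimnames = dn),
                class_size = setNames(n_c, levels(f)),
                tie_term = setNames(n_zero^3 - n_zero, colnames(m))))
  }

  g <- rep.int(seq_len(G), nnz_per_gene)
  dt <- data.table::data.table(g = g, code = codes[m@i + 1L], x = m@x)
  dt[, r := data.table::frank(x, ties.method = "average"), by = "g"]
  rank_full <- dt$r + n_zero[dt$g]

  # midrank tie groups among the stored values, plus the zero block
  cnt <- dt[, .N, by = c("g", "x")]
  tie_nz <- cnt[, list(tt = sum(as.numeric(N)^3 - N)), by = "g"]
  tie_term <- n_zero^3 - n_zero
  tie_term[tie_nz$g] <- tie_term[tie_nz$g] + tie_nz$tt

  # class x gene accumulators; sparseMatrix sums duplicate (class, gene) hits
  acc_mat <- function(vals)
    as.matrix(Matrix::sparseMatrix(i = dt$code, j = dt$g, x = vals, dims = c(C, G)))
  r_nz <- acc_mat(rank_full)
  nz_count <- acc_mat(rep(1, nrow(dt)))
  rank_sum <- r_nz + (matrix(n_c, C, G) - nz_count) *
    matrix(zero_rank, C, G, byrow = TRUE)
  dimnames(rank_sum) <- dimnames(nz_count) <- dn

  e_sum <- NULL
  if (expm1_sums) {
    e_sum <- acc_mat(expm1(dt$x))
    dimnames(e_sum) <- dn
  }
  list(rank_sum = rank_sum, nz_count = nz_count, expm1_sum = e_sum,
       class_size = setNames(n_c, levels(f)),
       tie_term = setNames(tie_term, colnames(m)))
}

#' @exportS3Method base::print
print.ovr_test <- function(x, ...) {
  cat(sprintf("one-vs-rest Wilcoxon: %d classes x %d genes over %d cells\n",
              length(x$classes), length(x$genes), x$n))
  invisible(x)
}

#' Write a one-vs-rest test result as a long TSV
#'
#' @param result An `ovr_test` from [wilcoxon_one_vs_rest()].
#' @param path Output file; columns `class`, `gene`, `U`, `z`, `p`.
#' @return Invisibly, the data.frame written.
#' @export
write_ovr_tsv <- function(result, path) {
  df <- data.frame(class = rep(result$classes, times = length(result$genes)),
                   gene = rep(result$genes, each = length(result$classes)),
                   U = as.vector(result$U), z = as.vector(result$z),
                   p = as.vector(result$p))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
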