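#' Marker-detection parameters
#'
#' Defaults mirror standard cluster-marker practice on log-normalized data:
#' a log2 fold-change screen at 0.5, Bonferroni-adjusted p below 0.05, and
#' detection in more than 10% of cells in at least one of the two groups.
#'
#' @param logfc_threshold Minimum log fold change (on the `fc_base` scale).
#' @param alpha Adjusted-p cutoff.
#' @param min_pct Minimum detection fraction in either group (strict `>`).
#' @param adjust_method `"bonferroni"` (classical FindMarkers convention) or
#'   `"bh"` (Benjamini-Hochberg).
#' @param fc_base Base of the fold-change logarithm, `"log2"` or `"ln"`.
#' @param pseudocount Added to both de-logged group means before the ratio.
#' @return A named list of parameters.
#' @export
marker_params <- function(logfc_threshold = 0.5, alpha = 0.05, min_pct = 0.1,
                          adjust_method = c("bonferroni", "bh"),
                          fc_base = c("log2", "ln"), pseudocount = 1) {
  stopifnot(logfc_threshold >= 0, min_pct >= 0, alpha > 0, alpha < 1,
            pseudocount >= 0)
  list(logfc_threshold = logfc_threshold, alpha = alpha, min_pct = min_pct,
       adjust_method = match.arg(adjust_method), fc_base = match.arg(fc_base),
       pseudocount = pseudocount)
}

#' Fold change and detection fractions for one class versus the rest
#'
#' On log-normalized data the group means are taken on the de-logged scale
#' (`expm1(x)`), a pseudocount is added to both, and the log ratio is
#' reported (base 2 by default). `pct_1`/`pct_2` are the fractions of cells
#' with a nonzero value in the class and in the rest.
#'
#' @param counts A lognorm-layer [SparseCounts-class] object.
#' @param labels Class label per cell.
#' @param class The class to contrast against all other cells.
#' @param params A [marker_params()] list (only `fc_base` and `pseudocount`
#'   are used).
#' @return A data.frame with one row per gene: `gene`, `log_fc`, `pct_1`,
#'   `pct_2`.
#' @export
fold_change <- function(counts, labels, class, params = marker_params()) {
  stopifnot(is(counts, "SparseCounts"))
  f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  if (!class %in% levels(f)) stop("unknown class: ", class)
  in_class <- f == class
  if (!any(in_class)) stop("class ", class, " is empty")
  if (all(in_class)) stop("class ", class, " covers all cells; empty complement")
  acc <- ovr_accumulate(counts, factor(ifelse(in_class, "class", "rest"),
                                       levels = c("class", "rest")),
                        expm1_sums = TRUE)
  fc <- fold_change_from_acc(acc, params)
  data.frame(gene = gene_ids(counts),
             log_fc = fc$log_fc["class", ], pct_1 = fc$pct_1["class", ],
             pct_2 = fc$pct_2["class", ], row.names = NULL)
}

# classes x genes fold changes / detection fractions from an ovr_accumulate()
# result with expm1 sums; rest statistics come from column totals minus the
# class accumulator, so the pass over the stored values is shared.
fold_change_from_acc <- function(acc, params) {
  n_c <- acc$class_size
  n <- sum(n_c)
  tot_e <- colSums(acc$expm1_sum)
  tot_nz <- colSums(acc$nz_count)
  mean_1 <- acc$expm1_sum / n_c
  mean_2 <- sweep(-acc$expm1_sum, 2, tot_e, `+`) / (n - n_c)
  base <- if (params$fc_base == "log2") 2 else exp(1)
  log_fc <- log((mean_1 + params$pseudocount) / (mean_2 + params$pseudocount),
                base = base)
  pct_1 <- acc$nz_count / n_c
  pct_2 <- sweep(-acc$nz_count, 2, tot_nz, `+`) / (n - n_c)
  list(log_fc = log_fc, pct_1 = pct_1, pct_2 = pct_2)
}

#' Multiple-testing adjustment
#'
#' @param p P-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @param m Number of tests (`>= length(p)` after removing `NA`s); defaults
#'   to `length(p)`.
#' @return Adjusted p-values (capped at 1); `NA`s are passed through.
#' @export
adjust_p <- function(p, method = c("bonferroni", "bh"), m = length(p)) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  if (m < sum(ok)) stop("m must be at least the number of tests")
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni", n = m)
}

#' Find marker genes for every class (one-vs-all-others)
#'
#' Combines [wilcoxon_one_vs_rest()], [fold_change()] and [adjust_p()] and
#' applies the marker criteria: `log_fc > logfc_threshold`,
#' `p_adj < alpha`, and `max(pct_1, pct_2) > min_pct`. Adjustment is per
#' class over the full gene panel (`m = n_genes`). With `prefilter = TRUE`
#' (default), genes failing the fold-change or detection screen for every
#' class skip the rank test; they are still reported, with `is_marker =
#' FALSE` and `NA` p-values. Pre-filtering never changes `is_marker`
#' decisions, it only suppresses redundant tests.
#'
#' @param counts A lognorm-layer [SparseCounts-class] object.
#' @param labels Class label per cell; at least two classes.
#' @param params A [marker_params()] list.
#' @param prefilter Skip the rank test for genes screened out in every class.
#' @param continuity Passed to [wilcoxon_one_vs_rest()].
#' @return A data.frame of class `marker_table` with one row per
#'   (class, gene): `class`, `gene`, `log_fc`, `pct_1`, `pct_2`, `p`,
#'   `p_adj`, `is_marker`; attribute `params` records the configuration
#'   (including `adjust_method`).
#' @export
find_all_markers <- function(counts, labels, params = marker_params(),
                             prefilter = TRUE, continuity = TRUE) {
  stopifnot(is(counts, "SparseCounts"))
  f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  f <- droplevels(f)
  if (nlevels(f) < 2) stop("at least two classes are required")
  G <- n_genes(counts)
  acc <- ovr_accumulate(counts, f, expm1_sums = TRUE)
  fc <- fold_change_from_acc(acc, params)

  screen_pass <- (fc$log_fc > params$logfc_threshold) &
    (pmax(fc$pct_1, fc$pct_2) > params$min_pct)
  test_gene <- if (prefilter) which(colSums(screen_pass) > 0) else seq_len(G)

  p <- matrix(NA_real_, nlevels(f), G, dimnames = list(levels(f), gene_ids(counts)))
  if (length(test_gene)) {
    res <- wilcoxon_one_vs_rest(subset_counts(counts, genes = test_gene), f,
                                continuity = continuity)
    p[, test_gene] <- res$p
  }
  p_adj <- p
  for (r in seq_len(nrow(p)))
    p_adj[r, ] <- adjust_p(p[r, ], method = params$adjust_method, m = G)

  # genes with zero detection anywhere carry no signal: neutral record
  undetected <- matrix(colSums(acc$nz_count) == 0, nlevels(f), G, byrow = TRUE)
  fc$log_fc[undetected] <- 0
  p[undetected] <- 1
  p_adj[undetected] <- 1

  is_marker <- screen_pass & !is.na(p_adj) & (p_adj < params$alpha)
  out <- data.frame(
    class = factor(rep(levels(f), times = G), levels = levels(f)),
    gene = rep(gene_ids(counts), each = nlevels(f)),
    log_fc = as.vector(fc$log_fc), pct_1 = as.vector(fc$pct_1),
    pct_2 = as.vector(fc$pct_2), p = as.vector(p), p_adj = as.vector(p_adj),
    is_marker = as.vector(is_marker), row.names = NULL)
  attr(out, "params") <- params
  class(out) <- c("marker_table", class(out))
  out
}

#' Marker counts per class
#'
#' @param markers A `marker_table` from [find_all_markers()].
#' @return Named integer vector: number of `is_marker` rows per class.
#' @export
count_markers <- function(markers) {
  stopifnot(inherits(markers, "marker_table"))
  tab <- table(markers$class[markers$is_marker])
  setNames(as.integer(tab), names(tab))
}

#' Write a marker table as TSV
#'
#' @param markers A `marker_table`.
#' @param path Output file.
#' @return Invisibly, `markers`.
#' @export
write_marker_tsv <- function(markers, path) {
  cols <- c("class", "gene", "log_fc", "pct_1", "pct_2", "p", "p_adj", "is_marker")
  write.table(markers[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(markers)
}
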