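#' Assign per-sex age deciles to donors and their cells
#'
#' Donors of each sex are cut into 10 groups at the empirical 10%..90%
#' quantiles of donor age (donor-level, not cell-level, so large donors do
#' not drag the boundaries). Intervals are left-open/right-closed; donors
#' with tied ages always land in the same decile, so populations can be
#' unequal under heavy ties. Every cell inherits its donor's decile.
#'
#' @param cells Per-cell data.frame with `donor_id`, `sex`, `age_years`.
#' @return A list: `cells` (input plus integer `decile` column) and `scheme`,
#'   a data.frame with one row per (sex, decile): age interval, donor count,
#'   cell count and `midpoint_age` (mean donor age in the decile).
#' @export
assign_age_deciles <- function(cells) {
  stopifnot(all(c("donor_id", "sex", "age_years") %in% names(cells)))
  cells$decile <- NA_integer_
  scheme <- list()
  for (sex in sort(unique(cells$sex))) {
    rows <- cells$sex == sex
    donors <- unique(cells[rows, c("donor_id", "age_years")])
    if (nrow(donors) < 10)
      stop("only ", nrow(donors), " donors of sex ", sex,
           "; need at least 10 for deciles (use fewer bins)")
    if (length(unique(donors$age_years)) < 10)
      stop("fewer than 10 distinct donor ages for sex ", sex,
           ": degenerate quantiles (use fewer bins)")
    breaks <- quantile(donors$age_years, probs = seq(0.1, 0.9, by = 0.1),
                       names = FALSE)
    donors$decile <- findInterval(donors$age_years, breaks, left.open = TRUE) + 1L
    cells$decile[rows] <- donors$decile[match(cells$donor_id[rows], donors$donor_id)]
    lo <- c(min(donors$age_years), breaks)
    hi <- c(breaks, max(donors$age_years))
    for (d in 1:10) {
      in_d <- donors$decile == d
      scheme[[paste(sex, d)]] <- data.frame(
        sex = sex, decile = d, age_lo = lo[d], age_hi = hi[d],
        n_donors = sum(in_d),
        n_cells = sum(rows & cells$decile == d),
        midpoint_age = if (any(in_d)) mean(donors$age_years[in_d]) else NA_real_)
    }
  }
  list(cells = cells, scheme = do.call(rbind, c(scheme, make.row.names = FALSE)))
}

#' Balanced downsampling of cells across deciles
#'
#' Within each (sex, cell_type) unit, every decile is downsampled without
#' replacement to the unit's minimum per-decile cell count, so the cell-type
#' count is identical across the deciles of each sex and marker detection has
#' equal power in every decile. Deterministic given `seed`.
#'
#' @param cells Per-cell data.frame with `sex`, `cell_type` and `decile`
#'   columns (see [assign_age_deciles()]).
#' @param seed Integer seed for the downsampling draw.
#' @return Sorted integer indices of retained cells. Units with an empty
#'   decile are dropped entirely, with a warning.
#' @export
balance_cells <- function(cells, seed = 1) {
  stopifnot(all(c("sex", "cell_type", "decile") %in% names(cells)))
  set.seed(substream_seed(seed, 4242))
  keep <- integer(0)
  for (sex in sort(unique(cells$sex))) {
    deciles <- sort(unique(cells$decile[cells$sex == sex]))
    for (ct in sort(unique(cells$cell_type[cells$sex == sex]))) {
      idx_by_d <- lapply(deciles, function(d)
        which(cells$sex == sex & cells$cell_type == ct & cells$decile == d))
      sizes <- lengths(idx_by_d)
      if (any(sizes == 0)) {
        warning("dropping unit (", sex, ", ", ct, "): empty decile(s) ",
                paste(deciles[sizes == 0], collapse = ","))
        next
      }
      m <- min(sizes)
      for (ix in idx_by_d)
        keep <- c(keep, if (length(ix) == m) ix else sort(sample(ix, m)))
    }
  }
  sort(keep)
}

#' Cell-type composition per sex decile
#'
#' Intended to run on the unbalanced cell table (before [balance_cells()]),
#' since balancing equalizes composition by construction.
#'
#' @param cells Per-cell data.frame with `sex`, `decile`, `cell_type`.
#' @return Data.frame with one row per (sex, decile, cell_type): `n` and
#'   `fraction`; fractions sum to 1 within each (sex, decile).
#' @export
composition_by_decile <- function(cells) {
  stopifnot(all(c("sex", "decile", "cell_type") %in% names(cells)))
  tab <- as.data.frame(table(sex = cells$sex, decile = cells$decile,
                             cell_type = cells$cell_type),
                       responseName = "n", stringsAsFactors = FALSE)
  tab$decile <- as.integer(tab$decile)
  tot <- stats::ave(tab$n, tab$sex, tab$decile, FUN = sum)
  tab$fraction <- ifelse(tot > 0, tab$n / tot, NA_real_)
  tab[order(tab$sex, tab$decile, tab$cell_type), , drop = FALSE]
}

#' Marker-count trajectories over age deciles
#'
#' For each sex and decile, runs [find_all_markers()] on that decile's cells
#' alone (each cell type versus all other cells of the same decile), counts
#' markers per cell type, and fits an ordinary least-squares line of marker
#' count on the decile's midpoint age. The slope (markers per year) and its
#' r-squared quantify drift of cell-type identity with age.
#'
#' @param counts A lognorm-layer [SparseCounts-class] object.
#' @param cells Per-cell data.frame with `sex`, `decile`, `cell_type`,
#'   row-aligned with `counts`; normally already balanced with
#'   [balance_cells()].
#' @param scheme Decile scheme from [assign_age_deciles()] (supplies midpoint
#'   ages).
#' @param params A [marker_params()] list.
#' @return A list: `counts` (data.frame sex, decile, midpoint_age, cell_type,
#'   n_markers) and `fits` (data.frame sex, cell_type, slope, intercept,
#'   r_squared). Deciles with fewer than two cell types are skipped with a
#'   warning.
#' @export
marker_trajectory <- function(counts, cells, scheme, params = marker_params()) {
  stopifnot(is(counts, "SparseCounts"), nrow(cells) == n_cells(counts),
            all(c("sex", "decile", "cell_type") %in% names(cells)))
  rows <- list()
  for (sex in sort(unique(cells$sex))) {
    for (d in sort(unique(cells$decile[cells$sex == sex]))) {
      idx <- which(cells$sex == sex & cells$decile == d)
      types <- unique(cells$cell_type[idx])
      if (length(types) < 2) {
        warning("skipping (", sex, ", decile ", d, "): single cell type")
        next
      }
      mk <- find_all_markers(subset_counts(counts, cells = idx),
                             cells$cell_type[idx], params = params)
      nm <- count_markers(mk)
      mid <- scheme$midpoint_age[scheme$sex == sex & scheme$decile == d]
      rows[[paste(sex, d)]] <- data.frame(
        sex = sex, decile = d, midpoint_age = mid,
        cell_type = names(nm), n_markers = as.integer(nm))
    }
  }
  counts_df <- do.call(rbind, c(rows, make.row.names = FALSE))
  fits <- list()
  for (sex in unique(counts_df$sex)) {
    for (ct in unique(counts_df$cell_type[counts_df$sex == sex])) {
      sub <- counts_df[counts_df$sex == sex & counts_df$cell_type == ct, ]
      if (nrow(sub) < 3 || length(unique(sub$midpoint_age)) < 2) next
      fit <- lm(n_markers ~ midpoint_age, data = sub)
      r2 <- if (var(sub$n_markers) > 0) summary(fit)$r.squared else 0
      fits[[paste(sex, ct)]] <- data.frame(
        sex = sex, cell_type = ct,
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        r_squared = r2)
    }
  }
  list(counts = counts_df,
       fits = do.call(rbind, c(fits, make.row.names = FALSE)))
}

#' PCA embedding on highly variable genes
#'
#' Selects the `n_var_genes` genes with highest variance of log-normalized
#' expression, centers and unit-scales each (constant genes are dropped with
#' a warning), and projects the cells onto the top principal components. The
#' sign of each component is fixed by making its largest-magnitude gene
#' loading positive, so embeddings are reproducible.
#'
#' @param counts A lognorm-layer [SparseCounts-class] object.
#' @param n_var_genes Number of variable genes to keep.
#' @param n_components Number of principal components.
#' @return A list of class `pca_embedding`: `scores` (cells x components),
#'   `loadings` (genes x components), `sdev`, `var_genes`.
#' @export
pca_embed <- function(counts, n_var_genes = 2000, n_components = 20) {
  stopifnot(is(counts, "SparseCounts"))
  m <- as_dgc(counts)
  n <- nrow(m)
  if (n < 2) stop("need at least two cells")
  n_var_genes <- min(n_var_genes, ncol(m))
  s1 <- Matrix::colSums(m)
  s2 <- Matrix::colSums(m^2)
  v <- (s2 - s1^2 / n) / (n - 1)
  sel <- order(v, decreasing = TRUE)[seq_len(n_var_genes)]
  const <- v[sel] <= .Machine$double.eps * 100
  if (any(const)) {
    warning("dropping ", sum(const), " constant gene(s) from the PCA panel")
    sel <- sel[!const]
  }
  if (length(sel) < 2) stop("fewer than two variable genes")
  n_components <- min(n_components, length(sel), n - 1)
  x <- scale(as.matrix(m[, sel, drop = FALSE]))
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    l <- pc$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  rownames(scores) <- cell_ids(counts)
  structure(list(scores = scores, loadings = loadings,
                 sdev = pc$sdev[seq_len(n_components)],
                 var_genes = gene_ids(counts)[sel]),
            class = "pca_embedding")
}

#' Mean Euclidean distance of cells to their own centroid
#'
#' @param scores A numeric matrix of embedding coordinates for the cells of
#'   one subset (rows = cells).
#' @param dims Columns (principal components) to use.
#' @return A list: `mean`, `se` (`sd/sqrt(n)`; 0 with `degenerate = TRUE`
#'   when `n = 1`), `n`, and the per-cell `distances`.
#' @export
dispersion_to_centroid <- function(scores, dims = 1:10) {
  scores <- as.matrix(scores)[, dims, drop = FALSE]
  if (nrow(scores) == 0) stop("empty subset")
  centroid <- colMeans(scores)
  d <- sqrt(rowSums(sweep(scores, 2, centroid)^2))
  list(mean = mean(d),
       se = if (length(d) > 1) sd(d) / sqrt(length(d)) else 0,
       n = length(d), degenerate = length(d) == 1, distances = d)
}

# Young/old age-group label; NA outside both windows.
age_group_of <- function(age, young_max = 40, old_min = 79) {
  ifelse(age < young_max, "young", ifelse(age > old_min, "old", NA_character_))
}

#' Within-cell-type dispersion by sex and age group
#'
#' For each (sex, age group, cell type) subset, computes the mean Euclidean
#' distance of the subset's cells to the subset centroid in PCA space --
#' the within-type transcriptome spread. Age groups follow the young/old
#' contrast: `young` = age below `young_max`, `old` = age above `old_min`;
#' cells in between are ignored.
#'
#' @param embedding A `pca_embedding` from [pca_embed()].
#' @param cells Per-cell data.frame with `sex`, `age_years`, `cell_type`,
#'   row-aligned with the embedding.
#' @param dims Principal components to use.
#' @param young_max,old_min Age cutoffs in years.
#' @param by_sex Keep sexes separate (`TRUE`) or pool them.
#' @return Data.frame with one row per subset: `sex`, `age_group`,
#'   `cell_type`, `mean_dist`, `se`, `n_cells`.
#' @export
dispersion_by_group <- function(embedding, cells, dims = 1:10,
                                young_max = 40, old_min = 79, by_sex = TRUE) {
  stopifnot(inherits(embedding, "pca_embedding"),
            nrow(cells) == nrow(embedding$scores))
  grp <- age_group_of(cells$age_years, young_max, old_min)
  sexes <- if (by_sex) sort(unique(cells$sex)) else "all"
  out <- list()
  for (sex in sexes) {
    sex_ok <- if (by_sex) cells$sex == sex else rep(TRUE, nrow(cells))
    for (ag in c("young", "old")) {
      for (ct in sort(unique(cells$cell_type))) {
        idx <- which(sex_ok & !is.na(grp) & grp == ag & cells$cell_type == ct)
        if (!length(idx)) next
        dd <- dispersion_to_centroid(embedding$scores[idx, , drop = FALSE], dims)
        out[[paste(sex, ag, ct)]] <- data.frame(
          sex = sex, age_group = ag, cell_type = ct,
          mean_dist = dd$mean, se = dd$se, n_cells = dd$n)
      }
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Distance of every cell to the global centroid across cell types
#'
#' The convergence statistic: one centroid is computed over all the group's
#' cells (all cell types together) and each cell's Euclidean distance to it
#' is summarized per cell type and overall. If cell types converge with age,
#' these distances shrink; pure within-type dispersal leaves the type
#' centroids (and hence the bulk of this distance) in place.
#'
#' @param scores Embedding coordinates of the group's cells (rows = cells).
#' @param cell_types Cell-type label per row of `scores`.
#' @param dims Principal components to use.
#' @return A list: `overall` (mean, se, n over all cells) and `per_type`
#'   data.frame (`cell_type`, `mean_dist`, `se`, `n_cells`); at least two
#'   cell types are required.
#' @export
convergence_distance <- function(scores, cell_types, dims = 1:10) {
  scores <- as.matrix(scores)[, dims, drop = FALSE]
  if (length(unique(cell_types)) < 2)
    stop("convergence distance needs at least two cell types in the group")
  centroid <- colMeans(scores)
  d <- sqrt(rowSums(sweep(scores, 2, centroid)^2))
  per_type <- do.call(rbind, lapply(sort(unique(cell_types)), function(ct) {
    di <- d[cell_types == ct]
    data.frame(cell_type = ct, mean_dist = mean(di),
               se = if (length(di) > 1) sd(di) / sqrt(length(di)) else 0,
               n_cells = length(di))
  }))
  list(overall = list(mean = mean(d),
                      se = if (length(d) > 1) sd(d) / sqrt(length(d)) else 0,
                      n = length(d)),
       per_type = per_type)
}

#' Classify an atlas into dispersion versus convergence signatures
#'
#' Contrasts young and old cells (pooling sexes) on two summaries computed in
#' PCA space: the within-type spread (mean distance of each type's cells to
#' the type centroid, [dispersion_to_centroid()]) and the between-type
#' separation (mean distance of the type centroids to the global centroid --
#' a centroid-level summary, so it does not inflate mechanically when
#' within-type noise grows). The dispersion signature is: within-type spread
#' increases with age for every type while between-type separation is stable
#' (within `tol`); the convergence signature is the reverse: between-type
#' separation drops by more than `tol` while within-type spread is stable.
#'
#' @param embedding A `pca_embedding`.
#' @param cells Per-cell data.frame with `age_years`, `cell_type`.
#' @param dims Principal components to use.
#' @param young_max,old_min Age cutoffs.
#' @param tol Relative-change tolerance defining "stable" (default 10%).
#' @return A list: `within` (data.frame cell_type, young, old, rel_change),
#'   `between` (young, old, rel_change), and `regime` in
#'   `c("dispersion", "convergence", "ambiguous")`.
#' @export
regime_signature <- function(embedding, cells, dims = 1:10,
                             young_max = 40, old_min = 79, tol = 0.10) {
  stopifnot(inherits(embedding, "pca_embedding"),
            nrow(cells) == nrow(embedding$scores))
  grp <- age_group_of(cells$age_years, young_max, old_min)
  stats_for <- function(ag) {
    idx <- which(!is.na(grp) & grp == ag)
    if (!length(idx)) stop("no cells in age group ", ag)
    sc <- embedding$scores[idx, dims, drop = FALSE]
    ct <- cells$cell_type[idx]
    types <- sort(unique(ct))
    within <- vapply(types, function(t)
      dispersion_to_centroid(sc[ct == t, , drop = FALSE], seq_along(dims))$mean,
      numeric(1))
    centroids <- t(vapply(types, function(t)
      colMeans(sc[ct == t, , drop = FALSE]), numeric(length(dims))))
    global <- colMeans(sc)
    between <- mean(sqrt(rowSums(sweep(centroids, 2, global)^2)))
    list(within = setNames(within, types), between = between)
  }
  y <- stats_for("young"); o <- stats_for("old")
  types <- intersect(names(y$within), names(o$within))
  within <- data.frame(cell_type = types,
                       young = y$within[types], old = o$within[types],
                       rel_change = o$within[types] / y$within[types] - 1,
                       row.names = NULL)
  between <- list(young = y$between, old = o$between,
                  rel_change = o$between / y$between - 1)
  regime <- "ambiguous"
  if (all(within$rel_change > 0) && abs(between$rel_change) < tol) {
    regime <- "dispersion"
  } else if (between$rel_change < -tol && all(abs(within$rel_change) < tol)) {
    regime <- "convergence"
  }
  list(within = within, between = between, regime = regime)
}

#' Per-cell aging score from a gene signature
#'
#' Two formulations are supported. `z_mean`: each signature gene's
#' log-normalized expression is Z-normalized across all cells and the
#' per-cell score is the mean over signature genes (needs the lognorm
#' layer). `umi_ratio`: the per-cell fraction of raw UMIs falling on
#' signature genes (needs the raw layer; invariant to any normalization,
#' always in `[0, 1]`). Signature genes absent from the matrix are dropped
#' with a warning; an empty intersection is an error.
#'
#' @param counts A [SparseCounts-class] object; layer must match `method`.
#' @param genes Character vector of signature gene ids (typically <= 30).
#' @param method `"z_mean"` or `"umi_ratio"`.
#' @param cells Optional per-cell data.frame (row-aligned) with `cell_type`
#'   and/or `decile` columns for group summaries.
#' @return A list: `score` (per-cell numeric, named by cell id), `genes`
#'   (the genes used), `method`, and, when `cells` is given, `by_cell_type`
#'   and `by_decile` mean-score summaries.
#' @export
aging_score <- function(counts, genes, method = c("z_mean", "umi_ratio"),
                        cells = NULL) {
  method <- match.arg(method)
  stopifnot(is(counts, "SparseCounts"))
  use <- intersect(genes, gene_ids(counts))
  if (!length(use)) stop("none of the signature genes are present in the matrix")
  if (length(use) < length(genes))
    warning("dropping ", length(genes) - length(use),
            " signature gene(s) absent from the matrix")
  m <- as_dgc(counts)
  if (method == "z_mean") {
    if (counts_layer(counts) != "lognorm")
      stop("z_mean scores are defined on the lognorm layer")
    x <- as.matrix(m[, use, drop = FALSE])
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " constant signature gene(s)")
      x <- x[, sds > 0, drop = FALSE]
      use <- use[sds > 0]
      if (!length(use)) stop("all signature genes are constant")
    }
    score <- rowMeans(scale(x))
  } else {
    if (counts_layer(counts) != "raw")
      stop("umi_ratio scores are defined on the raw layer")
    tot <- Matrix::rowSums(m)
    sig <- Matrix::rowSums(m[, use, drop = FALSE])
    score <- ifelse(tot > 0, sig / tot, 0)
  }
  score <- setNames(as.numeric(score), cell_ids(counts))
  out <- list(score = score, genes = use, method = method)
  if (!is.null(cells)) {
    stopifnot(nrow(cells) == n_cells(counts))
    if ("cell_type" %in% names(cells))
      out$by_cell_type <- stats::aggregate(
        list(mean_score = score), by = list(cell_type = cells$cell_type), FUN = mean)
    if ("decile" %in% names(cells))
      out$by_decile <- stats::aggregate(
        list(mean_score = score),
        by = list(sex = cells$sex, decile = cells$decile), FUN = mean)
  }
  out
}

#' Read or write a gene list (one symbol per line)
#'
#' @param path File path.
#' @return `read_gene_list()` returns a character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes Character vector of gene symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
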