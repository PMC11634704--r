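#' Parameterize a synthetic single-cell atlas
#'
#' The generator draws UMI counts per gene and cell from a negative binomial
#' (gamma-Poisson) law with a cell-type-specific mean and an age-scaled
#' overdispersion. Cell-type identity is carried entirely by planted marker
#' genes: each type owns `markers_per_type` disjoint genes whose mean is
#' shifted up by `marker_log2_shift` log2 units in cells of that type; all
#' other genes share one baseline profile. Three ground-truth regimes
#' realize competing hypotheses about aging:
#'
#' * `"null"` -- nothing changes with age.
#' * `"dispersion"` -- cell-intrinsic transcriptional heterogeneity grows
#'   with age. Two log-normal noise sources with `sigma^2 = log(k(age))`
#'   (`k` from `dispersion_law`; the multiplicative heterogeneity variance
#'   `e^{sigma^2}` equals `k`, and `k = 1` means no noise) are applied to
#'   the negative-binomial means: an independent log-median-1 modulation of
#'   every (cell, gene) mean, which spreads cells around their type's
#'   log-expression profile and erodes the rank-test separability of the
#'   planted markers; and per-cell activity factors on a few shared
#'   "expression programs" (fixed random subsets of non-marker genes,
#'   common to all types), which give the within-type spread the
#'   correlated low-dimensional structure that principal components pick
#'   up, while leaving relative type-centroid positions untouched.
#' * `"convergence"` -- marker shifts (the type-specific repertoire) are
#'   shrunk toward the shared baseline by `s(age)` from `convergence_law`,
#'   moving type centroids together while within-type noise stays put.
#'
#' Baseline gene means are drawn log-normally and rescaled once so the
#' expected zero fraction matches `target_sparsity` (~90% zeros, typical for
#' droplet UMI data). Per-cell library sizes vary log-normally
#' (`library_size_sigma`) so normalization and QC are exercised.
#'
#' @param n_genes Number of genes.
#' @param n_types Number of cell types (named `typeA`, `typeB`, ...).
#' @param markers_per_type Planted marker genes per type (disjoint).
#' @param marker_log2_shift Log2 mean shift (>= 0) of a type's markers in its own
#'   cells; a scalar, or a vector of length `markers_per_type` for graded
#'   marker strengths.
#' @param donors_per_sex Donors per sex.
#' @param age_range Donor ages are drawn uniformly over this range (years).
#' @param donor_ages Optional list with elements `F` and `M` of explicit
#'   donor ages, overriding `age_range`.
#' @param cells_per_donor Cells per donor.
#' @param base_mean_log_sd Log-normal sd of baseline gene means.
#' @param size0 Baseline negative-binomial size (inverse overdispersion).
#' @param dispersion_law `list(type = "constant", k = 1)` or
#'   `list(type = "linear", k_young = , k_old = )`, mapping donor age
#'   linearly over `age_range` to the heterogeneity multiplier `k`
#'   (the variance factor of the log-normal expression modulation).
#' @param regime `"null"`, `"dispersion"` or `"convergence"`.
#' @param convergence_law `list(s_young = , s_old = )`: linear-in-age
#'   shrinkage fraction of the marker shifts (0 = intact identity,
#'   1 = types fully collapsed).
#' @param composition_law Optional `function(age)` returning cell-type
#'   probabilities (length `n_types`); `NULL` = equal proportions.
#' @param library_size_sigma Log-normal sd of per-cell size factors.
#' @param target_sparsity Expected fraction of zero entries, in (0, 1).
#' @param seed Integer seed; the atlas is a deterministic function of the
#'   spec. Each donor has an independent RNG substream derived from
#'   `(seed, sex, donor index)`, so adding donors leaves existing donors'
#'   draws unchanged.
#' @return A list of class `atlas_spec`.
#' @export
atlas_spec <- function(n_genes = 2000, n_types = 3, markers_per_type = 10,
                       marker_log2_shift = 2,
                       donors_per_sex = 20, age_range = c(20, 90),
                       donor_ages = NULL, cells_per_donor = 100,
                       base_mean_log_sd = 1, size0 = 2,
                       dispersion_law = list(type = "constant", k = 1),
                       regime = c("null", "dispersion", "convergence"),
                       convergence_law = list(s_young = 0, s_old = 0.5),
                       composition_law = NULL,
                       library_size_sigma = 0.3, target_sparsity = 0.9,
                       seed = 1) {
  regime <- match.arg(regime)
  stopifnot(n_genes >= 1, n_types >= 2, markers_per_type >= 1,
            markers_per_type * n_types <= n_genes,
            length(marker_log2_shift) %in% c(1L, markers_per_type),
            all(marker_log2_shift >= 0),
            cells_per_donor >= 1, size0 > 0,
            target_sparsity > 0, target_sparsity < 1)
  structure(list(n_genes = n_genes, n_types = n_types,
                 markers_per_type = markers_per_type,
                 marker_log2_shift = marker_log2_shift,
                 donors_per_sex = donors_per_sex, age_range = age_range,
                 donor_ages = donor_ages, cells_per_donor = cells_per_donor,
                 base_mean_log_sd = base_mean_log_sd, size0 = size0,
                 dispersion_law = dispersion_law, regime = regime,
                 convergence_law = convergence_law,
                 composition_law = composition_law,
                 library_size_sigma = library_size_sigma,
                 target_sparsity = target_sparsity, seed = seed),
            class = "atlas_spec")
}

# Overdispersion multiplier k(age); only the dispersion regime departs from 1.
dispersion_at_age <- function(spec, age) {
  if (spec$regime != "dispersion") return(rep(1, length(age)))
  law <- spec$dispersion_law
  if (identical(law$type, "constant")) return(rep(law$k %||% 1, length(age)))
  frac <- (age - spec$age_range[1]) / diff(spec$age_range)
  frac <- pmin(pmax(frac, 0), 1)
  law$k_young + frac * (law$k_old - law$k_young)
}

# Marker-shift shrinkage s(age) in [0, 1); only the convergence regime moves.
shrinkage_at_age <- function(spec, age) {
  if (spec$regime != "convergence") return(rep(0, length(age)))
  law <- spec$convergence_law
  frac <- (age - spec$age_range[1]) / diff(spec$age_range)
  frac <- pmin(pmax(frac, 0), 1)
  s <- law$s_young + frac * (law$s_old - law$s_young)
  pmin(pmax(s, 0), 0.999)
}

# Derived-seed substream: deterministic, independent of draw order elsewhere.
substream_seed <- function(seed, ...) {
  key <- c(seed, ...)
  h <- 0
  for (k in key) h <- (h * 69069 + as.numeric(k)) %% 2147483647
  as.integer(h)
}

# Rescale baseline means so the expected zero fraction hits target_sparsity.
# Expectation is over genes and types at the baseline dispersion and unit
# library size; marker shifts (affecting 1/n_types of cells for each type's
# markers) are included.
calibrate_base_means <- function(spec, base_shape, shift_mat) {
  size <- spec$size0
  p0 <- function(mult) {
    mu <- base_shape * mult                       # n_genes baseline means
    mu_type <- outer(mu, rep(1, spec$n_types)) * shift_mat
    mean((size / (size + mu_type))^size)
  }
  f <- function(lmult) p0(exp(lmult)) - spec$target_sparsity
  lo <- log(1e-8); hi <- log(1e8)
  if (f(lo) < 0 || f(hi) > 0)
    stop("infeasible target_sparsity for this mean/dispersion configuration")
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Generate a synthetic sparse single-cell atlas with known ground truth
#'
#' @param spec An [atlas_spec()].
#' @return A list with `counts` (raw-layer [SparseCounts-class]),
#'   `cells` (per-cell annotation data.frame: `cell_id`, `donor_id`,
#'   `cell_type`, `age_years`, `sex`, `pct_mito`, `n_genes_detected`,
#'   `total_umi`) and `truth` (marker assignment `gene -> type`, per-marker
#'   shifts, donor table, regime parameters, calibrated gene means).
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  types <- paste0("type", LETTERS[seq_len(spec$n_types)])
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  shifts <- rep_len(spec$marker_log2_shift, spec$markers_per_type)

  # baseline gene shape and marker layout from the atlas-level stream
  set.seed(substream_seed(spec$seed, 1))
  lz <- stats::rnorm(spec$n_genes, 0, spec$base_mean_log_sd)
  marker_idx <- matrix(seq_len(spec$n_types * spec$markers_per_type),
                       nrow = spec$markers_per_type)  # disjoint blocks
  # markers live on well-expressed genes (upper quartile of the baseline
  # profile): cell-type markers are expressed genes, not dropout-dominated
  # ones, and their baseline is detectable in non-owner types too
  lz[marker_idx] <- stats::qnorm(runif(length(marker_idx), 0.75, 1)) *
    spec$base_mean_log_sd
  base_shape <- exp(lz)
  shift_mat <- matrix(1, spec$n_genes, spec$n_types)  # fold factor per (gene, type)
  for (t in seq_len(spec$n_types))
    shift_mat[marker_idx[, t], t] <- 2^shifts
  mult <- calibrate_base_means(spec, base_shape, shift_mat)
  base_mu <- base_shape * mult
  # shared expression programs: disjoint random subsets of non-marker genes
  # whose per-cell activity varies with the dispersion law; shared by all
  # types, so their noise spreads cells without moving relative centroids
  non_marker <- setdiff(seq_len(spec$n_genes), as.vector(marker_idx))
  n_prog <- 3L
  prog_pool <- sample(non_marker, min(length(non_marker),
                                      ceiling(0.6 * length(non_marker))))
  program_sets <- split(prog_pool, rep_len(seq_len(n_prog), length(prog_pool)))

  donors <- list()
  for (sex in c("F", "M")) {
    ages <- spec$donor_ages[[sex]]
    n_d <- if (is.null(ages)) spec$donors_per_sex else length(ages)
    for (d in seq_len(n_d)) {
      set.seed(substream_seed(spec$seed, match(sex, c("F", "M")), d))
      age <- if (is.null(ages))
        runif(1, spec$age_range[1], spec$age_range[2]) else ages[d]
      donors[[paste0(sex, d)]] <- list(
        donor_id = sprintf("donor_%s%02d", sex, d), sex = sex, age = age,
        seed = substream_seed(spec$seed, match(sex, c("F", "M")), d, 17))
    }
  }

  blocks <- vector("list", length(donors))
  cell_rows <- vector("list", length(donors))
  for (i in seq_along(donors)) {
    dn <- donors[[i]]
    set.seed(dn$seed)
    k <- dispersion_at_age(spec, dn$age)
    s <- shrinkage_at_age(spec, dn$age)
    probs <- if (is.null(spec$composition_law)) rep(1 / spec$n_types, spec$n_types)
             else spec$composition_law(dn$age)
    type_of <- sample.int(spec$n_types, spec$cells_per_donor, replace = TRUE,
                          prob = probs)
    lib <- rlnorm(spec$cells_per_donor, 0, spec$library_size_sigma)
    eff_shift <- shift_mat^(1 - s)            # convergence shrinks log-shifts
    mu <- outer(base_mu, lib) * eff_shift[, type_of]   # genes x cells
    if (k > 1) {
      sigma <- sqrt(log(k))   # heterogeneity variance factor e^{sigma^2} = k
      # cell-intrinsic heterogeneity: independent log-median-1 modulation of
      # every (cell, gene) mean. The log-expression profile of each type
      # stays centred while cells spread around it and rank-test
      # separability of the planted markers erodes.
      mu <- mu * exp(sigma * stats::rnorm(length(mu)))
      # program-activity heterogeneity: one mean-1 factor per (cell, program)
      # scaling that program's genes. Shared by all types, it gives the
      # within-type spread the correlated, low-dimensional structure real
      # transcriptomes show, without moving relative type centroids.
      for (ps in program_sets) {
        pf <- exp(sigma * stats::rnorm(spec$cells_per_donor) - sigma^2 / 2)
        mu[ps, ] <- mu[ps, ] * rep(pf, each = length(ps))
      }
    }
    counts <- matrix(rnbinom(length(mu), size = spec$size0, mu = mu),
                     nrow = spec$n_genes)
    blocks[[i]] <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    cell_rows[[i]] <- data.frame(
      cell_id = sprintf("%s_c%03d", dn$donor_id, seq_len(spec$cells_per_donor)),
      donor_id = dn$donor_id, cell_type = types[type_of],
      age_years = dn$age, sex = dn$sex,
      pct_mito = round(runif(spec$cells_per_donor, 0, 10), 3))
  }
  m <- do.call(cbind, blocks)                  # genes x cells
  cells <- do.call(rbind, cell_rows)
  rownames(m) <- genes
  colnames(m) <- cells$cell_id
  counts <- orient_gene_major(m, layer = "raw")
  cells <- cbind(cells, cell_qc_stats(counts))

  marker_map <- data.frame(
    gene = genes[as.vector(marker_idx)],
    cell_type = rep(types, each = spec$markers_per_type),
    log2_shift = rep(shifts, times = spec$n_types))
  truth <- list(markers = marker_map,
                donors = do.call(rbind, lapply(donors, function(d)
                  data.frame(donor_id = d$donor_id, sex = d$sex, age_years = d$age))),
                regime = spec$regime,
                dispersion_law = spec$dispersion_law,
                convergence_law = spec$convergence_law,
                base_mu = setNames(base_mu, genes),
                mean_multiplier = mult, spec = spec)
  list(counts = counts, cells = cells, truth = truth)
}

#' Generate a plain random sparse integer matrix with class labels
#'
#' Used for oracle fuzzing of the rank engine: nonzero positions are placed
#' uniformly at random, values are positive integers, labels are uniform over
#' the classes. Deterministic given `seed`.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param density Fraction of stored entries, in (0, 1].
#' @param n_classes Number of class labels.
#' @param max_count Values are uniform on `1..max_count` (small by design so
#'   ties are frequent and tie corrections are exercised).
#' @param seed Integer seed.
#' @return A list with `counts` (raw [SparseCounts-class], cells x genes) and
#'   `labels` (factor of length `n_cells`).
#' @export
generate_random_sparse <- function(n_genes, n_cells, density, n_classes = 2,
                                   max_count = 10, seed = 1) {
  stopifnot(density > 0, density <= 1, n_classes >= 1)
  set.seed(substream_seed(seed, 99))
  total <- as.numeric(n_genes) * n_cells
  if (total > .Machine$integer.max) stop("matrix too large for this generator")
  nnz <- round(density * total)
  pos <- sort(sample.int(total, nnz))
  j <- (pos - 1L) %/% n_cells + 1L          # gene index
  i <- (pos - 1L) %% n_cells + 1L           # cell index
  vals <- sample.int(max_count, nnz, replace = TRUE)
  m <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(vals),
                            dims = c(n_cells, n_genes),
                            dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                            sprintf("g%04d", seq_len(n_genes))))
  labels <- factor(sample(paste0("class", seq_len(n_classes)), n_cells,
                          replace = TRUE))
  list(counts = sparse_counts(m, layer = "raw"), labels = labels)
}
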