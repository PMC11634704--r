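# Minimal cell table builder: one row per cell, donors with given ages.
cells_from_donors <- function(ages_f, ages_m = ages_f + 0.5, cells_per_donor = 4,
                              types = c("T", "B")) {
  rows <- list()
  for (sex in c("F", "M")) {
    ages <- if (sex == "F") ages_f else ages_m
    for (d in seq_along(ages)) {
      id <- sprintf("%s%02d", sex, d)
      rows[[id]] <- data.frame(
        cell_id = sprintf("%s_c%d", id, seq_len(cells_per_donor)),
        donor_id = id, sex = sex, age_years = ages[d],
        cell_type = rep_len(types, cells_per_donor))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

test_that("age deciles split donors at per-sex age quantiles", {
  cells <- cells_from_donors(ages_f = 18:117, cells_per_donor = 2)
  dec <- assign_age_deciles(cells)
  tab <- table(unique(dec$cells[dec$cells$sex == "F",
                                c("donor_id", "decile")])$decile)
  expect_equal(unname(as.integer(tab)), rep(10, 10))  # 10 donors per decile
  # cells inherit the donor's decile
  one <- dec$cells[dec$cells$donor_id == "F01", "decile"]
  expect_equal(length(unique(one)), 1L)
  # scheme covers 20 (sex, decile) groups with midpoint ages
  expect_equal(nrow(dec$scheme), 20L)
  expect_true(all(is.finite(dec$scheme$midpoint_age)))
  expect_true(all(diff(dec$scheme$midpoint_age[dec$scheme$sex == "F"]) > 0))
})

test_that("age deciles keep tied donor ages together and reject degenerate input", {
  ages <- c(20, 25, 30, 35, rep(40, 8), 45, 50, 55, 60, 65, 70, 75, 80, 85,
            90, 95, 100, 102, 104, 106)
  cells <- cells_from_donors(ages_f = ages, ages_m = ages + 1,
                             cells_per_donor = 1)
  dec <- assign_age_deciles(cells)
  d40 <- unique(dec$cells$decile[dec$cells$sex == "F" &
                                 dec$cells$age_years == 40])
  expect_length(d40, 1)   # all tied donors share one decile

  expect_error(assign_age_deciles(cells_from_donors(rep(50, 20))),
               "distinct donor ages")
  expect_error(assign_age_deciles(cells_from_donors(c(20, 30, 40))),
               "at least 10")
})

test_that("balance_cells equalizes counts across deciles deterministically", {
  set.seed(77)
  cells <- cells_from_donors(ages_f = seq(20, 96, 4), cells_per_donor = 30)
  # thin at random so per-decile counts differ before balancing
  cells <- cells[sort(sample(nrow(cells), round(0.7 * nrow(cells)))), ]
  dec <- assign_age_deciles(cells)
  keep <- balance_cells(dec$cells, seed = 3)
  bal <- dec$cells[keep, ]
  for (sex in c("F", "M")) for (ct in c("T", "B")) {
    counts <- table(bal$decile[bal$sex == sex & bal$cell_type == ct])
    expect_equal(length(unique(as.integer(counts))), 1L)
  }
  expect_identical(balance_cells(dec$cells, seed = 3), keep)
  expect_false(identical(balance_cells(dec$cells, seed = 4), keep))
  # already balanced input is untouched
  even <- cells_from_donors(ages_f = seq(20, 96, 4), cells_per_donor = 10)
  dev <- assign_age_deciles(even)
  expect_identical(balance_cells(dev$cells, seed = 1), seq_len(nrow(even)))
})

test_that("composition fractions sum to one per (sex, decile)", {
  cells <- cells_from_donors(ages_f = seq(20, 96, 4), cells_per_donor = 8)
  dec <- assign_age_deciles(cells)
  comp <- composition_by_decile(dec$cells)
  sums <- tapply(comp$fraction, list(comp$sex, comp$decile), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(comp$fraction[comp$cell_type == "T"] == 0.5))
})

test_that("a constant response across deciles fits a flat trajectory", {
  atlas <- generate_atlas(atlas_spec(n_genes = 150, n_types = 2,
                                     markers_per_type = 6, marker_log2_shift = 2,
                                     donors_per_sex = 2, cells_per_donor = 40,
                                     seed = 9))
  ln <- log_normalize(atlas$counts)
  # the same cells replicated as all 10 deciles of one sex
  n <- n_cells(ln)
  reps <- 10
  m <- as(ln, "dgCMatrix")
  bigm <- do.call(rbind, replicate(reps, m, simplify = FALSE))
  rownames(bigm) <- sprintf("r%d_%s", rep(seq_len(reps), each = n),
                            rep(cell_ids(ln), reps))
  big <- sparse_counts(bigm, layer = "lognorm")
  cells <- data.frame(sex = "F", decile = rep(seq_len(reps), each = n),
                      cell_type = rep(atlas$cells$cell_type, reps))
  scheme <- data.frame(sex = "F", decile = 1:10, midpoint_age = seq(25, 85, length.out = 10))
  tr <- marker_trajectory(big, cells, scheme)
  per_type <- split(tr$counts$n_markers, tr$counts$cell_type)
  for (v in per_type) expect_equal(length(unique(v)), 1L)
  expect_equal(tr$fits$slope, rep(0, nrow(tr$fits)))
})

test_that("pca_embed finds exact low-rank structure deterministically", {
  # points on the line y = 2x: one component carries all variance
  xy <- cbind(seq(-2, 2, length.out = 30), 2 * seq(-2, 2, length.out = 30)) + 5
  sc <- counts_from_dense(xy, layer = "lognorm")
  emb <- pca_embed(sc, n_var_genes = 2, n_components = 2)
  expect_gt(emb$sdev[1]^2 / sum(emb$sdev^2), 1 - 1e-10)

  rl <- random_labelled(n_genes = 40, n_cells = 80, seed = 31)
  emb1 <- pca_embed(rl$lognorm, n_var_genes = 30, n_components = 5)
  # permutation equivariance
  set.seed(2); perm <- sample(80)
  emb2 <- pca_embed(subset_counts(rl$lognorm, cells = perm),
                    n_var_genes = 30, n_components = 5)
  expect_equal(unname(emb2$scores), unname(emb1$scores[perm, ]),
               tolerance = 1e-8)
  # full-rank reconstruction reproduces the scaled panel
  full <- pca_embed(rl$lognorm, n_var_genes = 10, n_components = 10)
  x <- scale(as.matrix(rl$lognorm)[, full$var_genes])
  recon <- full$scores %*% t(full$loadings)
  expect_equal(unname(recon), unname(x[, ]), tolerance = 1e-8)
})

test_that("distance-to-centroid summaries obey exact geometry", {
  same <- matrix(3, nrow = 5, ncol = 2)
  expect_equal(dispersion_to_centroid(same, dims = 1:2)$mean, 0)
  two <- rbind(c(1, 0), c(-1, 0))
  d2 <- dispersion_to_centroid(two, dims = 1:2)
  expect_equal(d2$mean, 1)
  expect_equal(dispersion_to_centroid(2 * two, dims = 1:2)$mean, 2)
  one <- dispersion_to_centroid(matrix(1:2, 1), dims = 1:2)
  expect_true(one$degenerate)
  expect_equal(one$se, 0)

  # two equal-size types at +-d: each type's mean distance to the global
  # centroid is d
  emb <- rbind(matrix(rep(c(4, 0), 10), ncol = 2, byrow = TRUE),
               matrix(rep(c(-4, 0), 10), ncol = 2, byrow = TRUE))
  cv <- convergence_distance(emb, rep(c("x", "y"), each = 10), dims = 1:2)
  expect_equal(cv$per_type$mean_dist, c(4, 4))
  expect_equal(cv$overall$mean, 4)
  expect_error(convergence_distance(emb, rep("x", 20), dims = 1:2),
               "two cell types")
})

test_that("aging scores follow both stated formulations", {
  raw <- counts_from_dense(rbind(c(5, 5, 0), c(0, 4, 4), c(2, 0, 2)))
  colnames(raw) <- c("sig1", "sig2", "other")
  # umi_ratio: all-in-list and none-in-list extremes
  sc <- aging_score(raw, c("sig1", "sig2"), method = "umi_ratio")
  expect_equal(unname(sc$score[1]), 1)
  expect_equal(unname(sc$score[2]), 0.5)
  expect_true(all(sc$score >= 0 & sc$score <= 1))

  # z_mean: a cell sitting at every signature gene's mean scores 0
  ln <- counts_from_dense(rbind(c(1, 2), c(3, 4), c(2, 3)), layer = "lognorm")
  colnames(ln) <- c("a", "b")
  z <- aging_score(ln, c("a", "b"), method = "z_mean")
  expect_equal(unname(z$score[3]), 0)

  expect_warning(aging_score(ln, c("a", "nope"), method = "z_mean"), "absent")
  expect_error(aging_score(ln, "nope", method = "z_mean"), "none of the")
  expect_error(aging_score(ln, "a", method = "umi_ratio"), "raw layer")
})

test_that("group summaries follow the cell table", {
  rl <- random_labelled(n_genes = 30, n_cells = 60, seed = 44)
  cells <- data.frame(sex = rep(c("F", "M"), 30),
                      cell_type = rep(c("T", "B", "NK"), 20),
                      decile = rep(1:5, 12))
  sc <- aging_score(rl$lognorm, gene_ids(rl$lognorm)[1:5], method = "z_mean",
                    cells = cells)
  expect_equal(sort(sc$by_cell_type$cell_type), sort(unique(cells$cell_type)))
  expect_equal(nrow(sc$by_decile), 10)
  manual <- mean(sc$score[cells$cell_type == "T"])
  expect_equal(sc$by_cell_type$mean_score[sc$by_cell_type$cell_type == "T"],
               manual)
})
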