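# Accumulation profiles, differential calling, clustering and PCA.

toy_im <- function(values, meta) {
  structure(list(values = values, meta = meta), class = "intensity_matrix")
}

sim_im <- function(scenario = "null", seed = 1, bio_sd = 0.5,
                   tech_sd = 0.15, injections = 3L) {
  lib <- test_lib()
  design <- study_design(injections = injections)
  truth <- simulation_truth(lib, scenario = scenario, bio_sd = bio_sd,
                            tech_sd = tech_sd)
  generate_intensities(design, truth, seed = seed)
}

test_that("family percentages sum to 100 and recover generator targets", {
  lib <- test_lib()
  # two compounds, equal intensity, two families -> 50/50
  m <- matrix(c(5, 5, 5, 5), 2, 2,
              dimnames = list(c("s1", "s2"), c("Daidzein", "Tricin Glc I")))
  meta <- data.frame(sample_id = c("s1", "s2"), cultivar = "LR1",
                     tissue = "leaf", treatment = "control",
                     replicate = 1:2)
  fam <- family_relative_abundance(toy_im(m, meta), lib)
  expect_equal(fam$pct[fam$family == "flavone"], 50)
  expect_equal(fam$pct[fam$family == "isoflavone"], 50)

  # noise-free simulated matrix inverts to the configured shares
  truth <- simulation_truth(lib, bio_sd = 0, tech_sd = 0)
  im <- generate_intensities(study_design(injections = 1), truth, seed = 1)
  fam <- family_relative_abundance(im, lib)
  leaf <- fam[fam$tissue == "leaf" & fam$cultivar == "LR2", ]
  expect_equal(leaf$pct[leaf$family == "flavone"], 85, tolerance = 1e-9)
  expect_equal(tapply(fam$pct, paste(fam$tissue, fam$cultivar), sum),
               rep(100, 8), tolerance = 1e-9, ignore_attr = TRUE)
  root <- fam[fam$tissue == "root" & fam$cultivar == "LR1", ]
  expect_equal(root$pct[root$family == "isoflavone"], 82, tolerance = 1e-9)
})

test_that("glyco profile recovers the aglycone share and sums to 100", {
  lib <- test_lib()
  truth <- simulation_truth(lib, bio_sd = 0, tech_sd = 0)
  im <- generate_intensities(study_design(injections = 1), truth, seed = 1)
  gp <- glyco_profile(im, lib)
  root <- gp[gp$tissue == "root" & gp$cultivar == "LR3", ]
  expect_equal(root$pct[root$glyco_class == "Agly"], 50, tolerance = 1e-9)
  expect_equal(tapply(gp$pct, paste(gp$tissue, gp$cultivar), sum),
               rep(100, 8), tolerance = 1e-9, ignore_attr = TRUE)
  acy <- attr(gp, "acylated_pct")
  expect_true(all(acy$pct > 0 & acy$pct < 100))

  # all-aglycone matrix: Agly is everything
  m <- matrix(c(3, 4), 2, 1, dimnames = list(c("s1", "s2"), "Daidzein"))
  meta <- data.frame(sample_id = c("s1", "s2"), cultivar = "LR1",
                     tissue = "root", treatment = "control", replicate = 1:2)
  gp1 <- glyco_profile(toy_im(m, meta), lib)
  expect_equal(gp1$pct[gp1$glyco_class == "Agly"], 100)
})

test_that("leaf/root ratios reproduce the configured tolerance ordering", {
  lib <- test_lib()
  truth <- simulation_truth(lib, bio_sd = 0, tech_sd = 0)
  im <- generate_intensities(study_design(injections = 1), truth, seed = 1)
  lr <- leaf_root_ratio(im)
  expect_equal(unname(lr["LR1"]), 4.6, tolerance = 1e-9)
  expect_equal(unname(lr["LR4"]), 16.0, tolerance = 1e-9)
  expect_true(all(diff(lr[c("LR1", "LR2", "LR3", "LR4")]) > 0))

  # identical tissues -> ratio 1
  m <- matrix(2, 2, 1, dimnames = list(c("a", "b"), "Daidzein"))
  meta <- data.frame(sample_id = c("a", "b"), cultivar = "LR1",
                     tissue = c("leaf", "root"), treatment = "control",
                     replicate = 1)
  expect_equal(unname(leaf_root_ratio(toy_im(m, meta))), 1)
})

test_that("the log2 threshold is derived from the linear cutoff", {
  expect_equal(round(log2_fc_threshold(2.5), 4), 1.3219)
  expect_equal(round(log2_fc_threshold(2.5), 1), 1.3)
  expect_equal(log2_fc_threshold(0.4), -log2_fc_threshold(2.5))
})

test_that("differential_test recovers exact effects in the noise-free limit", {
  im <- sim_im("hg", bio_sd = 0, tech_sd = 0, injections = 1)
  res <- differential_test(im, "leaf", "LR1")
  expect_identical(nrow(res), 46L)
  dz <- res[res$compound == "Daidzein", ]
  expect_equal(dz$log2fc, 2.6, tolerance = 1e-9)
  expect_equal(dz$fc, 2^2.6, tolerance = 1e-9)
  # identical arms: fc 1, unchanged
  nul <- res[res$compound == "Tricin Glc I", ]
  expect_equal(nul$fc, 1, tolerance = 1e-12)
  expect_identical(nul$regulation, "unchanged")
  # fc/log2fc identity holds across the table
  expect_equal(res$log2fc, log2(res$fc))
})

test_that("regulation flags re-derive from the printed thresholds", {
  im <- sim_im("hg", seed = 42)
  res <- differential_test(im, "root", "LR2")
  redo <- ifelse(res$fc > 2.5 & res$p_value < 0.05, "up",
          ifelse(res$fc < 0.4 & res$p_value < 0.05, "down", "unchanged"))
  expect_identical(res$regulation, redo)
  expect_error(differential_test(im, "root", "nope"), "replicates")
})

test_that("effects are recovered and type-I error is controlled", {
  # scaled-down recovery study: 60 seeded simulations of one tissue x
  # cultivar cell (the full 200-seed version runs in the acceptance suite)
  lib <- test_lib()
  truth <- simulation_truth(lib, scenario = "hg")
  design <- study_design(cultivars = "LR2", tissues = "root")
  g <- truth$grid
  eff <- g[g$tissue == "root" & g$cultivar == "LR2", ]
  strong <- eff$compound[eff$effect_log2fc >= 1.5]
  null_cp <- eff$compound[eff$effect_log2fc == 0]
  est <- matrix(NA_real_, 60, 46,
                dimnames = list(NULL, eff$compound))
  pvals <- est
  for (s in 1:60) {
    im <- generate_intensities(design, truth, seed = 1000 + s)
    res <- differential_test(im, "root", "LR2")
    est[s, res$compound] <- res$log2fc
    pvals[s, res$compound] <- res$p_value
  }
  bias <- colMeans(est)[eff$compound] - eff$effect_log2fc
  expect_lt(max(abs(bias[strong])), 0.2)
  # directional correctness for strong effects
  expect_gte(mean(est[, strong] > 0), 0.95)
  # raw p < 0.05 rate on true nulls
  t1 <- mean(pvals[, null_cp] < 0.05)
  expect_gt(t1, 0.02)
  expect_lt(t1, 0.09)
})

test_that("hierarchical clustering uses Pearson distance, complete linkage", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  cl <- hierarchical_cluster(x)
  h <- cl$hclust
  # identical-profile rows merge at distance 0 (r = 1)
  expect_equal(min(h$height), 0, tolerance = 1e-12)
  # perfectly anti-correlated rows sit at distance 2
  expect_equal(max(h$height), 2, tolerance = 1e-12)
  expect_identical(length(h$height), nrow(x) - 1L)

  # zero-variance rows are excluded with a warning
  y <- rbind(x, flat = c(1, 1, 1, 1))
  expect_warning(cl2 <- hierarchical_cluster(y), "zero-variance")
  expect_identical(cl2$dropped, "flat")

  # leaf and root samples split at the top level
  lib <- test_lib()
  truth <- simulation_truth(lib, bio_sd = 0.3, tech_sd = 0.1)
  im <- generate_intensities(study_design(injections = 1), truth, seed = 3)
  cl3 <- hierarchical_cluster(log2(im$values))
  grp <- stats::cutree(cl3$hclust, k = 2)
  leaf_grp <- unique(grp[im$meta$tissue == "leaf"])
  root_grp <- unique(grp[im$meta$tissue == "root"])
  expect_identical(length(leaf_grp), 1L)
  expect_identical(length(root_grp), 1L)
  expect_false(leaf_grp == root_grp)

  nwk <- cluster_newick(cl)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("autoscaled PCA matches the SVD oracle and its invariants", {
  set.seed(21)
  x <- matrix(rnorm(15 * 8), 15, 8,
              dimnames = list(paste0("s", 1:15), paste0("v", 1:8)))
  p <- pca_autoscaled(x)
  # autoscaling: column means 0, SD 1
  expect_equal(colMeans(p$scaled), rep(0, 8), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply(p$scaled, 2, sd), rep(1, 8), tolerance = 1e-9,
               ignore_attr = TRUE)
  # independent oracle: explained variance from a fresh decomposition
  xs <- scale(x)
  ev_oracle <- svd(xs)$d^2 / sum(svd(xs)$d^2)
  expect_equal(p$explained_variance, ev_oracle[seq_along(p$explained_variance)],
               tolerance = 1e-9)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-9)
  # scores x loadings' reconstructs the autoscaled data
  expect_equal(p$scores %*% t(p$loadings), unclass(xs), tolerance = 1e-9,
               ignore_attr = TRUE)
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("rank-1 data put all variance on PC1 and degenerate input errors", {
  u <- 1:6
  x <- cbind(a = u, b = 2 * u, c = -u)
  p <- pca_autoscaled(x)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)
  expect_warning(p2 <- pca_autoscaled(cbind(x, flat = rep(1, 6))),
                 "zero-variance")
  expect_identical(p2$dropped, "flat")
  expect_error(pca_autoscaled(x[, 1, drop = FALSE]), ">= 2")
})
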