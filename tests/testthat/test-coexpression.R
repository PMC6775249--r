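test_that("MAD filter drops exactly the non-varying features", {
  set.seed(1)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  expect_equal(mad_filter(x)$n_dropped, 0)
  x[c(3, 8, 15), ] <- 7  # constant rows, MAD = 0
  flt <- mad_filter(x)
  expect_equal(flt$n_dropped, 3)
  expect_setequal(flt$dropped, c("f3", "f8", "f15"))
  expect_error(mad_filter(matrix(1, 4, 5)), "all features")
})

test_that("scale-free fit index is exact on a constructed power law", {
  # connectivities placed at bin centers with frequency proportional to 1/k:
  # log10(freq) vs log10(k) is exactly linear with slope -1
  k <- rep(c(1, 2, 4, 8), times = c(64, 32, 16, 8))
  fit <- suppressWarnings(sncpipe:::scale_free_index(k, n_bins = 10))
  expect_equal(unname(fit["rsq"]), 1, tolerance = 1e-12)
  expect_equal(unname(fit["slope"]), -1, tolerance = 1e-12)
  # beta = 0 degenerates to constant connectivity -> NA
  set.seed(2)
  x <- matrix(rnorm(600), 30, 20)
  s0 <- scale_free_fit(x, powers = 0)
  expect_true(is.na(s0$rsq))
  # mean connectivity decreases in beta
  sc <- scale_free_fit(x, powers = c(1, 2, 4, 6, 8))
  expect_true(all(diff(sc$mean_k) < 0))
  expect_error(scale_free_fit(x[1:10, ], powers = 6), "20 features")
})

test_that("TOM matches the brute-force oracle and its edge cases", {
  # two perfectly adjacent nodes
  A2 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(tom_from_adjacency(A2)[1, 2], 1)
  # empty network
  A0 <- diag(4)
  expect_true(all(tom_from_adjacency(A0)[upper.tri(A0)] == 0))
  # random network vs triple loop
  set.seed(4)
  r <- matrix(runif(100), 10, 10)
  A <- (r + t(r)) / 2
  diag(A) <- 1
  expect_lt(max(abs(tom_from_adjacency(A) - tom_oracle(A))), 1e-10)
  expect_error(tom_from_adjacency(matrix(runif(9), 3, 3)), "symmetric")
  # range invariants
  tom <- tom_from_adjacency(A)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_true(isSymmetric(tom))
  expect_true(all(diag(tom) == 1))
})

test_that("branch cutting recovers planted modules and rejects bad input", {
  md <- simulate_module_data(sim_config(seed = 11, n_samples_per_group = 10))
  A <- adjacency_matrix(md$matrix)
  tom <- tom_from_adjacency(A)
  mods <- cluster_and_cut(1 - tom)
  expect_s3_class(mods, "snc_modules")
  non_grey <- setdiff(unique(mods$labels), "grey")
  expect_equal(length(non_grey), 3)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(mods$labels, md$truth$module)
  expect_gte(ari, 0.8)
  expect_error(cluster_and_cut(1 - tom, deep_split = 7), "0..4")
  # minimum module size larger than the feature count: everything grey
  all_grey <- cluster_and_cut(1 - tom, min_module_size = nrow(tom) + 1)
  expect_true(all(all_grey$labels == "grey"))
})

test_that("module labels are invariant to feature input order", {
  skip_if_not_installed("mclust")
  md <- simulate_module_data(sim_config(seed = 12, n_samples_per_group = 10,
                                        n_module_features = 100))
  tom <- tom_from_adjacency(adjacency_matrix(md$matrix))
  m1 <- cluster_and_cut(1 - tom)
  set.seed(1)
  perm <- sample(nrow(tom))
  m2 <- cluster_and_cut((1 - tom)[perm, perm])
  expect_equal(mclust::adjustedRandIndex(m1$labels[perm], m2$labels), 1)
})

test_that("eigengenes summarize modules with the documented orientation", {
  set.seed(21)
  n <- 12
  v <- rnorm(n)
  # module of identical profiles: variance explained 1, eigengene ~ profile
  x <- matrix(rep(v, each = 5), 5, n,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:n)))
  labs <- setNames(rep("blue", 5), rownames(x))
  eg <- module_eigengenes(x, labs)
  expect_equal(eg$var_explained[["blue"]], 1)
  expect_equal(abs(cor(eg$eigengenes[, "blue"], v)), 1, tolerance = 1e-9)
  # orientation: mean correlation with members is nonnegative
  expect_gte(mean(cor(eg$eigengenes[, "blue"], t(x))), 0)
  # flipping all member signs leaves the eigengene equal up to orientation
  eg2 <- module_eigengenes(-x, labs)
  expect_equal(abs(cor(eg$eigengenes[, "blue"], eg2$eigengenes[, "blue"])),
               1, tolerance = 1e-9)
  # latent-factor module at moderate noise: eigengene tracks the factor
  fac <- rnorm(20)
  xm <- t(sapply(1:30, function(i) fac + rnorm(20, 0, 0.3)))
  rownames(xm) <- paste0("g", 1:30)
  eg3 <- module_eigengenes(xm, setNames(rep("red", 30), rownames(xm)))
  expect_gte(abs(cor(eg3$eigengenes[, "red"], fac)), 0.95)
  expect_warning(module_eigengenes(xm[1, , drop = FALSE],
                                   setNames("red", "g1")), "single")
})

test_that("module membership and gene significance match their definitions", {
  md <- simulate_module_data(sim_config(seed = 31, n_samples_per_group = 8))
  x <- md$matrix
  tom <- tom_from_adjacency(adjacency_matrix(x))
  mods <- cluster_and_cut(1 - tom)
  eg <- module_eigengenes(x, mods)
  # plant a feature equal to an eigengene and one equal to the trait
  mod1 <- colnames(eg$eigengenes)[1]
  x2 <- rbind(x, as_eigengene = eg$eigengenes[, mod1], as_trait = md$trait)
  st <- membership_and_significance(x2, eg, md$trait)
  expect_equal(unname(st$mm["as_eigengene", mod1]), 1, tolerance = 1e-9)
  expect_equal(unname(st$gs["as_trait"]), 1, tolerance = 1e-9)
  expect_true(all(abs(st$mm) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(st$gs >= 0 & st$gs <= 1, na.rm = TRUE))
  # balanced orthogonal construction: GS = 0
  ortho <- rep(c(1, -1), length.out = ncol(x))[order(md$trait)]
  x3 <- rbind(x, ortho = ortho)
  st3 <- membership_and_significance(x3, eg, md$trait)
  expect_equal(unname(st3$gs["ortho"]), 0, tolerance = 1e-9)
  # zero-variance feature flagged as NA
  x4 <- rbind(x, flat = rep(1, ncol(x)))
  st4 <- membership_and_significance(x4, eg, md$trait)
  expect_true(is.na(st4$gs["flat"]))
})

test_that("module-trait statistics single out the trait-linked module", {
  md <- simulate_module_data(sim_config(seed = 41, n_samples_per_group = 10))
  res <- run_coexpression(md$matrix, md$trait)
  mt <- res$module_trait
  # the module recovering the trait-linked planted set attains max |r|
  best <- mt$module[which.max(abs(mt$r))]
  truth_mod <- md$truth$module[match(names(res$modules$labels),
                                     md$truth$feature)]
  planted_trait_members <- names(res$modules$labels)[truth_mod == "M1"]
  best_members <- names(res$modules$labels)[res$modules$labels == best]
  expect_gt(length(intersect(best_members, planted_trait_members)) /
              length(planted_trait_members), 0.8)
  expect_lt(mt$p[mt$module == best], 1e-4)
  # eigengene equal to the trait: r = 1, tiny p
  eg_t <- matrix(scale(md$trait), ncol = 1,
                 dimnames = list(colnames(md$matrix), "traitmod"))
  mt2 <- module_trait_stats(eg_t, md$trait)
  expect_equal(mt2$r, 1, tolerance = 1e-9)
  expect_lt(mt2$p, 1e-6)
  expect_error(module_trait_stats(eg_t, rep(1, nrow(eg_t))), "constant")
})

test_that("permuted traits rarely produce significant modules", {
  md <- simulate_module_data(sim_config(seed = 51, n_samples_per_group = 10))
  res <- run_coexpression(md$matrix, md$trait)
  eg <- res$eigengenes$eigengenes
  set.seed(99)
  clean <- vapply(1:200, function(i) {
    tr <- sample(md$trait)
    mt <- module_trait_stats(eg, tr)
    all(mt$p >= 0.01)
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("MM-GS scatter statistics flag trait-linked modules", {
  md <- simulate_module_data(sim_config(seed = 61, n_samples_per_group = 10))
  res <- run_coexpression(md$matrix, md$trait, classes = md$truth$class)
  mt <- res$module_trait
  best <- mt$module[which.max(abs(mt$r))]
  sc <- mm_gs_scatter_stats(res$stats, res$modules, best,
                            classes = res$classes)
  expect_gt(sc$r, 0)
  expect_lt(sc$p, 0.05)
  expect_true(all(!grepl("^mir", sc$non_mirna_members)))
  # GS == MM by construction gives r = 1
  st_fake <- list(mm = matrix(seq(0.1, 0.9, length.out = 5), 5, 1,
                              dimnames = list(paste0("f", 1:5), "m")),
                  gs = setNames(seq(0.1, 0.9, length.out = 5),
                                paste0("f", 1:5)))
  labs <- setNames(rep("m", 5), paste0("f", 1:5))
  expect_equal(mm_gs_scatter_stats(st_fake, labs, "m")$r, 1)
  expect_error(mm_gs_scatter_stats(st_fake, labs[1:2], "m"), "at least 3")
})
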