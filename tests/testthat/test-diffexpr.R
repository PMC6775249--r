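test_that("TMM factors behave on canonical cases", {
  set.seed(1)
  y <- matrix(rnbinom(2000, mu = 50, size = 5), ncol = 2)
  # identical columns
  expect_equal(unname(tmm_factors(cbind(y[, 1], y[, 1]))), c(1, 1))
  # pure depth difference: all M-values zero, handled by library size
  expect_equal(unname(tmm_factors(cbind(y[, 1], 2L * y[, 1]))), c(1, 1))
  # geometric mean one on arbitrary input
  y3 <- matrix(rnbinom(3000, mu = 30, size = 2), ncol = 3)
  f <- tmm_factors(y3)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  expect_error(tmm_factors(cbind(y[, 1], 0L * y[, 1])), "all-zero")
})

test_that("TMM corrects composition bias", {
  # 30% of genes 8-fold up in sample 2 only; abundances are drawn at the
  # scale of well-expressed fragment features (hundreds to thousands of
  # counts), where the composition shift dominates counting noise. After
  # normalization the median M-value of unchanged genes should sit at zero.
  set.seed(42)
  G <- 5000
  mu <- rlnorm(G, 7, 1)
  de <- seq_len(0.3 * G)
  mu2 <- mu
  mu2[de] <- mu2[de] * 8
  y <- cbind(rpois(G, mu), rpois(G, mu2))
  libs <- colSums(y)
  f <- tmm_factors(y, libs)
  eff <- libs * f
  keep <- !(seq_len(G) %in% de) & y[, 1] > 0 & y[, 2] > 0
  M <- log2((y[keep, 2] / eff[2]) / (y[keep, 1] / eff[1]))
  expect_lt(abs(median(M)), 0.05)
  # and the factors agree with the reference TMM implementation
  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(edgeR::DGEList(counts = y),
                               method = "TMM")$samples$norm.factors
  expect_equal(unname(f), fe, tolerance = 1e-3)
})

test_that("average CPM matches its definition", {
  # single sample, prior 0: plain CPM
  expect_equal(unname(average_cpm(matrix(100), lib_sizes = 1e6,
                                  prior_count = 0)), 100)
  # all-zero counts with a prior: equal positive floor
  z <- average_cpm(matrix(0, 5, 3), lib_sizes = rep(1e6, 3), prior_count = 2)
  expect_true(all(z > 0))
  expect_equal(max(z) - min(z), 0)
  # random matrix equals a direct per-sample recomputation
  set.seed(7)
  y <- matrix(rpois(60, 40), 20, 3)
  libs <- colSums(y)
  f <- tmm_factors(y, libs)
  got <- average_cpm(y, f, libs, prior_count = 2)
  eff <- libs * f
  pr <- 2 * eff / mean(eff)
  manual <- 2^rowMeans(sapply(1:3, function(j) {
    log2((y[, j] + pr[j]) / (eff[j] + 2 * pr[j]) * 1e6)
  }))
  expect_equal(unname(got), unname(manual))
})

test_that("dispersion estimation recovers the generating value", {
  grp <- factor(rep(c("a", "b"), each = 5))
  # Poisson data: common dispersion collapses toward zero
  cs0 <- simulate_counts(sim_config(seed = 71, n_features = 2000,
                                    dispersion = 0, de_fraction = 0))
  d0 <- estimate_dispersion(cs0$counts, grp)
  expect_lt(d0$common, 0.01)
  # NB phi = 0.1
  cs1 <- simulate_counts(sim_config(seed = 72, n_features = 2000,
                                    dispersion = 0.1, de_fraction = 0))
  d1 <- estimate_dispersion(cs1$counts, grp)
  expect_gt(d1$common, 0.07)
  expect_lt(d1$common, 0.13)
  expect_equal(d1$bcv, sqrt(d1$common))
  # infinite prior: tagwise collapses onto common
  d2 <- estimate_dispersion(cs1$counts[1:200, ], grp, prior_df = 1e9)
  expect_true(all(abs(d2$tagwise - d2$common) < 1e-12))
  # moderate prior: tagwise spread shrinks toward common but is not constant
  d3 <- estimate_dispersion(cs1$counts[1:200, ], grp, prior_df = 10)
  expect_gt(sd(d3$tagwise), 0)
})

test_that("exact test agrees with independent enumeration on small counts", {
  grp <- factor(rep(c("a", "b"), each = 3))
  set.seed(11)
  for (phi in c(0, 0.05, 0.2)) {
    y <- matrix(rnbinom(120, mu = 4, size = 2), 20, 6)
    res <- exact_test(y, grp, rep(phi, 20), factors = rep(1, 6),
                      lib_sizes = rep(1000, 6))
    Nbar <- 1000
    for (g in 1:20) {
      s1 <- sum(y[g, 1:3])
      s2 <- sum(y[g, 4:6])
      expect_equal(res$p[g], exact_test_oracle(s1, s2, 3, 3, phi),
                   tolerance = 1e-10)
    }
  }
})

test_that("exact test edge cases and invariances hold", {
  grp <- factor(rep(c("a", "b"), each = 2))
  # symmetric split with equal library sizes: p = 1
  y <- matrix(c(5L, 5L, 5L, 5L), 1, 4)
  res <- exact_test(y, grp, 0.1, factors = rep(1, 4), lib_sizes = rep(1e4, 4))
  expect_equal(res$p, 1)
  # zero-total feature: p = 1 by convention
  y0 <- matrix(0L, 1, 4)
  expect_equal(exact_test(y0, grp, 0.1, factors = rep(1, 4),
                          lib_sizes = rep(1e4, 4))$p, 1)
  # label swap leaves p unchanged, flips log2FC
  set.seed(3)
  y2 <- matrix(rnbinom(40, mu = 20, size = 5), 10, 4)
  libs <- rep(5e3, 4)
  a <- exact_test(y2, grp, 0.1, rep(1, 4), libs)
  b <- exact_test(y2, factor(grp, levels = rev(levels(grp))), 0.1,
                  rep(1, 4), libs)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  # uniform depth rescaling leaves log2FC unchanged
  c3 <- exact_test(3L * y2, grp, 0.1, rep(1, 4), 3 * libs)
  expect_equal(a$log2fc, c3$log2fc, tolerance = 1e-9)
})

test_that("paired LRT recognizes a null feature and rejects bad designs", {
  groups <- factor(rep(c("n", "t"), times = 4))
  blocks <- factor(rep(paste0("P", 1:4), each = 2))
  # identical counts within every patient: no condition effect
  y <- matrix(rep(c(10L, 10L, 40L, 40L, 25L, 25L, 14L, 14L), each = 3),
              nrow = 3, byrow = FALSE)
  res <- paired_lrt(y, groups, blocks, rep(0.05, 3),
                    factors = rep(1, 8), lib_sizes = rep(1e4, 8))
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-6)
  expect_true(all(res$p > 0.999))
  # incomplete blocks rejected
  expect_error(paired_lrt(y[, -1], groups[-1], blocks[-1], rep(0.05, 3)),
               "incomplete")
})

test_that("BH adjustment equals the step-up oracle and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(5)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # invariant to input order
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("DE tables use the signed display fold-change convention", {
  tst <- data.frame(feature = c("a", "b", "c"),
                    p = c(0.01, 0.5, 0.2),
                    log2fc = c(2, -log2(6.1), 0))
  y <- matrix(50L, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  tab <- de_table(tst, y)
  expect_equal(tab$fc_display[tab$feature == "a"], 4)
  expect_equal(tab$fc_display[tab$feature == "b"], -6.1)
  expect_equal(tab$fc_display[tab$feature == "c"], 1)
  expect_true(all(diff(tab$p) >= 0))
  # significance filtering
  tab$fdr <- c(0.01, 0.2, 1)
  expect_equal(significant_set(tab, 0.05)$feature, "a")
  expect_equal(nrow(significant_set(tab, 1.0001)), 3)
  tab$fdr <- rep(1, 3)
  expect_equal(nrow(significant_set(tab)), 0)
})

test_that("MDS distances and embedding match a hand-computed 3-point case", {
  # duplicated sample: zero distance, identical coordinates
  set.seed(9)
  y <- matrix(rpois(300, 60), 100, 3)
  y <- cbind(y, y[, 3])
  mds <- mds_coordinates(y, top_n = 100)
  expect_equal(mds$dist[3, 4], 0)
  expect_equal(mds$coords[3, ], mds$coords[4, ], tolerance = 1e-9)
  # 3 samples, 2 features: distances computable by hand, classical scaling
  # cross-checked with an independent double-centering eigendecomposition
  y2 <- matrix(c(100L, 100L,
                 400L, 100L,
                 100L, 400L), nrow = 2)
  expect_warning(m3 <- mds_coordinates(y2, top_n = 5, prior_count = 0,
                                       lib_sizes = rep(1e6, 3),
                                       factors = rep(1, 3)), "clamped")
  lc <- log2(y2 / 1e6 * 1e6)
  dhand <- function(i, j) sqrt(mean((lc[, i] - lc[, j])^2))
  expect_equal(m3$dist[1, 2], dhand(1, 2))
  expect_equal(m3$dist[2, 3], dhand(2, 3))
  D2 <- m3$dist^2
  J <- diag(3) - matrix(1 / 3, 3, 3)
  B <- -0.5 * J %*% D2 %*% J
  ev <- eigen(B, symmetric = TRUE)
  pts <- ev$vectors[, 1:2] %*% diag(sqrt(pmax(ev$values[1:2], 0)))
  expect_equal(abs(unname(m3$coords)), abs(pts), tolerance = 1e-8)
  # two separated groups split along dimension 1
  cs <- simulate_counts(sim_config(seed = 77, n_features = 500,
                                   de_fraction = 0.3, de_fold = 8))
  mg <- mds_coordinates(cs$counts)
  d1 <- mg$coords[, 1]
  expect_true(all(d1[cs$groups == "case"] > 0) ==
                all(d1[cs$groups == "control"] < 0) ||
              all(d1[cs$groups == "case"] < 0) ==
                all(d1[cs$groups == "control"] > 0))
  side <- d1 > 0
  expect_true(all(side[cs$groups == "case"]) && !any(side[cs$groups == "control"]) ||
              !any(side[cs$groups == "case"]) && all(side[cs$groups == "control"]))
})

test_that("exact test cross-checks against an established NB implementation", {
  skip_if_not_installed("edgeR")
  cs <- simulate_counts(sim_config(seed = 88, n_features = 300))
  y <- cs$counts
  grp <- cs$groups
  phi <- 0.1
  lib <- colSums(y)
  ours <- exact_test(y, grp, phi, factors = rep(1, ncol(y)), lib_sizes = lib)
  d <- edgeR::DGEList(counts = y, group = grp)
  d$samples$norm.factors <- 1
  et <- edgeR::exactTest(d, dispersion = phi)
  # method conventions differ in detail (pseudo-count equalization,
  # two-sided rule), so agreement is checked on the p-value scale rank-wise
  # and for order-of-magnitude correspondence on clearly DE features
  expect_gt(cor(-log10(ours$p), -log10(et$table$PValue), method = "spearman"),
            0.98)
  strong <- et$table$PValue < 1e-6
  expect_true(all(ours$p[strong] < 1e-3))
})
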