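#' Trimmed mean of M-values normalization factors
#'
#' Between-sample normalization correcting RNA composition bias. The
#' reference sample is the column whose upper-quartile CPM is closest to the
#' mean of upper quartiles. For each sample, genes expressed in both sample
#' and reference contribute an M-value (log2 ratio of proportions) and an
#' A-value (average log2 proportion); after trimming `trimM` of the M
#' distribution and `trimA` of the A distribution from each tail, the factor
#' is two to the precision-weighted mean of the remaining M-values. Factors
#' are rescaled to geometric mean one.
#'
#' @param counts features x samples nonnegative integer matrix.
#' @param lib_sizes optional library sizes (default column sums).
#' @param trimM proportion of M-values trimmed from each tail (default 0.3).
#' @param trimA proportion of A-values trimmed from each tail (default 0.05).
#' @return numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, trimM = 0.3, trimA = 0.05) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (ncol(counts) < 2L) stop("need at least two samples", call. = FALSE)
  lib_sizes <- lib_sizes %||% colSums(counts)
  zero <- which(lib_sizes <= 0)
  if (length(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero] %||% zero, collapse = ", "),
         call. = FALSE)
  }
  # reference column: upper-quartile CPM closest to the mean upper quartile
  uq <- apply(sweep(counts, 2, lib_sizes, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref],
             trimM, trimA)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Weighted trimmed mean of M-values of one sample against the reference.
tmm_pair <- function(y, yr, n, nr, trimM, trimA) {
  keep <- y > 0 & yr > 0
  if (!any(keep)) return(1)
  y <- y[keep]; yr <- yr[keep]
  M <- log2((y / n) / (yr / nr))
  A <- 0.5 * log2((y / n) * (yr / nr))
  # delta-method weights (inverse asymptotic variance of M)
  w <- 1 / ((n - y) / (n * y) + (nr - yr) / (nr * yr))
  if (max(abs(M)) < 1e-6) return(1)  # identical composition
  nk <- length(M)
  loM <- floor(nk * trimM) + 1; hiM <- nk + 1 - loM
  loA <- floor(nk * trimA) + 1; hiA <- nk + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  kept <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(kept)) return(1)
  2 ^ (sum(w[kept] * M[kept]) / sum(w[kept]))
}

#' Average counts-per-million across libraries
#'
#' Per-feature overall abundance: two to the mean (over samples) of
#' log2 CPM computed on prior-augmented counts and effective library sizes
#' (library size times normalization factor). The prior count is scaled per
#' sample in proportion to its effective depth so the floor is comparable
#' across libraries.
#'
#' @param counts features x samples matrix.
#' @param factors normalization factors (default all 1).
#' @param lib_sizes library sizes (default column sums).
#' @param prior_count pseudo-count added at the average depth (default 2).
#' @return named numeric vector of average CPM per feature.
#' @export
average_cpm <- function(counts, factors = NULL, lib_sizes = NULL,
                        prior_count = 2) {
  counts <- as.matrix(counts)
  lib_sizes <- lib_sizes %||% colSums(counts)
  factors <- factors %||% rep(1, ncol(counts))
  2 ^ rowMeans(log2_cpm(counts, factors, lib_sizes, prior_count))
}

# log2 CPM matrix on prior-augmented counts; shared by average_cpm, MDS and
# the coexpression input transform.
log2_cpm <- function(counts, factors = NULL, lib_sizes = NULL,
                     prior_count = 2) {
  counts <- as.matrix(counts)
  lib_sizes <- lib_sizes %||% colSums(counts)
  factors <- factors %||% rep(1, ncol(counts))
  eff <- lib_sizes * factors
  pr <- prior_count * eff / mean(eff)
  log2(sweep(sweep(counts, 2, pr, "+"), 2, eff + 2 * pr, "/") * 1e6)
}

#' Estimate negative-binomial dispersions
#'
#' Common dispersion maximizes the summed per-feature NB adjusted profile
#' log-likelihood: cell means (group means for unpaired designs, patient
#' means for blocked designs) are profiled out at each candidate dispersion,
#' with effective library sizes as offsets, and a Cox-Reid-style
#' `0.5 * log det(X'WX)` adjustment corrects the downward bias of the plain
#' profile MLE at small sample sizes. Tagwise dispersions maximize a
#' weighted likelihood shrinking each feature toward the common value with
#' weight `prior_df`.
#'
#' @param counts features x samples matrix.
#' @param groups factor with two levels (unpaired cells).
#' @param blocks optional blocking factor (paired design); if given, cells
#'   are blocks rather than groups.
#' @param factors,lib_sizes normalization factors and library sizes.
#' @param prior_df shrinkage weight for tagwise estimation (default 10).
#' @return list of class `snc_dispersion`: `common`, `tagwise`, `bcv`
#'   (= sqrt(common)), `prior_df`.
#' @export
estimate_dispersion <- function(counts, groups, blocks = NULL,
                                factors = NULL, lib_sizes = NULL,
                                prior_df = 10) {
  counts <- as.matrix(counts)
  lib_sizes <- lib_sizes %||% colSums(counts)
  factors <- factors %||% rep(1, ncol(counts))
  eff <- lib_sizes * factors
  if (sum(lib_sizes > 0) < 2L) stop("need at least two non-empty samples",
                                    call. = FALSE)
  cells <- if (is.null(blocks)) factor(groups) else factor(blocks)
  if (min(table(cells)) < 2L) {
    stop("each cell needs at least two samples for dispersion estimation",
         call. = FALSE)
  }
  keep <- rowSums(counts) > 0
  Y <- counts[keep, , drop = FALSE]
  apl_total <- function(log_phi) sum(apl_by_feature(Y, eff, cells, exp(log_phi)))
  opt <- optimize(apl_total, interval = log(c(1e-6, 5)), maximum = TRUE)
  common <- exp(opt$maximum)
  if (apl_total(log(1e-8)) >= opt$objective) common <- 1e-8  # Poisson boundary
  # tagwise: grid centered on the common value (odd length => grid hits it)
  grid <- common * 2 ^ seq(-5, 5, length.out = 33)
  apl_mat <- vapply(grid, function(ph) apl_by_feature(Y, eff, cells, ph),
                    numeric(nrow(Y)))
  df_res <- max(ncol(Y) - nlevels(cells), 1)
  w0 <- prior_df / df_res
  wl <- apl_mat + w0 * matrix(colMeans(apl_mat), nrow(Y), length(grid),
                              byrow = TRUE)
  tw_kept <- grid[max.col(wl, ties.method = "first")]
  tagwise <- rep(common, nrow(counts))
  tagwise[keep] <- tw_kept
  names(tagwise) <- rownames(counts)
  structure(list(common = common, tagwise = tagwise,
                 bcv = sqrt(common), prior_df = prior_df),
            class = "snc_dispersion")
}

# Adjusted profile log-likelihood per feature at dispersion phi.
# Cell means are fitted by Newton iteration on the NB score equation;
# the CR adjustment is closed-form because X'WX is diagonal per cell.
apl_by_feature <- function(Y, eff, cells, phi) {
  G <- nrow(Y)
  ll <- numeric(G)
  adj <- numeric(G)
  for (cl in levels(cells)) {
    j <- which(cells == cl)
    Yc <- Y[, j, drop = FALSE]
    Nc <- eff[j]
    m <- rowSums(Yc) / sum(Nc)           # Poisson MLE start
    pos <- m > 0
    if (phi > 1e-8 && any(pos)) {
      for (it in 1:6) {                  # Newton on the NB score for m
        mu <- outer(m, Nc)
        den <- 1 + phi * mu
        f <- rowSums((Yc - mu) / den)
        fp <- -rowSums(sweep(den^-2, 2, Nc, "*") * (1 + phi * Yc))
        step <- ifelse(pos, f / fp, 0)
        m <- pmax(m - step, m * 0.1)
      }
    }
    mu <- outer(m, Nc)
    if (phi > 1e-8) {
      ll <- ll + rowSums(dnbinom(Yc, size = 1 / phi, mu = pmax(mu, 1e-12),
                                 log = TRUE))
      w <- mu / (1 + phi * mu)
    } else {
      ll <- ll + rowSums(dpois(Yc, pmax(mu, 1e-12), log = TRUE))
      w <- mu
    }
    adj <- adj + 0.5 * log(pmax(rowSums(w), 1e-12))
  }
  ll - adj
}

#' Negative-binomial exact test for a two-group comparison
#'
#' Conditional test on each feature's two-group total after equalizing
#' library sizes: counts are rescaled to the mean effective library size and
#' rounded, group sums follow NB distributions with size n_g / phi, and the
#' two-sided p-value sums the probabilities of all splits of the total no
#' more probable than the observed one. With phi = 0 this reduces to the
#' conditional binomial test.
#'
#' @param counts features x samples matrix.
#' @param groups two-level factor; fold changes are reported as level 2 over
#'   level 1.
#' @param dispersions `snc_dispersion` object or numeric vector of per-feature
#'   phi.
#' @param factors,lib_sizes normalization.
#' @return data frame: feature, p, log2fc (prior-moderated), with all-zero
#'   features assigned p = 1.
#' @export
exact_test <- function(counts, groups, dispersions, factors = NULL,
                       lib_sizes = NULL) {
  counts <- as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required", call. = FALSE)
  lib_sizes <- lib_sizes %||% colSums(counts)
  factors <- factors %||% rep(1, ncol(counts))
  eff <- lib_sizes * factors
  phi <- if (inherits(dispersions, "snc_dispersion")) dispersions$tagwise
         else rep_len(dispersions, nrow(counts))
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  Nbar <- mean(eff)
  pseudo_u <- sweep(counts, 2, Nbar / eff, "*")
  pseudo <- round(pseudo_u)
  s1 <- rowSums(pseudo[, g1, drop = FALSE])
  s2 <- rowSums(pseudo[, !g1, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)), function(g) {
    exact_nb_pvalue(s1[g], s2[g], n1, n2, phi[g])
  }, numeric(1))
  # prior-moderated fold change on the CPM scale of the unrounded
  # equalized counts, so uniform depth rescaling leaves it unchanged
  pc <- 0.5
  cpm1 <- rowSums(pseudo_u[, g1, drop = FALSE]) / (n1 * Nbar) * 1e6
  cpm2 <- rowSums(pseudo_u[, !g1, drop = FALSE]) / (n2 * Nbar) * 1e6
  log2fc <- log2((cpm2 + pc) / (cpm1 + pc))
  data.frame(feature = rownames(counts) %||% seq_len(nrow(counts)),
             p = p, log2fc = log2fc, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Two-sided conditional NB p-value by full enumeration over splits of the
# total (the "sum of no-more-probable outcomes" convention).
exact_nb_pvalue <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  i <- 0:s
  if (phi <= 1e-10) {
    pr <- dbinom(i, s, n1 / (n1 + n2))
  } else {
    mu <- s / (n1 + n2)                  # common per-sample mean
    pr <- dnbinom(i, size = n1 / phi, mu = n1 * mu) *
      dnbinom(s - i, size = n2 / phi, mu = n2 * mu)
    tot <- sum(pr)
    if (tot <= 0 || !is.finite(tot)) return(1)
    pr <- pr / tot
  }
  pobs <- pr[s1 + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-10)]))
}

#' Patient-blocked negative-binomial likelihood-ratio test
#'
#' For complete paired designs: per feature, an NB log-linear model with
#' effective-library-size offsets and additive coefficients for block
#' (patient) and condition is fit by iteratively reweighted least squares at
#' the feature's estimated dispersion; the condition effect is tested by the
#' likelihood-ratio (deviance difference) statistic against chi-squared with
#' one degree of freedom.
#'
#' @param counts features x samples matrix.
#' @param groups two-level condition factor; log2FC is level 2 over level 1.
#' @param blocks blocking factor; every block must contain exactly one
#'   sample per condition.
#' @param dispersions `snc_dispersion` or numeric vector.
#' @param factors,lib_sizes normalization.
#' @return data frame: feature, p, log2fc, converged. Non-converged fits are
#'   flagged and given p = NA.
#' @export
paired_lrt <- function(counts, groups, blocks, dispersions,
                       factors = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  groups <- factor(groups)
  blocks <- factor(blocks)
  if (nlevels(groups) != 2L) stop("exactly two conditions required", call. = FALSE)
  tab <- table(blocks, groups)
  if (any(tab != 1L)) {
    stop("incomplete blocks: each block needs one sample per condition",
         call. = FALSE)
  }
  lib_sizes <- lib_sizes %||% colSums(counts)
  factors <- factors %||% rep(1, ncol(counts))
  off <- log(lib_sizes * factors)
  phi <- if (inherits(dispersions, "snc_dispersion")) dispersions$tagwise
         else rep_len(dispersions, nrow(counts))
  X_full <- stats::model.matrix(~ blocks + groups)
  X_null <- stats::model.matrix(~ blocks)
  cond_col <- ncol(X_full)
  res <- t(vapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]
    if (all(y == 0)) return(c(NA_real_, 0, 1))
    fam <- if (phi[g] <= 1e-8) poisson() else
      MASS::negative.binomial(theta = 1 / phi[g])
    f_full <- tryCatch(
      suppressWarnings(glm.fit(X_full, y, family = fam, offset = off)),
      error = function(e) NULL)
    f_null <- tryCatch(
      suppressWarnings(glm.fit(X_null, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(f_full) || is.null(f_null) ||
        !isTRUE(f_full$converged) || !isTRUE(f_null$converged)) {
      return(c(NA_real_, NA_real_, 0))
    }
    stat <- max(f_null$deviance - f_full$deviance, 0)
    c(pchisq(stat, df = 1, lower.tail = FALSE),
      f_full$coefficients[cond_col] / log(2), 1)
  }, numeric(3)))
  data.frame(feature = rownames(counts) %||% seq_len(nrow(counts)),
             p = res[, 1], log2fc = res[, 2], converged = res[, 3] == 1,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment controlling the FDR; delegates to
#' [stats::p.adjust()] after validating the input range.
#'
#' @param p vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted FDR vector in the original order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Assemble a differential-abundance result table
#'
#' Combines test output with average CPM and the signed display fold-change
#' convention (a halving prints as -2, not 0.5).
#'
#' @param test_result data frame with feature, p, log2fc.
#' @param counts,factors,lib_sizes for average CPM.
#' @return data frame of class `de_result`: feature, avg_cpm, log2fc,
#'   fc_display, p, fdr; rows ordered by p.
#' @export
de_table <- function(test_result, counts, factors = NULL, lib_sizes = NULL) {
  cpm <- average_cpm(counts, factors, lib_sizes)
  cpm_m <- if (is.null(names(cpm))) cpm else cpm[match(test_result$feature, names(cpm))]
  out <- data.frame(
    feature = test_result$feature,
    avg_cpm = as.numeric(cpm_m),
    log2fc = test_result$log2fc,
    fc_display = ifelse(test_result$log2fc >= 0,
                        2 ^ test_result$log2fc,
                        -2 ^ (-test_result$log2fc)),
    p = test_result$p,
    fdr = bh_adjust(test_result$p),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Features significant at an FDR threshold
#'
#' @param results `de_result` table (or any data frame with fdr and p).
#' @param fdr_threshold default 0.05 (the FDR < 5% convention).
#' @return subset of `results` with fdr below the threshold, sorted by p.
#' @export
significant_set <- function(results, fdr_threshold = 0.05) {
  stopifnot(all(c("p", "fdr") %in% names(results)))
  out <- results[!is.na(results$fdr) & results$fdr < fdr_threshold, ,
                 drop = FALSE]
  out[order(out$p), , drop = FALSE]
}

#' Sample ordination by leading log-fold-change multidimensional scaling
#'
#' The distance between two samples is the root-mean-square of the `top_n`
#' largest absolute log2 fold changes between them, computed on
#' prior-augmented log2 CPM (the "BCV distance" diagnostic for count data).
#' Classical metric scaling projects samples to two dimensions; each
#' dimension's sign is fixed so its largest-magnitude coordinate is
#' positive.
#'
#' @param counts features x samples matrix (>= 3 samples).
#' @param factors,lib_sizes normalization.
#' @param top_n number of leading fold changes per pair (default 500;
#'   clamped to the feature count with a warning).
#' @param prior_count pseudo-count for the log-CPM transform.
#' @return list with `coords` (samples x 2), `dist` (distance matrix),
#'   `eig` (eigenvalues).
#' @export
mds_coordinates <- function(counts, factors = NULL, lib_sizes = NULL,
                            top_n = 500, prior_count = 2) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3L) stop("need at least three samples", call. = FALSE)
  if (top_n > nrow(counts)) {
    warning("top_n exceeds feature count; clamped")
    top_n <- nrow(counts)
  }
  lc <- log2_cpm(counts, factors, lib_sizes, prior_count)
  n <- ncol(lc)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sq <- sort((lc[, i] - lc[, j])^2, decreasing = TRUE)[seq_len(top_n)]
      d[i, j] <- d[j, i] <- sqrt(mean(sq))
    }
  }
  co <- cmdscale(as.dist(d), k = 2, eig = TRUE)
  coords <- co$points
  if (ncol(coords) < 2) {  # degenerate (e.g. duplicated samples)
    coords <- cbind(coords, matrix(0, nrow(coords), 2 - ncol(coords)))
  }
  for (k in 1:2) {
    if (coords[which.max(abs(coords[, k])), k] < 0) coords[, k] <- -coords[, k]
  }
  colnames(coords) <- c("dim1", "dim2")
  list(coords = coords, dist = d, eig = co$eig)
}

#' One-call unpaired differential abundance analysis
#'
#' TMM normalization, dispersion estimation, NB exact test, BH adjustment.
#' Features with zero counts in all samples are dropped first (tallied).
#'
#' @param counts features x samples matrix.
#' @param groups two-level factor.
#' @param prior_df tagwise shrinkage weight.
#' @return list: `table` (de_result), `factors`, `dispersion`, `n_dropped`.
#' @export
run_exact_de <- function(counts, groups, prior_df = 10) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) > 0
  n_dropped <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  lib <- colSums(counts)
  f <- tmm_factors(counts, lib)
  disp <- estimate_dispersion(counts, groups, factors = f, lib_sizes = lib,
                              prior_df = prior_df)
  tst <- exact_test(counts, groups, disp, factors = f, lib_sizes = lib)
  list(table = de_table(tst, counts, f, lib), factors = f,
       dispersion = disp, n_dropped = n_dropped)
}

#' One-call paired differential abundance analysis
#'
#' TMM normalization, block-profiled dispersion estimation, patient-blocked
#' NB likelihood-ratio test, BH adjustment.
#'
#' @inheritParams run_exact_de
#' @param blocks blocking factor (complete blocks).
#' @return list: `table`, `factors`, `dispersion`, `n_dropped`.
#' @export
run_paired_de <- function(counts, groups, blocks, prior_df = 10) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) > 0
  n_dropped <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  lib <- colSums(counts)
  f <- tmm_factors(counts, lib)
  disp <- estimate_dispersion(counts, groups, blocks = blocks, factors = f,
                              lib_sizes = lib, prior_df = prior_df)
  tst <- paired_lrt(counts, groups, blocks, disp, factors = f, lib_sizes = lib)
  list(table = de_table(tst, counts, f, lib), factors = f,
       dispersion = disp, n_dropped = n_dropped)
}
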