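#' Median-absolute-deviation variability filter
#'
#' Removes features whose MAD across samples fails the variability rule
#' (default: MAD must exceed 0, i.e. constant features are dropped). The
#' rule threshold is exposed because published descriptions of such filters
#' are sometimes ambiguous; any nonnegative cutoff can be supplied.
#'
#' @param x features x samples numeric matrix.
#' @param mad_min features with MAD strictly greater than this are kept.
#' @return list: `matrix` (filtered), `n_kept`, `n_dropped`, `dropped`
#'   (feature ids).
#' @export
mad_filter <- function(x, mad_min = 0) {
  x <- as.matrix(x)
  m <- apply(x, 1, mad)
  keep <- m > mad_min
  if (!any(keep)) stop("all features dropped by the MAD filter", call. = FALSE)
  list(matrix = x[keep, , drop = FALSE],
       n_kept = sum(keep), n_dropped = sum(!keep),
       dropped = rownames(x)[!keep] %||% which(!keep))
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` with unit diagonal. Unsigned adjacency is
#' used throughout, consistent with defining module membership and gene
#' significance through absolute correlations.
#'
#' @param x features x samples matrix.
#' @param beta soft power (default 6).
#' @return symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(x, beta = 6) {
  a <- abs(cor(t(x)))^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each power, connectivity `k_i` is the off-diagonal adjacency row sum;
#' features are binned by k (default 10 equal-width bins) and the fit index
#' is the R-squared of the regression of log10 bin frequency on log10 mean
#' bin connectivity, reported with the slope sign. Degenerate all-equal
#' connectivities yield NA.
#'
#' @param x features x samples matrix (>= 20 features).
#' @param powers candidate beta values.
#' @param n_bins histogram bins for the degree distribution.
#' @return data frame: power, rsq, slope, mean_k.
#' @export
scale_free_fit <- function(x, powers = c(1:10, 12, 14, 16, 18, 20),
                           n_bins = 10) {
  x <- as.matrix(x)
  if (nrow(x) < 20L) stop("need at least 20 features", call. = FALSE)
  ac <- abs(cor(t(x)))
  diag(ac) <- 0
  res <- lapply(powers, function(b) {
    k <- rowSums(ac^b)
    fit <- scale_free_index(k, n_bins)
    data.frame(power = b, rsq = fit["rsq"], slope = fit["slope"],
               mean_k = mean(k), row.names = NULL)
  })
  do.call(rbind, res)
}

# R^2 and slope of log10(freq) ~ log10(mean k) over connectivity bins.
scale_free_index <- function(k, n_bins = 10) {
  if (diff(range(k)) < 1e-12) return(c(rsq = NA_real_, slope = NA_real_))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & mk > 0
  if (sum(ok) < 3) return(c(rsq = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[ok]) ~ log10(mk[ok]))
  c(rsq = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' Topological overlap matrix from an adjacency matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over u distinct from i and j, connectivities computed with zero
#' diagonal, and unit diagonal by definition.
#'
#' @param A symmetric adjacency with entries in `[0, 1]`.
#' @return symmetric TOM matrix, entries in `[0, 1]`, diagonal 1.
#' @export
tom_from_adjacency <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(A < -1e-12) || any(A > 1 + 1e-12)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  A0 <- A
  diag(A0) <- 0
  k <- rowSums(A0)
  L <- A0 %*% A0                       # L_ij = sum_u a_iu a_uj, u != i, j
  kmin <- outer(k, k, pmin)
  tom <- (L + A0) / (kmin + 1 - A0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

# WGCNA-style ordered module color palette; "grey" is reserved for
# unassigned features.
module_palette <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange", "darkorange", "white", "skyblue")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("module", seq_len(n - length(base))))
}

#' Average-linkage clustering with adaptive branch cutting
#'
#' Hierarchically clusters the TOM dissimilarity and cuts the dendrogram at
#' an adaptive height placed between the 5th percentile of merge heights
#' (the scale of tight within-module joins) and a static ceiling just below
#' the top of the tree. `deep_split` selects the fraction of that span:
#' larger values cut lower, splitting the tree more finely. Connected
#' branches below the cut with at least `min_module_size` leaves become
#' modules; all remaining features are "grey" (unassigned). When even the
#' lowest merges sit above the ceiling -- the signature of a structureless
#' (pure noise) dissimilarity -- everything is grey. Module colors are
#' assigned by decreasing size, ties broken by the smallest member index.
#'
#' @param dissim square symmetric dissimilarity matrix (1 - TOM).
#' @param deep_split integer 0-4 (default 3).
#' @param min_module_size smallest reportable module (default 10).
#' @param cut_height ceiling as a fraction of the maximum merge height
#'   (default 0.99); branches joining above it are never merged.
#' @return list of class `snc_modules`: `labels` (named color per feature),
#'   `sizes` (named module sizes, grey last), `dendrogram` (hclust),
#'   `cut_at` (the height used), `unassigned_label` ("grey").
#' @export
cluster_and_cut <- function(dissim, deep_split = 3, min_module_size = 10,
                            cut_height = 0.99) {
  dissim <- as.matrix(dissim)
  if (nrow(dissim) != ncol(dissim) ||
      !isSymmetric(unname(dissim), tol = 1e-8)) {
    stop("dissimilarity must be square and symmetric", call. = FALSE)
  }
  if (!deep_split %in% 0:4) stop("deep_split must be in 0..4", call. = FALSE)
  n <- nrow(dissim)
  ids <- rownames(dissim) %||% paste0("f", seq_len(n))
  rownames(dissim) <- colnames(dissim) <- ids
  hc <- hclust(as.dist(dissim), method = "average")
  heights <- hc$height
  hi <- cut_height * max(heights)
  lo <- unname(quantile(heights, 0.05))
  frac <- c(0.94, 0.88, 0.82, 0.76, 0.70)[deep_split + 1]
  hstar <- lo + frac * max(hi - lo, 0)
  labels <- rep("grey", n)
  if (hstar > min(heights)) {
    cl <- cutree(hc, h = hstar)
    sizes <- table(cl)
    keep <- as.integer(names(sizes)[sizes >= min_module_size])
    if (length(keep)) {
      first <- vapply(keep, function(k) min(which(cl == k)), integer(1))
      ord <- keep[order(-as.integer(sizes[as.character(keep)]), first)]
      cols <- module_palette(length(ord))
      for (i in seq_along(ord)) labels[cl == ord[i]] <- cols[i]
    }
  }
  names(labels) <- ids
  tab <- table(labels)
  non_grey <- sort(tab[names(tab) != "grey"], decreasing = TRUE)
  sizes <- c(non_grey, tab[names(tab) == "grey"])
  structure(list(labels = labels, sizes = sizes, dendrogram = hc,
                 cut_at = hstar, unassigned_label = "grey"),
            class = "snc_modules")
}

#' @export
print.snc_modules <- function(x, ...) {
  cat("coexpression modules:\n")
  print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' Per module: features are standardized and the eigengene is the first
#' right singular vector of the module submatrix (the representative sample
#' profile), sign-oriented so the mean correlation with member features is
#' nonnegative. Grey (unassigned) features get no eigengene.
#'
#' @param x features x samples matrix.
#' @param labels per-feature module labels (from [cluster_and_cut()] or a
#'   named character vector).
#' @return list: `eigengenes` (samples x modules matrix), `var_explained`
#'   (per module).
#' @export
module_eigengenes <- function(x, labels) {
  x <- as.matrix(x)
  if (inherits(labels, "snc_modules")) labels <- labels$labels
  stopifnot(length(labels) == nrow(x))
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey modules", call. = FALSE)
  E <- matrix(NA_real_, ncol(x), length(mods),
              dimnames = list(colnames(x), mods))
  ve <- setNames(numeric(length(mods)), mods)
  for (mod in mods) {
    Xm <- x[labels == mod, , drop = FALSE]
    Xs <- t(scale(t(Xm)))
    if (nrow(Xm) == 1L) {
      warning("module '", mod, "' has a single feature")
      e <- as.numeric(Xs[1, ])
      e <- e / sqrt(sum(e^2))
      E[, mod] <- e
      ve[mod] <- 1
      next
    }
    sv <- svd(Xs)
    e <- sv$v[, 1]
    if (mean(cor(e, t(Xm))) < 0) e <- -e
    E[, mod] <- e
    ve[mod] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = E, var_explained = ve)
}

# correlation p-value via the t distribution with n - 2 df
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  2 * pt(t, df = n - 2, lower.tail = FALSE)
}

#' Module membership and trait gene significance
#'
#' MM (kME) is the Pearson correlation of each feature's profile with each
#' module eigengene. GS is the absolute Pearson correlation of the feature
#' with the binary sample trait (the signed value is also returned); its
#' p-value comes from the correlation t-test with n - 2 degrees of freedom.
#' Zero-variance features yield NA, flagged rather than dropped.
#'
#' @param x features x samples matrix.
#' @param eigengenes samples x modules matrix (from [module_eigengenes()]).
#' @param trait numeric 0/1 per sample (cancer = 1, normal = 0).
#' @return list: `mm` (features x modules), `gs` (absolute), `gs_signed`,
#'   `gs_p`.
#' @export
membership_and_significance <- function(x, eigengenes, trait) {
  x <- as.matrix(x)
  if (is.list(eigengenes)) eigengenes <- eigengenes$eigengenes
  stopifnot(length(trait) == ncol(x))
  n <- ncol(x)
  sds <- apply(x, 1, sd)
  ok <- sds > 0
  mm <- matrix(NA_real_, nrow(x), ncol(eigengenes),
               dimnames = list(rownames(x), colnames(eigengenes)))
  mm[ok, ] <- cor(t(x[ok, , drop = FALSE]), eigengenes)
  gs_signed <- rep(NA_real_, nrow(x))
  gs_signed[ok] <- as.numeric(cor(t(x[ok, , drop = FALSE]), trait))
  gs <- abs(gs_signed)
  gs_p <- ifelse(is.na(gs_signed), NA_real_, cor_pvalue(gs_signed, n))
  names(gs) <- names(gs_signed) <- names(gs_p) <- rownames(x)
  list(mm = mm, gs = gs, gs_signed = gs_signed, gs_p = gs_p)
}

#' Module-trait correlations and per-module GS summaries
#'
#' Pearson correlation of every module eigengene with the trait, two-sided
#' t-test p, plus the per-module mean GS and mean -log10 GS p that drive the
#' module-significance barplots.
#'
#' @param eigengenes samples x modules matrix or [module_eigengenes()] output.
#' @param trait numeric per sample (non-constant).
#' @param stats optional [membership_and_significance()] output for the GS
#'   summaries.
#' @param labels optional per-feature module labels matching `stats`.
#' @return data frame: module, r, p, mean_gs, mean_neglog10_gs_p.
#' @export
module_trait_stats <- function(eigengenes, trait, stats = NULL, labels = NULL) {
  if (is.list(eigengenes)) eigengenes <- eigengenes$eigengenes
  if (sd(trait) == 0) stop("trait is constant", call. = FALSE)
  n <- nrow(eigengenes)
  r <- as.numeric(cor(eigengenes, trait))
  p <- cor_pvalue(r, n)
  out <- data.frame(module = colnames(eigengenes), r = r, p = p,
                    mean_gs = NA_real_, mean_neglog10_gs_p = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(stats) && !is.null(labels)) {
    if (inherits(labels, "snc_modules")) labels <- labels$labels
    for (i in seq_len(nrow(out))) {
      idx <- which(labels == out$module[i])
      out$mean_gs[i] <- mean(stats$gs[idx], na.rm = TRUE)
      out$mean_neglog10_gs_p[i] <- mean(-log10(pmax(stats$gs_p[idx], 1e-300)),
                                        na.rm = TRUE)
    }
  }
  out
}

#' MM-GS relationship within a module
#'
#' Pearson correlation (and p) between module membership and gene
#' significance over the module's features -- high values indicate the
#' module's hub features are also the most trait-relevant. Non-miRNA member
#' ids are returned as the annotation surface for scatter plots.
#'
#' @param stats [membership_and_significance()] output.
#' @param labels per-feature module labels.
#' @param module module color to analyze (size >= 3).
#' @param classes optional per-feature class vector (miRNA / tRNA_half /
#'   YRNA_fragment).
#' @return list: module, n, r, p, non_mirna_members.
#' @export
mm_gs_scatter_stats <- function(stats, labels, module, classes = NULL) {
  if (inherits(labels, "snc_modules")) labels <- labels$labels
  idx <- which(labels == module)
  if (length(idx) < 3L) stop("module must have at least 3 features",
                             call. = FALSE)
  mm <- abs(stats$mm[idx, module])
  gs <- stats$gs[idx]
  ok <- !is.na(mm) & !is.na(gs)
  r <- cor(mm[ok], gs[ok])
  non_mirna <- if (!is.null(classes)) {
    names(labels)[idx][classes[idx] != "miRNA"]
  } else {
    character(0)
  }
  list(module = module, n = sum(ok), r = r, p = cor_pvalue(r, sum(ok)),
       non_mirna_members = non_mirna)
}

#' Full coexpression analysis in one call
#'
#' MAD filter, unsigned soft-threshold adjacency (beta = 6), TOM, average
#' linkage with adaptive branch cutting (deepSplit 3, minimum module size
#' 10), eigengenes, MM/GS, and module-trait statistics.
#'
#' @param x pooled features x samples matrix (log2 CPM scale).
#' @param trait 0/1 per sample.
#' @param beta soft power.
#' @param deep_split,min_module_size tree-cut parameters.
#' @param classes optional per-feature class tags.
#' @param mad_min MAD filter threshold.
#' @return list: `filtered`, `modules`, `eigengenes`, `stats`,
#'   `module_trait`, `power_scan`.
#' @export
run_coexpression <- function(x, trait, beta = 6, deep_split = 3,
                             min_module_size = 10, classes = NULL,
                             mad_min = 0) {
  flt <- mad_filter(x, mad_min)
  xm <- flt$matrix
  if (!is.null(classes)) {
    classes <- classes[match(rownames(xm), rownames(x))]
  }
  scan <- if (nrow(xm) >= 20) scale_free_fit(xm) else NULL
  A <- adjacency_matrix(xm, beta)
  tom <- tom_from_adjacency(A)
  mods <- cluster_and_cut(1 - tom, deep_split, min_module_size)
  if (all(mods$labels == mods$unassigned_label)) {
    return(list(filtered = flt, modules = mods, eigengenes = NULL,
                stats = NULL, module_trait = NULL, power_scan = scan,
                classes = classes))
  }
  eg <- module_eigengenes(xm, mods)
  st <- membership_and_significance(xm, eg, trait)
  mt <- module_trait_stats(eg, trait, st, mods)
  list(filtered = flt, modules = mods, eigengenes = eg, stats = st,
       module_trait = mt, power_scan = scan, classes = classes)
}
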