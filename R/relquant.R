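validate_ct <- function(ct) {
  req <- c("sample_id", "gene_id", "Ct", "group")
  if (!is.data.frame(ct) || !all(req %in% names(ct))) {
    stop("Ct table needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(ct$Ct <= 0, na.rm = TRUE)) stop("Ct values must be positive",
                                          call. = FALSE)
  ct
}

#' Relative quantification by the double-delta-Ct method
#'
#' Technical replicates are averaged per (sample, gene). Per sample,
#' `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the control group's
#' mean dCt (equivalently, divides by the geometric mean control quantity);
#' fold change is `2^-ddCt`. In `mode = "paired"` the ddCt is instead taken
#' within each sample pair (case minus its matched control, via `pair_id`).
#'
#' @param ct Ct table (sample_id, gene_id, Ct, group, optionally pair_id).
#' @param target target gene id.
#' @param reference endogenous reference (housekeeping) gene id.
#' @param control_group label of the control group.
#' @param mode "control_mean" (default) or "paired".
#' @return data frame: sample_id, group, dct, ddct, fold.
#' @export
ddct_fold_changes <- function(ct, target, reference, control_group,
                              mode = c("control_mean", "paired")) {
  mode <- match.arg(mode)
  ct <- validate_ct(ct)
  stopifnot(control_group %in% ct$group)
  # average technical replicates
  agg <- stats::aggregate(Ct ~ sample_id + gene_id + group, data = ct,
                          FUN = mean)
  tgt <- agg[agg$gene_id == target, ]
  ref <- agg[agg$gene_id == reference, ]
  if (!nrow(tgt)) stop("target gene '", target, "' not in table", call. = FALSE)
  miss <- setdiff(tgt$sample_id, ref$sample_id)
  if (length(miss)) {
    stop("missing reference Ct for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dct <- tgt$Ct - ref$Ct[match(tgt$sample_id, ref$sample_id)]
  out <- data.frame(sample_id = tgt$sample_id, group = tgt$group, dct = dct,
                    stringsAsFactors = FALSE)
  if (mode == "control_mean") {
    ctrl_mean <- mean(out$dct[out$group == control_group])
    out$ddct <- out$dct - ctrl_mean
  } else {
    if (!"pair_id" %in% names(ct)) stop("paired mode needs pair_id",
                                        call. = FALSE)
    pair <- ct$pair_id[match(out$sample_id, ct$sample_id)]
    ctrl <- out$group == control_group
    ctrl_dct <- setNames(out$dct[ctrl], pair[ctrl])
    out$ddct <- out$dct - ctrl_dct[pair]
  }
  out$fold <- 2^(-out$ddct)
  rownames(out) <- NULL
  out
}

#' Two-sample t-test on log-transformed fold changes
#'
#' Student's (equal-variance) two-sided t-test on log2 fold changes;
#' Welch's version available via `var_equal = FALSE`.
#'
#' @param folds_case,folds_control positive fold changes per group (>= 2
#'   each).
#' @param var_equal pool variances (default TRUE).
#' @return list: p, t, mean_log2fc_case, mean_log2fc_control.
#' @export
log_fold_test <- function(folds_case, folds_control, var_equal = TRUE) {
  if (length(folds_case) < 2L || length(folds_control) < 2L) {
    stop("need at least two fold changes per group", call. = FALSE)
  }
  if (any(c(folds_case, folds_control) <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  lt <- t.test(log2(folds_case), log2(folds_control), var.equal = var_equal)
  list(p = lt$p.value, t = unname(lt$statistic),
       mean_log2fc_case = mean(log2(folds_case)),
       mean_log2fc_control = mean(log2(folds_control)))
}

#' qPCR analysis of all target genes in a Ct table
#'
#' Runs [ddct_fold_changes()] and [log_fold_test()] for every non-reference
#' gene.
#'
#' @inheritParams ddct_fold_changes
#' @param case_group label of the case (e.g. tumor) group.
#' @return data frame: gene, mean_fold_case, p.
#' @export
run_relquant <- function(ct, reference, control_group, case_group,
                         mode = "control_mean") {
  ct <- validate_ct(ct)
  genes <- setdiff(unique(ct$gene_id), reference)
  rows <- lapply(genes, function(g) {
    fc <- ddct_fold_changes(ct, g, reference, control_group, mode)
    tst <- log_fold_test(fc$fold[fc$group == case_group],
                         fc$fold[fc$group == control_group])
    data.frame(gene = g,
               mean_fold_case = 2^mean(log2(fc$fold[fc$group == case_group])),
               p = tst$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
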