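#' Build a validated miRNA-target interaction universe
#'
#' Filters an interaction table to rows whose evidence matches a
#' strong-evidence list (default: reporter assay, Western blot; matched
#' case-insensitively as substrings), normalizes identifiers (trimmed
#' whitespace, case-folded for matching), and deduplicates edges. The
#' resulting universe is the population for all overtargeting statistics:
#' its miRNAs are both the hypergeometric population and the pool for
#' random-set draws.
#'
#' @param table data frame with miRNA, gene and evidence columns.
#' @param mirna_col,gene_col,evidence_col column names.
#' @param strong_evidence character vector of accepted evidence substrings;
#'   `NULL` disables the filter.
#' @return list of class `snc_universe`: `edges` (mirna, gene),
#'   `mirnas`, `genes`, `n_mirnas`, `n_genes`, `targets_per_gene` (named T_g),
#'   `incidence` (genes x miRNAs logical matrix), `n_filtered_rows`,
#'   `n_duplicate_edges`.
#' @export
build_universe <- function(table,
                           mirna_col = "mirna", gene_col = "gene",
                           evidence_col = "evidence",
                           strong_evidence = c("reporter assay",
                                               "western blot")) {
  stopifnot(is.data.frame(table),
            all(c(mirna_col, gene_col) %in% names(table)))
  n0 <- nrow(table)
  if (!is.null(strong_evidence)) {
    if (!evidence_col %in% names(table)) {
      stop("evidence column '", evidence_col, "' not found", call. = FALSE)
    }
    ev <- tolower(table[[evidence_col]])
    pat <- tolower(strong_evidence)
    keep <- Reduce(`|`, lapply(pat, function(p) grepl(p, ev, fixed = TRUE)))
    table <- table[keep, , drop = FALSE]
  }
  mir <- tolower(trimws(table[[mirna_col]]))
  gene <- toupper(trimws(table[[gene_col]]))
  ok <- mir != "" & gene != "" & !is.na(mir) & !is.na(gene)
  edges <- unique(data.frame(mirna = mir[ok], gene = gene[ok],
                             stringsAsFactors = FALSE))
  if (!nrow(edges)) stop("empty universe after evidence filtering",
                         call. = FALSE)
  mirnas <- sort(unique(edges$mirna))
  genes <- sort(unique(edges$gene))
  inc <- matrix(FALSE, length(genes), length(mirnas),
                dimnames = list(genes, mirnas))
  inc[cbind(match(edges$gene, genes), match(edges$mirna, mirnas))] <- TRUE
  structure(list(edges = edges, mirnas = mirnas, genes = genes,
                 n_mirnas = length(mirnas), n_genes = length(genes),
                 targets_per_gene = rowSums(inc), incidence = inc,
                 n_filtered_rows = n0 - sum(ok),
                 n_duplicate_edges = sum(ok) - nrow(edges)),
            class = "snc_universe")
}

#' @export
print.snc_universe <- function(x, ...) {
  cat(sprintf("interaction universe: %d edges, %d miRNAs, %d genes\n",
              nrow(x$edges), x$n_mirnas, x$n_genes))
  invisible(x)
}

#' Select the top module miRNAs by module membership
#'
#' Ranks a module's miRNA-class features by MM (descending), breaking ties
#' by GS then lexically, and returns the top `k` after intersecting with the
#' universe. Members absent from the universe are reported.
#'
#' @param stats [membership_and_significance()] output.
#' @param labels per-feature module labels.
#' @param module module color.
#' @param classes per-feature class vector; miRNAs are selected.
#' @param universe `snc_universe` (ids matched after lowercase/whitespace
#'   normalization).
#' @param k number of miRNAs to select (default 10).
#' @return list: `selected` (normalized ids), `ranking` (data frame),
#'   `absent_from_universe`.
#' @export
select_top_module_mirnas <- function(stats, labels, module, classes,
                                     universe = NULL, k = 10) {
  if (inherits(labels, "snc_modules")) labels <- labels$labels
  idx <- which(labels == module & classes == "miRNA")
  if (!length(idx)) stop("module '", module, "' contains no miRNA features",
                         call. = FALSE)
  ids <- names(labels)[idx]
  mm <- abs(stats$mm[idx, module])
  gs <- stats$gs[idx]
  ord <- order(-mm, -gs, ids)
  ranking <- data.frame(mirna = ids[ord], mm = mm[ord], gs = gs[ord],
                        stringsAsFactors = FALSE)
  norm_ids <- tolower(trimws(ranking$mirna))
  absent <- character(0)
  if (!is.null(universe)) {
    in_univ <- norm_ids %in% universe$mirnas
    absent <- ranking$mirna[!in_univ]
    ranking <- ranking[in_univ, , drop = FALSE]
    norm_ids <- norm_ids[in_univ]
  }
  if (nrow(ranking) < k) {
    warning(sprintf("module '%s' has only %d usable miRNAs (k = %d)",
                    module, nrow(ranking), k))
  }
  sel <- norm_ids[seq_len(min(k, length(norm_ids)))]
  list(selected = sel, ranking = ranking, absent_from_universe = absent)
}

#' Hypergeometric overtargeting test
#'
#' For each gene targeted by at least one of the `k` selected miRNAs, the
#' upper-tail hypergeometric probability that a uniformly drawn size-k miRNA
#' set from the universe would hit the gene at least as often:
#' `P(X >= x)`, `X ~ Hypergeometric(N_mirnas, T_g, k)`. BH adjustment is
#' applied over the tested genes only (untargeted genes contribute no
#' network proportion and are excluded).
#'
#' @param selected character vector of selected miRNA ids (must be in the
#'   universe).
#' @param universe `snc_universe`.
#' @param fdr_threshold significance threshold on the BH-adjusted p.
#' @return data frame of class `snc_overtargeting`: gene, x (selected miRNAs
#'   hitting it), t_g (universe miRNAs hitting it), p, fdr, significant;
#'   ordered by p.
#' @export
overtargeting_test <- function(selected, universe, fdr_threshold = 0.05) {
  stopifnot(inherits(universe, "snc_universe"))
  selected <- unique(tolower(trimws(selected)))
  if (!length(selected)) stop("no selected miRNAs", call. = FALSE)
  if (!all(selected %in% universe$mirnas)) {
    stop("selected miRNAs absent from the universe: ",
         paste(setdiff(selected, universe$mirnas), collapse = ", "),
         call. = FALSE)
  }
  k <- length(selected)
  x <- rowSums(universe$incidence[, selected, drop = FALSE])
  tg <- universe$targets_per_gene
  tested <- x >= 1
  p <- phyper(x[tested] - 1, tg[tested], universe$n_mirnas - tg[tested], k,
              lower.tail = FALSE)
  out <- data.frame(gene = universe$genes[tested], x = x[tested],
                    t_g = tg[tested], p = p, fdr = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < fdr_threshold
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snc_overtargeting", "data.frame")
  out
}

#' Random-set empirical significance of an overtargeted-gene count
#'
#' Draws `n_iter` random miRNA sets of size `k` uniformly without
#' replacement from the universe, reruns the overtargeting test for each,
#' and records the number of significantly overtargeted genes. The headline
#' empirical p is the raw fraction of iterations reaching at least the
#' observed count. Because the iteration statistic is an integer count, the
#' raw fraction is discrete (and conservative); a randomized Monte-Carlo p
#' with uniform tie-breaking, which is exactly Uniform(0,1) under the null,
#' is also returned for calibration diagnostics.
#'
#' @param universe `snc_universe`.
#' @param k random-set size (<= number of universe miRNAs).
#' @param observed_count observed number of significantly overtargeted genes.
#' @param n_iter iterations (default 100000; fewer than 100 warns).
#' @param fdr_threshold per-iteration significance threshold.
#' @param seed RNG seed.
#' @return list of class `snc_random_set`: `empirical_p`, `randomized_p`,
#'   `observed_count`, `counts` (per iteration), `n_iter`, `seed`.
#' @export
random_set_pvalue <- function(universe, k, observed_count, n_iter = 100000,
                              fdr_threshold = 0.05, seed = 1L) {
  stopifnot(inherits(universe, "snc_universe"))
  if (k > universe$n_mirnas) stop("k exceeds the number of universe miRNAs",
                                  call. = FALSE)
  if (n_iter < 100) warning("fewer than 100 iterations: unstable estimate")
  counts <- with_seed(seed, {
    simulate_overtarget_counts(universe, k, n_iter, fdr_threshold)
  })
  emp <- sum(counts >= observed_count) / n_iter
  rand_p <- with_seed(seed + 1L, {
    (sum(counts > observed_count) +
       runif(1) * (1 + sum(counts == observed_count))) / (n_iter + 1)
  })
  structure(list(empirical_p = emp, randomized_p = rand_p,
                 observed_count = observed_count, counts = counts,
                 n_iter = n_iter, seed = seed, fdr_threshold = fdr_threshold),
            class = "snc_random_set")
}

# Number of significantly overtargeted genes for n_iter uniform random
# k-subsets of the universe miRNAs. Vectorized over genes via the incidence
# matrix; BH is applied per iteration over genes with x >= 1.
simulate_overtarget_counts <- function(universe, k, n_iter, fdr_threshold) {
  inc <- universe$incidence
  tg <- universe$targets_per_gene
  N <- universe$n_mirnas
  counts <- integer(n_iter)
  for (b in seq_len(n_iter)) {
    sel <- sample.int(N, k)
    x <- rowSums(inc[, sel, drop = FALSE])
    tested <- x >= 1
    if (!any(tested)) {
      counts[b] <- 0L
      next
    }
    p <- phyper(x[tested] - 1, tg[tested], N - tg[tested], k,
                lower.tail = FALSE)
    counts[b] <- sum(p.adjust(p, "BH") < fdr_threshold)
  }
  counts
}

#' Export the selected-miRNA / overtargeted-gene bipartite network
#'
#' Writes the edges between selected miRNAs and significantly overtargeted
#' genes as SIF, a GraphML document, and a TSV edge list, plus a node
#' attribute table.
#'
#' @param selected selected miRNA ids.
#' @param result `snc_overtargeting` table.
#' @param universe `snc_universe`.
#' @param prefix output path prefix; files `<prefix>.sif`,
#'   `<prefix>.graphml`, `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`.
#' @return data frame of edges (mirna, gene), invisibly.
#' @export
export_network <- function(selected, result, universe, prefix) {
  stopifnot(inherits(universe, "snc_universe"))
  selected <- tolower(trimws(selected))
  sig <- result$gene[result$significant]
  edges <- universe$edges[universe$edges$mirna %in% selected &
                            universe$edges$gene %in% sig, , drop = FALSE]
  if (!nrow(edges)) warning("empty network: no significant genes")
  writeLines(
    if (nrow(edges)) sprintf("%s\ttargets\t%s", edges$mirna, edges$gene)
    else character(0),
    paste0(prefix, ".sif"))
  mir_ids <- unique(edges$mirna)
  nodes <- rbind(
    data.frame(id = mir_ids, type = rep("miRNA", length(mir_ids)),
               x = rep(NA_real_, length(mir_ids)),
               p = rep(NA_real_, length(mir_ids)),
               fdr = rep(NA_real_, length(mir_ids)),
               stringsAsFactors = FALSE),
    data.frame(id = sig, type = rep("gene", length(sig)),
               x = result$x[result$significant],
               p = result$p[result$significant],
               fdr = result$fdr[result$significant],
               stringsAsFactors = FALSE)
  )
  xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  gml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <graph id="overtargeting" edgedefault="directed">',
    sprintf('    <node id="%s"><data key="type">%s</data></node>',
            xml_escape(nodes$id), nodes$type),
    if (nrow(edges)) sprintf('    <edge source="%s" target="%s"/>',
                             xml_escape(edges$mirna), xml_escape(edges$gene)),
    "  </graph>", "</graphml>"
  )
  writeLines(gml, paste0(prefix, ".graphml"))
  write_tsv_report(edges, paste0(prefix, "_edges.tsv"))
  write_tsv_report(nodes, paste0(prefix, "_nodes.tsv"))
  invisible(edges)
}

#' Hypergeometric term enrichment over a gene universe
#'
#' Upper-tail hypergeometric test per annotation term: given the query set
#' (e.g. significantly overtargeted genes) inside the universe, the
#' probability of at least the observed overlap with the term's gene set.
#' BH adjustment across terms; the enriched set applies both the raw-p and
#' FDR thresholds.
#'
#' @param query character vector of genes (subset of `universe_genes`).
#' @param annotation data frame with gene and term columns (optionally
#'   term_name).
#' @param universe_genes all genes eligible for the query.
#' @param p_threshold,fdr_threshold thresholds defining the enriched set.
#' @return data frame: term, term_name, overlap, term_size, query_size,
#'   universe_size, p, fdr, enriched; ordered by p.
#' @export
term_enrichment <- function(query, annotation, universe_genes,
                            p_threshold = 0.01, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(annotation),
            all(c("gene", "term") %in% names(annotation)))
  if (!nrow(annotation)) stop("empty annotation", call. = FALSE)
  universe_genes <- unique(toupper(trimws(universe_genes)))
  query <- unique(toupper(trimws(query)))
  if (!all(query %in% universe_genes)) {
    stop("query genes outside the universe", call. = FALSE)
  }
  ann <- annotation
  ann$gene <- toupper(trimws(ann$gene))
  ann <- ann[ann$gene %in% universe_genes, , drop = FALSE]
  N <- length(universe_genes)
  nq <- length(query)
  terms <- split(ann$gene, ann$term)
  term_names <- if ("term_name" %in% names(ann)) {
    vapply(split(as.character(ann$term_name), ann$term), `[`, character(1), 1)
  } else {
    setNames(names(terms), names(terms))
  }
  rows <- lapply(names(terms), function(tm) {
    tg <- unique(terms[[tm]])
    ov <- sum(query %in% tg)
    p <- phyper(ov - 1, length(tg), N - length(tg), nq, lower.tail = FALSE)
    data.frame(term = tm, term_name = unname(term_names[tm]), overlap = ov,
               term_size = length(tg), query_size = nq, universe_size = N,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$enriched <- out$p < p_threshold & out$fdr < fdr_threshold
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
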