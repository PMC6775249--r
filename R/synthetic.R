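#' Simulation configuration for the synthetic small-RNA study
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. The defaults emulate the study design the pipeline is built for:
#' five subjects per group, negative-binomial counts with biological
#' coefficient of variation sqrt(phi) ~ 0.3, a heavy-tailed abundance
#' distribution, a trait-linked coexpression module among smaller neutral
#' ones, and a validated miRNA-target universe with a planted overtargeted
#' gene set.
#'
#' @param seed integer seed; identical seeds give bit-identical outputs.
#' @param n_samples_per_group samples per group (default 5, a typical serum
#'   biomarker cohort size).
#' @param n_features number of count features simulated (default 2000).
#' @param library_size_range numeric length-2, min/max sequencing depth per
#'   library (default 0.8e6 - 1.2e6 reads).
#' @param dispersion NB dispersion phi (>= 0); BCV = sqrt(phi). Default 0.1.
#' @param de_fraction proportion of features differentially abundant.
#' @param de_fold fold change (>= 1) applied to DE features in group 2; half
#'   of the DE features go up, half down.
#' @param module_spec list of `list(size =, trait_linked =)` describing the
#'   planted coexpression modules.
#' @param n_module_features total features in the pooled expression matrix;
#'   features beyond the planted modules are pure noise ("unassigned").
#' @param noise_sd Gaussian noise sd added around module latent factors, and
#'   around the trait for the trait-linked factor.
#' @param universe_spec list with `n_mirnas`, `n_genes`,
#'   `background_edge_prob`, `planted_gene_count`, `planted_target_prob`,
#'   `planted_mirna_count`.
#' @param reads_per_locus reads emitted per locus per sample by
#'   [simulate_fragment_reads()].
#' @param decoy_mix named numeric: fractions of reads per locus emitted as
#'   `wrong_length`, `three_prime`, and `internal` decoys. The remainder are
#'   true 5'-anchored 30-34 nt fragments.
#' @return object of class `snc_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples_per_group = 5L,
                       n_features = 2000L,
                       library_size_range = c(8e5, 1.2e6),
                       dispersion = 0.1,
                       de_fraction = 0.1,
                       de_fold = 6,
                       module_spec = list(
                         list(size = 40L, trait_linked = TRUE),
                         list(size = 30L, trait_linked = FALSE),
                         list(size = 20L, trait_linked = FALSE)
                       ),
                       n_module_features = 150L,
                       noise_sd = 0.5,
                       universe_spec = list(
                         n_mirnas = 100L, n_genes = 1000L,
                         background_edge_prob = 0.1,
                         planted_gene_count = 50L,
                         planted_target_prob = 0.8,
                         planted_mirna_count = 10L
                       ),
                       reads_per_locus = 100L,
                       decoy_mix = c(wrong_length = 0.10,
                                     three_prime = 0.05,
                                     internal = 0.05)) {
  stopifnot_scalar_number(seed, "seed")
  stopifnot_scalar_number(n_samples_per_group, "n_samples_per_group", lower = 1)
  stopifnot_scalar_number(n_features, "n_features", lower = 1)
  stopifnot(length(library_size_range) == 2L,
            all(library_size_range >= 1),
            library_size_range[1] <= library_size_range[2])
  stopifnot_scalar_number(dispersion, "dispersion", lower = 0)
  stopifnot_scalar_number(de_fraction, "de_fraction", lower = 0, upper = 1)
  stopifnot_scalar_number(de_fold, "de_fold", lower = 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(n_module_features, "n_module_features", lower = 1)
  stopifnot_scalar_number(reads_per_locus, "reads_per_locus", lower = 1)
  stopifnot(is.list(module_spec),
            all(vapply(module_spec, function(m) m$size >= 1, logical(1))))
  if (sum(vapply(module_spec, `[[`, numeric(1), "size")) > n_module_features) {
    stop("module sizes exceed n_module_features", call. = FALSE)
  }
  us <- universe_spec
  stopifnot(us$n_mirnas >= 1, us$n_genes >= 1,
            us$background_edge_prob >= 0, us$background_edge_prob <= 1,
            us$planted_target_prob >= 0, us$planted_target_prob <= 1,
            us$planted_gene_count >= 0,
            us$planted_target_prob > us$background_edge_prob ||
              us$planted_gene_count == 0)
  us$planted_mirna_count <- us$planted_mirna_count %||% 10L
  stopifnot(names(decoy_mix) %in% c("wrong_length", "three_prime", "internal"),
            all(decoy_mix >= 0), sum(decoy_mix) < 1)
  structure(
    list(seed = as.integer(seed),
         n_samples_per_group = as.integer(n_samples_per_group),
         n_features = as.integer(n_features),
         library_size_range = as.numeric(library_size_range),
         dispersion = dispersion,
         de_fraction = de_fraction,
         de_fold = de_fold,
         module_spec = module_spec,
         n_module_features = as.integer(n_module_features),
         noise_sd = noise_sd,
         universe_spec = us,
         reads_per_locus = as.integer(reads_per_locus),
         decoy_mix = decoy_mix),
    class = "snc_sim_config"
  )
}

#' Synthetic tRNA/YRNA gene annotation
#'
#' Generates a BED-like locus table with the coordinate conventions the
#' profiler expects (1-based inclusive, stranded). Loci are spaced far apart
#' so that no simulated read can overlap two different loci by accident.
#'
#' @param n_trna,n_yrna number of tRNA and YRNA loci.
#' @param seed integer seed.
#' @return data frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `class`.
#' @export
simulate_annotation <- function(n_trna = 15L, n_yrna = 5L, seed = 1L) {
  stopifnot(n_trna + n_yrna >= 1)
  with_seed(seed, {
    n <- n_trna + n_yrna
    cls <- c(rep("tRNA", n_trna), rep("YRNA", n_yrna))
    len <- ifelse(cls == "tRNA", sample(71:74, n, replace = TRUE),
                  sample(94:101, n, replace = TRUE))
    start <- 10000L + (seq_len(n) - 1L) * 5000L + sample(0:999, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    data.frame(
      locus_id = ifelse(cls == "tRNA",
                        sprintf("tRNA-sim-%02d", seq_len(n)),
                        sprintf("YRNA-sim-%02d", seq_len(n))),
      chrom = sample(paste0("chr", 1:6), n, replace = TRUE),
      start = start,
      end = start + len - 1L,
      strand = strand,
      class = cls,
      stringsAsFactors = FALSE
    )
  })
}

#' Random reference sequences for an annotation
#'
#' One sequence per locus, in biological (5' to 3') orientation, for use
#' with the exact substring aligner.
#'
#' @param annotation locus table as from [simulate_annotation()].
#' @param seed integer seed.
#' @return named character vector of ACGT sequences.
#' @export
simulate_reference_sequences <- function(annotation, seed = 1L) {
  validate_annotation(annotation)
  with_seed(seed, {
    len <- annotation$end - annotation$start + 1L
    seqs <- vapply(len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- annotation$locus_id
    seqs
  })
}

#' Simulate aligned small-RNA reads anchored at gene 5' ends
#'
#' Emits, per locus and sample, a planned mixture of true fragments (30-34 nt
#' starting exactly at the locus's biological 5' terminus, strand-aware) and
#' three decoy classes: wrong-length reads at the 5' end, 3'-anchored reads,
#' and internally offset reads. The returned truth table records the intended
#' per-locus 5' count, which the profiler must recover exactly.
#'
#' @param annotation locus table (see [simulate_annotation()]).
#' @param cfg a [sim_config()].
#' @param samples character vector of sample ids; defaults to
#'   `S1..S<n_samples_per_group>`.
#' @return list with `reads` (data frame: read_id, chrom, start, end, strand,
#'   length, sample_id, planned class) and `truth` (locus x sample matrix of
#'   planted 5' counts).
#' @export
simulate_fragment_reads <- function(annotation, cfg = sim_config(),
                                    samples = NULL) {
  validate_annotation(annotation)
  if (nrow(annotation) == 0L) stop("annotation is empty", call. = FALSE)
  stopifnot(inherits(cfg, "snc_sim_config"))
  samples <- samples %||% paste0("S", seq_len(cfg$n_samples_per_group))

  R <- cfg$reads_per_locus
  n_wrong <- round(cfg$decoy_mix[["wrong_length"]] * R)
  n_3p <- round(cfg$decoy_mix[["three_prime"]] * R)
  n_int <- round(cfg$decoy_mix[["internal"]] * R)
  n_true <- R - n_wrong - n_3p - n_int
  stopifnot(n_true >= 0)

  with_seed(cfg$seed, {
    out <- vector("list", nrow(annotation) * length(samples))
    idx <- 0L
    for (s in samples) {
      for (i in seq_len(nrow(annotation))) {
        loc <- annotation[i, ]
        L <- loc$end - loc$start + 1L
        cls <- c(rep("true_5p", n_true), rep("wrong_length", n_wrong),
                 rep("three_prime", n_3p), rep("internal", n_int))
        len <- integer(length(cls))
        off <- integer(length(cls))  # 5' offset of read start from locus 5'
        len[cls == "true_5p"] <- sample(30:34, n_true, replace = TRUE)
        off[cls == "true_5p"] <- 0L
        if (n_wrong > 0) {
          bad_len <- c(20:29, 35:min(45, L))
          len[cls == "wrong_length"] <- sample(bad_len, n_wrong, replace = TRUE)
          off[cls == "wrong_length"] <- 0L
        }
        if (n_3p > 0) {
          l3 <- sample(30:34, n_3p, replace = TRUE)
          len[cls == "three_prime"] <- l3
          off[cls == "three_prime"] <- L - l3
        }
        if (n_int > 0) {
          li <- sample(30:34, n_int, replace = TRUE)
          len[cls == "internal"] <- li
          # keep the read inside the gene and its 5' end off both termini
          off[cls == "internal"] <- vapply(li, function(l) {
            sample(seq(2L, max(2L, L - l - 1L)), 1L)
          }, integer(1))
        }
        # map 5' offset to genomic coordinates (minus strand: 5' = end)
        if (loc$strand == "+") {
          gstart <- loc$start + off
          gend <- gstart + len - 1L
        } else {
          gend <- loc$end - off
          gstart <- gend - len + 1L
        }
        idx <- idx + 1L
        out[[idx]] <- data.frame(
          read_id = sprintf("%s_%s_r%04d", s, loc$locus_id, seq_along(cls)),
          chrom = loc$chrom, start = gstart, end = gend,
          strand = loc$strand, length = len, sample_id = s,
          planned_class = cls, stringsAsFactors = FALSE
        )
      }
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    truth <- matrix(as.integer(n_true), nrow = nrow(annotation),
                    ncol = length(samples),
                    dimnames = list(annotation$locus_id, samples))
    list(reads = reads, truth = truth)
  })
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Gene means are drawn log-normal (meanlog 4, sdlog 1.5) to mimic the wide
#' dynamic range of small-RNA abundances; counts are NB with mean scaled by
#' library size and dispersion `cfg$dispersion`. A `de_fraction` of features
#' is multiplied by `de_fold` in group 2, half up and half down.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (features x samples integer matrix), `groups`
#'   (factor), `lib_sizes`, and `truth` (data frame: feature, is_de,
#'   direction, true_log2fc).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "snc_sim_config"))
  with_seed(cfg$seed, {
    G <- cfg$n_features
    n <- 2L * cfg$n_samples_per_group
    groups <- factor(rep(c("control", "case"), each = cfg$n_samples_per_group),
                     levels = c("control", "case"))
    libs <- runif(n, cfg$library_size_range[1], cfg$library_size_range[2])
    mu0 <- rlnorm(G, meanlog = 4, sdlog = 1.5)
    n_de <- round(cfg$de_fraction * G)
    de_idx <- if (n_de > 0) sample.int(G, n_de) else integer(0)
    dir <- rep(0, G)
    if (n_de > 0) {
      up <- de_idx[seq_len(ceiling(n_de / 2))]
      down <- setdiff(de_idx, up)
      dir[up] <- 1
      dir[down] <- -1
    }
    fc <- cfg$de_fold ^ dir  # group-2 multiplier
    mean_lib <- mean(libs)
    counts <- matrix(0L, G, n)
    for (j in seq_len(n)) {
      m <- mu0 * (libs[j] / mean_lib)
      if (groups[j] == "case") m <- m * fc
      counts[, j] <- if (cfg$dispersion <= 0) {
        rpois(G, m)
      } else {
        rnbinom(G, size = 1 / cfg$dispersion, mu = m)
      }
    }
    feat <- sprintf("feat_%04d", seq_len(G))
    dimnames(counts) <- list(feat, paste0(ifelse(groups == "control", "N", "C"),
                                          rep(seq_len(cfg$n_samples_per_group), 2)))
    list(counts = counts, groups = groups, lib_sizes = colSums(counts),
         truth = data.frame(feature = feat, is_de = dir != 0,
                            direction = dir,
                            true_log2fc = dir * log2(cfg$de_fold),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a paired (blocked) count matrix with patient effects
#'
#' Companion to [simulate_counts()] for the matched tumor/normal design:
#' each block (patient) contributes one sample per condition, with a
#' patient-specific log-normal baseline multiplier creating strong
#' between-block variation.
#'
#' @param cfg a [sim_config()].
#' @param block_sd sd of per-patient log-normal baseline effects (log2 scale).
#' @return list with `counts`, `groups`, `blocks`, `truth` (as in
#'   [simulate_counts()]).
#' @export
simulate_paired_counts <- function(cfg = sim_config(), block_sd = 1) {
  stopifnot(inherits(cfg, "snc_sim_config"))
  with_seed(cfg$seed + 1L, {
    G <- cfg$n_features
    B <- cfg$n_samples_per_group
    n <- 2L * B
    blocks <- factor(rep(paste0("P", seq_len(B)), each = 2))
    groups <- factor(rep(c("normal", "tumor"), times = B),
                     levels = c("normal", "tumor"))
    libs <- runif(n, cfg$library_size_range[1], cfg$library_size_range[2])
    mu0 <- rlnorm(G, meanlog = 4, sdlog = 1.5)
    # per-feature, per-patient baseline wobble (the "patient effect")
    block_fx <- matrix(2 ^ rnorm(G * B, 0, block_sd), G, B)
    n_de <- round(cfg$de_fraction * G)
    de_idx <- if (n_de > 0) sample.int(G, n_de) else integer(0)
    dir <- rep(0, G)
    if (n_de > 0) {
      up <- de_idx[seq_len(ceiling(n_de / 2))]
      dir[up] <- 1
      dir[setdiff(de_idx, up)] <- -1
    }
    fc <- cfg$de_fold ^ dir
    mean_lib <- mean(libs)
    counts <- matrix(0L, G, n)
    for (j in seq_len(n)) {
      b <- as.integer(blocks[j])
      m <- mu0 * block_fx[, b] * (libs[j] / mean_lib)
      if (groups[j] == "tumor") m <- m * fc
      counts[, j] <- if (cfg$dispersion <= 0) {
        rpois(G, m)
      } else {
        rnbinom(G, size = 1 / cfg$dispersion, mu = m)
      }
    }
    feat <- sprintf("feat_%04d", seq_len(G))
    dimnames(counts) <- list(feat, paste0(blocks, "_", substr(groups, 1, 1)))
    list(counts = counts, groups = groups, blocks = blocks,
         truth = data.frame(feature = feat, is_de = dir != 0, direction = dir,
                            true_log2fc = dir * log2(cfg$de_fold),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate an expression matrix with planted coexpression modules
#'
#' Each planted module is a latent factor plus Gaussian noise; the
#' trait-linked module's factor is a noisy copy of the binary trait
#' (cancer = 1, normal = 0). Features beyond the planted modules are pure
#' noise and labeled "unassigned" in the truth table. Features are tagged
#' with a class (miRNA / tRNA_half / YRNA_fragment) to emulate the pooled
#' small-RNA table the coexpression stage consumes.
#'
#' @param cfg a [sim_config()].
#' @param mirna_ids optional character vector; if given, the trait-linked
#'   module's first miRNA-class features are renamed to these ids (to tie the
#'   module to a simulated interaction universe).
#' @return list with `matrix` (features x samples), `trait` (0/1 per sample),
#'   `truth` (feature, module, class).
#' @export
simulate_module_data <- function(cfg = sim_config(), mirna_ids = NULL) {
  stopifnot(inherits(cfg, "snc_sim_config"))
  n <- 2L * cfg$n_samples_per_group
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  sizes <- vapply(cfg$module_spec, `[[`, numeric(1), "size")
  if (sum(sizes) > cfg$n_module_features) {
    stop("module sizes exceed n_module_features", call. = FALSE)
  }
  with_seed(cfg$seed + 2L, {
    trait <- rep(c(0, 1), each = cfg$n_samples_per_group)
    trait_std <- as.numeric(scale(trait))
    G <- cfg$n_module_features
    X <- matrix(rnorm(G * n), G, n)  # noise background
    labels <- rep("unassigned", G)
    row <- 1L
    for (m in seq_along(cfg$module_spec)) {
      spec <- cfg$module_spec[[m]]
      fac <- if (isTRUE(spec$trait_linked)) {
        trait_std + rnorm(n, 0, cfg$noise_sd)
      } else {
        rnorm(n)
      }
      for (i in seq_len(spec$size)) {
        loading <- runif(1, 0.7, 1.3) * sample(c(1, -1), 1, prob = c(0.8, 0.2))
        X[row, ] <- loading * fac + rnorm(n, 0, cfg$noise_sd)
        labels[row] <- paste0("M", m)
        row <- row + 1L
      }
    }
    cls <- sample(c("miRNA", "tRNA_half", "YRNA_fragment"), G, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
    feat <- ifelse(cls == "miRNA", sprintf("mir-feat-%03d", seq_len(G)),
                   ifelse(cls == "tRNA_half", sprintf("tRNA-feat-%03d-5p", seq_len(G)),
                          sprintf("YRNA-feat-%03d-5p", seq_len(G))))
    if (!is.null(mirna_ids)) {
      tl <- which(vapply(cfg$module_spec, function(s) isTRUE(s$trait_linked),
                         logical(1)))[1]
      if (!is.na(tl)) {
        slots <- which(labels == paste0("M", tl) & cls == "miRNA")
        k <- min(length(slots), length(mirna_ids))
        feat[slots[seq_len(k)]] <- mirna_ids[seq_len(k)]
      }
    }
    rownames(X) <- feat
    colnames(X) <- paste0(ifelse(trait == 0, "N", "C"),
                          rep(seq_len(cfg$n_samples_per_group), 2))
    list(matrix = X, trait = trait,
         truth = data.frame(feature = feat, module = labels, class = cls,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a validated miRNA-target interaction universe
#'
#' Background edges are independent Bernoulli draws per (miRNA, gene) pair; a
#' planted gene set receives edges from a designated miRNA set with a higher
#' probability, creating a recoverable overtargeting signal.
#'
#' @param cfg a [sim_config()]; see `universe_spec`.
#' @return list with `table` (data frame: mirna, gene, evidence), `truth`
#'   (planted gene ids and planted miRNA ids).
#' @export
simulate_interaction_universe <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "snc_sim_config"))
  us <- cfg$universe_spec
  if (us$n_mirnas < 1 || us$n_genes < 1) {
    stop("universe must contain at least one miRNA and one gene", call. = FALSE)
  }
  with_seed(cfg$seed + 3L, {
    mirnas <- sprintf("mir-sim-%03d", seq_len(us$n_mirnas))
    genes <- sprintf("GENE%04d", seq_len(us$n_genes))
    planted_mirnas <- mirnas[seq_len(min(us$planted_mirna_count, us$n_mirnas))]
    planted_genes <- if (us$planted_gene_count > 0) {
      genes[seq_len(min(us$planted_gene_count, us$n_genes))]
    } else {
      character(0)
    }
    P <- matrix(us$background_edge_prob, us$n_mirnas, us$n_genes,
                dimnames = list(mirnas, genes))
    if (length(planted_genes)) {
      P[planted_mirnas, planted_genes] <- us$planted_target_prob
    }
    hit <- matrix(rbinom(length(P), 1, as.vector(P)), nrow(P), ncol(P),
                  dimnames = dimnames(P)) == 1
    idx <- which(hit, arr.ind = TRUE)
    tab <- data.frame(
      mirna = mirnas[idx[, 1]], gene = genes[idx[, 2]],
      evidence = sample(c("Reporter assay", "Western blot"), nrow(idx),
                        replace = TRUE),
      stringsAsFactors = FALSE
    )
    tab <- tab[order(tab$mirna, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(planted_genes = planted_genes,
                      planted_mirnas = planted_mirnas))
  })
}

#' Simulate a gene-to-term annotation table
#'
#' Assigns each gene a handful of random terms; one designated term is
#' enriched for a given gene set (e.g. the planted overtargeted genes) so
#' that term enrichment has a recoverable signal.
#'
#' @param genes universe gene ids.
#' @param enriched_genes genes carrying the planted term.
#' @param n_terms number of background terms.
#' @param seed integer seed.
#' @return data frame: gene, term, term_name.
#' @export
simulate_term_annotation <- function(genes, enriched_genes = character(0),
                                     n_terms = 20L, seed = 1L) {
  stopifnot(length(genes) >= 1)
  with_seed(seed, {
    rows <- list()
    for (t in seq_len(n_terms)) {
      size <- sample(10:60, 1)
      rows[[t]] <- data.frame(
        gene = sample(genes, min(size, length(genes))),
        term = sprintf("TERM:%04d", t),
        term_name = sprintf("background process %d", t),
        stringsAsFactors = FALSE
      )
    }
    if (length(enriched_genes)) {
      rows[[n_terms + 1L]] <- data.frame(
        gene = enriched_genes,
        term = "TERM:PLANTED",
        term_name = "planted regulatory process",
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a qPCR Ct table for paired tumor/normal tissue
#'
#' Target genes have planted expression fold changes in tumor relative to
#' normal; the reference (housekeeping) gene is flat. Ct values follow
#' Ct = base - log2(expression) + noise, so a 2-fold expression increase
#' lowers Ct by one cycle.
#'
#' @param cfg a [sim_config()].
#' @param genes named numeric of true tumor/normal expression fold changes
#'   per target gene.
#' @param reference_gene reference gene id.
#' @param ct_sd Gaussian Ct noise (cycles).
#' @return data frame: sample_id, gene_id, Ct, group, pair_id.
#' @export
simulate_ct_table <- function(cfg = sim_config(),
                              genes = c(FBXO31_like = 0.4, WEE1_like = 0.5,
                                        RB1_like = 0.7, E2F1_like = 0.8),
                              reference_gene = "B2M",
                              ct_sd = 0.25) {
  stopifnot(inherits(cfg, "snc_sim_config"), length(genes) >= 1)
  with_seed(cfg$seed + 4L, {
    B <- cfg$n_samples_per_group
    rows <- list()
    base <- c(setNames(runif(length(genes), 22, 28), names(genes)),
              setNames(20, reference_gene))
    for (b in seq_len(B)) {
      for (grp in c("normal", "tumor")) {
        sample_id <- sprintf("P%d_%s", b, grp)
        for (g in c(names(genes), reference_gene)) {
          fc <- if (g == reference_gene || grp == "normal") 1 else genes[[g]]
          ct <- base[[g]] - log2(fc) + rnorm(1, 0, ct_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, gene_id = g, Ct = ct, group = grp,
            pair_id = paste0("P", b), stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}
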