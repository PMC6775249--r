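#' Default pipeline configuration
#'
#' A flat, diff-able list of stage toggles and parameters; can be written to
#' and read from YAML. All stage parameters are grouped by stage name. The
#' single global `seed` fans out to per-stage seeds through a fixed offset
#' table (see `derive_seed`), so a run is reproducible end to end from one
#' integer.
#'
#' @param seed global integer seed.
#' @return named list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, profile = TRUE, de = TRUE,
                  coexpress = TRUE, overtarget = TRUE, relquant = TRUE),
    inputs = list(reads = NULL, annotation = NULL, counts_serum = NULL,
                  counts_tissue = NULL, expression = NULL, universe = NULL,
                  term_annotation = NULL, ct = NULL),
    profile = list(tol = 0),
    de = list(fdr = 0.05, prior_df = 10, trimM = 0.3, trimA = 0.05),
    coexpress = list(beta = 6, deep_split = 3, min_module_size = 10,
                     mad_min = 0),
    overtarget = list(k = 10, n_iter = 2000, fdr = 0.05,
                      p_threshold = 0.01, enrich_fdr = 0.05),
    sim = list(n_samples_per_group = 5, n_features = 2000, dispersion = 0.1,
               de_fraction = 0.1, de_fold = 6)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config(config$seed %||% 1L)
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) base[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  # validate referenced input files before any stage runs
  for (nm in names(base$inputs)) {
    p <- base$inputs[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input file missing: ", nm, " = ", p, call. = FALSE)
    }
  }
  stopifnot(base$coexpress$deep_split %in% 0:4,
            base$de$fdr > 0, base$de$fdr <= 1,
            base$overtarget$k >= 1)
  base
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes profile -> differential abundance (unpaired serum-style and
#' paired tissue-style) -> coexpression -> overtargeting/enrichment ->
#' qPCR relative quantification, as toggled in the config. When no input
#' files are configured, the synthetic-data generators supply every input
#' (the self-contained benchmark mode). Every output table is TSV with a
#' config-hash header; a machine-readable JSON report summarizes seeds,
#' parameters, per-stage row counts and warnings. Rerunning with an
#' identical config reproduces all stochastic stages bit-identically.
#'
#' @param config config list or path to a YAML file (see
#'   [default_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @return the report list, invisibly; `report.json` and stage TSVs are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(cfg)
  hdr <- paste0("config_hash: ", hash)
  report <- list(package_version = as.character(utils::packageVersion("sncpipe")),
                 r_version = R.version.string,
                 seed = cfg$seed, config_hash = hash, config = cfg,
                 stages = list(), warnings = character(0))
  add_warning <- function(w) report$warnings <<- c(report$warnings, w)
  fail <- function(stage, e) {
    writeLines(paste0("FAILED at stage ", stage, ": ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  t_stage <- function(stage, expr) {
    t0 <- Sys.time()
    message(sprintf("[sncpipe] %s ...", stage))
    res <- tryCatch(expr, error = function(e) fail(stage, e))
    message(sprintf("[sncpipe] %s done (%.1fs)", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  sim <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    sim <- t_stage("simulate", {
      sc <- sim_config(seed = derive_seed(cfg$seed, "simulate"),
                       n_samples_per_group = cfg$sim$n_samples_per_group,
                       n_features = cfg$sim$n_features,
                       dispersion = cfg$sim$dispersion,
                       de_fraction = cfg$sim$de_fraction,
                       de_fold = cfg$sim$de_fold)
      ann <- simulate_annotation(seed = sc$seed)
      frag <- simulate_fragment_reads(ann, sc)
      serum <- simulate_counts(sc)
      tissue <- simulate_paired_counts(sc)
      univ_sim <- simulate_interaction_universe(sc)
      modules <- simulate_module_data(sc,
                                      mirna_ids = univ_sim$truth$planted_mirnas)
      terms <- simulate_term_annotation(
        genes = sort(unique(univ_sim$table$gene)),
        enriched_genes = univ_sim$truth$planted_genes,
        seed = sc$seed)
      ct <- simulate_ct_table(sc)
      list(cfg = sc, annotation = ann, fragments = frag, serum = serum,
           tissue = tissue, universe = univ_sim, modules = modules,
           terms = terms, ct = ct)
    })
    report$stages$simulate <- list(
      seed = sim$cfg$seed, n_reads = nrow(sim$fragments$reads),
      n_loci = nrow(sim$annotation),
      n_features = sim$cfg$n_features,
      n_universe_edges = nrow(sim$universe$table))
  }

  if (isTRUE(cfg$stages$profile)) {
    prof <- t_stage("profile", {
      if (!is.null(cfg$inputs$reads)) {
        reads <- read_aligned_reads(cfg$inputs$reads)
        ann <- read_annotation(cfg$inputs$annotation)
      } else {
        reads <- sim$fragments$reads
        ann <- sim$annotation
      }
      fc <- count_fragments(reads, ann, tol = cfg$profile$tol)
      f5t <- five_prime_fraction(reads, ann, "tRNA", tol = cfg$profile$tol)
      f5y <- tryCatch(
        five_prime_fraction(reads, ann, "YRNA", tol = cfg$profile$tol),
        error = function(e) NA_real_)
      write_tsv_report(cbind(locus_id = rownames(fc$counts),
                             as.data.frame(fc$counts)),
                       file.path(out_dir, "fragment_counts.tsv"), hdr)
      write_tsv_report(fragment_qc_summary(fc),
                       file.path(out_dir, "fragment_qc.tsv"), hdr)
      list(fc = fc, f5t = f5t, f5y = f5y)
    })
    report$stages$profile <- list(
      n_loci = nrow(prof$fc$counts),
      five_prime_fraction_trna = prof$f5t,
      five_prime_fraction_yrna = prof$f5y,
      rejected = as.list(colSums(prof$fc$rejections)))
  }

  if (isTRUE(cfg$stages$de)) {
    de <- t_stage("de", {
      serum_counts <- if (!is.null(cfg$inputs$counts_serum)) {
        as.matrix(read_tsv_report(cfg$inputs$counts_serum)[-1])
      } else {
        sim$serum$counts
      }
      serum_groups <- sim$serum$groups %||%
        factor(rep(c("control", "case"), each = ncol(serum_counts) / 2))
      serum <- run_exact_de(serum_counts, serum_groups,
                            prior_df = cfg$de$prior_df)
      tissue_counts <- if (!is.null(cfg$inputs$counts_tissue)) {
        as.matrix(read_tsv_report(cfg$inputs$counts_tissue)[-1])
      } else {
        sim$tissue$counts
      }
      tissue <- run_paired_de(tissue_counts, sim$tissue$groups,
                              sim$tissue$blocks, prior_df = cfg$de$prior_df)
      mds <- mds_coordinates(serum_counts, serum$factors,
                             top_n = min(500, nrow(serum_counts)))
      write_tsv_report(serum$table, file.path(out_dir, "de_serum.tsv"), hdr)
      write_tsv_report(tissue$table, file.path(out_dir, "de_tissue.tsv"), hdr)
      write_tsv_report(cbind(sample = rownames(mds$coords),
                             as.data.frame(mds$coords)),
                       file.path(out_dir, "mds_serum.tsv"), hdr)
      list(serum = serum, tissue = tissue, mds = mds)
    })
    report$stages$de <- list(
      n_significant_serum = nrow(significant_set(de$serum$table, cfg$de$fdr)),
      n_significant_tissue = nrow(significant_set(de$tissue$table, cfg$de$fdr)),
      bcv_serum = de$serum$dispersion$bcv,
      bcv_tissue = de$tissue$dispersion$bcv,
      dropped_serum = de$serum$n_dropped,
      dropped_tissue = de$tissue$n_dropped)
  }

  if (isTRUE(cfg$stages$coexpress)) {
    cx <- t_stage("coexpress", {
      if (!is.null(cfg$inputs$expression)) {
        tab <- read_tsv_report(cfg$inputs$expression)
        x <- as.matrix(tab[, !(names(tab) %in% c("feature", "class"))])
        rownames(x) <- tab$feature
        classes <- tab$class
        trait <- as.numeric(grepl("^C", colnames(x)))
      } else {
        x <- sim$modules$matrix
        classes <- sim$modules$truth$class
        trait <- sim$modules$trait
      }
      res <- run_coexpression(x, trait, beta = cfg$coexpress$beta,
                              deep_split = cfg$coexpress$deep_split,
                              min_module_size = cfg$coexpress$min_module_size,
                              classes = classes,
                              mad_min = cfg$coexpress$mad_min)
      write_tsv_report(data.frame(feature = names(res$modules$labels),
                                  module = res$modules$labels,
                                  class = res$classes %||% NA),
                       file.path(out_dir, "modules.tsv"), hdr)
      if (!is.null(res$module_trait)) {
        write_tsv_report(res$module_trait,
                         file.path(out_dir, "module_trait.tsv"), hdr)
        write_tsv_report(cbind(sample = rownames(res$eigengenes$eigengenes),
                               as.data.frame(res$eigengenes$eigengenes)),
                         file.path(out_dir, "eigengenes.tsv"), hdr)
        write_tsv_report(data.frame(feature = names(res$stats$gs),
                                    gs = res$stats$gs,
                                    gs_signed = res$stats$gs_signed,
                                    gs_p = res$stats$gs_p,
                                    as.data.frame(res$stats$mm)),
                         file.path(out_dir, "mm_gs.tsv"), hdr)
      }
      res
    })
    report$stages$coexpress <- list(
      n_features_kept = cx$filtered$n_kept,
      n_modules = sum(names(cx$modules$sizes) != "grey"),
      sizes = as.list(cx$modules$sizes),
      best_trait_module = if (!is.null(cx$module_trait)) {
        bt <- cx$module_trait[which.max(abs(cx$module_trait$r)), ]
        list(module = bt$module, r = bt$r, p = bt$p)
      })
  }

  if (isTRUE(cfg$stages$overtarget)) {
    ot <- t_stage("overtarget", {
      tab <- if (!is.null(cfg$inputs$universe)) {
        read_tsv_report(cfg$inputs$universe)
      } else {
        sim$universe$table
      }
      universe <- build_universe(tab)
      mt <- cx$module_trait
      if (is.null(mt)) stop("no coexpression modules available")
      # walk modules by decreasing |trait correlation| until one offers
      # miRNAs present in the universe
      sel <- NULL
      best <- NA_character_
      for (mod in mt$module[order(-abs(mt$r))]) {
        cand <- tryCatch(
          suppressWarnings(
            select_top_module_mirnas(cx$stats, cx$modules, mod, cx$classes,
                                     universe, k = cfg$overtarget$k)),
          error = function(e) NULL)
        if (!is.null(cand) && length(cand$selected)) {
          sel <- cand
          best <- mod
          break
        }
      }
      if (is.null(sel)) stop("no module provides miRNAs present in the universe")
      res <- overtargeting_test(sel$selected, universe,
                                fdr_threshold = cfg$overtarget$fdr)
      n_sig <- sum(res$significant)
      rs <- random_set_pvalue(universe, k = length(sel$selected),
                              observed_count = n_sig,
                              n_iter = cfg$overtarget$n_iter,
                              fdr_threshold = cfg$overtarget$fdr,
                              seed = derive_seed(cfg$seed, "overtarget"))
      export_network(sel$selected, res, universe,
                     file.path(out_dir, "network"))
      terms <- if (!is.null(cfg$inputs$term_annotation)) {
        read_tsv_report(cfg$inputs$term_annotation)
      } else {
        sim$terms
      }
      enr <- term_enrichment(res$gene[res$significant], terms,
                             universe$genes,
                             p_threshold = cfg$overtarget$p_threshold,
                             fdr_threshold = cfg$overtarget$enrich_fdr)
      write_tsv_report(res, file.path(out_dir, "overtargeting.tsv"), hdr)
      write_tsv_report(enr, file.path(out_dir, "enrichment.tsv"), hdr)
      write_tsv_report(data.frame(n_iter = rs$n_iter,
                                  observed = rs$observed_count,
                                  empirical_p = rs$empirical_p,
                                  randomized_p = rs$randomized_p),
                       file.path(out_dir, "random_set.tsv"), hdr)
      list(universe = universe, selection = sel, result = res, random = rs,
           enrichment = enr, module = best)
    })
    report$stages$overtarget <- list(
      module = ot$module,
      k = length(ot$selection$selected),
      n_overtargeted = sum(ot$result$significant),
      empirical_p = ot$random$empirical_p,
      n_enriched_terms = sum(ot$enrichment$enriched))
  }

  if (isTRUE(cfg$stages$relquant)) {
    rq <- t_stage("relquant", {
      ct <- if (!is.null(cfg$inputs$ct)) read_tsv_report(cfg$inputs$ct)
            else sim$ct
      res <- run_relquant(ct, reference = "B2M", control_group = "normal",
                          case_group = "tumor")
      write_tsv_report(res, file.path(out_dir, "relquant.tsv"), hdr)
      res
    })
    report$stages$relquant <- list(
      genes = rq$gene, folds = rq$mean_fold_case, p = rq$p)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
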