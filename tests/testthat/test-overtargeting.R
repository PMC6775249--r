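mini_universe_table <- function() {
  data.frame(
    mirna = c("miR-1", "miR-1", "miR-2", "miR-2", "miR-3", "miR-4", "miR-1"),
    gene = c("GA", "GB", "GA", "GC", "GC", "GD", "GA"),  # GA/miR-1 duplicated
    evidence = c("Reporter assay", "Western blot", "Luciferase reporter assay",
                 "Reporter assay", "Western blot", "Reporter assay",
                 "Reporter assay"),
    stringsAsFactors = FALSE
  )
}

test_that("universe construction filters, normalizes and deduplicates", {
  u <- build_universe(mini_universe_table())
  expect_equal(nrow(u$edges), 6)          # duplicate collapsed
  expect_equal(u$n_mirnas, 4)
  expect_equal(u$n_genes, 4)
  expect_equal(unname(u$targets_per_gene["GA"]), 2)
  # weak-evidence rows are excluded
  tab <- mini_universe_table()
  tab$evidence[4] <- "microarray"
  u2 <- build_universe(tab)
  expect_false(any(u2$edges$mirna == "mir-2" & u2$edges$gene == "GC"))
  # synthetic table with e unique strong edges yields universe size e
  us <- simulate_interaction_universe(sim_config(seed = 3))
  u3 <- build_universe(us$table)
  expect_equal(nrow(u3$edges), nrow(unique(us$table[c("mirna", "gene")])))
  expect_error(build_universe(within(tab, evidence <- "qPCR only")), "empty")
})

test_that("top-module miRNA selection follows the documented ranking", {
  mm <- matrix(c(0.9, 0.8, 0.8, 0.4, 0.95), 5, 1,
               dimnames = list(c("mir-a", "mir-b", "mir-c", "mir-d", "tRNA-x"),
                               "green"))
  gs <- setNames(c(0.5, 0.2, 0.6, 0.9, 0.99), rownames(mm))
  st <- list(mm = mm, gs = gs)
  labs <- setNames(rep("green", 5), rownames(mm))
  classes <- c("miRNA", "miRNA", "miRNA", "miRNA", "tRNA_half")
  sel <- select_top_module_mirnas(st, labs, "green", classes, k = 3)
  # hand-sorted: mir-a (0.9), then tie 0.8 broken by GS (mir-c > mir-b)
  expect_equal(sel$ranking$mirna[1:3], c("mir-a", "mir-c", "mir-b"))
  expect_equal(sel$selected, c("mir-a", "mir-c", "mir-b"))
  expect_warning(select_top_module_mirnas(st, labs, "green", classes, k = 10),
                 "only 4")
  expect_error(select_top_module_mirnas(st, labs, "green",
                                        rep("tRNA_half", 5)), "no miRNA")
})

test_that("overtargeting p-values match closed-form and exhaustive enumeration", {
  # 4-miRNA universe, gene hit by 2 of them, both selected: p = 1/6
  tab <- data.frame(mirna = c("m1", "m2", "m1", "m2", "m3", "m4"),
                    gene = c("G", "G", "H1", "H2", "H3", "H4"),
                    evidence = "reporter assay")
  u <- build_universe(tab)
  res <- overtargeting_test(c("m1", "m2"), u)
  expect_equal(res$p[res$gene == "G"], 1 / 6, tolerance = 1e-12)
  # only genes with x >= 1 are tested
  expect_false("H3" %in% res$gene)
  # gene targeted by every miRNA: p = 1
  tab2 <- rbind(tab, data.frame(mirna = c("m3", "m4"), gene = "G",
                                evidence = "reporter assay"))
  res2 <- overtargeting_test("m1", build_universe(tab2))
  expect_equal(res2$p[res2$gene == "G"], 1)
  # exhaustive enumeration over all k-subsets of a <= 12-miRNA universe
  us <- simulate_interaction_universe(sim_config(seed = 7, universe_spec = list(
    n_mirnas = 9, n_genes = 30, background_edge_prob = 0.3,
    planted_gene_count = 4, planted_target_prob = 0.95,
    planted_mirna_count = 3)))
  u3 <- build_universe(us$table)
  k <- 4
  sel <- u3$mirnas[1:k]
  res3 <- overtargeting_test(sel, u3)
  subsets <- combn(u3$n_mirnas, k)
  for (g in res3$gene[1:10]) {
    x_obs <- res3$x[res3$gene == g]
    hits <- which(u3$incidence[g, ])
    n_ge <- sum(apply(subsets, 2, function(s) sum(s %in% hits) >= x_obs))
    expect_equal(res3$p[res3$gene == g], n_ge / ncol(subsets),
                 tolerance = 1e-12)
  }
})

test_that("adding an edge from a selected miRNA never increases the p-value", {
  us <- simulate_interaction_universe(sim_config(seed = 9))
  u <- build_universe(us$table)
  sel <- u$mirnas[1:10]
  res <- overtargeting_test(sel, u)
  g <- res$gene[which(res$x < 10 & res$x >= 1)[1]]
  missing_sel <- setdiff(sel, u$edges$mirna[u$edges$gene == g])
  tab2 <- rbind(us$table,
                data.frame(mirna = missing_sel[1], gene = g,
                           evidence = "reporter assay"))
  res2 <- overtargeting_test(sel, build_universe(tab2))
  expect_lte(res2$p[res2$gene == g], res$p[res$gene == g])
})

test_that("random-set empirical p behaves at its boundaries and under planting", {
  us <- simulate_interaction_universe(sim_config(seed = 13, universe_spec = list(
    n_mirnas = 12, n_genes = 100, background_edge_prob = 0.15,
    planted_gene_count = 10, planted_target_prob = 0.95,
    planted_mirna_count = 6)))
  u <- build_universe(us$table)
  # k = all miRNAs: every draw identical, observed equals it -> p = 1
  res_all <- overtargeting_test(u$mirnas, u)
  rs_all <- random_set_pvalue(u, u$n_mirnas, sum(res_all$significant),
                              n_iter = 200, seed = 1)
  expect_equal(rs_all$empirical_p, 1)
  expect_true(all(rs_all$counts == rs_all$counts[1]))
  # planted overtargeting: small empirical p at modest iteration counts
  sel <- us$truth$planted_mirnas
  res <- overtargeting_test(sel, u)
  rs <- random_set_pvalue(u, length(sel), sum(res$significant),
                          n_iter = 2000, seed = 2)
  expect_lte(rs$empirical_p, 0.05)
  # reproducibility and the n_iter warning
  rs2 <- random_set_pvalue(u, length(sel), sum(res$significant),
                           n_iter = 2000, seed = 2)
  expect_identical(rs$counts, rs2$counts)
  expect_warning(random_set_pvalue(u, 3, 1, n_iter = 50, seed = 1), "100")
})

test_that("empirical p is a valid (super-uniform) Monte-Carlo p", {
  # under the null the raw fraction satisfies P(p <= alpha) <= alpha + eps
  us <- simulate_interaction_universe(sim_config(seed = 17, universe_spec = list(
    n_mirnas = 40, n_genes = 150, background_edge_prob = 0.2,
    planted_gene_count = 0, planted_target_prob = 0.9,
    planted_mirna_count = 0)))
  u <- build_universe(us$table)
  set.seed(5)
  B <- 60
  null_counts <- sncpipe:::simulate_overtarget_counts(u, 8, B, 0.05)
  ps <- vapply(seq_len(B), function(i) {
    random_set_pvalue(u, 8, null_counts[i], n_iter = 400,
                      seed = 1000 + i)$empirical_p
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= alpha), alpha + 2 * sqrt(alpha / B) + 0.05)
  }
})

test_that("network export writes consistent SIF/GraphML/TSV files", {
  tab <- data.frame(mirna = c("m1", "m2", "m1"), gene = c("G1", "G1", "G2"),
                    evidence = "reporter assay")
  u <- build_universe(tab)
  res <- overtargeting_test(c("m1", "m2"), u)
  res$significant <- res$gene == "G1"
  pre <- file.path(tempdir(), "net")
  edges <- export_network(c("m1", "m2"), res, u, pre)
  expect_equal(nrow(edges), 2)  # m1->G1, m2->G1
  expect_equal(length(readLines(paste0(pre, ".sif"))), 2)
  expect_true(file.exists(paste0(pre, ".graphml")))
  # edge count equals sum of x over significant genes
  expect_equal(nrow(edges), sum(res$x[res$significant]))
  # empty network warns but writes files
  res$significant <- rep(FALSE, nrow(res))
  expect_warning(export_network(c("m1"), res, u, file.path(tempdir(), "net0")),
                 "empty")
  expect_equal(length(readLines(file.path(tempdir(), "net0.sif"))), 0)
})

test_that("term enrichment matches hypergeometric enumeration", {
  genes <- sprintf("G%02d", 1:20)
  ann <- data.frame(gene = genes[1:5], term = "T1", term_name = "five genes")
  # query = exactly the term's genes: p = 1 / C(20,5)
  enr <- term_enrichment(genes[1:5], ann, genes)
  expect_equal(enr$p, 1 / choose(20, 5), tolerance = 1e-12)
  # every universe gene carries the term -> p = 1
  annall <- data.frame(gene = genes, term = "T2", term_name = "all")
  expect_equal(term_enrichment(genes[1:4], annall, genes)$p, 1)
  # zero overlap -> p = 1 for the upper tail
  enr0 <- term_enrichment(genes[6:9], ann, genes)
  expect_equal(enr0$p, 1)
  expect_error(term_enrichment(genes[1:2], ann[0, ], genes), "empty")
  expect_error(term_enrichment("NOPE", ann, genes), "outside")
})
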