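test_that("extreme probabilities give exact planted structure", {
  cfg <- synthesis_config(seed = 7, n_proteins = 10,
                          community_sizes = c(5, 5), p_within = 1,
                          p_background = 0)
  g <- gen_ppi(cfg)
  expect_equal(igraph::ecount(g), 20)          # two 5-cliques
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  expect_equal(sort(comp$csize), c(5, 5))
  expect_true(all(igraph::transitivity(g, type = "local") == 1))
})

test_that("background edge count follows its binomial expectation", {
  # small background probability so the activity-weight cap is negligible
  n <- 200; p_bg <- 0.01
  n_pairs <- choose(n, 2) - 2 * choose(5, 2)   # non-community pairs
  expectation <- p_bg * n_pairs
  s3 <- 3 * sqrt(n_pairs * p_bg * (1 - p_bg))
  counts <- vapply(1:20, function(s) {
    cfg <- synthesis_config(seed = s, n_proteins = n,
                            community_sizes = c(5, 5), p_within = 0.9,
                            p_background = p_bg)
    g <- gen_ppi(cfg)
    comm <- unlist(planted_communities(cfg))
    el <- igraph::as_data_frame(g)
    sum(!(el$from %in% comm & el$to %in% comm))
  }, numeric(1))
  expect_true(all(abs(counts - expectation) < s3))
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- synthesis_config(seed = 42, n_proteins = 60,
                          community_sizes = c(8, 8), corpus_size = 50,
                          n_datasets = 2, n_per_group = 3)
  g1 <- gen_ppi(cfg); g2 <- gen_ppi(cfg)
  expect_identical(igraph::as_data_frame(g1), igraph::as_data_frame(g2))
  a1 <- gen_metal_annotations(cfg, g1)
  a2 <- gen_metal_annotations(cfg, g1)
  expect_identical(a1$entries, a2$entries)
  expect_identical(gen_corpus(cfg), gen_corpus(cfg))
  e1 <- gen_expression(cfg); e2 <- gen_expression(cfg)
  expect_identical(e1[[1]]$matrix, e2[[1]]$matrix)
  expect_identical(gen_cohort(cfg), gen_cohort(cfg))
})

test_that("metal annotations exercise the retention filter and multi-metal rule", {
  cfg <- synthesis_config(seed = 3)
  g <- gen_ppi(cfg)
  ann <- gen_metal_annotations(cfg, g)
  sizes <- lengths(ann$entries)
  expect_true(any(sizes < 10))                  # undersized group present
  kept <- group_by_metal(ann, 10)
  expect_false(any(lengths(kept$entries) < 10))
  expect_lt(length(kept$entries), length(ann$entries))
  # at least one protein annotated to two retained metals
  all_p <- unlist(kept$entries)
  expect_true(any(table(all_p) >= 2))
})

test_that("corpus enrichment plants positive PMI with 3-abstract support", {
  cfg <- synthesis_config(seed = 5)
  pdp <- planted_pd_proteins(cfg)
  corpus <- gen_corpus(cfg)
  stats <- count_cooccurrence(corpus, synthetic_protein_names(cfg$n_proteins))
  planted <- stats[stats$symbol %in% pdp, ]
  expect_true(all(planted$n_xy >= 3))
  expect_true(all(planted$pmi > 0))
  # odds 1: no planted association; PMI of observed pairs centred near 0
  cfg0 <- synthesis_config(seed = 5, enrichment_odds = 1, p_mention = 0.05)
  stats0 <- count_cooccurrence(gen_corpus(cfg0),
                               synthetic_protein_names(cfg0$n_proteins))
  expect_lt(abs(mean(stats0$pmi, na.rm = TRUE)), 0.35)
  # a tiny corpus cannot honour the 3-abstract guarantee
  expect_error(gen_corpus(synthesis_config(seed = 5, corpus_size = 4)),
               "corpus too small")
})

test_that("null expression data give uniform per-gene p-values", {
  cfg <- synthesis_config(seed = 11, n_proteins = 60,
                          community_sizes = c(8, 8), n_datasets = 1,
                          n_per_group = 10)
  studies <- gen_expression(cfg, genes = paste0("G", 1:2000),
                            de_genes = character())
  pv <- per_gene_pvalues(studies[[1]])$p
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted DE genes reach significance after Fisher combination", {
  cfg <- synthesis_config(seed = 13)
  studies <- gen_expression(cfg)
  de <- attr(studies, "de_genes")
  meta <- run_meta(studies)
  expect_true(all(meta$significant[meta$gene %in% de]))
  # effect 2, n=20/20, noise 1: per-study noncentrality ~ 6.3
  expect_true(all(meta$p[meta$gene %in% de] < 1e-6))
})

test_that("cohort marginals match the configured summary table", {
  cfg <- synthesis_config(seed = 17)
  cohort <- gen_cohort(cfg)
  ref <- pd_metal_reference()
  ca <- ref[ref$fluid == "serum" & ref$metal == "calcium", ]
  x <- cohort$serum_calcium[cohort$group == "control"]
  se <- ca$control_sd / sqrt(ca$n_per_group)
  expect_lt(abs(mean(x) - ca$control_mean), 3 * se)
  expect_equal(sum(!is.na(cohort$csf_iron[cohort$group == "PD"])), 42)
})

test_that("copula correlations are realized and invalid matrices rejected", {
  cc <- data.frame(var1 = "serum_copper", var2 = "dct_b2m", rho = 0.9)
  cfg <- synthesis_config(seed = 19, cohort_correlations = cc)
  cohort <- gen_cohort(cfg)
  dct <- cohort$ct_b2m - cohort$ct_actb
  r <- cor(cohort$serum_copper[cohort$group == "control"],
           dct[cohort$group == "control"])
  expect_gt(r, 0.8); expect_lt(r, 0.97)
  bad <- data.frame(var1 = c("serum_copper", "serum_copper", "serum_iron"),
                    var2 = c("serum_iron", "dct_b2m", "dct_b2m"),
                    rho = c(0.9, 0.9, -0.9))
  expect_error(gen_cohort(synthesis_config(cohort_correlations = bad)),
               "positive semi-definite")
})
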