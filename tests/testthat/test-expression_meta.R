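make_study <- function(m, groups, batch = "b1") {
  expression_study(m, groups, batch)
}

test_that("normalization heuristic and override behave as documented", {
  m <- matrix(c(1024, 2, 4, 8, 512, 256, 64, 128), 2, 4,
              dimnames = list(c("G1", "G2"), paste0("S", 1:4)))
  st <- make_study(m, c("control", "control", "case", "case"))
  out <- normalize_dataset(st)
  expect_equal(out$matrix["G1", "S1"], 10)      # log2(1024)
  low <- make_study(m / 100, c("control", "control", "case", "case"))
  expect_message(out2 <- normalize_dataset(low), "passthrough")
  expect_equal(out2$matrix, low$matrix)
  out3 <- normalize_dataset(low, force = TRUE)
  expect_equal(out3$matrix, log2(low$matrix))
  m[1, 1] <- -1
  bad <- make_study(m, c("control", "control", "case", "case"))
  expect_error(normalize_dataset(bad, force = TRUE), "G1")
})

test_that("per-gene tests agree with stats::t.test on both variants", {
  set.seed(5)
  m <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:20)))
  groups <- rep(c("control", "case"), each = 10)
  st <- make_study(m, groups)
  for (variant in c("pooled", "welch")) {
    res <- per_gene_pvalues(st, variant = variant)
    for (g in c("G1", "G5", "G10")) {
      tt <- t.test(m[g, groups == "case"], m[g, groups == "control"],
                   var.equal = variant == "pooled")
      expect_equal(res$p[res$gene == g], tt$p.value, tolerance = 1e-12)
    }
  }
  # constant gene convention
  m["G1", ] <- 3
  res <- per_gene_pvalues(make_study(m, groups))
  expect_equal(res$p[res$gene == "G1"], 1)
})

test_that("null simulations are calibrated and planted shifts detected", {
  set.seed(6)
  n_genes <- 2500
  m <- matrix(rnorm(n_genes * 20), n_genes, 20,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", 1:20)))
  groups <- rep(c("control", "case"), each = 10)
  res <- per_gene_pvalues(make_study(m, groups))
  fpr <- mean(res$p <= 0.05)
  expect_gte(fpr, 0.03); expect_lte(fpr, 0.07)
  # 3-pooled-SD shift at n = 10/10: noncentrality ~ 6.7
  # power at alpha 0.001 with noncentrality ~ 6.7 is near 1 but not 1
  m2 <- m[1:20, ]
  m2[, groups == "case"] <- m2[, groups == "case"] + 3
  res2 <- per_gene_pvalues(make_study(m2, groups))
  expect_gte(mean(res2$p < 0.001), 0.9)
  expect_true(all(res2$p < 0.05))
})

test_that("Fisher combination matches its chi-square closed forms", {
  one <- fisher_combine(0.05)
  expect_equal(one$p, 0.05, tolerance = 1e-14)   # k = 1 identity
  pair <- fisher_combine(c(0.05, 0.05))
  expect_equal(pair$X, 11.983, tolerance = 1e-3)
  expect_equal(pair$df, 4L)
  expect_equal(pair$p, pchisq(pair$X, 4, lower.tail = FALSE))
  expect_equal(fisher_combine(c(0.2, 1))$X, fisher_combine(0.2)$X)
  expect_error(fisher_combine(c(0.05, 0)), "machine epsilon")
  # identity across magnitudes
  for (p in c(1e-8, 1e-3, 0.5, 1))
    expect_equal(fisher_combine(p)$p, p, tolerance = 1e-12)
})

test_that("meta-analysis combines across studies and is order invariant", {
  cfg <- synthesis_config(seed = 33, n_proteins = 60,
                          community_sizes = c(8, 8), n_datasets = 3,
                          n_per_group = 10)
  studies <- gen_expression(cfg)
  meta1 <- run_meta(studies)
  meta2 <- run_meta(rev(studies))
  expect_equal(meta1, meta2)
  de <- attr(studies, "de_genes")
  expect_true(all(meta1$significant[meta1$gene %in% de]))
  # direction matches the planted signs
  signs <- attr(studies, "de_signs")
  dirs <- meta1$direction[match(names(signs), meta1$gene)]
  expect_equal(dirs, unname(ifelse(signs > 0, "up", "down")))
  # null genes flagged at ~ alpha
  null_genes <- setdiff(meta1$gene, de)
  expect_lt(mean(meta1$significant[meta1$gene %in% null_genes]), 0.15)
})

test_that("a gene measured in one study keeps that study's p-value", {
  set.seed(7)
  m1 <- matrix(rnorm(40), 2, 20,
               dimnames = list(c("G1", "G2"), paste0("S", 1:20)))
  m2 <- matrix(rnorm(40), 2, 20,
               dimnames = list(c("G2", "G3"), paste0("T", 1:20)))
  groups <- rep(c("control", "case"), each = 10)
  studies <- list(make_study(m1, groups, "b1"), make_study(m2, groups, "b2"))
  meta <- run_meta(studies)
  solo <- per_gene_pvalues(studies[[1]])
  expect_equal(meta$p[meta$gene == "G1"], solo$p[solo$gene == "G1"],
               tolerance = 1e-12)
  expect_equal(meta$k[meta$gene == "G2"], 2L)
  unmeasured <- run_meta(studies, genes = c("G1", "ABSENT"))
  expect_equal(unmeasured$direction[unmeasured$gene == "ABSENT"],
               "unmeasured")
})

test_that("batch merging removes offsets and preserves labels", {
  set.seed(8)
  base <- matrix(rnorm(100), 10, 10,
                 dimnames = list(paste0("G", 1:10), paste0("S", 1:10)))
  groups <- rep(c("control", "case"), each = 5)
  s1 <- make_study(base, groups, "b1")
  s2 <- make_study(base + 4, groups, "b2")     # constant offset only
  colnames(s2$matrix) <- paste0("T", 1:10)
  merged <- merge_with_batch_adjust(list(s1, s2))
  for (g in rownames(merged$matrix)) {
    m_by_batch <- tapply(merged$matrix[g, ], merged$batch, mean)
    expect_lt(diff(range(m_by_batch)), 1e-9)
  }
  expect_equal(unname(table(merged$groups)[c("control", "case")]),
               c(10L, 10L), ignore_attr = TRUE)
  # single-sample batch rejected
  tiny <- make_study(base, groups, "b3")
  tiny$matrix <- tiny$matrix[, 1, drop = FALSE]
  tiny$groups <- tiny$groups[1]; tiny$batch <- tiny$batch[1]
  expect_error(merge_with_batch_adjust(list(s1, tiny)), "single sample")
})

test_that("batch-free data survive merging up to a per-gene affine map", {
  set.seed(9)
  cfg <- synthesis_config(seed = 34, n_proteins = 40,
                          community_sizes = c(6, 6), n_datasets = 2,
                          n_per_group = 8, batch_sd = 0)
  studies <- gen_expression(cfg)
  merged <- merge_with_batch_adjust(studies)
  raw <- cbind(studies[[1]]$matrix, studies[[2]]$matrix)
  for (g in rownames(merged$matrix)[1:5]) {
    fit <- cor(merged$matrix[g, ], raw[g, ])
    expect_gt(fit, 0.9)
  }
})
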