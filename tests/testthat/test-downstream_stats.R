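test_that("hypergeometric enrichment matches closed forms", {
  universe <- paste0("U", 1:100)
  sets <- list(hit = universe[1:10], other = universe[51:70])
  res <- hypergeom_enrich(universe[1:10], sets, universe)
  # query equal to the full 10-gene set: unique most-extreme table
  expect_equal(res$p[res$set == "hit"], 1 / choose(100, 10),
               tolerance = 1e-12)
  # zero overlap with a small set in a big universe: p near 1
  res0 <- hypergeom_enrich(universe[1:5], list(s = universe[96:100]),
                           universe)
  expect_gt(res0$p, 0.7)
  # urn check M=20, K=5, n=5, k=3 against the exact tail sum
  uni <- paste0("G", 1:20)
  res3 <- hypergeom_enrich(c(uni[1:3], uni[6:7]), list(s = uni[1:5]), uni)
  exact <- sum(vapply(3:5, function(j)
    choose(5, j) * choose(15, 5 - j), numeric(1))) / choose(20, 5)
  expect_equal(res3$p, exact, tolerance = 1e-12)
  expect_error(hypergeom_enrich("A", sets, character()), "universe")
})

test_that("hypergeometric tail matches exhaustive enumeration for M <= 25", {
  set.seed(10)
  for (i in 1:20) {
    M <- sample(5:25, 1)
    K <- sample(1:M, 1)
    n <- sample(1:M, 1)
    uni <- paste0("g", seq_len(M))
    gene_set <- uni[seq_len(K)]
    query <- sample(uni, n)
    k <- length(intersect(query, gene_set))
    res <- hypergeom_enrich(query, list(s = gene_set), uni)
    # enumerate all possible overlap counts j >= k
    exact <- sum(vapply(k:min(n, K), function(j)
      choose(K, j) * choose(M - K, n - j), numeric(1))) / choose(M, n)
    expect_equal(res$p, exact, tolerance = 1e-10)
  }
})

test_that("BH q-values are monotone and bounded below by p", {
  set.seed(11)
  uni <- paste0("x", 1:50)
  sets <- setNames(lapply(1:8, function(i) sample(uni, 10)),
                   paste0("s", 1:8))
  res <- hypergeom_enrich(sample(uni, 12), sets, uni)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(diff(res$q) >= -1e-12))      # ordered by p
  expect_equal(res$q, p.adjust(res$p, "BH"))
})

test_that("candidate prioritization scores co-annotation similarity", {
  ann <- list(s1 = c("T1", "T2", "C1"), s2 = c("T1", "T2", "C1"),
              s3 = c("T1", "C2"), s4 = c("ZZZ"))
  res <- prioritize_candidates(c("T1", "T2"), c("C1", "C2", "C3"), ann)
  expect_equal(res$candidate, c("C1", "C2", "C3"))
  # hand-computed: profiles T1={s1,s2,s3}, T2={s1,s2}; C1={s1,s2}
  # mean Jaccard(C1) = (2/3 + 1)/2
  expect_equal(res$score[1], mean(c(2 / 3, 1)))
  # C2={s3}: (1/3 + 0)/2
  expect_equal(res$score[2], mean(c(1 / 3, 0)))
  expect_equal(res$score[3], 0)                # no annotation -> 0, flagged
  expect_equal(res$n_annotations[3], 0L)
  # shared-everything candidate ranks first; lexicographic tie-break
  res2 <- prioritize_candidates("T1", c("B", "A"),
                                list(s1 = c("T1", "A", "B")))
  expect_equal(res2$candidate, c("A", "B"))
})

test_that("summary t-tests match raw-data t-tests and textbook values", {
  tt <- ttest_from_summary(summary_stats(10, 2, 16),
                           summary_stats(12, 2, 16), variant = "pooled")
  expect_equal(tt$t, -2.828427, tolerance = 1e-6)
  expect_equal(tt$df, 30)
  expect_equal(tt$p, 0.008257, tolerance = 1e-4)
  eq <- ttest_from_summary(summary_stats(5, 1, 10), summary_stats(5, 1, 10))
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  # agreement with stats::t.test computed from the raw data
  set.seed(12)
  x <- rnorm(14, 3, 2); y <- rnorm(19, 4, 1.5)
  sx <- summary_stats(mean(x), sd(x), length(x))
  sy <- summary_stats(mean(y), sd(y), length(y))
  for (variant in c("welch", "pooled")) {
    ours <- ttest_from_summary(sx, sy, variant = variant)
    ref <- t.test(x, y, var.equal = variant == "pooled")
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the published serum copper row reproduces its bound", {
  ref <- pd_metal_reference()
  cu <- ref[ref$fluid == "serum" & ref$metal == "copper", ]
  tt <- ttest_from_summary(
    summary_stats(cu$control_mean, cu$control_sd, cu$n_per_group),
    summary_stats(cu$pd_mean, cu$pd_sd, cu$n_per_group))
  expect_equal(abs(tt$t), 5.80, tolerance = 0.01)
  expect_lt(tt$p, 0.001)
})

test_that("ddct follows the 2^-ddCt definition", {
  mk_cohort <- function(d_ct_ctrl, d_ct_pd) {
    n <- length(d_ct_ctrl)
    as_cohort_table(data.frame(
      subject = paste0("s", seq_len(2 * n)),
      group = rep(c("control", "PD"), each = n),
      ct_actb = rep(18, 2 * n),
      ct_b2m = 18 + c(d_ct_ctrl, d_ct_pd)))
  }
  same <- ddct(mk_cohort(c(5, 6, 5, 6), c(5, 6, 5, 6)), "B2M")
  expect_equal(same$ddct, 0); expect_equal(same$fold, 1)
  up <- ddct(mk_cohort(c(5, 6, 5, 6), c(4, 5, 4, 5)), "B2M")
  expect_equal(up$ddct, -1); expect_equal(up$fold, 2)
  # hand-computed toy: ddCt = mean(4.5) - mean(6) = -1.5 -> fold 2^1.5
  toy <- ddct(mk_cohort(c(5.5, 6.5, 5.5, 6.5), c(4, 5, 4, 5)), "B2M")
  expect_equal(toy$ddct, -1.5)
  expect_equal(toy$fold, 2^1.5, tolerance = 1e-12)
  expect_error(ddct(mk_cohort(c(5, 6), c(5, 6)), "MISSING"), "ct_missing")
})

test_that("ddct excludes samples with missing Ct and reports the count", {
  tab <- data.frame(subject = paste0("s", 1:8),
                    group = rep(c("control", "PD"), each = 4),
                    ct_actb = 18, ct_b2m = 18 + c(5, 6, 5, NA, 4, 5, 4, 5))
  expect_message(res <- ddct(as_cohort_table(tab), "B2M"), "1 sample")
  expect_equal(res$n_control, 3)
  expect_equal(res$n_excluded, 1)
})

test_that("correlation interdependency handles exact and planted cases", {
  tab <- as_cohort_table(data.frame(
    subject = paste0("s", 1:10), group = rep("control", 10),
    serum_a = 1:10, serum_b = 10:1, serum_c = 1:10))
  res <- interdependency_matrix(tab,
                                pairs = rbind(c("serum_a", "serum_c"),
                                              c("serum_a", "serum_b")))
  expect_equal(res$r[res$var2 == "serum_c"], 1)
  expect_equal(res$r[res$var2 == "serum_b"], -1)
  # planted copula correlation recovered within sampling bounds
  cc <- data.frame(var1 = "serum_copper", var2 = "dct_sod1", rho = -0.7)
  cohort <- gen_cohort(synthesis_config(seed = 44,
                                        cohort_correlations = cc))
  cohort$dct_sod1_obs <- cohort$ct_sod1 - cohort$ct_actb
  res2 <- interdependency_matrix(cohort,
                                 pairs = rbind(c("serum_copper",
                                                 "dct_sod1_obs")))
  r_ctrl <- res2$r[res2$group == "control"]
  expect_gt(r_ctrl, -0.85); expect_lt(r_ctrl, -0.5)
  # too few complete pairs -> not computable
  tab$serum_a[1:8] <- NA
  res3 <- interdependency_matrix(tab,
                                 pairs = rbind(c("serum_a", "serum_b")))
  expect_true(is.na(res3$r))
})
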