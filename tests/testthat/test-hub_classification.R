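# small separable two-class expression study for classifier checks
separable_study <- function(n_per_group = 30, n_genes = 6, gap = 5,
                            seed = 1) {
  set.seed(seed)
  genes <- paste0("G", seq_len(n_genes))
  ctrl <- matrix(rnorm(n_genes * n_per_group), n_genes)
  case <- matrix(rnorm(n_genes * n_per_group, gap), n_genes)
  m <- cbind(ctrl, case)
  rownames(m) <- genes
  colnames(m) <- paste0("S", seq_len(2 * n_per_group))
  expression_study(m, rep(c("control", "case"), each = n_per_group))
}

test_that("hub feature extraction reports missing genes deterministically", {
  st <- separable_study()
  hub <- new_hub(members = c("G3", "G1", "G5", "G2", "G4", "G6"))
  f <- extract_hub_features(st, hub)
  expect_equal(colnames(f$X), paste0("G", 1:6))   # lexicographic
  expect_equal(nrow(f$X), 60)
  hub2 <- new_hub(members = c("G1", "G2", "G3", "G4", "NOPE1", "NOPE2"))
  expect_warning(f2 <- extract_hub_features(st, hub2), "NOPE1")
  expect_equal(ncol(f2$X), 4)
  expect_setequal(f2$missing, c("NOPE1", "NOPE2"))
  expect_error(extract_hub_features(st, new_hub(members = c("NO", "WAY"))),
               "no gene")
})

test_that("MCC matches its closed form and conventions", {
  expect_equal(mcc(5, 5, 0, 0), 1)
  expect_equal(mcc(0, 0, 5, 5), -1)
  expect_equal(mcc(10, 0, 5, 0), 0)              # one-class predictions
  expect_equal(mcc(3, 4, 1, 2), 10 / sqrt(600))
  expect_error(mcc(0, 0, 0, 0), "empty")
})

test_that("cross-validation separates separable data for every algorithm", {
  st <- separable_study()
  f <- extract_hub_features(st, new_hub(members = paste0("G", 1:6)))
  for (alg in classifier_roster()) {
    rep <- crossval_classify(f$X, f$y, alg, folds = 5, repeats = 2,
                             seed = 11)
    expect_gte(rep$accuracy, 0.95)
  }
})

test_that("permuted labels give chance-level accuracy", {
  st <- separable_study(n_per_group = 25, gap = 0, seed = 3)
  f <- extract_hub_features(st, new_hub(members = paste0("G", 1:6)))
  rep <- crossval_classify(f$X, f$y, "lda", folds = 5, repeats = 4, seed = 5)
  n <- length(f$y)
  majority <- max(table(f$y)) / n
  se <- sqrt(majority * (1 - majority) / (n * 4))
  expect_lt(abs(rep$accuracy - majority), 3 * se + 0.1)
})

test_that("cross-validation is seeded and internally consistent", {
  st <- separable_study(seed = 4)
  f <- extract_hub_features(st, new_hub(members = paste0("G", 1:6)))
  r1 <- crossval_classify(f$X, f$y, "random_forest", folds = 4,
                          repeats = 2, seed = 9)
  r2 <- crossval_classify(f$X, f$y, "random_forest", folds = 4,
                          repeats = 2, seed = 9)
  expect_identical(r1[c("tp", "tn", "fp", "fn")],
                   r2[c("tp", "tn", "fp", "fn")])
  # pooled metrics are mutually consistent
  with(r1, {
    P <- tp + fn; N <- tn + fp
    expect_equal(accuracy, (sensitivity * P + specificity * N) / (P + N))
    expect_equal(mcc, metallonet::mcc(tp, tn, fp, fn))
  })
  expect_error(crossval_classify(f$X, f$y, "quantum_forest"), "roster")
  expect_error(crossval_classify(f$X, f$y, "lda", folds = 40), "folds")
})

test_that("cross-validation matches a hand-rolled no-leakage oracle", {
  st <- separable_study(n_per_group = 12, gap = 1.2, seed = 6)
  f <- extract_hub_features(st, new_hub(members = paste0("G", 1:6)))
  rep <- crossval_classify(f$X, f$y, "lda", folds = 3, repeats = 1,
                           seed = 21)
  # oracle: same fold construction, training-only standardization, lda
  X <- f$X; y <- f$y
  set.seed(21L)
  fold_id <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(1:3, length(idx))
  }
  tp <- tn <- fp <- fn <- 0
  for (fold in 1:3) {
    test <- fold_id == fold
    mu <- colMeans(X[!test, ]); sdv <- apply(X[!test, ], 2, sd)
    xtr <- scale(X[!test, ], mu, sdv); xte <- scale(X[test, ], mu, sdv)
    pred <- predict(MASS::lda(xtr, grouping = y[!test]), xte)$class
    tp <- tp + sum(pred == "case" & y[test] == "case")
    tn <- tn + sum(pred == "control" & y[test] == "control")
    fp <- fp + sum(pred == "case" & y[test] == "control")
    fn <- fn + sum(pred == "control" & y[test] == "case")
  }
  expect_equal(unlist(rep[c("tp", "tn", "fp", "fn")]),
               c(tp = tp, tn = tn, fp = fp, fn = fn))
})

test_that("stratified folds keep the class ratio within one sample", {
  y <- factor(rep(c("control", "case"), c(18, 27)),
              levels = c("control", "case"))
  set.seed(2)
  fold_id <- metallonet:::stratified_folds(y, 9)
  for (f in 1:9) {
    tab <- table(y[fold_id == f])
    expect_equal(unname(tab[["control"]]), 2)
    expect_equal(unname(tab[["case"]]), 3)
  }
})

test_that("hub ranking orders by accuracy with planted informative panels", {
  rep_row <- function(hub, acc, mcc = acc)
    data.frame(hub = hub, algorithm = paste0("a", 1:4),
               n_features = 5, sensitivity = acc, specificity = acc,
               accuracy = acc, mcc = mcc)
  reports <- rbind(rep_row("good", 0.9), rep_row("bad", 0.5))
  rk <- rank_hubs(reports, top_k = 1)
  expect_equal(rk$hub, c("good", "bad"))
  expect_equal(rk$selected, c(TRUE, FALSE))
  rk2 <- rank_hubs(reports, top_k = 10)
  expect_true(all(rk2$selected))               # top_k larger than hub count
})

test_that("informative hubs outrank noise hubs on planted expression", {
  wins <- 0L
  for (s in 1:3) {
    cfg <- synthesis_config(seed = 40 + s)
    studies <- gen_expression(cfg)
    merged <- merge_with_batch_adjust(studies)
    de <- attr(studies, "de_genes")
    null_genes <- setdiff(rownames(merged$matrix), de)
    set.seed(s)
    hubs <- c(
      setNames(lapply(1:3, function(i)
        new_hub(members = sample(de, 6))), paste0("info", 1:3)),
      setNames(lapply(1:5, function(i)
        new_hub(members = sample(null_genes, 6))), paste0("noise", 1:5)))
    reports <- evaluate_hubs(merged, hubs,
                             roster = c("lda", "logistic", "naive_bayes",
                                        "knn"),
                             folds = 5, repeats = 1, seed = s)
    rk <- rank_hubs(reports, top_k = 3)
    if (all(grepl("^info", rk$hub[1:3]))) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
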