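#' Log2-normalize an expression study
#'
#' Microarray series arrive either as raw intensities or already
#' log-transformed; a simple heuristic (maximum value > 50) decides, and
#' `force` overrides it. Raw intensities must be positive.
#'
#' @param study an [expression_study()].
#' @param force `NA` (heuristic), `TRUE` (always log2) or `FALSE` (never).
#' @return The study on log2 scale with `normalized = TRUE`.
#' @export
normalize_dataset <- function(study, force = NA) {
  m <- study$matrix
  do_log <- if (is.na(force)) max(m, na.rm = TRUE) > 50 else isTRUE(force)
  if (do_log) {
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("nonpositive raw intensity at e.g. gene ",
           rownames(m)[bad[1, 1]], ", sample ", colnames(m)[bad[1, 2]],
           " (", nrow(bad), " cell(s))")
    study$matrix <- log2(m)
  } else {
    message("values look already log-scaled; passthrough")
  }
  study$normalized <- TRUE
  study
}

#' Per-gene two-sample t-test p-values for one study
#'
#' Two-sided two-sample t-test of case vs control per gene on log2
#' intensities (pooled variance by default, Welch optional), with the
#' effect sign `sign(case mean - control mean)`. A gene with zero variance
#' in both groups and equal means gets `p = 1` by convention.
#'
#' @param study an [expression_study()].
#' @param variant `"pooled"` or `"welch"`.
#' @return data.frame: `gene`, `p`, `sign`, `delta` (case - control mean).
#' @export
per_gene_pvalues <- function(study, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  m <- study$matrix
  case <- m[, study$groups == "case", drop = FALSE]
  ctrl <- m[, study$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
  delta <- m1 - m2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(m))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- delta / se
  p <- 2 * pt(-abs(t), df)
  degenerate <- se == 0
  p[degenerate & delta == 0] <- 1          # constant gene convention
  p[degenerate & delta != 0] <- 0 + .Machine$double.xmin
  data.frame(gene = rownames(m), p = unname(p),
             sign = sign(unname(delta)), delta = unname(delta),
             stringsAsFactors = FALSE)
}

#' Combine p-values by Fisher's method
#'
#' `X = -2 * sum(log(p_i))` referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom. With a single p-value the
#' combination is the identity.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return List: `X`, `df`, `p`.
#' @export
fisher_combine <- function(pvals) {
  stopifnot(length(pvals) >= 1)
  if (any(pvals <= 0))
    stop("p = 0 input; floor p-values at machine epsilon before combining")
  if (any(pvals > 1)) stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(pvals))
  k <- length(pvals)
  list(X = X, df = 2L * k, p = pchisq(X, df = 2 * k, lower.tail = FALSE))
}

#' Meta-analysis of genes across expression studies
#'
#' Per gene, collects the per-study two-sample t-test p-values and effect
#' signs from every study measuring it, combines them with Fisher's
#' method, and calls a direction: `up`/`down` when all studies significant
#' at `alpha` agree in sign (all studies' signs when none is individually
#' significant), otherwise `discordant`. With `significant_only = TRUE`
#' only per-study p-values at or below `alpha` enter the combination (the
#' literal reading of combining "significant" p-values); genes with no
#' significant study are then reported with `p = NA`.
#'
#' @param studies list of [expression_study()] objects.
#' @param genes genes to analyze; default: union over studies.
#' @param alpha significance level (default 0.05).
#' @param variant t-test variant, see [per_gene_pvalues()].
#' @param significant_only combine only per-study p <= alpha.
#' @return data.frame: gene, k (studies measuring it), X, df, p,
#'   direction, significant. Genes measured nowhere get `k = 0` and NA
#'   statistics.
#' @export
run_meta <- function(studies, genes = NULL, alpha = 0.05,
                     variant = "pooled", significant_only = FALSE) {
  stopifnot(length(studies) >= 2)
  per <- lapply(studies, per_gene_pvalues, variant = variant)
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(per, `[[`, "gene"))))
  genes <- sort(unique(clean_symbols(genes)))
  res <- lapply(genes, function(g) {
    ps <- numeric(); sg <- numeric()
    for (d in per) {
      i <- match(g, d$gene)
      if (!is.na(i)) { ps <- c(ps, d$p[i]); sg <- c(sg, d$sign[i]) }
    }
    k <- length(ps)
    if (k == 0L)
      return(data.frame(gene = g, k = 0L, X = NA_real_, df = NA_integer_,
                        p = NA_real_, direction = "unmeasured",
                        significant = FALSE, stringsAsFactors = FALSE))
    use <- if (significant_only) ps <= alpha else rep(TRUE, k)
    if (!any(use))
      return(data.frame(gene = g, k = k, X = NA_real_, df = NA_integer_,
                        p = NA_real_, direction = "ns",
                        significant = FALSE, stringsAsFactors = FALSE))
    fc <- fisher_combine(pmax(ps[use], .Machine$double.xmin))
    sig_signs <- sg[ps <= alpha]
    dir_signs <- if (length(sig_signs)) sig_signs else sg
    direction <- if (all(dir_signs > 0)) "up"
    else if (all(dir_signs < 0)) "down" else "discordant"
    data.frame(gene = g, k = k, X = fc$X, df = fc$df, p = fc$p,
               direction = direction, significant = fc$p <= alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Merge studies with location-scale batch adjustment
#'
#' Restricts to the genes shared by all studies, concatenates samples, and
#' removes additive/multiplicative batch effects per gene: within each
#' batch the gene is centered and scaled, then the pooled mean and SD are
#' restored. This is a transparent location-scale counterpart of
#' empirical-Bayes batch adjustment: after it, per-gene within-batch means
#' are identical across batches. Group labels are preserved and the batch
#' of origin recorded.
#'
#' @param studies list of [expression_study()] objects (each becomes one
#'   batch; every batch needs >= 2 samples).
#' @return A merged [expression_study()].
#' @export
merge_with_batch_adjust <- function(studies) {
  stopifnot(length(studies) >= 1)
  shared <- Reduce(intersect, lapply(studies, function(s) rownames(s$matrix)))
  if (length(shared) == 0L) stop("no gene shared by all studies")
  shared <- sort(shared)
  mats <- list(); groups <- character(); batch <- character()
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    if (ncol(s$matrix) < 2L) stop("batch with a single sample: study ", i)
    b <- unique(s$batch)
    bid <- if (length(b) == 1L) b else paste0("study", i)
    m <- s$matrix[shared, , drop = FALSE]
    colnames(m) <- paste0(bid, ".", colnames(m))
    mats[[i]] <- m
    groups <- c(groups, unname(s$groups))
    batch <- c(batch, rep(bid, ncol(m)))
  }
  merged <- do.call(cbind, mats)
  pooled_mean <- rowMeans(merged)
  pooled_sd <- apply(merged, 1, sd)
  adj <- merged
  for (b in unique(batch)) {
    cols <- batch == b
    mb <- rowMeans(merged[, cols, drop = FALSE])
    sb <- apply(merged[, cols, drop = FALSE], 1, sd)
    sb[sb == 0] <- 1                     # flat within batch: center only
    adj[, cols] <- (merged[, cols, drop = FALSE] - mb) / sb
  }
  adj <- adj * pooled_sd + pooled_mean
  expression_study(adj, groups, batch, platform = "merged",
                   normalized = TRUE)
}
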