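#' Hypergeometric (over-representation) enrichment against gene sets
#'
#' Classic urn model per gene set: upper-tail hypergeometric probability
#' of drawing at least the observed overlap when `n` query genes are drawn
#' from a universe of `M` genes of which `K` belong to the set, followed
#' by Benjamini-Hochberg adjustment across sets.
#'
#' @param query gene set of interest (e.g. hub proteins); members outside
#'   the universe are reported and dropped.
#' @param gene_sets named list from [read_gene_sets()].
#' @param universe background gene universe.
#' @return data.frame per set: `set`, `k` (overlap), `K` (set size in
#'   universe), `n` (query size), `M` (universe size), `p`, `q` (BH),
#'   `genes` (overlap, comma-joined); ordered by p.
#' @export
hypergeom_enrich <- function(query, gene_sets, universe) {
  universe <- unique(clean_symbols(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(clean_symbols(query))
  outside <- setdiff(query, universe)
  if (length(outside))
    warning(length(outside), " query gene(s) outside universe dropped: ",
            paste(head(outside, 5), collapse = ", "))
  query <- intersect(query, universe)
  n <- length(query)
  M <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(clean_symbols(gene_sets[[nm]])), universe)
    K <- length(set)
    hit <- intersect(query, set)
    k <- length(hit)
    p <- if (K == 0L || n == 0L) 1 else
      phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, M = M, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), c("set", "k", "K", "n", "M", "p", "q", "genes")]
}

#' Rank candidate proteins by annotation similarity to a training set
#'
#' A transparent co-annotation prioritizer: each protein's profile is the
#' set of annotation gene sets containing it; a candidate's score is the
#' mean Jaccard similarity between its profile and each training protein's
#' profile. Candidates with no annotation score 0 and are flagged. This is
#' a deliberately simple stand-in for web-service functional
#' prioritization, chosen for determinism and auditability.
#'
#' @param training nonempty training protein set (e.g. text-mined disease
#'   proteins excluding hub members).
#' @param candidates proteins to rank (e.g. one hub's members).
#' @param annotations named list of annotation gene sets (GMT).
#' @return data.frame in rank order: `candidate`, `score`, `n_annotations`,
#'   `rank` (ties broken lexicographically).
#' @export
prioritize_candidates <- function(training, candidates, annotations) {
  training <- unique(clean_symbols(training))
  candidates <- unique(clean_symbols(candidates))
  stopifnot(length(training) > 0)
  profile <- function(p) names(annotations)[vapply(annotations, function(s)
    p %in% s, logical(1))]
  tr_prof <- lapply(training, profile)
  jac <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0L) 0 else length(intersect(a, b)) / length(u)
  }
  score <- vapply(candidates, function(cand) {
    pc <- profile(cand)
    if (length(pc) == 0L) return(0)
    mean(vapply(tr_prof, function(tp) jac(pc, tp), numeric(1)))
  }, numeric(1))
  n_ann <- vapply(candidates, function(cand) length(profile(cand)),
                  integer(1))
  out <- data.frame(candidate = candidates, score = unname(score),
                    n_annotations = unname(n_ann), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$candidate), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Two-sample t-test from printed summary statistics
#'
#' Computes the two-sided two-sample t-test directly from (mean, SD, n)
#' pairs, as needed to audit published cohort tables. Welch
#' (Satterthwaite) by default; pooled-variance variant available.
#'
#' @param a,b [summary_stats()] objects (or lists with mean/sd/n).
#' @param variant `"welch"` or `"pooled"`.
#' @return List: `t`, `df`, `p`. Equal means with both SDs zero give
#'   `t = 0, p = 1` by convention.
#' @export
ttest_from_summary <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(a$n >= 2, b$n >= 2, a$sd >= 0, b$sd >= 0)
  if (a$sd == 0 && b$sd == 0) {
    if (a$mean == b$mean) return(list(t = 0, df = a$n + b$n - 2, p = 1))
    stop("both SDs zero with unequal means: t undefined")
  }
  if (variant == "welch") {
    se2 <- a$sd^2 / a$n + b$sd^2 / b$n
    t <- (a$mean - b$mean) / sqrt(se2)
    df <- se2^2 / ((a$sd^2 / a$n)^2 / (a$n - 1) +
                     (b$sd^2 / b$n)^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Reference cohort metal summary table
#'
#' The published serum and CSF metal concentration summaries (mean, SD in
#' ug/L; n = 87 per group for serum, 42 for CSF) with the printed p-value
#' bounds, used both as the default targets of the synthetic cohort
#' generator and as input to the summary t-test audit.
#'
#' @return data.frame: fluid, metal, control_mean, control_sd, pd_mean,
#'   pd_sd, n_per_group, printed_p_bound.
#' @export
pd_metal_reference <- function() {
  data.frame(
    fluid = rep(c("serum", "csf"), each = 5),
    metal = rep(c("aluminum", "calcium", "copper", "iron", "magnesium"), 2),
    control_mean = c(4.11, 64825, 1133, 1265, 20031,
                     3.12, 26291.15, 27, 221, 23030),
    control_sd = c(1.52, 1514, 127, 439, 1923,
                   0.886, 5411.9, 4.78, 28, 2659),
    pd_mean = c(4.755, 72303, 909, 1091, 21276,
                2.43, 28447.38, 24.4, 172, 25466),
    pd_sd = c(1.4, 1720, 337, 434, 1915,
              1.42, 3378.10, 8.06, 83.8, 3512),
    n_per_group = rep(c(87L, 42L), each = 5),
    printed_p_bound = c(0.02, 0.001, 0.001, 0.009, 0.0006,
                        0.03, 0.03, 0.029, 0.002, 0.00055),
    stringsAsFactors = FALSE)
}

#' Audit a cohort summary table with two-sample t-tests
#'
#' Recomputes the group-comparison t-test for every analyte row of a
#' summary table in the format of [pd_metal_reference()] and reports
#' whether the computed p-value respects the printed bound. Rows whose
#' printed bound cannot be reproduced from their own summaries are flagged
#' (`reproduced = FALSE`), not altered.
#'
#' @param reference summary table, default [pd_metal_reference()].
#' @param variant t-test variant, see [ttest_from_summary()].
#' @return The table with `t`, `df`, `p` and `reproduced` appended.
#' @export
audit_metal_table <- function(reference = pd_metal_reference(),
                              variant = "welch") {
  res <- t(vapply(seq_len(nrow(reference)), function(i) {
    r <- reference[i, ]
    tt <- ttest_from_summary(
      summary_stats(r$control_mean, r$control_sd, r$n_per_group),
      summary_stats(r$pd_mean, r$pd_sd, r$n_per_group), variant = variant)
    c(tt$t, tt$df, tt$p)
  }, numeric(3)))
  reference$t <- res[, 1]
  reference$df <- res[, 2]
  reference$p <- res[, 3]
  reference$reproduced <- reference$p <= reference$printed_p_bound
  reference
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)` (reference: a
#' housekeeping gene such as beta-actin); `ddCt` is the PD-minus-control
#' difference of group mean dCt; the fold change is `2^-ddCt` (so
#' `ddCt = -1` means 2-fold upregulation in PD). The group comparison
#' p-value is a two-sided t-test on the per-sample dCt values.
#'
#' @param cohort a [as_cohort_table()] data.frame with `ct_<gene>` columns.
#' @param target target gene symbol (column `ct_<target>`).
#' @param reference housekeeping gene symbol (default `ACTB`).
#' @return List of class `ddct_result`: gene, mean dCt per group, ddct,
#'   fold, p, n per group (samples with missing Ct excluded, count
#'   reported).
#' @export
ddct <- function(cohort, target, reference = "ACTB") {
  tcol <- paste0("ct_", tolower(target))
  rcol <- paste0("ct_", tolower(reference))
  if (!tcol %in% names(cohort)) stop("missing Ct column: ", tcol)
  if (!rcol %in% names(cohort)) stop("missing Ct column: ", rcol)
  d_ct <- cohort[[tcol]] - cohort[[rcol]]
  ok <- !is.na(d_ct)
  n_excluded <- sum(!ok)
  if (n_excluded) message(n_excluded, " sample(s) excluded for missing Ct")
  d_ct <- d_ct[ok]
  grp <- cohort$group[ok]
  m_pd <- mean(d_ct[grp == "PD"])
  m_ctrl <- mean(d_ct[grp == "control"])
  dd <- m_pd - m_ctrl
  p <- tryCatch(stats::t.test(d_ct[grp == "PD"],
                              d_ct[grp == "control"])$p.value,
                error = function(e) NA_real_)
  structure(list(gene = toupper(target), reference = toupper(reference),
                 dct_control = m_ctrl, dct_pd = m_pd, ddct = dd,
                 fold = 2^(-dd), p = p,
                 n_control = sum(grp == "control"), n_pd = sum(grp == "PD"),
                 n_excluded = n_excluded),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("%s vs %s: ddCt = %.3f, fold = %.3f (%s in PD), p = %.4g\n",
              x$gene, x$reference, x$ddct, x$fold,
              if (x$fold > 1) "up" else if (x$fold < 1) "down" else "flat",
              x$p))
  invisible(x)
}

#' Pairwise correlation interdependency analysis
#'
#' Correlation between measured variables of a cohort table — serum vs CSF
#' metal concentrations, metal concentration vs gene-expression dCt — with
#' pairwise-complete deletion and a two-sided test per pair. Pairs with
#' fewer than 3 complete observations are reported as not computable.
#'
#' @param cohort a [as_cohort_table()] data.frame.
#' @param pairs 2-column matrix or list of length-2 character vectors of
#'   column names; default: all pairs of numeric analyte/Ct columns.
#' @param method `"pearson"` or `"spearman"`.
#' @param by_group if `TRUE`, one row per pair per cohort group.
#' @return data.frame: group, var1, var2, n, r, p (r/p `NA` when not
#'   computable).
#' @export
interdependency_matrix <- function(cohort, pairs = NULL,
                                   method = c("pearson", "spearman"),
                                   by_group = TRUE) {
  method <- match.arg(method)
  if (is.null(pairs)) {
    vars <- grep("^(serum|csf|ct)_", names(cohort), value = TRUE)
    pairs <- t(combn(vars, 2))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  groups <- if (by_group) unique(cohort$group) else "all"
  rows <- list()
  for (g in groups) {
    sub <- if (identical(g, "all")) cohort else cohort[cohort$group == g, ]
    for (i in seq_len(nrow(pairs))) {
      v1 <- pairs[i, 1]; v2 <- pairs[i, 2]
      x <- sub[[v1]]; y <- sub[[v2]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, var1 = v1, var2 = v2, n = n, r = NA_real_,
          p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, var1 = v1, var2 = v2, n = n,
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
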