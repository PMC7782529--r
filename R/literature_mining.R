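#' Count protein/disease co-occurrence across an abstract corpus
#'
#' Tokenizes each document on non-word boundaries and counts, per protein
#' symbol, the number of documents mentioning the symbol (`n_x`), the
#' disease (`n_y`), and both (`n_xy`). Symbol matching is exact uppercase
#' token matching (gene symbols collide with English words under
#' case-insensitive matching); disease terms are matched case-insensitively
#' as phrases. A document counts once however many times a term repeats.
#'
#' @param corpus named character vector or list, document ID -> text.
#' @param symbols protein symbols to score.
#' @param disease_terms disease phrases (default `"Parkinson's disease"`).
#' @return data.frame, one row per symbol: `symbol`, `n_x`, `n_y`, `n_xy`,
#'   `N`, `pmi` (bits; `NA` when `n_xy = 0`).
#' @export
count_cooccurrence <- function(corpus, symbols,
                               disease_terms = "Parkinson's disease") {
  stopifnot(length(corpus) > 0)
  txt <- unlist(corpus, use.names = FALSE)
  N <- length(txt)
  symbols <- sort(unique(clean_symbols(symbols)))
  toks <- lapply(txt, function(d)
    unique(strsplit(d, "[^A-Za-z0-9'_-]+")[[1]]))
  has_disease <- vapply(txt, function(d)
    any(vapply(disease_terms, function(term)
      grepl(term, d, ignore.case = TRUE, fixed = FALSE), logical(1))),
    logical(1), USE.NAMES = FALSE)
  n_y <- sum(has_disease)
  n_x <- integer(length(symbols))
  n_xy <- integer(length(symbols))
  for (i in seq_along(symbols)) {
    present <- vapply(toks, function(tt) symbols[i] %in% tt, logical(1))
    n_x[i] <- sum(present)
    n_xy[i] <- sum(present & has_disease)
  }
  out <- data.frame(symbol = symbols, n_x = n_x, n_y = n_y, n_xy = n_xy,
                    N = N, stringsAsFactors = FALSE)
  out$pmi <- NA_real_
  pos <- out$n_xy > 0
  if (any(pos))
    out$pmi[pos] <- pmi(out$n_xy[pos], out$n_x[pos], out$n_y[pos], out$N[pos])
  out
}

#' Pointwise mutual information of a co-occurrence count
#'
#' `log2( (n_xy * N) / (n_x * n_y) )` — the log-ratio of the observed
#' document co-occurrence probability to the one expected under
#' independence. Zero at independence; undefined (error) when `n_xy = 0`,
#' which callers must treat distinctly from a low score.
#'
#' @param n_xy documents mentioning both terms (>= 1).
#' @param n_x,n_y documents mentioning each term alone.
#' @param N total documents.
#' @return PMI in bits (vectorized).
#' @export
pmi <- function(n_xy, n_x, n_y, N) {
  if (any(n_xy < 1)) stop("pmi undefined for n_xy = 0")
  stopifnot(all(n_xy <= pmin(n_x, n_y)), all(pmin(n_x, n_y) <= N))
  log2((n_xy * N) / (n_x * n_y))
}

#' Select disease-associated proteins from co-occurrence statistics
#'
#' A protein is called disease-associated when it co-occurs with the
#' disease term in at least `min_docs` abstracts (the study requires three)
#' with PMI above `min_pmi` (default 0: positive association).
#'
#' @param stats data.frame from [count_cooccurrence()].
#' @param min_docs minimum co-occurrence document count.
#' @param min_pmi PMI cutoff (exclusive).
#' @return Character vector of selected symbols (sorted).
#' @export
select_pd_proteins <- function(stats, min_docs = 3, min_pmi = 0) {
  sel <- stats$n_xy >= min_docs & !is.na(stats$pmi) & stats$pmi > min_pmi
  sort(stats$symbol[sel])
}

#' Annotate hubs with literature-mined disease proteins
#'
#' Each hub is tagged with the intersection of its members and the
#' text-mined disease protein set; hubs with at least one such member are
#' retained (the study keeps 18 of 24 top hubs this way).
#'
#' @param hubs list of [new_hub()] objects.
#' @param pd_proteins character vector of disease-associated symbols.
#' @return List: `hubs` (all, annotated via their `pd_proteins` slot) and
#'   `retained` (the subset with a nonempty annotation).
#' @export
annotate_hubs <- function(hubs, pd_proteins) {
  pd_proteins <- clean_symbols(pd_proteins)
  hubs <- lapply(hubs, function(h) {
    h$pd_proteins <- intersect(h$members, pd_proteins)
    h
  })
  list(hubs = hubs,
       retained = hubs[vapply(hubs, function(h)
         length(h$pd_proteins) > 0, logical(1))])
}

#' Read a corpus from a 2-column TSV (doc_id, text) or a directory of .txt
#' @param path TSV path or directory.
#' @return Named character vector, doc ID -> text.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    return(setNames(vapply(files, function(f)
      paste(readLines(f, warn = FALSE), collapse = " "), character(1)),
      sub("\\.txt$", "", basename(files))))
  }
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   quote = "", colClasses = "character")
  stopifnot(ncol(df) >= 2)
  setNames(df[[2]], df[[1]])
}

#' Write a corpus as a 2-column TSV
#' @param corpus named character vector.
#' @param path output path.
#' @export
write_corpus <- function(corpus, path) {
  write.table(data.frame(doc_id = names(corpus),
                         text = unname(unlist(corpus))),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
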