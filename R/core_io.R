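#' @importFrom stats pchisq pt phyper p.adjust prcomp cor cor.test qnorm
#'   rnorm runif rbinom sd var median setNames aggregate predict quantile
#' @importFrom utils read.delim write.table head combn
NULL

# Canonical protein-symbol form: uppercase, whitespace-stripped.  Symbols
# arrive merged from several source databases, so everything is normalised
# on ingestion.
clean_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

#' Construct a protein interaction graph
#'
#' The package represents every network — the reference interactome, each
#' metal protein network, Erdos-Renyi nulls and pathway networks — as an
#' undirected simple [igraph][igraph::igraph-package] graph with a `weight`
#' edge attribute and a `label` graph attribute giving the network class
#' (`"metal"`, `"random"` or `"pathway"`).
#'
#' @param from,to character vectors of endpoint protein symbols.
#' @param weight numeric edge weights (recycled); must be positive.
#' @param nodes optional extra node names (isolated nodes are kept).
#' @param label network class tag.
#' @return An undirected simple igraph object; symmetric duplicates are
#'   collapsed (first weight kept) and self-loops dropped.
#' @export
interaction_graph <- function(from = character(), to = character(),
                              weight = 1, nodes = NULL,
                              label = c("metal", "random", "pathway")) {
  label <- match.arg(label)
  from <- clean_symbols(from)
  to <- clean_symbols(to)
  stopifnot(length(from) == length(to))
  weight <- rep_len(as.numeric(weight), length(from))
  if (any(weight <= 0)) stop("edge weights must be positive")
  loops <- from == to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
  }
  # canonical order so A-B and B-A collapse
  lo <- pmin(from, to); hi <- pmax(from, to)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]; weight <- weight[!dup]
  vnames <- unique(c(lo, hi, clean_symbols(nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, weight = weight,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = vnames))
  g$label <- label
  g
}

#' Read a protein-protein interaction edge list
#'
#' Supports plain two/three-column TSV (`from`, `to`, optional `weight`)
#' and Cytoscape SIF (`from`, `interaction-type`, `to`, further partners).
#' Symmetric duplicate edges are collapsed and self-loops dropped with a
#' message; missing weights default to 1.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"sif"`.
#' @param label network class tag for the result.
#' @return An [interaction_graph()].
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif"),
                           label = "metal") {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty edge-list file: ", path)
    return(interaction_graph(label = label))
  }
  from <- character(); to <- character(); w <- numeric(); iso <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (dialect == "tsv") {
      if (length(tok) == 1L) { # isolated node from a round-tripped graph
        iso <- c(iso, tok[1])
        next
      }
      if (length(tok) < 2L)
        stop("malformed edge line ", i, " in ", path, ": ", lines[i])
      wt <- if (length(tok) >= 3L) suppressWarnings(as.numeric(tok[3])) else 1
      if (is.na(wt))
        stop("malformed weight on line ", i, " in ", path)
      from <- c(from, tok[1]); to <- c(to, tok[2]); w <- c(w, wt)
    } else {
      if (length(tok) == 1L) { # isolated node line is legal SIF
        iso <- c(iso, tok[1])
        next
      }
      if (length(tok) < 3L)
        stop("malformed SIF line ", i, " in ", path, ": ", lines[i])
      for (p in tok[-(1:2)]) {
        from <- c(from, tok[1]); to <- c(to, p); w <- c(w, 1)
      }
    }
  }
  loop <- from == to
  if (any(loop)) message(sum(loop), " self-loop(s) dropped in ", basename(path))
  interaction_graph(from[!loop], to[!loop], w[!loop],
                    nodes = unique(c(iso, from[loop])), label = label)
}

#' Write an interaction graph as a 3-column TSV edge list
#'
#' Isolated nodes are written as single-token lines so that a write/read
#' round trip reproduces node and edge sets exactly.
#'
#' @param graph an [interaction_graph()].
#' @param path output file path.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(el))
    writeLines(paste(el$from, el$to, format(el$weight, trim = TRUE),
                     sep = "\t"), con)
  iso <- igraph::V(graph)$name[igraph::degree(graph) == 0]
  if (length(iso)) writeLines(iso, con)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: per line, set name, description, then member genes,
#'   tab-separated. Gene symbols are uppercased.
#' @return Named list of character vectors. Sets with no genes are skipped
#'   with a warning; a duplicated set name is an error.
#' @export
read_gene_sets <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(tok) < 2L)
      stop("malformed GMT line ", i, " in ", path)
    nm <- trimws(tok[1])
    if (nm %in% names(out)) stop("duplicate gene-set name: ", nm)
    genes <- unique(clean_symbols(tok[-(1:2)]))
    if (length(genes) < 1L) {
      warning("gene set '", nm, "' has no genes; skipped")
      next
    }
    out[[nm]] <- genes
  }
  out
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description column (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Construct an expression study
#'
#' Container for one case/control expression dataset: a genes x samples
#' matrix of (log2) intensities with a group and batch label per sample,
#' mirroring a single microarray series in a multi-cohort meta-analysis.
#'
#' @param matrix numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames).
#' @param groups character/factor per sample, levels `control`/`case`.
#' @param batch single batch (dataset) identifier, or one per sample.
#' @param platform free-text platform note.
#' @param normalized logical; `TRUE` once on log2 scale.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(matrix, groups, batch = "batch1",
                             platform = "", normalized = TRUE) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("matrix must have unique gene rownames")
  if (is.null(colnames(matrix))) stop("matrix must have sample colnames")
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix))
    stop("one group label per sample required")
  bad <- setdiff(unique(groups), c("control", "case"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (any(table(factor(groups, c("control", "case"))) < 2L))
    stop("need >= 2 samples per group")
  batch <- rep_len(as.character(batch), ncol(matrix))
  structure(list(matrix = matrix, groups = setNames(groups, colnames(matrix)),
                 batch = setNames(batch, colnames(matrix)),
                 platform = platform, normalized = normalized),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study: ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples (", sum(x$groups == "control"), " control / ",
      sum(x$groups == "case"), " case), batch(es): ",
      paste(unique(x$batch), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an expression study from a matrix TSV plus a sample sheet
#'
#' @param path TSV with gene IDs in the first column and one column per
#'   sample.
#' @param meta TSV sample sheet with columns `sample`, `group`, `batch`.
#' @return An [expression_study()].
#' @export
read_expression <- function(path, meta) {
  m <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- clean_symbols(m[[1]])
  mat <- as.matrix(m[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(m[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop("non-numeric expression value at gene ", genes[bad[1, 1]],
         ", sample ", colnames(mat)[bad[1, 2]])
  }
  rownames(mat) <- genes
  sheet <- read.delim(meta, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group", "batch") %in% names(sheet)))
  missing_meta <- setdiff(colnames(mat), sheet$sample)
  if (length(missing_meta))
    stop("samples in matrix but not in sheet: ",
         paste(missing_meta, collapse = ", "))
  sheet <- sheet[match(colnames(mat), sheet$sample), ]
  ok <- !is.na(sheet$group) & !is.na(sheet$batch)
  if (any(!ok))
    warning("samples lacking group/batch metadata rejected: ",
            paste(colnames(mat)[!ok], collapse = ", "))
  expression_study(mat[, ok, drop = FALSE], sheet$group[ok], sheet$batch[ok])
}

#' Write an expression study to a matrix TSV plus sample sheet
#' @param study an [expression_study()].
#' @param path,meta output paths for the matrix and the sample sheet.
#' @export
write_expression <- function(study, path, meta) {
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(study$matrix),
                         group = unname(study$groups),
                         batch = unname(study$batch)),
              meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Metal-to-protein annotation table
#'
#' @param entries named list: metal symbol -> character vector of
#'   binding-protein symbols (uppercased, deduplicated). A protein bound to
#'   several metals appears under each of them.
#' @return Object of class `metal_protein_table`.
#' @export
metal_protein_table <- function(entries) {
  stopifnot(is.list(entries), !is.null(names(entries)),
            !anyDuplicated(names(entries)))
  entries <- lapply(entries, function(p) sort(unique(clean_symbols(p))))
  if (any(lengths(entries) == 0L)) stop("empty protein set in annotation table")
  structure(list(entries = entries), class = "metal_protein_table")
}

#' @export
print.metal_protein_table <- function(x, ...) {
  cat("metal_protein_table: ", length(x$entries), " metals, ",
      length(unique(unlist(x$entries))), " distinct proteins\n", sep = "")
  sz <- sort(lengths(x$entries), decreasing = TRUE)
  cat(paste0(names(sz), "(", sz, ")", collapse = " "), "\n")
  invisible(x)
}

#' Read a metal annotation TSV (columns `metal`, `protein`)
#' @param path TSV path.
#' @return A [metal_protein_table()].
#' @export
read_metal_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metal", "protein") %in% names(df)))
  metal_protein_table(split(df$protein, df$metal))
}

#' Write a metal annotation table as TSV
#' @param table a [metal_protein_table()].
#' @param path output path.
#' @export
write_metal_annotations <- function(table, path) {
  df <- data.frame(
    metal = rep(names(table$entries), lengths(table$entries)),
    protein = unlist(table$entries, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary statistics triple (mean, sd, n)
#'
#' Minimal container for a printed cohort summary cell; the input to
#' [ttest_from_summary()].
#'
#' @param mean,sd,n mean, standard deviation (>= 0) and group size (>= 2).
#' @export
summary_stats <- function(mean, sd, n) {
  stopifnot(is.finite(mean), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

#' Read a cohort table (per-subject analyte and Ct columns)
#' @param path TSV with columns `subject`, `group` (control/PD) and numeric
#'   analyte / Ct columns.
#' @return data.frame of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "group") %in% names(df)))
  as_cohort_table(df)
}

#' Mark a data frame as a cohort table
#' @param df data.frame with `subject` and `group` columns; remaining numeric
#'   columns are analyte concentrations (ug/L) or qPCR Ct values (cycles).
#' @export
as_cohort_table <- function(df) {
  stopifnot(all(c("subject", "group") %in% names(df)))
  bad <- setdiff(unique(df$group), c("control", "PD"))
  if (length(bad)) stop("cohort group must be control/PD; got: ",
                        paste(bad, collapse = ", "))
  num <- vapply(df, is.numeric, logical(1))
  conc <- grep("^(serum|csf)_", names(df), value = TRUE)
  if (any(vapply(df[conc], function(x) any(x < 0, na.rm = TRUE), logical(1))))
    stop("negative concentration in cohort table")
  ct <- grep("^ct_", names(df), value = TRUE)
  for (cc in ct)
    if (any(df[[cc]] <= 0 | df[[cc]] >= 45, na.rm = TRUE))
      stop("Ct values must lie in (0, 45): column ", cc)
  class(df) <- c("cohort_table", "data.frame")
  df
}

# md5 digests of a set of files, named by basename (run-manifest helper)
file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  setNames(as.character(tools::md5sum(paths)), basename(paths))
}
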