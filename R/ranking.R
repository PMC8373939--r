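#' Read a per-gene differential-expression statistics table
#'
#' Expects a TSV with a header and at least the columns `gene` and `stat`
#' (a signed per-gene differential statistic such as a Wald Z value);
#' optional columns `lfc` and `pvalue` are carried along.
#'
#' @param path Path to the TSV.
#' @return A data frame with columns `gene`, `stat` and, when present,
#'   `lfc` and `pvalue`.
#' @export
read_de_stats <- function(path) {
  if (!file.exists(path)) stop("stats table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "stat")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("stats table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  df$gene <- trimws(as.character(df$gene))
  df$stat <- as.numeric(df$stat)
  df
}

#' Build the ranked gene list
#'
#' Orders all profiled genes by decreasing magnitude of their differential
#' statistic; position 1 is the most perturbed gene. The ranking metric is
#' `|stat|`, so the direction of regulation does not matter. Records with a
#' non-finite statistic are excluded with a warning; ties in `|stat|` are
#' broken by lexicographic gene id so the order is reproducible.
#'
#' @param records Data frame with columns `gene` and `stat` (as from
#'   [read_de_stats()] or [gene_level_statistic()]).
#' @return A `ranked_gene_list`: list with `genes` (ordered ids), `metric`
#'   (aligned non-increasing weights `|stat|`) and `N` (number of genes).
#' @examples
#' rl <- build_ranked_list(data.frame(gene = c("a", "b", "c"),
#'                                    stat = c(-3.2, 1.1, 2.0)))
#' rl$genes
#' @export
build_ranked_list <- function(records) {
  stopifnot(is.data.frame(records), all(c("gene", "stat") %in% names(records)))
  gene <- trimws(as.character(records$gene))
  stat <- as.numeric(records$stat)
  if (any(!nzchar(gene))) stop("empty gene id in statistics records")
  ok <- is.finite(stat)
  if (!any(ok)) stop("no record has a finite statistic")
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) excluded (non-finite statistic)",
            call. = FALSE)
    gene <- gene[ok]; stat <- stat[ok]
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene id(s): ",
         paste(utils::head(unique(gene[duplicated(gene)]), 5), collapse = ", "))
  }
  metric <- abs(stat)
  ord <- .lex_order(-metric, gene)
  structure(list(genes = gene[ord], metric = metric[ord],
                 N = length(gene)),
            class = "ranked_gene_list")
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat("Ranked gene list: N =", x$N, "genes\n")
  k <- min(5L, x$N)
  cat("  top:", paste(sprintf("%s (%.3g)", x$genes[seq_len(k)],
                              x$metric[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene-by-sample count matrix
#'
#' TSV with a header; first column `gene`, remaining columns samples.
#'
#' @param path Path to the TSV.
#' @return Integer-like matrix with genes as rownames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count matrix not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[[1]] != "gene")
    stop("count matrix ", path, ": first column must be named 'gene'")
  genes <- trimws(as.character(df[[1]]))
  if (anyDuplicated(genes)) stop("duplicate gene ids in count matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("count matrix must be non-negative and finite")
  rownames(m) <- genes
  m
}

#' Read two-group sample labels
#'
#' Headerless two-column TSV: sample id, group label. Exactly two distinct
#' groups are required.
#'
#' @param path Path to the TSV.
#' @return Named character vector of group labels (names are sample ids).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("label file must have exactly 2 columns: ", path)
  labels <- stats::setNames(trimws(as.character(df[[2]])),
                            trimws(as.character(df[[1]])))
  if (length(unique(labels)) != 2)
    stop("label file must define exactly two groups; found ",
         length(unique(labels)))
  labels
}

#' Built-in two-group gene-level statistic
#'
#' A simple consistent per-gene differential statistic, needed so the
#' sample-label permutation mode can recompute the ranking under shuffled
#' labels. Counts are library-size normalized to counts-per-million, a
#' pseudocount of 0.5 is added before taking log2, a Welch two-sample t-test
#' compares the groups, and the two-sided p-value is converted to a standard
#' normal quantile carrying the sign of the mean log2-CPM difference. The
#' reference group is the lexicographically smaller label, so with a
#' `control`/`treated` design the sign is treated minus control, and
#' swapping the two groups negates every statistic. Genes with zero counts
#' in all samples
#' get statistic 0. This is deliberately not a negative-binomial fit: the
#' permutation machinery only needs some statistic recomputable under label
#' shuffles, and users with a proper DE fit should supply its statistics
#' directly.
#'
#' @param counts Gene-by-sample count matrix (rownames are gene ids).
#' @param labels Vector of two group labels, one per column (or a named
#'   vector matched to colnames).
#' @return Data frame with columns `gene`, `stat`, `lfc`.
#' @export
gene_level_statistic <- function(counts, labels) {
  stopifnot(is.matrix(counts))
  if (!is.null(names(labels)) && !is.null(colnames(counts))) {
    miss <- setdiff(colnames(counts), names(labels))
    if (length(miss) > 0)
      stop("no label for sample(s): ", paste(miss, collapse = ", "))
    labels <- labels[colnames(counts)]
  }
  if (length(labels) != ncol(counts))
    stop("need one label per sample column")
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two groups required")
  ia <- which(labels == groups[[1]])
  ib <- which(labels == groups[[2]])
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples for the built-in statistic")
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  cpm <- t(t(counts) / lib) * 1e6
  lcpm <- log2(cpm + 0.5)
  n <- nrow(counts)
  stat <- numeric(n)
  lfc <- numeric(n)
  allzero <- rowSums(counts) == 0
  for (i in seq_len(n)) {
    if (allzero[[i]]) next
    a <- lcpm[i, ia]; b <- lcpm[i, ib]
    d <- mean(b) - mean(a)
    lfc[[i]] <- d
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      stat[[i]] <- if (d == 0) 0 else sign(d) * 38  # beyond any finite quantile
      next
    }
    p <- tryCatch(stats::t.test(b, a)$p.value, error = function(e) 1)
    stat[[i]] <- sign(d) * stats::qnorm(.clamp_p(p) / 2, lower.tail = FALSE)
  }
  data.frame(gene = rownames(counts), stat = stat, lfc = lfc,
             stringsAsFactors = FALSE)
}
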