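#' Signaling pathway perturbation analysis
#'
#' Fits the full four-step pathway perturbation model to a ranked
#' differential-expression gene list and a pathway collection:
#' \enumerate{
#'   \item For every pathway, a weighted running-sum statistic over the
#'     ranked list yields a signed effect score (ES); a permutation null
#'     (gene-set resampling by default, or sample-label reshuffling when a
#'     count matrix is supplied) gives a nominal p-value and a normalized
#'     Z-score.
#'   \item Each Z is weighted by pathway size: `log2(Ng) * Z`.
#'   \item Significant pathways (nominal `p < alpha`) are aggregated per
#'     top-level functional category into a normalized effect score,
#'     `NES = mean(weighted scores) * log2(n_significant)`.
#'   \item The total effect score (TES) is the sum of the category NES.
#' }
#'
#' @param stats Data frame with columns `gene` and `stat` (per-gene signed
#'   differential statistic, e.g. a Wald Z), or NULL when `counts` and
#'   `labels` are given (the built-in two-group statistic is then used).
#' @param collection A `pathway_collection` (see [read_gmt()],
#'   [set_categories()]).
#' @param counts,labels Optional gene-by-sample count matrix and two-group
#'   labels; required for `mode = "sample_label"`, and used to derive
#'   `stats` via [gene_level_statistic()] when `stats` is NULL.
#' @param mode Permutation scheme: `"gene_set"` (default; resample member
#'   genes from the ranked list) or `"sample_label"` (reshuffle condition
#'   labels and recompute statistic and ranking).
#' @param n_perm Number of permutations per pathway (default 500).
#' @param alpha Nominal significance level for the TES filter (default
#'   0.05; no multiplicity correction is applied on this path, but a
#'   Benjamini-Hochberg column is reported).
#' @param seed Integer seed. Per-pathway permutation streams are derived
#'   from it and the pathway id, so results do not depend on evaluation
#'   order.
#' @param min_size Minimum effective pathway size (default 2).
#' @param log_base Base of the size-weighting logarithm (default 2).
#' @param nes_n_plus_one Use `log2(n + 1)` in the category NES.
#' @param matching_sign_z Normalize Z against the matching-sign null
#'   portion only.
#' @param exclude_uncategorized Drop the reserved `"Uncategorized"`
#'   category from the TES sum.
#' @param panel Optional character vector of pathway ids to report Z and p
#'   for (e.g. a cancer-related pathway panel).
#' @param quiet Suppress progress messages.
#' @return An object of class `"sppa"`: a list with components
#'   \describe{
#'     \item{tes}{the total effect score,}
#'     \item{category_scores}{data frame (category, n_pathways,
#'       n_significant, nes),}
#'     \item{pathway_results}{data frame (pathway, size_effective, es,
#'       p_nominal, p_bh, z, es_weighted, significant, degenerate,
#'       categories),}
#'     \item{panel}{panel data frame or NULL,}
#'     \item{provenance}{alpha, n_perm, mode, seed and the other switches.}
#'   }
#' @examples
#' sim <- simulate_pathways(sppa_sim_config(n_genes = 300, n_categories = 2,
#'                                          pathways_per_category = 3,
#'                                          n_planted = 1, seed = 1))
#' de <- simulate_de_stats(sppa_sim_config(n_genes = 300, seed = 1),
#'                         sim$collection, sim$planted)
#' fit <- sppa(de, sim$collection, n_perm = 50, seed = 1, quiet = TRUE)
#' fit
#' @export
sppa <- function(stats = NULL, collection, counts = NULL, labels = NULL,
                 mode = c("gene_set", "sample_label"), n_perm = 500,
                 alpha = 0.05, seed = 1, min_size = 2, log_base = 2,
                 nes_n_plus_one = FALSE, matching_sign_z = FALSE,
                 exclude_uncategorized = FALSE, panel = NULL,
                 quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "pathway_collection"))
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (is.null(stats)) {
    if (is.null(counts) || is.null(labels))
      stop("supply either a stats table or counts + labels")
    stats <- gene_level_statistic(counts, labels)
  }
  if (mode == "sample_label" && (is.null(counts) || is.null(labels)))
    stop("sample_label mode requires counts and labels")

  L <- build_ranked_list(stats)
  collection <- restrict_to_universe(collection, L$genes, min_size = min_size,
                                     quiet = quiet)
  if (length(collection$sets) == 0)
    stop("no pathway survives restriction to the ranked universe")
  if (length(collection$category_of) == 0)
    collection <- set_categories(collection, list())

  perm_rankings <- NULL
  if (mode == "sample_label") {
    .msg("precomputing ", n_perm, " permuted rankings (sample-label mode)",
         quiet = quiet)
    perm_rankings <- permute_rankings(counts, labels, n_perm, seed)
  }

  ids <- names(collection$sets)
  .msg("scoring ", length(ids), " pathways (", mode, " mode, ", n_perm,
       " permutations)", quiet = quiet)
  results <- lapply(ids, function(id) {
    score_pathway(L, collection$sets[[id]], n_perm = n_perm, mode = mode,
                  seed = seed, alpha = alpha, perm_rankings = perm_rankings,
                  matching_sign_z = matching_sign_z, id = id)
  })
  weighted <- lapply(results, weight_effect_score, log_base = log_base)

  cats <- collection$categories
  if (exclude_uncategorized) cats <- setdiff(cats, "Uncategorized")
  cat_scores <- lapply(cats, score_category, weighted = weighted,
                       membership = collection$category_of,
                       nes_n_plus_one = nes_n_plus_one)
  tes <- if (length(cat_scores) > 0) total_effect_score(cat_scores) else 0

  p_nom <- vapply(results, `[[`, numeric(1), "p_nominal")
  pathway_results <- data.frame(
    pathway = ids,
    size_effective = vapply(results, `[[`, integer(1), "size_effective"),
    es = vapply(results, `[[`, numeric(1), "es"),
    p_nominal = p_nom,
    p_bh = stats::p.adjust(p_nom, method = "BH"),
    z = vapply(results, `[[`, numeric(1), "z"),
    es_weighted = vapply(weighted, `[[`, numeric(1), "es_weighted"),
    significant = vapply(results, `[[`, logical(1), "significant"),
    degenerate = vapply(results, `[[`, logical(1), "degenerate"),
    categories = vapply(ids, function(id)
      paste(collection$category_of[[id]], collapse = "|"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  category_scores <- data.frame(
    category = vapply(cat_scores, `[[`, character(1), "category"),
    n_pathways = vapply(cat_scores, `[[`, integer(1), "n_pathways"),
    n_significant = vapply(cat_scores, `[[`, integer(1), "n_significant"),
    nes = vapply(cat_scores, `[[`, numeric(1), "nes"),
    stringsAsFactors = FALSE, row.names = NULL)

  panel_df <- if (!is.null(panel)) panel_report(results, panel) else NULL

  structure(list(
    tes = tes,
    category_scores = category_scores,
    pathway_results = pathway_results,
    panel = panel_df,
    results = results,
    provenance = list(alpha = alpha, n_perm = n_perm, mode = mode,
                      seed = seed, min_size = min_size, log_base = log_base,
                      nes_n_plus_one = nes_n_plus_one,
                      matching_sign_z = matching_sign_z,
                      exclude_uncategorized = exclude_uncategorized,
                      n_genes = L$N, n_pathways = length(ids),
                      n_dropped = collection$n_dropped,
                      version = as.character(utils::packageVersion("sppa")))),
    class = "sppa")
}

#' @export
print.sppa <- function(x, ...) {
  pr <- x$provenance
  cat("Signaling pathway perturbation analysis\n")
  cat(sprintf("  %d genes, %d pathways, %d categories (%s mode, %d permutations, alpha = %g)\n",
              pr$n_genes, pr$n_pathways, nrow(x$category_scores), pr$mode,
              pr$n_perm, pr$alpha))
  cat(sprintf("  significant pathways: %d\n",
              sum(x$pathway_results$significant)))
  cat(sprintf("  Total effect score (TES): %.4f\n", x$tes))
  invisible(x)
}

#' Summarize a pathway perturbation analysis
#'
#' @param object An `sppa` fit.
#' @param n_top Number of top pathways to display (default 10).
#' @param ... Unused.
#' @return `object`, invisibly, after printing category scores and the top
#'   pathways by weighted effect score.
#' @export
summary.sppa <- function(object, n_top = 10, ...) {
  print(object)
  cs <- object$category_scores
  cs <- cs[order(-cs$nes), , drop = FALSE]
  cat("\nCategory scores (NES):\n")
  print(format(cs, digits = 4), row.names = FALSE)
  pr <- object$pathway_results
  pr <- pr[order(-abs(pr$es_weighted)), , drop = FALSE]
  cat("\nTop pathways by |weighted ES|:\n")
  print(format(utils::head(pr[, c("pathway", "size_effective", "es",
                                  "p_nominal", "z", "es_weighted",
                                  "significant")], n_top),
               digits = 4), row.names = FALSE)
  if (!is.null(object$panel)) {
    cat("\nPanel:\n")
    print(format(object$panel, digits = 4), row.names = FALSE)
  }
  invisible(object)
}

#' Category-level coefficients of an sppa fit
#'
#' @param object An `sppa` fit.
#' @param ... Unused.
#' @return Named numeric vector of per-category normalized effect scores;
#'   their sum is the TES.
#' @export
coef.sppa <- function(object, ...) {
  stats::setNames(object$category_scores$nes,
                  object$category_scores$category)
}

#' Plot category effect scores
#'
#' Horizontal barplot of the per-category normalized effect scores whose
#' sum is the TES.
#'
#' @param x An `sppa` fit.
#' @param ... Passed to [graphics::barplot()].
#' @return The fit, invisibly.
#' @export
plot.sppa <- function(x, ...) {
  cs <- x$category_scores[order(x$category_scores$nes), , drop = FALSE]
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(cs$nes, names.arg = cs$category, horiz = TRUE,
                    las = 1, xlab = "category NES",
                    main = sprintf("TES = %.2f", x$tes), ...)
  invisible(x)
}
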