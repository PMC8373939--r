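# Size weighting, category-level normalized effect scores, total effect
# score, and the cancer-panel report.

#' Weight a pathway effect score by pathway size
#'
#' Pathways range from a handful of genes to over a thousand, and their
#' contribution to the overall impact should reflect that. The weighted
#' score is `log2(Ng) * Z`, where Ng is the number of member genes present
#' in the ranked universe and Z the permutation-normalized effect score.
#' A degenerate Z (null with zero spread) contributes 0, as does a
#' single-gene pathway (log2(1) = 0).
#'
#' @param result An `enrichment_result` from [score_pathway()].
#' @param log_base Base of the size logarithm (default 2).
#' @return A `weighted_score`: list with `id`, `es_weighted`, `significant`.
#' @examples
#' r <- structure(list(id = "P", z = 2.5, size_effective = 4L,
#'                     degenerate = FALSE, significant = TRUE),
#'                class = "enrichment_result")
#' weight_effect_score(r)$es_weighted  # log2(4) * 2.5 = 5
#' @export
weight_effect_score <- function(result, log_base = 2) {
  stopifnot(inherits(result, "enrichment_result"))
  ng <- result$size_effective
  if (is.null(ng) || ng < 1) stop("size_effective must be >= 1")
  w <- if (result$degenerate) 0 else log(ng, base = log_base) * result$z
  structure(list(id = result$id, es_weighted = w,
                 significant = isTRUE(result$significant)),
            class = "weighted_score")
}

#' Normalized effect score of a functional category
#'
#' Aggregates the significant member pathways of one top-level category:
#' `NES = mean(W) * log2(n)`, where W are the size-weighted scores of the
#' category's significant pathways and n their count. With n = 0 the NES
#' is 0; n = 1 also yields 0 because log2(1) = 0 (a documented consequence
#' of the formula; the `n + 1` variant avoids it, see `nes_n_plus_one`).
#'
#' @param category Category label.
#' @param weighted List of `weighted_score` objects (all pathways).
#' @param membership Named list mapping pathway id to its category labels
#'   (the `category_of` component of a `pathway_collection`).
#' @param nes_n_plus_one Use `log2(n + 1)` instead of `log2(n)`.
#' @return A `category_score`: list with `category`, `n_pathways`,
#'   `n_significant`, `nes`.
#' @export
score_category <- function(category, weighted, membership,
                           nes_n_plus_one = FALSE) {
  ids <- names(membership)
  member <- vapply(membership, function(x) category %in% x, logical(1))
  if (!any(member) && !(category %in% unlist(membership, use.names = FALSE)))
    stop("unknown category: ", category)
  mem_ids <- ids[member]
  wmap <- stats::setNames(weighted, vapply(weighted, `[[`, character(1), "id"))
  wmem <- wmap[intersect(mem_ids, names(wmap))]
  sig <- vapply(wmem, `[[`, logical(1), "significant")
  W <- vapply(wmem[sig], `[[`, numeric(1), "es_weighted")
  n <- length(W)
  nes <- if (n == 0) 0 else mean(W) * log2(if (nes_n_plus_one) n + 1 else n)
  structure(list(category = category, n_pathways = length(mem_ids),
                 n_significant = n, nes = nes),
            class = "category_score")
}

#' Total effect score
#'
#' The sum of the normalized effect scores over all top-level functional
#' categories: a single number summarizing the overall transcriptomic
#' impact of the exposure.
#'
#' @param category_scores List of `category_score` objects (each category
#'   once).
#' @return Numeric TES.
#' @export
total_effect_score <- function(category_scores) {
  if (length(category_scores) == 0) stop("need at least one category")
  cats <- vapply(category_scores, `[[`, character(1), "category")
  if (anyDuplicated(cats)) stop("each category must appear exactly once")
  sum(vapply(category_scores, `[[`, numeric(1), "nes"))
}

#' Report Z and p for a fixed pathway panel
#'
#' Extracts the permutation Z-score and nominal p-value for a user-supplied
#' list of pathways (for example a panel of cancer-related pathways).
#' Requested pathways absent from the scored collection are listed rather
#' than silently dropped.
#'
#' @param results List of `enrichment_result` objects.
#' @param panel Character vector of pathway ids.
#' @return Data frame with columns `pathway`, `z`, `p_nominal`,
#'   `degenerate`, `present`.
#' @export
panel_report <- function(results, panel) {
  ids <- vapply(results, `[[`, character(1), "id")
  if (length(panel) == 0)
    return(data.frame(pathway = character(0), z = numeric(0),
                      p_nominal = numeric(0), degenerate = logical(0),
                      present = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(panel, function(p) {
    i <- match(p, ids)
    if (is.na(i)) {
      data.frame(pathway = p, z = NA_real_, p_nominal = NA_real_,
                 degenerate = NA, present = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      r <- results[[i]]
      data.frame(pathway = p, z = r$z, p_nominal = r$p_nominal,
                 degenerate = r$degenerate, present = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
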