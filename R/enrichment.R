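# Core weighted running-sum scoring: per-pathway effect score, permutation
# null, nominal P and Z normalization.

# Resolve a gene set against a ranked list: 1-based hit positions (sorted)
# and the metric weights at those positions.
.hits_in_list <- function(L, genes) {
  pos <- match(genes, L$genes)
  pos <- sort(pos[!is.na(pos)])
  list(pos = pos, w = L$metric[pos])
}

# Effect score from hit positions alone, O(N_H). The running sum is piecewise
# linear in discrete position: it rises by w_k/N_R at hit k and falls by
# 1/(N - N_H) per miss. Its extrema over all N positions occur either at a
# hit position (candidate maxima) or at the position just before a hit /
# at the end of the list (candidate minima), so only hits are visited.
.es_from_hits <- function(pos, w, N) {
  nh <- length(pos)
  nr <- sum(w)
  miss_dec <- 1 / (N - nh)
  cumw <- cumsum(w) / nr
  k <- seq_len(nh)
  at_hit <- cumw - (pos - k) * miss_dec          # value at each hit position
  before_hit <- c(0, cumw[-nh]) - (pos - 1 - (k - 1)) * miss_dec
  cand <- c(at_hit, before_hit, 0)               # 0: value at end of list
  i <- which.max(abs(cand))
  es <- cand[[i]]
  amax <- abs(es)
  # positive wins an exact tie between a positive and a negative extreme
  if (es < 0 && any(cand == amax)) es <- amax
  es
}

#' Running-sum profile of a gene set over a ranked list
#'
#' Walks the ranked list from the most to the least perturbed gene. At a
#' member ("hit") gene the statistic increases by its metric weight divided
#' by the total member weight N_R; at a non-member ("miss") it decreases by
#' 1/(N - N_H). Both components reach 1 at the end of the list, so the
#' profile terminates at 0.
#'
#' @param L A `ranked_gene_list`.
#' @param S Character vector of member gene ids, or a gene-set entry from a
#'   `pathway_collection` (a list with a `genes` component).
#' @return A `running_sum_profile`: list with `values` (length-N profile),
#'   `n_hits` (N_H), `weight_total` (N_R) and `hit_positions`.
#' @examples
#' L <- build_ranked_list(data.frame(gene = paste0("g", 1:5),
#'                                   stat = c(5, 4, 3, 2, 1)))
#' p <- running_sum(L, c("g1", "g3"))
#' round(p$values, 4)
#' @export
running_sum <- function(L, S) {
  stopifnot(inherits(L, "ranked_gene_list"))
  genes <- if (is.list(S)) S$genes else S
  h <- .hits_in_list(L, genes)
  nh <- length(h$pos)
  if (nh == 0) stop("empty effective set: no member gene is in the ranked list")
  if (nh == L$N) stop("set equals universe (miss decrement undefined)")
  nr <- sum(h$w)
  if (nr == 0) stop("all member metrics are zero (N_R = 0)")
  inc <- rep(-1 / (L$N - nh), L$N)
  inc[h$pos] <- h$w / nr
  values <- cumsum(inc)
  structure(list(values = values, n_hits = nh, weight_total = nr,
                 hit_positions = h$pos),
            class = "running_sum_profile")
}

#' Effect score of a running-sum profile
#'
#' The effect score ES is the profile value of maximal absolute magnitude,
#' carrying its sign: large positive when the set's genes concentrate at the
#' top of the ranked list, large negative when they concentrate at the
#' bottom. On an exact tie between a positive and a negative extreme of
#' equal magnitude the positive one is returned.
#'
#' @param profile A `running_sum_profile` from [running_sum()].
#' @return Signed effect score in `[-1, 1]`.
#' @export
effect_score <- function(profile) {
  stopifnot(inherits(profile, "running_sum_profile"))
  v <- profile$values
  amax <- max(abs(v))
  if (amax == 0) return(0)
  if (any(v == amax)) amax else -amax
}

#' Permutation null distribution of the effect score
#'
#' Two null-construction schemes are supported. `gene_set` mode resamples
#' member positions: each permutation draws N_H genes uniformly without
#' replacement from the ranked list (their observed metrics kept) and
#' recomputes the effect score. `sample_label` mode reassigns the two-group
#' condition labels, recomputes the gene-level statistic and the ranking,
#' and rescores the original set; it requires the count matrix and labels.
#'
#' @param L A `ranked_gene_list`.
#' @param S Member gene ids (or a gene-set entry).
#' @param n_perm Number of permutations (default 500).
#' @param mode `"gene_set"` or `"sample_label"`.
#' @param seed Integer seed; the same seed and inputs give identical nulls.
#' @param counts,labels Required for `sample_label` mode.
#' @param exhaustive In `gene_set` mode, enumerate all `choose(N, N_H)`
#'   subsets instead of sampling (small instances only).
#' @param perm_rankings Optional precomputed list of permuted
#'   `ranked_gene_list` objects for `sample_label` mode (shared across
#'   pathways by [sppa()]); overrides `counts`/`labels`.
#' @return A `null_distribution`: list with `scores`, `n_perm`, `mode`,
#'   `seed`.
#' @export
build_null <- function(L, S, n_perm = 500, mode = c("gene_set", "sample_label"),
                       seed = 1, counts = NULL, labels = NULL,
                       exhaustive = FALSE, perm_rankings = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(L, "ranked_gene_list"))
  if (!exhaustive && (!is.numeric(n_perm) || n_perm < 1))
    stop("n_perm must be >= 1")
  genes <- if (is.list(S)) S$genes else S
  h <- .hits_in_list(L, genes)
  nh <- length(h$pos)
  if (nh == 0) stop("empty effective set")
  if (mode == "gene_set") {
    if (exhaustive) {
      subsets <- utils::combn(L$N, nh, simplify = FALSE)
      scores <- vapply(subsets, function(p)
        .es_from_hits(p, L$metric[p], L$N), numeric(1))
      n_perm <- length(scores)
    } else {
      set.seed(seed)
      scores <- numeric(n_perm)
      for (b in seq_len(n_perm)) {
        p <- sort.int(sample.int(L$N, nh))
        scores[[b]] <- .es_from_hits(p, L$metric[p], L$N)
      }
    }
  } else {
    if (is.null(perm_rankings)) {
      if (is.null(counts) || is.null(labels))
        stop("sample_label mode requires a count matrix and labels")
      perm_rankings <- permute_rankings(counts, labels, n_perm, seed)
    }
    n_perm <- length(perm_rankings)
    scores <- vapply(perm_rankings, function(Lp) {
      hp <- .hits_in_list(Lp, genes)
      if (length(hp$pos) == 0 || sum(hp$w) == 0) return(0)
      .es_from_hits(hp$pos, hp$w, Lp$N)
    }, numeric(1))
  }
  structure(list(scores = scores, n_perm = n_perm, mode = mode, seed = seed),
            class = "null_distribution")
}

#' Precompute permuted rankings for sample-label mode
#'
#' Shuffles the group labels (a balanced reassignment: the label multiset is
#' preserved), recomputes the built-in gene-level statistic and re-ranks, for
#' each of `n_perm` permutations. The result depends only on the inputs and
#' the seed, so it can be shared across all pathways.
#'
#' @param counts Gene-by-sample count matrix.
#' @param labels Two-group labels, one per column.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List of `ranked_gene_list` objects, one per permutation.
#' @export
permute_rankings <- function(counts, labels, n_perm = 500, seed = 1) {
  if (!is.null(names(labels)) && !is.null(colnames(counts)))
    labels <- labels[colnames(counts)]
  set.seed(seed)
  lapply(seq_len(n_perm), function(b) {
    lab_p <- sample(labels)
    build_ranked_list(suppressWarnings(gene_level_statistic(counts, lab_p)))
  })
}

#' Nominal permutation p-value
#'
#' One-sided: the observed effect score is compared with the portion of the
#' null distribution sharing its sign (null zeros are counted in the
#' positive portion). Counts are floored at one so the p-value is never 0.
#' If the matching-sign portion is empty, `1 / (n_perm + 1)` is returned and
#' the result is flagged.
#'
#' @param es Observed signed effect score.
#' @param null A `null_distribution`.
#' @return p-value in (0, 1]; attribute `"empty_portion"` is TRUE when the
#'   matching-sign portion was empty.
#' @export
nominal_p <- function(es, null) {
  stopifnot(inherits(null, "null_distribution"))
  s <- null$scores
  if (length(s) == 0) stop("empty null distribution")
  M <- if (es >= 0) s[s >= 0] else s[s < 0]
  if (length(M) == 0) {
    p <- 1 / (null$n_perm + 1)
    attr(p, "empty_portion") <- TRUE
    return(p)
  }
  p <- max(sum(abs(M) >= abs(es)), 1) / length(M)
  attr(p, "empty_portion") <- FALSE
  p
}

#' Z-normalized effect score
#'
#' Standardizes the observed effect score against the full permutation null
#' (both signs; the matching-sign variant is available via
#' `matching_sign = TRUE`). The standard deviation uses the n-1 denominator.
#' A null with zero spread is degenerate: the Z value is undefined, flagged,
#' and treated as 0 downstream.
#'
#' @param es Observed signed effect score.
#' @param null A `null_distribution` with at least 2 scores.
#' @param matching_sign Standardize against the matching-sign portion only.
#' @return Z value; attributes `"degenerate"`, `"null_mean"`, `"null_sd"`.
#' @export
z_score <- function(es, null, matching_sign = FALSE) {
  stopifnot(inherits(null, "null_distribution"))
  s <- null$scores
  if (matching_sign) s <- if (es >= 0) s[s >= 0] else s[s < 0]
  if (length(s) < 2) stop("need at least 2 null scores for Z normalization")
  mu <- mean(s)
  sdev <- stats::sd(s)
  if (sdev == 0) {
    z <- NA_real_
    attr(z, "degenerate") <- TRUE
  } else {
    z <- (es - mu) / sdev
    attr(z, "degenerate") <- FALSE
  }
  attr(z, "null_mean") <- mu
  attr(z, "null_sd") <- sdev
  z
}

#' Score a single pathway
#'
#' Composes the running sum, effect score, permutation null, nominal p-value
#' and Z normalization for one gene set, and marks it significant when
#' `p < alpha`.
#'
#' @inheritParams build_null
#' @param alpha Significance level on the nominal p-value (default 0.05).
#' @param matching_sign_z Standardize Z against the matching-sign portion.
#' @param id Pathway identifier used for reporting and to derive the
#'   per-pathway RNG substream; defaults to `S$id` when `S` is a gene-set
#'   entry.
#' @param substream Derive the permutation seed from `seed` and `id` so
#'   results are invariant to pathway evaluation order (default TRUE; set
#'   FALSE to use `seed` directly).
#' @return An `enrichment_result`: list with `id`, `es`, `p_nominal`, `z`,
#'   `null_mean`, `null_sd`, `size_effective`, `significant`, `degenerate`,
#'   `mode`, `n_perm`.
#' @export
score_pathway <- function(L, S, n_perm = 500,
                          mode = c("gene_set", "sample_label"), seed = 1,
                          alpha = 0.05, counts = NULL, labels = NULL,
                          perm_rankings = NULL, matching_sign_z = FALSE,
                          id = NULL, substream = TRUE) {
  mode <- match.arg(mode)
  if (is.null(id)) id <- if (is.list(S)) S$id else "set"
  prof <- running_sum(L, S)
  es <- effect_score(prof)
  sub_seed <- if (substream) .substream_seed(seed, id) else seed
  null <- build_null(L, S, n_perm = n_perm, mode = mode, seed = sub_seed,
                     counts = counts, labels = labels,
                     perm_rankings = perm_rankings)
  p <- nominal_p(es, null)
  z <- z_score(es, null, matching_sign = matching_sign_z)
  degenerate <- isTRUE(attr(z, "degenerate"))
  structure(list(id = id, es = es, p_nominal = as.numeric(p),
                 z = if (degenerate) NA_real_ else as.numeric(z),
                 null_mean = attr(z, "null_mean"),
                 null_sd = attr(z, "null_sd"),
                 size_effective = prof$n_hits,
                 significant = as.numeric(p) < alpha,
                 degenerate = degenerate,
                 empty_portion = isTRUE(attr(p, "empty_portion")),
                 mode = mode, n_perm = null$n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Pathway %s: Ng = %d, ES = %.4f, p = %.4g, Z = %s%s\n",
              x$id, x$size_effective, x$es, x$p_nominal,
              if (x$degenerate) "degenerate" else sprintf("%.3f", x$z),
              if (x$significant) " *" else ""))
  invisible(x)
}
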