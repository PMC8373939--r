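# Synthetic-data generators: pathway hierarchies, differential statistics
# and two-group count matrices with planted perturbed pathways, so every
# stage of the scoring pipeline is testable without external downloads.

#' Simulation configuration
#'
#' Collects the parameters of the synthetic-data generators and validates
#' them once. Defaults describe a reduced-scale study: a universe of 1,000
#' genes carrying 50 pathways in 5 top-level categories, 5 of them planted
#' as perturbed with a mean absolute-Z inflation of 3 — strong but realistic
#' for an acute exposure response. The count-matrix branch uses
#' negative-binomial counts at a common dispersion of 0.1 (typical for cell
#' line replicates), one million reads per sample, and 3 samples per group.
#'
#' @param n_genes Universe size.
#' @param n_categories,pathways_per_category Hierarchy shape.
#' @param set_size_range Length-2 integer range; set sizes are drawn
#'   log-uniform within it.
#' @param n_planted Number of perturbed (planted) pathways.
#' @param effect_mu Mean |Z| inflation for genes in planted pathways.
#' @param overlap_fraction Expected fraction of a set's genes shared with
#'   previously drawn sets (0 = pairwise disjoint where feasible).
#' @param nb_dispersion Common negative-binomial dispersion of the count
#'   model.
#' @param depth Expected library size (reads per sample).
#' @param n_per_group Samples per condition group.
#' @param planted_lfc log2 fold-change applied to planted-pathway genes in
#'   the treated group of the count model.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A validated `sppa_sim_config` list.
#' @export
sppa_sim_config <- function(n_genes = 1000, n_categories = 5,
                            pathways_per_category = 10,
                            set_size_range = c(10, 40), n_planted = 5,
                            effect_mu = 3, overlap_fraction = 0,
                            nb_dispersion = 0.1, depth = 1e6,
                            n_per_group = 3, planted_lfc = 2, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_categories = as.integer(n_categories),
              pathways_per_category = as.integer(pathways_per_category),
              set_size_range = as.integer(set_size_range),
              n_planted = as.integer(n_planted),
              effect_mu = effect_mu, overlap_fraction = overlap_fraction,
              nb_dispersion = nb_dispersion, depth = depth,
              n_per_group = as.integer(n_per_group),
              planted_lfc = planted_lfc, seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 10, cfg$n_categories >= 1,
            cfg$pathways_per_category >= 1,
            length(cfg$set_size_range) == 2,
            cfg$set_size_range[[1]] >= 2,
            cfg$set_size_range[[2]] >= cfg$set_size_range[[1]],
            cfg$n_planted >= 0, cfg$effect_mu >= 0,
            cfg$overlap_fraction >= 0, cfg$overlap_fraction <= 1,
            cfg$nb_dispersion > 0, cfg$depth > 0, cfg$n_per_group >= 2,
            is.finite(cfg$planted_lfc))
  if (cfg$n_planted > cfg$n_categories * cfg$pathways_per_category)
    stop("n_planted exceeds the total number of pathways")
  if (cfg$set_size_range[[2]] > cfg$n_genes)
    stop("set sizes exceed the gene universe")
  class(cfg) <- "sppa_sim_config"
  cfg
}

#' Simulate a hierarchical pathway collection
#'
#' Builds a pathway collection with the hierarchy shape of the config
#' (categories of equal pathway count), set sizes drawn log-uniform within
#' `set_size_range`, and `n_planted` pathways chosen as ground-truth
#' perturbed. With `overlap_fraction = 0` sets are drawn pairwise disjoint
#' while unassigned genes remain; a positive fraction draws that share of a
#' set's genes from genes already used by earlier sets.
#'
#' @param config An `sppa_sim_config`.
#' @return List with `collection` (a `pathway_collection` with categories
#'   attached), `planted` (character vector of planted pathway ids) and
#'   `universe` (all gene ids).
#' @export
simulate_pathways <- function(config) {
  stopifnot(inherits(config, "sppa_sim_config"))
  set.seed(.substream_seed(config$seed, "pathways"))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  n_sets <- config$n_categories * config$pathways_per_category
  lo <- log(config$set_size_range[[1]]); hi <- log(config$set_size_range[[2]])
  sizes <- pmin(round(exp(stats::runif(n_sets, lo, hi))), config$n_genes)
  sizes <- pmax(sizes, config$set_size_range[[1]])
  unused <- genes
  used <- character(0)
  sets <- vector("list", n_sets)
  ids <- sprintf("PW%03d", seq_len(n_sets))
  for (i in seq_len(n_sets)) {
    sz <- sizes[[i]]
    n_shared <- min(round(config$overlap_fraction * sz), length(used))
    shared <- if (n_shared > 0) sample(used, n_shared) else character(0)
    n_new <- sz - n_shared
    if (n_new <= length(unused)) {
      fresh <- if (n_new > 0) sample(unused, n_new) else character(0)
    } else {
      fresh <- c(unused, sample(setdiff(used, shared),
                                n_new - length(unused)))
    }
    members <- unique(c(shared, fresh))
    unused <- setdiff(unused, members)
    used <- union(used, members)
    sets[[i]] <- list(id = ids[[i]], name = paste("synthetic pathway", i),
                      genes = sort(members), size_raw = length(members),
                      size_effective = NA_integer_)
  }
  names(sets) <- ids
  cat_labels <- sprintf("Category%02d", seq_len(config$n_categories))
  category_of <- stats::setNames(
    as.list(rep(cat_labels, each = config$pathways_per_category)), ids)
  collection <- structure(list(sets = sets, category_of = category_of,
                               categories = cat_labels, n_dropped = 0L),
                          class = "pathway_collection")
  planted <- if (config$n_planted > 0) sort(sample(ids, config$n_planted))
             else character(0)
  list(collection = collection, planted = planted, universe = genes)
}

#' Simulate per-gene differential statistics with planted perturbation
#'
#' Background genes draw their statistic from a standard normal; genes
#' belonging to at least one planted pathway draw
#' `sign * Normal(effect_mu, 1)` with a random sign, emulating
#' direction-agnostic perturbation (the ranking uses |stat| only). A gene
#' in several planted pathways is drawn once.
#'
#' @param config An `sppa_sim_config`.
#' @param collection The `pathway_collection` from [simulate_pathways()].
#' @param planted Character vector of planted pathway ids.
#' @return Data frame with columns `gene`, `stat`.
#' @export
simulate_de_stats <- function(config, collection, planted) {
  stopifnot(inherits(config, "sppa_sim_config"),
            inherits(collection, "pathway_collection"))
  if (!all(planted %in% names(collection$sets)))
    stop("planted ids not all present in the collection")
  set.seed(.substream_seed(config$seed, "de_stats"))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  stat <- stats::rnorm(config$n_genes)
  planted_genes <- unique(unlist(lapply(collection$sets[planted],
                                        `[[`, "genes"), use.names = FALSE))
  idx <- match(intersect(planted_genes, genes), genes)
  if (length(idx) > 0) {
    signs <- sample(c(-1, 1), length(idx), replace = TRUE)
    stat[idx] <- signs * stats::rnorm(length(idx), mean = config$effect_mu)
  }
  data.frame(gene = genes, stat = stat, stringsAsFactors = FALSE)
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Gene-wise base abundances are log-normal; counts are negative binomial
#' with a common dispersion. Genes in planted pathways have their treated-
#' group mean multiplied by `2^planted_lfc`. Column order is all control
#' samples then all treated samples.
#'
#' @inheritParams simulate_de_stats
#' @return List with `counts` (gene-by-sample matrix) and `labels` (named
#'   group vector, levels `control` and `treated`).
#' @export
simulate_count_matrix <- function(config, collection, planted) {
  stopifnot(inherits(config, "sppa_sim_config"),
            inherits(collection, "pathway_collection"))
  if (!all(planted %in% names(collection$sets)))
    stop("planted ids not all present in the collection")
  set.seed(.substream_seed(config$seed, "counts"))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  base <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1.5)
  prop <- base / sum(base)
  mu_control <- prop * config$depth
  mu_treated <- mu_control
  planted_genes <- unique(unlist(lapply(collection$sets[planted],
                                        `[[`, "genes"), use.names = FALSE))
  idx <- match(intersect(planted_genes, genes), genes)
  if (length(idx) > 0) mu_treated[idx] <- mu_treated[idx] * 2^config$planted_lfc
  n <- config$n_per_group
  size <- 1 / config$nb_dispersion
  draw <- function(mu) matrix(stats::rnbinom(length(mu) * n, mu = mu,
                                             size = size),
                              nrow = length(mu), ncol = n)
  counts <- cbind(draw(mu_control), draw(mu_treated))
  rownames(counts) <- genes
  colnames(counts) <- c(sprintf("control_%d", seq_len(n)),
                        sprintf("treated_%d", seq_len(n)))
  labels <- stats::setNames(rep(c("control", "treated"), each = n),
                            colnames(counts))
  list(counts = counts, labels = labels)
}
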