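# Shared fixtures and independent oracles.

# The 5-gene worked instance: metrics 5,4,3,2,1 on genes g1..g5.
tiny_ranked_list <- function() {
  build_ranked_list(data.frame(gene = paste0("g", 1:5),
                               stat = c(5, 4, 3, 2, 1)))
}

# Brute-force running-sum oracle: evaluates P_hit - P_miss independently at
# every position (no incremental state).
oracle_profile <- function(L, members) {
  hit <- L$genes %in% members
  nh <- sum(hit)
  nr <- sum(L$metric[hit])
  vapply(seq_len(L$N), function(i) {
    idx <- seq_len(i)
    sum(L$metric[idx][hit[idx]]) / nr - sum(!hit[idx]) / (L$N - nh)
  }, numeric(1))
}

# Oracle effect score: value of maximal |value|, positive wins exact ties.
oracle_es <- function(values) {
  amax <- max(abs(values))
  if (amax == 0) return(0)
  if (any(values == amax)) amax else -amax
}

# Exhaustive gene-set-permutation p-value oracle for small instances.
oracle_exhaustive_p <- function(L, members) {
  es <- oracle_es(oracle_profile(L, members))
  nh <- sum(L$genes %in% members)
  subsets <- utils::combn(L$N, nh, simplify = FALSE)
  null <- vapply(subsets, function(p)
    oracle_es(oracle_profile(L, L$genes[p])), numeric(1))
  M <- if (es >= 0) null[null >= 0] else null[null < 0]
  max(sum(abs(M) >= abs(es)), 1) / length(M)
}

# Random small (L, S) instance for property tests.
random_instance <- function(N = sample(4:12, 1), nh = NULL) {
  genes <- sprintf("r%03d", seq_len(N))
  stat <- stats::rnorm(N)
  stat[abs(stat) < 1e-6] <- 0.5  # keep all metrics positive
  L <- build_ranked_list(data.frame(gene = genes, stat = stat))
  if (is.null(nh)) nh <- sample(seq_len(min(3, N - 1)), 1)
  list(L = L, S = sample(genes, nh))
}

# Write GMT/hierarchy fixtures for a tiny two-category collection.
write_tiny_fixtures <- function(dir) {
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("P1\tone\tg1\tg3",
               "P2\ttwo\tg4\tg5",
               "P3\tthree\tg2\tg4"), gmt)
  hier <- file.path(dir, "hier.tsv")
  writeLines(c("P1\tCatA", "P2\tCatA", "P3\tCatB"), hier)
  stats <- file.path(dir, "stats.tsv")
  writeLines(c("gene\tstat", paste(paste0("g", 1:5), c(5, 4, 3, 2, 1),
                                   sep = "\t")), stats)
  list(gmt = gmt, hier = hier, stats = stats)
}
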