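fit_small <- function(seed = 1, ...) {
  cfg <- sppa_sim_config(n_genes = 400, n_categories = 3,
                         pathways_per_category = 4,
                         set_size_range = c(8, 20), n_planted = 3,
                         effect_mu = 3, seed = seed)
  sim <- simulate_pathways(cfg)
  de <- simulate_de_stats(cfg, sim$collection, sim$planted)
  list(fit = sppa(de, sim$collection, n_perm = 100, seed = seed,
                  quiet = TRUE, ...),
       sim = sim)
}

test_that("sppa returns a coherent fit: TES = sum of category NES", {
  out <- fit_small()
  fit <- out$fit
  expect_s3_class(fit, "sppa")
  expect_equal(fit$tes, sum(fit$category_scores$nes), tolerance = 1e-9)
  expect_equal(coef(fit), setNames(fit$category_scores$nes,
                                   fit$category_scores$category))
  expect_equal(nrow(fit$pathway_results), 12L)
  expect_true(all(fit$pathway_results$p_nominal > 0 &
                    fit$pathway_results$p_nominal <= 1))
  expect_true(all(abs(fit$pathway_results$es) <= 1 + 1e-12))
  # planted pathways should dominate the significant calls
  expect_true(all(out$sim$planted %in%
                    fit$pathway_results$pathway[fit$pathway_results$significant]))
})

test_that("sppa is deterministic in the seed and order-invariant", {
  f1 <- fit_small(seed = 3)$fit
  f2 <- fit_small(seed = 3)$fit
  expect_identical(f1$pathway_results, f2$pathway_results)
  expect_identical(f1$tes, f2$tes)

  # reversing the order of the sets leaves every per-pathway score unchanged
  cfg <- sppa_sim_config(n_genes = 400, n_categories = 3,
                         pathways_per_category = 4,
                         set_size_range = c(8, 20), n_planted = 3,
                         effect_mu = 3, seed = 3)
  sim <- simulate_pathways(cfg)
  de <- simulate_de_stats(cfg, sim$collection, sim$planted)
  rev_col <- sim$collection
  rev_col$sets <- rev(rev_col$sets)
  rev_col$category_of <- rev_col$category_of[names(rev_col$sets)]
  f3 <- sppa(de, rev_col, n_perm = 100, seed = 3, quiet = TRUE)
  pr1 <- f1$pathway_results[order(f1$pathway_results$pathway), ]
  pr3 <- f3$pathway_results[order(f3$pathway_results$pathway), ]
  rownames(pr1) <- rownames(pr3) <- NULL
  expect_identical(pr1, pr3)
  expect_identical(f1$tes, f3$tes)
})

test_that("TES additivity: dropping a category removes exactly its NES", {
  cfg <- sppa_sim_config(n_genes = 400, n_categories = 3,
                         pathways_per_category = 4,
                         set_size_range = c(8, 20), n_planted = 3,
                         effect_mu = 3, seed = 5)
  sim <- simulate_pathways(cfg)
  de <- simulate_de_stats(cfg, sim$collection, sim$planted)
  full <- sppa(de, sim$collection, n_perm = 100, seed = 5, quiet = TRUE)
  drop_cat <- full$category_scores$category[[1]]
  keep_ids <- names(Filter(function(x) !(drop_cat %in% x),
                           sim$collection$category_of))
  sub <- sim$collection
  sub$sets <- sub$sets[keep_ids]
  sub$category_of <- sub$category_of[keep_ids]
  sub$categories <- setdiff(sub$categories, drop_cat)
  part <- sppa(de, sub, n_perm = 100, seed = 5, quiet = TRUE)
  nes_dropped <- full$category_scores$nes[
    full$category_scores$category == drop_cat]
  expect_equal(part$tes, full$tes - nes_dropped, tolerance = 1e-9)
  # untouched categories keep their scores bit-for-bit
  common <- intersect(part$category_scores$category,
                      full$category_scores$category)
  expect_identical(
    part$category_scores$nes[match(common, part$category_scores$category)],
    full$category_scores$nes[match(common, full$category_scores$category)])
})

test_that("panel, methods and input validation behave", {
  out <- fit_small(seed = 2, panel = c("PW001", "PW002", "NOPE"))
  fit <- out$fit
  expect_equal(nrow(fit$panel), 3L)
  expect_false(fit$panel$present[[3]])
  expect_output(print(fit), "Total effect score")
  expect_output(summary(fit), "Category scores")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()

  cfg <- sppa_sim_config(n_genes = 100, seed = 1,
                         set_size_range = c(5, 10))
  sim <- simulate_pathways(sppa_sim_config(n_genes = 100, n_categories = 1,
                                           pathways_per_category = 2,
                                           set_size_range = c(5, 10),
                                           n_planted = 0, seed = 1))
  de <- data.frame(gene = sprintf("g%05d", 1:100), stat = rnorm(100))
  expect_error(sppa(de, sim$collection, n_perm = 0, quiet = TRUE), "n_perm")
  expect_error(sppa(de, sim$collection, alpha = 1.5, quiet = TRUE), "alpha")
  expect_error(sppa(NULL, sim$collection, quiet = TRUE), "supply")
})

test_that("run_simulate + run_score produce consistent, re-readable outputs", {
  dir_sim <- withr::local_tempdir()
  dir_out <- withr::local_tempdir()
  cfg <- sppa_sim_config(n_genes = 300, n_categories = 2,
                         pathways_per_category = 4,
                         set_size_range = c(6, 15), n_planted = 2,
                         effect_mu = 3, seed = 9)
  files <- run_simulate(cfg, dir_sim)
  expect_true(all(file.exists(file.path(
    dir_sim, c("sets.gmt", "hierarchy.tsv", "stats.tsv", "counts.tsv",
               "labels.tsv", "planted.txt")))))
  rc <- sppa_run_config(stats_path = file.path(dir_sim, "stats.tsv"),
                        gmt_path = file.path(dir_sim, "sets.gmt"),
                        hierarchy_path = file.path(dir_sim, "hierarchy.tsv"),
                        n_perm = 100, seed = 9, out_dir = dir_out,
                        quiet = TRUE)
  fit <- run_score(rc)
  expect_true(all(file.exists(file.path(
    dir_out, c("pathway_scores.tsv", "category_scores.tsv", "tes.json")))))
  tes_doc <- jsonlite::read_json(file.path(dir_out, "tes.json"))
  cats <- read.delim(file.path(dir_out, "category_scores.tsv"))
  expect_equal(tes_doc$tes, sum(cats$nes), tolerance = 1e-4)
  expect_equal(tes_doc$provenance$seed, 9L)
  expect_true(!is.null(tes_doc$provenance$input_md5$gmt))

  # planted pathways are recovered as significant
  planted <- readLines(file.path(dir_sim, "planted.txt"))
  ps <- read.delim(file.path(dir_out, "pathway_scores.tsv"))
  expect_true(all(ps$significant[ps$pathway %in% planted]))
})

test_that("repeat runs with the same configuration are byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  cfg <- sppa_sim_config(n_genes = 250, n_categories = 2,
                         pathways_per_category = 3,
                         set_size_range = c(5, 12), n_planted = 1,
                         seed = 21)
  run_simulate(cfg, d1); run_simulate(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  mk <- function(d, o) sppa_run_config(
    stats_path = file.path(d, "stats.tsv"), gmt_path = file.path(d, "sets.gmt"),
    hierarchy_path = file.path(d, "hierarchy.tsv"), n_perm = 80, seed = 21,
    out_dir = o, quiet = TRUE)
  run_score(mk(d1, o1)); run_score(mk(d2, o2))
  for (f in c("pathway_scores.tsv", "category_scores.tsv")) {
    expect_identical(readBin(file.path(o1, f), "raw", 1e6),
                     readBin(file.path(o2, f), "raw", 1e6), label = f)
  }
})

test_that("the CLI entry point scores fixtures and fails cleanly", {
  d <- withr::local_tempdir()
  o <- file.path(d, "out")
  fx <- write_tiny_fixtures(d)
  status <- sppa_cli(c("score", "--stats", fx$stats, "--gmt", fx$gmt,
                       "--hierarchy", fx$hier, "--n-perm", "50",
                       "--seed", "4", "--quiet", "--out", o))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(o, "tes.json")))

  expect_message(
    status_bad <- sppa_cli(c("score", "--gmt", "/nonexistent.gmt",
                             "--stats", fx$stats, "--quiet", "--out", o)),
    "error")
  expect_equal(status_bad, 1L)
  expect_equal(suppressMessages(sppa_cli(c("bogus"))), 2L)
})

test_that("sample-label mode runs end-to-end on simulated counts", {
  cfg <- sppa_sim_config(n_genes = 300, n_categories = 2,
                         pathways_per_category = 3,
                         set_size_range = c(8, 15), n_planted = 2,
                         planted_lfc = 3, n_per_group = 4, depth = 3e5,
                         seed = 15)
  sim <- simulate_pathways(cfg)
  cm <- simulate_count_matrix(cfg, sim$collection, sim$planted)
  fit <- sppa(stats = NULL, collection = sim$collection, counts = cm$counts,
              labels = cm$labels, mode = "sample_label", n_perm = 30,
              seed = 15, quiet = TRUE)
  expect_s3_class(fit, "sppa")
  expect_equal(fit$provenance$mode, "sample_label")
  expect_true(any(fit$pathway_results$significant[
    fit$pathway_results$pathway %in% sim$planted]))
})
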