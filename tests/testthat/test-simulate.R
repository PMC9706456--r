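test_that("configs enforce the inclusion rule and module constraints", {
  expect_error(simulation_config(n_samples = 6), "inclusion")
  expect_error(simulation_config(
    modules = tibble::tibble(name = "M1", size = 10, n_hubs = 2,
                             trait_cor = 0.5, conserved = TRUE)
  ), "minimum module size")
  expect_error(simulation_config(
    modules = tibble::tibble(name = "M1", size = 30, n_hubs = 2,
                             trait_cor = 1.5, conserved = TRUE)
  ), "\\[-1, 1\\]")
  expect_error(simulate_experiment(simulation_config(), "axolotl"),
               "axolotl")
})

test_that("noise-free factor modules have all pairwise correlations 1", {
  cfg <- simulation_config(
    modules = tibble::tibble(name = "M1", size = 30, n_hubs = 3,
                             trait_cor = 0.8, conserved = TRUE),
    n_noise = 0, noise_scale = 0, seed = 5
  )
  sim <- simulate_experiment(cfg, "human", 1)
  cm <- cor(t(sim$experiment$expression))
  expect_equal(unname(cm[upper.tri(cm)]),
               rep(1, sum(upper.tri(cm))), tolerance = 1e-12)
})

test_that("same config and seed reproduce byte-identical experiments", {
  cfg <- simulation_config(seed = 99)
  s1 <- simulate_experiment(cfg, "rat", 2)
  s2 <- simulate_experiment(cfg, "rat", 2)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("ground truth bookkeeping matches the configured layout", {
  cfg <- simulation_config(
    modules = tibble::tibble(name = c("M1", "M2"), size = c(30, 40),
                             n_hubs = c(4, 6), trait_cor = c(0.8, NA),
                             conserved = c(TRUE, FALSE)),
    n_noise = 100, seed = 8
  )
  sim <- simulate_experiment(cfg, "human", 1)
  tg <- sim$truth$genes
  expect_equal(as.integer(table(tg$module)[c("M1", "M2", "noise")]),
               c(30L, 40L, 100L))
  expect_equal(sum(tg$is_hub[tg$module == "M1"]), 4)
  expect_equal(sum(tg$is_hub[tg$module == "M2"]), 6)
  expect_equal(nrow(sim$experiment$expression), 170)
  # every planted hub belongs to exactly one planted module
  expect_true(all(tg$module[tg$is_hub] %in% c("M1", "M2")))
  # hubs carry the largest loadings in their module
  for (m in c("M1", "M2")) {
    sub <- tg[tg$module == m, ]
    expect_gte(min(sub$loading[sub$is_hub]), max(sub$loading[!sub$is_hub]))
  }
})

test_that("health-module factors hit the configured score correlation", {
  for (target in c(0.8, -0.6, 0.4)) {
    cfg <- simulation_config(
      modules = tibble::tibble(name = "M1", size = 30, n_hubs = 3,
                               trait_cor = target, conserved = TRUE),
      n_noise = 0, n_samples = 100, seed = round(100 * abs(target))
    )
    sim <- simulate_experiment(cfg, "human", 1)
    expect_equal(sim$truth$modules$factor_score_cor, target,
                 tolerance = 0.1)
  }
})

test_that("within-module correlations exceed between-module correlations", {
  cfg <- simulation_config(n_samples = 60, n_noise = 50, seed = 21)
  sim <- simulate_experiment(cfg, "human", 1)
  cm <- cor(t(sim$experiment$expression))
  mod <- sim$truth$genes$module
  within <- abs(cm[mod == "M1", mod == "M1"])
  between <- abs(cm[mod == "M1", mod == "noise"])
  expect_gt(mean(within[upper.tri(within)]), mean(between) + 0.2)
})

test_that("collections tag species, forbid duplicates and map conserved genes", {
  cfg <- simulation_config(species = c("human", "rat"),
                           experiments_per_species = 2, seed = 3)
  col <- simulate_collection(cfg)
  expect_equal(length(col$experiments), 4)
  sp <- vapply(col$experiments, function(e) e$species, character(1))
  expect_equal(as.integer(table(sp)[c("human", "rat")]), c(2L, 2L))

  # per-species namespaces are distinct
  h_genes <- rownames(col$experiments[["human_e01"]]$expression)
  r_genes <- rownames(col$experiments[["rat_e01"]]$expression)
  expect_equal(length(intersect(h_genes, r_genes)), 0)

  # the conserved module's symbols appear for both species
  conserved <- col$conserved_symbols
  expect_gte(length(conserved), 12)
  for (s in utils::head(conserved, 3)) {
    hit <- col$orthologs[col$orthologs$human_symbol == s, ]
    expect_gte(dplyr::n_distinct(hit$species), 2)
  }
})

test_that("counts platform yields integers with mean-variance inflation", {
  cfg <- simulation_config(platform = "counts", seed = 12)
  sim <- simulate_experiment(cfg, "human", 1)
  x <- sim$experiment$expression
  expect_true(all(x == round(x)))
  expect_true(all(x >= 0))
  means <- rowMeans(x)
  vars <- apply(x, 1, var)
  # Poisson sampling on a log-normal mean: variance at least ~ mean
  expect_gt(stats::cor(log1p(means), log1p(vars)), 0.8)
})

test_that("collections write a complete plain-text bundle", {
  cfg <- simulation_config(experiments_per_species = 1, n_noise = 10, seed = 4)
  col <- simulate_collection(cfg)
  dir <- withr::local_tempdir()
  write_collection(col, dir)
  files <- list.files(dir)
  expect_true("orthologs.tsv" %in% files)
  expect_true("ground_truth.json" %in% files)
  expect_true(any(grepl("human_e01_expression.tsv", files)))
  expect_true(any(grepl("rat_e01_metadata.tsv", files)))
  m <- read_expression_tsv(file.path(dir, "human_e01_expression.tsv"))
  expect_equal(dim(m), dim(col$experiments[["human_e01"]]$expression))
})
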