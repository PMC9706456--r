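# a minimal fitted network around a known factor structure
selection_fixture <- function(seed = 101, trait_cor = 0.8, n_samples = 12) {
  cfg <- simulation_config(
    modules = tibble::tibble(name = "M1", size = 40, n_hubs = 5,
                             trait_cor = trait_cor, conserved = TRUE),
    n_noise = 40, n_samples = n_samples, seed = seed
  )
  sim <- simulate_experiment(cfg, "human", 1)
  x <- suppressMessages(log_transform(sim$experiment$expression))
  net <- suppressWarnings(build_network(x, power = 6))
  list(net = net, sim = sim)
}

test_that("module-trait association reproduces r, p and the flag rule", {
  fx <- selection_fixture()
  phenotype <- fx$sim$truth$scores[, c("sample_id", "score")]
  assoc <- module_trait_association(fx$net, phenotype)
  expect_true(all(assoc$flagged == (assoc$p_value < 0.05)))
  m1 <- assoc[which.max(abs(assoc$r)), ]
  expect_gt(abs(m1$r), 0.6)
  expect_true(m1$flagged)

  # eigengene identical to the phenotype: r = 1, p ~ 0
  e <- fx$net$eigengenes[[1]]$eigengene
  fake <- tibble::tibble(sample_id = names(e), score = e)
  assoc2 <- module_trait_association(fx$net, fake)
  expect_equal(assoc2$r[1], 1, tolerance = 1e-10)
  expect_lt(assoc2$p_value[1], 1e-10)
})

test_that("p-value boundary behavior matches the t CDF at n = 12", {
  # solve for the critical r at df = 10: t = r sqrt(10) / sqrt(1 - r^2)
  t_crit <- qt(0.975, df = 10)
  r_crit <- t_crit / sqrt(10 + t_crit^2)
  expect_equal(r_crit, 0.576, tolerance = 1e-3)
  just_over <- healthnet:::cor_test_t_from_r(0.577, 12)
  just_under <- healthnet:::cor_test_t_from_r(0.575, 12)
  expect_lt(just_over, 0.05)
  expect_gt(just_under, 0.05)

  # r = 0 at any n gives p = 1
  x <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1)
  y <- c(1, 1, 1, 1, -2, -2, 1, 1, 1, 1, -2, -2)
  ct <- healthnet:::cor_test_t(x, y)
  expect_equal(ct$r, 0, tolerance = 1e-12)
  expect_equal(ct$p, 1, tolerance = 1e-12)
})

test_that("constant phenotype is rejected with reference to the scorecard", {
  fx <- selection_fixture()
  flat <- tibble::tibble(sample_id = colnames(fx$net$expression), score = 1)
  expect_error(module_trait_association(fx$net, flat), "scorecard")
})

test_that("hub ranking sorts by connectivity with lexicographic tie-break", {
  fx <- selection_fixture()
  assoc <- module_trait_association(fx$net, fx$sim$truth$scores)
  flagged <- assoc$module[assoc$flagged][1]
  hubs <- top_hub_genes(fx$net, flagged, assoc, cut = 30)
  expect_lte(nrow(hubs), 30)
  expect_true(all(diff(hubs$score) <= 0))
  k <- fx$net$connectivity[names(fx$net$modules)[fx$net$modules == flagged]]
  expect_equal(hubs$gene[1], names(k)[order(-k, names(k))][1])

  # a module smaller than the cut comes back whole
  all20 <- top_hub_genes(fx$net, flagged, assoc, cut = 1000)
  expect_equal(nrow(all20), sum(fx$net$modules == flagged))

  # unflagged modules are refused
  assoc_un <- assoc
  assoc_un$flagged <- FALSE
  expect_error(top_hub_genes(fx$net, flagged, assoc_un), "not health-associated")
})

test_that("explicit connectivity ties break lexicographically", {
  scores <- c(b2 = 1.0, a1 = 1.0, c3 = 0.5)
  out <- healthnet:::ranked_gene_list(names(scores), scores, cut = 3,
                                      basis = "hub", module = 1)
  expect_equal(out$gene, c("a1", "b2", "c3"))
  expect_true(out$tie[1] && out$tie[2])
})

test_that("membership ranking uses |kME| and keeps the signed value", {
  fx <- selection_fixture()
  assoc <- module_trait_association(fx$net, fx$sim$truth$scores)
  flagged <- assoc$module[assoc$flagged][1]
  memb <- top_membership_genes(fx$net, flagged, assoc, cut = 30)
  expect_true(all(diff(memb$score) <= 0))
  expect_equal(memb$score, unname(abs(memb$kme)))

  # the planted hubs (largest loadings) fill the top ranks
  planted <- fx$sim$truth$genes$gene[fx$sim$truth$genes$is_hub]
  expect_true(all(memb$gene[1:3] %in% planted))
})

test_that("direction is the sign product, with the inversion rule", {
  expect_equal(gene_direction(1, -1), "negative")
  expect_equal(gene_direction(-1, -1), "positive")
  expect_equal(gene_direction(1, 1), "positive")
  expect_equal(gene_direction(0, 1), "undetermined")
  expect_equal(gene_direction(c(0.5, -0.2), c(-3, -3)),
               c("negative", "positive"))
})

test_that("null modules are flagged at the nominal rate", {
  # 60 independent experiments whose only module has no planted association
  hits <- vapply(1:60, function(i) {
    cfg <- simulation_config(
      modules = tibble::tibble(name = "M1", size = 30, n_hubs = 3,
                               trait_cor = NA, conserved = FALSE),
      n_noise = 0, seed = 1000 + i
    )
    sim <- simulate_experiment(cfg, "human", 1)
    e <- module_eigengene(sim$experiment$expression,
                          sim$truth$genes$gene)
    ct <- healthnet:::cor_test_t(e$eigengene, sim$truth$scores$z)
    ct$p < 0.05
  }, logical(1))
  # exact binomial 99% bounds for 60 trials at rate 0.05
  expect_gte(sum(hits), qbinom(0.005, 60, 0.05))
  expect_lte(sum(hits), qbinom(0.995, 60, 0.05))
})

test_that("select_modules returns both bases with directions attached", {
  fx <- selection_fixture()
  sel <- select_modules(fx$net, fx$sim$truth$scores)
  expect_setequal(unique(sel$gene_lists$basis), c("hub", "membership"))
  expect_true(all(sel$gene_lists$direction %in%
                    c("positive", "negative", "undetermined")))
  # hub and membership lists of a strongly planted module share genes
  m <- sel$gene_lists$module[1]
  h <- sel$gene_lists$gene[sel$gene_lists$basis == "hub" &
                             sel$gene_lists$module == m]
  mm <- sel$gene_lists$gene[sel$gene_lists$basis == "membership" &
                              sel$gene_lists$module == m]
  expect_gte(length(intersect(h, mm)), 1)
})
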