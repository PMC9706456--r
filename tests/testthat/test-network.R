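test_that("correlation matrix handles identical, negated and worked profiles", {
  x <- rbind(
    g1 = c(1, 2, 3),
    g2 = c(1, 2, 3),
    g3 = -c(1, 2, 3),
    g4 = c(1, 2, 4)
  )
  colnames(x) <- paste0("s", 1:3)
  cm <- correlation_matrix(x)
  expect_equal(cm["g1", "g2"], 1.0)
  expect_equal(cm["g1", "g3"], -1.0)
  expect_equal(cm["g1", "g4"], 0.981980506, tolerance = 1e-8)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 4))
})

test_that("constant genes are dropped with a warning, not fatal", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1), flat = rep(7, 4))
  colnames(x) <- paste0("s", 1:4)
  expect_warning(cm <- correlation_matrix(x), "flat")
  expect_equal(rownames(cm), c("g1", "g2"))
})

test_that("adjacency matches the hand-powered values and is monotone", {
  cm <- matrix(c(1, -0.9, -0.9, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(adjacency_matrix(cm, 6)["a", "b"], 0.531441)
  cm2 <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(adjacency_matrix(cm2, 7)[1, 2], 0)
  expect_equal(adjacency_matrix(cm2, 7)[1, 1], 1)

  # increasing |cor| never decreases a_ij; increasing power never increases it
  r <- seq(0, 0.99, by = 0.01)
  a6 <- abs(r)^6
  expect_true(all(diff(a6) >= 0))
  a12 <- abs(r)^12
  expect_true(all(a12 <= a6))
})

test_that("TOM reproduces the 3-gene worked example", {
  tom <- topological_overlap(three_gene_adjacency())
  expect_equal(tom["g1", "g2"], 1.0 / 1.4, tolerance = 1e-12)
  expect_equal(tom, t(tom))
  expect_equal(unname(diag(tom)), rep(1, 3))
})

test_that("TOM equals the triple-loop oracle on random matrices", {
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- random_adjacency(15)
      expect_equal(topological_overlap(a), tom_oracle(a), tolerance = 1e-10)
    }
  })
})

test_that("TOM degenerate cases: empty network and maximal overlap", {
  a <- diag(4)
  rownames(a) <- colnames(a) <- paste0("g", 1:4)
  tom <- topological_overlap(a)
  expect_equal(unname(tom[upper.tri(tom)]), rep(0, 6))

  # two genes with identical 0/1 adjacency rows and a_ij = 1 overlap maximally
  b <- matrix(c(1, 1, 1,
                1, 1, 1,
                1, 1, 1), 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  expect_equal(topological_overlap(b)[1, 2], 1)
})

test_that("soft connectivity matches hand sums and ignores isolated genes", {
  k <- soft_connectivity(three_gene_adjacency())
  expect_equal(unname(k), c(1.3, 1.2, 0.9))
  expect_equal(unname(soft_connectivity(diag(3))), rep(0, 3))

  a4 <- rbind(cbind(three_gene_adjacency(), g4 = 0), g4 = c(0, 0, 0, 1))
  rownames(a4) <- colnames(a4) <- paste0("g", 1:4)
  expect_equal(unname(soft_connectivity(a4)[1:3]), c(1.3, 1.2, 0.9))
})

test_that("scale-free fit is perfect for an exact power law and flags degeneracy", {
  # construct k values whose equal-width bin counts follow p(k) proportional
  # to 1/k: bins centered at c with width 1 receive round(C/c) genes
  centers <- c(10, 20, 40, 80, 160)
  k <- unlist(lapply(centers, function(c) rep(c, round(3200 / c))))
  s <- suppressWarnings(healthnet:::scale_free_fit_stats(k, nbins = 16))
  expect_equal(s$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(s$slope, -1.0, tolerance = 1e-9)

  s2 <- healthnet:::scale_free_fit_stats(rep(5, 100))
  expect_true(is.na(s2$r_squared))
})

test_that("all-equal correlations raise the not-scale-free flag", {
  n <- 40
  cm <- matrix(1, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  fit <- pick_soft_power(cm)
  expect_false(fit$scale_free)
})

test_that("chosen power agrees with a brute-force reimplementation of the fit", {
  cfg <- simulation_config(seed = 31)
  sim <- simulate_experiment(cfg, "human", 1)
  x <- suppressMessages(log_transform(sim$experiment$expression))
  cm <- correlation_matrix(x)
  fit <- pick_soft_power(cm, candidates = 1:12)

  # independent oracle: same binning rule, re-derived by hand from the
  # definition of the connectivity vector
  oracle_r2 <- vapply(1:12, function(beta) {
    a <- abs(cm)^beta
    diag(a) <- 0
    k <- rowSums(a)
    breaks <- seq(min(k), max(k), length.out = 11)
    bin <- findInterval(k, breaks, rightmost.closed = TRUE)
    df <- data.frame(k = k, bin = bin)
    agg_n <- tapply(df$k, df$bin, length)
    agg_k <- tapply(df$k, df$bin, mean)
    if (length(agg_n) < 3) return(NA_real_)
    p <- agg_n / sum(agg_n)
    f <- lm(log10(p) ~ log10(agg_k))
    r2 <- summary(f)$r.squared
    if (coef(f)[2] >= 0) r2 <- -r2  # signed convention
    r2
  }, numeric(1))
  oracle_choice <- which(oracle_r2 >= 0.80)[1]
  expect_equal(fit$power, oracle_choice)
  expect_true(fit$scale_free)
})

test_that("module detection recovers planted blocks and handles few genes", {
  cfg <- simulation_config(
    modules = tibble::tibble(name = c("M1", "M2"), size = c(40, 35),
                             n_hubs = c(5, 5), trait_cor = c(0.8, NA),
                             conserved = c(TRUE, FALSE)),
    n_noise = 0, noise_scale = 0, seed = 13
  )
  sim <- simulate_experiment(cfg, "human", 1)
  x <- suppressMessages(log_transform(sim$experiment$expression))
  tom <- topological_overlap(adjacency_matrix(correlation_matrix(x), 6))
  modules <- detect_modules(tom)
  truth <- sim$truth$genes$module
  expect_gte(adjusted_rand_index(modules, truth), 0.9)
  expect_equal(sort(as.integer(table(modules)), decreasing = TRUE)[1:2],
               c(40L, 35L))

  small <- random_adjacency(20)
  expect_warning(lab <- detect_modules(topological_overlap(small), 30),
                 "fewer genes")
  expect_true(all(lab == 0))
})

test_that("module detection is invariant to gene order up to label names", {
  cfg <- simulation_config(n_noise = 30, seed = 17)
  sim <- simulate_experiment(cfg, "rat", 1)
  x <- suppressMessages(log_transform(sim$experiment$expression))
  tom <- topological_overlap(adjacency_matrix(correlation_matrix(x), 6))
  m1 <- detect_modules(tom)
  perm <- withr::with_seed(1, sample(nrow(tom)))
  m2 <- detect_modules(tom[perm, perm])
  expect_gte(adjusted_rand_index(m1[names(m2)], m2), 0.999)
})

test_that("eigengene matches the singular-vector oracle on random modules", {
  withr::with_seed(19, {
    for (i in 1:10) {
      x <- matrix(rnorm(10 * 8), 10,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
      e <- module_eigengene(x, rownames(x))
      z <- t(scale(t(x)))
      dec <- eigen(t(z) %*% z / (nrow(x)))
      v <- dec$vectors[, 1]
      expect_equal(abs(sum(e$eigengene * v)), 1, tolerance = 1e-8)
      expect_equal(e$var_explained, dec$values[1] / sum(dec$values),
                   tolerance = 1e-8)
      expect_equal(sum(e$eigengene^2), 1, tolerance = 1e-12)
    }
  })
})

test_that("eigengene of identical genes is the profile itself, variance 1", {
  prof <- c(1, 3, 2, 5, 4)
  x <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(x) <- paste0("s", 1:5)
  e <- module_eigengene(x, rownames(x))
  expect_equal(e$var_explained, 1.0)
  zp <- as.numeric(scale(prof))
  expect_equal(unname(e$eigengene), zp / sqrt(sum(zp^2)), tolerance = 1e-12)
})

test_that("half-x half-negated-x module has deterministic sign, variance 1", {
  prof <- c(2, 1, 4, 3, 6)
  x <- rbind(g1 = prof, g2 = prof, g3 = -prof, g4 = -prof)
  colnames(x) <- paste0("s", 1:5)
  e1 <- module_eigengene(x, rownames(x))
  e2 <- module_eigengene(x, rownames(x))
  expect_equal(e1$var_explained, 1.0)
  expect_identical(e1$eigengene, e2$eigengene)
  expect_error(module_eigengene(rbind(a = rep(1, 5), b = prof),
                                c("a", "b")), "constant")
})

test_that("kME: self-correlated gene 1, orthogonal gene 0, factor members 1", {
  e_prof <- c(1, -1, 1, -1, 1, -1) / sqrt(6)
  x <- rbind(
    same = e_prof,
    orth = c(1, 1, 1, 1, -2, -2)  # centered and orthogonal to e_prof
  )
  colnames(x) <- paste0("s", 1:6)
  kme <- module_membership(x, e_prof)
  expect_equal(unname(kme["same"]), 1.0)
  expect_equal(unname(kme["orth"]), 0.0, tolerance = 1e-12)

  # noise-free one-factor module: every member has |kME| = 1
  f <- c(0.3, -1, 2, 0.5, -0.7)
  x2 <- rbind(a = 2 * f, b = -0.5 * f, c = f + 1)
  colnames(x2) <- paste0("s", 1:5)
  e2 <- module_eigengene(x2, rownames(x2))
  expect_equal(unname(abs(module_membership(x2, e2))), rep(1, 3),
               tolerance = 1e-10)
})

test_that("network computation is invariant to gene-wise affine transforms", {
  cfg <- simulation_config(n_noise = 20, seed = 23)
  sim <- simulate_experiment(cfg, "human", 1)
  x <- suppressMessages(log_transform(sim$experiment$expression))
  net1 <- suppressWarnings(build_network(x, power = 6))
  scale_g <- runif(nrow(x), 0.5, 3)
  shift_g <- rnorm(nrow(x), 0, 5)
  net2 <- suppressWarnings(build_network(x * scale_g + shift_g, power = 6))
  expect_equal(net1$adjacency, net2$adjacency, tolerance = 1e-12)
  expect_equal(net1$modules, net2$modules)
  expect_equal(net1$connectivity, net2$connectivity, tolerance = 1e-10)
})

test_that("tidy/glance/network_edges expose the fitted network", {
  cfg <- simulation_config(n_noise = 20, seed = 29)
  sim <- simulate_experiment(cfg, "human", 1)
  x <- suppressMessages(log_transform(sim$experiment$expression))
  net <- suppressWarnings(build_network(x))
  td <- tidy(net)
  expect_named(td, c("gene", "module", "connectivity", "kme"))
  expect_equal(nrow(td), length(net$genes))
  gl <- glance(net)
  expect_equal(gl$n_modules, length(net$eigengenes))
  edges <- network_edges(net)
  expect_true(all(edges$tom >= net$min_interaction))
  p <- autoplot(net)
  expect_s3_class(p, "ggplot")
})
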