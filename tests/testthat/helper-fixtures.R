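# shared fixtures and independent oracles

# the worked 3-gene adjacency: a12 = 0.8, a13 = 0.5, a23 = 0.4
three_gene_adjacency <- function() {
  a <- matrix(c(1.0, 0.8, 0.5,
                0.8, 1.0, 0.4,
                0.5, 0.4, 1.0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  a
}

# brute-force TOM oracle: direct triple loop over the formula, independent
# of the matrix-product implementation
tom_oracle <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
      }
      tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(adj)
  tom
}

# random symmetric adjacency with entries in [0, 1] and unit diagonal
random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  rownames(a) <- colnames(a) <- paste0("g", seq_len(n))
  a
}

# adjusted Rand index between two partitions (contingency-table formula),
# independent of any clustering code under test
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  maximum <- (b + c) / 2
  (a - expected) / (maximum - expected)
}

# small metadata table covering the scorecard's base cases
demo_metadata <- function() {
  tibble::tibble(
    sample_id = paste0("s", 1:6),
    age = c("young", "young", "young", "old", "old", "old"),
    genotype = "wildtype",
    treatment = c("none", "health-improving", "health-reducing",
                  "none", "health-improving", "health-reducing")
  )
}

# a deterministic weighted factor-model matrix for eigengene checks
factor_model_matrix <- function(n_genes, n_samples, loadings = NULL,
                                noise = 0.3, seed = 42) {
  withr::with_seed(seed, {
    f <- rnorm(n_samples)
    loadings <- loadings %||% runif(n_genes, 0.5, 0.95)
    x <- loadings %*% t(f) +
      noise * matrix(rnorm(n_genes * n_samples), n_genes)
    rownames(x) <- paste0("g", seq_len(n_genes))
    colnames(x) <- paste0("s", seq_len(n_samples))
    x
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
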