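#' Configure a synthetic multi-species study
#'
#' Describes a collection of small expression experiments with planted
#' co-expression modules. Each planted module follows a one-factor model
#' x_gs = lambda_g * f_ms + sigma_g * eps_gs: genes load on a shared
#' per-sample factor, designated hub genes carry the largest loadings, and
#' for health modules the factor is constructed to correlate with the
#' per-sample latent health score at the configured target. Noise genes are
#' independent of everything.
#'
#' @param species Character vector of species tags (>= 2 for consensus
#'   testing).
#' @param experiments_per_species Experiments simulated per species.
#' @param n_samples Samples per experiment; must exceed 6, the study
#'   inclusion rule.
#' @param modules Tibble describing the planted modules: `size` (>= the
#'   downstream minimum module size), `n_hubs` (genes given the top
#'   loadings), `trait_cor` (target eigengene-score correlation, in
#'   \[-1, 1\]; `NA` plants a module with no health association, whose
#'   factor is drawn freely so null behavior is realistic), `conserved`
#'   (TRUE maps the module's genes to shared human symbols across species).
#' @param n_noise Independent noise genes per experiment.
#' @param noise_scale Multiplier on the residual term; 0 gives a noise-free
#'   factor model (all within-module correlations 1).
#' @param platform `"log-intensity"` (values on log2 scale) or `"counts"`
#'   (log-normal mean plus Poisson sampling, exercising the low-count
#'   filter).
#' @param min_module_size Downstream minimum module size the planted sizes
#'   are validated against; default 30.
#' @param seed Single seed from which all randomness flows.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(species = c("human", "rat"),
                              experiments_per_species = 2,
                              n_samples = 12,
                              modules = default_modules(),
                              n_noise = 100,
                              noise_scale = 1,
                              platform = c("log-intensity", "counts"),
                              min_module_size = 30,
                              seed = 1) {
  platform <- match.arg(platform)
  modules <- tibble::as_tibble(modules)
  stopifnot(all(c("size", "n_hubs", "trait_cor", "conserved") %in%
                  names(modules)))
  if (n_samples <= 6) {
    stop("n_samples must exceed 6: experiments with six or fewer samples ",
         "fail the study inclusion rule", call. = FALSE)
  }
  if (any(modules$size < min_module_size)) {
    stop("planted module sizes must be >= the minimum module size (",
         min_module_size, ") used downstream", call. = FALSE)
  }
  tc <- modules$trait_cor
  if (any(!is.na(tc) & (tc < -1 | tc > 1))) {
    stop("trait_cor targets must lie in [-1, 1]", call. = FALSE)
  }
  stopifnot(all(modules$n_hubs >= 1), all(modules$n_hubs <= modules$size),
            n_noise >= 0, noise_scale >= 0)
  if (is.null(modules$name)) {
    modules$name <- paste0("M", seq_len(nrow(modules)))
  }
  structure(
    list(species = species,
         experiments_per_species = experiments_per_species,
         n_samples = n_samples, modules = modules, n_noise = n_noise,
         noise_scale = noise_scale, platform = platform,
         min_module_size = min_module_size, seed = seed),
    class = "simulation_config"
  )
}

#' Default planted-module layout
#'
#' One conserved health module (target eigengene-score correlation 0.8,
#' 5 hubs, 40 genes) and one non-conserved module with no planted health
#' association (35 genes).
#'
#' @return A module tibble for [simulation_config()].
#' @export
default_modules <- function() {
  tibble::tibble(
    name = c("M1", "M2"),
    size = c(40, 35),
    n_hubs = c(5, 5),
    trait_cor = c(0.8, NA),
    conserved = c(TRUE, FALSE)
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>", length(x$species), "species x",
      x$experiments_per_species, "experiments,", x$n_samples,
      "samples each,", x$platform, "\n")
  cat("  modules:", paste0(x$modules$name, "(", x$modules$size, ")",
                           collapse = " "),
      "+", x$n_noise, "noise genes\n")
  invisible(x)
}

# gene naming: species-local IDs; conserved module genes share a human
# symbol across species, everything else maps to a species-private symbol
gene_catalog <- function(config, species) {
  abbrev <- substr(species, 1, 3)
  mods <- config$modules
  rows <- list()
  for (m in seq_len(nrow(mods))) {
    idx <- seq_len(mods$size[m])
    rows[[m]] <- tibble::tibble(
      gene = sprintf("%s_%s_g%03d", abbrev, tolower(mods$name[m]), idx),
      module = mods$name[m],
      is_hub = idx <= mods$n_hubs[m],
      human_symbol = if (mods$conserved[m]) {
        sprintf("%sG%03d", mods$name[m], idx)
      } else {
        sprintf("%s_%s_PRIV%03d", toupper(abbrev), mods$name[m], idx)
      }
    )
  }
  noise <- tibble::tibble(
    gene = sprintf("%s_noise_g%03d", abbrev, seq_len(config$n_noise)),
    module = "noise",
    is_hub = FALSE,
    human_symbol = sprintf("%s_NOISE%03d", toupper(abbrev),
                           seq_len(config$n_noise))
  )
  dplyr::bind_rows(rows, noise)
}

# loadings: hubs take the top band, non-hubs a descending band below it
module_loadings <- function(size, n_hubs) {
  hub <- seq(0.98, 0.92, length.out = n_hubs)
  rest <- if (size > n_hubs) {
    seq(0.88, 0.55, length.out = size - n_hubs)
  } else {
    numeric(0)
  }
  c(hub, rest)
}

# standardize to empirical mean 0, sd 1
std <- function(v) as.numeric(scale(v))

# a factor with empirical correlation to z exactly equal to rho: residualize
# a random draw on z, standardize both parts, mix
exact_cor_factor <- function(z, rho) {
  zs <- std(z)
  e <- rnorm(length(z))
  e <- std(e - zs * sum(e * zs) / sum(zs * zs))
  rho * zs + sqrt(1 - rho^2) * e
}

#' Simulate one expression experiment with ground truth
#'
#' Builds sample metadata (age and treatment factors), derives the latent
#' health score exactly as the default scorecard would, then draws module
#' factors and gene expression from the planted one-factor model. The
#' returned ground truth carries the true module assignment, hub flags,
#' loadings, human symbols and the latent score.
#'
#' @param config A [simulation_config()].
#' @param species One of the configured species.
#' @param index Experiment index within that species (1-based).
#' @return A list with `experiment` (fields `id`, `species`, `platform`,
#'   `expression` genes x samples matrix, `metadata` tibble) and `truth`
#'   (fields `genes`, `scores`, `modules`).
#' @export
simulate_experiment <- function(config, species, index = 1) {
  stopifnot(inherits(config, "simulation_config"))
  if (!species %in% config$species) {
    stop("species '", species, "' is not in the configuration", call. = FALSE)
  }
  exp_id <- sprintf("%s_e%02d", species, index)
  n <- config$n_samples
  with_seed(stable_seed(config$seed, exp_id), {
    sample_id <- sprintf("%s_s%02d", exp_id, seq_len(n))
    metadata <- tibble::tibble(
      sample_id = sample_id,
      age = rep(c("young", "old"), length.out = n),
      treatment = rep(c("none", "health-improving", "health-reducing"),
                      length.out = n)[sample(n)]
    )
    scores <- suppressWarnings(score_samples(metadata, scorecard()))
    z <- std(scores$score)
    catalog <- gene_catalog(config, species)
    mods <- config$modules
    expr <- matrix(NA_real_, nrow = nrow(catalog), ncol = n,
                   dimnames = list(catalog$gene, sample_id))
    factors <- matrix(NA_real_, nrow = nrow(mods), ncol = n,
                      dimnames = list(mods$name, sample_id))
    for (m in seq_len(nrow(mods))) {
      f <- if (is.na(mods$trait_cor[m])) {
        std(rnorm(n))
      } else {
        exact_cor_factor(z, mods$trait_cor[m])
      }
      factors[m, ] <- f
      lambda <- module_loadings(mods$size[m], mods$n_hubs[m])
      rows <- which(catalog$module == mods$name[m])
      eps <- matrix(rnorm(length(rows) * n), nrow = length(rows))
      expr[rows, ] <- lambda * matrix(f, nrow = length(rows), ncol = n,
                                      byrow = TRUE) +
        config$noise_scale * sqrt(1 - lambda^2) * eps
    }
    noise_rows <- which(catalog$module == "noise")
    if (length(noise_rows) > 0) {
      expr[noise_rows, ] <- rnorm(length(noise_rows) * n)
    }
    if (config$platform == "counts") {
      base_log2 <- runif(nrow(expr), 3, 8)
      mu <- 2^(base_log2 + expr)
      expr <- matrix(rpois(length(mu), lambda = mu), nrow = nrow(mu),
                     dimnames = dimnames(expr))
    } else {
      expr <- expr + runif(nrow(expr), 5, 10)
    }
    truth_genes <- catalog
    truth_genes$loading <- NA_real_
    for (m in seq_len(nrow(mods))) {
      truth_genes$loading[truth_genes$module == mods$name[m]] <-
        module_loadings(mods$size[m], mods$n_hubs[m])
    }
    list(
      experiment = list(id = exp_id, species = species,
                        platform = config$platform, expression = expr,
                        metadata = metadata),
      truth = list(
        genes = truth_genes,
        scores = dplyr::mutate(scores, z = z),
        modules = dplyr::mutate(
          mods,
          health = !is.na(.data$trait_cor) & .data$trait_cor != 0,
          factor_score_cor = vapply(seq_len(nrow(mods)), function(m) {
            cor(factors[m, ], z)
          }, numeric(1))
        )
      )
    )
  })
}

#' Simulate a multi-species collection with ortholog map
#'
#' Runs [simulate_experiment()] for every configured species and experiment
#' index, assembles the collection-wide ortholog table (conserved planted
#' genes share human symbols across species; all other genes map to
#' species-private symbols), and collects the ground truth.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_collection` with `experiments` (list
#'   of experiment objects keyed by ID), `truths` (ground truths keyed by
#'   ID), `orthologs` (tibble `species`, `gene`, `human_symbol`) and
#'   `conserved_symbols` (human symbols planted in >= 2 species).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  experiments <- list()
  truths <- list()
  ortho <- list()
  for (sp in config$species) {
    catalog <- gene_catalog(config, sp)
    ortho[[sp]] <- tibble::tibble(species = sp, gene = catalog$gene,
                                  human_symbol = catalog$human_symbol)
    for (i in seq_len(config$experiments_per_species)) {
      sim <- simulate_experiment(config, sp, i)
      id <- sim$experiment$id
      if (id %in% names(experiments)) {
        stop("duplicate experiment identifier: ", id, call. = FALSE)
      }
      experiments[[id]] <- sim$experiment
      truths[[id]] <- sim$truth
    }
  }
  orthologs <- dplyr::bind_rows(ortho)
  conserved <- orthologs |>
    dplyr::distinct(.data$species, .data$human_symbol) |>
    dplyr::count(.data$human_symbol) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(.data$human_symbol)
  structure(
    list(experiments = experiments, truths = truths, orthologs = orthologs,
         conserved_symbols = conserved, config = config),
    class = "simulated_collection"
  )
}

#' @export
print.simulated_collection <- function(x, ...) {
  cat("<simulated_collection>", length(x$experiments), "experiments,",
      length(unique(vapply(x$experiments, function(e) e$species,
                           character(1)))), "species,",
      length(x$conserved_symbols), "conserved symbols\n")
  invisible(x)
}

#' Write a simulated collection to disk
#'
#' One expression TSV and one metadata TSV per experiment, the ortholog TSV,
#' and the ground truth as JSON.
#'
#' @param collection A `simulated_collection`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "simulated_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(collection$experiments)) {
    e <- collection$experiments[[id]]
    write_expression_tsv(e$expression,
                         file.path(dir, paste0(id, "_expression.tsv")))
    readr::write_tsv(e$metadata, file.path(dir, paste0(id, "_metadata.tsv")))
  }
  write_ortholog_tsv(collection$orthologs, file.path(dir, "orthologs.tsv"))
  truth <- lapply(collection$truths, function(t) {
    list(genes = t$genes, scores = t$scores, modules = t$modules)
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
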