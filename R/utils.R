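# internal helpers shared across modules

# stable 32-bit seed derived from a string; used to give each experiment an
# independent, reproducible random stream from one global seed
stable_seed <- function(global_seed, id) {
  bytes <- utf8ToInt(id)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647L
  as.integer((as.numeric(global_seed) * 2654435761 + h) %% 2147483647)
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

check_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  x
}

# upper-triangle values of a symmetric matrix, each unordered pair once
upper_values <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
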