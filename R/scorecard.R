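#' Construct a health-phenotype scorecard
#'
#' A scorecard turns per-sample experimental factors into a within-experiment
#' health phenotype score. The convention encoded here assigns the young
#' untreated wildtype a score of 1 and old individuals a score of 0; every
#' applicable treatment rule then adds or subtracts its increment (0.2 by
#' default). Gene knock-downs, knock-outs, gene transfers and natural genetic
#' variants are treated like any other treatment: a rule on the factor column
#' that records them. Scores are comparable only within one experiment, never
#' across experiments.
#'
#' @param base Named numeric vector mapping age categories to base scores.
#' @param treatments Data frame with columns `factor` (metadata column name),
#'   `value` (factor level the rule applies to), `effect` (+1 improves health,
#'   -1 reduces it) and optionally `magnitude` (default 0.2 per rule).
#' @param age_column Metadata column holding the age category.
#' @param formula Optional custom arithmetic formula (a string evaluated over
#'   the metadata columns) that replaces the rule sum entirely; the escape
#'   hatch for experiments whose score needs bespoke arithmetic.
#' @param note Free-text provenance note.
#' @return An object of class `scorecard`.
#' @examples
#' card <- scorecard()
#' score_samples(
#'   data.frame(sample_id = "a", age = "young", treatment = "none"),
#'   card
#' )
#' @export
scorecard <- function(base = c(young = 1, old = 0),
                      treatments = default_treatment_rules(),
                      age_column = "age",
                      formula = NULL,
                      note = NULL) {
  stopifnot(is.numeric(base), !is.null(names(base)))
  treatments <- tibble::as_tibble(treatments)
  if (nrow(treatments) > 0) {
    stopifnot(all(c("factor", "value", "effect") %in% names(treatments)))
    if (!"magnitude" %in% names(treatments)) treatments$magnitude <- 0.2
    treatments$magnitude[is.na(treatments$magnitude)] <- 0.2
    if (any(!is.finite(treatments$magnitude))) {
      stop("treatment rule increments must be finite", call. = FALSE)
    }
  }
  structure(
    list(base = base, treatments = treatments, age_column = age_column,
         formula = formula, note = note),
    class = "scorecard"
  )
}

#' Default treatment rules
#'
#' Health-improving treatments add 0.2, health-reducing treatments subtract
#' 0.2, matching the default increments of the scorecard convention.
#'
#' @return A tibble of treatment rules.
#' @export
default_treatment_rules <- function() {
  tibble::tibble(
    factor = c("treatment", "treatment"),
    value = c("health-improving", "health-reducing"),
    effect = c(1, -1),
    magnitude = c(0.2, 0.2)
  )
}

#' @export
print.scorecard <- function(x, ...) {
  cat("<scorecard>\n")
  cat("  base (", x$age_column, "): ",
      paste(names(x$base), x$base, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  treatment rules:", nrow(x$treatments), "\n")
  if (!is.null(x$formula)) cat("  custom formula:", x$formula, "\n")
  invisible(x)
}

#' Score samples with a scorecard
#'
#' Applies the scorecard to a sample metadata table and returns one health
#' phenotype score per sample: base score for the sample's age category plus
#' the signed increments of every treatment rule whose factor value matches.
#' If the card carries a custom formula, the formula is evaluated over the
#' metadata columns instead.
#'
#' @param metadata Data frame with a `sample_id` column and the factor columns
#'   the card references.
#' @param card A [scorecard()].
#' @return A tibble with columns `sample_id` and `score`, plus an attribute
#'   `constant` flagging the degenerate all-equal case (downstream module
#'   selection refuses constant phenotypes).
#' @export
score_samples <- function(metadata, card) {
  stopifnot(inherits(card, "scorecard"))
  metadata <- tibble::as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata must have a 'sample_id' column", call. = FALSE)
  }
  if (!is.null(card$formula)) {
    score <- rlang::eval_tidy(rlang::parse_expr(card$formula), data = metadata)
    score <- as.numeric(score)
  } else {
    needed <- unique(c(card$age_column, card$treatments$factor))
    missing_cols <- setdiff(needed, names(metadata))
    if (length(missing_cols) > 0) {
      stop("metadata is missing factor column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    age <- as.character(metadata[[card$age_column]])
    unknown <- setdiff(unique(age), names(card$base))
    if (length(unknown) > 0) {
      stop("no base score for age categor", if (length(unknown) > 1) "ies: " else "y: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    score <- unname(card$base[age])
    if (nrow(card$treatments) > 0) {
      for (i in seq_len(nrow(card$treatments))) {
        rule <- card$treatments[i, ]
        hit <- as.character(metadata[[rule$factor]]) == rule$value
        score <- score + ifelse(hit, rule$effect * rule$magnitude, 0)
      }
    }
  }
  out <- tibble::tibble(sample_id = as.character(metadata$sample_id), score = score)
  constant <- length(unique(out$score)) <= 1
  if (constant) {
    warning("all samples received the same health phenotype score; ",
            "eigengene-trait correlation will be undefined", call. = FALSE)
  }
  attr(out, "constant") <- constant
  out
}

#' Validate a scorecard against sample metadata
#'
#' Report-only check: lists rules referencing absent factor columns, rules
#' that never fire, samples left at their bare base score, and the
#' constant-score condition.
#'
#' @inheritParams score_samples
#' @return A tibble of issues with columns `kind` and `detail`; zero rows
#'   means a clean card.
#' @export
validate_scorecard <- function(card, metadata) {
  stopifnot(inherits(card, "scorecard"))
  metadata <- tibble::as_tibble(metadata)
  issues <- list()
  add <- function(kind, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(kind = kind, detail = detail)
  }
  if (is.null(card$formula)) {
    needed <- unique(c(card$age_column, card$treatments$factor))
    for (col in setdiff(needed, names(metadata))) {
      add("missing_column", col)
    }
    if (nrow(card$treatments) > 0) {
      for (i in seq_len(nrow(card$treatments))) {
        rule <- card$treatments[i, ]
        if (rule$factor %in% names(metadata) &&
            !any(as.character(metadata[[rule$factor]]) == rule$value)) {
          add("unused_rule", paste0(rule$factor, "=", rule$value))
        }
      }
    }
  }
  scores <- tryCatch(
    suppressWarnings(score_samples(metadata, card)),
    error = function(e) NULL
  )
  if (!is.null(scores) && isTRUE(attr(scores, "constant"))) {
    add("constant_score", "all samples score identically")
  }
  if (length(issues) == 0) {
    tibble::tibble(kind = character(), detail = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Read a scorecard from YAML or JSON
#'
#' Scorecards are kept as declarative config files so per-experiment scoring
#' judgments stay auditable. The file holds `base` (age category to score),
#' optional `age_column`, a `treatments` list of rules (`factor`, `value`,
#' `effect`, optional `magnitude`), and an optional `formula` string.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scorecard file.
#' @return A [scorecard()].
#' @export
read_scorecard <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- unlist(raw$base)
  treatments <- if (is.null(raw$treatments)) {
    tibble::tibble(factor = character(), value = character(),
                   effect = numeric(), magnitude = numeric())
  } else {
    dplyr::bind_rows(lapply(raw$treatments, tibble::as_tibble))
  }
  scorecard(
    base = base,
    treatments = treatments,
    age_column = raw$age_column %||% "age",
    formula = raw$formula,
    note = raw$note
  )
}

#' Write a phenotype vector as two-column TSV
#'
#' @param scores Tibble from [score_samples()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phenotype_tsv <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(path)
}
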