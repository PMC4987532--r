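#' Per-host score tables for building removal orders
#'
#' A `score_table` maps host identifiers to a numeric score (continuous, or
#' integer ranks derived from ordinal categories such as IUCN risk classes)
#' together with a direction flag saying whether a higher score means a more
#' vulnerable host, i.e. one removed earlier in a score-ranked scenario.
#'
#' @param scores named numeric vector (names are host identifiers), or a
#'   data frame with columns `host` and `score`.
#' @param higher_is_vulnerable logical; `TRUE` (default) means higher scores
#'   are removed first in a `by_score` scenario.
#' @return an object of class `score_table`: a named numeric vector with a
#'   `higher_is_vulnerable` attribute.
#' @examples
#' vuln <- score_table(c(h1 = 0.9, h2 = 0.1))
#' @export
score_table <- function(scores, higher_is_vulnerable = TRUE) {
  if (is.data.frame(scores)) {
    if (!all(c("host", "score") %in% names(scores))) {
      stopf("score data frame must have columns `host` and `score`")
    }
    scores <- stats::setNames(as.numeric(scores$score), as.character(scores$host))
  }
  if (!is.numeric(scores) || is.null(names(scores)) || any(names(scores) == "")) {
    stopf("`scores` must be a named numeric vector or a host/score data frame")
  }
  if (anyDuplicated(names(scores))) stopf("duplicate host identifiers in score table")
  if (anyNA(scores)) stopf("missing score values")
  structure(as.numeric(stats::setNames(scores, names(scores))),
            names = names(scores),
            higher_is_vulnerable = isTRUE(higher_is_vulnerable),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Score table for %d hosts (higher score = %s vulnerable, removed %s)\n",
              length(x),
              if (attr(x, "higher_is_vulnerable")) "more" else "less",
              if (attr(x, "higher_is_vulnerable")) "earlier" else "later"))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read a score table from CSV
#'
#' Expected header `host,score`; alternatively an ordinal `category` column
#' can be mapped to integer ranks via `category_levels`, given in increasing
#' order of the quantity the direction flag describes (e.g.
#' `c("LC","NT","VU","EN","CR")` with `higher_is_vulnerable = TRUE` makes CR
#' the first-removed category).
#'
#' @param path CSV path.
#' @param host_column,score_column,category_column column names; when
#'   `category_column` is non-`NULL` it takes precedence over the score
#'   column.
#' @param category_levels character vector of categories in increasing score
#'   order; required with `category_column`.
#' @param higher_is_vulnerable direction flag, see [score_table()].
#' @return a [score_table()].
#' @export
read_scores <- function(path, host_column = "host", score_column = "score",
                        category_column = NULL, category_levels = NULL,
                        higher_is_vulnerable = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!host_column %in% names(df)) stopf("column '%s' not found in %s", host_column, path)
  if (!is.null(category_column)) {
    if (!category_column %in% names(df)) {
      stopf("column '%s' not found in %s", category_column, path)
    }
    if (is.null(category_levels)) {
      stopf("`category_levels` (categories in increasing score order) is required with a category column")
    }
    bad <- setdiff(unique(df[[category_column]]), category_levels)
    if (length(bad)) stopf("unknown categor%s: %s", if (length(bad) > 1) "ies" else "y",
                           paste(bad, collapse = ", "))
    val <- match(df[[category_column]], category_levels)
  } else {
    if (!score_column %in% names(df)) stopf("column '%s' not found in %s", score_column, path)
    val <- as.numeric(df[[score_column]])
  }
  score_table(stats::setNames(val, as.character(df[[host_column]])),
              higher_is_vulnerable = higher_is_vulnerable)
}

#' Map ordinal categories to a score table
#'
#' Convenience wrapper when categories are already in memory.
#'
#' @param categories named character vector, names are hosts.
#' @param levels categories in increasing score order.
#' @inheritParams score_table
#' @return a [score_table()] of integer ranks.
#' @export
ordinal_scores <- function(categories, levels, higher_is_vulnerable = TRUE) {
  bad <- setdiff(unique(categories), levels)
  if (length(bad)) stopf("unknown categor%s: %s", if (length(bad) > 1) "ies" else "y",
                         paste(bad, collapse = ", "))
  score_table(stats::setNames(match(categories, levels), names(categories)),
              higher_is_vulnerable = higher_is_vulnerable)
}

# Check score coverage of a network's hosts. strict: error on any missing
# host; otherwise return the missing set.
check_score_coverage <- function(scores, net, strict = TRUE) {
  stopifnot(inherits(scores, "score_table"), inherits(net, "bipartite_network"))
  missing <- setdiff(net$hosts, names(scores))
  if (strict && length(missing)) {
    stopf("score table does not cover host(s): %s", paste(missing, collapse = ", "))
  }
  missing
}

# Score vector oriented so that LARGER value = removed EARLIER,
# in the order of net$hosts.
removal_key <- function(scores, net) {
  check_score_coverage(scores, net, strict = TRUE)
  s <- as.numeric(scores)[match(net$hosts, names(scores))]
  if (attr(scores, "higher_is_vulnerable")) s else -s
}
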