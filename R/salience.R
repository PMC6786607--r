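# Salience-rating analysis: median/IQR aggregation over blocks and
# listeners, and rank-based (Friedman) tests for level and condition
# effects on the grand-median matrix.

#' Read a ratings CSV
#'
#' Expects columns `listener`, `condition`, `level_db_sl`, `block`,
#' `rating`. The very first block of a session serves as additional
#' training and is excluded by default.
#'
#' @param path CSV file path.
#' @param exclude_first_block Drop `block == min(block)` rows.
#' @return Tibble of class `rating_table`.
#' @export
read_rating_table <- function(path, exclude_first_block = TRUE) {
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("listener", "condition", "level_db_sl", "block", "rating")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    stop("ratings file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(tbl$rating < 0 | tbl$rating > 10)) {
    stop("ratings outside the 0-10 scale")
  }
  if (exclude_first_block) tbl <- tbl[tbl$block != min(tbl$block), ]
  class(tbl) <- c("rating_table", class(tbl))
  tbl
}

#' Aggregate ratings to medians and interquartile ranges
#'
#' @param table A rating table (columns `listener`, `condition`,
#'   `level_db_sl`, `rating`).
#' @return Tibble with per listener, condition and level `median` and
#'   `iqr` over blocks.
#' @export
aggregate_ratings <- function(table) {
  table |>
    dplyr::group_by(.data$listener, .data$condition, .data$level_db_sl) |>
    dplyr::summarise(
      median = stats::median(.data$rating),
      iqr = stats::IQR(.data$rating),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Grand-median condition-by-level matrix
#'
#' Medians over blocks per listener, then medians over listeners, arranged
#' with conditions in rows and sensation levels in columns.
#'
#' @inheritParams aggregate_ratings
#' @return Numeric matrix, conditions x levels.
#' @export
grand_median_matrix <- function(table) {
  per <- aggregate_ratings(table)
  grand <- per |>
    dplyr::group_by(.data$condition, .data$level_db_sl) |>
    dplyr::summarise(median = stats::median(.data$median),
                     .groups = "drop")
  wide <- grand |>
    tidyr::pivot_wider(names_from = "level_db_sl",
                       values_from = "median") |>
    dplyr::arrange(.data$condition)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$condition
  m
}

#' Friedman rank test for column effects
#'
#' Within-row mid-ranks with the standard tie-corrected statistic
#' \deqn{\chi^2 = \frac{(k-1)\sum_j (R_j - n(k+1)/2)^2}
#'                     {\sum_{ij} r_{ij}^2 - nk(k+1)^2/4}}
#' which reduces to the classical
#' \eqn{12/(nk(k+1))\sum R_j^2 - 3n(k+1)} without ties; the p-value comes
#' from the chi-square distribution with \eqn{k-1} degrees of freedom, or
#' from a within-row permutation null in the verification mode.
#'
#' @param m Numeric matrix: rows are blocks/subjects, columns are the
#'   treatments under test. No missing cells are allowed.
#' @param arrangement Label recording which factor forms the columns.
#' @param p_method `"chisq"` (asymptotic) or `"permutation"`.
#' @param n_perm Number of permutation replicates.
#' @param seed Optional seed for the permutation mode.
#' @return An object of class `friedman_rank_test`.
#' @export
#' @examples
#' friedman_rank_test(matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3,
#'                           byrow = TRUE))
friedman_rank_test <- function(m, arrangement = "columns",
                               p_method = c("chisq", "permutation"),
                               n_perm = 2000, seed = NULL) {
  p_method <- match.arg(p_method)
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed (no imputation)")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("at least 2 rows and 2 columns are required")
  stat_of <- function(mm) {
    r <- t(apply(mm, 1, rank)) # mid-ranks for ties
    cs <- colSums(r)
    num <- (k - 1) * sum((cs - n * (k + 1) / 2)^2)
    den <- sum(r^2) - n * k * (k + 1)^2 / 4
    if (den == 0) 0 else num / den
  }
  statistic <- stat_of(m)
  df <- k - 1
  p <- if (p_method == "chisq") {
    if (statistic == 0) 1 else stats::pchisq(statistic, df,
                                             lower.tail = FALSE)
  } else {
    with_seed(seed, {
      null <- replicate(n_perm, {
        stat_of(t(apply(m, 1, sample)))
      })
      (sum(null >= statistic) + 1) / (n_perm + 1)
    })
  }
  structure(
    list(statistic = statistic, df = df, p.value = p,
         arrangement = arrangement, n = n, k = k, p_method = p_method),
    class = "friedman_rank_test"
  )
}

#' @export
print.friedman_rank_test <- function(x, ...) {
  cat(sprintf(
    "<friedman_rank_test> %s: chi^2(%d) = %.2f, p %s (%d x %d, %s)\n",
    x$arrangement, x$df, x$statistic,
    format.pval(x$p.value, digits = 3), x$n, x$k, x$p_method
  ))
  invisible(x)
}

#' Tidy a Friedman rank test
#'
#' @param x A `friedman_rank_test`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p.value`,
#'   `arrangement`, `method`.
#' @exportS3Method generics::tidy
tidy.friedman_rank_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p.value = x$p.value,
    arrangement = x$arrangement, method = x$p_method
  )
}

#' @rdname tidy.friedman_rank_test
#' @exportS3Method generics::glance
glance.friedman_rank_test <- function(x, ...) tidy(x, ...)

#' Level-effect and condition-effect Friedman tests on a rating table
#'
#' Builds the grand-median matrix (conditions in rows, sensation levels in
#' columns), tests the level effect with levels as columns, transposes the
#' matrix, and tests the condition effect — two separate tests since the
#' Friedman procedure cannot assess interactions. With
#' `arrangement = "stacked"`, per-listener medians form the rows instead
#' of the grand medians (listener-by-condition rows for the level test and
#' listener-by-level rows for the condition test).
#'
#' @inheritParams aggregate_ratings
#' @param arrangement `"grand"` (default) or `"stacked"`.
#' @return List of class `salience_tests` with elements `level` and
#'   `condition`, both `friedman_rank_test` objects.
#' @export
run_experiment3_tests <- function(table, arrangement = c("grand",
                                                         "stacked")) {
  arrangement <- match.arg(arrangement)
  if (arrangement == "grand") {
    m <- grand_median_matrix(table)
    lev <- friedman_rank_test(m, "levels-as-columns")
    cond <- friedman_rank_test(t(m), "conditions-as-columns")
  } else {
    per <- aggregate_ratings(table) |>
      dplyr::select("listener", "condition", "level_db_sl", "median")
    lev_m <- per |>
      tidyr::pivot_wider(names_from = "level_db_sl",
                         values_from = "median") |>
      dplyr::select(-"listener", -"condition") |>
      as.matrix()
    cond_m <- per |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = "median") |>
      dplyr::select(-"listener", -"level_db_sl") |>
      as.matrix()
    lev <- friedman_rank_test(lev_m, "levels-as-columns")
    cond <- friedman_rank_test(cond_m, "conditions-as-columns")
  }
  structure(list(level = lev, condition = cond), class = "salience_tests")
}

#' @export
print.salience_tests <- function(x, ...) {
  cat("<salience_tests>\n  ")
  print(x$level)
  cat("  ")
  print(x$condition)
  invisible(x)
}

#' @rdname tidy.friedman_rank_test
#' @exportS3Method generics::tidy
tidy.salience_tests <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$level), effect = "level", .before = 1),
    dplyr::mutate(tidy(x$condition), effect = "condition", .before = 1)
  )
}
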