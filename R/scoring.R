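#' Dimension scores from a normalized panel
#'
#' A region-year's score on a capacity dimension is the within-dimension
#' weighted mean of its normalized member indicators,
#' `s_d = sum_{j in d} within_j * y_j`, hence always in `[0, 1]`.
#'
#' @param normalized a `normalized_panel`
#' @param weights a `weight_set`
#' @return data.frame: `region`, `category`, `year`, one column per
#'   dimension id
#' @export
dimension_scores <- function(normalized, weights) {
  if (anyNA(normalized$value)) stop_regcap("missing normalized cell")
  mat <- panel_matrix(normalized)
  inds <- names(weights$combined)
  miss <- setdiff(inds, colnames(mat))
  if (length(miss))
    stop_regcap("panel lacks indicator(s): ", paste(miss, collapse = ", "))
  mat <- mat[, inds, drop = FALSE]
  objs <- panel_objects(normalized)
  dims <- names(weights$dimension_weights)
  out <- objs
  for (d in dims) {
    member <- inds[weights$dimension_of[inds] == d]
    w <- weights$within_dimension[member]
    out[[d]] <- as.numeric(mat[, member, drop = FALSE] %*% w)
  }
  rownames(out) <- NULL
  out
}

#' Composite score from dimension scores
#'
#' The composite capacity index is the dimension-weighted sum
#' `sum_d W_d * s_d`. A `composite_3dp` column carries the value rounded
#' half-up to 3 decimals, the precision at which published score tables
#' print.
#'
#' @param dim_scores data.frame from [dimension_scores()], or any
#'   data.frame containing the dimension columns
#' @param weights a `weight_set` (only `dimension_weights` is used)
#' @return `dim_scores` with `composite` and `composite_3dp` columns
#' @export
composite_scores <- function(dim_scores, weights) {
  W_d <- weights$dimension_weights
  miss <- setdiff(names(W_d), names(dim_scores))
  if (length(miss))
    stop_regcap("dimension column(s) absent: ", paste(miss, collapse = ", "))
  comp <- as.matrix(dim_scores[, names(W_d), drop = FALSE]) %*% W_d
  dim_scores$composite <- as.numeric(comp)
  dim_scores$composite_3dp <- round_half_up(dim_scores$composite, 3)
  dim_scores
}

#' Competition ranking of composites
#'
#' Descending "1224" ranking: values tied at the comparison precision
#' share a rank and the following ranks are skipped. Published tables
#' print composites at 3 decimals and exhibit exactly this tie pattern, so
#' the default compares at 3 decimals (set `digits = NULL` for full
#' precision).
#'
#' @param composite numeric vector of composite scores
#' @param digits rounding applied before comparison (default 3)
#' @return integer ranks, 1 = best
#' @export
#' @examples
#' rank_regions(c(0.204, 0.172, 0.172, 0.162))  # 1 2 2 4
rank_regions <- function(composite, digits = 3) {
  v <- if (is.null(digits)) composite else round_half_up(composite, digits)
  vapply(v, function(x) 1L + sum(v > x), integer(1))
}

#' Count values strictly above their mean
#'
#' With `digits` set, the mean is rounded (half-up) to that precision
#' before the strict comparison — the convention used when counting
#' against a published table whose values and average are printed at fixed
#' precision.
#'
#' @param values numeric vector
#' @param digits optional precision at which the mean is compared
#' @return integer count
#' @export
count_above_mean <- function(values, digits = NULL) {
  if (!length(values)) stop_regcap("empty vector")
  m <- mean(values)
  if (!is.null(digits)) m <- round_half_up(m, digits)
  sum(values > m)
}

#' Group means and standard deviations of score columns
#'
#' Means and sample SDs (n-1 denominator) per regional category plus a
#' national row. A single-member group has no sample SD; it is reported as
#' 0 and flagged.
#'
#' @param scores data.frame with a `category` column and numeric score
#'   columns
#' @param columns score columns to summarize (default: all numeric except
#'   `year`/`rank`)
#' @return data.frame: `group`, `n`, then `<col>_mean`, `<col>_sd` pairs,
#'   and `sd_defined` flag
#' @export
group_means <- function(scores, columns = NULL) {
  if (is.null(columns)) {
    num <- vapply(scores, is.numeric, logical(1))
    columns <- setdiff(names(scores)[num], c("year", "rank", "composite_3dp"))
  }
  groups <- c("national", intersect(region_categories, unique(scores$category)))
  rows <- lapply(groups, function(g) {
    sub <- if (g == "national") scores else scores[scores$category == g, ]
    if (!nrow(sub)) stop_regcap("empty group: ", g)
    row <- data.frame(group = g, n = nrow(sub), stringsAsFactors = FALSE)
    for (col in columns) {
      row[[paste0(col, "_mean")]] <- mean(sub[[col]])
      row[[paste0(col, "_sd")]] <- if (nrow(sub) > 1) stats::sd(sub[[col]]) else 0
    }
    row$sd_defined <- nrow(sub) > 1
    row
  })
  do.call(rbind, rows)
}

#' Year-ordered group-mean trend table
#'
#' For each regional category (plus national) and score column, the group
#' mean per year and its year-over-year change, the tidy input for
#' dynamic-development panels.
#'
#' @param scores data.frame with `category`, `year` and score columns
#' @param columns score columns (default as in [group_means()])
#' @return data.frame: `group`, `column`, `year`, `mean`, `delta`
#' @export
trend_table <- function(scores, columns = NULL) {
  years <- sort(unique(scores$year))
  if (length(years) < 2) stop_regcap("need at least 2 years for a trend table")
  if (is.null(columns)) {
    num <- vapply(scores, is.numeric, logical(1))
    columns <- setdiff(names(scores)[num], c("year", "rank", "composite_3dp"))
  }
  groups <- c("national", intersect(region_categories, unique(scores$category)))
  out <- list()
  for (g in groups) {
    sub <- if (g == "national") scores else scores[scores$category == g, ]
    for (col in columns) {
      m <- vapply(years, function(y) mean(sub[[col]][sub$year == y]), numeric(1))
      out[[paste(g, col)]] <- data.frame(
        group = g, column = col, year = years, mean = m,
        delta = c(NA_real_, diff(m)), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score a normalized panel end to end
#'
#' Dimension scores, composite, printed-precision composite and
#' within-year competition ranks in one call.
#'
#' @inheritParams dimension_scores
#' @param rank_digits precision for ranking ties (see [rank_regions()])
#' @return a score table data.frame: `region`, `category`, `year`,
#'   dimension columns, `composite`, `composite_3dp`, `rank`
#' @export
score_panel <- function(normalized, weights, rank_digits = 3) {
  tab <- composite_scores(dimension_scores(normalized, weights), weights)
  tab$rank <- NA_integer_
  for (y in unique(tab$year)) {
    sel <- tab$year == y
    tab$rank[sel] <- rank_regions(tab$composite[sel], digits = rank_digits)
  }
  tab
}

#' The published 2022 provincial score table
#'
#' The printed 2022 table: per region its category, rank, composite and
#' five dimension scores at 3 decimals. Used as the fixture for
#' reconstruction checks and the regional ANOVA.
#'
#' @return data.frame with columns `region`, `category`, `rank`,
#'   `composite`, `resource`, `functional`, `performance`, `learning`,
#'   `internet`
#' @export
printed_scores_2022 <- function() {
  utils::read.csv(regcap_example("printed_scores_2022.csv"),
                  stringsAsFactors = FALSE)
}
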