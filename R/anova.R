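#' One-way fixed-effects ANOVA
#'
#' Classic decomposition by hand: between-group sum of squares over
#' `groups - 1` degrees of freedom against within-group sum of squares
#' over `N - groups`; `F = MSB / MSW` and the p-value is the upper tail of
#' the F distribution. Requires at least two groups of at least two
#' members each and positive within-group variance.
#'
#' @param values numeric vector of observations
#' @param grouping group label per observation
#' @return list with `F`, `p`, `df` (between, within), `groups`
#'   (data.frame `group`, `n`, `mean`, `sd`), `stars`
#' @export
one_way_anova <- function(values, grouping) {
  grouping <- as.character(grouping)
  if (length(values) != length(grouping))
    stop_regcap("values and grouping differ in length")
  keep <- !is.na(values)
  values <- values[keep]; grouping <- grouping[keep]
  groups <- unique(grouping)
  k <- length(groups)
  if (k < 2) stop_regcap("need at least 2 groups")
  n_g <- table(grouping)[groups]
  if (any(n_g < 2))
    stop_regcap("group(s) with fewer than 2 members: ",
                paste(groups[n_g < 2], collapse = ", "))
  N <- length(values)
  grand <- mean(values)
  means <- tapply(values, grouping, mean)[groups]
  ssb <- sum(n_g * (means - grand)^2)
  ssw <- sum((values - means[grouping])^2)
  df_b <- k - 1L
  df_w <- N - k
  if (ssw <= 0) stop_regcap("degenerate ANOVA: zero within-group variance")
  F_stat <- (ssb / df_b) / (ssw / df_w)
  p <- stats::pf(F_stat, df_b, df_w, lower.tail = FALSE)
  gtab <- data.frame(group = groups, n = as.integer(n_g),
                     mean = as.numeric(means),
                     sd = as.numeric(tapply(values, grouping, stats::sd)[groups]),
                     stringsAsFactors = FALSE)
  list(F = F_stat, p = p, df = c(between = df_b, within = df_w),
       groups = gtab, stars = significance_flags(p))
}

#' Significance stars for a p-value
#'
#' `"**"` below 0.01, `"*"` below 0.05, otherwise none — the flagging
#' convention of the published ANOVA table.
#'
#' @param p p-value(s) in `[0, 1]`
#' @return character vector of flags
#' @export
significance_flags <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_regcap("p outside [0, 1]")
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Regional ANOVA over every score column
#'
#' One-way ANOVA of each dimension score and the composite across the
#' eastern/central/western categories for one year, mirroring the
#' published variance-analysis table (group mean ± SD, F, p, stars).
#'
#' @param scores score table with `category`, score columns and optionally
#'   `year`
#' @param year year to analyze (default: the latest; ignored when the
#'   table has no `year` column)
#' @param columns score columns (default: dimensions + composite)
#' @return data.frame: `column`, `F`, `p`, `df_between`, `df_within`,
#'   `stars`, then `<group>_mean`/`<group>_sd` columns
#' @export
anova_by_column <- function(scores, year = NULL, columns = NULL) {
  sub <- if ("year" %in% names(scores)) {
    y <- year %||% max(scores$year)
    scores[scores$year == y, , drop = FALSE]
  } else scores
  if (!nrow(sub)) stop_regcap("no rows for year ", year)
  if (is.null(columns)) {
    num <- vapply(sub, is.numeric, logical(1))
    columns <- setdiff(names(sub)[num], c("year", "rank", "composite_3dp"))
  }
  rows <- lapply(columns, function(col) {
    a <- one_way_anova(sub[[col]], sub$category)
    row <- data.frame(column = col, F = a$F, p = a$p,
                      df_between = a$df[["between"]],
                      df_within = a$df[["within"]],
                      stars = a$stars, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(a$groups))) {
      row[[paste0(a$groups$group[i], "_mean")]] <- a$groups$mean[i]
      row[[paste0(a$groups$group[i], "_sd")]] <- a$groups$sd[i]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
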