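#' Raw indicator panel
#'
#' A `raw_panel` is a tidy long table of raw indicator values with columns
#' `region`, `category`, `year`, `indicator`, `value`. Every combination of
#' declared region, year and indicator is present as a row; unobserved
#' cells carry `NA` and are never silently dropped. Values carry the
#' indicator's native unit; normalization happens later.
#'
#' @param df data.frame with the five panel columns
#' @param schema an [indicator_schema()] the indicator ids are checked
#'   against (optional but recommended)
#' @return a `raw_panel` (data.frame subclass), rows ordered by region,
#'   year, indicator
#' @export
as_raw_panel <- function(df, schema = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("region", "category", "year", "indicator", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_regcap("panel lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$region <- trimws(as.character(df$region))
  df$category <- trimws(tolower(as.character(df$category)))
  df$year <- as.integer(df$year)
  df$indicator <- as.character(df$indicator)
  df$value <- as.numeric(df$value)

  bad_cat <- setdiff(unique(df$category), region_categories)
  if (length(bad_cat)) {
    rows <- which(df$category %in% bad_cat)
    stop_regcap("unknown region category '", bad_cat[1], "' (row ", rows[1],
                "); must be one of: ", paste(region_categories, collapse = ", "))
  }
  cat_per_region <- tapply(df$category, df$region, function(x) length(unique(x)))
  if (any(cat_per_region > 1))
    stop_regcap("region(s) with conflicting categories: ",
                paste(names(cat_per_region)[cat_per_region > 1], collapse = ", "))
  if (!is.null(schema)) {
    bad_ind <- setdiff(unique(df$indicator), schema_indicators(schema))
    if (length(bad_ind))
      stop_regcap("unknown indicator id(s): ", paste(bad_ind, collapse = ", "))
  }
  key <- paste(df$region, df$year, df$indicator, sep = "\r")
  if (anyDuplicated(key))
    stop_regcap("duplicate (region, year, indicator) row(s): ",
                paste(utils::head(gsub("\r", "/", key[duplicated(key)]), 3),
                      collapse = "; "))

  regions <- unique(df$region)
  years <- sort(unique(df$year))
  inds <- if (is.null(schema)) unique(df$indicator) else schema_indicators(schema)
  grid <- expand.grid(indicator = inds, year = years, region = regions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("region", "year", "indicator")]
  gkey <- paste(grid$region, grid$year, grid$indicator, sep = "\r")
  grid$value <- df$value[match(gkey, key)]
  cat_map <- df$category[match(grid$region, df$region)]
  out <- data.frame(region = grid$region, category = cat_map,
                    year = grid$year, indicator = grid$indicator,
                    value = grid$value, stringsAsFactors = FALSE)
  out <- out[order(match(out$region, regions), out$year,
                   match(out$indicator, inds)), ]
  rownames(out) <- NULL
  structure(out, class = c("raw_panel", "data.frame"),
            indicators = inds, years = years, regions = regions)
}

#' Read a raw panel from tidy CSV
#'
#' The canonical exchange format is long CSV with columns `region`,
#' `category`, `year`, `indicator`, `value` (UTF-8, `.` decimal). Empty
#' `value` fields become missing cells.
#'
#' @param path CSV file path
#' @inheritParams as_raw_panel
#' @return a `raw_panel`
#' @export
read_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_regcap("panel file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "numeric"))
  as_raw_panel(df, schema = schema)
}

#' Write a raw panel to tidy CSV
#'
#' Values are written at 12 significant digits so that
#' `read_panel(write_panel(p))` round-trips bit-stably at that precision.
#'
#' @param panel a `raw_panel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  out$value <- ifelse(is.na(out$value), "", formatC(out$value, digits = 12,
                                                    format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Structural validation report for a raw panel
#'
#' Report-only screening: missing cells, negative values for count or
#' percentage indicators, percentage values above 100, and per-indicator
#' coverage (share of non-missing cells).
#'
#' @param panel a `raw_panel`
#' @param schema an [indicator_schema()] (units drive the range checks)
#' @return list with data.frame `issues` (columns `type`, `region`, `year`,
#'   `indicator`, `value`) and named numeric `coverage`
#' @export
validate_panel <- function(panel, schema) {
  issues <- data.frame(type = character(), region = character(),
                       year = integer(), indicator = character(),
                       value = numeric(), stringsAsFactors = FALSE)
  add <- function(type, rows) {
    if (!nrow(rows)) return()
    issues <<- rbind(issues, data.frame(
      type = type, region = rows$region, year = rows$year,
      indicator = rows$indicator, value = rows$value,
      stringsAsFactors = FALSE))
  }
  add("missing", panel[is.na(panel$value), ])
  unit <- stats::setNames(schema$indicators$unit, schema$indicators$id)
  u <- unit[panel$indicator]
  pct <- !is.na(u) & u == "%"
  countlike <- !is.na(u) & u %in% c("piece", "count", "number of times")
  add("negative", panel[!is.na(panel$value) & panel$value < 0 & (pct | countlike), ])
  add("out-of-range", panel[!is.na(panel$value) & pct & panel$value > 100, ])
  coverage <- tapply(!is.na(panel$value), panel$indicator, mean)
  list(issues = issues,
       coverage = coverage[schema_indicators(schema)])
}

#' Published eastern/central/western classification of the 31 regions
#'
#' The Seventh Five-Year-Plan economic-belt classification: 12 eastern, 9
#' central and 10 western provincial-level regions. The two identically
#' romanized provinces are disambiguated as "Shanxi" (central) and
#' "Shaanxi" (western); "Mongolia" denotes Inner Mongolia.
#'
#' @return data.frame with columns `region`, `category`
#' @export
region_classification <- function() {
  utils::read.csv(regcap_example("region_categories.csv"),
                  stringsAsFactors = FALSE)
}

# distinct evaluation objects of a (possibly sliced) panel
panel_objects <- function(panel) {
  unique(panel[, c("region", "category", "year")])
}

# object x indicator value matrix, rows "region\ryear"
panel_matrix <- function(panel) {
  inds <- attr(panel, "indicators") %||% unique(panel$indicator)
  obj <- paste(panel$region, panel$year, sep = "\r")
  objs <- unique(obj)
  mat <- matrix(NA_real_, nrow = length(objs), ncol = length(inds),
                dimnames = list(objs, inds))
  mat[cbind(match(obj, objs), match(panel$indicator, inds))] <- panel$value
  mat
}
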