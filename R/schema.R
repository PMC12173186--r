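#' Indicator schema
#'
#' An `indicator_schema` declares the two-level structure of the index:
#' ordered capacity dimensions and, within them, ordered indicators, each
#' with a unit and a nature (`"positive"`: larger raw values are better;
#' `"negative"`: smaller are better). The nature decides which min-max
#' formula normalizes the indicator.
#'
#' @param dimensions data.frame with columns `id`, `name`
#' @param indicators data.frame with columns `id`, `name`, `unit`,
#'   `dimension`, `nature`
#' @return an `indicator_schema`: list with elements `dimensions`,
#'   `indicators` and `m` (indicator count)
#' @export
indicator_schema <- function(dimensions, indicators) {
  dimensions <- as.data.frame(dimensions, stringsAsFactors = FALSE)
  indicators <- as.data.frame(indicators, stringsAsFactors = FALSE)
  need_d <- c("id", "name")
  need_i <- c("id", "name", "unit", "dimension", "nature")
  if (!all(need_d %in% names(dimensions)))
    stop_regcap("dimensions must have columns: ", paste(need_d, collapse = ", "))
  if (!all(need_i %in% names(indicators)))
    stop_regcap("indicators must have columns: ", paste(need_i, collapse = ", "))
  if (anyDuplicated(dimensions$id))
    stop_regcap("duplicate dimension id: ",
                paste(unique(dimensions$id[duplicated(dimensions$id)]), collapse = ", "))
  if (anyDuplicated(indicators$id))
    stop_regcap("duplicate indicator id: ",
                paste(unique(indicators$id[duplicated(indicators$id)]), collapse = ", "))
  bad_dim <- setdiff(indicators$dimension, dimensions$id)
  if (length(bad_dim)) {
    off <- indicators$id[indicators$dimension %in% bad_dim]
    stop_regcap("indicator(s) ", paste(off, collapse = ", "),
                " reference undeclared dimension(s): ", paste(bad_dim, collapse = ", "))
  }
  bad_nat <- setdiff(indicators$nature, c("positive", "negative"))
  if (length(bad_nat)) {
    off <- indicators$id[!indicators$nature %in% c("positive", "negative")]
    stop_regcap("unknown nature for indicator(s) ", paste(off, collapse = ", "),
                ": ", paste(bad_nat, collapse = ", "))
  }
  empty <- setdiff(dimensions$id, indicators$dimension)
  if (length(empty))
    stop_regcap("dimension(s) without indicators: ", paste(empty, collapse = ", "))
  structure(
    list(dimensions = dimensions[, need_d],
         indicators = indicators[, need_i],
         m = nrow(indicators)),
    class = "indicator_schema")
}

#' Read an indicator schema from YAML
#'
#' Expected layout: top-level keys `dimensions` (list of `{id, name}`) and
#' `indicators` (list of `{id, name, unit, dimension, nature}`). Ordering in
#' the file is preserved.
#'
#' @param path path to a YAML file
#' @return an [indicator_schema()]
#' @export
#' @examples
#' sch <- read_schema(regcap_example("schema.yaml"))
#' sch$m
read_schema <- function(path) {
  if (!file.exists(path)) stop_regcap("schema file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_regcap("schema parse failure in '",
                                                  path, "': ", conditionMessage(e)))
  if (is.null(raw$dimensions) || is.null(raw$indicators))
    stop_regcap("schema must declare 'dimensions' and 'indicators': ", path)
  to_df <- function(lst, fields) {
    rows <- lapply(lst, function(x) {
      miss <- setdiff(fields, names(x))
      if (length(miss))
        stop_regcap("schema entry ", (x$id %||% "<no id>"),
                    " lacks field(s): ", paste(miss, collapse = ", "))
      as.data.frame(x[fields], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  indicator_schema(
    dimensions = to_df(raw$dimensions, c("id", "name")),
    indicators = to_df(raw$indicators, c("id", "name", "unit", "dimension", "nature")))
}

#' @export
print.indicator_schema <- function(x, ...) {
  cat("Indicator schema:", nrow(x$dimensions), "dimensions,", x$m, "indicators\n")
  for (d in x$dimensions$id) {
    ids <- x$indicators$id[x$indicators$dimension == d]
    cat("  ", d, ": ", paste(ids, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# indicator ids in schema order
schema_indicators <- function(schema) schema$indicators$id

# named map indicator -> dimension
dimension_of <- function(schema) {
  stats::setNames(schema$indicators$dimension, schema$indicators$id)
}

# named map indicator -> nature
nature_of <- function(schema) {
  stats::setNames(schema$indicators$nature, schema$indicators$id)
}
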