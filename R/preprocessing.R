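#' Fill missing panel cells by interpolation in year
#'
#' Interior gaps in each (region, indicator) year series are filled by
#' linear interpolation; gaps at the boundary of the series take the
#' nearest observed value. A series with no observation at all is an error
#' — there is nothing to interpolate from.
#'
#' @param panel a `raw_panel`
#' @return the completed `raw_panel`, with attribute `"imputed"`: a
#'   data.frame of the cells that were filled
#' @export
interpolate_missing <- function(panel) {
  out <- panel
  key <- paste(panel$region, panel$indicator, sep = "\r")
  imputed <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(panel$year[idx])]
    v <- panel$value[idx]
    if (!anyNA(v)) next
    obs <- which(!is.na(v))
    if (!length(obs)) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      stop_regcap("series fully missing for region '", parts[1],
                  "', indicator '", parts[2], "'")
    }
    filled <- if (length(obs) == 1L) {
      rep(v[obs], length(v))
    } else {
      stats::approx(panel$year[idx][obs], v[obs], xout = panel$year[idx],
                    method = "linear", rule = 2)$y
    }
    gap <- is.na(v)
    out$value[idx] <- filled
    imputed[[k]] <- out[idx[gap], c("region", "year", "indicator", "value")]
  }
  attr(out, "imputed") <- if (length(imputed)) {
    log <- do.call(rbind, imputed); rownames(log) <- NULL; log
  } else {
    data.frame(region = character(), year = integer(),
               indicator = character(), value = numeric())
  }
  out
}

#' Min-max normalize a single value
#'
#' Positive indicators map `x_min -> 0`, `x_max -> 1` via
#' `(x - x_min) / (x_max - x_min)`; negative indicators use the reverse
#' form `(x_max - x) / (x_max - x_min)`, so that a larger normalized value
#' always means better capacity.
#'
#' @param x raw value(s)
#' @param x_min,x_max normalization bounds, `x_min < x_max`
#' @param nature `"positive"` or `"negative"`
#' @return value(s) in `[0, 1]`
#' @export
#' @examples
#' normalize_value(5, 0, 10, "positive")  # 0.5
#' normalize_value(2, 1, 5, "negative")   # 0.75
normalize_value <- function(x, x_min, x_max, nature = c("positive", "negative")) {
  nature <- match.arg(nature)
  if (x_min >= x_max) stop_regcap("degenerate bounds: x_min >= x_max")
  if (any(x < x_min | x > x_max, na.rm = TRUE))
    stop_regcap("value outside [x_min, x_max]")
  if (nature == "positive") (x - x_min) / (x_max - x_min)
  else (x_max - x) / (x_max - x_min)
}

#' Normalize a complete panel to the unit interval
#'
#' Per-indicator bounds are the observed min and max over the chosen scope:
#' `"pooled_panel"` (default) pools all region-years so that scores are
#' comparable across years, `"per_year"` rescales within each year. An
#' indicator constant within its scope group carries no ordering
#' information; its cells are set to 0.5 with a warning (the entropy stage
#' then gives it zero weight). When frozen `bounds` are supplied (scoring
#' new data on an old scale), out-of-sample values are clipped to `[0, 1]`
#' with a warning.
#'
#' @param panel a complete `raw_panel` (run [interpolate_missing()] first)
#' @param schema an [indicator_schema()]; indicator nature selects the
#'   formula
#' @param scope `"pooled_panel"` or `"per_year"`
#' @param bounds optional frozen bounds: data.frame `indicator`, `x_min`,
#'   `x_max` (forces pooled scope semantics)
#' @return a `normalized_panel`: the panel with values in `[0, 1]`, plus
#'   attributes `bounds` (data.frame `indicator`, `scope_group`, `x_min`,
#'   `x_max`) and `scope`
#' @export
normalize_panel <- function(panel, schema,
                            scope = c("pooled_panel", "per_year"),
                            bounds = NULL) {
  scope <- match.arg(scope)
  if (anyNA(panel$value))
    stop_regcap("panel has missing cells; run interpolate_missing() first")
  nat <- nature_of(schema)
  bad <- setdiff(unique(panel$indicator), names(nat))
  if (length(bad)) stop_regcap("unknown indicator id(s): ", paste(bad, collapse = ", "))

  out <- panel
  grp <- if (scope == "per_year" && is.null(bounds)) {
    paste(panel$indicator, panel$year, sep = "\r")
  } else panel$indicator
  used <- list()
  clipped <- FALSE
  constant <- character()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ind <- panel$indicator[idx[1]]
    if (!is.null(bounds)) {
      row <- bounds[bounds$indicator == ind, ]
      if (!nrow(row)) stop_regcap("no frozen bounds for indicator ", ind)
      lo <- row$x_min[1]; hi <- row$x_max[1]
    } else {
      lo <- min(panel$value[idx]); hi <- max(panel$value[idx])
    }
    if (hi - lo <= 0) {
      constant <- c(constant, g)
      out$value[idx] <- 0.5
    } else {
      y <- if (nat[[ind]] == "positive") (panel$value[idx] - lo) / (hi - lo)
           else (hi - panel$value[idx]) / (hi - lo)
      if (!is.null(bounds) && any(y < 0 | y > 1)) {
        clipped <- TRUE
        y <- pmin(pmax(y, 0), 1)
      }
      out$value[idx] <- y
    }
    used[[g]] <- data.frame(indicator = ind, scope_group = g,
                            x_min = lo, x_max = hi, stringsAsFactors = FALSE)
  }
  if (length(constant))
    warning("constant indicator group(s) set to 0.5: ",
            paste(gsub("\r", " @ ", constant), collapse = ", "), call. = FALSE)
  if (clipped)
    warning("values outside frozen bounds clipped to [0, 1]", call. = FALSE)
  b <- do.call(rbind, used); rownames(b) <- NULL
  structure(out, class = c("normalized_panel", class(panel)),
            bounds = b, scope = scope)
}
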