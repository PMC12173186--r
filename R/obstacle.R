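#' Obstacle degrees for one evaluation object
#'
#' The obstacle degree of indicator j for an object is the share of the
#' object's total weighted shortfall attributable to j:
#' `P_j = (1 - y_j) * w_j / sum_k (1 - y_k) * w_k * 100`, where `y` is the
#' normalized value and `w` the combined indicator weight. Degrees are
#' nonnegative and sum to 100 per object. If every indicator is at its
#' ideal (`y = 1`) there is no shortfall: all degrees are 0 and the result
#' carries attribute `no_obstacles = TRUE`.
#'
#' @param y named normalized value vector for the object, in `[0, 1]`
#' @param weights a `weight_set` (or a named combined weight vector)
#' @return named vector of obstacle degrees in percent
#' @export
#' @examples
#' obstacle_degrees(c(a = 0.5, b = 1), c(a = 0.6, b = 0.4))  # 100, 0
obstacle_degrees <- function(y, weights) {
  w <- if (inherits(weights, "weight_set")) weights$combined else weights
  if (!is.null(names(y)) && !is.null(names(w))) w <- w[names(y)]
  if (length(y) != length(w)) stop_regcap("y and weights differ in length")
  if (any(y < -1e-12 | y > 1 + 1e-12)) stop_regcap("y outside [0, 1]")
  num <- (1 - y) * w
  denom <- sum(num)
  if (denom <= 0) {
    out <- stats::setNames(rep(0, length(y)), names(y))
    attr(out, "no_obstacles") <- TRUE
    return(out)
  }
  100 * num / denom
}

#' Obstacle degrees for every region-year in a panel
#'
#' @param normalized a `normalized_panel`
#' @param weights a `weight_set`
#' @return data.frame: `region`, `category`, `year`, one column of degrees
#'   (percent) per indicator
#' @export
obstacle_report <- function(normalized, weights) {
  mat <- panel_matrix(normalized)
  w <- weights$combined
  mat <- mat[, names(w), drop = FALSE]
  deg <- t(apply(mat, 1, obstacle_degrees, weights = w))
  out <- cbind(panel_objects(normalized), as.data.frame(deg))
  rownames(out) <- NULL
  out
}

#' Top obstacle factors
#'
#' The `k` largest obstacle degrees in descending order; ties are broken
#' by the indicator order of the degree vector (schema order), so results
#' are deterministic. `k` beyond the indicator count returns all.
#'
#' @param degrees named vector of obstacle degrees
#' @param k how many factors to keep
#' @return data.frame `indicator`, `degree`, sorted descending
#' @export
top_obstacles <- function(degrees, k = 2) {
  if (k < 1) stop_regcap("k must be at least 1")
  ord <- order(-degrees, seq_along(degrees))
  sel <- ord[seq_len(min(k, length(degrees)))]
  data.frame(indicator = names(degrees)[sel],
             degree = as.numeric(degrees[sel]),
             stringsAsFactors = FALSE)
}

#' Regional summary of obstacle degrees
#'
#' Aggregates per-object degree vectors to one vector per regional
#' category and year. `"mean_of_members"` (default) averages the member
#' objects' degree vectors and renormalizes to 100; `"profile"` instead
#' computes degrees of the category's mean normalized profile.
#'
#' @param normalized a `normalized_panel`
#' @param weights a `weight_set`
#' @param method aggregation convention
#' @return data.frame: `category`, `year`, one degree column per indicator
#' @export
regional_obstacle_summary <- function(normalized, weights,
                                      method = c("mean_of_members", "profile")) {
  method <- match.arg(method)
  inds <- names(weights$combined)
  rep_tab <- obstacle_report(normalized, weights)
  combos <- unique(rep_tab[, c("category", "year")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- rep_tab$category == combos$category[i] & rep_tab$year == combos$year[i]
    if (!any(sel)) stop_regcap("empty category ", combos$category[i])
    if (method == "mean_of_members") {
      v <- colMeans(rep_tab[sel, inds, drop = FALSE])
      if (sum(v) > 0) v <- 100 * v / sum(v)
    } else {
      sub <- normalized[normalized$category == combos$category[i] &
                          normalized$year == combos$year[i], ]
      ybar <- tapply(sub$value, sub$indicator, mean)[inds]
      v <- obstacle_degrees(ybar, weights)
    }
    cbind(combos[i, , drop = FALSE], as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
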