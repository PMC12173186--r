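#' Expert importance-score table
#'
#' Long table of importance scores: each of the consulted experts rates
#' every indicator on a 1-5 scale (5 = most important). These scores are
#' the sole input to the subjective weights.
#'
#' @param df data.frame with columns `expert`, `indicator`, `score`
#' @return an `expert_scores` data.frame
#' @export
as_expert_scores <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("expert", "indicator", "score")
  if (!all(need %in% names(df)))
    stop_regcap("expert scores need columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$score <- as.numeric(df$score)
  if (any(!df$score %in% 1:5))
    stop_regcap("expert scores must be integers in 1..5")
  n_ind <- tapply(df$indicator, df$expert, function(x) length(unique(x)))
  if (length(unique(n_ind)) > 1 || any(n_ind != length(unique(df$indicator))))
    stop_regcap("every expert must score every indicator exactly once")
  structure(df, class = c("expert_scores", "data.frame"))
}

#' Read expert scores from CSV
#' @param path CSV with columns `expert`, `indicator`, `score`
#' @return an `expert_scores` data.frame
#' @export
read_expert_scores <- function(path) {
  if (!file.exists(path)) stop_regcap("expert score file not found: ", path)
  as_expert_scores(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Subjective indicator weights from expert importance scores
#'
#' For each expert, an indicator's weight is its importance score divided
#' by that expert's total score over all indicators; the final subjective
#' weight is the unweighted mean of the per-expert weight vectors. Weights
#' sum to 1.
#'
#' @param scores an `expert_scores` table (or coercible data.frame)
#' @param indicators optional indicator ordering for the result
#' @return named numeric vector of subjective weights B_j
#' @export
#' @examples
#' sc <- data.frame(expert = "e1", indicator = c("a", "b", "c"),
#'                  score = c(5, 4, 1))
#' subjective_weights(sc)  # 0.5 0.4 0.1
subjective_weights <- function(scores, indicators = NULL) {
  scores <- as_expert_scores(scores)
  inds <- indicators %||% unique(scores$indicator)
  experts <- unique(scores$expert)
  acc <- numeric(length(inds)); names(acc) <- inds
  for (e in experts) {
    sub <- scores[scores$expert == e, ]
    d <- stats::setNames(sub$score, sub$indicator)[inds]
    acc <- acc + d / sum(d)
  }
  acc / length(experts)
}

#' Entropy decomposition of a normalized panel
#'
#' Treating each region-year in the slice as one of `n` evaluation
#' objects, computes per indicator the object proportions
#' `P_ij = y_ij / sum_i y_ij` and the information entropy
#' `E_j = -(1/ln n) * sum_i P_ij ln P_ij`, with `0 * ln 0 := 0`. A column
#' summing to zero carries no distributional information: its entropy is
#' defined as 1 (so it gets zero entropy weight) with a warning.
#'
#' @param normalized a `normalized_panel`
#' @param years optional year subset defining the object slice (default:
#'   all region-years pooled)
#' @param eps optional nonnegative shift added to every proportion before
#'   the logarithm (cross-checking aid; default 0 uses the exact
#'   `0 ln 0 = 0` limit)
#' @return list with `proportions` (object x indicator matrix), `entropy`
#'   (named vector E_j in `[0, 1]`) and `n` (object count)
#' @export
entropy_detail <- function(normalized, years = NULL, eps = 0) {
  panel <- normalized
  if (!is.null(years)) panel <- panel[panel$year %in% years, ]
  if (!nrow(panel)) stop_regcap("empty object slice")
  mat <- panel_matrix(panel)
  n <- nrow(mat)
  colsum <- colSums(mat)
  P <- sweep(mat, 2, colsum, "/")
  zero_cols <- colsum <= 0
  if (any(zero_cols)) {
    warning("all-zero normalized column(s), entropy set to 1: ",
            paste(colnames(mat)[zero_cols], collapse = ", "), call. = FALSE)
    P[, zero_cols] <- 0
  }
  plogp <- function(p) {
    p <- p + eps
    ifelse(p > 0, p * log(p), 0)
  }
  E <- -colSums(plogp(P)) / log(n)
  E[zero_cols] <- 1
  E <- pmin(pmax(E, 0), 1)
  list(proportions = P, entropy = E, n = n)
}

#' Entropy weights from indicator entropies
#'
#' `A_j = (1 - E_j) / (m - sum(E))`: indicators whose values are more
#' dispersed across objects (lower entropy) get larger objective weight.
#'
#' @param detail result of [entropy_detail()], or a named entropy vector
#' @param m indicator count (defaults to the length of the entropy vector)
#' @return named numeric vector of entropy weights A_j, summing to 1
#' @export
entropy_weights <- function(detail, m = NULL) {
  E <- if (is.list(detail)) detail$entropy else detail
  m <- m %||% length(E)
  if (m < 2) stop_regcap("need at least 2 indicators")
  denom <- m - sum(E)
  if (denom <= 0)
    stop_regcap("no objective information: every indicator has entropy 1")
  (1 - E) / denom
}

#' Combined subjective-objective weights
#'
#' The normalized elementwise product `W_j = A_j B_j / sum(A B)`, so an
#' indicator must matter both to the experts and in the data to retain
#' weight; in particular a constant indicator (entropy weight 0) always
#' ends with combined weight 0. Symmetric in its two arguments.
#'
#' @param A entropy (objective) weight vector
#' @param B subjective weight vector, same indicators
#' @return named combined weight vector W_j, summing to 1
#' @export
combine_weights <- function(A, B) {
  if (length(A) != length(B)) stop_regcap("weight vectors differ in length")
  if (!is.null(names(A)) && !is.null(names(B))) B <- B[names(A)]
  prod <- A * B
  if (sum(prod) <= 0) stop_regcap("all subjective-objective products are zero")
  prod / sum(prod)
}

#' Assemble the two-level weight system
#'
#' From combined indicator weights, the weight of a dimension is the sum of
#' its members' weights, and an indicator's within-dimension weight is its
#' share of that sum — so dimension weight times within-dimension weight
#' recovers the indicator weight.
#'
#' @param combined named combined indicator weights (summing to 1)
#' @param schema an [indicator_schema()]
#' @param subjective,entropy optionally the underlying vectors, stored for
#'   reporting
#' @param tol tolerance for the sum-to-one checks
#' @return a `weight_set`: list with `subjective`, `entropy`, `combined`,
#'   `dimension_weights`, `within_dimension`, `dimension_of`
#' @export
build_weight_set <- function(combined, schema, subjective = NULL,
                             entropy = NULL, tol = 1e-9) {
  inds <- schema_indicators(schema)
  if (!setequal(names(combined), inds))
    stop_regcap("combined weights must be named by the schema's indicators")
  combined <- combined[inds]
  if (abs(sum(combined) - 1) > tol)
    stop_regcap("combined weights do not sum to 1 (got ", sum(combined), ")")
  if (any(combined < 0)) stop_regcap("negative weight")
  dmap <- dimension_of(schema)
  W_d <- tapply(combined, dmap[inds], sum)[schema$dimensions$id]
  if (any(W_d <= 0))
    stop_regcap("dimension(s) with zero total weight: ",
                paste(names(W_d)[W_d <= 0], collapse = ", "))
  within <- as.numeric(combined / W_d[dmap[inds]])
  names(within) <- inds
  structure(list(subjective = subjective, entropy = entropy,
                 combined = combined,
                 dimension_weights = stats::setNames(as.numeric(W_d), names(W_d)),
                 within_dimension = within, dimension_of = dmap),
            class = "weight_set")
}

#' The published two-level weight system as a frozen weight set
#'
#' Loads the printed dimension weights (0.153, 0.218, 0.289, 0.210, 0.130)
#' and within-dimension weights. Printed rounding makes three
#' within-dimension vectors sum to 1.001; they are renormalized within
#' dimension before combined indicator weights are derived, and the
#' printed dimension weights are kept verbatim.
#'
#' @param schema an [indicator_schema()] (default: the bundled schema)
#' @return a `weight_set`
#' @export
printed_weight_set <- function(schema = read_schema(regcap_example("schema.yaml"))) {
  tab <- utils::read.csv(regcap_example("printed_weights.csv"),
                         stringsAsFactors = FALSE)
  inds <- schema_indicators(schema)
  tab <- tab[match(inds, tab$indicator), ]
  W_d <- tapply(tab$dimension_weight, tab$dimension, function(x) x[1])
  W_d <- W_d[schema$dimensions$id]
  within <- tab$within_weight
  for (d in names(W_d)) {
    sel <- tab$dimension == d
    s <- sum(within[sel])
    if (abs(s - 1) > 0.01)
      stop_regcap("printed within-dimension weights for '", d,
                  "' sum to ", s)
    within[sel] <- within[sel] / s
  }
  combined <- W_d[tab$dimension] * within
  names(combined) <- inds
  combined <- combined / sum(combined)
  ws <- build_weight_set(combined, schema)
  # keep the printed (verbatim) dimension weights for table comparisons
  ws$dimension_weights <- stats::setNames(as.numeric(W_d), names(W_d))
  ws$within_dimension <- stats::setNames(within, inds)
  ws
}

#' Full weighting stage: expert scores + normalized panel to weight set
#'
#' Convenience wrapper running [subjective_weights()], [entropy_detail()]
#' on the pooled panel, [entropy_weights()], [combine_weights()] and
#' [build_weight_set()]. Entropy weights are computed once on the pooled
#' panel and held fixed across years.
#'
#' @param normalized a `normalized_panel`
#' @param scores an `expert_scores` table
#' @param schema an [indicator_schema()]
#' @return a `weight_set`
#' @export
compute_weights <- function(normalized, scores, schema) {
  B <- subjective_weights(scores, indicators = schema_indicators(schema))
  A <- entropy_weights(entropy_detail(normalized), m = schema$m)
  W <- combine_weights(A, B)
  build_weight_set(W, schema, subjective = B, entropy = A)
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Weight set:", length(x$combined), "indicators,",
      length(x$dimension_weights), "dimensions\n")
  cat("Dimension weights:\n")
  print(round(x$dimension_weights, 3))
  invisible(x)
}

#' Write a weight set to YAML
#' @param weights a `weight_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_weights <- function(weights, path) {
  num <- function(v) if (is.null(v)) NULL else as.list(round(v, 6))
  yaml::write_yaml(list(subjective = num(weights$subjective),
                        entropy = num(weights$entropy),
                        combined = num(weights$combined),
                        dimension_weights = num(weights$dimension_weights),
                        within_dimension = num(weights$within_dimension)),
                   path)
  invisible(path)
}
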