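# shared fixtures and independent brute-force oracles

bundled_schema <- read_schema(regcap_example("schema.yaml"))

# minimal schema: one dimension per entry of `sizes`, indicators a1..,b1..
tiny_schema <- function(sizes = c(a = 2, b = 1), nature = "positive") {
  dims <- data.frame(id = names(sizes), name = names(sizes))
  inds <- do.call(rbind, lapply(names(sizes), function(d) {
    data.frame(id = paste0(d, seq_len(sizes[[d]])), name = "ind",
               unit = "index", dimension = d, nature = nature)
  }))
  indicator_schema(dims, inds)
}

# long panel from an object x indicator matrix (one year unless given)
panel_from_matrix <- function(mat, schema = NULL, years = NULL,
                              category = "eastern") {
  regions <- rownames(mat) %||% sprintf("r%02d", seq_len(nrow(mat)))
  years <- years %||% rep(2022L, nrow(mat))
  df <- expand.grid(indicator = colnames(mat), i = seq_len(nrow(mat)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(region = regions[df$i], category = category,
             year = years[df$i], indicator = df$indicator,
             value = mat[cbind(df$i, match(df$indicator, colnames(mat)))],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direct-summation entropy oracle on a nonnegative object x indicator matrix
oracle_entropy <- function(mat) {
  n <- nrow(mat)
  E <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    s <- 0
    tot <- sum(mat[, j])
    if (tot <= 0) { E[j] <- 1; next }
    for (i in seq_len(n)) {
      p <- mat[i, j] / tot
      if (p > 0) s <- s + p * log(p)
    }
    E[j] <- -s / log(n)
  }
  names(E) <- colnames(mat)
  E
}

# elementwise sums-of-squares ANOVA oracle
oracle_anova_F <- function(values, grouping) {
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in unique(grouping)) {
    v <- values[grouping == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    for (x in v) ssw <- ssw + (x - mean(v))^2
  }
  k <- length(unique(grouping))
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

# elementwise obstacle-degree oracle
oracle_obstacle <- function(y, w) {
  num <- numeric(length(y))
  for (j in seq_along(y)) num[j] <- (1 - y[j]) * w[j]
  out <- 100 * num / sum(num)
  names(out) <- names(y)
  out
}

# latent -> composite Spearman for one simulated seed
recovery_composite <- function(cfg, schema = bundled_schema, year = 2022) {
  panel <- interpolate_missing(simulate_panel(cfg, schema))
  np <- normalize_panel(panel, schema)
  ws <- compute_weights(np, simulate_expert_scores(cfg, schema), schema)
  st <- score_panel(np, ws)
  st[st$year == year, ]
}
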