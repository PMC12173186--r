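norm_panel_for <- function(mat, schema) {
  p <- as_raw_panel(panel_from_matrix(mat), schema)
  structure(p, class = c("normalized_panel", class(p)))
}

test_that("dimension scores are within-dimension weighted means", {
  sch <- tiny_schema(c(a = 2))
  ws <- build_weight_set(c(a1 = 0.5, a2 = 0.5), sch)
  np <- norm_panel_for(cbind(a1 = 1, a2 = 0), sch)
  expect_equal(dimension_scores(np, ws)$a, 0.5)
  np1 <- norm_panel_for(cbind(a1 = 1, a2 = 1), sch)
  expect_equal(dimension_scores(np1, ws)$a, 1)
})

test_that("printed dimension scores weighted by printed dimension weights give the printed composites", {
  ws <- printed_weight_set(bundled_schema)
  tab <- printed_scores_2022()
  got <- composite_scores(tab, ws)
  # every one of the 31 provinces reconstructs at 3 decimals
  expect_equal(got$composite_3dp, tab$composite)
  pick <- function(r) got$composite_3dp[got$region == r]
  expect_equal(pick("Beijing"), 0.172)
  expect_equal(pick("Jiangsu"), 0.204)
  expect_equal(pick("Xinjiang"), 0.038)
  zero <- tab[1, ]; zero[, names(ws$dimension_weights)] <- 0
  expect_equal(composite_scores(zero, ws)$composite, 0)
})

test_that("competition ranking shares ranks and skips the following ones", {
  expect_equal(rank_regions(c(0.204, 0.172, 0.172, 0.162)), c(1L, 2L, 2L, 4L))
  expect_equal(rank_regions(c(3, 2, 1)), c(1L, 2L, 3L))
  expect_equal(rank_regions(rep(0.5, 4)), rep(1L, 4))
  # printed table's full rank column is reproduced from its composites
  tab <- printed_scores_2022()
  expect_equal(rank_regions(tab$composite), tab$rank)
})

test_that("above-average counts are strict, with a printed-precision variant", {
  expect_equal(count_above_mean(c(1, 2, 3)), 1L)
  expect_equal(count_above_mean(rep(2, 5)), 0L)
  tab <- printed_scores_2022()
  # at the table's printed precision the published count of 13 is recovered
  expect_equal(count_above_mean(tab$composite, digits = 3), 13L)
})

test_that("group means and SDs match the printed averages", {
  tab <- printed_scores_2022()
  gm <- group_means(tab, columns = "composite")
  get <- function(g) gm$composite_mean[gm$group == g]
  expect_equal(round_half_up(get("national"), 3), 0.113)
  expect_equal(round_half_up(get("western"), 3), 0.092)
  expect_equal(gm$n[gm$group == "national"], 31L)
  single <- tab[tab$region == "Beijing", ]
  gs <- group_means(single, columns = "composite")
  east <- gs[gs$group == "eastern", ]
  expect_equal(east$composite_mean, 0.172)
  expect_equal(east$composite_sd, 0)
  expect_false(east$sd_defined)
})

test_that("trend tables carry group-mean series and year deltas", {
  sc <- data.frame(region = rep(c("A", "B"), 2), category = "eastern",
                   year = rep(2021:2022, each = 2),
                   composite = c(0.08, 0.12, 0.10, 0.14))
  tt <- trend_table(sc, columns = "composite")
  nat <- tt[tt$group == "national", ]
  expect_equal(nat$mean, c(0.10, 0.12))
  expect_equal(nat$delta, c(NA, 0.02))
  cst <- sc; cst$composite <- 0.1
  d <- trend_table(cst, columns = "composite")$delta
  expect_true(all(d[!is.na(d)] == 0))
})

test_that("a noise-free upward drift yields positive deltas everywhere", {
  cfg <- sim_config(seed = 5, noise_sd = 0, region_sd = 0.02, trend = 0.05,
                    missing_rate = 0)
  st <- local({
    p <- simulate_panel(cfg, bundled_schema)
    np <- normalize_panel(p, bundled_schema)
    score_panel(np, printed_weight_set(bundled_schema))
  })
  tt <- trend_table(st, columns = "composite")
  expect_true(all(tt$delta[!is.na(tt$delta)] > 0))
})

test_that("the composite is monotone in y and invariant to indicator order", {
  sch <- tiny_schema(c(a = 2, b = 2))
  set.seed(31)
  W <- runif(4); W <- W / sum(W)
  names(W) <- c("a1", "a2", "b1", "b2")
  ws <- build_weight_set(W, sch)
  for (rep in 1:10) {
    y <- runif(4); names(y) <- names(W)
    np <- norm_panel_for(t(y)[, names(W), drop = FALSE], sch)
    base <- composite_scores(dimension_scores(np, ws), ws)$composite
    j <- sample(4, 1)
    y2 <- y; y2[j] <- min(1, y2[j] + runif(1, 0, 1 - y2[j]))
    np2 <- norm_panel_for(t(y2)[, names(W), drop = FALSE], sch)
    bumped <- composite_scores(dimension_scores(np2, ws), ws)$composite
    expect_gte(bumped, base - 1e-12)
    # permuting indicator columns leaves the composite unchanged
    perm <- sample(4)
    np3 <- norm_panel_for(t(y)[, names(W)[perm], drop = FALSE], sch)
    expect_equal(composite_scores(dimension_scores(np3, ws), ws)$composite,
                 base, tolerance = 1e-12)
  }
})

test_that("score_panel composites decompose as the dimension-weighted sum", {
  cfg <- sim_config(seed = 9, missing_rate = 0)
  p <- simulate_panel(cfg, bundled_schema)
  np <- normalize_panel(p, bundled_schema)
  ws <- compute_weights(np, simulate_expert_scores(cfg, bundled_schema),
                        bundled_schema)
  st <- score_panel(np, ws)
  recomposed <- as.matrix(st[, names(ws$dimension_weights)]) %*%
    ws$dimension_weights
  expect_equal(st$composite, as.numeric(recomposed), tolerance = 5e-4)
  expect_true(all(st$composite >= 0 & st$composite <= 1))
})
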