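make_series_panel <- function(values, years = 2018:(2017 + length(values))) {
  sch <- tiny_schema(c(d = 1))
  df <- data.frame(region = "A", category = "eastern", year = years,
                   indicator = "d1", value = values)
  list(panel = as_raw_panel(df, sch), schema = sch)
}

test_that("interior gaps interpolate linearly, boundary gaps take nearest value", {
  p <- make_series_panel(c(1.0, NA, 3.0))$panel
  out <- interpolate_missing(p)
  expect_equal(out$value, c(1, 2, 3))
  log <- attr(out, "imputed")
  expect_equal(nrow(log), 1)
  expect_equal(log$year, 2019L)

  p2 <- make_series_panel(c(NA, 4.0))$panel
  expect_equal(interpolate_missing(p2)$value, c(4, 4))

  # single observation fills the whole series
  p3 <- make_series_panel(c(NA, 5.0, NA))$panel
  expect_equal(interpolate_missing(p3)$value, c(5, 5, 5))

  p4 <- make_series_panel(c(NA, NA))$panel
  expect_error(interpolate_missing(p4), "fully missing.*A.*d1")
})

test_that("min-max normalization maps values by indicator nature", {
  expect_equal(normalize_value(5, 0, 10, "positive"), 0.5)
  expect_equal(normalize_value(0, 0, 10, "positive"), 0)
  expect_equal(normalize_value(10, 0, 10, "positive"), 1)
  expect_equal(normalize_value(2, 1, 5, "negative"), 0.75)
  expect_equal(normalize_value(1, 1, 5, "negative"), 1)
  expect_error(normalize_value(11, 0, 10, "positive"), "outside")
  expect_error(normalize_value(5, 3, 3, "positive"), "degenerate")
})

test_that("panel normalization honours scope, nature and the constant-column policy", {
  sch <- tiny_schema(c(d = 1))
  mk <- function(vals, nature = "positive") {
    s <- tiny_schema(c(d = 1), nature = nature)
    df <- data.frame(region = c("A", "B", "C"), category = "eastern",
                     year = 2022, indicator = "d1", value = vals)
    list(p = as_raw_panel(df, s), s = s)
  }
  pos <- mk(c(1, 2, 3))
  expect_equal(normalize_panel(pos$p, pos$s)$value, c(0, 0.5, 1))
  neg <- mk(c(1, 2, 3), nature = "negative")
  expect_equal(normalize_panel(neg$p, neg$s)$value, c(1, 0.5, 0))
  cst <- mk(c(4, 4, 4))
  expect_warning(np <- normalize_panel(cst$p, cst$s), "constant")
  expect_equal(np$value, rep(0.5, 3))

  b <- attr(normalize_panel(pos$p, pos$s), "bounds")
  expect_equal(b$x_min, 1)
  expect_equal(b$x_max, 3)
})

test_that("per-year scope rescales within each year", {
  sch <- tiny_schema(c(d = 1))
  df <- data.frame(region = rep(c("A", "B"), 2), category = "eastern",
                   year = rep(2021:2022, each = 2), indicator = "d1",
                   value = c(0, 10, 100, 200))
  p <- as_raw_panel(df, sch)
  np <- normalize_panel(p, sch, scope = "per_year")
  expect_equal(sort(np$value[np$year == 2021]), c(0, 1))
  expect_equal(sort(np$value[np$year == 2022]), c(0, 1))
  pooled <- normalize_panel(p, sch, scope = "pooled_panel")
  expect_equal(max(pooled$value[pooled$year == 2021]), 10 / 200)
})

test_that("frozen bounds clip out-of-sample values with a warning", {
  sch <- tiny_schema(c(d = 1))
  df <- data.frame(region = c("A", "B"), category = "eastern", year = 2023,
                   indicator = "d1", value = c(-5, 15))
  p <- as_raw_panel(df, sch)
  bounds <- data.frame(indicator = "d1", x_min = 0, x_max = 10)
  expect_warning(np <- normalize_panel(p, sch, bounds = bounds), "clipped")
  expect_equal(np$value, c(0, 1))
})

test_that("normalization invariants hold on random panels", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    sch <- tiny_schema(c(d = 3), nature = sample(c("positive", "negative"), 1))
    mat <- matrix(rnorm(n * 3, sd = 10), n, 3,
                  dimnames = list(NULL, c("d1", "d2", "d3")))
    p <- as_raw_panel(panel_from_matrix(mat), sch)
    np <- normalize_panel(p, sch)
    # non-constant columns span exactly [0, 1]
    for (j in colnames(mat)) {
      v <- np$value[np$indicator == j]
      expect_lt(abs(min(v) - 0), 1e-12)
      expect_lt(abs(max(v) - 1), 1e-12)
    }
    expect_true(all(np$value >= 0 & np$value <= 1))
    # reverse formula is the complement of the direct one
    x <- runif(1, min(mat), max(mat))
    expect_equal(normalize_value(x, min(mat), max(mat), "negative"),
                 1 - normalize_value(x, min(mat), max(mat), "positive"))
    # affine rescaling of a raw positive indicator leaves y unchanged
    sch_pos <- tiny_schema(c(d = 3))
    p_pos <- as_raw_panel(panel_from_matrix(mat), sch_pos)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    mat2 <- a * mat + b
    p2 <- as_raw_panel(panel_from_matrix(mat2), sch_pos)
    expect_equal(normalize_panel(p2, sch_pos)$value,
                 normalize_panel(p_pos, sch_pos)$value, tolerance = 1e-10)
  }
})
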