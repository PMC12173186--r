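test_that("subjective weights are mean per-expert score shares", {
  one <- data.frame(expert = "e1", indicator = c("a", "b", "c"),
                    score = c(5, 4, 1))
  expect_equal(unname(subjective_weights(one)), c(0.5, 0.4, 0.1))

  eq <- data.frame(expert = "e1", indicator = letters[1:4], score = 3)
  expect_equal(unname(subjective_weights(eq)), rep(0.25, 4))

  two <- data.frame(expert = rep(c("A", "B"), each = 2),
                    indicator = rep(c("a", "b"), 2), score = c(4, 2, 2, 4))
  expect_equal(unname(subjective_weights(two)), c(0.5, 0.5))

  bad <- data.frame(expert = "e1", indicator = "a", score = 6)
  expect_error(subjective_weights(bad), "1..5")
})

norm_mat_panel <- function(mat) {
  sch <- tiny_schema(c(d = ncol(mat)))
  colnames(mat) <- paste0("d", seq_len(ncol(mat)))
  p <- as_raw_panel(panel_from_matrix(mat), sch)
  structure(p, class = c("normalized_panel", class(p)))
}

test_that("entropy decomposition matches hand-computed cases", {
  d0 <- entropy_detail(norm_mat_panel(cbind(c(0, 1))))
  expect_equal(unname(d0$entropy), 0)
  expect_equal(unname(d0$proportions[, 1]), c(0, 1))

  du <- entropy_detail(norm_mat_panel(cbind(c(0.4, 0.4))))
  expect_equal(unname(du$entropy), 1)

  d3 <- entropy_detail(norm_mat_panel(cbind(c(1, 2, 3))))
  expect_equal(unname(d3$proportions[, 1]), c(1/6, 1/3, 1/2))
  p <- c(1/6, 1/3, 1/2)
  expect_equal(unname(d3$entropy), -sum(p * log(p)) / log(3), tolerance = 1e-12)
  expect_equal(unname(d3$entropy), 0.9206, tolerance = 1e-4)

  expect_warning(dz <- entropy_detail(norm_mat_panel(cbind(c(0, 0), c(1, 2)))),
                 "all-zero")
  expect_equal(unname(dz$entropy[1]), 1)
})

test_that("entropy weights redistribute 1 - E over informative indicators", {
  expect_equal(unname(entropy_weights(c(1, 0))), c(0, 1))
  expect_equal(unname(entropy_weights(c(0.5, 0.5))), c(0.5, 0.5))
  p <- c(1/6, 1/3, 1/2)
  E <- -sum(p * log(p)) / log(3)
  expect_equal(unname(entropy_weights(c(E, 1))), c(1, 0))
  expect_error(entropy_weights(c(1, 1)), "no objective information")
  expect_error(entropy_weights(0.4, m = 1), "at least 2")
})

test_that("combined weights are the normalized product, symmetric in A and B", {
  expect_equal(unname(combine_weights(c(0.5, 0.5), c(0.8, 0.2))), c(0.8, 0.2))
  expect_equal(unname(combine_weights(c(0.8, 0.2), c(0.5, 0.5))), c(0.8, 0.2))
  got <- combine_weights(c(0.3, 0.7), c(0.6, 0.4))
  expect_equal(unname(got), c(0.18, 0.28) / 0.46, tolerance = 1e-12)
  expect_equal(unname(got), c(0.3913, 0.6087), tolerance = 1e-4)
  expect_error(combine_weights(c(1, 0), c(0, 1)), "zero")
})

test_that("two-level weight system aggregates and factorizes consistently", {
  sch <- tiny_schema(c(a = 2, b = 1))
  W <- c(a1 = 0.1, a2 = 0.2, b1 = 0.7)
  ws <- build_weight_set(W, sch)
  expect_equal(unname(ws$dimension_weights), c(0.3, 0.7))
  expect_equal(unname(ws$within_dimension), c(1/3, 2/3, 1))
  # dimension weight x within-dimension weight recovers the indicator weight
  expect_equal(unname(ws$dimension_weights[ws$dimension_of] * ws$within_dimension),
               unname(W))

  one <- tiny_schema(c(a = 2))
  ws1 <- build_weight_set(c(a1 = 0.4, a2 = 0.6), one)
  expect_equal(unname(ws1$dimension_weights), 1)
  expect_equal(unname(ws1$within_dimension), c(0.4, 0.6))

  expect_error(build_weight_set(c(a1 = 0, a2 = 0, b1 = 1), sch), "zero total")
})

test_that("published weight fixture reproduces the printed two-level system", {
  ws <- printed_weight_set(bundled_schema)
  expect_equal(unname(ws$dimension_weights),
               c(0.153, 0.218, 0.289, 0.210, 0.130))
  raw <- read.csv(regcap_example("printed_weights.csv"))
  for (d in unique(raw$dimension)) {
    expect_lt(abs(sum(raw$within_weight[raw$dimension == d]) - 1), 0.002)
  }
  expect_equal(sum(ws$combined), 1, tolerance = 1e-9)
})

test_that("weight vectors sum to one and the constant-indicator chain holds", {
  set.seed(23)
  for (rep in 1:20) {
    m <- sample(4:9, 1)
    n <- sample(5:12, 1)
    mat <- matrix(runif(n * m), n, m, dimnames = list(NULL, paste0("d", 1:m)))
    mat[, 2] <- 0.37  # constant indicator
    np <- norm_mat_panel(mat)
    sc <- data.frame(expert = rep(c("e1", "e2"), each = m),
                     indicator = rep(paste0("d", 1:m), 2),
                     score = sample(1:5, 2 * m, replace = TRUE))
    B <- subjective_weights(sc, paste0("d", 1:m))
    det <- entropy_detail(np)
    A <- entropy_weights(det, m)
    W <- combine_weights(A, B)
    expect_equal(sum(B), 1, tolerance = 1e-9)
    expect_equal(sum(A), 1, tolerance = 1e-9)
    expect_equal(sum(W), 1, tolerance = 1e-9)
    expect_true(all(c(A, B, W) >= 0))
    # constant indicator => E = 1 => A = 0 => W = 0 regardless of B
    expect_equal(unname(det$entropy["d2"]), 1, tolerance = 1e-12)
    expect_equal(unname(A["d2"]), 0, tolerance = 1e-12)
    expect_equal(unname(W["d2"]), 0, tolerance = 1e-12)
    # per-indicator proportions sum to 1
    expect_equal(unname(colSums(det$proportions)), rep(1, m), tolerance = 1e-12)
  }
})

test_that("entropy agrees with the direct-summation oracle on random panels", {
  set.seed(29)
  for (rep in 1:20) {
    mat <- matrix(runif(60), 10, 6, dimnames = list(NULL, paste0("d", 1:6)))
    mat[sample(60, 5)] <- 0  # exercise the 0 * log 0 limit
    got <- entropy_detail(norm_mat_panel(mat))$entropy
    expect_equal(unname(got), unname(oracle_entropy(mat)), tolerance = 1e-12)
  }
})
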