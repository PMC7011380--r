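test_that("co-occurrence counting matches a naive pair enumerator", {
  set.seed(21)
  for (trial in 1:6) {
    n_sent <- sample(c(3, 20, 50), 1)
    corpus <- matrix(sample(0:15, n_sent * 23, replace = TRUE), n_sent, 23)
    w <- sample(c(1, 5, 22), 1)
    weighting <- sample(c("inverse", "uniform"), 1)
    x <- build_cooccurrence(corpus, window = w,
                            distance_weighting = weighting)$x
    expect_equal(unname(x), naive_cooccurrence(corpus, w, weighting),
                 tolerance = 1e-12)
    expect_equal(x, t(x))  # symmetric window
  }
})

test_that("single-sentence closed forms hold", {
  # 23 copies of one token, uniform weights: x_tt = sum_p min(p-1,w)+min(23-p,w)
  sent <- matrix(rep(3L, 23), 1)
  for (w in c(1L, 5L, 22L)) {
    x <- build_cooccurrence(sent, window = w,
                            distance_weighting = "uniform")$x
    expected <- sum(pmin(0:22, w) + pmin(22:0, w))
    expect_equal(unname(x[4, 4]), expected)
    expect_equal(sum(x) - x[4, 4], 0)
  }
  # full-sentence window: row sum = 22 * (count of that token)
  sent <- matrix(sample(0:15, 23, replace = TRUE), 1)
  x <- build_cooccurrence(sent, window = 22L,
                          distance_weighting = "uniform")$x
  counts <- tabulate(sent + 1L, 16L)
  expect_equal(unname(rowSums(x)), 22 * counts)
})

test_that("co-occurrence statistics normalise and ratio behaves", {
  d <- toy_dataset()
  X <- build_cooccurrence(encode_dataset(d), window = 5)
  present <- which(rowSums(X$x) > 0)
  st <- cooccurrence_stats(X, tokens = present)
  expect_equal(unname(rowSums(st$P)), rep(1, length(present)))
  # ratio identity: i == j gives 1 wherever defined
  for (i in seq_along(present)) {
    r <- st$ratio[i, i, ]
    expect_equal(unname(r[st$P[i, ] > 0]),
                 rep(1, sum(st$P[i, ] > 0)))
  }
  expect_error(cooccurrence_stats(matrix(0, 3, 3)), "zero row total")
})

test_that("hand-computed 3-token ratios match", {
  x <- matrix(c(4, 2, 2,
                2, 2, 0,
                2, 0, 2), 3, 3, byrow = TRUE)
  st <- cooccurrence_stats(x)
  expect_equal(unname(st$row_totals), c(8, 4, 4))
  # P[1,1] = 4/8, P[2,1] = 2/4 -> ratio[1,2,1] = 1
  expect_equal(st$ratio[1, 2, 1], 1)
  # P[1,2] = 2/8 = 0.25, P[3,2] = 0 -> ratio with zero denominator is NA
  expect_true(is.na(st$ratio[1, 3, 2]))
  # ratio[2,3,1]: P[2,1]=0.5, P[3,1]=0.5 -> 1; ratio[3,2,3]: 0.5/0 undefined? P[2,3]=0 -> NA
  expect_equal(st$ratio[2, 3, 1], 1)
  expect_true(is.na(st$ratio[3, 2, 3]))
})

test_that("the cost is a weighted sum of squared log-count errors", {
  set.seed(5)
  x <- matrix(c(0, 3, 1, 0,
                3, 0, 2, 120,
                1, 2, 0, 4,
                0, 120, 4, 0), 4, 4, byrow = TRUE)
  params <- glove_init(vocab = 4, d = 3, seed = 2)
  # brute-force term-by-term summation
  manual <- 0
  for (i in 1:4) for (j in 1:4) {
    if (x[i, j] > 0) {
      f <- if (x[i, j] < params$x_max) (x[i, j] / params$x_max)^params$alpha else 1
      e <- sum(params$W[i, ] * params$C[j, ]) + params$b[i] +
        params$c_bias[j] - log(x[i, j])
      manual <- manual + f * e^2
    }
  }
  expect_equal(glove_cost(params, x), manual, tolerance = 1e-12)
  expect_gte(glove_cost(params, x), 0)
})

test_that("an exact-fit parameterisation has zero cost", {
  # rank-1 construction: log x_ij = b_i + c_j exactly, vectors zero
  b <- c(0.3, -0.2, 0.5)
  cb <- c(0.1, 0.4, -0.3)
  x <- exp(outer(b, cb, "+"))
  params <- structure(list(W = matrix(0, 3, 2), C = matrix(0, 3, 2),
                           b = b, c_bias = cb, x_max = 100, alpha = 0.75),
                      class = "glove_params")
  expect_equal(glove_cost(params, x), 0, tolerance = 1e-20)
})

test_that("analytic gradients match central differences", {
  set.seed(8)
  x <- matrix(stats::rpois(16, 3), 4, 4) * 1.0
  diag(x) <- 0
  params <- glove_init(vocab = 4, d = 3, seed = 3)
  g <- glove_gradient(params, x)
  eps <- 1e-6
  for (nm in c("W", "C", "b", "c_bias")) {
    for (ix in seq_along(params[[nm]])) {
      p2 <- params
      p2[[nm]][ix] <- p2[[nm]][ix] + eps
      up <- glove_cost(p2, x)
      p2[[nm]][ix] <- p2[[nm]][ix] - 2 * eps
      dn <- glove_cost(p2, x)
      num <- (up - dn) / (2 * eps)
      if (abs(num) > 1e-8) {
        expect_lt(abs(num - g[[nm]][ix]) / abs(num), 1e-4)
      }
    }
  }
})

test_that("training reduces the cost and is seed-deterministic", {
  d <- toy_dataset()
  X <- build_cooccurrence(encode_dataset(d), window = 5)
  fit1 <- fit_glove(X, d = 16, iterations = 100, seed = 4)
  fit2 <- fit_glove(X, d = 16, iterations = 100, seed = 4)
  expect_lt(utils::tail(fit1$cost_history, 1), fit1$cost_history[1])
  expect_identical(fit1$embedding, fit2$embedding)
  expect_identical(dim(fit1$embedding), c(16L, 16L))
  expect_true(all(is.finite(fit1$embedding)))
  # word-only composition differs from the sum composition
  fit3 <- fit_glove(X, d = 16, iterations = 100, seed = 4, combine = "word")
  expect_false(identical(fit3$embedding, fit1$embedding))
})

test_that("cost decreases monotonically at a small learning rate", {
  x <- matrix(c(0, 5, 2, 5, 0, 1, 2, 1, 0), 3, 3)
  fit <- fit_glove(x, d = 2, iterations = 200, learning_rate = 0.01,
                   seed = 6)
  expect_true(all(diff(fit$cost_history) <= 1e-10))
})

test_that("embeddings round-trip through the text serialisation", {
  d <- toy_dataset()
  X <- build_cooccurrence(encode_dataset(d))
  fit <- fit_glove(X, d = 5, iterations = 50, seed = 1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_embedding(fit$embedding, path)
  back <- read_embedding(path)
  expect_equal(unname(back), unname(fit$embedding), tolerance = 1e-12)
})
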