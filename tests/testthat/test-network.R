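small_spec <- function(variant = "full", head = "classification",
                       dropout_rate = 0.3) {
  network_spec(variant = variant, head = head, embedding_dim = 8,
               recurrent_units = 4, conv_filters = rep(4L, 5),
               conv_kernels = c(5L, 5L, 3L, 3L, 3L),
               dropout_rate = dropout_rate)
}

test_that("structural audits match each ablation variant", {
  set.seed(1)
  archs <- lapply(stats::setNames(nm = c("full", "no_lstm", "conv_lstm",
                                         "no_batchnorm", "no_dropout")),
                  function(v) build_network(small_spec(v)))
  audits <- lapply(archs, audit_network)
  expect_identical(audits$no_batchnorm$n_batchnorm, 0L)
  expect_identical(audits$no_dropout$n_dropout, 0L)
  expect_identical(audits$no_lstm$n_recurrent, 0L)
  expect_true(audits$conv_lstm$conv_before_recurrent)
  expect_false(audits$full$conv_before_recurrent)
  for (a in audits) expect_identical(a$n_conv, 5L)
  # dropout carries no parameters; batch norm does
  expect_identical(audits$no_dropout$n_parameters, audits$full$n_parameters)
  expect_lt(audits$no_batchnorm$n_parameters, audits$full$n_parameters)
})

test_that("spec invariants are enforced", {
  expect_error(network_spec(conv_filters = c(4, 4, 4)), "five")
  expect_error(network_spec(dense_sizes = c(10, 2)), "fixed")
  expect_error(build_network(small_spec(),
                             embedding_init = matrix(0, 8, 8)),
               "16 x 8")
})

test_that("the classification head normalises to a probability pair", {
  set.seed(2)
  arch <- build_network(small_spec())
  tok <- matrix(sample(0:15, 6 * 23, replace = TRUE), 6, 23)
  logits <- crisprot:::forward_network(arch$layers, tok, training = FALSE)
  p <- crisprot:::softmax_rows(logits)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
})

test_that("bilstm_forward with all-zero parameters gives zero outputs", {
  # sigma(0) = 0.5 for every gate, tanh(0) = 0, so cell state stays 0 and
  # the combined output is tanh(0) = 0 at every position
  u <- 3; d <- 2; tt <- 5
  zeros <- list(W_f = matrix(0, u + d, u), W_i = matrix(0, u + d, u),
                W_C = matrix(0, u + d, u), W_o = matrix(0, u + d, u),
                b_f = numeric(u), b_i = numeric(u), b_C = numeric(u),
                b_o = numeric(u), V = matrix(0, u, 2), V2 = matrix(0, u, 2))
  X <- matrix(stats::rnorm(tt * d), tt, d)
  out <- bilstm_forward(X, zeros)
  expect_equal(out, matrix(0, tt, 2))
  # with b_f = b_i = b_C = b_o = 0 and weights 0, every gate is exactly 0.5:
  # check via one scalar step of the oracle
  H <- scalar_bilstm_oracle(X, zeros)
  expect_equal(H, out)
})

test_that("the forward direction is causal", {
  set.seed(4)
  u <- 3; d <- 2; tt <- 6
  params <- random_bilstm_params(u, d, out_dim = u)
  # forward-only probe: make the backward direction inert by zeroing V2
  params$V2 <- matrix(0, u, u)
  X <- matrix(stats::rnorm(tt * d), tt, d)
  base <- bilstm_forward(X, params)
  X2 <- X
  X2[5, ] <- X2[5, ] + 1
  pert <- bilstm_forward(X2, params)
  expect_equal(pert[1:4, ], base[1:4, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pert[5, ], base[5, ])))
})

test_that("bilstm_forward matches the scalar gate-equation oracle", {
  set.seed(6)
  for (trial in 1:20) {
    u <- sample(2:4, 1); d <- sample(2:5, 1); tt <- sample(c(3, 8, 23), 1)
    params <- random_bilstm_params(u, d, out_dim = sample(2:3, 1))
    X <- matrix(stats::rnorm(tt * d), tt, d)
    expect_equal(bilstm_forward(X, params), scalar_bilstm_oracle(X, params),
                 tolerance = 1e-5)
  }
})

test_that("training logs one loss per planned batch and is deterministic", {
  d <- toy_dataset(n_per_guide = 10)  # 4 pos, 16 neg
  spec <- small_spec()
  emb <- matrix(stats::rnorm(16 * 8, 0, 0.1), 16, 8)
  m1 <- train_network(d, spec, embedding_init = emb, m = 4, epochs = 1,
                      seed = 31, validation_fraction = 0)
  expect_length(m1$training_log, 4L)  # floor(16/4) batches, 1 epoch
  m2 <- train_network(d, spec, embedding_init = emb, m = 4, epochs = 1,
                      seed = 31, validation_fraction = 0)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(utils::tail(m1$training_log, 1),
                   utils::tail(m2$training_log, 1))
})

test_that("predictions are probabilities aligned with the input", {
  d <- toy_dataset(n_per_guide = 10)
  spec <- small_spec()
  fit <- train_network(d, spec, m = 4, epochs = 2, seed = 8,
                       validation_fraction = 0)
  p <- predict_network(fit, d)
  expect_length(p, nrow(d))
  expect_true(all(p >= 0 & p <= 1))
  # single-row prediction works and matches the batch path
  p1 <- predict_network(fit, d[1, , drop = FALSE])
  expect_equal(p1, p[1], tolerance = 1e-10)
  # regression head stays in (0, 1)
  fitr <- train_network(d, small_spec(head = "regression"), m = 4,
                        epochs = 2, seed = 8, validation_fraction = 0)
  pr <- predict_network(fitr, d)
  expect_true(all(pr > 0 & pr < 1))
})

test_that("a separable toy is overfit to low loss and perfect ranking", {
  d <- separable_dataset()
  fit <- otnet(d, epochs = 60, m = 10, validation_fraction = 0, seed = 17,
               embedding_dim = 8, recurrent_units = 4,
               conv_filters = rep(4L, 5), glove_iterations = 50)
  el <- fit$model$epoch_log
  expect_lt(min(el$train_loss), 0.1)
  p <- predict(fit, d)
  expect_equal(ranking_metrics(d$label, p)$auroc, 1.0)
})

test_that("reordering convolution and recurrence changes the function", {
  d <- toy_dataset(n_per_guide = 10)
  emb <- matrix(stats::rnorm(16 * 8, 0, 0.1), 16, 8)
  a <- train_network(d, small_spec("full"), embedding_init = emb, m = 4,
                     epochs = 1, seed = 12, validation_fraction = 0)
  b <- train_network(d, small_spec("conv_lstm"), embedding_init = emb,
                     m = 4, epochs = 1, seed = 12, validation_fraction = 0)
  expect_gt(max(abs(predict_network(a, d) - predict_network(b, d))), 0)
})

test_that("the otnet interface exposes standard methods", {
  d <- toy_dataset(n_per_guide = 12)
  fit <- otnet(d, epochs = 2, m = 4, validation_fraction = 0, seed = 5,
               embedding_dim = 8, recurrent_units = 4,
               conv_filters = rep(4L, 5), glove_iterations = 50)
  expect_s3_class(fit, "otnet")
  expect_output(print(fit), "variant 'full'")
  s <- summary(fit)
  expect_output(print(s), "parameters")
  cf <- coef(fit)
  expect_true("bilstm" %in% names(cf))
  r <- residuals(fit, d)
  expect_length(r, nrow(d))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("training rejects degenerate inputs", {
  d <- toy_dataset(n_per_guide = 10)
  d$label <- 0L
  d$frequency <- 0
  expect_error(train_network(d, small_spec(), m = 4, epochs = 1, seed = 1),
               "both classes")
  expect_error(train_network(d, small_spec(head = "regression"), m = 4,
                             epochs = 1, seed = 1),
               "positive frequencies")
})
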