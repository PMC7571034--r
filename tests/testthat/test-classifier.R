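test_that("the forward pass matches a hand-rolled loop oracle", {
  set.seed(13)
  for (i in 1:20) {
    net <- random_small_net(seed = i)
    x <- rnorm(6)
    fw <- mlp_forward(x, net)
    expect_equal(sum(fw$prob), 1, tolerance = 1e-12)
    expect_true(all(fw$prob > 0))
    expect_equal(fw$prob, oracle_forward(x, net$weights), tolerance = 1e-10)
    # the pre-softmax activations are inner products of (h2, 1) with theta
    expect_equal(fw$activations,
                 drop(c(fw$h2, 1) %*% net$weights[[3]]), tolerance = 1e-12)
  }
  expect_error(mlp_forward(c(1, NA, 1, 1, 1, 1), random_small_net()),
               "finite")
})

test_that("all-zero weights give the uniform distribution over 8 classes", {
  net <- random_small_net()
  net$weights <- lapply(net$weights, function(w) w * 0)
  fw <- mlp_forward(rnorm(6), net)
  expect_equal(fw$prob, rep(1 / 8, 8), tolerance = 1e-12)
})

test_that("inflating one output column drives its probability toward 1", {
  net <- random_small_net(seed = 2)
  x <- abs(rnorm(6))
  probs <- vapply(c(0, 1, 3, 8), function(boost) {
    n2 <- net
    n2$weights[[3]][, 4] <- n2$weights[[3]][, 4] + boost
    mlp_forward(x, n2)$prob[4]
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_gt(probs[4], 0.99)
})

test_that("prediction takes the argmax with ties toward the lower class", {
  net <- random_small_net()
  net$weights <- lapply(net$weights, function(w) w * 0)  # uniform output
  x <- matrix(rnorm(12), 2, 6)
  expect_equal(predict(net, x), rep(net$classes[1], 2))
  set.seed(4)
  for (i in 1:10) {
    net <- random_small_net(seed = 100 + i)
    xi <- rnorm(6)
    expect_equal(predict(net, xi),
                 net$classes[which.max(oracle_forward(xi, net$weights))])
  }
})

test_that("backpropagation matches central-difference gradients", {
  set.seed(31)
  n <- 12
  x <- matrix(rnorm(n * 6), n, 6)
  y <- sample(1:8, n, replace = TRUE)
  w <- wearhar:::init_weights(6, c(4, 5), 8)
  # jitter all weights (incl. zero biases) away from the ReLU kinks where
  # the loss is not differentiable
  w <- lapply(w, function(m) m + matrix(rnorm(length(m), sd = 0.05),
                                        nrow(m), ncol(m)))
  loss <- function(wl) {
    p <- wearhar:::mlp_forward_batch(x, wl)[[3]]
    -mean(log(p[cbind(seq_len(n), y)]))
  }
  w1 <- wearhar:::sgd_step(x, y, w, lr = 1, n_out = 8)
  for (l in 1:3) {
    analytic <- (w[[l]] - w1[[l]])   # lr = 1: step equals the gradient
    numeric_grad <- matrix(0, nrow(w[[l]]), ncol(w[[l]]))
    eps <- 1e-6
    for (j in seq_len(nrow(w[[l]]))) for (k in seq_len(ncol(w[[l]]))) {
      wp <- w; wp[[l]][j, k] <- wp[[l]][j, k] + eps
      wm <- w; wm[[l]][j, k] <- wm[[l]][j, k] - eps
      numeric_grad[j, k] <- (loss(wp) - loss(wm)) / (2 * eps)
    }
    denom <- pmax(abs(numeric_grad), 1e-4)
    expect_lt(max(abs(analytic - numeric_grad) / denom), 1e-5)
  }
})

test_that("training is deterministic under a seed and fits separable data", {
  set.seed(17)
  n <- 150
  x <- matrix(rnorm(n * 120), n, 120)
  y <- ifelse(x[, 1] + x[, 2] > 0, "walk", "stand")
  x[, 3] <- x[, 3] + 3 * (y == "walk")   # make it easily separable
  f1 <- har_mlp(x, y, hidden = 4, max_epochs = 150, seed = 9)
  f2 <- har_mlp(x, y, hidden = 4, max_epochs = 150, seed = 9)
  expect_identical(f1$weights, f2$weights)
  expect_gte(f1$metrics[["train"]], 0.99)
  expect_error(har_mlp(x, rep("walk", n)), "2 classes")
})

test_that("the cost model reproduces the closed-form counts", {
  two <- cost_model(c(4, 8))
  expect_equal(two[["multiplications"]], 121 * 4 + 5 * 9 + 9 * 8)  # 601
  one <- cost_model(4)
  expect_equal(one[["weights"]], 121 * 4 + 4 * 8)                  # 516
  expect_equal(one[["memory_bytes"]], 516 * 4)
  expect_equal(cost_model(4, bytes_per_weight = 2)[["memory_bytes"]], 516 * 2)
  expect_error(cost_model(0), ">= 1")
  expect_error(cost_model(c(2, 2, 2)), "length 1 or 2")
})

test_that("the DSE selection rule prefers the cheapest near-optimal config", {
  set.seed(23)
  n <- 240
  x <- matrix(rnorm(n * 120), n, 120)
  y <- ifelse(x[, 1] > 0, "walk", ifelse(x[, 2] > 0, "sit", "stand"))
  x[, 3] <- x[, 3] + 2 * (y == "sit")
  x[, 4] <- x[, 4] + 2 * (y == "stand")
  dse <- run_dse(x, y, grid = list(2L, c(4L, 4L)), repeats = 3,
                 max_epochs = 60, seed = 5)
  expect_equal(nrow(dse$table), 2)
  expect_equal(ncol(dse$accuracies), 3)
  expect_true(all(is.finite(dse$accuracies)))
  # easily separable data: both configs tie, so the cheaper one is chosen
  expect_equal(dse$chosen_config,
               dse$table$config[which.min(dse$table$multiplications)])
  # a single-config grid returns that config
  solo <- run_dse(x, y, grid = list(c(4L, 4L)), repeats = 2, max_epochs = 40,
                  seed = 5)
  expect_equal(solo$chosen, c(4L, 4L))
  expect_error(run_dse(x, y, grid = list()), "empty")
})

test_that("model serialization to a flat text file round-trips", {
  net <- random_small_net(seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_mlp(net, path)
  net2 <- read_mlp(path)
  expect_equal(net2$weights, net$weights, tolerance = 1e-15)
  expect_equal(net2$classes, net$classes)
  expect_equal(net2$hidden, net$hidden)
})
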