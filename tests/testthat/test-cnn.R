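# tiny-but-real training setups; production-scale behavior is exercised in
# test-acceptance.R

tiny_cfg <- function(n_out = 31L, epochs = 3L, seed = 7L) {
  cnn_config(conv_channels = c(2L, 3L, 4L, 4L), dense_width = 8L,
             n_out = n_out, epochs = epochs, batch_size = 4L, seed = seed)
}

tiny_pairs <- function(n = 20L, H = 16L, W = 16L, C = 2L, n_out = 31L,
                       seed = 1L, f = NULL) {
  set.seed(seed)
  tensors <- array(rnorm(H * W * C * n), dim = c(H, W, C, n))
  targets <- if (is.null(f)) matrix(rnorm(n_out * n), n_out, n) else f(tensors)
  pair_dataset(tensors, targets, plant = paste0("p", rep(1:(n / 2), each = 2)))
}

test_that("layer shapes and parameter count are pure functions of config", {
  sh <- cnn_shapes(cnn_config())
  expect_equal(sh$shapes$conv1, c(3L, 3L, 5L, 8L))
  expect_equal(sh$shapes$dense1, c(256L, 4096L))
  expect_equal(sh$n_params, 1459261) # frozen golden value for the defaults
  sh1 <- cnn_shapes(cnn_config(layout = "concat_1d"))
  expect_equal(sh1$shapes$dense1, c(256L, 20480L))
  expect_error(cnn_config(conv_channels = c(8, 16)), "4 convolution")
})

test_that("the analytic gradient matches finite differences", {
  H <- 16L; W <- 16L; C <- 2L
  cfg <- tiny_cfg(n_out = 11L)
  w <- chromcast:::cnn_init(cfg, c(H, W, C))
  set.seed(52)
  tensors <- array(rnorm(H * W * C * 3), dim = c(H, W, C, 3))
  targets <- matrix(rnorm(11 * 3), 11, 3)
  gr <- chromcast:::cpp_cnn_grad(tensors, c(H, W, C), 1:3, targets, 1:3, w)
  lossfun <- function(wm) {
    mean(colMeans(abs(chromcast:::cpp_cnn_predict(tensors, c(H, W, C), 1:3, wm) -
                        targets)))
  }
  expect_equal(gr$loss, lossfun(w), tolerance = 1e-5)
  for (li in c(1, 5, 9, 11)) {
    for (i in sample(length(w[[li]]), 3)) {
      eps <- 1e-4
      wp <- w; wp[[li]][i] <- wp[[li]][i] + eps
      wm <- w; wm[[li]][i] <- wm[[li]][i] - eps
      num <- (lossfun(wp) - lossfun(wm)) / (2 * eps)
      if (abs(num) > 1e-5) {
        expect_equal(gr$grads[[li]][i], num, tolerance = 2e-2)
      }
    }
  }
})

test_that("training reduces the loss and records history", {
  f <- function(tensors) {
    n <- dim(tensors)[4L]
    base <- apply(tensors, 4, mean)
    outer(seq_len(31L) / 31, base) + 0.5
  }
  pairs <- tiny_pairs(n = 50L, f = f)
  m <- train_cnn(tiny_cfg(epochs = 2L), pairs)
  expect_equal(nrow(m$history), 2L)
  expect_lt(m$history$train_mae[2L], m$history$train_mae[1L])
})

test_that("a constant target is learned to near-zero MAE", {
  f <- function(tensors) matrix(0.7, 31L, dim(tensors)[4L])
  pairs <- tiny_pairs(n = 24L, f = f)
  cfg <- tiny_cfg(epochs = 40L)
  cfg$lr <- 1e-2
  m <- train_cnn(cfg, pairs)
  expect_lt(tail(m$history$train_mae, 1L), 0.05)
  expect_lt(tail(m$history$train_mae, 1L), m$history$train_mae[1L] / 5)
})

test_that("training and prediction are deterministic given the seed", {
  pairs <- tiny_pairs(n = 16L)
  m1 <- train_cnn(tiny_cfg(seed = 3L), pairs)
  m2 <- train_cnn(tiny_cfg(seed = 3L), pairs)
  expect_identical(m1$history$train_mae, m2$history$train_mae)
  expect_identical(m1$weights, m2$weights)
  p1 <- predict(m1, pairs, 1:4)
  expect_identical(p1, predict(m2, pairs, 1:4))
  expect_equal(dim(p1), c(31L, 4L))
  expect_true(all(is.finite(p1)))
})

test_that("NaN-producing configurations abort with a diagnostic", {
  pairs <- tiny_pairs(n = 12L)
  pairs$targets[1L, 1L] <- NaN
  expect_error(train_cnn(tiny_cfg(epochs = 1L), pairs), "NaN")
})

test_that("both layouts train end to end on matching shapes", {
  # the architecture adapts its dense stage to the input shape
  for (shape in list(c(32L, 16L, 1L), c(16L, 16L, 5L))) {
    set.seed(54)
    tensors <- array(rnorm(prod(shape) * 10), dim = c(shape, 10L))
    targets <- matrix(rnorm(210), 21L, 10L)
    pairs <- pair_dataset(tensors, targets)
    m <- train_cnn(cnn_config(conv_channels = c(2, 2, 3, 3), dense_width = 6,
                              n_out = 21L, epochs = 1L, seed = 2L), pairs)
    expect_equal(dim(predict(m, pairs, 1:2)), c(21L, 2L))
  }
})

test_that("predict validates tensor shapes", {
  pairs <- tiny_pairs(n = 12L)
  m <- train_cnn(tiny_cfg(epochs = 1L), pairs)
  bad <- array(0, dim = c(8, 8, 2, 1))
  expect_error(predict(m, bad), "shape")
})

test_that("split_data is seeded, disjoint, exhaustive, and group-aware", {
  sp <- split_data(100L, 0.85, seed = 9L, group_by_plant = FALSE)
  expect_length(sp$train, 85L)
  expect_length(sp$test, 15L)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_identical(sp, split_data(100L, 0.85, seed = 9L, group_by_plant = FALSE))

  pairs <- tiny_pairs(n = 20L) # 10 plants, 2 pairs each
  sp <- split_data(pairs, 0.8, seed = 4L)
  expect_length(intersect(unique(pairs$plant[sp$train]),
                          unique(pairs$plant[sp$test])), 0L)
  expect_error(split_data(8L, 0.85), "too few")
})
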