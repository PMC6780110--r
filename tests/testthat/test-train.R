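test_that("class frequencies use the images-containing-class denominator", {
  half <- matrix(rep(c(0L, 1L), each = 8), 4, 4)
  expect_equal(class_frequencies(half),
               c(background = 0.5, vessel = 0.5))
  # 10% vessel overall
  m <- matrix(0L, 10, 10); m[1, 1:10] <- 1L
  expect_equal(unname(class_frequencies(m)), c(0.9, 0.1))
  # an all-background mask adds to the background denominator only
  m2 <- matrix(0L, 10, 10)
  fr <- class_frequencies(list(m, m2))
  expect_equal(unname(fr), c((90 + 100) / 200, 10 / 100))
  expect_error(class_frequencies(list(m2)), "absent")
})

test_that("median-frequency weights follow w = median(freq)/freq", {
  expect_equal(unname(median_frequency_weights(c(0.5, 0.5))), c(1, 1))
  expect_equal(unname(median_frequency_weights(c(0.9, 0.1))),
               c(0.5 / 0.9, 5))
  f <- c(0.8, 0.2)
  expect_equal(median_frequency_weights(f),
               median_frequency_weights(10 * f))  # scale invariant
  expect_error(median_frequency_weights(c(0.5, 0)), "positive")
})

test_that("weighted cross-entropy matches hand sums and unit cases", {
  mask <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  onehot <- array(0, c(2, 2, 2))
  onehot[, , 2] <- mask; onehot[, , 1] <- 1 - mask
  expect_equal(weighted_cross_entropy(onehot, mask, c(2, 3)), 0)
  uni <- array(0.5, c(2, 2, 2))
  expect_equal(weighted_cross_entropy(uni, mask, c(1, 1)), log(2))
  # four pixels by hand with probabilities p_true = .9,.8,.6,.7
  prob <- array(0, c(2, 2, 2))
  prob[, , 2] <- matrix(c(0.9, 0.2, 0.4, 0.7), 2, 2)
  prob[, , 1] <- 1 - prob[, , 2]
  w <- c(0.5, 5)
  hand <- -(5 * log(0.9) + 0.5 * log(0.8) + 0.5 * log(0.6) +
              5 * log(0.7)) / 4
  expect_equal(weighted_cross_entropy(prob, mask, w), hand)
  expect_error(weighted_cross_entropy(uni, matrix(0L, 3, 3), w), "dims")
  # loss is non-negative and unit weights reduce to plain cross-entropy
  expect_gt(weighted_cross_entropy(uni, mask, c(1, 1)), 0)
})

test_that("zero learning rate leaves parameters unchanged", {
  pairs <- generate_dataset(2, synth_params(image_size = 32, seed = 2,
                                            width_range = c(1, 2)))
  model <- vn_init(plan_vessnet(c(32, 32, 3), 2, base_filters = 2), seed = 5)
  fit <- train_vessnet(model, pairs,
                       train_config(learning_rate = 0, batch_size = 2L,
                                    epochs = 1L, seed = 5))
  expect_equal(fit$model$params, model$params)
})

test_that("a short run reduces the class-balanced loss on toy data", {
  pairs <- generate_dataset(4, synth_params(image_size = 32, seed = 3,
                                            width_range = c(1, 2)))
  model <- vn_init(plan_vessnet(c(32, 32, 3), 2, base_filters = 4), seed = 6)
  fit <- train_vessnet(model, pairs,
                       train_config(learning_rate = 2e-3, batch_size = 2L,
                                    epochs = 4L, seed = 6))
  expect_equal(nrow(fit$history), 4L)
  expect_lt(fit$history$loss[4], fit$history$loss[1])
  # deterministic given the seed
  fit2 <- train_vessnet(model, pairs,
                        train_config(learning_rate = 2e-3, batch_size = 2L,
                                     epochs = 4L, seed = 6))
  expect_equal(fit$model$params, fit2$model$params)
})

test_that("degenerate training inputs are rejected", {
  model <- vn_init(plan_vessnet(c(32, 32, 3), 2, base_filters = 2), seed = 1)
  expect_error(train_vessnet(model, list(), train_config()), "empty")
  p <- generate_dataset(1, synth_params(image_size = 32, seed = 4,
                                        width_range = c(1, 2)))
  expect_error(train_vessnet(model, p, train_config(batch_size = 7L)),
               "fewer images")
})
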