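tiny_model <- function(size = 16, base = 4, seed = 3)
  vn_init(plan_vessnet(c(size, size, 3), 2, base_filters = base), seed = seed)

test_that("full forward pass matches the naive composed oracle", {
  model <- tiny_model()
  x <- withr::with_seed(21, array(runif(16 * 16 * 3), c(16, 16, 3)))
  got <- vn_forward(model, x)
  ref <- naive_forward(model, x)
  expect_lt(rel_err(got, ref), 1e-10)
})

test_that("residual-stream identities hold exactly on captured tensors", {
  model <- tiny_model()
  x <- withr::with_seed(22, array(runif(16 * 16 * 3), c(16, 16, 3)))
  tn <- attr(vn_forward(model, x, keep_tensors = TRUE), "tensors")
  for (b in c("ECB-2", "ECB-3", "ECB-4")) {
    # encoder add: block output is ReLU(S + F), elementwise
    expect_identical(tn[[b]]$block_output,
                     pmax(tn[[b]]$after_second_conv_bn +
                            tn[[b]]$projection_branch, 0), label = b)
  }
  for (i in 2:4) {
    d <- sprintf("DCB-%d", i); e <- sprintf("ECB-%d", i)
    # outer identity add: T' = K + T
    expect_identical(tn[[d]]$orsp_enriched,
                     tn[[d]]$after_first_relu + tn[[e]]$after_first_relu,
                     label = d)
    # inner projection add: Z = ReLU(S' + F)
    expect_identical(tn[[d]]$block_output,
                     pmax(tn[[d]]$after_second_conv_bn +
                            tn[[d]]$projection_branch, 0), label = d)
  }
  # terminal decoder block omits the projection branch
  expect_null(tn[["DCB-1"]]$projection_branch)
  expect_identical(tn[["DCB-1"]]$orsp_enriched,
                   tn[["DCB-1"]]$after_first_relu +
                     tn[["ECB-1"]]$after_first_relu)
})

test_that("probabilities normalize and output shape mirrors the input", {
  model <- tiny_model(size = 20)
  x <- withr::with_seed(23, array(runif(20 * 20 * 3), c(20, 20, 3)))
  prob <- vn_forward(model, x)
  expect_equal(dim(prob), c(20, 20, 2))
  expect_lt(max(abs(apply(prob, c(1, 2), sum) - 1)), 1e-6)
  expect_error(vn_forward(model, array(0, c(16, 16, 3))), "shape")
})

test_that("encoder block honours its contracts", {
  model <- tiny_model()
  x <- withr::with_seed(24, array(runif(16 * 16 * 3), c(16, 16, 3)))
  # zero weights, zero shift: every intermediate tensor is zero
  zmodel <- model
  for (nm in names(zmodel$params)) {
    zmodel$params[[nm]]$W[] <- 0
    zmodel$params[[nm]]$beta[] <- 0
    zmodel$params[[nm]]$b[] <- 0
  }
  r0 <- encoder_block_forward(zmodel, x, "ECB-1")
  expect_true(all(r0$tensors$after_first_relu == 0))
  expect_true(all(r0$output == 0))
  # with the projection branch zeroed, pre-ReLU output equals S
  pmodel <- model
  pmodel$params[["IRSP-1"]]$W[] <- 0
  pmodel$params[["IRSP-1"]]$gamma[] <- 0
  pmodel$params[["IRSP-1"]]$beta[] <- 0
  e1 <- encoder_block_forward(pmodel, x, "ECB-1")
  r <- encoder_block_forward(pmodel, e1$output, "ECB-2")
  expect_true(all(r$tensors$projection_branch == 0))
  expect_identical(r$tensors$block_output,
                   pmax(r$tensors$after_second_conv_bn, 0))
  # pool record restores the pre-pool shape
  expect_equal(r$pool_record$pre_pool_shape[1:2], c(8, 8))
  expect_error(encoder_block_forward(model, x, "ECB-2"), "shape")
})

test_that("decoder block honours its contracts", {
  model <- tiny_model()
  x <- withr::with_seed(25, array(runif(16 * 16 * 3), c(16, 16, 3)))
  e1 <- encoder_block_forward(model, x, "ECB-1")
  e2 <- encoder_block_forward(model, e1$output, "ECB-2")
  e3 <- encoder_block_forward(model, e2$output, "ECB-3")
  e4 <- encoder_block_forward(model, e3$output, "ECB-4")
  # zero outer-path feature: T' = K
  d4 <- decoder_block_forward(model, e4$output, e4$pool_record,
                              e4$orsp_tap * 0, "DCB-4")
  expect_identical(d4$tensors$orsp_enriched, d4$tensors$after_first_relu)
  expect_error(decoder_block_forward(model, e4$output, NULL,
                                     e4$orsp_tap, "DCB-4"), "record")
  expect_error(decoder_block_forward(model, e4$output, e4$pool_record,
                                     e3$orsp_tap, "DCB-4"), "shape")
})

test_that("constant input yields spatially constant first-block features", {
  model <- tiny_model(size = 20)
  x <- array(0.4, c(20, 20, 3))
  tap <- encoder_block_forward(model, x, "ECB-1")$orsp_tap
  interior <- tap[3:18, 3:18, , drop = FALSE]  # outside the 3x3 halo
  for (c in seq_len(dim(interior)[3]))
    expect_lt(diff(range(interior[, , c])), 1e-9)
})

test_that("argmax prediction breaks ties toward the non-vessel class", {
  prob <- array(0.5, c(2, 2, 2))
  expect_true(all(prob_to_mask(prob) == 0L))
  prob[1, 1, 2] <- 0.6; prob[1, 1, 1] <- 0.4
  expect_identical(prob_to_mask(prob)[1, 1], 1L)
})
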