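#' Initialize network parameters for a plan
#'
#' He-style initialisation for convolution weights (zero-mean Gaussian with
#' sd `sqrt(2 / fan_in)`), zero biases, and scale 1 / shift 0 for every
#' batch-normalization layer, under a fixed seed.
#'
#' Weight matrices are stored as `(kh*kw*in_channels) x out_channels`
#' matrices whose rows are ordered channel-major, then kernel row, then
#' kernel column, matching the im2col layout of the compiled kernels.
#'
#' @param plan a `vn_plan` from [plan_vessnet()].
#' @param seed integer seed for the initialisation.
#' @return An object of class `vn_model`: list with `plan` and `params`
#'   (one `list(W, b, gamma, beta)` per convolution layer, named as in the
#'   plan).
#' @export
vn_init <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "vn_plan"))
  specs <- conv_specs(plan)
  params <- list()
  withr::with_seed(as.integer(seed), {
    for (s in specs) {
      fan_in <- prod(s$kernel) * s$in_channels
      params[[s$name]] <- list(
        W = matrix(stats::rnorm(fan_in * s$out_channels,
                                sd = sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = s$out_channels),
        b = numeric(s$out_channels),
        gamma = rep(1, s$out_channels),
        beta = numeric(s$out_channels))
    }
  })
  structure(list(plan = plan, params = params), class = "vn_model")
}

#' @export
print.vn_model <- function(x, ...) {
  n <- sum(vapply(x$params, function(p)
    length(p$W) + length(p$b) + length(p$gamma) + length(p$beta), numeric(1)))
  cat(sprintf("vn_model: %s trainable parameters\n", format(n, big.mark = ",")))
  print(x$plan)
  invisible(x)
}

.bn_eps <- 1e-5

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# conv -> BN (-> optional ReLU) for one named layer; returns value + cache.
.conv_bn <- function(params, spec, x, want_cache = FALSE) {
  p <- params[[spec$name]]
  a <- cpp_conv2d(x, p$W, p$b, spec$kernel[1], spec$kernel[2])
  bn <- cpp_bn_forward(a, p$gamma, p$beta, .bn_eps)
  z <- bn$y
  y <- if (spec$relu_after) relu(z) else z
  cache <- if (want_cache)
    list(x = x, a = a, mean = bn$mean, invstd = bn$invstd, z = z) else NULL
  list(y = y, z = z, cache = cache)
}

# Backward through one conv->BN(->ReLU) layer. gy is the gradient at the
# layer output; returns gradient at the input plus parameter gradients.
.conv_bn_backward <- function(params, spec, cache, gy) {
  if (spec$relu_after) gy <- gy * (cache$z > 0)
  p <- params[[spec$name]]
  bnb <- cpp_bn_backward(cache$a, gy, p$gamma, cache$mean, cache$invstd)
  cvb <- cpp_conv2d_backward(cache$x, p$W, bnb$gx,
                             spec$kernel[1], spec$kernel[2])
  list(gx = cvb$gx,
       grads = list(W = cvb$gw, b = as.numeric(cvb$gb),
                    gamma = as.numeric(bnb$ggamma),
                    beta = as.numeric(bnb$gbeta)))
}

.check_shape <- function(x, expected, what) {
  if (!identical(unname(dim(x)), as.integer(unname(expected))))
    stop(what, ": expected shape ", paste(expected, collapse = "x"),
         ", got ", paste(dim(x), collapse = "x"))
  invisible(TRUE)
}

#' Forward pass through one encoder block
#'
#' Runs conv/BN/ReLU, then (for blocks with an inner residual path) the
#' second conv/BN plus the 1x1 projection branch of the block input, the
#' elementwise residual add `Y = S + F`, a ReLU, and 2x2 max pooling with
#' argmax recording. The first-ReLU activation `T` is returned as the tap
#' feeding the matching decoder block over the identity outer path.
#'
#' @param model a `vn_model`.
#' @param x input activation array `H x W x C`.
#' @param block_id encoder block id, e.g. `"ECB-2"`.
#' @return List with `output` (post-pool), `pool_record` (`indices`,
#'   `pre_pool_shape`), `orsp_tap` (`T`), and `tensors` (named intermediate
#'   activations: `block_input`, `after_first_relu`, `after_second_conv_bn`,
#'   `projection_branch`, `block_output`).
#' @export
encoder_block_forward <- function(model, x, block_id) {
  b <- .find_block(model$plan, block_id, "encoder")
  a1 <- b$layers[[1]]
  .check_shape(x, c(dim(x)[1:2], a1$in_channels), b$block_id)
  tap <- .conv_bn(model$params, a1, x)$y
  s <- .conv_bn(model$params, b$layers[[2]], tap)
  if (b$has_irsp) {
    f <- .conv_bn(model$params, b$irsp, x)$y
    y <- relu(s$y + f)
  } else {
    f <- NULL
    y <- s$y  # ECon-1_2 already applies its own ReLU
  }
  pl <- cpp_maxpool(y)
  list(output = pl$y,
       pool_record = list(indices = pl$idx, pre_pool_shape = dim(y)),
       orsp_tap = tap,
       tensors = list(block_input = x, after_first_relu = tap,
                      after_second_conv_bn = s$z, projection_branch = f,
                      block_output = y))
}

#' Forward pass through one decoder block
#'
#' Max-unpools the input with the recorded indices, applies conv/BN/ReLU
#' giving `K`, adds the identity outer-path feature (`T' = K + T`), applies
#' the second conv/BN giving `S'`, and for blocks with an inner residual
#' path adds the 1x1 projection of the unpooled block input (`Z = S' + F`)
#' followed by ReLU. The terminal block omits the projection add and ends
#' with the `num_classes`-filter conv/BN/ReLU.
#'
#' @param model a `vn_model`.
#' @param x input activation array (pre-unpool).
#' @param pool_record the matching encoder block's pooling record.
#' @param orsp_in the matching encoder block's first-ReLU tap.
#' @param block_id decoder block id, e.g. `"DCB-3"`.
#' @return List with `output` and `tensors` (`block_input` is the unpooled
#'   activation; `orsp_enriched` is `T'`).
#' @export
decoder_block_forward <- function(model, x, pool_record, orsp_in, block_id) {
  b <- .find_block(model$plan, block_id, "decoder")
  if (is.null(pool_record)) stop("missing pooling record for ", block_id)
  u <- cpp_unpool(x, pool_record$indices,
                  pool_record$pre_pool_shape[1], pool_record$pre_pool_shape[2])
  k <- .conv_bn(model$params, b$layers[[1]], u)$y
  .check_shape(orsp_in, dim(k), paste0(block_id, " outer residual input"))
  tp <- k + orsp_in
  s <- .conv_bn(model$params, b$layers[[2]], tp)
  if (b$has_irsp) {
    f <- .conv_bn(model$params, b$irsp, u)$y
    out <- relu(s$y + f)
  } else {
    f <- NULL
    out <- s$y  # terminal conv applies its own ReLU
  }
  list(output = out,
       tensors = list(block_input = u, after_first_relu = k,
                      orsp_enriched = tp, after_second_conv_bn = s$z,
                      projection_branch = f, block_output = out))
}

.find_block <- function(plan, block_id, role) {
  for (b in plan$blocks)
    if (b$block_id == block_id && b$role == role) return(b)
  stop("no ", role, " block ", block_id, " in plan")
}

#' Full forward pass: image to per-pixel class probabilities
#'
#' Runs the four encoder blocks (collecting pooling records and outer-path
#' taps), the four decoder blocks, and a per-pixel softmax over the final
#' `num_classes`-channel map.
#'
#' @param model a `vn_model`.
#' @param image numeric array `H x W x 3` in `[0, 1]`, spatial dims matching
#'   the plan.
#' @param keep_tensors if `TRUE`, attach every block's named intermediate
#'   activations as attribute `"tensors"` (feature-map inspection hook).
#' @return `H x W x num_classes` array of probabilities summing to 1 at
#'   every pixel.
#' @export
vn_forward <- function(model, image, keep_tensors = FALSE) {
  plan <- model$plan
  .check_shape(image, plan$input_shape, "input image")
  taps <- recs <- vector("list", 4L)
  tensors <- list()
  cur <- image
  for (b in plan$blocks) {
    if (b$role == "encoder") {
      r <- encoder_block_forward(model, cur, b$block_id)
      taps[[b$index]] <- r$orsp_tap
      recs[[b$index]] <- r$pool_record
    } else {
      r <- decoder_block_forward(model, cur, recs[[b$index]],
                                 taps[[b$index]], b$block_id)
    }
    if (keep_tensors) tensors[[b$block_id]] <- r$tensors
    cur <- r$output
  }
  prob <- softmax_channels(cur)
  if (keep_tensors) attr(prob, "tensors") <- tensors
  prob
}

#' Per-pixel softmax over the channel dimension
#'
#' @param z numeric array `H x W x C`.
#' @return Array of the same shape with channels summing to 1 per pixel.
#' @export
softmax_channels <- function(z) {
  m <- apply(z, c(1, 2), max)
  e <- exp(z - as.vector(m))
  s <- apply(e, c(1, 2), sum)
  e / as.vector(s)
}

#' Predict a binary vessel mask
#'
#' Argmax over the class probabilities; ties are assigned to the non-vessel
#' class (channel 1), a conservative choice for screening. Channel 2 is the
#' vessel class throughout the package.
#'
#' @param model a `vn_model`.
#' @param image numeric array `H x W x 3`.
#' @return Integer matrix `H x W` with values in `{0, 1}` (1 = vessel).
#' @export
vn_predict <- function(model, image) {
  prob <- vn_forward(model, image)
  prob_to_mask(prob)
}

#' @rdname vn_predict
#' @param prob `H x W x 2` probability array (channel 2 = vessel).
#' @export
prob_to_mask <- function(prob) {
  m <- (prob[, , 2] > prob[, , 1]) * 1L
  matrix(as.integer(m), nrow = dim(prob)[1])
}

#' Save or load a model
#'
#' The standard R serialization (RDS) with the plan embedded.
#'
#' @param model a `vn_model`.
#' @param path file path.
#' @return `vn_load` returns the model; `vn_save` its path, invisibly.
#' @export
vn_save <- function(model, path) {
  stopifnot(inherits(model, "vn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname vn_save
#' @export
vn_load <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "vn_model")) stop("not a serialized vn_model: ", path)
  m
}
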