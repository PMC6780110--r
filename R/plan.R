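#' Declarative plan of the dual-residual-stream vessel segmentation network
#'
#' Builds the layer/link graph of the 16-convolution encoder-decoder
#' (Vess-Net): four encoder blocks and four mirrored decoder blocks of two
#' 3x3 convolutions each, six projection (1x1 conv + BN, non-identity) inner
#' residual skip paths, four identity outer residual skip paths carrying the
#' first-activation feature of each encoder block to the matching decoder
#' block, four 2x2 max-pooling stages that record argmax indices, and four
#' max-unpooling stages that consume them. The final convolution has
#' `num_classes` filters and feeds a per-pixel softmax.
#'
#' Channel widths per stage are `base_filters * c(1, 2, 4, 8)`; the default
#' 64 gives the published layout (deepest map 27 x 27 x 512 for a
#' 447 x 447 x 3 input). Smaller `base_filters` keep the topology (layer and
#' link counts) while scaling the width down for CPU-sized experiments.
#'
#' @param input_shape integer vector `c(height, width, channels)`; channels
#'   must be 3 and both spatial dims at least 16 (four rounds of halving).
#' @param num_classes number of output classes (>= 2; 2 for vessel versus
#'   non-vessel).
#' @param base_filters width of the first stage; later stages double it.
#' @return An object of class `vn_plan`: list with `blocks` (eight block
#'   specs, encoder then decoder), `links` (ten residual link specs),
#'   `input_shape`, `num_classes`, `base_filters`.
#' @examples
#' plan <- plan_vessnet(c(64, 64, 3), 2)
#' sum(vapply(conv_specs(plan), function(s) all(s$kernel == 3), logical(1)))
#' @export
plan_vessnet <- function(input_shape = c(447L, 447L, 3L), num_classes = 2L,
                         base_filters = 64L) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape <= 0L))
    stop("input_shape must be three positive integers (height, width, channels)")
  if (input_shape[3] != 3L)
    stop("input images must have 3 channels")
  if (any(input_shape[1:2] < 16L))
    stop("spatial dims must be at least 16 to survive four pooling stages")
  if (num_classes < 2L)
    stop("num_classes must be at least 2")
  w <- as.integer(base_filters * c(1L, 2L, 4L, 8L))
  if (base_filters < 1L) stop("base_filters must be positive")

  conv_spec <- function(name, k, cin, cout, relu)
    list(name = name, kernel = c(k, k), in_channels = as.integer(cin),
         out_channels = as.integer(cout), has_bn = TRUE, relu_after = relu)

  blocks <- list()
  links <- list()
  # Encoder: first block has no inner projection path; blocks 2-4 do.
  cin <- input_shape[3]
  for (i in 1:4) {
    a <- conv_spec(sprintf("ECon-%d_1", i), 3L, cin, w[i], relu = TRUE)
    # second conv of blocks 2-4 is BN-only: ReLU comes after the residual add
    b <- conv_spec(sprintf("ECon-%d_2", i), 3L, w[i], w[i], relu = (i == 1L))
    irsp <- NULL
    if (i > 1L) {
      irsp <- conv_spec(sprintf("IRSP-%d", i - 1L), 1L, cin, w[i], relu = FALSE)
      links[[length(links) + 1L]] <- list(
        link_id = irsp$name, kind = "projection",
        source = sprintf("ECB-%d.input", i),
        target = sprintf("ECB-%d.add", i), projection = irsp)
    }
    blocks[[length(blocks) + 1L]] <- list(
      block_id = sprintf("ECB-%d", i), role = "encoder", index = i,
      layers = list(a, b), has_irsp = i > 1L, irsp = irsp,
      pool_or_unpool = "pool")
    cin <- w[i]
  }
  # Outer identity links: encoder first-ReLU tap -> decoder add point.
  for (i in 1:4)
    links[[length(links) + 1L]] <- list(
      link_id = sprintf("ORSP-%d", i), kind = "identity",
      source = sprintf("ECB-%d.relu1", i),
      target = sprintf("DCB-%d.add1", i), projection = NULL)
  # Decoder mirrors the encoder, deepest block first. Layer naming follows
  # the published tables, where the "_2" layer of a decoder block comes
  # first and the "_1" layer second.
  for (i in 4:1) {
    cin_b <- w[i]
    cout_b <- if (i > 1L) w[i - 1L] else num_classes
    first_name <- if (i == 1L) "DConv-1_2" else sprintf("DCon-%d_2", i)
    second_name <- if (i == 1L) "DConv-1_1" else sprintf("DCon-%d_1", i)
    a <- conv_spec(first_name, 3L, cin_b, cin_b, relu = TRUE)
    b <- conv_spec(second_name, 3L, cin_b, cout_b, relu = (i == 1L))
    irsp <- NULL
    if (i > 1L) {
      irsp <- conv_spec(sprintf("IRSP-%d", 8L - i), 1L, cin_b, cout_b,
                        relu = FALSE)
      links[[length(links) + 1L]] <- list(
        link_id = irsp$name, kind = "projection",
        source = sprintf("DCB-%d.input", i),
        target = sprintf("DCB-%d.add", i), projection = irsp)
    }
    blocks[[length(blocks) + 1L]] <- list(
      block_id = sprintf("DCB-%d", i), role = "decoder", index = i,
      layers = list(a, b), has_irsp = i > 1L, irsp = irsp,
      pool_or_unpool = "unpool")
  }
  structure(list(blocks = blocks, links = links, input_shape = input_shape,
                 num_classes = as.integer(num_classes),
                 base_filters = as.integer(base_filters)),
            class = "vn_plan")
}

#' All convolution layer specs of a plan
#'
#' @param plan a `vn_plan`.
#' @param include_projections include the 1x1 projection layers of the inner
#'   residual paths (default `TRUE`).
#' @return Named list of layer specs in execution order.
#' @export
conv_specs <- function(plan, include_projections = TRUE) {
  out <- list()
  for (b in plan$blocks) {
    out[[b$layers[[1]]$name]] <- b$layers[[1]]
    if (include_projections && b$has_irsp) out[[b$irsp$name]] <- b$irsp
    out[[b$layers[[2]]$name]] <- b$layers[[2]]
  }
  out
}

#' Trainable parameter count of one convolution layer
#'
#' Weights plus one bias per filter: `(kh * kw * in_channels + 1) * out_channels`.
#'
#' @param spec a convolution layer spec (see [conv_specs()]).
#' @return Integer parameter count.
#' @examples
#' p <- plan_vessnet()
#' conv_param_count(conv_specs(p)[["ECon-1_1"]])  # 1792
#' @export
conv_param_count <- function(spec)
  (prod(spec$kernel) * spec$in_channels + 1L) * spec$out_channels

#' Trainable parameter count of a layer's batch normalization
#'
#' One scale and one shift per channel; running statistics are
#' implementation-internal and not counted.
#'
#' @inheritParams conv_param_count
#' @return Integer parameter count (`2 * out_channels`).
#' @export
bn_param_count <- function(spec) 2L * spec$out_channels

#' Shape schedule of a plan
#'
#' Walks the plan and returns the output feature-map shape of every
#' convolution, pooling, and unpooling stage. 3x3 convolutions preserve
#' spatial dims (single-pixel zero padding, stride 1); each pooling halves
#' with floor division; each unpooling restores the recorded pre-pool shape,
#' so odd sizes (447 -> 223 -> 111 -> 55 -> 27) round-trip exactly and the
#' final output has the input's spatial size with `num_classes` channels.
#'
#' @param plan a `vn_plan`.
#' @return Named list mapping layer/stage name to `c(height, width, channels)`.
#' @export
infer_shapes <- function(plan) {
  shapes <- list()
  hw <- plan$input_shape[1:2]
  pre_pool <- vector("list", 4L)
  tap_shape <- vector("list", 4L)
  for (b in plan$blocks) {
    if (b$role == "decoder") {
      restored <- pre_pool[[b$index]]
      if (is.null(restored)) stop("missing pooling record for ", b$block_id)
      hw <- restored
      shapes[[sprintf("Unpool-%d", b$index)]] <-
        c(hw, b$layers[[1]]$in_channels)
    }
    a <- b$layers[[1]]
    shapes[[a$name]] <- c(hw, a$out_channels)
    if (b$role == "decoder") {
      tap <- tap_shape[[b$index]]
      if (!identical(unname(tap), unname(c(hw, a$out_channels))))
        stop("outer residual add would join mismatched shapes at ", b$block_id)
    } else {
      tap_shape[[b$index]] <- c(hw, a$out_channels)
    }
    if (b$has_irsp) {
      shapes[[b$irsp$name]] <- c(hw, b$irsp$out_channels)
      if (b$irsp$out_channels != b$layers[[2]]$out_channels)
        stop("inner residual add would join mismatched shapes at ", b$block_id)
    }
    shapes[[b$layers[[2]]$name]] <- c(hw, b$layers[[2]]$out_channels)
    if (b$role == "encoder") {
      pre_pool[[b$index]] <- hw
      hw <- hw %/% 2L
      shapes[[sprintf("Pool-%d", b$index)]] <- c(hw, b$layers[[2]]$out_channels)
    }
  }
  shapes
}

#' Printable architecture table
#'
#' Mirrors the per-layer layout of the network: block, layer name, kernel,
#' number of filters, output feature-map shape, and trainable parameter
#' counts split into convolution (weights + bias) and batch-normalization
#' (scale + shift) parts, with grand totals.
#'
#' @param plan a `vn_plan`.
#' @return A data frame of class `vn_plan_table`.
#' @export
describe_plan <- function(plan) {
  shapes <- infer_shapes(plan)
  fmt_shape <- function(s) sprintf("%d × %d × %d", s[1], s[2], s[3])
  rows <- list()
  add_row <- function(block, name, kernel, filters, shape, conv_p, bn_p)
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, name = name, kernel = kernel, filters = filters,
      shape = shape, conv_params = conv_p, bn_params = bn_p,
      stringsAsFactors = FALSE)
  layer_row <- function(block_id, spec) {
    add_row(block_id, spec$name,
            sprintf("%d × %d × %d", spec$kernel[1], spec$kernel[2],
                    spec$in_channels),
            spec$out_channels, fmt_shape(shapes[[spec$name]]),
            conv_param_count(spec), bn_param_count(spec))
  }
  for (b in plan$blocks) {
    if (b$role == "decoder") {
      nm <- sprintf("Unpool-%d", b$index)
      add_row(sprintf("Un-pooling-%d", b$index), nm, "2 × 2", NA,
              fmt_shape(shapes[[nm]]), NA, NA)
    }
    layer_row(b$block_id, b$layers[[1]])
    if (b$has_irsp) layer_row(b$block_id, b$irsp)
    layer_row(b$block_id, b$layers[[2]])
    if (b$role == "encoder") {
      nm <- sprintf("Pool-%d", b$index)
      add_row(sprintf("Pooling-%d", b$index), nm, "2 × 2", NA,
              fmt_shape(shapes[[nm]]), NA, NA)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "totals") <- c(conv = sum(out$conv_params, na.rm = TRUE),
                           bn = sum(out$bn_params, na.rm = TRUE))
  class(out) <- c("vn_plan_table", "data.frame")
  out
}

#' @export
print.vn_plan_table <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", format(v, big.mark = ","))
  df <- data.frame(Block = x$block, Name = x$name, Kernel = x$kernel,
                   Filters = ifelse(is.na(x$filters), "-", x$filters),
                   `Output size` = x$shape,
                   Parameters = ifelse(is.na(x$conv_params), "-",
                                       paste(fmt(x$conv_params), "+",
                                             fmt(x$bn_params))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  print(df, row.names = FALSE, right = FALSE)
  tot <- attr(x, "totals")
  cat(sprintf("Total trainable parameters: %s conv + %s BN = %s\n",
              fmt(tot["conv"]), fmt(tot["bn"]), fmt(sum(tot))))
  invisible(x)
}

#' @export
print.vn_plan <- function(x, ...) {
  n3 <- sum(vapply(conv_specs(x, FALSE), function(s) all(s$kernel == 3L),
                   logical(1)))
  cat(sprintf(paste0("Dual-residual-stream segmentation plan: %d x %d x %d ",
                     "input, %d classes\n  %d 3x3 conv layers, %d residual ",
                     "links (%d projection, %d identity), 4 pool / 4 unpool\n"),
              x$input_shape[1], x$input_shape[2], x$input_shape[3],
              x$num_classes, n3, length(x$links),
              sum(vapply(x$links, function(l) l$kind == "projection",
                         logical(1))),
              sum(vapply(x$links, function(l) l$kind == "identity",
                         logical(1)))))
  invisible(x)
}
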