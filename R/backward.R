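# Full-network backward pass. The forward here mirrors vn_forward but keeps
# per-layer caches; it is intentionally the same dataflow so that gradients
# follow both residual streams: the identity outer paths route gradient from
# each decoder add point back to the matching encoder first-ReLU tap, and
# the projection paths route gradient from each add point back to the block
# input.

.forward_cache <- function(model, image) {
  plan <- model$plan
  P <- model$params
  taps <- recs <- vector("list", 4L)
  caches <- list()
  cur <- image
  for (b in plan$blocks) {
    if (b$role == "encoder") {
      a1 <- .conv_bn(P, b$layers[[1]], cur, want_cache = TRUE)
      a2 <- .conv_bn(P, b$layers[[2]], a1$y, want_cache = TRUE)
      if (b$has_irsp) {
        fp <- .conv_bn(P, b$irsp, cur, want_cache = TRUE)
        y <- relu(a2$y + fp$y)
      } else {
        fp <- NULL
        y <- a2$y
      }
      pl <- cpp_maxpool(y)
      taps[[b$index]] <- a1$y
      recs[[b$index]] <- list(indices = pl$idx, pre_pool_shape = dim(y))
      caches[[b$block_id]] <- list(a1 = a1$cache, a2 = a2$cache,
                                   fp = fp$cache, pre_pool = y,
                                   idx = pl$idx)
      cur <- pl$y
    } else {
      rec <- recs[[b$index]]
      u <- cpp_unpool(cur, rec$indices,
                      rec$pre_pool_shape[1], rec$pre_pool_shape[2])
      a1 <- .conv_bn(P, b$layers[[1]], u, want_cache = TRUE)
      tp <- a1$y + taps[[b$index]]
      a2 <- .conv_bn(P, b$layers[[2]], tp, want_cache = TRUE)
      if (b$has_irsp) {
        fp <- .conv_bn(P, b$irsp, u, want_cache = TRUE)
        out <- relu(a2$y + fp$y)
      } else {
        fp <- NULL
        out <- a2$y
      }
      caches[[b$block_id]] <- list(a1 = a1$cache, a2 = a2$cache,
                                   fp = fp$cache, rec = rec,
                                   pre_relu = if (b$has_irsp) a2$y + fp$y,
                                   in_shape = dim(cur))
      cur <- out
    }
  }
  list(logits = cur, prob = softmax_channels(cur), caches = caches)
}

# gy: gradient of the loss wrt the network output (post final ReLU).
# Returns list(grads) named like model$params.
.backward <- function(model, fwd, gy) {
  plan <- model$plan
  P <- model$params
  caches <- fwd$caches
  grads <- list()
  add_g <- function(name, g) {
    if (is.null(grads[[name]])) grads[[name]] <<- g
    else grads[[name]] <<- Map(`+`, grads[[name]], g)
  }
  tap_grads <- vector("list", 4L)
  # decoder blocks in reverse execution order: DCB-1 .. DCB-4
  for (b in rev(plan$blocks)) {
    cc <- caches[[b$block_id]]
    if (b$role == "decoder") {
      if (b$has_irsp) {
        gz <- gy * (cc$pre_relu > 0)
        fb <- .conv_bn_backward(P, b$irsp, cc$fp, gz)
        add_g(b$irsp$name, fb$grads)
        g_u_proj <- fb$gx
      } else {
        gz <- gy  # terminal layer's own ReLU handled inside conv_bn_backward
        g_u_proj <- 0
      }
      b2 <- .conv_bn_backward(P, b$layers[[2]], cc$a2, gz)
      add_g(b$layers[[2]]$name, b2$grads)
      g_tp <- b2$gx
      tap_grads[[b$index]] <- g_tp  # identity outer path
      b1 <- .conv_bn_backward(P, b$layers[[1]], cc$a1, g_tp)
      add_g(b$layers[[1]]$name, b1$grads)
      g_u <- b1$gx + g_u_proj
      gy <- cpp_pool_gather(g_u, cc$rec$indices)
    } else {
      g_pre <- cpp_unpool(gy, cc$idx, dim(cc$pre_pool)[1],
                          dim(cc$pre_pool)[2])
      if (b$has_irsp) {
        gyb <- g_pre * (cc$pre_pool > 0)
        fb <- .conv_bn_backward(P, b$irsp, cc$fp, gyb)
        add_g(b$irsp$name, fb$grads)
        g_x_proj <- fb$gx
      } else {
        gyb <- g_pre  # ECon-1_2's ReLU handled inside conv_bn_backward
        g_x_proj <- 0
      }
      b2 <- .conv_bn_backward(P, b$layers[[2]], cc$a2, gyb)
      add_g(b$layers[[2]]$name, b2$grads)
      g_tap <- b2$gx + tap_grads[[b$index]]
      b1 <- .conv_bn_backward(P, b$layers[[1]], cc$a1, g_tap)
      add_g(b$layers[[1]]$name, b1$grads)
      gy <- b1$gx + g_x_proj
    }
  }
  grads
}
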