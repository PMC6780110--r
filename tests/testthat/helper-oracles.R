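# Independent reference implementations used as oracles: plain R loops,
# no shared code with the package's compiled kernels.

# direct per-pixel convolution; weight rows ordered channel-major, then
# kernel row, then kernel col, as documented for vn_init()
naive_conv <- function(x, W, b, kh, kw) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  cout <- ncol(W)
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  out <- array(0, c(h, w, cout))
  for (o in seq_len(cout)) {
    for (i in seq_len(h)) for (j in seq_len(w)) {
      acc <- b[o]
      for (c in seq_len(cin)) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
        si <- i + ki - 1 - ph; sj <- j + kj - 1 - pw
        if (si >= 1 && si <= h && sj >= 1 && sj <= w) {
          q <- (c - 1) * kh * kw + (ki - 1) * kw + kj
          acc <- acc + x[si, sj, c] * W[q, o]
        }
      }
      out[i, j, o] <- acc
    }
  }
  out
}

naive_bn <- function(x, gamma, beta, eps = 1e-5) {
  out <- x
  for (c in seq_len(dim(x)[3])) {
    v <- x[, , c]
    m <- mean(v)
    s <- mean((v - m)^2)
    out[, , c] <- gamma[c] * (v - m) / sqrt(s + eps) + beta[c]
  }
  out
}

naive_relu <- function(x) pmax(x, 0)

# 2x2/2 max pooling with 0-based column-major argmax indices per slice
naive_pool <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; nc <- dim(x)[3]
  ho <- h %/% 2; wo <- w %/% 2
  y <- idx <- array(0, c(ho, wo, nc))
  for (c in seq_len(nc)) for (jo in seq_len(wo)) for (io in seq_len(ho)) {
    win_i <- (2 * io - 1):(2 * io); win_j <- (2 * jo - 1):(2 * jo)
    vals <- x[win_i, win_j, c]
    k <- which.max(vals)  # column-major first max, matching the kernels
    bi <- win_i[(k - 1) %% 2 + 1]; bj <- win_j[(k - 1) %/% 2 + 1]
    y[io, jo, c] <- vals[k]
    idx[io, jo, c] <- (bj - 1) * h + (bi - 1)
  }
  list(y = y, idx = idx)
}

naive_unpool <- function(v, idx, h, w) {
  nc <- dim(v)[3]
  out <- array(0, c(h, w, nc))
  for (c in seq_len(nc)) for (jo in seq_len(ncol(idx[, , c, drop = FALSE])))
    for (io in seq_len(nrow(idx[, , c, drop = FALSE]))) {
      lin <- idx[io, jo, c]
      out[lin %% h + 1, lin %/% h + 1, c] <- v[io, jo, c]
    }
  out
}

# full forward pass composed only from the naive primitives above
naive_forward <- function(model, image) {
  plan <- model$plan
  P <- model$params
  layer <- function(spec, x, relu) {
    p <- P[[spec$name]]
    a <- naive_conv(x, p$W, p$b, spec$kernel[1], spec$kernel[2])
    z <- naive_bn(a, p$gamma, p$beta)
    if (relu) naive_relu(z) else z
  }
  taps <- recs <- vector("list", 4L)
  cur <- image
  for (b in plan$blocks) {
    if (b$role == "encoder") {
      tap <- layer(b$layers[[1]], cur, relu = TRUE)
      s <- layer(b$layers[[2]], tap, relu = b$layers[[2]]$relu_after)
      y <- if (b$has_irsp)
        naive_relu(s + layer(b$irsp, cur, relu = FALSE)) else s
      pl <- naive_pool(y)
      taps[[b$index]] <- tap
      recs[[b$index]] <- list(idx = pl$idx, h = dim(y)[1], w = dim(y)[2])
      cur <- pl$y
    } else {
      r <- recs[[b$index]]
      u <- naive_unpool(cur, r$idx, r$h, r$w)
      k <- layer(b$layers[[1]], u, relu = TRUE)
      tp <- k + taps[[b$index]]
      s <- layer(b$layers[[2]], tp, relu = b$layers[[2]]$relu_after)
      cur <- if (b$has_irsp)
        naive_relu(s + layer(b$irsp, u, relu = FALSE)) else s
    }
  }
  # softmax from first principles
  out <- array(0, dim(cur))
  for (i in seq_len(dim(cur)[1])) for (j in seq_len(dim(cur)[2])) {
    z <- cur[i, j, ]
    e <- exp(z - max(z))
    out[i, j, ] <- e / sum(e)
  }
  out
}

# Mann-Whitney pairwise concordance: AUC by exhaustive pair enumeration
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

rand_cube <- function(h, w, c, seed = 1) {
  withr::with_seed(seed, array(stats::rnorm(h * w * c), c(h, w, c)))
}

# small pair with deterministic content for augmentation tests
toy_pair <- function(h = 42, w = 42, seed = 1) {
  withr::with_seed(seed, {
    img <- array(stats::runif(h * w * 3), c(h, w, 3))
    mask <- matrix(rbinom(h * w, 1, 0.15), h, w)
  })
  sample_pair(img, mask)
}

rel_err <- function(a, b) max(abs(a - b)) / max(1e-12, max(abs(b)))
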