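#' Per-class pixel frequencies over a set of masks
#'
#' For each class c, `freq_c = (pixels of class c) / (total pixels of the
#' images that contain c)`, the convention used by median-frequency class
#' balancing: the denominator counts only images in which the class occurs.
#'
#' @param masks a list of binary matrices (or a single matrix), values in
#'   `{0, 1}` with 1 = vessel.
#' @return Named numeric vector `c(background = ..., vessel = ...)`.
#' @export
class_frequencies <- function(masks) {
  if (is.matrix(masks)) masks <- list(masks)
  if (length(masks) == 0L) stop("no masks supplied")
  counts <- c(background = 0, vessel = 0)
  denom <- c(background = 0, vessel = 0)
  for (m in masks) {
    .check_binary(m)
    nv <- sum(m)
    np <- length(m)
    counts <- counts + c(np - nv, nv)
    denom <- denom + c(if (nv < np) np else 0, if (nv > 0) np else 0)
  }
  if (any(denom == 0))
    stop("class absent from every mask: ",
         paste(names(denom)[denom == 0], collapse = ", "))
  counts / denom
}

#' Median-frequency class-balancing weights
#'
#' `w_c = median(freqs) / freq_c`, so rarer classes (vessel pixels, roughly
#' one in ten) receive proportionally larger loss weight.
#'
#' @param freqs per-class frequencies, all positive (see
#'   [class_frequencies()]).
#' @return Named numeric vector of positive weights.
#' @export
median_frequency_weights <- function(freqs) {
  if (any(freqs <= 0)) stop("all class frequencies must be positive")
  stats::median(freqs) / freqs
}

#' Class-weighted cross-entropy loss
#'
#' Mean over pixels of `-w_c(p) * log p_c(p)` where `c(p)` is the true class
#' of pixel p. Probabilities are clipped away from zero so the loss stays
#' finite. With unit weights this is the ordinary cross-entropy.
#'
#' @param prob `H x W x 2` probability array (channels summing to 1).
#' @param mask binary matrix of the same spatial dims (1 = vessel,
#'   channel 2).
#' @param weights length-2 positive weights `(background, vessel)`.
#' @param clip lower probability clip.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(prob, mask, weights = c(1, 1),
                                   clip = 1e-12) {
  if (!identical(dim(prob)[1:2], dim(mask)))
    stop("probability map and mask dims differ")
  .check_binary(mask)
  p_true <- ifelse(mask == 1, prob[, , 2], prob[, , 1])
  w <- ifelse(mask == 1, weights[2], weights[1])
  mean(-w * log(pmax(p_true, clip)))
}

#' Training configuration
#'
#' Defaults follow the published recipe: adaptive-moment (Adam)
#' optimisation at a constant learning rate of 5e-4, mini-batches of seven
#' images with partial final batches dropped, 15 epochs, per-epoch
#' shuffling, gradient clipping by global L2 norm, and a denominator
#' epsilon of 1e-6.
#'
#' @param learning_rate constant learning rate.
#' @param batch_size images per mini-batch (partial final batch dropped).
#' @param epochs number of passes over the training set.
#' @param beta1,beta2 Adam moment decay rates.
#' @param moment_epsilon Adam denominator epsilon.
#' @param grad_clip global L2-norm clipping threshold for the averaged
#'   mini-batch gradient.
#' @param shuffle_each_epoch reshuffle image order every epoch.
#' @param seed integer seed for shuffling.
#' @return A `vn_train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 7L,
                         epochs = 15L, beta1 = 0.9, beta2 = 0.999,
                         moment_epsilon = 1e-6, grad_clip = 1.0,
                         shuffle_each_epoch = TRUE, seed = 1L) {
  stopifnot(learning_rate >= 0, batch_size >= 1, epochs >= 1,
            moment_epsilon > 0, grad_clip > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 moment_epsilon = moment_epsilon, grad_clip = grad_clip,
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 seed = as.integer(seed)),
            class = "vn_train_config")
}

.grad_global_norm <- function(grads) {
  sq <- 0
  for (g in grads) for (v in g) sq <- sq + sum(v * v)
  sqrt(sq)
}

#' Train a model
#'
#' Mini-batch gradient descent with Adam: for each batch the per-image
#' gradients of the class-weighted cross-entropy are averaged, clipped by
#' global L2 norm, and applied. Class weights are computed once from the
#' training masks by median-frequency balancing. Images are consumed raw
#' apart from 0-1 intensity scaling done at load time; partial final
#' batches are dropped.
#'
#' @param model a `vn_model` (see [vn_init()]).
#' @param pairs list of sample pairs (see [sample_pair()]) whose dims match
#'   the model plan.
#' @param config a [train_config()].
#' @param class_weights optional fixed weights, bypassing median-frequency
#'   balancing.
#' @param verbose print one line per epoch.
#' @return List with the trained `model` and `history`, a data frame of
#'   per-epoch mean batch loss and pixel accuracy.
#' @export
train_vessnet <- function(model, pairs, config = train_config(),
                          class_weights = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "vn_model"), inherits(config, "vn_train_config"))
  if (length(pairs) == 0L) stop("empty training set")
  masks <- lapply(pairs, `[[`, "mask")
  if (is.null(class_weights))
    class_weights <- median_frequency_weights(class_frequencies(masks))
  P <- model$params
  mstate <- vstate <- lapply(P, function(p)
    list(W = p$W * 0, b = p$b * 0, gamma = p$gamma * 0, beta = p$beta * 0))
  step <- 0L
  n_batch <- length(pairs) %/% config$batch_size
  if (n_batch == 0L)
    stop("fewer images (", length(pairs), ") than one batch of ",
         config$batch_size)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- if (config$shuffle_each_epoch)
        sample.int(length(pairs)) else seq_along(pairs)
      ep_loss <- ep_acc <- 0
      for (bi in seq_len(n_batch)) {
        idx <- ord[((bi - 1L) * config$batch_size + 1L):
                     (bi * config$batch_size)]
        bgrads <- NULL
        bloss <- bacc <- 0
        for (i in idx) {
          img <- pairs[[i]]$image
          mask <- pairs[[i]]$mask
          fwd <- .forward_cache(list(plan = model$plan, params = P), img)
          bloss <- bloss +
            weighted_cross_entropy(fwd$prob, mask, class_weights)
          bacc <- bacc + mean(prob_to_mask(fwd$prob) == mask)
          gy <- .ce_output_gradient(fwd$prob, mask, class_weights)
          g <- .backward(list(plan = model$plan, params = P), fwd, gy)
          bgrads <- if (is.null(bgrads)) g else
            Map(function(a, b) Map(`+`, a, b), bgrads, g)
        }
        if (!is.finite(bloss))
          stop("non-finite loss at epoch ", epoch, ", batch ", bi,
               "; try a smaller learning rate")
        bgrads <- lapply(bgrads, function(g)
          lapply(g, function(v) v / length(idx)))
        gn <- .grad_global_norm(bgrads)
        if (gn > config$grad_clip) {
          sc <- config$grad_clip / gn
          bgrads <- lapply(bgrads, function(g) lapply(g, function(v) v * sc))
        }
        step <- step + 1L
        bc1 <- 1 - config$beta1^step
        bc2 <- 1 - config$beta2^step
        for (nm in names(P)) {
          for (fld in c("W", "b", "gamma", "beta")) {
            g <- bgrads[[nm]][[fld]]
            mstate[[nm]][[fld]] <- config$beta1 * mstate[[nm]][[fld]] +
              (1 - config$beta1) * g
            vstate[[nm]][[fld]] <- config$beta2 * vstate[[nm]][[fld]] +
              (1 - config$beta2) * g * g
            P[[nm]][[fld]] <- P[[nm]][[fld]] -
              config$learning_rate * (mstate[[nm]][[fld]] / bc1) /
                (sqrt(vstate[[nm]][[fld]] / bc2) + config$moment_epsilon)
          }
        }
        ep_loss <- ep_loss + bloss / length(idx)
        ep_acc <- ep_acc + bacc / length(idx)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = ep_loss / n_batch, accuracy = ep_acc / n_batch))
      if (verbose)
        message(sprintf("epoch %2d  loss %.4f  acc %.4f", epoch,
                        ep_loss / n_batch, ep_acc / n_batch))
    }
  })
  model$params <- P
  model$class_weights <- class_weights
  list(model = model, history = history)
}

# Gradient of the mean weighted cross-entropy wrt the network output
# (the activations entering the softmax).
.ce_output_gradient <- function(prob, mask, weights) {
  h <- dim(prob)[1]; w <- dim(prob)[2]
  onehot <- array(0, dim = dim(prob))
  onehot[, , 1] <- 1 - mask
  onehot[, , 2] <- mask
  wp <- ifelse(mask == 1, weights[2], weights[1])
  g <- prob - onehot
  g[, , 1] <- g[, , 1] * wp
  g[, , 2] <- g[, , 2] * wp
  g / (h * w)
}

.check_binary <- function(m) {
  if (!all(m %in% c(0, 1)))
    stop("mask must be binary with values in {0, 1}")
  invisible(TRUE)
}
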