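#' Paired image and ground-truth mask
#'
#' The unit every stage of the pipeline operates on: an RGB image and its
#' binary vessel mask, transformed identically by every augmentation, plus
#' a provenance string recording the transformation lineage.
#'
#' @param image numeric array `H x W x 3` in `[0, 1]`.
#' @param mask matrix `H x W` with values in `{0, 1}` (1 = vessel).
#' @param provenance lineage string.
#' @return A `vn_pair` list.
#' @export
sample_pair <- function(image, mask, provenance = "orig") {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (!is.matrix(mask) || !identical(dim(image)[1:2], dim(mask)))
    stop("mask must be a matrix with the image's spatial dims")
  .check_binary(mask)
  structure(list(image = image, mask = mask,
                 provenance = as.character(provenance)), class = "vn_pair")
}

#' One translate/flip/resize recipe
#'
#' Positive `dx` shifts content rightward (toward higher column index) and
#' positive `dy` downward (toward higher row index); the flip, if any, is
#' applied before the translation.
#'
#' @param dx,dy signed translation in pixels.
#' @param flip one of `"none"`, `"horizontal"`, `"vertical"`.
#' @param resized crop-resize back to the original dims (the published
#'   recipes always do).
#' @return A `vn_aug_combo` list.
#' @export
aug_combo <- function(dx = 0L, dy = 0L,
                      flip = c("none", "horizontal", "vertical"),
                      resized = TRUE) {
  flip <- match.arg(flip)
  structure(list(dx = as.integer(dx), dy = as.integer(dy), flip = flip,
                 resized = isTRUE(resized)), class = "vn_aug_combo")
}

.flip_matrix <- function(m, flip)
  switch(flip, none = m,
         horizontal = m[, rev(seq_len(ncol(m))), drop = FALSE],
         vertical = m[rev(seq_len(nrow(m))), , drop = FALSE])

.flip_array <- function(a, flip) {
  for (c in seq_len(dim(a)[3])) a[, , c] <- .flip_matrix(a[, , c], flip)
  a
}

# Nearest-neighbour resize by index mapping (pixel-centre convention);
# exactly the identity when sizes match, and closed over binary values.
nn_resize <- function(m, out_h, out_w) {
  ri <- pmin(nrow(m), floor((seq_len(out_h) - 0.5) * nrow(m) / out_h) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(out_w) - 0.5) * ncol(m) / out_w) + 1L)
  m[ri, ci, drop = FALSE]
}

.nn_resize_array <- function(a, out_h, out_w) {
  out <- array(0, dim = c(out_h, out_w, dim(a)[3]))
  for (c in seq_len(dim(a)[3])) out[, , c] <- nn_resize(a[, , c], out_h, out_w)
  out
}

#' Apply one translate/flip/crop-resize recipe to a pair
#'
#' Flips (if requested), shifts the content by `(dx, dy)`, crops the
#' maximal region that stayed in bounds, and resizes back to the original
#' dims with nearest-neighbour interpolation -- for the image and the mask
#' identically, so the mask stays binary.
#'
#' @param pair a [sample_pair()].
#' @param combo an [aug_combo()]; `|dx|` and `|dy|` must be below half the
#'   image dims.
#' @return The transformed `vn_pair` with extended provenance.
#' @export
translate_crop_resize <- function(pair, combo) {
  stopifnot(inherits(pair, "vn_pair"), inherits(combo, "vn_aug_combo"))
  h <- nrow(pair$mask); w <- ncol(pair$mask)
  if (abs(combo$dx) >= min(h, w) / 2 || abs(combo$dy) >= min(h, w) / 2)
    stop("translation exceeds half the image dims")
  img <- .flip_array(pair$image, combo$flip)
  msk <- .flip_matrix(pair$mask, combo$flip)
  rows <- if (combo$dy >= 0) seq_len(h - combo$dy) else seq.int(1 - combo$dy, h)
  cols <- if (combo$dx >= 0) seq_len(w - combo$dx) else seq.int(1 - combo$dx, w)
  img <- img[rows, cols, , drop = FALSE]
  msk <- msk[rows, cols, drop = FALSE]
  if (combo$resized) {
    img <- .nn_resize_array(img, h, w)
    msk <- nn_resize(msk, h, w)
  }
  tag <- sprintf("t(%d,%d,%s)", combo$dx, combo$dy, combo$flip)
  sample_pair(img, msk, paste(pair$provenance, tag, sep = "|"))
}

#' Stage 1: expand by horizontal and vertical flips
#'
#' Returns the originals followed by their horizontal flips and vertical
#' flips: 20 pairs become 60.
#'
#' @param pairs list of [sample_pair()]s.
#' @return List of `3 * length(pairs)` pairs.
#' @export
stage1_flips <- function(pairs) {
  flip_all <- function(flip, tag) lapply(pairs, function(p)
    sample_pair(.flip_array(p$image, flip), .flip_matrix(p$mask, flip),
                paste(p$provenance, tag, sep = "|")))
  c(pairs, flip_all("horizontal", "hflip"), flip_all("vertical", "vflip"))
}

#' Stage 2: recursive translate/flip/resize expansion
#'
#' Each recipe is applied to the entire accumulated set and the results
#' appended, doubling the set per recipe: 60 pairs and 3 recipes give
#' `60 * 2^3 = 480`.
#'
#' @param pairs list of pairs.
#' @param combos exactly three [aug_combo()]s (default: the published
#'   triples `(10,-10,none)`, `(15,15,vertical)`, `(20,-20,horizontal)`).
#' @return The expanded list.
#' @export
stage2_recursive <- function(pairs, combos = default_stage2_combos()) {
  if (length(combos) != 3L) stop("exactly 3 recipes required")
  acc <- pairs
  for (cb in combos)
    acc <- c(acc, lapply(acc, translate_crop_resize, combo = cb))
  acc
}

#' Stage 3: non-recursive translate/flip/resize expansion
#'
#' Each recipe is applied independently to the input set; only the new
#' pairs are returned: 480 pairs and 3 recipes give 1440.
#'
#' @param pairs list of pairs.
#' @param combos exactly three [aug_combo()]s (default: the published
#'   triples `(-10,10,none)`, `(-15,15,vertical)`, `(-20,20,horizontal)`).
#' @return List of `3 * length(pairs)` new pairs.
#' @export
stage3_nonrecursive <- function(pairs, combos = default_stage3_combos()) {
  if (length(combos) != 3L) stop("exactly 3 recipes required")
  unlist(lapply(combos, function(cb)
    lapply(pairs, translate_crop_resize, combo = cb)), recursive = FALSE)
}

#' @rdname stage2_recursive
#' @export
default_stage2_combos <- function() list(
  aug_combo(10L, -10L, "none"), aug_combo(15L, 15L, "vertical"),
  aug_combo(20L, -20L, "horizontal"))

#' @rdname stage3_nonrecursive
#' @export
default_stage3_combos <- function() list(
  aug_combo(-10L, 10L, "none"), aug_combo(-15L, 15L, "vertical"),
  aug_combo(-20L, 20L, "horizontal"))

#' Full three-stage dataset expansion
#'
#' Flip expansion (x3), recursive crop-resize expansion (x8) and one
#' non-recursive pass (x3 of the stage-2 output); the training set is the
#' union of stages 2 and 3, so 20 seed pairs become
#' `20*3*8 + 3*480 = 480 + 1440 = 1920`. Deterministic and seed-free.
#'
#' @param pairs list of seed [sample_pair()]s.
#' @param stage2,stage3 recipe lists (published defaults).
#' @return The expanded training list.
#' @export
augment_dataset <- function(pairs, stage2 = default_stage2_combos(),
                            stage3 = default_stage3_combos()) {
  if (length(pairs) == 0L) return(list())
  if (!all(vapply(pairs, inherits, logical(1), "vn_pair")))
    stop("inputs must be image/mask pairs")
  s2 <- stage2_recursive(stage1_flips(pairs), stage2)
  c(s2, stage3_nonrecursive(s2, stage3))
}
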