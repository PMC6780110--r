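#' Read an image file
#'
#' PNG and TIFF via the \pkg{png} and \pkg{tiff} packages, plain PNM
#' (PGM/PPM, ASCII or binary) via a built-in reader. Values are scaled to
#' `[0, 1]`; grayscale images are expanded to three identical channels and
#' any alpha channel is dropped. Pixels are `(row, col)` from the top-left.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, `.pgm`/`.ppm`/`.pnm`).
#' @return Numeric array `H x W x 3`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              pgm = , ppm = , pnm = read_pnm(path),
              stop("unsupported image format: .", ext,
                   " (png, tiff, pnm supported)"))
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), dim = c(dim(a)[1:2], 3L))
  a
}

#' @rdname read_image
#' @param image `H x W x 3` array in `[0, 1]` (PNG or TIFF only).
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(image, path),
         tif = , tiff = tiff::writeTIFF(image, path),
         stop("unsupported output format: .", ext))
  invisible(path)
}

#' Read or write a binary mask
#'
#' Masks are stored on disk as 8-bit images in `{0, 255}` and held in
#' memory in `{0, 1}`; reading binarizes at 0.5.
#'
#' @param path file path.
#' @return `read_mask`: integer matrix in `{0, 1}`.
#' @export
read_mask <- function(path) {
  a <- read_image(path)
  m <- (a[, , 1] >= 0.5) * 1L
  matrix(as.integer(m), nrow = dim(a)[1])
}

#' @rdname read_mask
#' @param mask binary matrix.
#' @export
write_mask <- function(mask, path) {
  .check_binary(mask)
  write_image(array(rep(as.numeric(mask), 3L), dim = c(dim(mask), 3L)), path)
}

# Minimal PNM (P2/P3/P5/P6) reader: no installed R package reads the
# format, which some classic retinal datasets use.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok_buf <- character(0)
  next_token <- function() {
    while (length(tok_buf) == 0L) {
      line <- readLines(con, n = 1L, warn = FALSE)
      if (length(line) == 0L) stop("truncated PNM header: ", path)
      line <- sub("#.*", "", line)
      tok_buf <<- strsplit(trimws(line), "\\s+")[[1]]
      tok_buf <<- tok_buf[nzchar(tok_buf)]
    }
    t <- tok_buf[1]; tok_buf <<- tok_buf[-1]; t
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic ", magic)
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxval > 255) stop("16-bit PNM not supported")
    as.integer(readBin(con, "raw", n = n))
  } else {
    v <- integer(0)
    while (length(v) < n) v <- c(v, as.integer(next_token()))
    v
  }
  if (length(vals) < n) stop("truncated PNM data: ", path)
  # file order is row-major, channels interleaved
  a <- array(vals[seq_len(n)] / maxval, dim = c(nch, w, h))
  aperm(a, c(3, 2, 1))
}

#' Load one image/mask pair, optionally resized to the network input
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbour and re-binarized at 0.5; the native-resolution mask is
#' kept as attribute `"native_mask"` for evaluation at original size.
#'
#' @param image_path,mask_path readable image files.
#' @param target_size optional `c(height, width)`, e.g. `c(447, 447)`.
#' @return A [sample_pair()].
#' @export
load_pair <- function(image_path, mask_path, target_size = NULL) {
  img <- read_image(image_path)
  msk <- read_mask(mask_path)
  if (!identical(dim(img)[1:2], dim(msk)))
    stop("image and mask dims differ: ", image_path)
  native <- NULL
  if (!is.null(target_size) && !identical(dim(msk),
                                          as.integer(target_size))) {
    native <- msk
    img <- .bilinear_resize(img, target_size[1], target_size[2])
    msk <- nn_resize(msk, target_size[1], target_size[2])
    msk <- matrix(as.integer(msk >= 0.5), nrow = target_size[1])
  }
  p <- sample_pair(img, msk,
                   provenance = basename(tools::file_path_sans_ext(image_path)))
  attr(p, "native_mask") <- native
  p
}

.bilinear_resize <- function(a, out_h, out_w) {
  r <- EBImage::resize(a, w = out_h, h = out_w, filter = "bilinear")
  array(pmin(pmax(as.numeric(r), 0), 1), dim = c(out_h, out_w, dim(a)[3]))
}

#' Scan a paired image/mask directory tree into a manifest
#'
#' Expects `root/images` and `root/masks` (or `root/1st_manual`, the
#' first-observer convention, preferred when both exist) with files matched
#' by name stem. The manifest is sorted lexicographically so it is stable
#' across filesystems.
#'
#' @param root dataset directory.
#' @return Data frame with columns `image`, `mask`, `split` (class
#'   `vn_manifest`).
#' @export
scan_dataset <- function(root) {
  img_dir <- file.path(root, "images")
  mask_dir <- Filter(dir.exists,
                     file.path(root, c("1st_manual", "masks")))[1]
  if (!dir.exists(img_dir) || is.na(mask_dir))
    stop("expected ", root, "/images plus masks/ or 1st_manual/")
  stems <- function(d) {
    f <- sort(list.files(d))
    stats::setNames(f, tools::file_path_sans_ext(f))
  }
  im <- stems(img_dir); mk <- stems(mask_dir)
  if (length(im) == 0L) {
    warning("empty dataset at ", root)
    return(structure(data.frame(image = character(), mask = character(),
                                split = character()),
                     class = c("vn_manifest", "data.frame")))
  }
  orphans <- c(setdiff(names(im), names(mk)), setdiff(names(mk), names(im)))
  if (length(orphans) > 0L)
    stop("orphan image or mask entries: ", paste(orphans, collapse = ", "))
  m <- data.frame(image = file.path(img_dir, im[sort(names(im))]),
                  mask = file.path(mask_dir, mk[sort(names(im))]),
                  split = NA_character_, stringsAsFactors = FALSE)
  structure(m, class = c("vn_manifest", "data.frame"))
}

#' Write a dataset of pairs to disk
#'
#' PNG pairs under `out/images` and `out/masks` plus a `manifest.tsv` with
#' provenance lineage.
#'
#' @param pairs list of [sample_pair()]s.
#' @param out output directory (created).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(pairs, out) {
  dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    nm <- sprintf("%04d.png", i)
    write_image(pairs[[i]]$image, file.path(out, "images", nm))
    write_mask(pairs[[i]]$mask, file.path(out, "masks", nm))
    data.frame(image = file.path("images", nm),
               mask = file.path("masks", nm),
               provenance = pairs[[i]]$provenance)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Load every pair listed in a manifest
#'
#' @param manifest a [scan_dataset()] manifest.
#' @param target_size optional `c(height, width)` passed to [load_pair()].
#' @return List of [sample_pair()]s.
#' @export
load_manifest <- function(manifest, target_size = NULL)
  Map(load_pair, manifest$image, manifest$mask,
      MoreArgs = list(target_size = target_size), USE.NAMES = FALSE)
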