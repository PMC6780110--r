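#' Count vessel pixels in a segmentation mask
#'
#' The raw biomarker behind visit-to-visit retinopathy screening: the
#' number of pixels labelled vessel (1) out of all pixels.
#'
#' @param mask binary matrix.
#' @return Named integer vector `c(vessel_pixels, total_pixels)`.
#' @export
vessel_pixel_count <- function(mask) {
  .check_binary(mask)
  c(vessel_pixels = as.integer(sum(mask)), total_pixels = length(mask))
}

#' Record of one screening visit
#'
#' @param visit_id identifier.
#' @param vessel_pixels,total_pixels pixel counts with
#'   `0 <= vessel_pixels <= total_pixels`.
#' @param date optional ISO date string.
#' @return A `vn_visit` list.
#' @export
visit_record <- function(visit_id, vessel_pixels, total_pixels,
                         date = NULL) {
  if (vessel_pixels < 0 || vessel_pixels > total_pixels)
    stop("vessel_pixels must lie in [0, total_pixels]")
  structure(list(visit_id = as.character(visit_id),
                 vessel_pixels = as.integer(vessel_pixels),
                 total_pixels = as.integer(total_pixels), date = date),
            class = "vn_visit")
}

#' Compare two registered visits by vessel-pixel count
#'
#' Vessel-pixel growth between registered images of consecutive visits
#' indicates swelling or creation of new vessels (diabetic retinopathy
#' suspect); shrinkage indicates narrowing (hypertensive retinopathy
#' suspect). The relative change `(curr - prev) / prev` is compared against
#' a symmetric threshold. The default 5% threshold is a configurable
#' placeholder, not a clinically validated cut-off.
#'
#' @param prev,curr [visit_record()]s with equal `total_pixels` (the images
#'   are assumed registered upstream).
#' @param threshold non-negative relative-change threshold.
#' @return A `vn_verdict` list with `status` (one of `"stable"`,
#'   `"diabetic-suspect"`, `"hypertensive-suspect"`) and `relative_change`.
#' @export
compare_visits <- function(prev, curr, threshold = 0.05) {
  stopifnot(inherits(prev, "vn_visit"), inherits(curr, "vn_visit"))
  if (threshold < 0) stop("threshold must be non-negative")
  if (prev$total_pixels != curr$total_pixels)
    stop("visits have mismatched image dims; register images first")
  if (prev$vessel_pixels == 0)
    stop("previous visit has zero vessel pixels; relative change undefined")
  change <- (curr$vessel_pixels - prev$vessel_pixels) / prev$vessel_pixels
  status <- if (change > threshold) "diabetic-suspect"
    else if (change < -threshold) "hypertensive-suspect"
    else "stable"
  structure(list(status = status, relative_change = change,
                 threshold = threshold, prev = prev$visit_id,
                 curr = curr$visit_id), class = "vn_verdict")
}

#' @export
print.vn_verdict <- function(x, ...) {
  cat(sprintf("%s -> %s: %+.1f%% vessel pixels (threshold %.1f%%) => %s\n",
              x$prev, x$curr, 100 * x$relative_change, 100 * x$threshold,
              x$status))
  invisible(x)
}
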