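#' Segmentation configuration
#'
#' @param method foreground thresholding method: `"otsu_log"` (default;
#'   Otsu computed on log1p-transformed intensities, robust for sparse
#'   images whose cells span a wide brightness range -- linear Otsu can
#'   place the threshold between dim and bright cells instead of between
#'   background and foreground), `"otsu"` (linear scale), or `"fixed"`
#'   (requires `threshold` on the raw gray scale).
#' @param threshold fixed gray-value threshold when `method = "fixed"`.
#' @param min_area_um2 objects smaller than this are discarded (µm²).
#' @param watershed split touching nuclei by distance-transform watershed.
#' @param watershed_tolerance minimum object-height separation (in distance
#'   map units, pixels) for the watershed split; larger values merge more.
#' @param fill_holes fill holes in the thresholded foreground.
#' @param pixel_size micrometres per pixel (> 0), used to convert areas.
#' @param exclude_border drop cells whose footprint touches the image
#'   border (their areas would be truncated).
#' @param background_subtract constant gray value subtracted from each
#'   channel before measurement (default 0).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(method = c("otsu_log", "otsu", "fixed"),
                                threshold = NULL, min_area_um2 = 10,
                                watershed = TRUE, watershed_tolerance = 1,
                                fill_holes = TRUE, pixel_size = 0.5,
                                exclude_border = TRUE,
                                background_subtract = 0) {
  method <- match.arg(method)
  stopifnot(pixel_size > 0, min_area_um2 >= 0)
  if (method == "fixed" && is.null(threshold)) {
    stop("method 'fixed' requires a threshold")
  }
  structure(list(method = method, threshold = threshold,
                 min_area_um2 = min_area_um2, watershed = watershed,
                 watershed_tolerance = watershed_tolerance,
                 fill_holes = fill_holes, pixel_size = pixel_size,
                 exclude_border = exclude_border,
                 background_subtract = background_subtract),
            class = "segmentation_config")
}

threshold_image <- function(x, config) {
  if (config$method == "fixed") return(x > config$threshold)
  if (max(x) == min(x)) return(NULL)       # degenerate, caller warns
  if (config$method == "otsu_log") x <- log1p(pmax(x, 0))
  # the threshold is derived from a smoothed copy so read-noise in the
  # background does not distort the histogram, but applied to the
  # original pixels so object boundaries are not blurred
  sm <- as.matrix(EBImage::gblur(EBImage::Image(x / max(x)), sigma = 2))
  th <- EBImage::otsu(EBImage::Image(pmin(pmax(sm, 0), 1)), range = c(0, 1))
  x / max(x) > th
}

#' Segment nuclei from the DAPI channel
#'
#' Thresholds the nuclear stain (Otsu by default), fills holes, optionally
#' splits touching nuclei by watershed on the distance transform, removes
#' objects below the minimum area, and returns a label mask with contiguous
#' labels 1..K (background 0).
#'
#' @param dapi 2D numeric matrix of nonnegative gray values.
#' @param config a [segmentation_config()].
#' @return Integer label matrix.
#' @export
segment_nuclei <- function(dapi, config = segmentation_config()) {
  stopifnot(is.matrix(dapi), all(dapi >= 0))
  bin <- threshold_image(dapi, config)
  if (is.null(bin)) {
    warning("degenerate image (all pixels equal); empty mask returned")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  if (config$fill_holes) {
    bin <- EBImage::fillHull(EBImage::Image(bin)) > 0
  }
  lab <- if (config$watershed) {
    EBImage::watershed(EBImage::distmap(EBImage::Image(bin)),
                       tolerance = config$watershed_tolerance, ext = 1)
  } else {
    EBImage::bwlabel(EBImage::Image(bin))
  }
  lab <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
  filter_small_relabel(lab, config)
}

# drop objects below the area cutoff and relabel 1..K by first occurrence
filter_small_relabel <- function(lab, config) {
  if (max(lab) == 0L) return(lab)
  min_px <- config$min_area_um2 / config$pixel_size^2
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_px & sizes > 0)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Segment cells from the phalloidin channel, seeded by nuclei
#'
#' Thresholds the F-actin (phalloidin) channel to a cell foreground and
#' partitions it among cells by propagation from the nucleus seeds: each
#' cell's label equals its seed nucleus label. Foreground regions without a
#' nucleus seed are discarded.
#'
#' @param phalloidin 2D numeric matrix, same dimensions as `nuclei`.
#' @param nuclei nucleus label mask from [segment_nuclei()].
#' @param config a [segmentation_config()].
#' @return Integer label matrix with labels matching `nuclei`.
#' @export
segment_cells <- function(phalloidin, nuclei,
                          config = segmentation_config()) {
  if (!all(dim(phalloidin) == dim(nuclei))) {
    stop("phalloidin channel and nucleus mask dimensions differ")
  }
  if (max(nuclei) == 0L) {
    warning("no nucleus seeds; empty cell mask returned")
    return(matrix(0L, nrow(phalloidin), ncol(phalloidin)))
  }
  bin <- threshold_image(phalloidin, config)
  if (is.null(bin)) {
    warning("degenerate phalloidin channel; empty cell mask returned")
    return(matrix(0L, nrow(phalloidin), ncol(phalloidin)))
  }
  if (config$fill_holes) {
    bin <- EBImage::fillHull(EBImage::Image(bin)) > 0
  }
  bin <- bin | nuclei > 0L   # seeds always belong to their cell
  lab <- EBImage::propagate(EBImage::Image(phalloidin / max(phalloidin)),
                            seeds = EBImage::Image(nuclei),
                            mask = EBImage::Image(bin))
  matrix(as.integer(lab), nrow(phalloidin), ncol(phalloidin))
}
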