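#' Image rendering configuration
#'
#' Parameters controlling synthetic fluorescence image generation: canvas
#' size in pixels, pixel size (micrometres per pixel), the constant DAPI
#' nuclear stain intensity, noise (Poisson shot noise on the signal plus
#' additive Gaussian read noise), optional Gaussian blur, and the minimum
#' spacing enforced between rendered cells.
#'
#' @param width,height canvas size in pixels (default 1024 x 1024).
#' @param pixel_size micrometres per pixel (default 0.5).
#' @param dapi_intensity gray value of the nuclear stain (default 120).
#' @param gaussian_sd sd of additive Gaussian read noise (default 5; 0 for
#'   noise-free rendering).
#' @param poisson apply Poisson shot noise to the signal (default TRUE).
#' @param blur_sigma Gaussian PSF blur sigma in pixels (default 0 = off).
#' @param min_spacing_um minimum edge-to-edge spacing between cells (µm).
#' @param max_retries placement attempts per cell before giving up.
#' @return A list of class `image_config`.
#' @export
image_config <- function(width = 1024, height = 1024, pixel_size = 0.5,
                         dapi_intensity = 120, gaussian_sd = 5,
                         poisson = TRUE, blur_sigma = 0,
                         min_spacing_um = 2, max_retries = 2000L) {
  stopifnot(width > 0, height > 0, pixel_size > 0, gaussian_sd >= 0,
            blur_sigma >= 0, min_spacing_um >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, dapi_intensity = dapi_intensity,
                 gaussian_sd = gaussian_sd, poisson = poisson,
                 blur_sigma = blur_sigma, min_spacing_um = min_spacing_um,
                 max_retries = as.integer(max_retries)),
            class = "image_config")
}

#' Render a synthetic multi-channel fluorescence image
#'
#' Renders each measured cell as a concentric ellipse pair: the cell
#' footprint (filled with the cell's F-actin intensity in the phalloidin
#' channel and with its marker intensities in the RBP4/SOD3/IFITM3
#' channels) and the nucleus (filled with the DAPI stain intensity).
#' Cells are placed by rejection sampling so that footprints never overlap
#' at the configured minimum spacing. Poisson shot noise and Gaussian read
#' noise are applied per config; channels are unsigned 16-bit.
#'
#' @param cells `cell_measurements` data.frame (see
#'   [sample_cell_measurements()]); if diameter/aspect columns are absent
#'   they are derived from the areas with aspect ratio 1.
#' @param config an [image_config()].
#' @param seed integer seed (placement, orientation, noise).
#' @return An object of class `synthetic_image`: list with `channels`
#'   (named list of matrices: dapi, phalloidin, rbp4, sod3, ifitm3),
#'   `nucleus_mask` and `cell_mask` (integer label matrices, background 0,
#'   cell i labelled i), `pixel_size`, and `cells` -- the ground-truth
#'   table with mask-derived areas in µm².
#' @export
render_image <- function(cells, config = image_config(), seed) {
  stopifnot(inherits(config, "image_config"))
  n <- nrow(cells)
  if (n < 1) stop("no cells to render")
  set.seed(as.integer(seed))
  px <- config$pixel_size

  cell_d <- if ("cell_diameter_um" %in% names(cells)) cells$cell_diameter_um
            else 2 * sqrt(cells$cell_area_um2 / pi)
  nuc_d <- if ("nucleus_diameter_um" %in% names(cells))
             cells$nucleus_diameter_um
           else 2 * sqrt(cells$nucleus_area_um2 / pi)
  ar <- if ("aspect_ratio" %in% names(cells)) cells$aspect_ratio
        else rep(1, n)

  # semi-axes in pixels; ellipse area equals the circle of the same diameter
  a_px <- (cell_d / 2) * sqrt(ar) / px
  b_px <- (cell_d / 2) / sqrt(ar) / px
  theta <- stats::runif(n, 0, pi)

  spacing_px <- config$min_spacing_um / px
  centers <- place_cells(n, a_px, config$width, config$height, spacing_px,
                         config$max_retries)

  cell_mask <- matrix(0L, config$height, config$width)
  nucleus_mask <- matrix(0L, config$height, config$width)
  for (i in seq_len(n)) {
    cell_mask <- draw_ellipse(cell_mask, i, centers[i, 1], centers[i, 2],
                              a_px[i], b_px[i], theta[i])
    scale <- nuc_d[i] / cell_d[i]
    nucleus_mask <- draw_ellipse(nucleus_mask, i, centers[i, 1],
                                 centers[i, 2], a_px[i] * scale,
                                 b_px[i] * scale, theta[i])
  }

  fill <- function(intensity_per_cell, mask) {
    ch <- matrix(0, config$height, config$width)
    on <- mask > 0L
    ch[on] <- intensity_per_cell[mask[on]]
    ch
  }
  channels <- list(
    dapi = fill(rep(config$dapi_intensity, n), nucleus_mask),
    phalloidin = fill(cells$factin, cell_mask),
    rbp4 = fill(cells$rbp4, cell_mask),
    sod3 = fill(cells$sod3, cell_mask),
    ifitm3 = fill(cells$ifitm3, cell_mask)
  )
  channels <- lapply(channels, function(ch) {
    if (config$blur_sigma > 0) {
      ch <- as.matrix(EBImage::gblur(EBImage::Image(ch),
                                     sigma = config$blur_sigma))
    }
    if (config$poisson) {
      ch[] <- stats::rpois(length(ch), lambda = ch)
    }
    if (config$gaussian_sd > 0) {
      ch <- ch + stats::rnorm(length(ch), sd = config$gaussian_sd)
    }
    # clamp to the 16-bit range; gray values stay continuous in memory
    # (integer quantization happens when writing TIFF)
    matrix(pmin(pmax(ch, 0), 65535), nrow(ch), ncol(ch))
  })

  gt <- data.frame(
    cell_id = seq_len(n),
    rbp4 = cells$rbp4, sod3 = cells$sod3, ifitm3 = cells$ifitm3,
    factin = cells$factin,
    cell_area_um2 = as.vector(table(factor(cell_mask[cell_mask > 0],
                                           levels = seq_len(n)))) * px^2,
    nucleus_area_um2 = as.vector(table(factor(
      nucleus_mask[nucleus_mask > 0], levels = seq_len(n)))) * px^2,
    centroid_x = centers[, 1], centroid_y = centers[, 2]
  )
  class(gt) <- c("cell_measurements", "data.frame")

  structure(list(channels = channels, nucleus_mask = nucleus_mask,
                 cell_mask = cell_mask, pixel_size = px, cells = gt),
            class = "synthetic_image")
}

# non-overlapping placement by rejection sampling; cells kept clear of the
# border so truncation never occurs
place_cells <- function(n, a_px, width, height, spacing_px, max_retries) {
  centers <- matrix(NA_real_, n, 2)
  margin <- a_px + spacing_px + 2
  if (any(2 * margin >= width | 2 * margin >= height)) {
    stop("canvas too small for requested cell sizes")
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      x <- stats::runif(1, margin[i], width - margin[i])
      y <- stats::runif(1, margin[i], height - margin[i])
      if (i == 1L) { ok <- TRUE } else {
        prev <- seq_len(i - 1L)
        dd <- sqrt((centers[prev, 1] - x)^2 + (centers[prev, 2] - y)^2)
        ok <- all(dd >= a_px[prev] + a_px[i] + spacing_px)
      }
      if (ok) { centers[i, ] <- c(x, y); placed <- TRUE; break }
    }
    if (!placed) {
      stop("could not place cell ", i, " after ", max_retries,
           " attempts (", i - 1L, " cells placed); ",
           "reduce cell count or enlarge canvas")
    }
  }
  centers
}

# rasterize a filled rotated ellipse into an integer label matrix
draw_ellipse <- function(mask, label, cx, cy, a, b, theta) {
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(max(a, b)) + 1
  xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  xg <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
  yg <- matrix(ys, length(ys), length(xs)) - cy
  u <- (xg * cos(theta) + yg * sin(theta)) / a
  v <- (-xg * sin(theta) + yg * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  sub <- mask[ys, xs]
  sub[inside] <- as.integer(label)
  mask[ys, xs] <- sub
  mask
}

#' Write a synthetic image bundle to disk
#'
#' Channels are written as one multi-page 16-bit TIFF (page order dapi,
#' phalloidin, rbp4, sod3, ifitm3), ground-truth label masks as separate
#' TIFFs, and the ground-truth cell table as CSV.
#'
#' @param img a [render_image()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_image <- function(img, dir) {
  stopifnot(inherits(img, "synthetic_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(lapply(img$channels, function(ch) ch / 65535),
                  file.path(dir, "channels.tiff"), bits.per.sample = 16L)
  tiff::writeTIFF(img$nucleus_mask / 65535,
                  file.path(dir, "nucleus_mask.tiff"), bits.per.sample = 16L)
  tiff::writeTIFF(img$cell_mask / 65535,
                  file.path(dir, "cell_mask.tiff"), bits.per.sample = 16L)
  utils::write.csv(img$cells, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(channel_order = names(img$channels),
                            pixel_size = img$pixel_size),
                       file.path(dir, "image_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a multi-channel TIFF as named channel matrices
#'
#' @param path TIFF file (multi-page).
#' @param channel_names names for the pages, in order.
#' @param scale multiply raw \[0,1\] TIFF values by this factor to recover
#'   gray levels (default 65535 for 16-bit).
#' @return Named list of numeric matrices.
#' @export
read_channels <- function(path, channel_names, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channel_names)) {
    stop("TIFF has ", length(pages), " pages but ", length(channel_names),
         " channel names were given")
  }
  out <- lapply(pages, function(p) round(p * scale))
  names(out) <- channel_names
  out
}
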