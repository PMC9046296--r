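#' Measure per-cell indicators from segmented channels
#'
#' For every segmented cell with a matching nucleus label, computes the
#' mean gray value of each marker channel over the cell footprint, the
#' cell area (pixel count x pixel_size²) and the nucleus area. Cells
#' without a matching nucleus label, cells touching the image border (when
#' `exclude_border` is set) and physically impossible cells (nucleus area
#' exceeding cell area) are excluded; exclusion counts are attached to the
#' result as the `"excluded"` attribute.
#'
#' @param channels named list of 2D matrices; must contain the marker
#'   channels `rbp4`, `sod3`, `ifitm3` and either `factin` or `phalloidin`
#'   (phalloidin stains F-actin).
#' @param cell_mask,nucleus_mask integer label matrices with corresponding
#'   labels (from [segment_cells()] / [segment_nuclei()]).
#' @param config a [segmentation_config()].
#' @return A `cell_measurements` data.frame with columns `cell_id`,
#'   `rbp4`, `sod3`, `ifitm3`, `factin`, `cell_area_um2`,
#'   `nucleus_area_um2`; attribute `excluded` lists counts by reason.
#' @export
measure_cells <- function(channels, cell_mask, nucleus_mask,
                          config = segmentation_config()) {
  if ("phalloidin" %in% names(channels) && !"factin" %in% names(channels)) {
    names(channels)[names(channels) == "phalloidin"] <- "factin"
  }
  need <- marker_names()
  if (!all(need %in% names(channels))) {
    stop("channels must include ", paste(need, collapse = ", "),
         " (phalloidin accepted for factin)")
  }
  dims <- lapply(c(channels[need], list(cell_mask, nucleus_mask)), dim)
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("channels and masks must share dimensions")
  }

  labels <- sort(setdiff(unique(as.integer(cell_mask)), 0L))
  nuc_labels <- setdiff(unique(as.integer(nucleus_mask)), 0L)
  no_nucleus <- setdiff(labels, nuc_labels)
  labels <- intersect(labels, nuc_labels)

  border <- integer(0)
  if (config$exclude_border && length(labels)) {
    edge <- unique(as.integer(c(cell_mask[1, ], cell_mask[nrow(cell_mask), ],
                                cell_mask[, 1], cell_mask[, ncol(cell_mask)])))
    border <- intersect(labels, setdiff(edge, 0L))
    labels <- setdiff(labels, border)
  }

  px2 <- config$pixel_size^2
  bg <- config$background_subtract
  rows <- lapply(labels, function(l) {
    in_cell <- cell_mask == l
    in_nuc <- nucleus_mask == l
    vals <- vapply(need, function(m) {
      mean(channels[[m]][in_cell]) - bg
    }, numeric(1))
    pos <- which(in_cell, arr.ind = TRUE)
    data.frame(cell_id = l, rbp4 = vals["rbp4"], sod3 = vals["sod3"],
               ifitm3 = vals["ifitm3"], factin = vals["factin"],
               cell_area_um2 = sum(in_cell) * px2,
               nucleus_area_um2 = sum(in_nuc) * px2,
               centroid_x = mean(pos[, 2]), centroid_y = mean(pos[, 1]))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), rbp4 = numeric(0), sod3 = numeric(0),
               ifitm3 = numeric(0), factin = numeric(0),
               cell_area_um2 = numeric(0), nucleus_area_um2 = numeric(0),
               centroid_x = numeric(0), centroid_y = numeric(0))
  rownames(out) <- NULL

  bad_geom <- out$nucleus_area_um2 > out$cell_area_um2
  excluded <- c(no_nucleus = length(no_nucleus), border = length(border),
                nucleus_larger_than_cell = sum(bad_geom))
  out <- out[!bad_geom, , drop = FALSE]
  class(out) <- c("cell_measurements", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

#' Randomly select detection-round cells
#'
#' Samples `k` measured cells uniformly without replacement (default 20,
#' one per detection round) with a mandatory seed for auditability. The
#' selection order is recorded as rounds 1..k in the returned table.
#'
#' @param measurements `cell_measurements` table with at least `k` rows.
#' @param k number of cells (detection rounds) to select.
#' @param seed integer seed.
#' @return The selected rows with a `round` column 1..k.
#' @export
select_cells <- function(measurements, k = DEFAULT_ROUNDS, seed) {
  n <- nrow(measurements)
  if (n < k) {
    stop("need at least ", k, " cells but only ", n,
         " are available (short by ", k - n, ")")
  }
  set.seed(as.integer(seed))
  idx <- sample.int(n, k, replace = FALSE)
  out <- measurements[idx, , drop = FALSE]
  out$round <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Match measured cells to a ground-truth table
#'
#' Pairs each measured cell with the ground-truth cell whose centroid is
#' nearest (segmentation label order is arbitrary, so ids cannot be
#' compared directly). Both tables need `centroid_x` / `centroid_y`
#' columns in pixels.
#'
#' @param measured,truth `cell_measurements` tables with centroids.
#' @return `truth` reordered to align row-by-row with `measured`.
#' @export
match_to_ground_truth <- function(measured, truth) {
  idx <- vapply(seq_len(nrow(measured)), function(i) {
    which.min((truth$centroid_x - measured$centroid_x[i])^2 +
                (truth$centroid_y - measured$centroid_y[i])^2)
  }, integer(1))
  if (anyDuplicated(idx)) {
    warning("ground-truth matching is not one-to-one")
  }
  truth[idx, , drop = FALSE]
}

#' Quantify an image end to end
#'
#' Convenience wrapper: segment nuclei from DAPI, cells from phalloidin,
#' then measure all marker channels.
#'
#' @param channels named list with at least `dapi`, `phalloidin`, `rbp4`,
#'   `sod3`, `ifitm3` matrices.
#' @param config a [segmentation_config()].
#' @return `cell_measurements` table (see [measure_cells()]).
#' @export
quantify_image <- function(channels, config = segmentation_config()) {
  need <- c("dapi", "phalloidin", "rbp4", "sod3", "ifitm3")
  if (!all(need %in% names(channels))) {
    stop("channels must include ", paste(need, collapse = ", "))
  }
  nuclei <- segment_nuclei(channels$dapi, config)
  cells <- segment_cells(channels$phalloidin, nuclei, config)
  measure_cells(channels, cells, nuclei, config)
}
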