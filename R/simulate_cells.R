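#' Sample synthetic per-cell measurements
#'
#' Draws per-cell biomarker intensities and cell/nucleus sizes from a stage
#' parameter set. Intensities are log-normal with the configured mean and
#' coefficient of variation (fluorescence intensities are positive and
#' right-skewed); cell and nucleus diameters come from a correlated
#' bivariate normal truncated to `0 < nucleus < cell`, and areas are ellipse
#' areas computed from the sampled equivalent diameters (so area does not
#' depend on the rendering aspect ratio).
#'
#' @param params a [make_stage_params()] object.
#' @param n_cells number of cells to draw (>= 1).
#' @param seed integer seed; draws are bit-reproducible for a fixed seed.
#' @return A data.frame of class `cell_measurements` with columns `cell_id`,
#'   `rbp4`, `sod3`, `ifitm3`, `factin` (mean gray values, arbitrary
#'   units), `cell_area_um2`, `nucleus_area_um2`, plus the sampled
#'   `cell_diameter_um`, `nucleus_diameter_um` and `aspect_ratio` used for
#'   rendering.
#' @examples
#' cells <- sample_cell_measurements(make_stage_params("P2"), 20, seed = 1)
#' all(cells$nucleus_area_um2 < cells$cell_area_um2)
#' @export
sample_cell_measurements <- function(params, n_cells, seed) {
  stopifnot(inherits(params, "stage_params"))
  if (length(n_cells) != 1L || n_cells < 1) {
    stop("n_cells must be a positive integer")
  }
  n_cells <- as.integer(n_cells)
  set.seed(as.integer(seed))

  vals <- lapply(marker_names(), function(m) {
    rlnorm_meancv(n_cells, params[[paste0(m, "_mean")]],
                  params[[paste0(m, "_cv")]])
  })
  names(vals) <- marker_names()

  d <- sample_diameters(n_cells,
                        params$cell_diameter_mean, params$cell_diameter_sd,
                        params$nucleus_diameter_mean,
                        params$nucleus_diameter_sd,
                        params$size_correlation)
  aspect <- stats::runif(n_cells, params$aspect_ratio_min,
                         params$aspect_ratio_max)

  out <- data.frame(
    cell_id = seq_len(n_cells),
    rbp4 = vals$rbp4, sod3 = vals$sod3,
    ifitm3 = vals$ifitm3, factin = vals$factin,
    cell_area_um2 = pi * (d$cell / 2)^2,
    nucleus_area_um2 = pi * (d$nucleus / 2)^2,
    cell_diameter_um = d$cell,
    nucleus_diameter_um = d$nucleus,
    aspect_ratio = aspect
  )
  class(out) <- c("cell_measurements", "data.frame")
  out
}

# log-normal draws parameterised by arithmetic mean and CV; cv = 0 gives
# the degenerate point mass at the mean
rlnorm_meancv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# correlated cell/nucleus diameters, rejection-truncated to the physically
# admissible region 0 < nucleus < cell
sample_diameters <- function(n, cell_mean, cell_sd, nuc_mean, nuc_sd, rho,
                             max_iter = 1000L) {
  draw <- function(k) {
    z1 <- stats::rnorm(k)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(k)
    list(cell = cell_mean + cell_sd * z1, nucleus = nuc_mean + nuc_sd * z2)
  }
  d <- draw(n)
  bad <- which(d$cell <= 0 | d$nucleus <= 0 | d$nucleus >= d$cell)
  iter <- 0L
  while (length(bad) && iter < max_iter) {
    r <- draw(length(bad))
    d$cell[bad] <- r$cell
    d$nucleus[bad] <- r$nucleus
    bad <- which(d$cell <= 0 | d$nucleus <= 0 | d$nucleus >= d$cell)
    iter <- iter + 1L
  }
  if (length(bad)) {
    stop("could not sample admissible diameters (nucleus < cell) after ",
         max_iter, " rejection rounds; check size parameters")
  }
  d
}

#' Simulate one sample's indicator profile
#'
#' Generates the 20-round indicator profile of a single sample at a given
#' dedifferentiation stage: for each of the six panel indicators, one value
#' per detection round (one randomly measured cell per round). By default
#' each stained marker is drawn from an independent set of cells (separate
#' coverslips); `shared_cells = TRUE` instead measures all four markers on
#' one shared cell table. Cell and nucleus size always come from one shared
#' draw (both are measured on the same DAPI/phalloidin staining).
#'
#' @param params a [make_stage_params()] object.
#' @param sample_id sample identifier.
#' @param n_rounds detection rounds per indicator (default 20).
#' @param seed integer seed.
#' @param batch_id batch identifier recorded on the profile.
#' @param shared_cells measure all markers on one shared cell set.
#' @return A [sample_profile()] object whose stage is the generating stage.
#' @export
simulate_sample_profile <- function(params, sample_id,
                                    n_rounds = DEFAULT_ROUNDS, seed,
                                    batch_id = "batch1",
                                    shared_cells = FALSE) {
  stopifnot(inherits(params, "stage_params"))
  vals <- matrix(NA_real_, nrow = n_rounds, ncol = length(chondro_panel()),
                 dimnames = list(NULL, chondro_panel()))
  if (shared_cells) {
    cells <- sample_cell_measurements(params, n_rounds, seed)
    for (m in marker_names()) vals[, m] <- cells[[m]]
    vals[, "cell_size"] <- cells$cell_area_um2
    vals[, "nucleus_size"] <- cells$nucleus_area_um2
  } else {
    for (i in seq_along(marker_names())) {
      m <- marker_names()[i]
      cells <- sample_cell_measurements(params, n_rounds,
                                        seed = as.integer(seed) + i)
      vals[, m] <- cells[[m]]
    }
    cells <- sample_cell_measurements(params, n_rounds,
                                      seed = as.integer(seed) + 5L)
    vals[, "cell_size"] <- cells$cell_area_um2
    vals[, "nucleus_size"] <- cells$nucleus_area_um2
  }
  sample_profile(sample_id, vals, stage = params$stage, batch_id = batch_id)
}
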