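#' Single-cell QC configuration
#'
#' Thresholds for the single-cell QC filters and the pseudotime pattern
#' classifier.
#'
#' @param min_genes_per_cell cells expressing fewer genes are removed
#'   (default 500; a cell "expresses" a gene when its count is nonzero).
#' @param min_cells_per_gene genes expressed in fewer cells are removed
#'   (default 10).
#' @param total_sd_window half-width, in sample sds, of the total-count
#'   window around the mean within which cells qualify (default 2;
#'   boundary cells are retained, closed interval).
#' @param q_threshold BH-adjusted q-value cutoff for dynamic genes
#'   (default 0.01).
#' @param top_n maximum number of dynamic genes returned (default 1000).
#' @param n_bins pseudotime bins for pattern classification (default 10).
#' @param flat_range flat-rejection threshold: a gene whose smoothed
#'   bin-mean range is below this fraction of its value range is FLAT
#'   (default 0.1).
#' @param net_change net-change threshold: a non-flat gene whose scaled
#'   net change is below this is non-monotone, hence TIDE_WAVE
#'   (default 0.2; must exceed `flat_range`).
#' @param tau_early midpoint-crossing fraction at or below which a
#'   decreasing gene is IMMEDIATE_DOWN (default 0.3).
#' @param tau_late crossing fraction at or above which an increasing gene
#'   is DELAYED_UP (default 0.7; must exceed `tau_early`).
#' @param min_prominence minimum prominence (on the \[0,1\] scaled bins) for
#'   an internal extremum to count toward the tide-wave rule.
#' @return List of class `qc_config`.
#' @export
qc_config <- function(min_genes_per_cell = 500, min_cells_per_gene = 10,
                      total_sd_window = 2, q_threshold = 0.01,
                      top_n = 1000, n_bins = 10, flat_range = 0.1,
                      net_change = 0.2, tau_early = 0.3, tau_late = 0.7,
                      min_prominence = 0.15) {
  stopifnot(min_genes_per_cell > 0, min_cells_per_gene > 0,
            total_sd_window > 0, q_threshold > 0, top_n > 0, n_bins >= 3,
            flat_range > 0, net_change > flat_range,
            tau_early > 0, tau_late > tau_early, min_prominence >= 0)
  structure(as.list(environment()), class = "qc_config")
}

#' Single-cell QC filters
#'
#' The three QC steps applied, in this fixed order, before trajectory
#' analysis:
#' \enumerate{
#'   \item `filter_cells_min_genes()` -- remove cells expressing fewer
#'     than `min_genes_per_cell` genes;
#'   \item `filter_genes_min_cells()` -- remove genes expressed in fewer
#'     than `min_cells_per_gene` cells;
#'   \item `qualify_cells_total_counts()` -- keep cells whose total counts
#'     fall within mean +/- `total_sd_window` sample sds (closed
#'     interval, n-1 denominator).
#' }
#'
#' @param tm a [trajectory_matrix()].
#' @param config a [qc_config()].
#' @return Filtered `trajectory_matrix` (pseudotime subset accordingly).
#' @export
filter_cells_min_genes <- function(tm, config = qc_config()) {
  stopifnot(inherits(tm, "trajectory_matrix"))
  keep <- colSums(tm$expr > 0) >= config$min_genes_per_cell
  if (!any(keep)) stop("QC removed every cell (min genes per cell)")
  subset_trajectory(tm, cells = keep)
}

#' @rdname filter_cells_min_genes
#' @export
filter_genes_min_cells <- function(tm, config = qc_config()) {
  stopifnot(inherits(tm, "trajectory_matrix"))
  keep <- rowSums(tm$expr > 0) >= config$min_cells_per_gene
  if (!any(keep)) stop("QC removed every gene (min cells per gene)")
  subset_trajectory(tm, genes = keep)
}

#' @rdname filter_cells_min_genes
#' @export
qualify_cells_total_counts <- function(tm, config = qc_config()) {
  stopifnot(inherits(tm, "trajectory_matrix"))
  if (ncol(tm$expr) < 2L) {
    warning("single cell: total-count window undefined, kept unchanged")
    return(tm)
  }
  totals <- colSums(tm$expr)
  mu <- mean(totals)
  s <- stats::sd(totals)          # n-1 denominator
  lo <- mu - config$total_sd_window * s
  hi <- mu + config$total_sd_window * s
  keep <- totals >= lo & totals <= hi
  if (!any(keep)) stop("QC removed every cell (total-count window)")
  out <- subset_trajectory(tm, cells = keep)
  attr(out, "total_count_bounds") <- c(lower = lo, upper = hi)
  out
}

#' @rdname filter_cells_min_genes
#' @export
qc_pipeline <- function(tm, config = qc_config()) {
  qualify_cells_total_counts(
    filter_genes_min_cells(filter_cells_min_genes(tm, config), config),
    config)
}

subset_trajectory <- function(tm, genes = NULL, cells = NULL) {
  if (!is.null(genes)) {
    tm$expr <- tm$expr[genes, , drop = FALSE]
    if (!is.null(tm$true_class)) tm$true_class <- tm$true_class[genes]
  }
  if (!is.null(cells)) {
    tm$expr <- tm$expr[, cells, drop = FALSE]
    tm$pseudotime <- tm$pseudotime[cells]
  }
  tm
}
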