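#' Simulate a pseudotime trajectory matrix
#'
#' Generates a genes x cells expression matrix along a uniform pseudotime
#' on \[0, 1\], with pattern genes drawn from five canonical temporal
#' archetypes plus flat background genes:
#' \describe{
#'   \item{IMMEDIATE_DOWN}{step down at early pseudotime (default 0.15)}
#'   \item{GRADUAL_DOWN}{linear decrease}
#'   \item{DELAYED_UP}{step up at late pseudotime (default 0.85)}
#'   \item{GRADUAL_UP}{linear increase}
#'   \item{TIDE_WAVE}{one full sinusoidal period (two internal extrema)}
#'   \item{FLAT}{constant background}
#' }
#' Each gene is `baseline + amplitude * template(t) + N(0, noise_sd)`,
#' truncated at zero (expression is nonnegative).
#'
#' @param n_per_class named vector/list of gene counts per pattern class
#'   (names from [pattern_classes()] except FLAT), or a single count used
#'   for all five classes.
#' @param n_flat number of flat background genes.
#' @param n_cells number of cells (>= 20).
#' @param noise_sd Gaussian noise sd (>= 0) on the expression scale.
#' @param seed integer seed.
#' @param baseline,amplitude expression offset and dynamic range of the
#'   templates.
#' @return An object of class `trajectory_matrix`: list with `expr`
#'   (genes x cells matrix, cells in pseudotime order), `pseudotime`
#'   (length = cells), and `true_class` (named per gene).
#' @export
simulate_trajectory_matrix <- function(n_per_class = 10, n_flat = 50,
                                       n_cells = 300, noise_sd = 0.2,
                                       seed, baseline = 1, amplitude = 2) {
  classes <- setdiff(pattern_classes(), "FLAT")
  if (length(n_per_class) == 1L && is.null(names(n_per_class))) {
    n_per_class <- stats::setNames(rep(n_per_class, length(classes)),
                                   classes)
  }
  n_per_class <- unlist(n_per_class)
  bad <- setdiff(names(n_per_class), classes)
  if (length(bad)) stop("unknown pattern class(es): ",
                        paste(bad, collapse = ", "))
  if (any(n_per_class < 0) || n_flat < 0) stop("negative gene counts")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_cells < 20) stop("n_cells must be >= 20")

  set.seed(as.integer(seed))
  pt <- sort(stats::runif(n_cells, 0, 1))

  gene_classes <- c(rep(names(n_per_class), n_per_class),
                    rep("FLAT", n_flat))
  n_genes <- length(gene_classes)
  if (!n_genes) stop("no genes requested")

  expr <- matrix(NA_real_, n_genes, n_cells)
  for (g in seq_len(n_genes)) {
    mu <- baseline + amplitude * pattern_template(gene_classes[g], pt)
    expr[g, ] <- pmax(mu + stats::rnorm(n_cells, sd = noise_sd), 0)
  }
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  dimnames(expr) <- list(gene_ids,
                         sprintf("cell_%04d", seq_len(n_cells)))
  structure(list(expr = expr, pseudotime = pt,
                 true_class = stats::setNames(gene_classes, gene_ids)),
            class = "trajectory_matrix")
}

# canonical archetype templates on [0, 1], range [0, 1]
pattern_template <- function(class, t, step_down_at = 0.15,
                             step_up_at = 0.85) {
  switch(class,
         IMMEDIATE_DOWN = as.numeric(t < step_down_at),
         GRADUAL_DOWN = 1 - t,
         DELAYED_UP = as.numeric(t >= step_up_at),
         GRADUAL_UP = t,
         TIDE_WAVE = 0.5 + 0.5 * sin(2 * pi * t),
         FLAT = rep(0.5, length(t)),
         stop("unknown pattern class: ", class))
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat("<trajectory_matrix>", nrow(x$expr), "genes x", ncol(x$expr),
      "cells\n")
  if (!is.null(x$true_class)) {
    print(table(x$true_class))
  }
  invisible(x)
}

#' Build a trajectory matrix from components
#'
#' @param expr genes x cells numeric matrix (nonnegative, no missing
#'   values).
#' @param pseudotime numeric vector, one nonnegative value per cell.
#' @param true_class optional named per-gene class labels.
#' @export
trajectory_matrix <- function(expr, pseudotime, true_class = NULL) {
  expr <- as.matrix(expr)
  if (length(pseudotime) != ncol(expr)) {
    stop("pseudotime length (", length(pseudotime),
         ") must equal the number of cells (", ncol(expr), ")")
  }
  if (anyNA(expr) || anyNA(pseudotime)) stop("missing values not allowed")
  if (any(pseudotime < 0)) stop("pseudotime must be nonnegative")
  structure(list(expr = expr, pseudotime = as.numeric(pseudotime),
                 true_class = true_class),
            class = "trajectory_matrix")
}

#' Write / read trajectory matrices as CSV
#'
#' The expression matrix is written genes x cells with gene ids in the
#' first column; pseudotime as a separate one-column CSV.
#'
#' @param tm a `trajectory_matrix`.
#' @param expr_path,pseudotime_path CSV paths.
#' @export
write_trajectory <- function(tm, expr_path, pseudotime_path) {
  utils::write.csv(data.frame(gene = rownames(tm$expr), tm$expr,
                              check.names = FALSE),
                   expr_path, row.names = FALSE)
  utils::write.csv(data.frame(pseudotime = tm$pseudotime),
                   pseudotime_path, row.names = FALSE)
  invisible(expr_path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(expr_path, pseudotime_path) {
  df <- utils::read.csv(expr_path, check.names = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  pt <- utils::read.csv(pseudotime_path)$pseudotime
  trajectory_matrix(expr, pt)
}
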