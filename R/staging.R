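#' Build a staged reference model
#'
#' Assembles stage-labeled profiles (all four stages P0, P2, P4, P8 must be
#' represented) into a feature matrix, normalizes it to integers in
#' \[0, 14000\], sorts detection rounds within each column, and freezes the
#' normalization parameters so that query samples can later be projected
#' into the same coordinate system.
#'
#' @param profiles list of stage-labeled [sample_profile()] objects.
#' @return An object of class `reference_model`: the normalized,
#'   round-sorted `feature_matrix`, the per-sample stage labels, and the
#'   frozen `norm_params`.
#' @export
build_reference <- function(profiles) {
  stages <- vapply(profiles, `[[`, "", "stage")
  missing <- setdiff(stage_levels(), stages)
  if (length(missing)) {
    stop("stage ", paste(missing, collapse = ", "), " absent from profiles")
  }
  if (any(stages == "UNKNOWN")) stop("reference profiles must be staged")
  m <- sort_rounds(normalize_matrix(assemble_matrix(profiles)))
  structure(list(matrix = m, stages = m$stage,
                 norm_params = m$norm_params, panel = chondro_panel()),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat("<reference_model>", length(x$stages), "reference samples:",
      paste(sprintf("%s (%s)", names(x$stages), x$stages), collapse = ", "),
      "\n")
  invisible(x)
}

#' Sample-to-sample distance matrix
#'
#' Euclidean distances between samples of a normalized feature matrix, each
#' sample represented by its concatenated per-indicator round vector (6
#' indicators x 20 rounds = 120 dimensions by default). This is the
#' distance underlying the sample-to-sample heatmap used to compare donor
#' chondrocytes with the staged model.
#'
#' @param m normalized `feature_matrix`.
#' @param log1p_transform apply `log1p` to the values first (optional
#'   variance stabilization).
#' @return Symmetric matrix of distances with zero diagonal, dimnames =
#'   sample ids.
#' @export
sample_distance_matrix <- function(m, log1p_transform = FALSE) {
  stopifnot(inherits(m, "feature_matrix"))
  if (m$state != "normalized") stop("matrix must be normalized first")
  v <- sample_vectors(m)
  if (log1p_transform) v <- log1p(v)
  if (nrow(v) == 1L) {
    warning("single sample: distance matrix is 1x1 zero")
  }
  as.matrix(stats::dist(v))
}

#' PCA embedding of samples
#'
#' Column-centered principal component analysis of the per-sample
#' 120-dimensional vectors. Components are ordered by decreasing explained
#' variance; each component's sign is fixed so its largest-magnitude
#' loading is positive (reproducible orientation).
#'
#' @param m normalized `feature_matrix` with >= 2 samples.
#' @param n_components number of components to return (default 2).
#' @param log1p_transform apply `log1p` first.
#' @return List with `coords` (samples x components), `explained_variance`
#'   (fraction per returned component) and the fitted `rotation`/`center`
#'   needed to project new samples.
#' @export
pca_embed <- function(m, n_components = 2, log1p_transform = FALSE) {
  stopifnot(inherits(m, "feature_matrix"))
  v <- sample_vectors(m)
  if (log1p_transform) v <- log1p(v)
  if (nrow(v) < 2L) stop("PCA needs at least 2 samples")
  k_max <- min(nrow(v) - 1L, ncol(v))
  if (n_components > k_max) {
    warning("only ", k_max, " components available; truncating")
    n_components <- k_max
  }
  fit <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  # deterministic sign: largest-|loading| positive
  for (j in k) {
    load <- fit$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      fit$rotation[, j] <- -load
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  list(coords = fit$x[, k, drop = FALSE],
       explained_variance = ev[k],
       rotation = fit$rotation[, k, drop = FALSE],
       center = fit$center,
       log1p_transform = log1p_transform)
}

#' Assign a dedifferentiation stage to a query sample
#'
#' Projects a query profile into the reference model's frozen normalization,
#' sorts its rounds, computes the Euclidean distance to every reference
#' sample, and assigns the stage of the nearest reference. Confidence is
#' the two-nearest-stage ratio `d_other / (d_other + d_assigned)` where
#' `d_other` is the distance to the nearest reference of a different stage:
#' 1 means the query coincides with a reference, values at or below 0.5
#' raise the ambiguity flag. Exact ties between stages are broken toward
#' the earlier stage and flagged ambiguous. A query whose nearest-reference
#' distance exceeds `out_of_model_factor` times the median within-reference
#' distance is additionally flagged `out_of_model` ("not close to any
#' group") rather than trusted as a firm call.
#'
#' @param query a [sample_profile()] with the model's indicator panel.
#' @param model a [build_reference()] model.
#' @param out_of_model_factor multiple of the median reference-to-reference
#'   distance beyond which a query is flagged out-of-model (default 1.5).
#' @return An object of class `staging_result`: list with `sample_id`,
#'   `distances` (named per reference sample), `stage`, `confidence`,
#'   `ambiguous`, `out_of_model`, `n_clipped`, `pca` (reference coords,
#'   query coords, explained variance).
#' @export
assign_stage <- function(query, model, out_of_model_factor = 1.5) {
  stopifnot(inherits(query, "sample_profile"),
            inherits(model, "reference_model"))
  missing <- setdiff(model$panel, colnames(query$values))
  if (length(missing)) {
    stop("query lacks indicator(s): ", paste(missing, collapse = ", "))
  }
  norm <- apply_normalization(query, model$norm_params)
  qvec <- as.vector(apply(norm$values[, model$panel, drop = FALSE], 2, sort))

  ref_vecs <- sample_vectors(model$matrix)
  d <- sqrt(colSums((t(ref_vecs) - qvec)^2))
  names(d) <- rownames(ref_vecs)

  stages <- model$stages[names(d)]
  # nearest distance per stage, then nearest stage with earlier-stage
  # tie-break
  d_stage <- vapply(stage_levels(), function(s) min(d[stages == s]),
                    numeric(1))
  best <- stage_levels()[which.min(d_stage)]  # which.min takes first = earlier
  d_best <- d_stage[best]
  d_other <- min(d_stage[setdiff(stage_levels(), best)])
  tie <- sum(d_stage == d_best) > 1L
  confidence <- if (d_best == 0 && d_other == 0) 0.5 else
    unname(d_other / (d_other + d_best))
  ambiguous <- tie || confidence <= 0.5

  ref_d <- stats::dist(ref_vecs)
  out_of_model <- d_best > out_of_model_factor * stats::median(ref_d)

  pca <- pca_embed(model$matrix, n_components = min(2, nrow(ref_vecs) - 1))
  qcoord <- (qvec - pca$center) %*% pca$rotation

  structure(list(sample_id = query$sample_id, distances = d,
                 stage = best, confidence = confidence,
                 ambiguous = ambiguous, out_of_model = out_of_model,
                 n_clipped = norm$n_clipped,
                 pca = list(reference_coords = pca$coords,
                            query_coords = qcoord,
                            explained_variance = pca$explained_variance)),
            class = "staging_result")
}

#' @export
print.staging_result <- function(x, ...) {
  cat("<staging_result>", x$sample_id, "-> stage", x$stage,
      sprintf("(confidence %.3f%s%s)\n", x$confidence,
              if (x$ambiguous) ", ambiguous" else "",
              if (x$out_of_model) ", out-of-model" else ""))
  invisible(x)
}

#' Serialize / load a reference model
#'
#' The model is written as a plain-text bundle: the normalized round-sorted
#' matrix as wide CSV, and stages, panel and normalization parameters as a
#' JSON sidecar.
#'
#' @param model a `reference_model`.
#' @param dir output directory (created if needed).
#' @return `write_reference()` returns `dir` invisibly; `read_reference()`
#'   returns the `reference_model`.
#' @export
write_reference <- function(model, dir) {
  stopifnot(inherits(model, "reference_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(model$matrix$values,
                   file.path(dir, "reference_matrix.csv"),
                   row.names = FALSE)
  meta <- list(sample_id = model$matrix$sample_id,
               indicator = model$matrix$indicator,
               batch_id = model$matrix$batch_id,
               stages = as.list(model$stages),
               panel = model$panel,
               norm_params = model$norm_params)
  jsonlite::write_json(meta, file.path(dir, "reference_meta.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  values <- as.matrix(utils::read.csv(
    file.path(dir, "reference_matrix.csv"), check.names = FALSE))
  meta <- jsonlite::read_json(file.path(dir, "reference_meta.json"),
                              simplifyVector = TRUE)
  stages <- unlist(meta$stages)
  m <- structure(list(values = values, sample_id = meta$sample_id,
                      indicator = meta$indicator, batch_id = meta$batch_id,
                      stage = stages, state = "normalized",
                      norm_params = as.data.frame(meta$norm_params)),
                 class = "feature_matrix")
  structure(list(matrix = m, stages = stages,
                 norm_params = m$norm_params, panel = meta$panel),
            class = "reference_model")
}
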