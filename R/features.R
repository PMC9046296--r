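#' Feature matrix: rounds x (sample, indicator)
#'
#' The staging system captures measurements in a matrix whose rows are
#' detection rounds (1..20) and whose columns are (sample, indicator) pairs
#' over the six-indicator panel. Raw matrices are normalized per indicator
#' to integers in \[0, 14000\] before distance/PCA analysis.
#'
#' `assemble_matrix()` builds the raw matrix from a list of profiles;
#' column order is deterministic: samples in input order crossed with
#' indicators in panel order.
#'
#' @param profiles non-empty list of [sample_profile()] objects sharing the
#'   round count.
#' @return An object of class `feature_matrix`: list with `values` (rounds x
#'   columns numeric matrix), per-column `sample_id`, `indicator`,
#'   `batch_id`, per-sample `stage`, a `state` flag (`"raw"` or
#'   `"normalized"`), and, once normalized, `norm_params` (per-indicator
#'   min/max).
#' @export
assemble_matrix <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  if (!all(vapply(profiles, inherits, TRUE, "sample_profile"))) {
    stop("profiles must be sample_profile objects")
  }
  rounds <- vapply(profiles, function(p) nrow(p$values), 1L)
  if (length(unique(rounds)) != 1L) {
    bad <- profiles[[which(rounds != rounds[1])[1]]]$sample_id
    stop("inconsistent round count in sample '", bad, "'")
  }
  panel <- chondro_panel()
  values <- do.call(cbind, lapply(profiles, function(p) p$values[, panel]))
  sample_id <- rep(vapply(profiles, `[[`, "", "sample_id"),
                   each = length(panel))
  indicator <- rep(panel, length(profiles))
  batch_id <- rep(vapply(profiles, `[[`, "", "batch_id"),
                  each = length(panel))
  colnames(values) <- paste(sample_id, indicator, sep = "|")
  stages <- vapply(profiles, `[[`, "", "stage")
  names(stages) <- vapply(profiles, `[[`, "", "sample_id")
  structure(list(values = values, sample_id = sample_id,
                 indicator = indicator, batch_id = batch_id,
                 stage = stages, state = "raw", norm_params = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$values), "rounds x", ncol(x$values),
      "columns (", length(unique(x$sample_id)), "samples x",
      length(unique(x$indicator)), "indicators ),", x$state, "\n")
  invisible(x)
}

#' Normalize a feature matrix to integers in \[0, 14000\]
#'
#' Per indicator (across all samples and rounds jointly), values are mapped
#' linearly so the indicator minimum becomes 0 and the maximum 14000, then
#' rounded half-up to integers. An indicator that is constant over the
#' fitted set maps to 0 everywhere (with a warning). The fitted (min, max)
#' per indicator are stored on the matrix so queries can later be projected
#' into the same coordinate system with [apply_normalization()].
#'
#' @param m raw `feature_matrix`.
#' @param scope `"indicator"` (default) fits min/max per indicator;
#'   `"global"` fits one min/max over the whole matrix.
#' @return Normalized `feature_matrix` with `norm_params` attached.
#' @examples
#' # values 5, 10, 20 map to 0, 4667, 14000
#' @export
normalize_matrix <- function(m, scope = c("indicator", "global")) {
  stopifnot(inherits(m, "feature_matrix"))
  scope <- match.arg(scope)
  if (m$state != "raw") stop("matrix is already normalized")
  if (!all(is.finite(m$values))) stop("matrix contains non-finite values")
  inds <- unique(m$indicator)
  if (scope == "global") {
    rng <- range(m$values)
    params <- data.frame(indicator = inds, min = rng[1], max = rng[2])
  } else {
    params <- do.call(rbind, lapply(inds, function(ind) {
      rng <- range(m$values[, m$indicator == ind, drop = FALSE])
      data.frame(indicator = ind, min = rng[1], max = rng[2])
    }))
  }
  out <- m
  for (i in seq_len(nrow(params))) {
    cols <- m$indicator == params$indicator[i]
    lo <- params$min[i]; hi <- params$max[i]
    if (hi == lo) {
      warning("indicator '", params$indicator[i],
              "' is constant; normalized to 0")
      out$values[, cols] <- 0
    } else {
      out$values[, cols] <-
        round_half_up((m$values[, cols] - lo) / (hi - lo) * NORM_MAX)
    }
  }
  out$state <- "normalized"
  out$norm_params <- params
  out
}

#' Project a query profile into a fitted normalization
#'
#' Applies previously fitted per-indicator (min, max) parameters to a query
#' profile: the same linear map to \[0, 14000\], rounded half-up, then
#' clipped to the range (the reference range defines the model's domain, so
#' out-of-range query values saturate rather than extrapolate).
#'
#' @param query a [sample_profile()].
#' @param params `norm_params` data.frame from a normalized
#'   [normalize_matrix()] result (columns indicator, min, max).
#' @return List with `values` (rounds x indicators integer matrix) and
#'   `n_clipped` (count of values clipped to the range).
#' @export
apply_normalization <- function(query, params) {
  stopifnot(inherits(query, "sample_profile"))
  missing <- setdiff(colnames(query$values), params$indicator)
  if (length(missing)) {
    stop("normalization params missing indicator(s): ",
         paste(missing, collapse = ", "))
  }
  out <- query$values
  n_clipped <- 0L
  for (ind in colnames(out)) {
    i <- match(ind, params$indicator)
    lo <- params$min[i]; hi <- params$max[i]
    if (hi == lo) {
      out[, ind] <- 0
      next
    }
    v <- round_half_up((out[, ind] - lo) / (hi - lo) * NORM_MAX)
    n_clipped <- n_clipped + sum(v < 0 | v > NORM_MAX)
    out[, ind] <- pmin(pmax(v, 0), NORM_MAX)
  }
  list(values = out, n_clipped = n_clipped)
}

#' Sort detection rounds within each column
#'
#' Rounds are exchangeable (each is an independently selected cell, not a
#' matched observation across indicators), so within every (sample,
#' indicator) column the values are sorted ascending. All downstream
#' distances then become exactly invariant to the order in which cells were
#' measured -- the hard version of the round-reordering robustness check.
#'
#' @param m `feature_matrix`.
#' @return The matrix with each column sorted ascending. Idempotent.
#' @export
sort_rounds <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  m$values <- apply(m$values, 2, sort)
  m
}

#' Harmonize batches through a shared anchor sample
#'
#' Different staining batches are made comparable through the one sample
#' present in every batch (the Model-P2 healthy control): per batch and
#' indicator, an affine map is fitted sending the batch anchor's (median,
#' IQR) onto the first batch anchor's (median, IQR), and applied to every
#' sample of that batch. Robust location/scale anchoring is used because
#' only a single shared sample exists per batch.
#'
#' @param batches list of >= 2 raw `feature_matrix` objects, each containing
#'   the anchor sample.
#' @param anchor_sample_id sample id of the shared anchor (e.g. Model-P2).
#' @return One merged raw `feature_matrix` (first batch's scale).
#' @export
harmonize_batches <- function(batches, anchor_sample_id) {
  if (length(batches) < 2L) stop("need at least 2 batches to harmonize")
  for (b in seq_along(batches)) {
    if (!anchor_sample_id %in% batches[[b]]$sample_id) {
      stop("anchor sample '", anchor_sample_id, "' absent from batch ", b)
    }
  }
  ref <- batches[[1]]
  inds <- unique(ref$indicator)
  anchor_stats <- function(m, ind) {
    col <- m$values[, m$sample_id == anchor_sample_id & m$indicator == ind]
    c(med = stats::median(col), iqr = stats::IQR(col))
  }
  mapped <- lapply(seq_along(batches), function(b) {
    m <- batches[[b]]
    if (b == 1L) return(m)
    for (ind in inds) {
      s_ref <- anchor_stats(ref, ind)
      s_b <- anchor_stats(m, ind)
      cols <- m$indicator == ind
      if (s_b["iqr"] == 0) {
        warning("anchor IQR is 0 for indicator '", ind, "' in batch ", b,
                "; median shift only")
        m$values[, cols] <- m$values[, cols] - s_b["med"] + s_ref["med"]
      } else {
        gain <- s_ref["iqr"] / s_b["iqr"]
        m$values[, cols] <- (m$values[, cols] - s_b["med"]) * gain +
          s_ref["med"]
      }
    }
    m
  })
  merged <- mapped[[1]]
  for (b in seq_along(mapped)[-1]) {
    m <- mapped[[b]]
    merged$values <- cbind(merged$values, m$values)
    merged$sample_id <- c(merged$sample_id, m$sample_id)
    merged$indicator <- c(merged$indicator, m$indicator)
    merged$batch_id <- c(merged$batch_id, m$batch_id)
    new_stages <- m$stage[setdiff(names(m$stage), names(merged$stage))]
    merged$stage <- c(merged$stage, new_stages)
  }
  colnames(merged$values) <- make.unique(
    paste(merged$sample_id, merged$indicator, sep = "|"))
  merged
}

# per-sample flattened vectors (rounds x indicators concatenated in panel
# order) used for distances and PCA; rows = samples
sample_vectors <- function(m) {
  samples <- unique(m$sample_id)
  panel <- intersect(chondro_panel(), unique(m$indicator))
  out <- t(vapply(samples, function(s) {
    unlist(lapply(panel, function(ind) {
      m$values[, which(m$sample_id == s & m$indicator == ind)[1]]
    }), use.names = FALSE)
  }, numeric(nrow(m$values) * length(panel))))
  rownames(out) <- samples
  out
}
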