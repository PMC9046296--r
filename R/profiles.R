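#' Sample indicator profile
#'
#' A `sample_profile` holds one sample's detection-round measurements for
#' the six-indicator panel: a rounds x indicators numeric matrix (default
#' 20 rounds), the sample and batch identifiers, and the stage label
#' (`"UNKNOWN"` for query samples awaiting staging).
#'
#' @param sample_id sample identifier (non-empty string).
#' @param values numeric matrix, rounds x indicators, with column names
#'   exactly [chondro_panel()]; all values finite and >= 0.
#' @param stage stage label, one of P0/P2/P4/P8 or `"UNKNOWN"`.
#' @param batch_id batch identifier.
#' @return An object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, values, stage = "UNKNOWN",
                           batch_id = "batch1") {
  if (length(sample_id) != 1L || !nzchar(sample_id)) {
    stop("sample_id must be a non-empty string")
  }
  values <- as.matrix(values)
  if (is.null(colnames(values)) ||
      !setequal(colnames(values), chondro_panel())) {
    stop("profile '", sample_id, "' must have exactly the indicator columns ",
         paste(chondro_panel(), collapse = ", "))
  }
  values <- values[, chondro_panel(), drop = FALSE]
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("profile '", sample_id, "' has non-finite or negative values")
  }
  if (!(stage %in% c(stage_levels(), "UNKNOWN"))) {
    stop("invalid stage label: ", stage)
  }
  structure(list(sample_id = sample_id, batch_id = batch_id,
                 stage = stage, values = values),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("<sample_profile>", x$sample_id, "| stage", x$stage,
      "| batch", x$batch_id, "|", nrow(x$values), "rounds x",
      ncol(x$values), "indicators\n")
  invisible(x)
}

#' Read and write profiles as long-format CSV
#'
#' Profiles are exchanged as long CSV with columns
#' `sample_id, batch_id, stage, indicator, round, value` (one row per
#' indicator per detection round).
#'
#' @param profiles list of [sample_profile()] objects.
#' @param path CSV file path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   returns a list of `sample_profile` objects.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, batch_id = p$batch_id,
               stage = p$stage,
               indicator = rep(colnames(p$values), each = nrow(p$values)),
               round = rep(seq_len(nrow(p$values)), ncol(p$values)),
               value = as.vector(p$values))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "batch_id", "stage", "indicator", "round", "value")
  if (!all(need %in% names(df))) {
    stop("profile CSV must have columns ", paste(need, collapse = ", "))
  }
  lapply(split(df, factor(df$sample_id, levels = unique(df$sample_id))),
         function(d) {
           rounds <- sort(unique(d$round))
           vals <- matrix(NA_real_, length(rounds), length(chondro_panel()),
                          dimnames = list(NULL, chondro_panel()))
           for (ind in unique(d$indicator)) {
             di <- d[d$indicator == ind, ]
             vals[match(di$round, rounds), ind] <- di$value
           }
           sample_profile(d$sample_id[1], vals, stage = d$stage[1],
                          batch_id = d$batch_id[1])
         })
}

#' Convert measured cells to a sample profile
#'
#' Turns a table of per-cell measurements (as produced by [measure_cells()]
#' and subset by [select_cells()]) into a [sample_profile()]: each selected
#' cell becomes one detection round, markers map to their intensity columns
#' and cell/nucleus size to the measured areas.
#'
#' @param measurements `cell_measurements` data.frame with the marker and
#'   area columns.
#' @inheritParams sample_profile
#' @export
measurements_to_profile <- function(measurements, sample_id,
                                    stage = "UNKNOWN", batch_id = "batch1") {
  need <- c(marker_names(), "cell_area_um2", "nucleus_area_um2")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns ", paste(need, collapse = ", "))
  }
  vals <- cbind(as.matrix(measurements[, marker_names()]),
                cell_size = measurements$cell_area_um2,
                nucleus_size = measurements$nucleus_area_um2)
  sample_profile(sample_id, vals, stage = stage, batch_id = batch_id)
}
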