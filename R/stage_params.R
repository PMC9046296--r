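#' Per-stage simulation parameters
#'
#' Build the parameter set describing one dedifferentiation stage of the
#' synthetic chondrocyte model: per-marker intensity mean and coefficient of
#' variation for the four stained biomarkers, cell and nucleus diameter mean
#' and sd, the cell--nucleus size correlation, and the cell aspect-ratio
#' range used when rendering images.
#'
#' Defaults are read from the packaged YAML config
#' (`inst/extdata/stage_params.yaml`); they are illustrative values that
#' encode the biphasic ordinal structure of the dedifferentiation model:
#' RBP4 and SOD3 intensities peak at P2, IFITM3 and F-actin intensities and
#' cell/nucleus size increase monotonically from P0 to P8.
#'
#' @param stage one of `"P0"`, `"P2"`, `"P4"`, `"P8"`.
#' @param overrides named list of parameter overrides; names must match
#'   existing parameter fields (e.g. `rbp4_mean`, `cell_diameter_sd`,
#'   `size_correlation`).
#' @param config optional parameter config as returned by
#'   [load_stage_config()]; defaults to the packaged config.
#' @return An object of class `stage_params`: a named list with elements
#'   `stage`, `<marker>_mean`, `<marker>_cv` for the four markers,
#'   `cell_diameter_mean`, `cell_diameter_sd`, `nucleus_diameter_mean`,
#'   `nucleus_diameter_sd`, `size_correlation`, `aspect_ratio_min`,
#'   `aspect_ratio_max`.
#' @examples
#' p2 <- make_stage_params("P2")
#' p0 <- make_stage_params("P0", overrides = list(rbp4_mean = 7))
#' p2$rbp4_mean > p0$rbp4_mean
#' @export
make_stage_params <- function(stage, overrides = list(), config = NULL) {
  assert_stage(stage)
  if (is.null(config)) config <- load_stage_config()
  base <- config$stages[[stage]]
  params <- c(list(stage = stage), base,
              list(size_correlation = config$size_correlation,
                   aspect_ratio_min = config$aspect_ratio_min))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(params))
    if (length(bad)) {
      stop("unknown override key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    params[names(overrides)] <- overrides
  }
  validate_stage_params(structure(params, class = "stage_params"))
}

#' @rdname make_stage_params
#' @param path path to a YAML stage-parameter config; default is the
#'   packaged illustrative config.
#' @export
load_stage_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stage_params.yaml",
                        package = "chondrostage", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(stage_levels(), names(cfg$stages))
  if (length(missing)) {
    stop("stage config missing stage(s): ", paste(missing, collapse = ", "))
  }
  cfg
}

validate_stage_params <- function(p) {
  for (m in marker_names()) {
    mu <- p[[paste0(m, "_mean")]]
    cv <- p[[paste0(m, "_cv")]]
    if (!is.finite(mu) || mu <= 0) stop("mean for ", m, " must be > 0")
    if (!is.finite(cv) || cv < 0 || cv > 1) {
      stop("cv for ", m, " must be in [0, 1]")
    }
  }
  if (p$nucleus_diameter_mean >= p$cell_diameter_mean) {
    stop("nucleus diameter mean must be smaller than cell diameter mean")
  }
  if (p$cell_diameter_mean <= 0 || p$nucleus_diameter_mean <= 0) {
    stop("diameter means must be > 0")
  }
  if (p$cell_diameter_sd < 0 || p$nucleus_diameter_sd < 0) {
    stop("diameter sds must be >= 0")
  }
  if (p$size_correlation < 0 || p$size_correlation >= 1) {
    stop("size_correlation must be in [0, 1)")
  }
  if (p$aspect_ratio_min < 1 || p$aspect_ratio_max < p$aspect_ratio_min) {
    stop("aspect ratio range invalid")
  }
  p
}

#' @export
print.stage_params <- function(x, ...) {
  cat("<stage_params> stage", x$stage, "\n")
  for (m in marker_names()) {
    cat(sprintf("  %-7s mean %7.2f  cv %.2f\n", m,
                x[[paste0(m, "_mean")]], x[[paste0(m, "_cv")]]))
  }
  cat(sprintf("  cell diameter %.1f +/- %.1f um, nucleus %.1f +/- %.1f um\n",
              x$cell_diameter_mean, x$cell_diameter_sd,
              x$nucleus_diameter_mean, x$nucleus_diameter_sd))
  invisible(x)
}
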