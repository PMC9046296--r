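#' Indicator panel and stage labels
#'
#' The staging system scores each sample on six visual indicators: the mean
#' fluorescence intensity of four immunostained biomarkers (RBP4, SOD3,
#' IFITM3, F-actin) plus cell size and nucleus size measured from phalloidin
#' and DAPI staining. Each indicator is observed over a fixed number of
#' detection rounds (one randomly selected cell per round, default 20).
#'
#' @return `chondro_panel()` returns the character vector of the six
#'   indicator names, in canonical order. `stage_levels()` returns the
#'   ordered passage-stage labels `P0 < P2 < P4 < P8`.
#' @export
chondro_panel <- function() {
  c("rbp4", "sod3", "ifitm3", "factin", "cell_size", "nucleus_size")
}

#' @rdname chondro_panel
#' @export
stage_levels <- function() c("P0", "P2", "P4", "P8")

#' @rdname chondro_panel
#' @export
pattern_classes <- function() {
  c("IMMEDIATE_DOWN", "GRADUAL_DOWN", "DELAYED_UP", "GRADUAL_UP",
    "TIDE_WAVE", "FLAT")
}

# Upper bound of the normalized integer scale used for feature matrices.
NORM_MAX <- 14000L

# Number of detection rounds per indicator per sample.
DEFAULT_ROUNDS <- 20L

#' @rdname chondro_panel
#' @param stage a stage label
#' @export
is_early_stage <- function(stage) stage %in% c("P0", "P2")

marker_names <- function() c("rbp4", "sod3", "ifitm3", "factin")

# round half-up to integer (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

# deterministic sub-seed per named module stream, kept within 32-bit range
derive_seed <- function(seed, stream) {
  offs <- c(cells = 11L, images = 23L, trajectories = 37L, reference = 53L,
            queries = 71L, select = 89L, misc = 101L)
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  (as.integer(seed) %% 1000003L) * 2011L + offs[[stream]]
}

assert_stage <- function(stage) {
  if (length(stage) != 1L || !stage %in% stage_levels()) {
    stop("stage must be one of ", paste(stage_levels(), collapse = ", "),
         " (got: ", paste(stage, collapse = ","), ")", call. = FALSE)
  }
  stage
}
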