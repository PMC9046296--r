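#' Rank genes dynamically regulated along pseudotime
#'
#' Tests each gene for association with pseudotime by a likelihood-ratio
#' comparison of a natural-spline mean model against a constant mean
#' (Gaussian likelihood on log1p-transformed values), adjusts p-values by
#' Benjamini-Hochberg, and returns the genes with q below the threshold
#' (default 0.01), ranked by q then by effect size (range of the fitted
#' trajectory), truncated to the top `top_n` (default 1000).
#'
#' @param tm a QC'd [trajectory_matrix()].
#' @param config a [qc_config()].
#' @param spline_df spline degrees of freedom (default 3).
#' @return data.frame with columns `gene`, `p_value`, `q_value`, `effect`,
#'   ordered by rank.
#' @export
rank_dynamic_genes <- function(tm, config = qc_config(), spline_df = 3) {
  stopifnot(inherits(tm, "trajectory_matrix"))
  pt <- tm$pseudotime
  if (length(unique(pt)) < 3L) {
    stop("need at least 3 distinct pseudotime values")
  }
  df <- min(spline_df, length(unique(pt)) - 1L)
  basis <- splines::ns(pt, df = df)
  n <- length(pt)
  X <- cbind(1, basis)

  res <- t(apply(tm$expr, 1, function(y) {
    y <- log1p(y)
    rss0 <- sum((y - mean(y))^2)
    fit <- stats::lm.fit(X, y)
    rss1 <- sum(fit$residuals^2)
    if (rss0 <= .Machine$double.eps) return(c(p = 1, effect = 0))
    stat <- n * log(rss0 / max(rss1, .Machine$double.eps * rss0))
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    c(p = p, effect = diff(range(fit$fitted.values)))
  }))

  q <- stats::p.adjust(res[, "p"], method = "BH")
  out <- data.frame(gene = rownames(tm$expr), p_value = res[, "p"],
                    q_value = q, effect = res[, "effect"],
                    row.names = NULL)
  out <- out[out$q_value < config$q_threshold, , drop = FALSE]
  out <- out[order(out$q_value, -out$effect), , drop = FALSE]
  utils::head(out, config$top_n)
}

#' Classify a gene's temporal expression pattern
#'
#' Bins the log1p trajectory into `n_bins` equal-width pseudotime bins,
#' smooths the bin means (moving average of 3) and min-max scales them to
#' \[0, 1\]. Features: the bin-mean range relative to the gene's value
#' range (R), the scaled net change from first to last bin (Delta), the
#' number of prominent internal extrema (E), and the first pseudotime
#' fraction at which the scaled profile crosses 0.5 (t_half, linearly
#' interpolated between bin centers). Decision rule:
#' FLAT if R < `flat_range`; else TIDE_WAVE if E >= 2 or |Delta| <
#' `net_change`; else for decreasing genes IMMEDIATE_DOWN if t_half <=
#' `tau_early` else GRADUAL_DOWN; for increasing genes DELAYED_UP if
#' t_half >= `tau_late` else GRADUAL_UP.
#'
#' The rule is invariant to positive affine transforms of the expression
#' values (scaling is per gene).
#'
#' @param expr numeric expression vector (one gene).
#' @param pseudotime numeric vector, same length.
#' @param config a [qc_config()].
#' @param log_transform apply log1p before binning (default TRUE).
#' @return List with `class` (one of [pattern_classes()]) and the features
#'   `range_ratio`, `net_change`, `n_extrema`, `t_half`.
#' @export
classify_pattern <- function(expr, pseudotime, config = qc_config(),
                             log_transform = TRUE) {
  if (length(expr) != length(pseudotime)) {
    stop("expression and pseudotime lengths differ")
  }
  if (length(expr) < config$n_bins) {
    stop("need at least n_bins = ", config$n_bins, " cells")
  }
  y <- if (log_transform) log1p(expr) else expr
  bins <- bin_means(y, pseudotime, config$n_bins)
  sm <- smooth3(bins)

  value_range <- diff(range(y))
  if (value_range == 0) {
    return(list(class = "FLAT", range_ratio = 0, net_change = 0,
                n_extrema = 0L, t_half = NA_real_))
  }
  R <- diff(range(sm)) / value_range
  if (R < config$flat_range) {
    return(list(class = "FLAT", range_ratio = R, net_change = 0,
                n_extrema = 0L, t_half = NA_real_))
  }
  scaled <- (sm - min(sm)) / diff(range(sm))
  E <- count_prominent_extrema(scaled, config$min_prominence)
  # net change and crossing come from the unsmoothed bin means: edge
  # smoothing would bias the crossing of an exactly linear gene off 0.5
  scaled_raw <- (bins - min(bins)) / diff(range(bins))
  delta <- scaled_raw[length(scaled_raw)] - scaled_raw[1]
  t_half <- crossing_time(scaled_raw, decreasing = delta < 0)

  class <- if (E >= 2L || abs(delta) < config$net_change) {
    "TIDE_WAVE"
  } else if (delta < 0) {
    if (!is.na(t_half) && t_half <= config$tau_early) "IMMEDIATE_DOWN"
    else "GRADUAL_DOWN"
  } else {
    if (!is.na(t_half) && t_half >= config$tau_late) "DELAYED_UP"
    else "GRADUAL_UP"
  }
  list(class = class, range_ratio = R, net_change = unname(delta),
       n_extrema = E, t_half = t_half)
}

# equal-width pseudotime bin means; empty bins linearly interpolated
bin_means <- function(y, pt, n_bins) {
  lo <- min(pt); hi <- max(pt)
  idx <- pmin(pmax(floor((pt - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  m <- vapply(seq_len(n_bins),
              function(b) if (any(idx == b)) mean(y[idx == b]) else NA_real_,
              numeric(1))
  if (anyNA(m)) {
    known <- which(!is.na(m))
    m <- stats::approx(known, m[known], xout = seq_len(n_bins),
                       rule = 2)$y
  }
  m
}

# centered moving average of 3 with shrunken edges
smooth3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - 1):min(n, i + 1)])
  }, numeric(1))
}

# internal extrema surviving a prominence filter: turning points are
# iteratively removed while the smallest monotone segment between adjacent
# turning points is shallower than the threshold; an internal turning
# point that is the global extreme of the profile is structural by
# definition and never pruned
count_prominent_extrema <- function(v, thresh) {
  idx <- turning_points(v)
  vals <- v[idx]
  protected <- function(vals) vals == max(v) | vals == min(v)
  while (length(vals) > 2L) {
    amps <- abs(diff(vals))
    ord <- order(amps)
    dropped <- FALSE
    for (j in ord) {
      if (amps[j] >= thresh) break
      cand <- intersect(c(j, j + 1L), seq(2L, length(vals) - 1L))
      cand <- cand[!protected(vals[cand])]
      if (length(cand)) {
        vals <- vals[-cand]
        vals <- vals[keep_alternating(vals)]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  max(length(vals) - 2L, 0L)
}

turning_points <- function(v) {
  d <- diff(v)
  s <- sign(d)
  s[s == 0] <- NA
  # carry direction over flat runs
  for (i in seq_along(s)) if (is.na(s[i]) && i > 1) s[i] <- s[i - 1]
  s[is.na(s)] <- 1
  internal <- which(diff(s) != 0) + 1L
  c(1L, internal, length(v))
}

keep_alternating <- function(vals) {
  if (length(vals) <= 2L) return(rep(TRUE, length(vals)))
  keep <- rep(TRUE, length(vals))
  repeat {
    active <- which(keep)
    if (length(active) <= 2L) break
    changed <- FALSE
    for (k in seq(2L, length(active) - 1L)) {
      a <- vals[active[k - 1]]; b <- vals[active[k]]; c <- vals[active[k + 1]]
      if ((b - a) * (c - b) >= 0) {      # not a turning point any more
        keep[active[k]] <- FALSE
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  keep
}

# first bin-center fraction where the scaled profile crosses 0.5
crossing_time <- function(scaled, decreasing) {
  n <- length(scaled)
  centers <- (seq_len(n) - 0.5) / n
  hit <- if (decreasing) scaled <= 0.5 else scaled >= 0.5
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(centers[1])
  a <- scaled[i - 1]; b <- scaled[i]
  if (a == b) return(centers[i])
  frac <- (0.5 - a) / (b - a)
  centers[i - 1] + frac * (centers[i] - centers[i - 1])
}

#' Classify every gene in a trajectory matrix
#'
#' @param tm a [trajectory_matrix()].
#' @param config a [qc_config()].
#' @return data.frame (gene, class, range_ratio, net_change, n_extrema,
#'   t_half) with a `class_counts` attribute; if the matrix carries true
#'   labels, a `true_class` column and a `confusion` attribute are added.
#' @export
classify_all <- function(tm, config = qc_config()) {
  stopifnot(inherits(tm, "trajectory_matrix"))
  rows <- lapply(rownames(tm$expr), function(g) {
    f <- classify_pattern(tm$expr[g, ], tm$pseudotime, config)
    data.frame(gene = g, class = f$class, range_ratio = f$range_ratio,
               net_change = f$net_change, n_extrema = f$n_extrema,
               t_half = f$t_half)
  })
  out <- do.call(rbind, rows)
  attr(out, "class_counts") <- table(factor(out$class,
                                            levels = pattern_classes()))
  if (!is.null(tm$true_class)) {
    out$true_class <- unname(tm$true_class[out$gene])
    attr(out, "confusion") <- table(
      true = factor(out$true_class, levels = pattern_classes()),
      predicted = factor(out$class, levels = pattern_classes()))
  }
  out
}
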