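test_that("minimum-genes cell filter applies the exact <500 boundary", {
  set.seed(1)
  expr <- matrix(1, 600, 3)
  expr[500:600, 1] <- 0      # cell 1 expresses 499 genes
  expr[501:600, 2] <- 0      # cell 2 expresses exactly 500
  tm <- trajectory_matrix(expr, pseudotime = c(0.1, 0.5, 0.9))
  out <- filter_cells_min_genes(tm)
  expect_equal(ncol(out$expr), 2L)
  expect_equal(out$pseudotime, c(0.5, 0.9))
})

test_that("minimum-cells gene filter applies the exact <10 boundary", {
  expr <- matrix(0, 3, 20)
  expr[1, 1:9] <- 5          # expressed in 9 cells -> removed
  expr[2, 1:10] <- 5         # expressed in 10 cells -> retained
  expr[3, ] <- 1
  rownames(expr) <- c("g9", "g10", "gall")
  tm <- trajectory_matrix(expr, pseudotime = seq(0, 1, length.out = 20))
  out <- filter_genes_min_cells(tm)
  expect_equal(rownames(out$expr), c("g10", "gall"))
})

test_that("total-count qualification keeps the closed mean +/- 2 sd window", {
  set.seed(7)
  expr <- matrix(stats::rpois(100 * 101, 10), 100, 101)
  expr[, 101] <- 100         # one extreme cell
  tm <- trajectory_matrix(expr, pseudotime = seq(0, 1, length.out = 101))
  out <- qualify_cells_total_counts(tm)
  totals <- colSums(expr)
  lo <- mean(totals) - 2 * sd(totals); hi <- mean(totals) + 2 * sd(totals)
  expect_equal(ncol(out$expr), sum(totals >= lo & totals <= hi))
  expect_false(101 %in% which(totals >= lo & totals <= hi))

  # all-equal totals: sd = 0, everything retained (closed interval)
  eq <- trajectory_matrix(matrix(2, 5, 25),
                          pseudotime = seq(0, 1, length.out = 25))
  expect_equal(ncol(qualify_cells_total_counts(eq)$expr), 25L)

  single <- trajectory_matrix(matrix(1:5, 5, 1), pseudotime = 0.5)
  expect_warning(kept <- qualify_cells_total_counts(single), "single cell")
  expect_equal(ncol(kept$expr), 1L)
})

test_that("QC filters match independent brute-force oracles", {
  cfg <- qc_config(min_genes_per_cell = 10, min_cells_per_gene = 5)
  set.seed(123)
  for (i in 1:100) {
    expr <- random_count_matrix(50, 30, lambda = stats::runif(1, 0.5, 3))
    tm <- trajectory_matrix(expr, pseudotime = stats::runif(30))

    keep_cells <- bf_filter_cells_min_genes(expr, cfg$min_genes_per_cell)
    if (any(keep_cells)) {
      out <- filter_cells_min_genes(tm, cfg)
      expect_identical(out$expr, expr[, keep_cells, drop = FALSE])
    } else {
      expect_error(filter_cells_min_genes(tm, cfg), "every cell")
    }

    keep_genes <- bf_filter_genes_min_cells(expr, cfg$min_cells_per_gene)
    if (any(keep_genes)) {
      out <- filter_genes_min_cells(tm, cfg)
      expect_identical(out$expr, expr[keep_genes, , drop = FALSE])
    } else {
      expect_error(filter_genes_min_cells(tm, cfg), "every gene")
    }

    keep_tot <- bf_qualify_totals(expr, cfg$total_sd_window)
    out <- qualify_cells_total_counts(tm, cfg)
    expect_identical(out$expr, expr[, keep_tot, drop = FALSE])
  }
})

test_that("QC order is fixed as cells -> genes -> totals", {
  # order matters here: cell 5 sits exactly at the min-genes threshold
  # only thanks to a rare gene that the gene filter removes. Filtering
  # cells first (the fixed order) keeps cell 5; genes-first would not.
  expr <- matrix(0, 5, 5,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:5)))
  expr[1:4, 1:4] <- 3
  expr[3:5, 5] <- 3                  # cell 5 expresses g3, g4, g5
  tm <- trajectory_matrix(expr, pseudotime = seq(0, 1, length.out = 5))
  cfg <- qc_config(min_genes_per_cell = 3, min_cells_per_gene = 3,
                   total_sd_window = 100)
  out <- qc_pipeline(tm, cfg)
  expect_equal(rownames(out$expr), c("g1", "g2", "g3", "g4"))
  expect_true("c5" %in% colnames(out$expr))
  expect_equal(ncol(out$expr), 5L)
})

test_that("dynamic-gene ranking separates trajectory genes from flat ones", {
  pt <- seq(0, 1, length.out = 60)
  expr <- rbind(constant = rep(5, 60), linear = 1 + 4 * pt)
  tm <- trajectory_matrix(expr, pt)
  ranked <- rank_dynamic_genes(tm)
  expect_false("constant" %in% ranked$gene)
  expect_true("linear" %in% ranked$gene)
  expect_lt(ranked$q_value[ranked$gene == "linear"], 0.01)

  expect_error(rank_dynamic_genes(
    trajectory_matrix(matrix(1:8, 2, 4), c(0, 0, 1, 1))), "distinct")
})

test_that("selected dynamic genes are predominantly true pattern genes", {
  tm <- simulate_trajectory_matrix(n_per_class = 10, n_flat = 950,
                                   n_cells = 300, noise_sd = 0.2, seed = 5)
  ranked <- rank_dynamic_genes(tm)
  hits <- tm$true_class[ranked$gene] != "FLAT"
  expect_gte(mean(hits), 0.9)
  expect_lte(nrow(ranked), 1000L)
})

test_that("the pattern rule classifies the canonical archetypes", {
  pt <- seq(0, 1, length.out = 300)
  cases <- list(
    IMMEDIATE_DOWN = as.numeric(pt < 0.15),
    GRADUAL_DOWN = 1 - pt,
    DELAYED_UP = as.numeric(pt >= 0.85),
    GRADUAL_UP = pt,
    TIDE_WAVE = 0.5 + 0.5 * sin(2 * pi * pt),
    FLAT = rep(0.7, 300)
  )
  for (cls in names(cases)) {
    got <- classify_pattern(1 + 2 * cases[[cls]], pt)
    expect_equal(got$class, cls, info = cls)
  }
  # the sine shows exactly its two internal extrema
  expect_equal(classify_pattern(1 + 2 * cases$TIDE_WAVE, pt)$n_extrema, 2L)
  # linear decrease crosses the midpoint at one half (on its own scale)
  expect_equal(classify_pattern(1 + 2 * cases$GRADUAL_DOWN, pt,
                                log_transform = FALSE)$t_half,
               0.5, tolerance = 0.01)
})

test_that("pattern classification is invariant to positive affine maps", {
  pt <- seq(0, 1, length.out = 200)
  set.seed(8)
  y <- 1 + 2 * (1 - pt) + rnorm(200, sd = 0.1)
  base <- classify_pattern(y, pt, log_transform = FALSE)
  for (a in c(0.5, 3)) for (b in c(0, 10)) {
    got <- classify_pattern(a * y + b, pt, log_transform = FALSE)
    expect_equal(got$class, base$class)
    expect_equal(got$n_extrema, base$n_extrema)
  }
  expect_error(classify_pattern(1:5, seq(0, 1, length.out = 5)),
               "n_bins")
})

test_that("whole-matrix classification recovers generator labels", {
  # zero noise: all five template classes plus flat, perfectly recovered
  tm0 <- simulate_trajectory_matrix(n_per_class = 2, n_flat = 4,
                                    n_cells = 200, noise_sd = 0, seed = 3)
  cls0 <- classify_all(tm0)
  expect_true(all(cls0$class == cls0$true_class))
  expect_equal(sum(attr(cls0, "class_counts")), nrow(tm0$expr))

  # default noise: >= 85% of pattern genes recover their label
  tm <- simulate_trajectory_matrix(n_per_class = 10, n_flat = 50,
                                   n_cells = 300, noise_sd = 0.2,
                                   seed = 11)
  cls <- classify_all(tm)
  is_pat <- cls$true_class != "FLAT"
  expect_gte(mean(cls$class[is_pat] == cls$true_class[is_pat]), 0.85)
})
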