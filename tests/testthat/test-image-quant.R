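test_that("rendering places every cell with consistent masks and table", {
  cells <- small_cells(5)
  img <- render_image(cells, zero_noise_config(), seed = 2)
  expect_named(img$channels, c("dapi", "phalloidin", "rbp4", "sod3",
                               "ifitm3"))
  expect_equal(dim(img$nucleus_mask), dim(img$channels$dapi))

  # exactly 5 connected components in the ground-truth nucleus mask
  lab <- EBImage::bwlabel(EBImage::Image(img$nucleus_mask > 0))
  expect_equal(max(lab), 5)
  expect_true(all(tabulate(img$cell_mask[img$cell_mask > 0]) > 0))

  # uniform fill: marker channel inside each cell mask equals the input
  for (i in seq_len(5)) {
    expect_equal(mean(img$channels$rbp4[img$cell_mask == i]),
                 cells$rbp4[i], tolerance = 1e-12)
  }
  # masks vs table consistency (areas measured off the masks themselves)
  px2 <- img$pixel_size^2
  for (i in seq_len(5)) {
    expect_equal(sum(img$cell_mask == i) * px2,
                 img$cells$cell_area_um2[i], tolerance = 1e-12)
  }
})

test_that("rendering is seed-deterministic and fails loudly when full", {
  cells <- small_cells(4)
  a <- render_image(cells, small_image_config(), seed = 3)
  b <- render_image(cells, small_image_config(), seed = 3)
  expect_identical(a, b)

  big <- small_cells(4)
  big$cell_diameter_um <- rep(80, 4)   # cannot fit a 420 px canvas
  expect_error(render_image(big, small_image_config(), seed = 1),
               "canvas too small|could not place")
})

test_that("nucleus segmentation handles blank, clean and touching inputs", {
  cfg <- segmentation_config()
  expect_warning(blank <- segment_nuclei(matrix(0, 50, 50), cfg),
                 "degenerate")
  expect_equal(max(blank), 0L)
  expect_warning(segment_nuclei(matrix(3, 40, 40), cfg), "degenerate")

  cells <- small_cells(5)
  img <- render_image(cells, zero_noise_config(), seed = 2)
  lab <- segment_nuclei(img$channels$dapi, cfg)
  expect_equal(max(lab), 5)
  # per-nucleus areas within 2% of ground truth
  meas_area <- sort(tabulate(lab[lab > 0]))
  true_area <- sort(tabulate(img$nucleus_mask[img$nucleus_mask > 0]))
  expect_true(all(abs(meas_area / true_area - 1) < 0.02))

  # two overlapping discs with distinct centres split by watershed
  xy <- expand.grid(x = 1:160, y = 1:160)
  d1 <- sqrt((xy$x - 65)^2 + (xy$y - 80)^2)
  d2 <- sqrt((xy$x - 95)^2 + (xy$y - 80)^2)
  im <- matrix(0, 160, 160)
  im[cbind(xy$y, xy$x)[d1 <= 18 | d2 <= 18, ]] <- 100
  expect_equal(max(segment_nuclei(im, cfg)), 2)
  no_ws <- segmentation_config(watershed = FALSE)
  expect_equal(max(segment_nuclei(im, no_ws)), 1)
})

test_that("cell segmentation is seeded by nuclei and labels correspond", {
  cfg <- segmentation_config()
  # single nucleus seed claims the whole foreground component
  fg <- matrix(0, 60, 60); fg[20:40, 20:40] <- 50
  seeds <- matrix(0L, 60, 60); seeds[28:32, 28:32] <- 1L
  lab <- segment_cells(fg, seeds, cfg)
  expect_equal(sort(unique(as.integer(lab))), c(0L, 1L))
  expect_true(all(lab[fg > 0] == 1L))

  expect_warning(out <- segment_cells(fg, matrix(0L, 60, 60), cfg),
                 "no nucleus seeds")
  expect_equal(max(out), 0L)
  expect_error(segment_cells(fg, matrix(0L, 10, 10), cfg), "dimensions")

  cells <- small_cells(5)
  img <- render_image(cells, zero_noise_config(), seed = 2)
  nuc <- segment_nuclei(img$channels$dapi, cfg)
  cel <- segment_cells(img$channels$phalloidin, nuc, cfg)
  expect_equal(length(setdiff(unique(as.integer(cel)), 0L)), 5)
  meas_area <- sort(tabulate(cel[cel > 0]))
  true_area <- sort(tabulate(img$cell_mask[img$cell_mask > 0]))
  expect_true(all(abs(meas_area / true_area - 1) < 0.02))
})

test_that("measurement recovers uniform regions and unit conversion", {
  ch <- matrix(0, 40, 40)
  mask <- matrix(0L, 40, 40)
  mask[11:20, 11:20] <- 1L            # 100-pixel "cell"
  nuc <- matrix(0L, 40, 40); nuc[14:17, 14:17] <- 1L
  v <- 37.5
  ch[mask == 1L] <- v
  channels <- list(rbp4 = ch, sod3 = ch, ifitm3 = ch, factin = ch)
  cfg <- segmentation_config(pixel_size = 0.5, exclude_border = FALSE)
  m <- measure_cells(channels, mask, nuc, cfg)
  expect_equal(nrow(m), 1L)
  expect_equal(m$rbp4, v)
  expect_equal(m$cell_area_um2, 100 * 0.25)  # 100 px at 0.5 um/px = 25 um2
})

test_that("measurement is invariant to label renumbering", {
  cells <- small_cells(4)
  img <- render_image(cells, zero_noise_config(), seed = 6)
  cfg <- segmentation_config()
  a <- measure_cells(img$channels, img$cell_mask, img$nucleus_mask, cfg)
  # renumber labels 1..4 -> 4..1
  remap <- c(4L, 3L, 2L, 1L)
  cm <- img$cell_mask; nm <- img$nucleus_mask
  cm[img$cell_mask > 0] <- remap[img$cell_mask[img$cell_mask > 0]]
  nm[img$nucleus_mask > 0] <- remap[img$nucleus_mask[img$nucleus_mask > 0]]
  b <- measure_cells(img$channels, cm, nm, cfg)
  cols <- c("rbp4", "sod3", "ifitm3", "factin", "cell_area_um2",
            "nucleus_area_um2")
  expect_equal(a[order(a$rbp4), cols], b[order(b$rbp4), cols],
               ignore_attr = TRUE)
})

test_that("zero-noise quantification equals the generator ground truth", {
  cells <- small_cells(6, seed = 4)
  img <- render_image(cells, zero_noise_config(), seed = 4)
  meas <- quantify_image(img$channels)
  expect_equal(nrow(meas), nrow(img$cells))
  gt <- match_to_ground_truth(meas, img$cells)
  for (m in c("rbp4", "sod3", "ifitm3", "factin")) {
    expect_equal(meas[[m]], gt[[m]], tolerance = 1e-6)
  }
  expect_true(all(abs(meas$cell_area_um2 / gt$cell_area_um2 - 1) < 0.02))
  expect_true(all(abs(meas$nucleus_area_um2 / gt$nucleus_area_um2 - 1)
                  < 0.02))
  expect_true(all(meas$nucleus_area_um2 <= meas$cell_area_um2))
})

test_that("cell selection is exhaustive, seeded and guards shortfalls", {
  cells <- small_cells(20)
  sel <- select_cells(cells, k = 20, seed = 1)
  expect_setequal(sel$cell_id, cells$cell_id)
  expect_equal(sel$round, 1:20)

  many <- small_cells(50)
  s1 <- select_cells(many, k = 20, seed = 9)
  s2 <- select_cells(many, k = 20, seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1$cell_id, select_cells(many, 20, 10)$cell_id))

  expect_error(select_cells(small_cells(19), k = 20, seed = 1),
               "short by 1")
})

test_that("synthetic image bundles round-trip through TIFF/CSV", {
  cells <- small_cells(3)
  img <- render_image(cells, zero_noise_config(), seed = 8)
  dir <- tempfile()
  write_synthetic_image(img, dir)
  ch <- read_channels(file.path(dir, "channels.tiff"),
                      names(img$channels))
  # 16-bit quantization on write: within one gray level (writer truncates)
  expect_true(max(abs(ch$rbp4 - img$channels$rbp4)) <= 1 + 1e-9)
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(gt$cell_area_um2, img$cells$cell_area_um2)
})
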