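test_that("matrix assembly has deterministic shape and column order", {
  p1 <- make_test_profile("a"); p2 <- make_test_profile("b", offset = 5)
  m <- assemble_matrix(list(p1, p2))
  expect_equal(dim(m$values), c(20L, 12L))
  expect_equal(m$sample_id[1:6], rep("a", 6))
  expect_equal(m$indicator[1:6], chondro_panel())
  expect_equal(m$state, "raw")

  # permuted input order: same values up to column permutation
  m2 <- assemble_matrix(list(p2, p1))
  expect_equal(m2$values[, colnames(m$values)], m$values)

  expect_error(assemble_matrix(list()), "no profiles")
  short <- make_test_profile("c", n_rounds = 10)
  expect_error(assemble_matrix(list(p1, short)), "round count.*'c'")
})

test_that("normalization maps each indicator onto integers 0..14000", {
  # hand-computed: {5, 10, 20} -> {0, 4667, 14000}
  vals <- matrix(rep(c(5, 10, 20), 6), nrow = 3,
                 dimnames = list(NULL, chondro_panel()))
  # round count differs from default; assembly accepts consistent profiles
  p <- sample_profile("s", vals)
  nm <- normalize_matrix(assemble_matrix(list(p)))
  expect_equal(unname(nm$values[, 1]), c(0, 4667, 14000))

  # bounds and integrality on any non-constant synthetic matrix
  profs <- lapply(stage_levels(), function(s)
    simulate_sample_profile(make_stage_params(s), s, seed = match(s, stage_levels())))
  nm <- normalize_matrix(assemble_matrix(profs))
  expect_true(all(nm$values == round(nm$values)))
  for (ind in chondro_panel()) {
    v <- nm$values[, nm$indicator == ind]
    expect_equal(min(v), 0)
    expect_equal(max(v), 14000)
  }
  # monotonicity: value order preserved within indicator
  raw <- assemble_matrix(profs)
  for (ind in chondro_panel()) {
    o_raw <- order(raw$values[, raw$indicator == ind])
    v_norm <- nm$values[, nm$indicator == ind][o_raw]
    expect_true(all(diff(v_norm) >= 0))
  }
})

test_that("constant indicators normalize to zero with a warning", {
  vals <- matrix(1:20, 20, 6, dimnames = list(NULL, chondro_panel()))
  vals[, "sod3"] <- 7
  p <- sample_profile("s", vals)
  expect_warning(nm <- normalize_matrix(assemble_matrix(list(p))),
                 "sod3.*constant")
  expect_true(all(nm$values[, nm$indicator == "sod3"] == 0))
})

test_that("normalization at a fixed 0..14000 range is idempotent", {
  vals <- matrix(seq(0, 14000, length.out = 20), 20, 6,
                 dimnames = list(NULL, chondro_panel()))
  vals <- round(vals)
  p <- sample_profile("s", vals)
  nm <- normalize_matrix(assemble_matrix(list(p)))
  expect_equal(unname(nm$values), unname(vals))
})

test_that("frozen normalization projects and clips query values", {
  profs <- lapply(stage_levels(), function(s)
    simulate_sample_profile(make_stage_params(s), s, seed = match(s, stage_levels())))
  nm <- normalize_matrix(assemble_matrix(profs))
  params <- nm$norm_params

  # a reference profile maps to its own normalized columns
  q <- apply_normalization(profs[[2]], params)
  expect_equal(unname(q$values),
               unname(nm$values[, nm$sample_id == "P2"]))
  expect_equal(q$n_clipped, 0L)

  # endpoint maps to 14000; beyond-range clips and is counted
  hi <- params$max[params$indicator == "rbp4"]
  vals <- profs[[1]]$values
  vals[1, "rbp4"] <- hi
  vals[2, "rbp4"] <- hi * 2
  qp <- sample_profile("q", vals)
  qn <- apply_normalization(qp, params)
  expect_equal(unname(qn$values[1, "rbp4"]), 14000)
  expect_equal(unname(qn$values[2, "rbp4"]), 14000)
  expect_gte(qn$n_clipped, 1L)
})

test_that("round sorting is idempotent and permutation-invariant", {
  p <- make_test_profile("a")
  m <- assemble_matrix(list(p))
  m$values[, 1] <- c(3, 1, 2, m$values[4:20, 1])
  s1 <- sort_rounds(m)
  expect_equal(unname(s1$values[1:3, 1]), c(1, 2, 3))
  expect_identical(sort_rounds(s1)$values, s1$values)

  # any within-column permutation gives the identical sorted matrix
  set.seed(42)
  mp <- m
  for (j in seq_len(ncol(mp$values))) {
    mp$values[, j] <- sample(mp$values[, j])
  }
  expect_identical(sort_rounds(mp)$values, s1$values)
})

test_that("batch harmonization through the anchor is affine-exact", {
  anchor <- make_test_profile("ModelP2", stage = "P2")
  other_a <- make_test_profile("d1", offset = 3)
  batch_a <- assemble_matrix(list(anchor, other_a))

  # batch B = batch A with gain 2: harmonization restores A's scale exactly
  batch_b <- batch_a
  batch_b$values <- batch_a$values * 2
  batch_b$batch_id <- rep("batch2", length(batch_b$batch_id))
  merged <- harmonize_batches(list(batch_a, batch_b), "ModelP2")
  b_anchor_cols <- which(merged$sample_id == "ModelP2" &
                           merged$batch_id == "batch2")
  a_anchor_cols <- which(merged$sample_id == "ModelP2" &
                           merged$batch_id != "batch2")
  expect_equal(unname(merged$values[, b_anchor_cols]),
               unname(merged$values[, a_anchor_cols]))

  expect_error(harmonize_batches(list(batch_a), "ModelP2"), "at least 2")
  expect_error(harmonize_batches(list(batch_a, batch_b), "missing"),
               "absent")
})

test_that("harmonization collapses simulated gain/offset batch effects", {
  set.seed(17)
  anchor1 <- simulate_sample_profile(make_stage_params("P2"), "ModelP2",
                                     seed = 100)
  batch1 <- assemble_matrix(list(anchor1))
  # same biological sample remeasured with per-indicator gain and offset
  batch2 <- batch1
  gains <- stats::runif(6, 1.2, 2.5); offs <- stats::runif(6, 5, 40)
  for (i in seq_along(chondro_panel())) {
    cols <- batch2$indicator == chondro_panel()[i]
    batch2$values[, cols] <- batch2$values[, cols] * gains[i] + offs[i]
  }
  batch2$batch_id <- rep("batch2", length(batch2$batch_id))
  pre <- sqrt(sum((batch2$values - batch1$values)^2))
  merged <- harmonize_batches(list(batch1, batch2), "ModelP2")
  post <- sqrt(sum((merged$values[, 7:12] - merged$values[, 1:6])^2))
  expect_lt(post, 0.01 * pre)
})

test_that("profiles round-trip through long-format CSV", {
  p1 <- make_test_profile("a", stage = "P2")
  p2 <- make_test_profile("b", offset = 2)
  path <- tempfile(fileext = ".csv")
  write_profiles(list(p1, p2), path)
  back <- read_profiles(path)
  expect_equal(back[["a"]]$values, p1$values)
  expect_equal(back[["a"]]$stage, "P2")
  expect_equal(back[["b"]]$values, p2$values)
})
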