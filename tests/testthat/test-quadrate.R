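test_that("grid construction tiles the roi with fully interior cells", {
  sc <- make_scene(matrix(0L, 1000, 1000))
  g <- build_grid(sc, target_cells = 100)
  expect_equal(g$cell_side_px, 100L)
  expect_equal(nrow(g$cells), 100L)

  g1 <- build_grid(sc, target_cells = 1)
  expect_equal(g1$cell_side_px, 1000L)
  expect_equal(nrow(g1$cells), 1L)

  # disc-shaped roi: every kept cell lies inside the disc, count < target
  n <- 400
  roi <- rasterize_roi(list(type = "ellipse", centre_r = (n + 1) / 2,
                            centre_c = (n + 1) / 2, semi_r = n / 2 - 1,
                            semi_c = n / 2 - 1), n, n)
  sc2 <- make_scene(matrix(0L, n, n), roi = roi)
  g2 <- build_grid(sc2, target_cells = 100)
  expect_lt(nrow(g2$cells), 100)
  side <- g2$cell_side_px
  for (i in seq_len(nrow(g2$cells)))
    expect_true(all(roi[g2$cells$r0[i] + 0:(side - 1),
                        g2$cells$c0[i] + 0:(side - 1)]))
  expect_error(build_grid(make_scene(matrix(0L, 5, 5),
                                     roi = matrix(FALSE, 5, 5))), "empty")
})

test_that("systematic cell selection is strided, seeded and reproducible", {
  sc <- make_scene(matrix(0L, 1000, 1000))
  g <- build_grid(sc, 100)
  s <- select_cells(g, k = 10, seed = 42)
  expect_length(s$selected_ids, 10)
  expect_equal(unique(diff(s$selected_ids)), 10L)    # stride = n/k
  expect_true(all(diff(s$selected_ids) > 0))
  expect_true(s$selected_ids[1] >= 1 && s$selected_ids[1] <= 10)
  expect_identical(select_cells(g, 10, seed = 42)$selected_ids,
                   s$selected_ids)
  expect_identical(sort(select_cells(g, 100, seed = 1)$selected_ids),
                   1:100)                            # k = n takes all
  expect_error(select_cells(g, 101, seed = 1), "cannot select")
  expect_error(select_cells(g, 0, seed = 1), "positive")
  expect_error(select_cells(g, 10), "seed")
})

test_that("counting frame excludes objects crossing top or right edges only", {
  lab <- matrix(0L, 30, 30)
  lab <- place_block(lab, 14, 14, 3, 3, 1L)   # strictly inside cell
  lab <- place_block(lab, 9, 14, 4, 3, 2L)    # straddles top boundary
  lab <- place_block(lab, 14, 9, 3, 4, 3L)    # straddles left boundary
  lab <- place_block(lab, 14, 19, 3, 4, 4L)   # straddles right boundary
  lab <- place_block(lab, 19, 14, 4, 3, 5L)   # straddles bottom boundary
  sc <- make_scene(lab)
  cell <- list(r0 = 11, c0 = 11)              # cell [11,21) x [11,21)
  ids <- count_cell(sc, cell, side = 10)
  expect_identical(ids, c(1L, 3L, 5L))        # top and right crossers out

  # the left-straddler is excluded from the left neighbour (its right edge)
  expect_false(3L %in% count_cell(sc, list(r0 = 11, c0 = 1), side = 10))
  # the top-straddler belongs to the cell above
  expect_true(2L %in% count_cell(sc, list(r0 = 1, c0 = 11), side = 10))

  # full 3x3 tiling counts every object exactly once
  g <- build_grid(sc, target_cells = 9)
  census <- census_counts(sc, g)
  expect_identical(sort(census), 1:5)
})

test_that("tiling conservation holds on simulated hard-core scenes", {
  for (seed in 1:5) {
    sim <- sim_scene(roi_mm = c(1, 2), lambda = 20, radius_um = 30,
                     seed = seed)
    g <- build_grid(sim$scene, 100)
    census <- census_counts(sim$scene, g)
    expect_identical(anyDuplicated(census), 0L)
    expect_true(all(interior_tiling_ids(sim$scene, g) %in% census))
  }
})

test_that("quantification reproduces the three estimators and unit identity", {
  # one 0.01 mm^2 object inside one 1 mm^2 cell
  lab <- matrix(0L, 100, 100)                 # 1 mm^2 at 0.01 mm/px
  lab <- place_block(lab, 40, 40, 10, 10, 1L) # 100 px = 0.01 mm^2
  sc <- make_scene(lab, mm_per_px = 0.01)
  g <- select_cells(build_grid(sc, 1), 1, seed = 1)
  q <- quantify_scene(sc, g)
  expect_equal(q$sample$N_s, 1L)
  expect_equal(q$sample$A_c, 1)
  expect_equal(q$stats$density, 1)
  expect_equal(q$stats$mean_size, 10000)
  expect_equal(q$stats$coverage, 1)

  # empty scene: zero density and coverage, mean size missing
  sc0 <- make_scene(matrix(0L, 100, 100), mm_per_px = 0.01)
  q0 <- quantify_scene(sc0, select_cells(build_grid(sc0, 4), 2, seed = 1))
  expect_equal(q0$sample$N_s, 0L)
  expect_equal(q0$stats$density, 0)
  expect_equal(q0$stats$coverage, 0)
  expect_true(is.na(q0$stats$mean_size))
  expect_gt(q0$sample$A_c, 0)

  # unit identity coverage = density * mean_size * 1e-4 on random scenes
  for (seed in 1:8) {
    sim <- sim_scene(roi_mm = c(1, 2), lambda = 15, radius_um = 30,
                     seed = seed)
    g <- select_cells(build_grid(sim$scene, 100), 10, seed = seed)
    q <- quantify_scene(sim$scene, g)
    if (q$sample$N_s > 0)
      expect_equal(q$stats$coverage,
                   q$stats$density * q$stats$mean_size * 1e-4)
  }
})

test_that("an object spanning two selected cells is counted once", {
  lab <- matrix(0L, 20, 40)
  lab <- place_block(lab, 5, 18, 3, 6, 1L)    # straddles the cell boundary
  sc <- make_scene(lab, mm_per_px = 0.01)
  g <- build_grid(sc, 2)                      # two 20x20 cells
  g$selected_ids <- c(1L, 2L); g$seed <- 0L
  q <- quantify_scene(sc, g)
  expect_equal(q$sample$N_s, 1L)
})

test_that("determinism: same scene and seed give identical samples", {
  sim <- sim_scene(roi_mm = c(1, 2), lambda = 20, radius_um = 30, seed = 3)
  run <- function() {
    g <- select_cells(build_grid(sim$scene, 100), 10, seed = 99)
    quantify_scene(sim$scene, g)
  }
  expect_identical(run(), run())
})

test_that("head volume is the commutative product of head dimensions", {
  expect_equal(head_volume(10, 5, 4), 200)
  expect_equal(head_volume(1, 1, 1), 1)
  expect_equal(head_volume(4, 10, 5), head_volume(10, 5, 4))
  expect_error(head_volume(0, 5, 4), "positive")
  expect_error(head_volume(10, -5, 4), "positive")
})

test_that("species aggregation reports mean and sem, sem missing at n = 1", {
  df <- data.frame(species = c("a", "a", "a", "b", "c", "c"),
                   density = c(2, 4, 6, 5, 3, 3))
  out <- aggregate_species(df)
  a <- out[out$species == "a", ]
  expect_equal(a$n, 3L)
  expect_equal(a$density_mean, 4)
  expect_equal(a$density_sem, 2 / sqrt(3))    # sd = 2 by hand
  expect_true(is.na(out$density_sem[out$species == "b"]))
  expect_equal(out$density_sem[out$species == "c"], 0)
  expect_error(aggregate_species(data.frame()), "non-empty")
})
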