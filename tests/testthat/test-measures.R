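test_that("morphometrics follow their definitions exactly", {
  # degenerate cyst: one cell of area 82, no lumen
  st <- empty_state(20, 20)
  st <- add_object(st, hex_disc_sites(82, 10, 10), kind = "cell")
  m <- measure(st)
  expect_equal(m$cell_number, 1)
  expect_equal(m$cyst_area, 82)
  expect_equal(m$cellular_to_cyst_ratio, 1)
  expect_equal(m$mean_cell_area, 82)
  expect_equal(m$lumen_count, 0)

  # ring cyst arithmetic
  st2 <- ring_state(width = 40, n_cells = 8)
  o <- st2$objects
  m2 <- measure(st2)
  expect_equal(m2$cell_number, 8)
  expect_equal(m2$cyst_area, sum(o$A))
  expect_equal(m2$lumen_area, o$A[1])
  expect_equal(m2$mean_cell_area, (sum(o$A) - o$A[1]) / 8)
  expect_equal(m2$cellular_to_cyst_ratio, (sum(o$A) - o$A[1]) / sum(o$A))
  expect_true(m2$is_single_lumen)
  expect_true(m2$is_slsl)
  # the cyst perimeter equals the boundary of the non-matrix region
  per <- 0
  occ <- which(st2$owner != 0L, arr.ind = TRUE)
  for (k in 1:6) {
    nb <- owner_vec(st2, occ[, 1] - 1L + HEX_DC_T[k], occ[, 2] - 1L + HEX_DR_T[k])
    per <- per + sum(nb == 0L)
  }
  expect_equal(m2$cyst_perimeter, per)
})

test_that("metrics recomputed from an exported snapshot match the live values", {
  p <- resolve_params("control")
  r <- run_simulation(p, n_days = 3, seed = 12)
  live <- measure(r$final_state)
  f <- tempfile(fileext = ".txt")
  snapshot_write(r$final_state, f)
  reloaded <- measure(snapshot_read(f))
  unlink(f)
  for (col in c("cell_number", "cyst_area", "lumen_area", "cyst_perimeter",
                "mean_cell_area", "cellular_to_cyst_ratio", "lumen_count",
                "is_single_lumen", "is_slsl")) {
    expect_equal(reloaded[[col]], live[[col]], info = col)
  }
})

test_that("SLSL requires one lumen and full bilateral contact of every cell", {
  st <- ring_state(width = 40, n_cells = 6)
  expect_true(classify_slsl(st))

  # an interior cell without matrix contact breaks SLSL
  st2 <- ring_state(width = 40, lumen_r = 3, outer_r = 8, n_cells = 6)
  lum_sites <- object_sites(st2, 1)
  patch <- lum_sites[hex_distance(lum_sites$col, lum_sites$row, 20, 20) >= 3, ][1:6, ]
  st2$owner[cbind(patch$col + 1, patch$row + 1)] <- 0L
  st2$objects$A[1] <- st2$objects$A[1] - 6L
  st2 <- add_object(st2, patch, kind = "cell", cell_state = "polarized")
  expect_false(classify_slsl(st2))

  # two lumens are never SLSL even with full contact
  st3 <- ring_state(width = 40, n_cells = 6)
  one <- object_sites(st3, 4)[1, ]
  st3$owner[one$col + 1, one$row + 1] <- 0L
  st3$objects$A[4] <- st3$objects$A[4] - 1L
  st3 <- add_object(st3, one, kind = "lumen")
  expect_equal(measure(st3)$lumen_count, 2)
  expect_false(classify_slsl(st3))
})

test_that("physical scaling multiplies areas by 2.25 and perimeters by 0.75", {
  p <- sim_params()
  m <- data.frame(cyst_area = 100, lumen_area = 40, mean_cell_area = 10,
                  cyst_perimeter = 40, cellular_to_cyst_ratio = 0.6)
  s <- scale_to_physical(m, p)
  expect_equal(s$cyst_area, 225)
  expect_equal(s$cyst_perimeter, 30)
  expect_equal(s$cellular_to_cyst_ratio, 0.6)
  # linearity
  m2 <- m; m2$cyst_area <- 60
  expect_equal(scale_to_physical(m, p)$cyst_area +
                 scale_to_physical(m2, p)$cyst_area,
               scale_to_physical(data.frame(cyst_area = 160), p)$cyst_area)
})

test_that("batch summaries equal a hand computation on a small fixture", {
  mk <- function(cells, lum_n, slsl) {
    data.frame(day = 0:1, cell_number = cells, cyst_area = cells * 50,
               lumen_area = 10, cyst_perimeter = 30,
               mean_cell_area = 45, cellular_to_cyst_ratio = 0.9,
               lumen_count = lum_n, is_single_lumen = lum_n == 1,
               is_slsl = slsl, has_dying_matrix_contact = FALSE,
               has_dying_no_matrix = c(FALSE, TRUE))
  }
  traj <- list(mk(c(2, 4), c(1, 1), c(TRUE, TRUE)),
               mk(c(2, 6), c(0, 2), c(FALSE, FALSE)),
               mk(c(2, 5), c(1, 1), c(FALSE, TRUE)))
  s <- batch_summaries(traj)
  expect_equal(s$n, c(3, 3))
  expect_equal(s$cell_number_mean, c(2, 5))
  expect_equal(s$cell_number_sd, c(0, 1))
  expect_equal(s$cell_number_cov, c(0, 0.2))
  expect_equal(s$pct_single_lumen, c(100 * 2 / 3, 100 * 2 / 3))
  expect_equal(s$pct_multi_lumen, c(0, 100 / 3))
  expect_equal(s$pct_slsl, c(100 / 3, 100 * 2 / 3))
  expect_equal(s$pct_dying_no_matrix, c(0, 100))
  # identical replicates: zero SD and CoV
  s0 <- batch_summaries(list(mk(c(3, 3), 1, TRUE), mk(c(3, 3), 1, TRUE)))
  expect_equal(s0$cell_number_sd, c(0, 0))
  expect_error(batch_summaries(list(mk(c(1, 1), 1, TRUE))), "two replicates")
})

test_that("dying durations pair start and completion per replicate and cell", {
  ev <- data.frame(
    replicate = c(1, 1, 1, 2, 2),
    cycle = c(10, 19, 30, 5, 18),
    id = c(4, 4, 7, 4, 4),
    event = c("death_start", "death_complete", "death_start",
              "death_start", "death_complete"))
  d <- mean_dying_duration(ev)
  expect_equal(d$n, 2)
  expect_equal(sort(d$durations), c(9, 13))
  expect_equal(d$mean, 11)
  dh <- mean_dying_duration(ev, units = "hours")
  expect_equal(dh$mean, 5.5)
})
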