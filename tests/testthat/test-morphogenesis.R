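test_that("the wedge rule drives the target area as specified", {
  p <- sim_params()
  # no lumen contact: target moves to the ideal wedge area
  expect_equal(target_area_update(60, 6, 0, p), 82)
  # hand evaluation: A=60, M=6, L=3 -> W = 60*36/27 = 80, TA = 60 + 2 = 62
  expect_equal(wedge_area(60, 6, 3), 80)
  expect_equal(target_area_update(60, 6, 3, p), 62)
  # W equal to the ideal leaves TA at the current area
  expect_equal(target_area_update(41, 2, sqrt(2), p), 41)  # W = 82: fixed point
  A <- 41; M <- 4; L <- 2
  W <- wedge_area(A, M, L)
  expect_equal(target_area_update(A, M, L, p), min(82, max(1, A + 82 - W)))
  # L >= M: diverging wedge clamps the target at its floor
  expect_equal(target_area_update(40, 2, 5, p), 1)
  # apical-only cell keeps its area
  expect_equal(target_area_update(40, 0, 5, p), 40)
  # error case M = 0, L = 0: no wedge, target moves to wedgeArea
  expect_equal(wedge_area(30, 0, 0), 30)
  expect_equal(target_area_update(30, 0, 0, p), 82)
})

test_that("stabilized cells hold a small area that grows slightly with lumen contact", {
  p <- sim_params()
  expect_equal(stabilized_target_area(0, p), 48)
  L <- seq(0, 20, by = 2)
  ta <- vapply(L, stabilized_target_area, 1, params = p)
  expect_true(all(diff(ta) >= 0))
  p0 <- sim_params(stable_area_slope = 0)
  expect_true(all(vapply(L, stabilized_target_area, 1, params = p0) == 48))
})

test_that("the target perimeter is the scaled circle perimeter of the current area", {
  p1 <- sim_params(k_perim = 1)
  expect_equal(target_perimeter(82, p1), 0.6 * 2 * sqrt(pi * 82))
  expect_equal(round(target_perimeter(82, p1), 2), 19.26)
  p <- sim_params()
  expect_equal(target_perimeter(50, p), target_perimeter(50, p))
  expect_equal(target_perimeter(4 * 50, p) / target_perimeter(50, p), 2)
  # stretch is zero for relaxed cells and positive above target
  expect_equal(cell_stretch(30, 30), 0)
  expect_equal(cell_stretch(20, 30), 0)
  expect_equal(cell_stretch(45, 30), 0.5)
})

test_that("polarization counters start on first matrix contact within the specified bounds", {
  p <- sim_params(width = 20, height = 20, attempts_factor = 0)
  draws <- sapply(1:40, function(s) {
    st <- empty_state(20, 20)
    st <- add_object(st, hex_disc_sites(20, 10, 10), kind = "cell",
                     TA = 20, TP = target_perimeter(20), cycle_counter = 500)
    set.seed(s)
    out <- run_cycle(st, p)
    out$state$objects$polar_counter[1]
  })
  expect_true(all(draws >= 0.75 * 42 & draws <= 1.25 * 42))
  expect_gt(max(draws) - min(draws), 5)   # genuinely random draws
  # a cell never contacting matrix (enclosed by lumen) never polarizes
  st2 <- empty_state(30, 30)
  ctr_sites <- hex_disc_sites(7, 15, 15)
  st2 <- add_object(st2, ctr_sites, kind = "cell", TA = 7,
                    TP = target_perimeter(7), cycle_counter = 1e4)
  all60 <- hex_disc_sites(60, 15, 15)
  ann <- all60[!paste(all60$col, all60$row) %in%
                 paste(ctr_sites$col, ctr_sites$row), ]
  st2 <- add_object(st2, ann, kind = "lumen", TA = nrow(ann))
  set.seed(6)
  out <- run_cycle(st2, sim_params(width = 30, height = 30,
                                    attempts_factor = 0,
                                    death_rate_lumen = 0), 20)
  o <- out$state$objects
  expect_false(o$polar_started[1])
  expect_equal(o$state[1], 0L)
})

test_that("the cell cycle decrements only above the doubling threshold and slowly when stabilized", {
  p <- sim_params(width = 20, height = 20, attempts_factor = 0,
                   death_rate_epi = 0, death_rate_lumen = 0)
  # A = 20 <= doubling_area/2 = 20.5: counter frozen
  st <- empty_state(20, 20)
  st <- add_object(st, hex_disc_sites(20, 10, 10), kind = "cell",
                   TA = 20, TP = target_perimeter(20), cycle_counter = 400)
  st$cycle <- 10L
  set.seed(1)
  out <- run_cycle(st, p, 50)
  expect_equal(out$state$objects$cycle_counter[1], 400)

  # non-stabilized cell above the threshold decrements every cycle
  st2 <- empty_state(20, 20)
  st2 <- add_object(st2, hex_disc_sites(30, 10, 10), kind = "cell",
                    TA = 30, TP = target_perimeter(30), cycle_counter = 400)
  st2$cycle <- 10L
  set.seed(1)
  out2 <- run_cycle(st2, p, 50)
  expect_equal(out2$state$objects$cycle_counter[1], 350)

  # stabilized cell decrements with probability 1 - stable_cycle_delay
  st3 <- empty_state(20, 20)
  st3 <- add_object(st3, hex_disc_sites(30, 10, 10), kind = "cell",
                    cell_state = "stabilized", TA = 30,
                    TP = target_perimeter(30), cycle_counter = 1e4)
  st3$cycle <- 10L
  set.seed(2)
  out3 <- run_cycle(st3, p, 400)
  dec <- 1e4 - out3$state$objects$cycle_counter[1]
  se <- sqrt(400 * 0.15 * 0.85)
  expect_lt(abs(dec - 0.15 * 400), 3 * se)
})

test_that("division halves the area, stores midbodies and jitters the daughter's polarity clock", {
  p <- sim_params(width = 40, height = 40)
  st <- ring_state(width = 40)
  st$objects$polar_counter[3] <- 30
  st$objects$polar_started[3] <- TRUE
  pre_centroid <- centroid(st, 3)
  A0 <- st$objects$A[3]
  set.seed(10)
  res <- divide_cell(st, p, 3)
  expect_gt(res$daughter, 0)
  s2 <- res$state
  a_parent <- s2$objects$A[3]
  a_daughter <- s2$objects$A[res$daughter]
  expect_equal(a_parent + a_daughter, A0)
  expect_lte(abs(a_parent - a_daughter), 1)
  expect_gte(a_parent, a_daughter)
  expect_equal(unname(c(s2$objects$mb_x[3], s2$objects$mb_y[3])),
               unname(pre_centroid), tolerance = 1e-9)
  expect_equal(s2$objects$mb_x[res$daughter], s2$objects$mb_x[3])
  # both counters redrawn on [0.75, 1.25] * cell_cycle (after first division)
  expect_true(s2$objects$cycle_counter[3] >= 0.75 * 70 - 1e-9)
  expect_true(s2$objects$cycle_counter[3] <= 1.25 * 70 + 1e-9)
  # daughter polarity clock centered on the parent's
  set.seed(123)
  deltas <- replicate(400, {
    r <- divide_cell(st, p, 3)
    r$state$objects$polar_counter[r$daughter] - 30
  })
  expect_true(all(abs(deltas) <= 0.5 * 42 + 1e-9))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se + 1e-9)
})

test_that("the reversed division axis is perpendicular to the oriented axis", {
  st <- ring_state(width = 40)
  p1 <- sim_params(width = 40, height = 40, division_reg = 1)
  p3 <- sim_params(width = 40, height = 40, division_reg = 3)
  set.seed(5); ax1 <- division_axis(st, p1, 3)
  set.seed(5); ax3 <- division_axis(st, p3, 3)
  expect_lt(abs(sum(ax1 * ax3)), 1e-9)
  # one-site cells defer division
  st1 <- empty_state(9, 9)
  st1 <- add_object(st1, data.frame(col = 4, row = 4), kind = "cell")
  res <- divide_cell(st1, sim_params(width = 9, height = 9), 1)
  expect_equal(res$daughter, 0)
})

test_that("oriented division axes point at the lumen while random axes are isotropic", {
  st <- ring_state(width = 40)
  ctr <- centroid(st, 1)
  p1 <- sim_params(width = 40, height = 40, division_reg = 1)
  p0 <- sim_params(width = 40, height = 40, division_reg = 0)
  set.seed(8)
  for (id in 2:7) {
    ax <- division_axis(st, p1, id)
    cellc <- centroid(st, id)
    radial <- (ctr - cellc) / sqrt(sum((ctr - cellc)^2))
    # mode-1 axis aligned with the centroid -> lumen-centroid direction
    expect_gt(abs(sum(ax * radial)), 0.97)
  }
  angs <- replicate(200, { a <- division_axis(st, p0, 2); atan2(a[2], a[1]) })
  expect_gt(diff(range(angs)), 5)   # spans the circle
})

test_that("death initiation follows the contact-dependent rates and shrinkage the staircase", {
  # zero rates: nothing ever dies
  p0 <- resolve_params("control", overrides = list(death_rate_epi = 0,
                                                   death_rate_lumen = 0))
  r <- run_simulation(p0, n_days = 3, seed = 2)
  expect_false(any(r$events$event %in% c("death_start", "death_complete")))

  # matrix-contacting death frequency ~ death_rate_epi
  p <- sim_params(width = 20, height = 20, attempts_factor = 0,
                   death_rate_epi = 0.02, death_rate_lumen = 0)
  starts <- 0; trials <- 0
  for (s in 1:10) {
    st <- empty_state(20, 20)
    st <- add_object(st, hex_disc_sites(20, 10, 10), kind = "cell",
                     TA = 20, TP = target_perimeter(20), cycle_counter = 1e4)
    st$cycle <- 10L
    set.seed(s + 50)
    out <- run_cycle(st, p, 200)
    ev <- out$events
    d <- ev$cycle[ev$event == "death_start"]
    if (length(d)) { starts <- starts + 1; trials <- trials + d[1] }
    else trials <- trials + 200
  }
  rate <- starts / trials
  se <- sqrt(0.02 * 0.98 / trials)
  expect_lt(abs(rate - 0.02), 3 * se)

  # dying target-area staircase: 82 -> 73 -> ... -> 0 after 10 decrements
  pd <- sim_params(width = 20, height = 20, attempts_factor = 0,
                    death_rate_epi = 0, death_rate_lumen = 0)
  st <- empty_state(20, 20)
  st <- add_object(st, hex_disc_sites(20, 10, 10), kind = "cell",
                   TA = 82, TP = target_perimeter(20), dying = TRUE,
                   cycle_counter = 1e4)
  tas <- numeric(11)
  for (i in 1:11) {
    out <- run_cycle(st, pd)
    st <- out$state
    tas[i] <- st$objects$TA[1]
  }
  expect_equal(tas, c(73, 64, 55, 46, 37, 28, 19, 10, 1, 0, 0))
})

test_that("lumen creation requires the specified local conditions", {
  # two adjacent polarized matrix-contacting cells, neither touching lumen,
  # midbody inside the cluster -> exactly one new 1-site lumen
  p <- sim_params(width = 20, height = 20, attempts_factor = 0,
                   death_rate_epi = 0, death_rate_lumen = 0)
  mk <- function(state1 = "polarized", state2 = "polarized") {
    st <- empty_state(20, 20)
    ctr <- unlist(hex_xy(10, 10))
    left <- hex_disc_sites(40, 10, 10)
    xy <- hex_xy(left$col, left$row)
    side1 <- left[xy$x <= ctr[1], ]
    side2 <- left[xy$x > ctr[1], ]
    st <- add_object(st, side1, kind = "cell", cell_state = state1,
                     TA = nrow(side1), TP = target_perimeter(nrow(side1)),
                     cycle_counter = 1e4, midbody = ctr)
    st <- add_object(st, side2, kind = "cell", cell_state = state2,
                     TA = nrow(side2), TP = target_perimeter(nrow(side2)),
                     cycle_counter = 1e4, midbody = ctr)
    st$cycle <- 10L
    st$first_division_done <- TRUE
    st
  }
  st <- mk()
  set.seed(1)
  out <- run_cycle(st, p)
  o <- out$state$objects
  expect_equal(sum(o$kind == 1 & o$alive), 1)
  expect_equal(o$A[o$kind == 1 & o$alive], 1)
  expect_true("lumen_create" %in% out$events$event)

  # an unpolarized partner blocks creation
  st2 <- mk(state2 = "unpolarized")
  set.seed(1)
  out2 <- run_cycle(st2, p)
  expect_equal(sum(out2$state$objects$kind == 1), 0)

  # stabilized cells meeting all geometric conditions create nothing
  st3 <- mk(state1 = "stabilized", state2 = "stabilized")
  set.seed(1)
  out3 <- run_cycle(st3, p)
  expect_equal(sum(out3$state$objects$kind == 1), 0)

  # a cell already contacting a lumen creates nothing new
  st4 <- ring_state(width = 30, n_cells = 4)
  set.seed(1)
  out4 <- run_cycle(st4, sim_params(width = 30, height = 30,
                                     attempts_factor = 0,
                                     death_rate_epi = 0,
                                     death_rate_lumen = 0))
  expect_equal(sum(out4$state$objects$kind == 1 & out4$state$objects$alive), 1)
})

test_that("the cell state machine only moves forward", {
  p <- resolve_params("control")
  r <- run_simulation(p, n_days = 6, seed = 31)
  ev <- r$events
  # per cell: polarize at most once, stabilize at most once, and any
  # stabilize after the polarize
  for (id in unique(ev$id[ev$event %in% c("polarize", "stabilize")])) {
    pol <- ev$cycle[ev$id == id & ev$event == "polarize"]
    stab <- ev$cycle[ev$id == id & ev$event == "stabilize"]
    expect_lte(length(pol), 1)
    expect_lte(length(stab), 1)
    if (length(stab) && length(pol)) expect_gt(stab, pol)
  }
  # dying is absorbing: death_start at most once per cell
  expect_false(any(duplicated(ev$id[ev$event == "death_start"])))
})
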