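test_that("the +/-25 percent window reproduces the printed day-3 bounds", {
  w <- window25(8.9)
  expect_equal(unname(w), c(6.675, 11.125))
  expect_equal(round(unname(w), 1), c(6.7, 11.1))
  expect_equal(unname(window25(100)), c(75, 125))
  expect_equal(diff(window25(40)), c(high = 0.5 * 40))
  expect_error(window25(0), "positive")
  expect_error(window25(-3), "positive")
})

test_that("SM1 counts the in-window fraction and applies the 9-of-10-day rule", {
  ref <- data.frame(day = 0:10, mean = 10)
  # all replicates on the reference mean pass every day
  sim <- expand.grid(day = 0:10, rep = 1:5)
  sim$value <- 10
  r <- sm1(sim[, c("day", "value")], ref)
  expect_true(all(r$per_day$fraction == 1))
  expect_true(r$pass)
  # everything at twice the mean fails
  sim2 <- sim; sim2$value <- 20
  r2 <- sm1(sim2[, c("day", "value")], ref)
  expect_true(all(r2$per_day$fraction == 0))
  expect_false(r2$pass)
  # hand-counted fixture: 7 of 10 values inside (6.675, 11.125)
  vals <- c(7, 8, 9, 10, 11, 12, 5, 6.8, 11.0, 13)
  r3 <- sm1(data.frame(day = 3, value = vals),
            data.frame(day = 3, mean = 8.9))
  expect_equal(r3$per_day$fraction, 0.7)
  expect_error(sm1(data.frame(day = 4, value = 1),
                   data.frame(day = 3, mean = 8.9)), "day")
})

test_that("SM1 equals a brute-force counting oracle on random fixtures", {
  set.seed(15)
  for (rep in 1:25) {
    mu <- runif(1, 5, 50)
    vals <- runif(30, 0.5 * mu, 1.6 * mu)
    r <- sm1(data.frame(day = 1, value = vals),
             data.frame(day = 1, mean = mu))
    expect_equal(r$per_day$fraction, oracle_sm1_fraction(vals, mu))
  }
})

test_that("SM2 compares coefficients of variation with the prespecified verdicts", {
  set.seed(2)
  ref <- data.frame(day = 1:10, mean = 10, sd = 2)           # CoV 0.2
  sim <- do.call(rbind, lapply(1:10, function(d)
    data.frame(day = d, value = rnorm(40, 10, 2))))
  r <- sm2(sim, ref)
  expect_true(all(r$per_day$sm2 < 0.15))
  expect_equal(r$verdict, "strong")
  # a constant CoV offset of 0.2 gives medium (passes < 0.25, fails < 0.15)
  r2 <- list(per_day = data.frame(day = 1:10, sm2 = 0.2))
  ref4 <- data.frame(day = 1:10, mean = 10, sd = 4)          # CoV 0.4
  sim2 <- do.call(rbind, lapply(1:10, function(d) {
    v <- rnorm(200, 10, 2)
    data.frame(day = d, value = 10 + (v - mean(v)) * 2 / sd(v))  # exact CoV 0.2
  }))
  r2 <- sm2(sim2, ref4)
  expect_true(all(abs(r2$per_day$sm2 - 0.2) < 1e-9))
  expect_equal(r2$verdict, "medium")
  # symmetry in the two series
  expect_equal(abs(0.2 - 0.4), abs(0.4 - 0.2))
  expect_error(sm2(data.frame(day = 1, value = c(1, 2)),
                   data.frame(day = 1, mean = 10)), "SD")
})

test_that("SSM1 is SM1 of the reference against itself", {
  raw <- data.frame(day = rep(1:3, each = 4), value = rep(c(10, 20, 30), each = 4))
  r <- ssm1(raw)
  expect_true(all(r$per_day$fraction == 1))
  set.seed(9)
  raw2 <- data.frame(day = 1, value = runif(50, 2, 20))
  ref2 <- data.frame(day = 1, mean = mean(raw2$value))
  expect_equal(ssm1(raw2)$per_day$fraction,
               sm1(raw2, ref2)$per_day$fraction)
  # uniform values over (0.5m, 1.5m) fall inside the window half the time
  set.seed(33)
  m <- 100
  raw3 <- data.frame(day = 1, value = runif(4000, 0.5 * m, 1.5 * m))
  f <- ssm1(raw3)$per_day$fraction
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 4000) + 0.02)
})

test_that("strengthening thresholds never turns a failing verdict into a pass", {
  set.seed(21)
  verdict_at <- function(sm2_vals, strong, medium) {
    if (sum(sm2_vals < strong) >= 9) "strong"
    else if (sum(sm2_vals < medium) >= 8) "medium"
    else "fail"
  }
  rank <- c(fail = 0, medium = 1, strong = 2)
  for (rep in 1:50) {
    v <- runif(10, 0, 0.4)
    base <- verdict_at(v, 0.15, 0.25)
    tighter <- verdict_at(v, 0.10, 0.20)
    expect_lte(rank[tighter], rank[base])
  }
})

test_that("reference tables round-trip and are validated", {
  ref <- data.frame(day = rep(0:5, 2),
                    metric = rep(c("cell_number", "cyst_area"), each = 6),
                    mean = c(2 * 1.6^(0:5), 200 * 1.5^(0:5)))
  ref$sd <- ref$mean * 0.25
  f <- tempfile(fileext = ".csv")
  write.csv(ref, f, row.names = FALSE)
  back <- read_reference_series(f)
  expect_equal(back$mean, ref$mean)
  bad <- ref[ref$day != 3, ]
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_reference_series(f), "contiguous")
  unlink(f)
})

test_that("sm_report scores every shared metric of a batch", {
  set.seed(44)
  ref <- data.frame(day = rep(1:10, 2),
                    metric = rep(c("cell_number", "cyst_area"), each = 10),
                    mean = c(2 * 1.35^(1:10), 150 * 1.45^(1:10)))
  ref$sd <- ref$mean * 0.3
  traj <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(replicate = i, day = 1:10,
               cell_number = 2 * 1.35^(1:10) * runif(10, 0.9, 1.1),
               cyst_area = 150 * 1.45^(1:10) * runif(10, 0.9, 1.1))
  }))
  rep <- sm_report(traj, ref)
  expect_setequal(rep$summary$metric, c("cell_number", "cyst_area"))
  expect_true(all(rep$summary$sm1_pass))
  expect_true(all(rep$cell_number$sm1$per_day$fraction >= 0.5))
})
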