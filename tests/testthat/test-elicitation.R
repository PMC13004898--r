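test_that("CRRA utility evaluates the power/log family correctly", {
  expect_equal(crra_value(10, 0), 10)
  expect_equal(crra_value(exp(1), 1), 1)
  expect_equal(crra_value(28, 2), -1 / 28)
  # raw CRRA utility diverges at r = 1; what choice inversion relies on is
  # continuity of utility *differences* across the log case
  du <- function(r) crra_value(36, r) - crra_value(24, r)
  expect_equal(du(1 - 1e-7), log(36) - log(24), tolerance = 1e-5)
  expect_equal(du(1 + 1e-7), log(36) - log(24), tolerance = 1e-5)
  expect_equal(du(1), log(36) - log(24))
  expect_error(crra_value(-3, 0.5), "positive")
  expect_error(lottery_eu(lottery(-2, 28, "D"), 0.5), "D")
})

test_that("lottery expected utility averages the two outcomes", {
  expect_equal(lottery_eu(lottery(28, 28), 0), 28)
  expect_equal(lottery_eu(lottery(24, 36), 0), 30)
  expect_equal(lottery_eu(lottery(12, 60), 0.5),
               0.5 * (2 * sqrt(12) + 2 * sqrt(60)))
})

test_that("adjacent-lottery indifference points solve the menu", {
  menu <- beg_menu()
  r_ab <- indifference_r(menu$lotteries[[1]], menu$lotteries[[2]])
  r_cd <- indifference_r(menu$lotteries[[3]], menu$lotteries[[4]])
  r_ef <- indifference_r(menu$lotteries[[5]], menu$lotteries[[6]])
  expect_equal(round(r_ab, 2), 3.46)
  expect_equal(round(r_cd, 2), 0.71)
  expect_lt(abs(r_ef), 1e-6)
  expect_error(indifference_r(lottery(5, 9), lottery(5, 9)), "identical")
  expect_error(indifference_r(lottery(10, 10), lottery(11, 11)), "sign")
})

test_that("menu inversion partitions the real line", {
  iv <- menu_crra_intervals(beg_menu())
  expect_equal(iv$upper[1], Inf)
  expect_equal(iv$lower[nrow(iv)], -Inf)
  # adjacent intervals share endpoints and are ordered
  expect_equal(iv$lower[-nrow(iv)], iv$upper[-1])
  expect_true(all(iv$lower <= iv$upper))
  # zero (risk neutrality) lies in exactly one interval under left-closure
  inside <- iv$lower <= 0 & 0 < iv$upper
  expect_equal(sum(inside), 1L)
  # two-lottery menu: two half-lines meeting at the single root
  m2 <- lottery_menu(lottery(28, 28), lottery(24, 36))
  iv2 <- menu_crra_intervals(m2)
  expect_equal(iv2$lower[1], iv2$upper[2])
  # a shuffled (non-monotone) menu is rejected
  bad <- lottery_menu(lottery(16, 52), lottery(28, 28), lottery(24, 36))
  expect_error(menu_crra_intervals(bad), "decreasing")
})

test_that("lottery moments use the two-point n-1 convention", {
  m <- lottery_moments(lottery(24, 36))
  expect_equal(m$expected_value, 30)
  expect_equal(m$std_dev, 12 / sqrt(2))
  expect_equal(lottery_moments(lottery(10, 10))$std_dev, 0)
  expect_gt(lottery_moments(lottery(-2, 28))$std_dev, 0)
})

test_that("exponential discount bounds invert PV = FV/(1+d)^t", {
  expect_equal(round(weekly_discount_bound(25, 28, 2.43), 4), 0.0477)
  expect_equal(round(weekly_discount_bound(25, 45, 6.71), 4), 0.0915)
  expect_equal(weekly_discount_bound(25, 25, 3), 0)
  expect_error(weekly_discount_bound(-1, 10, 2), "positive")
})

test_that("MPL first-switch coding brackets the discount rate", {
  p <- load_instruments()$mpl_panels$one_month
  b <- mpl_bounds(p)
  iv <- mpl_interval(c("A", "A", "A", "A", "B", "B"), p)
  expect_equal(round(c(iv$lower, iv$upper), 4), c(0.1069, 0.1485))
  expect_true(iv$consistent)
  all_a <- mpl_interval(rep("A", 6), p)
  expect_equal(round(all_a$lower, 4), 0.1880)
  expect_equal(all_a$upper, Inf)
  all_b <- mpl_interval(rep("B", 6), p)
  expect_equal(all_b$lower, -Inf)
  expect_equal(all_b$upper, b[1])
  zig <- mpl_interval(c("A", "B", "A", "B", "B", "B"), p)
  expect_false(zig$consistent)
  expect_equal(zig$switch_row, 2L)
  expect_equal(c(zig$lower, zig$upper), c(b[1], b[2]))
  expect_error(mpl_interval(character(0), p), "empty")
  expect_error(mpl_interval(c("A", "B"), p), "expected")
})

test_that("binary codings follow the instrument definitions", {
  expect_equal(la_binary(c(1, 3, 4, 6)), c(1, 1, 0, 0))
  expect_error(la_binary(7), "1..6")
  # horizons beyond the next year count as long
  expect_equal(planning_binary(c(0, 3, 4, 6)), c(0, 0, 1, 1))
  expect_error(planning_binary(9), "0..6")
})

test_that("disadvantage index applies threshold and missingness policy", {
  expect_equal(disadvantage_index(c(1, 1, 0, 0))$binary, 1L)
  expect_equal(disadvantage_index(c(1, 1, 0, 0))$count, 2L)
  mz <- disadvantage_index(c(0, NA, 0, 0))
  expect_equal(mz$count, 0L)
  expect_equal(mz$binary, 0L)
  expect_equal(disadvantage_index(c(1, 1, 1, 1))$count, 4L)
  mi <- disadvantage_index(rbind(c(0, NA, 1, 1), c(1, 0, 0, 0)),
                           policy = "missing_indicator")
  expect_equal(mi$any_missing, c(1L, 0L))
  expect_equal(mi$binary, c(1L, 0L))
  cc <- disadvantage_index(rbind(c(0, NA, 1, 1), c(1, 1, 0, 0)),
                           policy = "complete_case")
  expect_equal(cc$exclude, c(1L, 0L))
  expect_true(is.na(cc$binary[1]))
  # configurable threshold
  expect_equal(disadvantage_index(c(1, 0, 0, 0), threshold = 1)$binary, 1L)
})

test_that("round trip: EU-argmax menu choice lands in the inferred interval", {
  menu <- beg_menu()
  iv <- menu_crra_intervals(menu)
  pow <- function(x, r) if (abs(1 - r) < 1e-9) log(x) else x^(1 - r) / (1 - r)
  set.seed(101)
  rs <- runif(400, -5, 5)
  # keep away from interval boundaries where the argmax ties
  bounds <- iv$lower[is.finite(iv$lower)]
  rs <- rs[vapply(rs, function(r) min(abs(r - bounds)) > 1e-3, logical(1))]
  for (r in rs) {
    eus <- vapply(menu$lotteries, function(l)
      0.5 * (pow(l$low, r) + pow(l$high, r)), numeric(1))
    k <- which.max(eus)
    expect_true(iv$lower[k] <= r && r < iv$upper[k])
  }
})

test_that("round trip: monotone MPL rule yields an interval containing d", {
  p <- load_instruments()$mpl_panels$two_month
  b <- mpl_bounds(p)
  set.seed(202)
  ds <- runif(400, -0.5, 0.3)
  for (d in ds) {
    choice <- ifelse(b > d, "B", "A")   # future option when its rate beats d
    iv <- mpl_interval(choice, p)
    expect_true(iv$consistent)
    expect_true(iv$lower <= d && d <= iv$upper)
  }
})
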