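test_that("dice_score matches hand-derived cases and conventions", {
  a <- matrix(0, 4, 4); a[2:3, 2:3] <- 1
  expect_equal(dice_score(a, a), 1)

  b <- matrix(0, 4, 4); b[1, 1] <- 1
  d <- matrix(0, 4, 4); d[4, 4] <- 1
  expect_equal(dice_score(b, d), 0)

  # X = {(1,1),(1,2)}, Y = {(1,2),(1,3)}: overlap 1, sizes 2+2
  x <- matrix(0, 3, 3); x[1, 1:2] <- 1
  y <- matrix(0, 3, 3); y[1, 2:3] <- 1
  expect_equal(dice_score(x, y), 0.5)

  expect_equal(dice_score(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  expect_error(dice_score(matrix(0, 2, 2), matrix(0, 3, 2)), "mismatch")
  expect_error(dice_score(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("assd matches hand-derived cases and rejects empty masks", {
  a <- matrix(0, 5, 5); a[2:3, 2:3] <- 1
  expect_equal(assd(a, a), 0)

  m1 <- matrix(0, 3, 7); m1[2, 2] <- 1
  m2 <- matrix(0, 3, 7); m2[2, 5] <- 1
  expect_equal(assd(m1, m2), 3)

  # 1-px-thick bar translated perpendicularly by 1: every surface point is
  # exactly 1 away from the other surface
  b1 <- matrix(0, 6, 9); b1[2, 2:6] <- 1
  b2 <- matrix(0, 6, 9); b2[3, 2:6] <- 1
  expect_equal(assd(b1, b2), 1)
  # filled rectangle translated by 1: overlapping perimeter points have
  # distance 0, so ASSD < 1; agreement with the all-pairs oracle instead
  r1 <- matrix(0, 6, 9); r1[2:5, 2:4] <- 1
  r2 <- matrix(0, 6, 9); r2[2:5, 3:5] <- 1
  expect_equal(assd(r1, r2), oracle_assd(r1, r2))
  expect_lt(assd(r1, r2), 1)

  expect_error(assd(matrix(0, 3, 7), m1), "empty")
  expect_error(assd(m1, m2, paired = TRUE), NA) # equal sizes: allowed
  r3 <- matrix(0, 6, 9); r3[2, 2] <- 1
  expect_error(assd(r1, r3, paired = TRUE), "equal")
})

test_that("dice and assd agree with brute-force oracles on random masks", {
  set.seed(42)
  for (i in 1:200) {
    x <- random_mask()
    y <- random_mask()
    expect_identical(dice_score(x, y), oracle_dice(x, y))
    if (sum(x) > 0 && sum(y) > 0) {
      expect_lt(abs(assd(x, y) - oracle_assd(x, y)), 1e-9)
    }
  }
})

test_that("dice and assd are symmetric", {
  set.seed(7)
  for (i in 1:25) {
    x <- random_mask(); y <- random_mask()
    expect_equal(dice_score(x, y), dice_score(y, x))
    if (sum(x) > 0 && sum(y) > 0) expect_equal(assd(x, y), assd(y, x))
  }
})

test_that("dice_loss behaves as 1 - soft dice with smoothing", {
  y <- matrix(0, 6, 6); y[2:4, 2:5] <- 1
  expect_lt(dice_loss(y, y), 0.05)
  expect_gt(dice_loss(1 - y, y), 0.95)
  # for hard probabilities, 1 - dice_loss approaches dice_score
  set.seed(3)
  for (i in 1:20) {
    p <- random_mask(12, 12, 0.5)
    q <- random_mask(12, 12, 0.5)
    if (sum(p) + sum(q) == 0) next
    expect_lt(abs((1 - dice_loss(p, q)) - dice_score(p, q)), 0.05)
  }
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("manual-vs-auto comparison recovers exact and degenerate relations", {
  man <- c(250, 270, 290, 310, 330)
  fit <- compare_manual_auto(man, man)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)

  neg <- compare_manual_auto(man, -man + 500)
  expect_equal(neg$r, -1)

  # brute-force Pearson for (1,2),(2,3),(3,5)
  x <- c(1, 2, 3); y <- c(2, 3, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(compare_manual_auto(x, y)$r, r_hand)

  expect_error(compare_manual_auto(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(compare_manual_auto(c(1, 1, 1), c(1, 2, 3)), "variance")
  g <- glance(compare_manual_auto(x, y))
  expect_named(g, c("r", "slope", "intercept", "n"))
})
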