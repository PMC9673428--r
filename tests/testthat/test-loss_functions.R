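one_hot_prob <- function(mask, C) {
  p <- array(0, c(dim(mask), C))
  for (c in 0:(C - 1)) p[, , c + 1][mask == c] <- 1
  p
}

test_that("soft Dice loss matches hand evaluations", {
  # perfect one-hot overlap -> 0 in the eps limit
  tg <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_equal(soft_dice_loss(one_hot_prob(tg, 2), tg), 0, tolerance = 1e-6)
  # all mass on the wrong class -> 1
  wrong <- one_hot_prob(1L - tg, 2)
  expect_equal(soft_dice_loss(wrong, tg), 1, tolerance = 1e-5)
  # prob 1.0 on 2 of 4 foreground pixels, 4 true foreground pixels:
  # 1 - 2*2 / (2 + 4) = 1/3
  pr <- array(0, c(2, 2, 2))
  pr[, , 2] <- c(1, 1, 0, 0); pr[, , 1] <- 1 - pr[, , 2]
  expect_equal(soft_dice_loss(pr, matrix(1L, 2, 2)), 1 / 3, tolerance = 1e-5)
  expect_error(soft_dice_loss(pr, matrix(0L, 3, 3)), "shapes")
  expect_error(soft_dice_loss(pr, matrix(5L, 2, 2)), "labels")
})

test_that("log-cosh Dice transform has its closed-form values and monotonicity", {
  expect_equal(log_cosh_dice_loss(0), 0)
  expect_equal(log_cosh_dice_loss(1), log(cosh(1)), tolerance = 1e-10)
  expect_equal(log_cosh_dice_loss(1), 0.43378, tolerance = 1e-4)
  grid <- seq(0, 1, by = 0.05)
  expect_true(all(diff(log_cosh_dice_loss(grid)) > 0))
  expect_error(log_cosh_dice_loss(-0.1), ">= 0")
})

test_that("focal loss matches its closed forms and reduces to cross-entropy", {
  # single pixel with p_t = 0.5, gamma = 2: 0.25 * ln 2
  pr <- array(c(0.5, 0.5), c(1, 1, 2))
  expect_equal(focal_loss(pr, matrix(0L, 1, 1)), 0.25 * log(2), tolerance = 1e-10)
  expect_equal(focal_loss(pr, matrix(0L, 1, 1)), 0.17329, tolerance = 1e-4)
  # p_t = 1 everywhere -> 0
  tg <- matrix(sample(0:2, 16, TRUE), 4, 4)
  expect_equal(focal_loss(one_hot_prob(tg, 3), tg), 0)
  # gamma = 0, alpha = 1 is mean cross-entropy
  set.seed(303)
  pr <- random_prob(4, 4, 3)
  pt <- pr[cbind(as.vector(row(tg)), as.vector(col(tg)), as.vector(tg) + 1)]
  expect_equal(focal_loss(pr, tg, loss_weights(focal_gamma = 0)),
               mean(-log(pt)), tolerance = 1e-10)
})

test_that("focal Dice loss composes its components with the 4:1 weights", {
  w <- loss_weights()
  expect_equal(w$omega1 / w$omega2, 4)
  expect_equal(focal_dice_combine(0.1, 0.5, w),
               4 * 0.1 + 0.5 * log(cosh(0.5)), tolerance = 1e-12)
  expect_equal(focal_dice_combine(0.1, 0.5, w), 0.4601, tolerance = 1e-4)
  # zero iff (eps-limit) perfect
  tg <- matrix(sample(0:3, 64, TRUE), 8, 8)
  fd <- focal_dice_loss(one_hot_prob(tg, 4), tg)
  expect_equal(fd$total, 0, tolerance = 1e-5)
  set.seed(404)
  fd2 <- focal_dice_loss(random_prob(8, 8, 4), tg)
  expect_gt(fd2$total, 0)
  expect_equal(fd2$total,
               focal_dice_combine(fd2$components$focal, fd2$components$dice),
               tolerance = 1e-12)
})

test_that("the adaptive factor increases with the Dice loss", {
  for (g in c(0.5, 1, 2)) {
    grid <- seq(0.01, 1, by = 0.01)
    fac <- grid^g
    expect_true(all(diff(fac) > 0))
    term <- fac * log_cosh_dice_loss(grid)
    expect_true(all(diff(term) > 0))
  }
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(505)
  pr <- random_prob(4, 4, 3)
  tg <- matrix(sample(0:2, 16, TRUE), 4, 4)
  w <- loss_weights()
  lg <- scunet:::focal_dice_grad(pr, tg, w)
  expect_equal(lg$total, focal_dice_loss(pr, tg, w)$total, tolerance = 1e-12)
  h <- 1e-6
  for (probe in 1:10) {
    i <- sample(length(pr), 1)
    pp <- pr; pp[i] <- pp[i] + h
    pm <- pr; pm[i] <- pm[i] - h
    fd <- (scunet:::focal_dice_grad(pp, tg, w)$total -
             scunet:::focal_dice_grad(pm, tg, w)$total) / (2 * h)
    expect_equal(lg$dprob[i], fd, tolerance = 1e-4)
  }
})

test_that("one gradient step decreases the loss on a 2-pixel toy problem", {
  set.seed(606)
  pr <- random_prob(1, 2, 2)
  tg <- matrix(c(0L, 1L), 1, 2)
  w <- loss_weights()
  lg <- scunet:::focal_dice_grad(pr, tg, w)
  step <- pr - 0.01 * array(lg$dprob, dim(pr))
  step <- pmax(step, 1e-6)
  step <- step / array(rep(apply(step, c(1, 2), sum), 2), dim(step))
  after <- focal_dice_loss(step, tg)$total
  expect_lt(after, lg$total)
})
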