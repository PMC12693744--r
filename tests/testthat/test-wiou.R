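test_that("wiou_v1 matches the hand-worked example", {
  pred <- box(0, 0, 2, 2); target <- box(1, 1, 3, 3)
  # L_IoU = 6/7, centers (1,1) and (2,2), enclosing box 3x3 => R = exp(2/18)
  expect_equal(wiou_v1(pred, target), exp(1 / 9) * 6 / 7, tolerance = 1e-12)
  expect_equal(round(wiou_v1(pred, target), 4), 0.9579)
  expect_equal(wiou_v1(pred, pred), 0)
  # concentric boxes: distance term vanishes, loss reduces to L_IoU
  a <- box(0, 0, 4, 4); b <- box(1, 1, 3, 3)
  expect_equal(wiou_v1(a, b), iou_loss(a, b))
})

test_that("EMA follows the first-batch-mean then linear-update rule", {
  st <- ema_state()
  expect_false(st$initialised)
  st <- update_ema(st, c(0.5))
  expect_equal(st$mean_iou_loss, 0.5)
  st <- update_ema(st, c(0.0), wiou_params(ema_decay = 0.9))
  expect_equal(st$mean_iou_loss, 0.45)
  # constant batches converge to the constant
  st2 <- ema_state()
  for (i in 1:200) st2 <- update_ema(st2, rep(0.3, 4))
  expect_equal(st2$mean_iou_loss, 0.3)
  expect_error(update_ema(ema_state(), numeric(0)), "non-empty")
})

test_that("EMA mean stays in [0, 1] for arbitrary valid batches", {
  set.seed(10)
  st <- ema_state()
  for (i in 1:100) {
    st <- update_ema(st, runif(sample(1:8, 1)))
    expect_gte(st$mean_iou_loss, 0); expect_lte(st$mean_iou_loss, 1)
  }
})

test_that("anomaly degree is the ratio to the running mean", {
  st <- update_ema(ema_state(), 0.4)
  expect_equal(anomaly_degree(0.4, st), 1)
  expect_equal(anomaly_degree(0.8, st), 2)
  expect_equal(anomaly_degree(0, st), 0)
  expect_error(anomaly_degree(0.5, ema_state()), "uninitialised")
})

test_that("focusing coefficient pivots at beta = delta and vanishes at 0", {
  for (alpha in c(1.1, 1.5, 1.9, 3)) {
    for (delta in c(0.5, 1, 3, 5)) {
      p <- wiou_params(alpha = alpha, delta = delta)
      expect_equal(focusing_coefficient(delta, p), 1)
      expect_equal(focusing_coefficient(0, p), 0)
    }
  }
  expect_equal(focusing_coefficient(1, wiou_params(1.9, 3)), 1.9^2 / 3)
  expect_lt(abs(focusing_coefficient(1, wiou_params(1.9, 3)) - 1.2033), 1e-4)
})

test_that("focusing coefficient is non-monotonic with an interior maximum", {
  p <- wiou_params(alpha = 1.9, delta = 3)
  beta <- seq(0, 20, by = 0.001)
  r <- focusing_coefficient(beta, p)
  expect_true(all(r >= 0))
  i_max <- which.max(r)
  expect_gt(i_max, 1); expect_lt(i_max, length(beta))
  # the analytic argmax of beta * alpha^(delta-beta) is 1/log(alpha)
  expect_lt(abs(beta[i_max] - 1 / log(p$alpha)), 0.01)
})

test_that("focusing coefficient reduces to beta/delta as alpha approaches 1", {
  p <- wiou_params(alpha = 1 + 1e-9, delta = 2.5)
  beta <- seq(0, 10, by = 0.5)
  expect_equal(focusing_coefficient(beta, p), beta / 2.5, tolerance = 1e-6)
})

test_that("wiou_v3 composes coefficient, anomaly degree and v1 loss", {
  pred <- box(0, 0, 2, 2); target <- box(1, 1, 3, 3)
  p <- wiou_params(alpha = 1.9, delta = 3)
  # mean equal to this pair's L_IoU makes beta = 1
  st <- update_ema(ema_state(), 6 / 7)
  expected <- (1.9^2 / 3) * exp(1 / 9) * 6 / 7
  expect_equal(wiou_v3(pred, target, st, p), expected, tolerance = 1e-12)
  expect_lt(abs(wiou_v3(pred, target, st, p) - 1.1524), 1e-3)
  # perfect overlap is zero whatever the state
  expect_equal(wiou_v3(pred, pred, st, p), 0)
  # beta = delta makes the loss equal wiou_v1
  st2 <- update_ema(ema_state(), (6 / 7) / 3)
  expect_equal(wiou_v3(pred, target, st2, p), wiou_v1(pred, target))
})

test_that("hyperparameter domains are enforced", {
  expect_error(wiou_params(alpha = 1), "alpha")
  expect_error(wiou_params(delta = 0), "delta")
  expect_error(wiou_params(ema_decay = 1), "ema_decay")
})

test_that("focusing_table tabulates r over a beta grid", {
  tab <- focusing_table(wiou_params(1.9, 3), beta_max = 6, n = 7)
  expect_equal(tab$beta, seq(0, 6, by = 1))
  expect_equal(tab$r[4], 1)  # beta = 3 = delta
})
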