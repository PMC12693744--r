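dets_at <- function(centers, conf = 0.9) {
  lapply(seq_len(nrow(centers)), function(i) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    detection(box(cx - 10, cy - 10, cx + 10, cy + 10),
              if (length(conf) > 1) conf[i] else conf)
  })
}

test_that("system reliability reproduces the binomial tail sum", {
  pol <- voting_policy(3, 2)
  expect_equal(system_reliability(0.8, pol), 0.896)
  expect_equal(system_reliability(1, pol), 1)
  expect_equal(system_reliability(0.5, pol), 0.5)  # 4 of 8 outcomes
  expect_equal(system_reliability(0, pol), 0)
})

test_that("system reliability equals exhaustive outcome enumeration", {
  brute <- function(p, n, t) {
    total <- 0
    for (m in 0:(2^n - 1)) {
      bits <- as.integer(intToBits(m))[1:n]
      if (sum(bits) >= t) {
        total <- total + prod(ifelse(bits == 1, p, 1 - p))
      }
    }
    total
  }
  set.seed(12)
  for (i in 1:12) {
    n <- sample(1:10, 1); t <- sample(1:n, 1); p <- runif(1)
    expect_equal(system_reliability(p, voting_policy(n, t)), brute(p, n, t),
                 tolerance = 1e-12)
  }
})

test_that("reliability is monotone in p and beats single-frame detection", {
  pol <- voting_policy(3, 2)
  p_grid <- seq(0, 1, by = 0.01)
  r <- system_reliability(p_grid, pol)
  expect_true(all(diff(r) >= -1e-12))
  above_half <- p_grid >= 0.5
  expect_true(all(r[above_half] >= p_grid[above_half] - 1e-12))
})

test_that("presence vote requires T positive frames out of N", {
  pol <- voting_policy(3, 2)
  pos <- function(i) frame_result(i, dets_at(cbind(100, 100)))
  neg <- function(i) frame_result(i, list())
  expect_true(fuse_presence(list(pos(0), pos(1), neg(2)), pol))
  expect_false(fuse_presence(list(neg(0), neg(1), neg(2)), pol))
  expect_false(fuse_presence(list(pos(0), neg(1), neg(2)), pol))
  expect_error(fuse_presence(list(pos(0), pos(1)), pol), "expected 3 frames")
})

test_that("presence vote ignores detection order within frames", {
  pol <- voting_policy(3, 2)
  d <- dets_at(rbind(c(50, 50), c(200, 80)), conf = c(0.4, 0.9))
  f1 <- frame_result(0, d)
  f2 <- frame_result(0, rev(d))
  rest <- list(frame_result(1, d), frame_result(2, list()))
  expect_identical(fuse_presence(c(list(f1), rest), pol),
                   fuse_presence(c(list(f2), rest), pol))
})

test_that("count fusion clusters detections across frames", {
  pol <- voting_policy(3, 2, match_radius = 40)
  # one stable egg drifting slightly: one cluster with full support
  frames <- list(
    frame_result(0, dets_at(cbind(100, 100))),
    frame_result(1, dets_at(cbind(108, 95))),
    frame_result(2, dets_at(cbind(96, 104))))
  dec <- fuse_count(frames, pol)
  expect_true(dec$egg_present)
  expect_equal(dec$fused_count, 1)
  expect_equal(dec$per_egg_support[[1]]$frames, 0:2)

  # two eggs in frames 1-2, only one re-seen in frame 3: both retained
  frames2 <- list(
    frame_result(0, dets_at(rbind(c(100, 100), c(300, 200)))),
    frame_result(1, dets_at(rbind(c(105, 102), c(298, 195)))),
    frame_result(2, dets_at(cbind(102, 99))))
  dec2 <- fuse_count(frames2, pol)
  expect_equal(dec2$fused_count, 2)

  # a spurious single-frame detection is filtered out
  frames3 <- list(
    frame_result(0, dets_at(cbind(400, 300))),
    frame_result(1, list()),
    frame_result(2, list()))
  dec3 <- fuse_count(frames3, pol)
  expect_equal(dec3$fused_count, 0)
  expect_false(dec3$egg_present)
})

test_that("count fusion keeps distinct eggs apart and presence consistent", {
  pol <- voting_policy(3, 2)
  frames <- list(
    frame_result(0, dets_at(rbind(c(100, 100), c(500, 100), c(300, 250)))),
    frame_result(1, dets_at(rbind(c(103, 98), c(495, 104), c(302, 252)))),
    frame_result(2, dets_at(rbind(c(99, 101), c(501, 99), c(297, 248)))))
  dec <- fuse_count(frames, pol)
  expect_equal(dec$fused_count, 3)
  expect_identical(dec$egg_present, dec$fused_count >= 1)
  for (s in dec$per_egg_support) expect_gte(length(s$frames), pol$threshold)
})

test_that("Monte-Carlo cycles converge to the analytic miss rate", {
  pol <- voting_policy(3, 2)
  expect_equal(simulate_cycles(1, pol, 2000, seed = 1), 0)
  expect_equal(simulate_cycles(0, pol, 2000, seed = 2), 1)
  miss <- simulate_cycles(0.8, pol, 100000, seed = 3)
  sigma <- sqrt(0.104 * 0.896 / 100000)
  expect_lt(abs(miss - 0.104), 3 * sigma)
  # deterministic given the seed
  expect_identical(miss, simulate_cycles(0.8, pol, 100000, seed = 3))
})

test_that("voting policy domain errors", {
  expect_error(voting_policy(3, 4), "1 <= T <= N")
  expect_error(voting_policy(0, 0), ">= 1")
  expect_error(system_reliability(1.2, voting_policy(3, 2)), "p_detect")
})
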