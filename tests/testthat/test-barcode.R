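gray3 <- function(r, g, b) {
  rgb <- array(0, c(1, 1, 3)); rgb[1, 1, ] <- c(r, g, b)
  to_grayscale(rgb)[1, 1]
}

test_that("grayscale conversion follows the weighted average", {
  expect_equal(gray3(255, 255, 255), 255L)
  expect_equal(gray3(0, 255, 0), 150L)  # round(0.587 * 255)
  expect_equal(gray3(0, 0, 0), 0L)
  # the alternative red weight remains selectable but must renormalise
  alt <- grayscale_coeffs(0.229, 0.587, 0.184)
  rgb <- array(255, c(1, 1, 3))
  expect_equal(to_grayscale(rgb, alt)[1, 1], 255L)
  expect_error(grayscale_coeffs(0.229, 0.587, 0.114), "sum to 1")
  expect_error(to_grayscale(matrix(1, 2, 2)), "H x W x 3")
})

test_that("median filter removes impulses and preserves step edges", {
  img <- matrix(100L, 8, 8)
  salt <- img; salt[4, 5] <- 255L
  expect_equal(median_filter_3x3(salt), img)
  step <- matrix(rep(c(50L, 200L), each = 4 * 10), 10, 8)
  expect_equal(median_filter_3x3(step), step)
  expect_error(median_filter_3x3(matrix(1L, 2, 5)), "3 x 3")
})

test_that("median filter matches a per-window sort oracle", {
  oracle <- function(img) {
    h <- nrow(img); w <- ncol(img); out <- img
    for (y in 1:h) for (x in 1:w) {
      ys <- pmin(pmax(1, (y - 1):(y + 1)), h)
      xs <- pmin(pmax(1, (x - 1):(x + 1)), w)
      out[y, x] <- sort(as.vector(img[ys, xs]))[5]
    }
    out
  }
  set.seed(17)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
    expect_equal(median_filter_3x3(img), oracle(img))
  }
})

test_that("otsu picks the smallest maximiser of between-class variance", {
  h <- integer(256); h[50 + 1] <- 40L; h[200 + 1] <- 60L
  expect_equal(otsu_threshold(h), 50L)
  h2 <- integer(256); h2[1] <- 30L; h2[256] <- 30L
  expect_equal(otsu_threshold(h2), 0L)
  h3 <- integer(256); h3[100] <- 10L
  expect_error(otsu_threshold(h3), "degenerate")
})

test_that("otsu matches an independent raw-pixel class-statistics scan", {
  oracle <- function(v) {
    best_t <- 0L; best <- -Inf
    n <- length(v)
    for (t in 0:255) {
      lo <- v[v <= t]; hi <- v[v > t]
      if (length(lo) == 0 || length(hi) == 0) next
      s <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
      if (s > best + 1e-12) { best <- s; best_t <- t }
    }
    best_t
  }
  set.seed(18)
  for (i in 1:100) {
    # bimodal-ish random images like the binarisation stage sees
    v <- as.integer(round(c(rnorm(80, 60, 20), rnorm(40, 190, 25))))
    v <- pmin(255L, pmax(0L, v))
    expect_equal(otsu_threshold(histogram256(v)), oracle(v))
  }
})

test_that("binarize thresholds strictly above t and is idempotent", {
  img <- matrix(c(0L, 255L, 10L, 200L), 2, 2)
  expect_equal(binarize(img, 255), matrix(FALSE, 2, 2))
  expect_equal(binarize(img, 0), img > 0)
  bin <- binarize(img, 100)
  again <- binarize(matrix(ifelse(bin, 255L, 0L), 2, 2), 100)
  expect_equal(again, bin)
})

test_that("canny finds thin edges and suppresses sub-threshold gradients", {
  expect_true(!any(canny_edges(matrix(128, 30, 30))))
  step <- matrix(0, 30, 40); step[, 21:40] <- 255
  e <- canny_edges(step)
  # a single-pixel-wide vertical line near the step
  interior <- 5:25
  expect_true(all(rowSums(e[interior, ]) == 1))
  edge_cols <- apply(e[interior, ], 1, which)
  expect_true(all(abs(edge_cols - 20.5) <= 1.5))
  # a weak bump below the low threshold leaves no edge
  bump <- matrix(100, 30, 30); bump[15, 15] <- 103
  expect_true(!any(canny_edges(bump, low = 50, high = 150)))
  expect_error(canny_edges(step, low = 150, high = 50), "low")
})

test_that("canny is deterministic", {
  set.seed(19)
  img <- matrix(runif(900, 0, 255), 30, 30)
  expect_identical(canny_edges(img), canny_edges(img))
})

test_that("contours trace one boundary per component", {
  img <- matrix(FALSE, 30, 40)
  img[5:14, 5:24] <- TRUE           # 20 x 10 rectangle
  cts <- find_contours(img)
  expect_length(cts, 1)
  # boundary of a filled w x h rectangle encloses (w-1)(h-1) as a polygon
  expect_equal(nestscan:::polygon_area(cts[[1]]), 19 * 9)
  img[20:25, 30:36] <- TRUE
  expect_length(find_contours(img), 2)
  expect_length(find_contours(matrix(FALSE, 5, 5)), 0)
})

test_that("min-area rectangle side lengths are rotation invariant", {
  th <- 30 * pi / 180
  pts <- expand.grid(x = seq(0, 60, by = 1), y = seq(0, 30, by = 1))
  pts <- as.matrix(pts[pts$x %in% c(0, 60) | pts$y %in% c(0, 30), ])
  rot <- cbind(pts[, 1] * cos(th) - pts[, 2] * sin(th),
               pts[, 1] * sin(th) + pts[, 2] * cos(th))
  r0 <- min_area_rect(pts); r1 <- min_area_rect(rot)
  expect_equal(sort(c(r0$width, r0$height)), c(30, 60), tolerance = 1e-6)
  expect_equal(sort(c(r1$width, r1$height)), c(30, 60), tolerance = 1e-3)
  expect_equal(r1$aspect, 2, tolerance = 1e-3)
})

test_that("candidate screening keeps 2:1 rectangles and drops the rest", {
  img <- matrix(FALSE, 300, 400)
  img[50:149, 100:299] <- TRUE      # 200 x 100 target
  set.seed(20)
  for (i in 1:5) {                  # small noise blobs
    y <- sample(200:290, 1); x <- sample(10:80, 1)
    img[y:(y + 3), x:(x + 3)] <- TRUE
  }
  cands <- screen_barcode_candidates(find_contours(img), min_area = 500)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$aspect, 2, tolerance = 0.05)

  sq <- matrix(FALSE, 200, 200); sq[50:149, 50:149] <- TRUE
  expect_length(screen_barcode_candidates(find_contours(sq), min_area = 500), 0)

  # the same 2:1 rectangle rotated 30 degrees is still kept
  th <- 30 * pi / 180
  rot <- matrix(FALSE, 400, 400)
  for (u in seq(-100, 100, by = 0.5)) for (v in c(-50, 50)) {
    x <- round(200 + u * cos(th) - v * sin(th))
    y <- round(200 + u * sin(th) + v * cos(th))
    rot[y, x] <- TRUE
  }
  for (v in seq(-50, 50, by = 0.5)) for (u in c(-100, 100)) {
    x <- round(200 + u * cos(th) - v * sin(th))
    y <- round(200 + u * sin(th) + v * cos(th))
    rot[y, x] <- TRUE
  }
  cands_rot <- screen_barcode_candidates(find_contours(rot), min_area = 500)
  expect_length(cands_rot, 1)
  expect_equal(cands_rot[[1]]$aspect, 2, tolerance = 0.05)
})

test_that("the locate-then-decode chain recovers the embedded position", {
  s <- render_scene(small_scene(n_eggs = 2, seed = 21))
  lab <- read_cage_label(s$rgb)
  expect_equal(lab$uid, s$truth$uid)
  expect_equal(lab$code, s$truth$ean)
  # the located region approximates the true label rectangle
  expect_gt(iou(lab$region$bbox, s$truth$barcode_region$bbox), 0.9)
})

test_that("debug dumps write every intermediate stage", {
  s <- render_scene(small_scene(n_eggs = 0, seed = 22))
  dir <- withr::local_tempdir()
  read_cage_label(s$rgb, debug_dir = dir)
  expect_setequal(list.files(dir),
                  c("01_gray.png", "02_median.png", "03_binary.png",
                    "04_edges.png", "05_candidates.png"))
})
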