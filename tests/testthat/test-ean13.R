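random_ean13 <- function() {
  d12 <- paste(sample(0:9, 12, replace = TRUE), collapse = "")
  paste0(d12, ean13_check_digit(d12))
}

# paste a barcode raster into a flat canvas rotated about the canvas center
rotate_into_canvas <- function(bar, theta_deg, H, W, bg = 60L) {
  th <- theta_deg * pi / 180
  bh <- nrow(bar); bw <- ncol(bar)
  cx <- W / 2; cy <- H / 2
  xs <- matrix(rep(0:(W - 1), each = H), H, W) - cx
  ys <- matrix(rep(0:(H - 1), times = W), H, W) - cy
  bx <- round(xs * cos(th) + ys * sin(th) + bw / 2)
  by <- round(-xs * sin(th) + ys * cos(th) + bh / 2)
  canvas <- matrix(bg, H, W)
  inside <- bx >= 0 & bx < bw & by >= 0 & by < bh
  canvas[inside] <- bar[cbind(by[inside] + 1L, bx[inside] + 1L)]
  canvas
}

test_that("the check digit follows the weighted-sum rule", {
  expect_equal(ean13_check_digit("200001012104"), "5")
  expect_equal(ean13_check_digit("000000000000"), "0")
  expect_silent(ean13_validate("2000010121045"))
  expect_error(ean13_validate("2000010121044"), class = "nestscan_corrupt_code")
  expect_error(ean13_validate("12345"), "13 decimal digits")
})

test_that("rendered barcodes have the documented module geometry", {
  img <- render_ean13("2000010121045", module_px = 3, quiet_modules = 10)
  expect_equal(ncol(img), (95 + 2 * 10) * 3)
  expect_true(all(img %in% c(0L, 255L)))
  # quiet zones are blank
  expect_true(all(img[, 1:(10 * 3)] == 255))
  expect_error(render_ean13("2000010121044"), class = "nestscan_corrupt_code")
  expect_error(render_ean13("2000010121045", quiet_modules = 5), ">= 9")
})

test_that("decode inverts render for random codes", {
  set.seed(15)
  for (i in 1:200) {
    code <- random_ean13()
    img <- render_ean13(code, module_px = sample(2:4, 1))
    expect_equal(decode_ean13(img)$code, code)
  }
})

test_that("decode survives 1% impulse noise after median filtering", {
  set.seed(16)
  for (i in 1:25) {
    code <- random_ean13()
    img <- render_ean13(code, module_px = 4)
    n <- round(0.01 * length(img))
    idx <- sample.int(length(img), n)
    img[idx] <- ifelse(runif(n) < 0.5, 0L, 255L)
    expect_equal(decode_ean13(median_filter_3x3(img))$code, code)
  }
})

test_that("decode reads mirrored and rotated regions", {
  code <- "2000010121045"
  bar <- render_ean13(code, module_px = 4)
  # reading direction unknown: reversed columns must still decode
  expect_equal(decode_ean13(bar[, ncol(bar):1])$code, code)
  canvas <- rotate_into_canvas(bar, 20, 700, 800)
  reg <- barcode_region(400, 350, ncol(bar), nrow(bar), angle_deg = 20)
  expect_equal(decode_ean13(canvas, reg)$code, code)
  # and the same region described with the opposite orientation
  reg2 <- barcode_region(400, 350, ncol(bar), nrow(bar), angle_deg = 200)
  expect_equal(decode_ean13(canvas, reg2)$code, code)
})

test_that("every single-module corruption is caught, never silently accepted", {
  code <- "2000010121045"
  img <- render_ean13(code, module_px = 4, quiet_modules = 9)
  for (k in 1:95) {
    img2 <- img
    cols <- ((9 + k - 1) * 4 + 1):((9 + k) * 4)
    img2[, cols] <- 255L - img2[, cols]
    res <- tryCatch(decode_ean13(img2), error = function(e) e)
    if (inherits(res, "error")) {
      expect_true(inherits(res, "nestscan_no_barcode") ||
                    inherits(res, "nestscan_corrupt_code"))
    } else {
      # a decode may only succeed if its checksum is genuinely valid
      expect_silent(ean13_validate(res$code))
    }
  }
})

test_that("blank images raise a no-barcode error", {
  expect_error(decode_ean13(matrix(255L, 60, 500)),
               class = "nestscan_no_barcode")
})
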