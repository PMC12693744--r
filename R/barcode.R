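#' Grayscale conversion coefficients
#'
#' Weighted-average RGB-to-luma conversion. The default weights are the
#' ITU-R BT.601 luma coefficients (0.299, 0.587, 0.114); an alternative red
#' weight of 0.229 is sometimes quoted for this pipeline and can be
#' selected explicitly, but the coefficients must always sum to 1.
#'
#' @param r_coef,g_coef,b_coef non-negative channel weights summing to 1
#'   (within 1e-6).
#' @return An object of class `"grayscale_coeffs"`.
#' @export
grayscale_coeffs <- function(r_coef = 0.299, g_coef = 0.587, b_coef = 0.114) {
  v <- c(r_coef, g_coef, b_coef)
  if (any(v < 0) || abs(sum(v) - 1) > 1e-6) {
    stop("coefficients must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(r_coef = r_coef, g_coef = g_coef, b_coef = b_coef),
            class = "grayscale_coeffs")
}

#' Convert an RGB image to 8-bit grayscale
#'
#' `Y = round(r R + g G + b B)` clamped to \[0, 255\].
#'
#' @param rgb H x W x 3 numeric array with 8-bit channel values (0-255).
#' @param coeffs a [grayscale_coeffs()].
#' @return integer matrix (H x W) in \[0, 255\].
#' @export
to_grayscale <- function(rgb, coeffs = grayscale_coeffs()) {
  if (!is.array(rgb) || length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop("rgb must be an H x W x 3 array", call. = FALSE)
  }
  y <- coeffs$r_coef * rgb[, , 1] + coeffs$g_coef * rgb[, , 2] +
    coeffs$b_coef * rgb[, , 3]
  matrix(as.integer(pmin(255, pmax(0, round(y)))), dim(rgb)[1], dim(rgb)[2])
}

check_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("expected a numeric grayscale matrix", call. = FALSE)
  }
  img
}

#' 3x3 median filter
#'
#' Each pixel is replaced by the median of its 3x3 neighbourhood (borders
#' by edge replication): removes isolated impulse (salt-and-pepper) noise
#' while preserving the step edges between barcode bars and spaces.
#'
#' @param img grayscale matrix, at least 3 x 3.
#' @return filtered matrix of the same shape.
#' @export
median_filter_3x3 <- function(img) {
  check_gray(img)
  if (nrow(img) < 3 || ncol(img) < 3) {
    stop("image must be at least 3 x 3", call. = FALSE)
  }
  storage.mode(img) <- "integer"
  median_filter_3x3_cpp(img)
}

#' 256-bin intensity histogram
#'
#' @param img grayscale matrix with values in \[0, 255\].
#' @return integer vector of 256 counts (bin i holds value i-1).
#' @export
histogram256 <- function(img) {
  v <- if (is.integer(img)) img else as.integer(round(img))
  rng <- range(v)
  if (rng[1] < 0L || rng[2] > 255L) {
    stop("values must lie in [0, 255]", call. = FALSE)
  }
  tabulate(v + 1L, nbins = 256L)
}

#' Otsu threshold from a histogram
#'
#' Exhaustively scans every threshold t in 0..255 and returns the one
#' maximising the between-class variance
#' `w0(t) w1(t) (mu0(t) - mu1(t))^2`, where class 0 holds the pixels with
#' value <= t. Ties break to the smallest t.
#'
#' @param hist integer vector of 256 bin counts (see [histogram256()]).
#' @return integer threshold t* in \[0, 255\].
#' @export
otsu_threshold <- function(hist) {
  if (length(hist) != 256 || any(hist < 0)) {
    stop("hist must be 256 non-negative counts", call. = FALSE)
  }
  n <- sum(hist)
  if (sum(hist > 0) < 2) {
    stop("degenerate image: histogram occupies fewer than two bins",
         call. = FALSE)
  }
  levels <- 0:255
  csum <- cumsum(hist)            # pixels with value <= t
  cmean <- cumsum(hist * levels)
  total_mean <- cmean[256] / n
  w0 <- csum / n
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- ifelse(valid, cmean / csum, 0)
  mu1 <- ifelse(valid, (cmean[256] - cmean) / (n - csum), 0)
  sigma_b2 <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  as.integer(levels[which.max(sigma_b2)])  # which.max takes the first = smallest t
}

#' Binarise a grayscale image
#'
#' Pixels strictly above the threshold become foreground.
#'
#' @param img grayscale matrix.
#' @param t threshold in \[0, 255\].
#' @return logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(img, t) {
  check_gray(img)
  if (t < 0 || t > 255) stop("t must lie in [0, 255]", call. = FALSE)
  img > t
}

#' Canny edge detection
#'
#' The four-stage detector: Gaussian smoothing, Sobel 3x3 gradient
#' magnitude and direction, non-maximum suppression with 4-sector direction
#' quantisation, and double thresholding with hysteresis (weak edges kept
#' only when 8-connected to a strong edge).
#'
#' @param img grayscale matrix (0-255 scale).
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param low,high hysteresis thresholds on the Sobel gradient magnitude
#'   (0-255 intensity scale); `low < high` required.
#' @return logical edge map.
#' @export
canny_edges <- function(img, sigma = 1.4, low = 50, high = 150) {
  check_gray(img)
  if (low >= high) stop("low must be < high", call. = FALSE)
  canny_cpp(matrix(as.numeric(img), nrow(img), ncol(img)), sigma, low, high)
}

#' Trace external contours of a binary image
#'
#' One boundary per 8-connected foreground component, traced in a
#' consistent orientation by Moore-neighbour tracing from each component's
#' topmost-leftmost pixel. Contour points are pixel centers in 0-based
#' (x, y) coordinates, so the traced boundary of a filled w x h rectangle
#' encloses a shoelace area of (w-1)(h-1).
#'
#' @param img logical matrix.
#' @return list of n x 2 integer matrices (columns x, y), one per
#'   component, ordered by component discovery (top-to-bottom scan).
#' @export
find_contours <- function(img) {
  stopifnot(is.matrix(img))
  img <- matrix(as.logical(img), nrow(img), ncol(img))
  lab <- label_components_cpp(img)
  n <- attr(lab, "n_components")
  if (n == 0) return(list())
  trace_contours_cpp(lab, n)
}

polygon_area <- function(contour) {
  if (nrow(contour) < 3) return(0)
  x <- contour[, 1]; y <- contour[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Rotated barcode region
#'
#' A rotated rectangle (center, side lengths, angle of the `width` axis in
#' degrees, measured from the x axis towards positive y) plus its
#' axis-aligned bounding [box()].
#'
#' @param center_x,center_y rectangle center in pixels.
#' @param width,height side lengths in pixels, both > 0.
#' @param angle_deg rotation of the width axis.
#' @return An object of class `"barcode_region"` with an `aspect` field
#'   (long side / short side).
#' @export
barcode_region <- function(center_x, center_y, width, height, angle_deg = 0) {
  if (width <= 0 || height <= 0) {
    stop("width and height must be > 0", call. = FALSE)
  }
  th <- angle_deg * pi / 180
  dx <- abs(width / 2 * cos(th)) + abs(height / 2 * sin(th))
  dy <- abs(width / 2 * sin(th)) + abs(height / 2 * cos(th))
  structure(list(center_x = center_x, center_y = center_y,
                 width = width, height = height, angle_deg = angle_deg,
                 aspect = max(width, height) / min(width, height),
                 bbox = box(center_x - dx, center_y - dy,
                            center_x + dx, center_y + dy)),
            class = "barcode_region")
}

#' Minimum-area enclosing rectangle of a point set
#'
#' Rotating-calipers over the convex hull: the minimum-area rectangle has a
#' side collinear with a hull edge. Side lengths are rotation invariant, so
#' the long/short aspect ratio survives in-plane rotation of the contour.
#'
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return a [barcode_region()].
#' @export
min_area_rect <- function(points) {
  points <- points[, 1:2, drop = FALSE]
  rx <- range(points[, 1]); ry <- range(points[, 2])
  if (rx[1] == rx[2] && ry[1] == ry[2]) {  # all points coincide
    return(barcode_region(rx[1], ry[1], 1e-9, 1e-9, 0))
  }
  hull_idx <- grDevices::chull(points[, 1], points[, 2])
  hull <- points[hull_idx, , drop = FALSE]
  hull <- hull[!duplicated(hull), , drop = FALSE]
  n <- nrow(hull)
  if (n < 3) {  # collinear points: degenerate rectangle along the segment
    d <- hull[2, ] - hull[1, ]
    len <- sqrt(sum(d^2))
    ang <- atan2(d[2], d[1]) * 180 / pi
    ctr <- colMeans(hull)
    return(barcode_region(ctr[1], ctr[2], len, 1e-9, ang))
  }
  best <- NULL; best_area <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    wdt <- max(pu) - min(pu); hgt <- max(pv) - min(pv)
    area <- wdt * hgt
    if (area < best_area) {
      cu <- (max(pu) + min(pu)) / 2; cv <- (max(pv) + min(pv)) / 2
      ctr <- cu * u + cv * v
      best_area <- area
      best <- barcode_region(ctr[1], ctr[2], max(wdt, 1e-9), max(hgt, 1e-9),
                             atan2(u[2], u[1]) * 180 / pi)
    }
  }
  best
}

#' Screen contours for barcode-shaped candidates
#'
#' Keeps contours whose minimum-area rectangle is large enough and whose
#' long/short side ratio lies within `target_ratio * (1 +/- ratio_tol)` —
#' the approximately 2:1 label shape that cage grids, nests and drinking
#' cups do not share. Candidates are returned sorted by rectangle area,
#' largest first.
#'
#' @param contours list of contours from [find_contours()].
#' @param min_area minimum rectangle area in px^2.
#' @param target_ratio expected long/short ratio (> 1), default 2.
#' @param ratio_tol relative tolerance around `target_ratio`, default 0.25.
#' @param max_area optional maximum rectangle area in px^2.
#' @return list of [barcode_region()] objects, area-descending.
#' @export
screen_barcode_candidates <- function(contours, min_area,
                                      target_ratio = 2.0, ratio_tol = 0.25,
                                      max_area = Inf) {
  if (target_ratio <= 1) stop("target_ratio must be > 1", call. = FALSE)
  regions <- list()
  for (ct in contours) {
    if (nrow(ct) < 4) next
    reg <- min_area_rect(ct)
    area <- reg$width * reg$height
    if (area < min_area || area > max_area) next
    if (reg$aspect < target_ratio * (1 - ratio_tol) ||
        reg$aspect > target_ratio * (1 + ratio_tol)) next
    regions[[length(regions) + 1L]] <- reg
  }
  if (length(regions) == 0) return(regions)
  areas <- vapply(regions, function(r) r$width * r$height, numeric(1))
  regions[order(-areas)]
}

#' Locate and decode the cage barcode in a scene image
#'
#' The full positioning chain: grayscale conversion, 3x3 median filtering,
#' Otsu binarisation, Canny edge detection, contour extraction, 2:1
#' aspect-ratio screening, and EAN-13 decoding of the candidates in
#' decreasing area order (decoding reads the median-filtered grayscale, so
#' scanline binarisation adapts to local lighting). The decoded code's
#' position payload is parsed and range-checked.
#'
#' @param rgb H x W x 3 RGB array (0-255), or a grayscale matrix.
#' @param coeffs a [grayscale_coeffs()].
#' @param min_area_frac minimum candidate rectangle area as a fraction of
#'   the image area, default 0.001.
#' @param ratio_tol aspect-ratio tolerance (see
#'   [screen_barcode_candidates()]).
#' @param prefix EAN-13 embedding prefix (see [extract_from_ean13()]).
#' @param canny_sigma,canny_low,canny_high Canny parameters.
#' @param debug_dir optional directory: when given, intermediate stages are
#'   written there as PNG files.
#' @return list with `code` (13 digits), `uid` (8 digits), `position`
#'   (a [position_code()]), and `region` (the decoded candidate).
#' @export
read_cage_label <- function(rgb, coeffs = grayscale_coeffs(),
                            min_area_frac = 0.001, ratio_tol = 0.25,
                            prefix = "2000", canny_sigma = 1.4,
                            canny_low = 50, canny_high = 150,
                            debug_dir = NULL) {
  gray <- if (is.matrix(rgb)) rgb else to_grayscale(rgb, coeffs)
  filtered <- median_filter_3x3(gray)
  t_star <- otsu_threshold(histogram256(filtered))
  bin <- binarize(filtered, t_star)
  edges <- canny_edges(matrix(ifelse(bin, 255, 0), nrow(bin), ncol(bin)),
                       sigma = canny_sigma, low = canny_low, high = canny_high)
  contours <- find_contours(edges)
  cands <- screen_barcode_candidates(
    contours, min_area = min_area_frac * length(gray),
    ratio_tol = ratio_tol)
  if (!is.null(debug_dir)) {
    dump_debug_images(debug_dir, gray, filtered, bin, edges, cands)
  }
  if (length(cands) == 0) {
    no_barcode_error("no contour passed the barcode shape screen")
  }
  last_err <- NULL
  for (reg in cands) {
    res <- tryCatch(decode_ean13(filtered, reg), error = function(e) e)
    if (!inherits(res, "error")) {
      pos <- extract_from_ean13(res$code, prefix)
      return(list(code = res$code, uid = format_position(pos),
                  position = pos, region = reg, votes = res$votes))
    }
    last_err <- res
  }
  stop(last_err)
}

dump_debug_images <- function(dir, gray, filtered, bin, edges, cands) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(gray / 255, file.path(dir, "01_gray.png"))
  png::writePNG(filtered / 255, file.path(dir, "02_median.png"))
  png::writePNG(bin * 1, file.path(dir, "03_binary.png"))
  png::writePNG(edges * 1, file.path(dir, "04_edges.png"))
  overlay <- gray / 255
  for (reg in cands) {
    b <- reg$bbox
    xs <- round(b[["x_min"]]):round(b[["x_max"]])
    ys <- round(b[["y_min"]]):round(b[["y_max"]])
    xs <- xs[xs >= 0 & xs < ncol(gray)]; ys <- ys[ys >= 0 & ys < nrow(gray)]
    overlay[ys + 1, range(xs) + 1] <- 1
    overlay[range(ys) + 1, xs + 1] <- 1
  }
  png::writePNG(overlay, file.path(dir, "05_candidates.png"))
  invisible(dir)
}
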