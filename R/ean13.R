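# EAN-13 symbology: 95 modules = start guard (101) + 6 left digits (7
# modules each, L or G parity) + center guard (01010) + 6 right digits
# (R patterns) + end guard (101). The leading 13th digit is not printed as
# bars; it is encoded in the L/G parity sequence of the left half.

EAN13_L <- c("0001101", "0011001", "0010011", "0111101", "0100011",
             "0110001", "0101111", "0111011", "0110111", "0001011")
EAN13_G <- c("0100111", "0110011", "0011011", "0100001", "0011101",
             "0111001", "0000101", "0010001", "0001001", "0010111")
EAN13_R <- c("1110010", "1100110", "1101100", "1000010", "1011100",
             "1001110", "1010000", "1000100", "1001000", "1110100")
EAN13_PARITY <- c("LLLLLL", "LLGLGG", "LLGGLG", "LLGGGL", "LGLLGG",
                  "LGGLLG", "LGGGLL", "LGLGLG", "LGLGGL", "LGGLGL")

no_barcode_error <- function(msg) {
  stop(errorCondition(msg, class = c("nestscan_no_barcode", "error", "condition")))
}
corrupt_code_error <- function(msg) {
  stop(errorCondition(msg, class = c("nestscan_corrupt_code", "error", "condition")))
}

digits_of <- function(s) as.integer(strsplit(s, "")[[1]])

#' EAN-13 check digit
#'
#' Weighted sum over the 12 data digits: odd positions (1st, 3rd, ...)
#' weight 1, even positions weight 3; the check digit brings the total to a
#' multiple of 10.
#'
#' @param data12 string of exactly 12 decimal digits.
#' @return the check digit as a single character.
#' @examples
#' ean13_check_digit("200001012104")  # "5"
#' @export
ean13_check_digit <- function(data12) {
  if (!grepl("^[0-9]{12}$", data12)) {
    stop("data12 must be a string of exactly 12 decimal digits", call. = FALSE)
  }
  d <- digits_of(data12)
  s <- sum(d[seq(1, 12, 2)]) + 3 * sum(d[seq(2, 12, 2)])
  as.character((10 - s %% 10) %% 10)
}

#' @rdname ean13_check_digit
#' @param ean candidate 13-digit string; an error is raised if malformed or
#'   if the check digit is wrong.
#' @export
ean13_validate <- function(ean) {
  if (length(ean) != 1 || !is.character(ean) || !grepl("^[0-9]{13}$", ean)) {
    stop("EAN-13 code must be a string of exactly 13 decimal digits",
         call. = FALSE)
  }
  expected <- ean13_check_digit(substr(ean, 1, 12))
  if (substr(ean, 13, 13) != expected) {
    corrupt_code_error(sprintf(
      "EAN-13 checksum mismatch: expected check digit %s, found %s",
      expected, substr(ean, 13, 13)))
  }
  invisible(ean)
}

# 95-element 0/1 module vector (1 = bar) for a validated 13-digit code.
ean13_modules <- function(ean) {
  ean13_validate(ean)
  d <- digits_of(ean)
  parity <- strsplit(EAN13_PARITY[d[1] + 1L], "")[[1]]
  left <- vapply(seq_len(6), function(j) {
    tab <- if (parity[j] == "L") EAN13_L else EAN13_G
    tab[d[j + 1L] + 1L]
  }, character(1))
  right <- vapply(seq_len(6), function(j) EAN13_R[d[j + 7L] + 1L], character(1))
  bits <- paste0("101", paste(left, collapse = ""), "01010",
                 paste(right, collapse = ""), "101")
  as.integer(strsplit(bits, "")[[1]])
}

#' Render an EAN-13 barcode as a grayscale raster
#'
#' Black bars (0) on a white (255) background with quiet zones on both
#' sides; the fixture-side inverse of [decode_ean13()].
#'
#' @param ean 13-digit code with a valid check digit.
#' @param module_px width of one module in pixels.
#' @param height_px bar height; default half the total width, giving the
#'   approximately 2:1 label aspect used on cage signs.
#' @param quiet_modules quiet-zone width on each side in modules, >= 9.
#' @return integer matrix (H x W) with values 0 or 255.
#' @export
render_ean13 <- function(ean, module_px = 4L, height_px = NULL,
                         quiet_modules = 9L) {
  module_px <- as.integer(module_px)
  quiet_modules <- as.integer(quiet_modules)
  if (quiet_modules < 9L) stop("quiet_modules must be >= 9", call. = FALSE)
  if (module_px < 1L) stop("module_px must be >= 1", call. = FALSE)
  mods <- ean13_modules(ean)
  width <- (95L + 2L * quiet_modules) * module_px
  if (is.null(height_px)) height_px <- as.integer(round(width / 2))
  cols <- c(rep(0L, quiet_modules), mods, rep(0L, quiet_modules))
  col_vals <- ifelse(rep(cols, each = module_px) == 1L, 0L, 255L)
  matrix(rep(col_vals, each = height_px), nrow = height_px, ncol = width)
}

# Quantise the 4 element widths of one digit to modules summing to 7.
runs_to_modules <- function(w) {
  scaled <- w * 7 / sum(w)
  m <- pmin(4L, pmax(1L, as.integer(round(scaled))))
  resid <- scaled - m
  guard <- 0L
  while (sum(m) != 7L && guard < 8L) {
    if (sum(m) < 7L) {
      i <- which.max(ifelse(m < 4L, resid, -Inf))
      m[i] <- m[i] + 1L
    } else {
      i <- which.min(ifelse(m > 1L, resid, Inf))
      m[i] <- m[i] - 1L
    }
    resid <- scaled - m
    guard <- guard + 1L
  }
  if (sum(m) != 7L) return(NULL)
  m
}

pattern_string <- function(modules, first_bit) {
  bits <- character(0)
  bit <- first_bit
  for (m in modules) {
    bits <- c(bits, strrep(as.character(bit), m))
    bit <- 1L - bit
  }
  paste(bits, collapse = "")
}

# Decode one scanline in both reading directions (the located region's
# orientation is only known up to 180 degrees).
decode_scanline_both <- function(vals) {
  c(decode_scanline_profile(vals), decode_scanline_profile(rev(vals)))
}

# Decode one scanline intensity profile. Returns candidate 13-digit strings
# (usually 0 or 1) without enforcing the checksum.
decode_scanline_profile <- function(vals) {
  vals <- as.numeric(vals)
  if (length(vals) < 95 || length(unique(round(vals))) < 2) return(character(0))
  t_star <- otsu_threshold(histogram256(round(pmin(255, pmax(0, vals)))))
  dark <- vals <= t_star
  r <- rle(dark)
  n_runs <- length(r$lengths)
  out <- character(0)
  bar_starts <- which(r$values)
  for (s in bar_starts) {
    if (s + 58L > n_runs) break
    w <- r$lengths[s:(s + 58L)]
    m_est <- sum(w) / 95
    if (m_est < 1) next
    fixed <- c(1:3, 28:32, 57:59)  # start guard, center guard, end guard
    if (any(w[fixed] < 0.4 * m_est | w[fixed] > 1.8 * m_est)) next
    parity <- character(6); digits <- integer(12); ok <- TRUE
    for (j in 1:6) {
      mods <- runs_to_modules(w[(4L + 4L * (j - 1L)):(7L + 4L * (j - 1L))])
      if (is.null(mods)) { ok <- FALSE; break }
      pat <- pattern_string(mods, 0L)  # left digits start with a space
      hit_l <- match(pat, EAN13_L); hit_g <- match(pat, EAN13_G)
      if (!is.na(hit_l)) { digits[j] <- hit_l - 1L; parity[j] <- "L" }
      else if (!is.na(hit_g)) { digits[j] <- hit_g - 1L; parity[j] <- "G" }
      else { ok <- FALSE; break }
    }
    if (!ok) next
    for (j in 1:6) {
      mods <- runs_to_modules(w[(33L + 4L * (j - 1L)):(36L + 4L * (j - 1L))])
      if (is.null(mods)) { ok <- FALSE; break }
      pat <- pattern_string(mods, 1L)  # right digits start with a bar
      hit <- match(pat, EAN13_R)
      if (is.na(hit)) { ok <- FALSE; break }
      digits[j + 6L] <- hit - 1L
    }
    if (!ok) next
    first <- match(paste(parity, collapse = ""), EAN13_PARITY)
    if (is.na(first)) next
    out <- c(out, paste0(first - 1L, paste(digits, collapse = "")))
  }
  out
}

#' Decode an EAN-13 barcode from a grayscale image
#'
#' Scans evenly spaced scanlines across the barcode region (parallel to the
#' region's long axis, so in-plane rotation is handled), binarises each
#' scanline with its own Otsu threshold, measures the 95-module
#' bar/space structure, decodes the left half via L/G parity (recovering
#' the implicit leading digit) and the right half via R patterns, takes a
#' majority vote across scanlines, and verifies the check digit.
#'
#' @param img grayscale image matrix (0-255).
#' @param region optional [barcode_region()]; when `NULL` the whole image
#'   is treated as an axis-aligned barcode.
#' @param n_scanlines number of scanlines, >= 5.
#' @param inset pixels trimmed from each end of every scanline, keeping
#'   samples inside the label backing.
#' @return list with `code` (13-digit string) and `votes` (number of
#'   scanlines agreeing on it).
#' @export
decode_ean13 <- function(img, region = NULL, n_scanlines = 7L, inset = 3) {
  stopifnot(is.matrix(img))
  n_scanlines <- max(5L, as.integer(n_scanlines))
  candidates <- character(0)
  fractions <- seq(0.28, 0.72, length.out = n_scanlines)
  if (is.null(region)) {
    rows <- unique(pmax(1L, pmin(nrow(img), round(fractions * nrow(img)))))
    for (ri in rows) {
      candidates <- c(candidates, decode_scanline_both(img[ri, ]))
    }
  } else {
    stopifnot(inherits(region, "barcode_region"))
    long_side <- max(region$width, region$height)
    short_side <- min(region$width, region$height)
    theta <- region$angle_deg * pi / 180
    if (region$height > region$width) theta <- theta + pi / 2
    u <- c(cos(theta), sin(theta))   # along the long side
    v <- c(-sin(theta), cos(theta))  # along the short side
    t_seq <- seq(-long_side / 2 + inset, long_side / 2 - inset, by = 1)
    if (length(t_seq) < 95) no_barcode_error("region too small to hold a barcode")
    for (f in fractions) {
      off <- (f - 0.5) * (short_side - 2 * inset)
      px <- region$center_x + t_seq * u[1] + off * v[1]
      py <- region$center_y + t_seq * u[2] + off * v[2]
      vals <- bilinear_sample(img, px, py)
      candidates <- c(candidates, decode_scanline_both(vals))
    }
  }
  if (length(candidates) == 0) {
    no_barcode_error("no scanline produced a well-formed 95-module structure")
  }
  tab <- sort(table(candidates), decreasing = TRUE)
  # prefer the most-voted checksum-valid candidate
  for (code in names(tab)) {
    ok <- tryCatch({ ean13_validate(code); TRUE },
                   nestscan_corrupt_code = function(e) FALSE)
    if (ok) return(list(code = code, votes = unname(tab[[code]])))
  }
  corrupt_code_error(sprintf(
    "scanlines agree on '%s' but its check digit is invalid", names(tab)[1]))
}

# Bilinear interpolation of img (rows = y, cols = x, 0-based continuous
# coordinates at pixel centers) at points (px, py); replicated borders.
bilinear_sample <- function(img, px, py) {
  h <- nrow(img); w <- ncol(img)
  px <- pmin(pmax(px, 0), w - 1); py <- pmin(pmax(py, 0), h - 1)
  x0 <- floor(px); y0 <- floor(py)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- px - x0; fy <- py - y0
  idx <- function(yy, xx) img[cbind(yy + 1, xx + 1)]
  (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy * idx(y1, x0) + fx * fy * idx(y1, x1)
}
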