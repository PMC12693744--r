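#' Read and write 8-bit images as PNG
#'
#' Images move through the package on the 0-255 scale: RGB as H x W x 3
#' arrays, grayscale as H x W matrices. PNG files store channels in
#' \[0, 1\]; these helpers convert.
#'
#' @param path PNG file path.
#' @return `read_image_png()` returns an H x W x 3 array (grayscale files
#'   are replicated to three channels).
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (is.matrix(img)) {
    img <- array(rep(img, 3), dim = c(nrow(img), ncol(img), 3))
  }
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  round(img * 255)
}

#' @rdname read_image_png
#' @param img H x W x 3 array or H x W matrix on the 0-255 scale.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Package configuration
#'
#' Nested defaults for every tunable stage, overridable from a YAML file
#' with matching sections (`detector`, `fusion`, `barcode`, `loss`,
#' `simulation`); values absent from the file keep their defaults.
#'
#' @param path optional YAML file.
#' @return nested configuration list.
#' @export
nestscan_config <- function(path = NULL) {
  cfg <- list(
    detector = list(conf_threshold = 0.25, min_area = 1500,
                    max_area = 30000, axis_ratio_max = 1.8),
    fusion = list(n_frames = 3, threshold = 2, sample_interval = 10,
                  match_radius = 40),
    barcode = list(r_coef = 0.299, g_coef = 0.587, b_coef = 0.114,
                   min_area_frac = 0.001, target_ratio = 2.0,
                   ratio_tol = 0.25, canny_sigma = 1.4, canny_low = 50,
                   canny_high = 150, prefix = "2000"),
    loss = list(alpha = 1.9, delta = 3.0, ema_decay = 0.9,
                simam_lambda = 1e-4),
    simulation = list(width = 1920, height = 1080, n_eggs = 2,
                      noise_density = 0.01, p_occlude = 0.0,
                      egg_jitter = 6, module_px = 4)
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (section in names(user)) {
      if (section %in% names(cfg) && is.list(user[[section]])) {
        cfg[[section]] <- utils::modifyList(cfg[[section]], user[[section]])
      }
    }
  }
  cfg
}
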