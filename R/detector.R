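#' Reference detector configuration
#'
#' The classical reference detector stands in for a trained neural detector
#' so the whole inspection chain runs end to end; any detector honouring
#' the provider contract (see [run_provider()]) can replace it.
#'
#' @param conf_threshold detections below this confidence are discarded;
#'   default 0.25, the operating point chosen to favour recall.
#' @param min_area,max_area component pixel-area band for egg-sized blobs
#'   (defaults sized for eggs at 1920x1080).
#' @param axis_ratio_max maximum long/short side ratio of the component's
#'   minimum-area rectangle; eggs are mildly elongated ellipses.
#' @return An object of class `"detector_config"`.
#' @export
detector_config <- function(conf_threshold = 0.25, min_area = 1500,
                            max_area = 30000, axis_ratio_max = 1.8) {
  if (conf_threshold < 0 || conf_threshold > 1) {
    stop("conf_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (min_area >= max_area) stop("min_area must be < max_area", call. = FALSE)
  structure(list(conf_threshold = conf_threshold, min_area = min_area,
                 max_area = max_area, axis_ratio_max = axis_ratio_max),
            class = "detector_config")
}

#' Classical reference egg detector
#'
#' Deterministic chain: grayscale conversion, Otsu binarisation, 8-connected
#' component extraction, then per-component ellipse-likeness scoring.
#' A component is kept when its pixel area lies in
#' `[min_area, max_area]` and its minimum-area-rectangle side ratio is at
#' most `axis_ratio_max`. The fill ratio compares the component's pixel
#' area with the area of the ellipse inscribed in its minimum-area
#' rectangle (`pi/4` of the rectangle), so a clean ellipse scores ~1;
#' confidence = fill ratio x (short side / long side), and detections
#' below `conf_threshold` are dropped. Detections are returned in
#' descending confidence.
#'
#' @param rgb H x W x 3 RGB array (0-255) or a grayscale matrix.
#' @param cfg a [detector_config()].
#' @param frame_index,timestamp passed through to the [frame_result()].
#' @return a [frame_result()].
#' @export
detect_eggs <- function(rgb, cfg = detector_config(),
                        frame_index = 0L, timestamp = NA_real_) {
  gray <- if (is.matrix(rgb)) rgb else to_grayscale(rgb)
  t_star <- otsu_threshold(histogram256(gray))
  bin <- binarize(gray, t_star)
  lab <- label_components_cpp(bin)
  n <- attr(lab, "n_components")
  dets <- list()
  if (n > 0) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    cand <- which(areas >= cfg$min_area & areas <= cfg$max_area)
    if (length(cand) > 0) {
      h <- nrow(lab)
      idx <- which(lab > 0L)
      labv <- lab[idx]
      keep <- labv %in% cand
      idx <- idx[keep]; labv <- labv[keep]
      ys <- (idx - 1L) %% h       # 0-based row = y
      xs <- (idx - 1L) %/% h      # 0-based col = x
      for (l in cand) {
        sel <- labv == l
        px <- cbind(xs[sel], ys[sel])
        rect <- min_area_rect(px)
        long_side <- max(rect$width, rect$height)
        short_side <- min(rect$width, rect$height)
        if (long_side / short_side > cfg$axis_ratio_max) next
        # rect of pixel centers underestimates the true footprint by ~1 px
        fill <- min(1, areas[l] / (pi / 4 * (rect$width + 1) * (rect$height + 1)))
        conf <- fill * (short_side / long_side)
        if (conf < cfg$conf_threshold) next
        b <- box(min(px[, 1]), min(px[, 2]), max(px[, 1]) + 1, max(px[, 2]) + 1)
        dets[[length(dets) + 1L]] <- detection(b, conf)
      }
    }
  }
  if (length(dets) > 1) {
    dets <- dets[order(-vapply(dets, `[[`, numeric(1), "confidence"))]
  }
  frame_result(frame_index, dets, timestamp)
}

#' Run a detection provider over a cycle of frames
#'
#' The provider contract: any callable mapping an image to a
#' [frame_result()]. Results are re-indexed 0..N-1 in input order. A
#' provider error on one frame is contained: that frame becomes an empty
#' result (a "no" vote for the fusion stage) and a warning is emitted.
#'
#' @param frames list of images.
#' @param provider function taking an image and returning a `frame_result`.
#' @return list of [frame_result()] objects, one per frame.
#' @export
run_provider <- function(frames, provider) {
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fi <- i - 1L
    res <- tryCatch(provider(frames[[i]]), error = function(e) {
      warning(sprintf("detection provider failed on frame %d: %s",
                      fi, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res) || !inherits(res, "frame_result")) {
      res <- frame_result(fi, list())
    } else {
      res$frame_index <- fi
    }
    out[[i]] <- res
  }
  out
}
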