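#' Axis-aligned bounding box
#'
#' Boxes use continuous pixel coordinates with the origin at the top-left
#' corner of the image, x increasing rightwards and y increasing downwards.
#' A box is a real rectangle: no +/-1 pixel correction is applied to areas,
#' and zero-area boxes are rejected rather than clamped so that degenerate
#' geometry surfaces as an error at the point of construction.
#'
#' @param x_min,y_min,x_max,y_max box corners in pixels; `x_min < x_max`
#'   and `y_min < y_max` are required.
#' @return An object of class `"box"`: a named numeric vector with fields
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @examples
#' b <- box(0, 0, 10, 10)
#' box_area(b)
#' @export
box <- function(x_min, y_min, x_max, y_max) {
  v <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (anyNA(v) || !all(is.finite(v))) {
    stop("box coordinates must be finite numbers", call. = FALSE)
  }
  if (v[["x_min"]] >= v[["x_max"]] || v[["y_min"]] >= v[["y_max"]]) {
    stop("degenerate box: x_min < x_max and y_min < y_max are required",
         call. = FALSE)
  }
  structure(v, class = "box")
}

as_box <- function(b) {
  if (inherits(b, "box")) return(b)
  if (is.numeric(b) && length(b) == 4) {
    return(box(b[[1]], b[[2]], b[[3]], b[[4]]))
  }
  stop("cannot interpret object as a box", call. = FALSE)
}

#' @rdname box
#' @param b a `box`.
#' @export
box_area <- function(b) {
  b <- as_box(b)
  unname((b[["x_max"]] - b[["x_min"]]) * (b[["y_max"]] - b[["y_min"]]))
}

#' @rdname box
#' @export
box_center <- function(b) {
  b <- as_box(b)
  c(x = unname(b[["x_min"]] + b[["x_max"]]) / 2,
    y = unname(b[["y_min"]] + b[["y_max"]]) / 2)
}

#' Intersection over union of two boxes
#'
#' The base overlap quantity behind the IoU regression loss: intersection
#' area divided by union area. Symmetric, bounded in \[0, 1\], exactly 0 for
#' disjoint boxes and 1 for identical boxes.
#'
#' @param a,b valid boxes (see [box()]).
#' @return IoU in \[0, 1\].
#' @examples
#' iou(box(0, 0, 10, 10), box(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ix <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
  iy <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
  inter <- max(0, ix) * max(0, iy)
  union <- box_area(a) + box_area(b) - inter
  inter / union
}

#' IoU loss
#'
#' `1 - iou(a, b)`: zero for a perfect match, one for disjoint boxes.
#'
#' @inheritParams iou
#' @return loss in \[0, 1\].
#' @export
iou_loss <- function(a, b) 1 - iou(a, b)

#' Smallest box enclosing two boxes
#'
#' @inheritParams iou
#' @return a `box` containing both inputs.
#' @export
enclosing_box <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  box(min(a[["x_min"]], b[["x_min"]]), min(a[["y_min"]], b[["y_min"]]),
      max(a[["x_max"]], b[["x_max"]]), max(a[["y_max"]], b[["y_max"]]))
}

#' Single-class egg detection
#'
#' @param box a `box`.
#' @param confidence detection confidence in \[0, 1\].
#' @return An object of class `"detection"`.
#' @export
detection <- function(box, confidence) {
  box <- as_box(box)
  confidence <- as.numeric(confidence)
  if (is.na(confidence) || confidence < 0 || confidence > 1) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  structure(list(box = box, confidence = confidence, label = "egg"),
            class = "detection")
}

#' Per-frame detection result
#'
#' @param frame_index integer frame index, >= 0, unique within a cycle.
#' @param detections list of [detection()] objects (possibly empty).
#' @param timestamp acquisition time in seconds from cycle start.
#' @return An object of class `"frame_result"`.
#' @export
frame_result <- function(frame_index, detections = list(), timestamp = NA_real_) {
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0) {
    stop("frame_index must be a non-negative integer", call. = FALSE)
  }
  stopifnot(is.list(detections))
  for (d in detections) {
    if (!inherits(d, "detection")) {
      stop("detections must be a list of detection objects", call. = FALSE)
    }
  }
  structure(list(frame_index = frame_index,
                 timestamp = as.numeric(timestamp),
                 detections = detections),
            class = "frame_result")
}

#' @export
print.frame_result <- function(x, ...) {
  cat(sprintf("<frame %d: %d detection(s)>\n",
              x$frame_index, length(x$detections)))
  invisible(x)
}

#' Read and write detections as JSON lines
#'
#' One JSON object per line with fields `frame`, `x_min`, `y_min`, `x_max`,
#' `y_max`, `confidence`; the sidecar format shared by the detector, the
#' fusion stage and the command-line tools.
#'
#' @param frames list of [frame_result()] objects.
#' @param path file path.
#' @return `write_detections_jsonl()` returns the path invisibly;
#'   `read_detections_jsonl()` returns a list of `frame_result` objects
#'   ordered by frame index.
#' @export
write_detections_jsonl <- function(frames, path) {
  lines <- character(0)
  for (fr in frames) {
    for (d in fr$detections) {
      b <- d$box
      lines <- c(lines, jsonlite::toJSON(
        list(frame = fr$frame_index,
             x_min = unname(b[["x_min"]]), y_min = unname(b[["y_min"]]),
             x_max = unname(b[["x_max"]]), y_max = unname(b[["y_max"]]),
             confidence = d$confidence),
        auto_unbox = TRUE, digits = NA))
    }
    if (length(fr$detections) == 0) {
      lines <- c(lines, jsonlite::toJSON(
        list(frame = fr$frame_index), auto_unbox = TRUE))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_detections_jsonl
#' @export
read_detections_jsonl <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  idx <- vapply(recs, function(r) as.integer(r$frame), integer(1))
  out <- list()
  for (fi in sort(unique(idx))) {
    dets <- list()
    for (r in recs[idx == fi]) {
      if (!is.null(r$x_min)) {
        dets[[length(dets) + 1L]] <- detection(
          box(r$x_min, r$y_min, r$x_max, r$y_max), r$confidence)
      }
    }
    out[[length(out) + 1L]] <- frame_result(fi, dets)
  }
  out
}
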