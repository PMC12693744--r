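#' Synthetic cage-scene specification
#'
#' Describes one nest scene as the inspection camera would see it: a dark
#' nest-floor background crossed by a wire grid, up to six light egg
#' ellipses placed without mutual overlap, a printed EAN-13 cage label at
#' an approximately 2:1 aspect on the cage exterior, and impulse
#' (salt-and-pepper) sensor noise. All randomness (layout, noise,
#' occlusion) derives from one seed via independent sub-streams, so the
#' layout is comparable across noise or occlusion settings.
#'
#' @param width,height frame size in pixels (default 1920 x 1080, the
#'   acquisition resolution).
#' @param n_eggs number of eggs, 0-6 (a cage nest holds at most 6).
#' @param egg_axis_a,egg_axis_b ranges of the egg semi-axes in pixels.
#' @param egg_gray range of egg albedo gray levels (eggs are light).
#' @param background_gray nest floor gray level.
#' @param wire_pitch,wire_thickness,wire_gray wire-grid geometry and tone.
#' @param position a [position_code()] embedded in the cage label.
#' @param module_px barcode module width in pixels.
#' @param noise_density fraction of pixels hit by impulse noise; default 1%.
#' @param seed integer RNG seed.
#' @return An object of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 1920L, height = 1080L, n_eggs = 2L,
                       egg_axis_a = c(38, 52), egg_axis_b = c(30, 42),
                       egg_gray = c(200, 235), background_gray = 70,
                       wire_pitch = 90L, wire_thickness = 4L, wire_gray = 35,
                       position = position_code(1, 1, 21, 4),
                       module_px = 4L, noise_density = 0.01, seed = 1L) {
  stopifnot(inherits(position, "position_code"))
  if (n_eggs < 0 || n_eggs > 6) stop("n_eggs must be 0-6", call. = FALSE)
  if (noise_density < 0 || noise_density > 1) {
    stop("noise_density must lie in [0, 1]", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_eggs = as.integer(n_eggs),
                 egg_axis_a = egg_axis_a, egg_axis_b = egg_axis_b,
                 egg_gray = egg_gray, background_gray = background_gray,
                 wire_pitch = as.integer(wire_pitch),
                 wire_thickness = as.integer(wire_thickness),
                 wire_gray = wire_gray, position = position,
                 module_px = as.integer(module_px),
                 noise_density = noise_density, seed = as.integer(seed)),
            class = "scene_spec")
}

boxes_intersect <- function(a, b, margin = 0) {
  !(a[["x_max"]] + margin <= b[["x_min"]] ||
      b[["x_max"]] + margin <= a[["x_min"]] ||
      a[["y_max"]] + margin <= b[["y_min"]] ||
      b[["y_max"]] + margin <= a[["y_min"]])
}

# Deterministic scene layout: label placement and egg geometry.
make_layout <- function(spec) {
  local_seed(sub_seed(spec$seed, 1L), {
    ean <- embed_in_ean13(spec$position)
    bar_w <- (95L + 2L * 9L) * spec$module_px
    pad_x <- 2L * spec$module_px
    lab_w <- bar_w + 2L * pad_x
    lab_h <- as.integer(round(lab_w / 2))
    pad_y <- max(4L, as.integer(round(0.06 * lab_h)))
    bar_h <- lab_h - 2L * pad_y
    margin <- 20L
    lx <- as.integer(round(runif(1, margin, spec$width - lab_w - margin)))
    ly <- as.integer(round(runif(1, margin, 0.25 * spec$height)))
    label_box <- box(lx, ly, lx + lab_w, ly + lab_h)
    eggs <- list()
    tries <- 0L
    while (length(eggs) < spec$n_eggs && tries < 400L) {
      tries <- tries + 1L
      a <- runif(1, spec$egg_axis_a[1], spec$egg_axis_a[2])
      b <- runif(1, spec$egg_axis_b[1], spec$egg_axis_b[2])
      if (b > a) { tmp <- a; a <- b; b <- tmp }
      theta <- runif(1, 0, pi)
      ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
      ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
      cx <- runif(1, margin + ex, spec$width - margin - ex)
      cy <- runif(1, margin + ey, spec$height - margin - ey)
      bb <- box(cx - ex, cy - ey, cx + ex, cy + ey)
      ok <- !boxes_intersect(bb, label_box, margin = 12)
      if (ok) {
        for (e in eggs) {
          if (boxes_intersect(bb, e$bbox, margin = 8)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      eggs[[length(eggs) + 1L]] <- list(
        cx = cx, cy = cy, a = a, b = b, theta = theta,
        albedo = runif(1, spec$egg_gray[1], spec$egg_gray[2]), bbox = bb)
    }
    if (length(eggs) < spec$n_eggs) {
      stop("could not place all eggs without overlap; reduce n_eggs or egg size",
           call. = FALSE)
    }
    list(spec = spec, ean = ean, label_x = lx, label_y = ly,
         label_w = lab_w, label_h = lab_h, pad_x = pad_x, pad_y = pad_y,
         bar_h = bar_h, eggs = eggs)
  })
}

draw_ellipse <- function(canvas, cx, cy, a, b, theta, value, shading = 0.12) {
  h <- nrow(canvas); w <- ncol(canvas)
  ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  x0 <- max(0L, floor(cx - ex)); x1 <- min(w - 1L, ceiling(cx + ex))
  y0 <- max(0L, floor(cy - ey)); y1 <- min(h - 1L, ceiling(cy + ey))
  if (x1 < x0 || y1 < y0) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(ys - cy, xs - cx, function(yy, xx) xx)
  dy <- outer(ys - cy, xs - cx, function(yy, xx) yy)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  r2 <- u^2 + v^2
  mask <- r2 <= 1
  sub <- canvas[ys + 1L, xs + 1L, drop = FALSE]
  sub[mask] <- round(value * (1 - shading * r2[mask]))
  canvas[ys + 1L, xs + 1L] <- sub
  canvas
}

render_from_layout <- function(layout, noise_seed, occlude = FALSE,
                               jitter = NULL) {
  spec <- layout$spec
  h <- spec$height; w <- spec$width
  canvas <- matrix(as.integer(spec$background_gray), h, w)
  # wire grid (behind the eggs: the camera looks down onto the nest floor;
  # frontal occlusion by the pigeon body is modelled per frame instead)
  if (spec$wire_pitch > 0 && spec$wire_thickness > 0) {
    wire_cols <- which((0:(w - 1)) %% spec$wire_pitch < spec$wire_thickness)
    wire_rows <- which((0:(h - 1)) %% spec$wire_pitch < spec$wire_thickness)
    canvas[, wire_cols] <- as.integer(spec$wire_gray)
    canvas[wire_rows, ] <- as.integer(spec$wire_gray)
  }
  # eggs (optionally jittered per frame)
  frame_boxes <- list()
  for (i in seq_along(layout$eggs)) {
    e <- layout$eggs[[i]]
    dx <- if (is.null(jitter)) 0 else jitter[i, 1]
    dy <- if (is.null(jitter)) 0 else jitter[i, 2]
    canvas <- draw_ellipse(canvas, e$cx + dx, e$cy + dy, e$a, e$b, e$theta,
                           e$albedo)
    ex <- sqrt((e$a * cos(e$theta))^2 + (e$b * sin(e$theta))^2)
    ey <- sqrt((e$a * sin(e$theta))^2 + (e$b * cos(e$theta))^2)
    frame_boxes[[i]] <- box(e$cx + dx - ex, e$cy + dy - ey,
                            e$cx + dx + ex, e$cy + dy + ey)
  }
  # cage label: white backing with the rendered barcode
  bar <- render_ean13(layout$ean, module_px = spec$module_px,
                      height_px = layout$bar_h, quiet_modules = 9L)
  backing <- matrix(255L, layout$label_h, layout$label_w)
  backing[(layout$pad_y + 1L):(layout$pad_y + layout$bar_h),
          (layout$pad_x + 1L):(layout$pad_x + ncol(bar))] <- bar
  canvas[(layout$label_y + 1L):(layout$label_y + layout$label_h),
         (layout$label_x + 1L):(layout$label_x + layout$label_w)] <- backing
  # transient occlusion: the pigeon body covers the whole nest region
  if (occlude) {
    if (length(layout$eggs) > 0) {
      cxs <- vapply(layout$eggs, `[[`, numeric(1), "cx")
      cys <- vapply(layout$eggs, `[[`, numeric(1), "cy")
      span <- max(vapply(layout$eggs, function(e) max(e$a, e$b), numeric(1)))
      ocx <- mean(cxs); ocy <- mean(cys)
      ra <- (max(cxs) - min(cxs)) / 2 + span + 60
      rb <- (max(cys) - min(cys)) / 2 + span + 60
    } else {
      ocx <- spec$width / 2; ocy <- spec$height * 0.6
      ra <- spec$width * 0.2; rb <- spec$height * 0.25
    }
    canvas <- draw_ellipse(canvas, ocx, ocy, max(ra, rb * 0.8), rb,
                           0, 105, shading = 0.05)
  }
  # impulse noise
  if (spec$noise_density > 0) {
    canvas <- local_seed(noise_seed, {
      n_noise <- round(spec$noise_density * h * w)
      idx <- sample.int(h * w, n_noise)
      vals <- ifelse(runif(n_noise) < 0.5, 0L, 255L)
      canvas[idx] <- vals
      canvas
    })
  }
  rgb <- array(0, dim = c(h, w, 3))
  rgb[, , 1] <- canvas; rgb[, , 2] <- canvas; rgb[, , 3] <- canvas
  list(rgb = rgb, frame_boxes = frame_boxes)
}

#' Render one synthetic cage scene
#'
#' Deterministic given `spec$seed`: the same spec always yields a
#' bit-identical image.
#'
#' @param spec a [scene_spec()].
#' @return list with `rgb` (H x W x 3 array, 0-255) and `truth`, a
#'   `scene_truth` list carrying the true egg boxes, the embedded uid, the
#'   label region and per-egg occlusion flags.
#' @export
render_scene <- function(spec) {
  layout <- make_layout(spec)
  res <- render_from_layout(layout, noise_seed = sub_seed(spec$seed, 2L))
  truth <- structure(list(
    egg_boxes = res$frame_boxes,
    uid = format_position(spec$position),
    ean = layout$ean,
    barcode_region = barcode_region(
      layout$label_x + layout$label_w / 2, layout$label_y + layout$label_h / 2,
      layout$label_w, layout$label_h, 0),
    occluded = rep(FALSE, length(res$frame_boxes))),
    class = "scene_truth")
  list(rgb = res$rgb, truth = truth)
}

#' Inspection-cycle specification
#'
#' One cycle photographs the same nest `n_frames` times at
#' `interval`-second spacing. Each frame is independently occluded with
#' probability `p_occlude` (the pigeon body covering the nest — all eggs
#' hidden at once, the label on the cage exterior still visible), and egg
#' centers drift by up to `egg_jitter` pixels between frames (eggs rolling
#' slightly as the parent moves).
#'
#' @param scene a [scene_spec()].
#' @param n_frames frames per cycle, default 3.
#' @param interval seconds between frames, default 10.
#' @param p_occlude per-frame occlusion probability in \[0, 1\].
#' @param egg_jitter maximum per-frame egg drift in pixels, default 6.
#' @return An object of class `"cycle_spec"`.
#' @export
cycle_spec <- function(scene = scene_spec(), n_frames = 3L, interval = 10,
                       p_occlude = 0.0, egg_jitter = 6) {
  stopifnot(inherits(scene, "scene_spec"))
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (p_occlude < 0 || p_occlude > 1) {
    stop("p_occlude must lie in [0, 1]", call. = FALSE)
  }
  structure(list(scene = scene, n_frames = as.integer(n_frames),
                 interval = interval, p_occlude = p_occlude,
                 egg_jitter = egg_jitter),
            class = "cycle_spec")
}

#' Render one inspection cycle
#'
#' @param cspec a [cycle_spec()].
#' @return list with `frames` (list of RGB arrays), `truth` (as in
#'   [render_scene()]), `occluded` (per-frame logical), and `frame_boxes`
#'   (per-frame true egg boxes after jitter).
#' @export
render_cycle <- function(cspec) {
  stopifnot(inherits(cspec, "cycle_spec"))
  spec <- cspec$scene
  layout <- make_layout(spec)
  occluded <- local_seed(sub_seed(spec$seed, 3L),
                         runif(cspec$n_frames) < cspec$p_occlude)
  frames <- vector("list", cspec$n_frames)
  frame_boxes <- vector("list", cspec$n_frames)
  base_boxes <- NULL
  for (f in seq_len(cspec$n_frames)) {
    jitter <- NULL
    if (spec$n_eggs > 0) {
      jitter <- local_seed(sub_seed(spec$seed, 10L + f), matrix(
        runif(2L * spec$n_eggs, -cspec$egg_jitter, cspec$egg_jitter),
        ncol = 2))
    }
    res <- render_from_layout(layout, noise_seed = sub_seed(spec$seed, 20L + f),
                              occlude = occluded[f], jitter = jitter)
    frames[[f]] <- res$rgb
    frame_boxes[[f]] <- res$frame_boxes
    if (f == 1L) base_boxes <- res$frame_boxes
  }
  truth <- structure(list(
    egg_boxes = base_boxes,
    uid = format_position(spec$position),
    ean = layout$ean,
    barcode_region = barcode_region(
      layout$label_x + layout$label_w / 2, layout$label_y + layout$label_h / 2,
      layout$label_w, layout$label_h, 0),
    occluded = occluded),
    class = "scene_truth")
  list(frames = frames, truth = truth, occluded = occluded,
       frame_boxes = frame_boxes)
}

#' Presence-level simulation of many inspection cycles
#'
#' For noise-free scenes the per-frame presence outcome of an occupied
#' nest is determined by the occlusion draw alone, so large cycle counts
#' can be simulated at the Bernoulli level without rasterising frames:
#' each frame of each cycle is occluded independently with probability
#' `p_occlude`, and the T-of-N vote is applied. Returns the observed miss
#' rate, which converges to `1 - system_reliability(1 - p_occlude,
#' policy)`.
#'
#' @param p_occlude per-frame occlusion probability.
#' @param policy a [voting_policy()].
#' @param n_cycles number of cycles.
#' @param seed RNG seed.
#' @return observed miss rate in \[0, 1\].
#' @export
simulate_presence_cycles <- function(p_occlude, policy = voting_policy(),
                                     n_cycles = 10000L, seed = 1L) {
  simulate_cycles(1 - p_occlude, policy, n_cycles, seed)
}
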