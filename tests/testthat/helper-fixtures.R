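# Desk-scale fixtures: small frames keep unit tests quick while preserving
# every structural feature of the full-resolution scenes (wire grid, label
# geometry, egg ellipses, impulse noise).

small_scene <- function(n_eggs = 2L, seed = 1L, noise_density = 0.01, ...) {
  scene_spec(width = 640L, height = 360L, n_eggs = n_eggs,
             egg_axis_a = c(16, 22), egg_axis_b = c(13, 18),
             wire_pitch = 60L, wire_thickness = 3L,
             module_px = 2L, noise_density = noise_density, seed = seed, ...)
}

small_detector <- function(...) {
  detector_config(min_area = 300, max_area = 4000, ...)
}

# Pixel-sampling Monte-Carlo IoU estimate, independent of the closed form.
mc_iou <- function(a, b, n = 50000L) {
  enc <- enclosing_box(a, b)
  xs <- runif(n, enc[["x_min"]], enc[["x_max"]])
  ys <- runif(n, enc[["y_min"]], enc[["y_max"]])
  in_box <- function(bx) {
    xs >= bx[["x_min"]] & xs <= bx[["x_max"]] &
      ys >= bx[["y_min"]] & ys <= bx[["y_max"]]
  }
  ia <- in_box(a); ib <- in_box(b)
  both <- sum(ia & ib); either <- sum(ia | ib)
  list(est = both / either,
       se = sqrt(both / n * (1 - both / n) / n) * n / either)
}

random_box <- function(max_coord = 100) {
  x <- sort(runif(2, 0, max_coord)); y <- sort(runif(2, 0, max_coord))
  box(x[1], y[1], x[2] + 1, y[2] + 1)
}
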