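# Small fixtures built in code.

square_mask <- function(x, y, side) {
  list(rbind(c(x, y), c(x + side, y), c(x + side, y + side), c(x, y + side)))
}

rect_mask <- function(x, y, w, h) {
  list(rbind(c(x, y), c(x + w, y), c(x + w, y + h), c(x, y + h)))
}

# A non-convex L-shaped ring.
l_mask <- function(x = 0, y = 0, s = 10) {
  list(rbind(c(x, y), c(x + s, y), c(x + s, y + s / 2), c(x + s / 2, y + s / 2),
             c(x + s / 2, y + s), c(x, y + s)))
}

simple_annotation <- function(id, sp, x, y, side = 10, polyline = TRUE) {
  fish_annotation(id, sp, square_mask(x, y, side),
                  size_polyline = if (polyline)
                    rbind(c(x, y + side / 2), c(x + side, y + side / 2))
                  else NULL)
}

simple_detection <- function(sp, x, y, side = 10, conf = 0.9) {
  detection_instance(sp, square_mask(x, y, side), confidence = conf)
}

capsule_points <- function(len, wid, cx, cy, angle = 0) {
  ring <- traymetry:::capsule_ring(len, wid)
  R <- rbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  sweep(ring %*% t(R), 2, -c(cx, cy))
}

# Fast scene config for tests: fewer fish per tray.
test_scene_config <- function(...) {
  scene_config(fish_per_tray = c(3, 6), ...)
}
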