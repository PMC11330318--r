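# Shared fixtures: small, fast synthetic scales and independent oracles used
# across the suite.

# A compact scale that renders in ~0.1 s; noise-free variants derive from it.
small_sim_params <- function(seed = 1L, ...) {
  defaults <- list(
    image_width = 320L, image_height = 320L,
    focus_radius = 10, n_freshwater_rings = 6, n_marine_rings = 8,
    fw_base_spacing = 8, marine_base_spacing = 12,
    seasonal_amplitude = 2, seasonal_period = 4,
    band_sigma = 1, band_contrast = 0.45,
    noise_sigma = 0.02, eccentricity = 0.1, breakage_prob = 0,
    jitter = 0.05, seed = seed
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(scale_sim_params, defaults)
}

clean_sim_params <- function(seed = 1L, ...) {
  small_sim_params(seed = seed, noise_sigma = 0, jitter = 0,
                   breakage_prob = 0, ...)
}

# Random valid box inside [0, lim]^2. Corners land on a 0.1 px lattice so the
# 0.05-step counting grid of iou_grid_oracle never straddles a box edge and
# the pixel count is exact.
random_box <- function(lim = 100) {
  draw <- function() round(sort(runif(2, 0, lim)), 1)
  x <- draw()
  y <- draw()
  while (diff(x) < 1) x <- draw()
  while (diff(y) < 1) y <- draw()
  bbox(x[1], y[1], x[2], y[2], score = runif(1))
}

random_boxes <- function(n, lim = 100) {
  if (n == 0) return(bbox())
  do.call(rbind, lapply(seq_len(n), function(i) random_box(lim)))
}

# Pixel-counting IOU oracle on a fine grid: counts grid cells whose centres
# fall inside each box, entirely independent of the analytic implementation.
iou_grid_oracle <- function(a, b, step = 0.05) {
  x_lo <- min(a$x_min, b$x_min); x_hi <- max(a$x_max, b$x_max)
  y_lo <- min(a$y_min, b$y_min); y_hi <- max(a$y_max, b$y_max)
  xs <- seq(x_lo + step / 2, x_hi, by = step)
  ys <- seq(y_lo + step / 2, y_hi, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  in_a <- gx >= a$x_min & gx <= a$x_max & gy >= a$y_min & gy <= a$y_max
  in_b <- gx >= b$x_min & gx <= b$x_max & gy >= b$y_min & gy <= b$y_max
  sum(in_a & in_b) / sum(in_a | in_b)
}

# Step-function area oracle for average precision: numerically accumulates
# the area under the monotone precision envelope, written independently of
# the implementation's vectorised form.
ap_step_oracle <- function(tp_flags, n_gt) {
  n <- length(tp_flags)
  cum_tp <- 0
  precision <- numeric(n)
  recall <- numeric(n)
  for (i in seq_len(n)) {
    if (tp_flags[i]) cum_tp <- cum_tp + 1
    precision[i] <- cum_tp / i
    recall[i] <- cum_tp / n_gt
  }
  # monotone envelope by explicit backward scan
  for (i in rev(seq_len(n - 1))) {
    if (precision[i] < precision[i + 1]) precision[i] <- precision[i + 1]
  }
  area <- 0
  prev_r <- 0
  for (i in seq_len(n)) {
    area <- area + (recall[i] - prev_r) * precision[i]
    prev_r <- recall[i]
  }
  area
}

# Scalar clip-rectangle IOU written independently of the package's
# vectorised form.
iou_scalar_oracle <- function(a, b) {
  cx1 <- if (a$x_min > b$x_min) a$x_min else b$x_min
  cy1 <- if (a$y_min > b$y_min) a$y_min else b$y_min
  cx2 <- if (a$x_max < b$x_max) a$x_max else b$x_max
  cy2 <- if (a$y_max < b$y_max) a$y_max else b$y_max
  if (cx2 <= cx1 || cy2 <= cy1) return(0)
  inter <- (cx2 - cx1) * (cy2 - cy1)
  total <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  inter / total
}

# Plain double-loop greedy matcher used as the enumeration oracle on small
# instances: processes detections by descending score and scans every ground
# truth for the best available IOU.
match_oracle <- function(detections, ground_truths, thr = 0.5) {
  n_det <- nrow(detections)
  n_gt <- nrow(ground_truths)
  used <- rep(FALSE, n_gt)
  assigned <- rep(NA_integer_, n_det)
  for (i in order(-detections$score, seq_len(n_det))) {
    best_j <- 0
    best_iou <- -1
    for (j in seq_len(n_gt)) {
      if (used[j]) next
      v <- iou_scalar_oracle(detections[i, ], ground_truths[j, ])
      if (v > best_iou) {
        best_iou <- v
        best_j <- j
      }
    }
    if (best_j > 0 && best_iou >= thr) {
      used[best_j] <- TRUE
      assigned[i] <- best_j
    }
  }
  assigned
}

# Bisection root-find of the ray-ellipse intersection distance: the point at
# parameter t along the ray at `angle` (degrees) lies on the ellipse with
# vertical major radius r and minor radius r * (1 - ecc).
ray_ellipse_bisection <- function(r, angle, ecc, t_hi = 1e4) {
  th <- angle * pi / 180
  ux <- cos(th)
  uy <- -sin(th)
  b <- r * (1 - ecc)
  f <- function(t) (t * ux / b)^2 + (t * uy / r)^2 - 1
  lo <- 0
  hi <- t_hi
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
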