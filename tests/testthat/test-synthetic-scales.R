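test_that("ring radii follow the configured spacing profile", {
  # constant-spacing closed form, no jitter, no seasonal swing
  p <- clean_sim_params(focus_radius = 10, n_freshwater_rings = 3,
                        n_marine_rings = 0, fw_base_spacing = 5,
                        band_sigma = 1)
  expect_equal(generate_ring_radii(p), c(15, 20, 25))

  # successive differences reproduce the spacing formula evaluated here
  p2 <- clean_sim_params(n_freshwater_rings = 5, n_marine_rings = 12,
                         seasonal_amplitude = 2, seasonal_period = 6)
  radii <- generate_ring_radii(p2)
  expected <- c(rep(8, 5), 12 + 2 * sin(2 * pi * (1:12) / 6))
  expect_equal(diff(c(p2$focus_radius, radii)), expected, tolerance = 1e-12)

  # jitter stays within its configured multiplicative bounds
  p3 <- small_sim_params(seed = 11, jitter = 0.05)
  r3 <- generate_ring_radii(p3)
  sp3 <- diff(c(p3$focus_radius, r3))
  base <- c(rep(8, 6), 12 + 2 * sin(2 * pi * (1:8) / 4))
  expect_true(all(sp3 / base >= 0.95 & sp3 / base <= 1.05))

  # same seed, same radii
  expect_identical(generate_ring_radii(small_sim_params(seed = 4)),
                   generate_ring_radii(small_sim_params(seed = 4)))
})

test_that("ring radii are strictly increasing over random parameter draws", {
  set.seed(99)
  for (k in 1:25) {
    bs <- runif(1, 0.8, 1.5)
    fw <- runif(1, 2.2 * bs / 0.8, 9)
    ma <- fw + runif(1, 1, 8)
    amp <- runif(1, 0, min(2, ma - 2.2 * bs / 0.8 - fw * 0.01))
    p <- small_sim_params(seed = k, fw_base_spacing = fw,
                          marine_base_spacing = ma,
                          seasonal_amplitude = min(amp, ma - 2.5 * bs - 0.5),
                          band_sigma = bs,
                          n_freshwater_rings = sample(0:8, 1),
                          n_marine_rings = sample(1:8, 1))
    expect_true(all(diff(generate_ring_radii(p)) > 0))
  }
})

test_that("parameter combinations violating resolvability are rejected", {
  expect_error(small_sim_params(fw_base_spacing = 2, band_sigma = 1.2),
               "band_sigma")
  expect_error(small_sim_params(fw_base_spacing = 14), "narrow")
})

test_that("rendered rings are dark bands at their analytic positions", {
  p <- clean_sim_params(eccentricity = 0.15)
  sc <- render_scale(p)
  img <- sc$image
  cx <- p$focus_center[1]
  cy <- p$focus_center[2]
  radii <- sc$ring_major_radii
  # horizontally from the focus, a ring sits at minor radius r * (1 - e)
  on_ring <- img[round(cy) + 1, round(cx + radii * (1 - p$eccentricity)) + 1]
  mids <- (radii[-length(radii)] + radii[-1]) / 2
  between <- img[round(cy) + 1, round(cx + mids * (1 - p$eccentricity)) + 1]
  expect_true(all(on_ring < min(between)))
  expect_true(min(between) - max(on_ring) >= p$band_contrast / 2)
})

test_that("noise-free rendering is symmetric and seed-deterministic", {
  # grid-compatible centre so x-reflection maps pixel to pixel
  p <- clean_sim_params(focus_center = c(159.5, 159.5))
  img <- render_scale(p)$image
  expect_equal(img, img[, rev(seq_len(ncol(img)))], tolerance = 1e-12)

  p2 <- small_sim_params(seed = 8, breakage_prob = 0.3)
  expect_identical(render_scale(p2)$image, render_scale(p2)$image)
})

test_that("rendering fails when the outermost ring does not fit", {
  expect_error(render_scale(small_sim_params(n_marine_rings = 40)),
               "too small")
})

test_that("ground-truth transect boxes sit at the ray-ellipse intersection", {
  p <- clean_sim_params(eccentricity = 0)
  sc <- render_scale(p)
  gt <- ground_truth_for_transect(sc, 37, width = 10)
  # circle case: centre columns equal the major radii exactly
  expect_equal((gt$x_min + gt$x_max) / 2,
               sc$ring_major_radii[seq_len(nrow(gt))], tolerance = 1e-9)

  p2 <- clean_sim_params(eccentricity = 0.2)
  sc2 <- render_scale(p2)
  gt0 <- ground_truth_for_transect(sc2, 0, width = 10)
  expect_equal((gt0$x_min + gt0$x_max) / 2,
               (sc2$ring_major_radii * 0.8)[seq_len(nrow(gt0))],
               tolerance = 1e-9)

  # arbitrary angle: centres match an independent bisection root-find
  for (ang in c(23, 45, 111, 180, -30)) {
    gta <- ground_truth_for_transect(sc2, ang, width = 10)
    oracle <- vapply(sc2$ring_major_radii[seq_len(nrow(gta))],
                     ray_ellipse_bisection, numeric(1),
                     angle = ang, ecc = 0.2)
    expect_equal((gta$x_min + gta$x_max) / 2, oracle, tolerance = 1e-6)
  }

  # boxes are ordered and sized by the band width convention
  expect_true(all(diff((gt$x_min + gt$x_max) / 2) > 0))
  expect_equal(unique(gt$x_max - gt$x_min),
               2 * max(2 * p$band_sigma, 1.5))
  expect_equal(unique(gt$y_max - gt$y_min), 10)
})

test_that("reference detection closes the loop on a noise-free transect", {
  p <- clean_sim_params()
  sc <- render_scale(p)
  width <- transect_width(sc$focus_box)
  len <- transect_length_for_width(p$focus_center, 60, p$image_width,
                                   p$image_height, width)
  tr <- extract_transect(sc$image,
                         transect_spec(p$focus_center, 60, width, len))
  det <- detect_circuli(tr)
  gt <- ground_truth_for_transect(sc, 60, width)
  expect_equal(nrow(det), nrow(gt))
  expect_true(all(abs(det$center_column - (gt$x_min + gt$x_max) / 2) <= 1.5))
})
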