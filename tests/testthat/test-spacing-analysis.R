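make_detections <- function(centers, width = 4, height = 6) {
  det <- bbox(centers - width / 2, 0, centers + width / 2, height,
              score = rep(0.9, length(centers)))
  det$center_column <- centers
  det
}

test_that("distances come from sorted centres, duplicates collapse", {
  det <- make_detections(c(10, 22, 37))
  expect_equal(centers_to_distances(det), c(10, 22, 37))
  expect_equal(centers_to_distances(make_detections(numeric())), numeric())

  dup <- make_detections(c(10, 10, 20))
  expect_warning(d <- centers_to_distances(dup), "duplicate")
  expect_equal(d, c(10, 20))

  unsorted <- make_detections(c(30, 10))
  expect_error(centers_to_distances(unsorted), "sorted")
})

test_that("spacings are first differences with telescoping sum", {
  expect_equal(compute_spacings(c(10, 22, 37)), c(12, 15))
  expect_warning(s <- compute_spacings(42), "fewer than 2")
  expect_equal(s, numeric())
  expect_equal(compute_spacings(seq(5, 50, by = 4.5)),
               rep(4.5, 10), tolerance = 1e-12)

  set.seed(11)
  for (k in 1:10) {
    d <- sort(runif(sample(2:40, 1), 0, 500))
    d <- d[c(TRUE, diff(d) > 1e-6)]
    sp <- compute_spacings(d)
    expect_equal(sum(sp), d[length(d)] - d[1]) # telescoping
  }
})

test_that("normalization divides by the transect maximum and is idempotent", {
  s <- spacing_series("t1", 0, c(5, 10, 20))
  np <- normalize_profile(s)
  expect_equal(np$normalized_distances, c(0.25, 0.5, 1.0))
  expect_equal(max(np$normalized_distances), 1)
  expect_equal(np$spacings, c(5, 10)) # carried over unchanged

  # already-normalized input is unchanged; outputs always in (0, 1]
  s2 <- spacing_series("t2", 0, np$normalized_distances)
  np2 <- normalize_profile(s2)
  expect_equal(np2$normalized_distances, np$normalized_distances)
  expect_true(all(np2$normalized_distances > 0 &
                    np2$normalized_distances <= 1))

  # rescaling distances by any positive constant does not change the profile
  s3 <- spacing_series("t3", 0, c(5, 10, 20) * 7.3)
  expect_equal(normalize_profile(s3)$normalized_distances,
               np$normalized_distances)

  expect_error(normalize_profile(spacing_series("e", 0, numeric())), "empty")

  np_s <- normalize_profile(s, normalize_spacings = TRUE)
  expect_equal(np_s$normalized_spacings, c(0.5, 1))
})

test_that("aggregation interpolates onto the grid and averages profiles", {
  prof <- function(id, distances) {
    normalize_profile(spacing_series(id, 0, distances))
  }
  # identical profiles replicated: aggregate equals the single profile curve
  p1 <- prof("a", c(10, 20, 30, 40, 50))
  agg1 <- aggregate_transects(list(p1), grid_size = 21)
  agg3 <- aggregate_transects(list(p1, p1, p1), grid_size = 21)
  expect_equal(agg3$mean_spacing, agg1$mean_spacing)
  expect_equal(agg3$n_profiles, 3)

  # constant spacings 4 and 8 average to 6 on the shared support
  pa <- prof("a", seq(4, 40, by = 4))
  pb <- prof("b", seq(8, 80, by = 8))
  agg <- aggregate_transects(list(pa, pb), grid_size = 41)
  shared <- agg$n_at_grid == 2
  expect_true(any(shared))
  expect_equal(unique(round(agg$mean_spacing[shared], 9)), 6)
  expect_true(all(diff(agg$grid) > 0))

  # quantile band contains the mean where defined
  both <- !is.na(agg$mean_spacing) & !is.na(agg$lower_q)
  expect_true(all(agg$lower_q[both] - 1e-9 <= agg$mean_spacing[both] &
                    agg$mean_spacing[both] <= agg$upper_q[both] + 1e-9))

  expect_error(aggregate_transects(list()), "no profiles")
})

test_that("seasonal cycles appear as minima of the aggregated mean curve", {
  # build exact spacing series from simulated ring radii at several angles;
  # the number of interior minima in the marine zone must equal the number
  # of complete seasonal cycles
  p <- clean_sim_params(n_freshwater_rings = 4, n_marine_rings = 16,
                        seasonal_period = 8, seasonal_amplitude = 2,
                        image_width = 640, image_height = 640,
                        eccentricity = 0)
  sc <- render_scale(p)
  profs <- lapply(c(0, 45, 90, 135, 180), function(ang) {
    gt <- ground_truth_for_transect(sc, ang, 10)
    normalize_profile(spacing_series(paste0("a", ang), ang,
                                     (gt$x_min + gt$x_max) / 2))
  })
  agg <- aggregate_transects(profs, grid_size = 200)
  ok <- which(!is.na(agg$mean_spacing))
  m <- agg$mean_spacing[ok]
  # restrict to the marine zone: beyond the freshwater plateau
  marine_start <- which(m > (p$fw_base_spacing + p$marine_base_spacing) / 2)[1]
  mm <- m[marine_start:length(m)]
  sgn <- sign(diff(mm))
  sgn <- sgn[sgn != 0]
  interior_minima <- sum(diff(sgn) > 0)
  n_cycles <- floor(p$n_marine_rings / p$seasonal_period)
  expect_equal(interior_minima, n_cycles)
})

test_that("tidy spacing tables carry one row per spacing", {
  s1 <- spacing_series("t0", 0, c(10, 20, 35), scores = c(0.9, 0.8, 0.7))
  s2 <- spacing_series("t90", 90, c(5, 9))
  tab <- spacings_table(list(s1, s2), scale_id = "s1")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$spacing_px, c(10, 15, 4))
  expect_equal(tab$score[1:2], c(0.8, 0.7))
  expect_true(all(tab$normalized_distance > 0 & tab$normalized_distance <= 1))
})
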