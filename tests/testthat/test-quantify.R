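test_that("disk segmentation recovers radius and centroid", {
  for (r in c(10, 20, 50)) {
    img <- render_droplet_frame(dim = 4 * r + 20, droplet_radius_px = r,
                                cluster_radius_px = 1, dc = 0,
                                intensities = c(background = 0,
                                                droplet = 1, cluster = 1))
    objs <- segment_disk_objects(img, threshold = 0.5)
    expect_equal(nrow(objs), 1)
    expect_lt(abs(objs$radius_px - r) / r, 0.02)
    truth_c <- attr(img, "truth")$droplet_center
    expect_lt(abs(objs$row - truth_c[1]), 1)
    expect_lt(abs(objs$col - truth_c[2]), 1)
  }
})

test_that("blank images yield an empty object table", {
  expect_equal(nrow(segment_disk_objects(matrix(0, 50, 50),
                                         threshold = 0.5)), 0)
  expect_equal(nrow(segment_disk_objects(matrix(0.2, 50, 50))), 0)
})

test_that("disjoint disks are segmented separately with correct areas", {
  img <- matrix(0, 120, 120)
  mk <- function(cr, cc, r) {
    rows <- matrix(0:119, 120, 120); cols <- t(rows)
    (rows - cr)^2 + (cols - cc)^2 <= r^2
  }
  img[mk(30, 30, 15)] <- 1
  img[mk(85, 85, 22)] <- 1
  objs <- segment_disk_objects(img, threshold = 0.5)
  expect_equal(nrow(objs), 2)
  areas <- sort(objs$area_px)
  expect_lt(abs(areas[1] - pi * 15^2) / (pi * 15^2), 0.02)
  expect_lt(abs(areas[2] - pi * 22^2) / (pi * 22^2), 0.02)
})

test_that("DC-ratio follows its definition and validates geometry", {
  at <- function(row, col, r = NULL) {
    tibble::tibble(row = row, col = col,
                   radius_px = r %||% NA_real_)
  }
  expect_equal(dc_ratio(at(50, 50, 60), at(50, 50)), 0)
  expect_equal(dc_ratio(at(0, 0, 60), at(0, 30)), 0.5)
  expect_error(dc_ratio(at(0, 0, 20), at(0, 30)),
               class = "actotug_invalid_geometry")
})

test_that("measured DC-ratio is invariant under translation and rotation", {
  base <- list(dc = 0.6, r_drop = 60, r_clust = 15)
  vals <- purrr::map_dbl(
    list(c(0, 0), c(0, pi / 2), c(12, 0), c(-8, pi)),
    function(shift) {
      img <- render_droplet_frame(
        dim = 180, droplet_radius_px = base$r_drop,
        cluster_radius_px = base$r_clust, dc = base$dc,
        angle = shift[2],
        center = c(89.5 + shift[1], 89.5 - shift[1])
      )
      measure_droplet_cluster(img)$dc_ratio
    }
  )
  expect_true(all(abs(vals - base$dc) < 0.02))
  expect_lt(diff(range(vals)), 0.01)
})

test_that("kymograph extraction samples a fixed line per frame", {
  frame <- matrix(runif(100 * 100), 100, 100)
  stack <- array(rep(frame, 5), dim = c(100, 100, 5))
  kymo <- extract_kymograph(stack, from = c(10, 10), to = c(90, 90))
  expect_true(all(apply(kymo, 1, function(r) diff(range(r)) == 0)))
  expect_error(extract_kymograph(array(frame, dim = c(100, 100, 1)),
                                 c(10, 10), c(90, 90)),
               class = "actotug_invalid_input")
  expect_error(extract_kymograph(stack, c(-5, 10), c(90, 90)),
               class = "actotug_invalid_input")
})

test_that("wave statistics recover generator velocity and period", {
  cases <- expand.grid(v = c(0.5, 1, 2, 4), T_period = c(35, 50))
  for (k in seq_len(nrow(cases))) {
    v <- cases$v[k]; T_period <- cases$T_period[k]
    waves <- flat_waves(v, T_period)
    series <- generate_wave_series(120, waves, n_waves = 6)
    kymo <- render_kymograph(series, duration = 6 * T_period + 60 / v)
    ws <- wave_stats(kymo)
    expect_equal(ws$velocity_um_s, v, tolerance = 0.05)
    expect_equal(ws$period_s, T_period, tolerance = 0.05)
  }
})

test_that("wave statistics tolerate intensity noise", {
  waves <- flat_waves(1.9, 44)
  series <- generate_wave_series(200, waves, n_waves = 6)
  kymo <- render_kymograph(series, duration = 360, noise_sd = 0.2,
                           seed = 17) # ridge peak ~1, SNR ~5
  ws <- wave_stats(kymo)
  expect_equal(ws$velocity_um_s, 1.9, tolerance = 0.1)
  expect_equal(ws$period_s, 44, tolerance = 0.1)
})

test_that("too few ridges raise an insufficient-waves error", {
  waves <- flat_waves(1.9, 44)
  series <- generate_wave_series(200, waves, n_waves = 1)
  kymo <- render_kymograph(series, duration = 50)
  expect_error(wave_stats(kymo), class = "actotug_insufficient_waves")
})

test_that("filament measurement applies the shape filters", {
  # a straight 100-px stick, 3 px wide, at 0.1 um/px measures 10 um
  img <- generate_filament_image(10, pixel_size = 0.1, dim = 200,
                                 angles = 0, seed = 5)
  m <- measure_filament_lengths(img, pixel_size = 0.1)
  expect_true(m$passes_filter)
  expect_equal(m$length_um, 10, tolerance = 0.05)

  # a filled disk has near-zero eccentricity and is rejected
  disk <- render_droplet_frame(dim = 80, droplet_radius_px = 15,
                               cluster_radius_px = 1, dc = 0,
                               intensities = c(background = 0, droplet = 1,
                                               cluster = 1))
  md <- measure_filament_lengths(disk)
  expect_false(any(md$passes_filter))
  expect_lt(md$eccentricity[1], 0.9)

  # an elongated blob above the area cut is rejected despite eccentricity
  bar <- matrix(0, 120, 120)
  bar[40:59, 10:110] <- 1 # 20 x 101 = 2020 px, ecc ~0.98
  mb <- measure_filament_lengths(bar)
  expect_false(any(mb$passes_filter))
  expect_gt(mb$eccentricity[1], 0.9)
  expect_gte(mb$area_px[1], 1300)
})

test_that("skeleton pixel counts match geometric length for straight sticks", {
  img <- generate_filament_image(c(2, 4, 6), pixel_size = 0.1, dim = 256,
                                 angles = c(0, pi / 4, pi / 2), seed = 3)
  truth <- attr(img, "truth")
  m <- measure_filament_lengths(img, pixel_size = 0.1)
  expect_equal(nrow(m), 3)
  measured_px <- sort(m$length_um / 0.1)
  expect_true(all(abs(measured_px - sort(truth$length_px_truth)) <= 1))
})

test_that("skeletonization thins to one-pixel width", {
  mask <- matrix(FALSE, 40, 40)
  mask[18:20, 5:35] <- TRUE # horizontal bar, 3 px thick
  skel <- skeletonize(mask)
  expect_true(all(colSums(skel[, 6:34]) <= 1))
  # thinning erodes blunt bar ends by up to ~2 px in total
  expect_true(sum(skel) >= 28 && sum(skel) <= 31)
})

test_that("top-fraction mean takes the ceiling of the count", {
  expect_equal(top_fraction_mean(1:100, 0.05), 98)
  expect_equal(top_fraction_mean(7, 0.05), 7)
  expect_error(top_fraction_mean(numeric(0)),
               class = "actotug_invalid_input")
  # sampled lengths hit the configured top-5% target
  lens <- sample_filament_lengths(500, target_top_mean = 5.7, seed = 21)
  expect_equal(top_fraction_mean(lens), 5.7, tolerance = 0.1)
})
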