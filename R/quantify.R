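#' Segment disk-like objects in a grayscale image
#'
#' Binarizes the image (Otsu threshold by default, or a fixed numeric
#' threshold), labels connected components and reports, per object, the
#' intensity-unweighted centroid and the radius of the equal-area disk
#' (`radius = sqrt(area / pi)`), mirroring how droplet and cluster radii are
#' read off bright-field images. Coordinates are 0-based pixel centres.
#'
#' @param image Numeric matrix (rows x cols), values in any range.
#' @param threshold `"otsu"` or a numeric cut in image units.
#' @param min_area Drop components smaller than this many pixels.
#' @param pixel_size Pixel size in um/pixel, recorded in the output.
#'
#' @return A tibble with one row per object: `object_id`, `row`, `col`
#'   (0-based centroid), `area_px`, `radius_px`, `radius_um`, `pixel_size`.
#'   Empty tibble when nothing is above threshold.
#' @examples
#' img <- render_droplet_frame(dim = 64, droplet_radius_px = 20,
#'                             cluster_radius_px = 5, dc = 0)
#' segment_disk_objects(img)
#' @export
segment_disk_objects <- function(image, threshold = "otsu", min_area = 0,
                                 pixel_size = 1) {
  stopifnot(is.matrix(image), is.numeric(image))
  mask <- binarize_image(image, threshold)
  if (!any(mask)) {
    return(tibble(object_id = integer(), row = numeric(), col = numeric(),
                  area_px = numeric(), radius_px = numeric(),
                  radius_um = numeric(), pixel_size = numeric()))
  }
  labels <- EBImage::bwlabel(mask)
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  stats_df <- tibble(
    object_id = as.integer(lab),
    row = idx[, 1] - 1,  # 0-based pixel centres
    col = idx[, 2] - 1
  ) |>
    dplyr::group_by(.data$object_id) |>
    dplyr::summarise(row = mean(.data$row), col = mean(.data$col),
                     area_px = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$area_px >= min_area) |>
    dplyr::mutate(radius_px = sqrt(.data$area_px / pi),
                  radius_um = .data$radius_px * pixel_size,
                  pixel_size = pixel_size)
  stats_df
}

binarize_image <- function(image, threshold) {
  if (identical(threshold, "otsu")) {
    rng <- range(image)
    if (diff(rng) == 0) return(matrix(FALSE, nrow(image), ncol(image)))
    scaled <- (image - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    scaled > th
  } else {
    check_number(threshold, "threshold")
    image > threshold
  }
}

#' DC-ratio from segmented droplet and cluster
#'
#' Distance between the droplet centre and the cluster centroid divided by
#' the droplet radius. Errors if the cluster centroid lies outside the
#' droplet.
#'
#' @param droplet,cluster One-row tibbles as returned by
#'   [segment_disk_objects()] (columns `row`, `col`, `radius_px`).
#'
#' @return Dimensionless DC-ratio in `[0, 1]`.
#' @export
dc_ratio <- function(droplet, cluster) {
  check_columns(droplet, c("row", "col", "radius_px"), "droplet")
  check_columns(cluster, c("row", "col"), "cluster")
  stopifnot(nrow(droplet) == 1, nrow(cluster) == 1)
  d <- sqrt((droplet$row - cluster$row)^2 + (droplet$col - cluster$col)^2)
  if (d > droplet$radius_px) {
    abort("Cluster centroid lies outside the droplet.",
          class = "actotug_invalid_geometry")
  }
  d / droplet$radius_px
}

#' Measure droplet, cluster and DC-ratio in one synthetic frame
#'
#' Convenience wrapper for frames in which the droplet interior and the
#' cluster have distinct intensity levels: the droplet is segmented with a
#' low threshold, the cluster with a high one, and the largest object of
#' each pass is used.
#'
#' @param image Numeric matrix.
#' @param droplet_threshold,cluster_threshold Numeric intensity cuts.
#' @inheritParams segment_disk_objects
#' @return A list with elements `droplet`, `cluster` (one-row tibbles) and
#'   `dc_ratio`.
#' @export
measure_droplet_cluster <- function(image, droplet_threshold = 0.25,
                                    cluster_threshold = 0.75,
                                    pixel_size = 1) {
  biggest <- function(th) {
    objs <- segment_disk_objects(image, threshold = th,
                                 pixel_size = pixel_size)
    if (!nrow(objs)) {
      abort("No object found at the given threshold.",
            class = "actotug_invalid_input")
    }
    objs[which.max(objs$area_px), ]
  }
  droplet <- biggest(droplet_threshold)
  cluster <- biggest(cluster_threshold)
  list(droplet = droplet, cluster = cluster,
       dc_ratio = dc_ratio(droplet, cluster))
}

#' Extract a kymograph along a line through an image stack
#'
#' Samples intensity by bilinear interpolation along a fixed line in every
#' frame and stacks the profiles over time (rows = position along the line,
#' columns = frames).
#'
#' @param stack 3-D numeric array `[rows, cols, frames]` with >= 2 frames.
#' @param from,to Line endpoints `c(row, col)` in 0-based pixel coordinates;
#'   must lie inside the frame.
#' @param n_samples Samples along the line; defaults to one per pixel of
#'   line length.
#' @param pixel_size um per pixel.
#' @param frame_interval Seconds per frame, default 3.
#'
#' @return A matrix of class `kymograph` with attributes `space_step_um` and
#'   `time_step_s`.
#' @export
extract_kymograph <- function(stack, from, to, n_samples = NULL,
                              pixel_size = 1, frame_interval = 3) {
  if (length(dim(stack)) != 3 || dim(stack)[3] < 2) {
    abort("`stack` must be an array with >= 2 frames.",
          class = "actotug_invalid_input")
  }
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  inside <- function(p) p[1] >= 0 && p[1] <= nr - 1 && p[2] >= 0 &&
    p[2] <= nc - 1
  if (!inside(from) || !inside(to)) {
    abort("Line endpoints must lie inside the frame.",
          class = "actotug_invalid_input")
  }
  len_px <- sqrt(sum((to - from)^2))
  n_samples <- n_samples %||% max(2L, ceiling(len_px) + 1L)
  s <- seq(0, 1, length.out = n_samples)
  rows <- from[1] + s * (to[1] - from[1])
  cols <- from[2] + s * (to[2] - from[2])
  kymo <- vapply(seq_len(dim(stack)[3]), function(f) {
    bilinear_sample(stack[, , f], rows, cols)
  }, numeric(n_samples))
  structure(kymo, class = c("kymograph", "matrix"),
            space_step_um = len_px * pixel_size / (n_samples - 1),
            time_step_s = frame_interval)
}

# bilinear interpolation at 0-based (row, col) positions
bilinear_sample <- function(img, rows, cols) {
  r0 <- pmin(pmax(floor(rows), 0), nrow(img) - 2)
  c0 <- pmin(pmax(floor(cols), 0), ncol(img) - 2)
  fr <- rows - r0
  fc <- cols - c0
  i <- function(r, c) img[cbind(r + 1, c + 1)]
  (1 - fr) * (1 - fc) * i(r0, c0) + fr * (1 - fc) * i(r0 + 1, c0) +
    (1 - fr) * fc * i(r0, c0 + 1) + fr * fc * i(r0 + 1, c0 + 1)
}

#' Wave velocity and period from a kymograph
#'
#' Works on the boundary-to-centre half of the kymograph in two stages.
#' First, global estimates anchor the search: the ridge slope comes from the
#' spatial shift that best correlates successive frames, and the period from
#' the lag that maximizes the temporal autocorrelation. Second, individual
#' wave events are detected as intensity peaks in a thin band just inside
#' the boundary (band depth adapted to the estimated slope so fast ridges
#' are not missed between frames); passage-time differences of the first
#' `n_waves` intervals give the period, and each of the first `n_waves`
#' ridges is tracked inward -- over the first third of the transit -- to fit
#' its initial slope. Statistics are means with SD over those events.
#'
#' @param kymo A `kymograph` (rows = space from the boundary inward,
#'   columns = frames).
#' @param n_waves Number of wave events to average, default 3.
#' @param min_prominence Band peaks below this fraction of the band
#'   intensity range are ignored.
#'
#' @return A one-row tibble: `velocity_um_s`, `velocity_sd`, `period_s`,
#'   `period_sd`, `n_waves`.
#' @export
wave_stats <- function(kymo, n_waves = 3, min_prominence = 0.4) {
  stopifnot(inherits(kymo, "kymograph") || is.matrix(kymo))
  dx <- attr(kymo, "space_step_um") %||% 1
  dt <- attr(kymo, "time_step_s") %||% 1
  half <- max(4L, floor(nrow(kymo) / 2))  # boundary-to-centre span
  H <- unclass(kymo)[seq_len(half), , drop = FALSE]
  if (diff(range(H)) == 0) {
    abort("Kymograph carries no ridges.",
          class = "actotug_insufficient_waves")
  }

  shift_px <- ridge_shift_per_frame(H)          # global slope anchor
  lag_frames <- dominant_period_lag(H)          # global period anchor

  # wave passage events: peaks of the intensity maximum over a boundary
  # band deep enough that a ridge cannot cross it between two frames
  band <- min(half - 1L, max(3L, ceiling(1.5 * shift_px)))
  trace <- colMeans(H[seq_len(band), , drop = FALSE])
  trace <- stats::filter(trace, rep(1 / 3, 3), sides = 2)
  trace[is.na(trace)] <- 0
  rng <- range(trace)
  thr <- rng[1] + min_prominence * diff(rng)
  min_sep <- max(3L, floor(lag_frames / 4))
  peaks <- local_maxima(as.numeric(trace), thr, min_sep = min_sep)
  if (length(peaks) < 3) {
    abort(sprintf("Only %d wave ridge(s) detected; need >= 3.",
                  length(peaks)),
          class = "actotug_insufficient_waves")
  }

  intervals <- diff(peaks)[seq_len(min(n_waves, length(peaks) - 1))]
  period_s <- mean(intervals) * dt
  period_sd <- stats::sd(intervals * dt)
  if (is.na(period_sd)) period_sd <- 0

  # per-event initial slope: tracked with a window that follows the
  # globally estimated slope, over the first third of the transit (extended
  # just enough for fast ridges that cross it in under three frames), and
  # never beyond the next wave's arrival
  third <- max(3L, floor(half / 3))
  stop_pos <- max(third, min(half - 1L, ceiling(3.5 * shift_px)))
  win <- max(3L, ceiling(shift_px))
  n_events <- min(n_waves, length(peaks))
  speeds <- purrr::map_dbl(seq_len(n_events), function(k) {
    t0 <- peaks[k]
    f_max <- if (k < length(peaks)) peaks[k + 1] - 1L else ncol(H)
    expect_pos <- max(1, min(band, shift_px))
    track_rows <- numeric()
    track_frames <- integer()
    f <- t0
    while (expect_pos < stop_pos && f <= f_max) {
      lo <- max(1L, floor(expect_pos - win))
      hi <- min(half, ceiling(expect_pos + win))
      window <- H[lo:hi, f]
      if (max(window) >= thr) {
        pos <- lo + which.max(window) - 1L
        track_rows <- c(track_rows, pos)
        track_frames <- c(track_frames, f)
        expect_pos <- pos + shift_px
      } else {
        expect_pos <- expect_pos + shift_px
      }
      f <- f + 1L
    }
    if (length(track_rows) < 3) return(NA_real_)
    unname(coef(lm(track_rows ~ track_frames))[2]) * dx / dt
  })
  speeds <- speeds[!is.na(speeds)]
  if (length(speeds) < 1) {
    abort("Could not track any ridge far enough to fit a slope.",
          class = "actotug_insufficient_waves")
  }
  tibble(
    velocity_um_s = mean(speeds),
    velocity_sd = if (length(speeds) > 1) stats::sd(speeds) else 0,
    period_s = period_s,
    period_sd = period_sd,
    n_waves = length(speeds)
  )
}

# spatial shift per frame maximizing the correlation between successive
# frames, refined by parabolic interpolation (sub-pixel)
ridge_shift_per_frame <- function(H) {
  Hc <- H - mean(H)
  n <- nrow(Hc)
  max_shift <- n - 2L
  score <- vapply(0:max_shift, function(s) {
    a <- Hc[1:(n - s), -ncol(Hc), drop = FALSE]
    b <- Hc[(1 + s):n, -1, drop = FALSE]
    sum(a * b) / length(a)
  }, numeric(1))
  refine_peak(score, which.max(score)) - 1
}

# autocorrelation lag (frames) of the kymograph in time; the first lag whose
# normalized score comes within 10% of the global maximum is the period.
# Temporal smoothing softens commensurability artifacts between the frame
# interval and the true period.
dominant_period_lag <- function(H) {
  Hc <- H - mean(H)
  Hc <- t(apply(Hc, 1, function(r) {
    sm <- stats::filter(r, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- 0
    as.numeric(sm)
  }))
  n_t <- ncol(Hc)
  max_lag <- max(3L, floor(n_t / 2))
  score <- vapply(2:max_lag, function(lag) {
    a <- Hc[, 1:(n_t - lag), drop = FALSE]
    b <- Hc[, (1 + lag):n_t, drop = FALSE]
    sum(a * b) / length(a)
  }, numeric(1))
  cand <- which(score >= 0.9 * max(score))[1]
  if (is.na(cand) || max(score) <= 0) cand <- which.max(score)
  refine_peak(score, cand) + 1
}

# parabolic refinement of a discrete peak position
refine_peak <- function(score, i) {
  if (i <= 1 || i >= length(score)) return(i)
  num <- score[i - 1] - score[i + 1]
  den <- score[i - 1] - 2 * score[i] + score[i + 1]
  if (den == 0) return(i)
  i + 0.5 * num / den
}

local_maxima <- function(x, threshold, min_sep = 3L) {
  n <- length(x)
  cand <- which(x >= threshold &
                  x >= c(-Inf, x[-n]) &
                  x >= c(x[-1], -Inf))
  if (!length(cand)) return(integer())
  keep <- cand[1]
  for (p in cand[-1]) {
    if (p - keep[length(keep)] >= min_sep) {
      keep <- c(keep, p)
    } else if (x[p] > x[keep[length(keep)]]) {
      keep[length(keep)] <- p
    }
  }
  keep
}

#' Measure filament lengths in a fluorescence-like image
#'
#' Binarizes, labels components, computes per-component area and ellipse
#' eccentricity (from central second moments), keeps skinny unbranched
#' objects (eccentricity > 0.9) of reasonable size (area < 1300 px),
#' skeletonizes each to one-pixel width and reports the skeleton pixel count
#' times the pixel size as the filament length. The pixel-count rule matches
#' the stick-area convention and undercounts diagonal runs by up to sqrt(2).
#'
#' @param image Numeric matrix.
#' @param pixel_size um per pixel.
#' @param threshold `"otsu"` or numeric.
#' @param min_eccentricity Eccentricity filter, default 0.9 (exclusive).
#' @param max_area Area filter in pixels, default 1300 (exclusive).
#'
#' @return A tibble with one row per component: `object_id`, `area_px`,
#'   `eccentricity`, `passes_filter`, `length_um` (`NA` for rejected
#'   components).
#' @export
measure_filament_lengths <- function(image, pixel_size = 1,
                                     threshold = "otsu",
                                     min_eccentricity = 0.9,
                                     max_area = 1300) {
  stopifnot(is.matrix(image))
  mask <- binarize_image(image, threshold)
  if (!any(mask)) {
    return(tibble(object_id = integer(), area_px = numeric(),
                  eccentricity = numeric(), passes_filter = logical(),
                  length_um = numeric()))
  }
  labels <- EBImage::bwlabel(mask)
  ids <- sort(unique(labels[labels > 0]))
  purrr::map_dfr(ids, function(id) {
    comp <- labels == id
    idx <- which(comp, arr.ind = TRUE)
    area <- nrow(idx)
    ecc <- ellipse_eccentricity(idx)
    ok <- ecc > min_eccentricity && area < max_area
    len <- if (ok) sum(skeletonize(comp)) * pixel_size else NA_real_
    tibble(object_id = as.integer(id), area_px = area, eccentricity = ecc,
           passes_filter = ok, length_um = len)
  })
}

# eccentricity of the second-moment ellipse of a pixel set
ellipse_eccentricity <- function(idx) {
  if (nrow(idx) < 2) return(0)
  r <- idx[, 1] - mean(idx[, 1])
  c <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  if (l1 <= 0) return(0)
  sqrt(pmax(0, 1 - l2 / l1))
}

#' Skeletonize a binary mask to one-pixel width
#'
#' Zhang-Suen thinning: iteratively removes boundary pixels that do not
#' break 8-connectivity until the shape is a one-pixel-wide skeleton.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  img <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)  # zero padding
  img[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) - dr
    cs <- seq_len(ncol(m)) - dc
    ok_r <- rs >= 1 & rs <= nrow(m)
    ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours clockwise from north: p2..p9
      p2 <- shift(img, -1, 0);  p3 <- shift(img, -1, 1)
      p4 <- shift(img, 0, 1);   p5 <- shift(img, 1, 1)
      p6 <- shift(img, 1, 0);   p7 <- shift(img, 1, -1)
      p8 <- shift(img, 0, -1);  p9 <- shift(img, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- Reduce(`+`, purrr::map(1:8, function(k) {
        (seqs[[k]] == 0L) * (seqs[[k + 1]] == 1L)
      }))
      if (pass == 1) {
        cond <- img == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- img == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- img[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] == 1L
  out
}

#' Mean of the largest fraction of values
#'
#' Mean of the `ceiling(fraction * n)` largest values; with the default 5%
#' this is the "top 5% average" summary used for filament-length
#' distributions.
#'
#' @param lengths Numeric vector, non-empty.
#' @param fraction Fraction in (0, 1], default 0.05.
#' @return Mean of the top values.
#' @examples
#' top_fraction_mean(1:100) # 98
#' @export
top_fraction_mean <- function(lengths, fraction = 0.05) {
  if (!length(lengths)) {
    abort("`lengths` must be non-empty.", class = "actotug_invalid_input")
  }
  check_number(fraction, "fraction", min = 0, max = 1, strict_min = TRUE)
  k <- ceiling(fraction * length(lengths))
  mean(sort(lengths, decreasing = TRUE)[seq_len(k)])
}
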