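meta_px <- image_meta()   # 0.183 um/px

# Render one clean frame: one bright elliptical islet plus straight
# filopodia at given angles/lengths (um), growing from the boundary.
render_test_frame <- function(angles_deg, lengths_um, ny = 256, nx = 256,
                              cy = 128, cx = 128, ry = 55, rx = 55,
                              seed = 1, rcfg = render_config()) {
  set.seed(seed)
  ps <- rcfg$pixel_size
  int <- matrix(0, ny, nx)
  int[filoscaffold:::filled_ellipse(ny, nx, cy, cx, ry, rx)] <- 1
  gt <- NULL
  for (i in seq_along(angles_deg)) {
    th <- angles_deg[i] * pi / 180
    b <- c(cy + ry * sin(th), cx + rx * cos(th))
    tip <- b + lengths_um[i] / ps * c(sin(th), cos(th))
    int <- filoscaffold:::draw_segment(int, b, tip,
                                       rcfg$filopodium_width_um / ps,
                                       rcfg$filopodium_intensity)
    gt <- rbind(gt, data.frame(base_y = b[1], base_x = b[2],
                               tip_y = tip[1], tip_x = tip[2],
                               length_um = lengths_um[i]))
  }
  int <- filoscaffold:::gauss_blur2d(int, rcfg$psf_sigma / ps)
  img <- matrix(rpois(ny * nx, rcfg$background + rcfg$photon_scale * int) +
                  rnorm(ny * nx, 0, rcfg$gaussian_read_noise_sd), ny)
  list(img = img, gt = gt)
}

test_that("islet perimeters match the analytic circle within 5%", {
  fr <- render_test_frame(numeric(0), numeric(0), ry = 60, rx = 60)
  isl <- segment_islets(fr$img, meta_px)
  expect_equal(nrow(isl$table), 1)
  expect_equal(isl$table$perimeter_um, 2 * pi * 60 * 0.183,
               tolerance = 0.05)
})

test_that("morphological opening keeps thin protrusions out of the body", {
  fr <- render_test_frame(seq(0, 324, by = 36), rep(4, 10), ry = 50, rx = 50)
  isl <- segment_islets(fr$img, meta_px)
  expect_equal(nrow(isl$table), 1)
  gt_area <- pi * 50 * 50 * 0.183^2
  expect_lt(abs(isl$table$area_um2 - gt_area) / gt_area, 0.03)
})

test_that("blank frames give no islets and no detections", {
  set.seed(2)
  img <- matrix(100 + rnorm(256^2, 0, 3), 256)
  isl <- segment_islets(img, meta_px)
  expect_equal(nrow(isl$table), 0)
  det <- detect_filopodia(img, isl, meta_px)
  expect_equal(nrow(det$table), 0)
})

test_that("an islet without filopodia yields zero detections", {
  fr <- render_test_frame(numeric(0), numeric(0))
  isl <- segment_islets(fr$img, meta_px)
  det <- detect_filopodia(fr$img, isl, meta_px)
  expect_equal(nrow(det$table), 0)
})

test_that("planted filopodia are recovered with high recall and precision", {
  set.seed(10)
  angles <- seq(0, 342, by = 18)
  n_f <- 2
  tp <- 0; n_gt <- 0; n_det <- 0
  for (f in seq_len(n_f)) {
    lens <- runif(length(angles), 1.8, 6)
    fr <- render_test_frame(angles, lens, seed = 20 + f)
    isl <- segment_islets(fr$img, meta_px)
    det <- detect_filopodia(fr$img, isl, meta_px, frame_index = f)
    n_gt <- n_gt + nrow(fr$gt)
    n_det <- n_det + nrow(det$table)
    for (r in seq_len(nrow(fr$gt))) {
      d <- sqrt((det$table$tip_x_px - fr$gt$tip_x[r])^2 +
                (det$table$tip_y_px - fr$gt$tip_y[r])^2)
      if (length(d) && min(d) <= 3) tp <- tp + 1
    }
  }
  expect_gte(n_gt, 30)
  expect_gte(tp / n_gt, 0.9)            # recall
  expect_gte(tp / n_det, 0.9)           # precision (tip within 3 px)
})

test_that("sub-minimum-length protrusions are rejected", {
  fr <- render_test_frame(45, 0.5, seed = 5)
  isl <- segment_islets(fr$img, meta_px)
  det <- detect_filopodia(fr$img, isl, meta_px, min_length_um = 1)
  expect_equal(nrow(det$table), 0)
})

test_that("detections never overlap the islet body masks", {
  fix <- tracked_movie_fixture()
  det <- fix$det
  for (f in unique(det$table$frame)[1:10]) {
    body <- which(fix$islets$labels[[f]] > 0)
    rows <- which(det$table$frame == f)
    for (j in rows) {
      k <- which(det$keys[, 1] == f & det$keys[, 2] == det$table$id[j])
      expect_length(intersect(det$pixels[[k]], body), 0)
    }
  }
})

test_that("skeleton length sums axial and diagonal steps", {
  horiz <- cbind(rep(5, 11), 1:11)
  expect_equal(skeleton_length(horiz, 0.2), 2.0)
  diag <- cbind(1:11, 1:11)
  expect_equal(skeleton_length(diag, 0.2), 10 * sqrt(2) * 0.2)
  expect_equal(skeleton_length(cbind(1, 1), 0.2), 0)
})

test_that("measured length of a planted straight filopodium is accurate", {
  fr <- render_test_frame(30, 5, seed = 6)
  isl <- segment_islets(fr$img, meta_px)
  det <- detect_filopodia(fr$img, isl, meta_px)
  expect_equal(nrow(det$table), 1)
  expect_lt(abs(det$table$length_um - 5), 0.183 + 0.25)   # 1 px + 5%
})

test_that("filopodium orientation folds against the reference axis", {
  expect_equal(filopodium_orientation(c(0, 0), c(1, 1), c(1, 0)), 45)
  expect_equal(filopodium_orientation(c(2, 3), c(5, 3), c(1, 0)), 0)
  expect_equal(filopodium_orientation(c(0, 0), c(0, 2), c(1, 0)), 90)
  expect_error(filopodium_orientation(c(1, 1), c(1, 1), c(1, 0)),
               "zero-length")
})

test_that("isotropic generation yields a uniform orientation histogram", {
  # ground-truth orientations at n = 1000 (chi-squared GOF, 9 bins)
  kcfg <- calibrate_kinematics()
  set.seed(31)
  isl <- filoscaffold:::gen_islets(c(256, 256), 0.183, 1, c(11, 15),
                                   kcfg$max_length + 1)
  ang <- c()
  while (length(ang) < 1000) {
    g <- filoscaffold:::simulate_movie_gt(kcfg, isl, 0.183, c(1, 0))
    gt <- g$table[!duplicated(g$table$id), ]
    if (!nrow(gt)) next
    a <- vapply(seq_len(nrow(gt)), function(r)
      filopodium_orientation(c(gt$base_x_px[r], gt$base_y_px[r]),
                             c(gt$tip_x_px[r], gt$tip_y_px[r]), c(1, 0)), 0)
    ang <- c(ang, a)
  }
  ang <- ang[1:1000]
  h <- table(cut(ang, seq(0, 90, by = 10), include.lowest = TRUE))
  expect_gt(chisq.test(h)$p.value, 0.01)
  # measured orientations agree: per-track angles (tracked detections of
  # one filopodium are correlated, so pool one angle per track) have the
  # random-field mean of 45 degrees
  fix <- tracked_movie_fixture()
  tab <- fix$tracks$table
  per_track <- tapply(seq_len(nrow(tab)), tab$track, function(rows) {
    r <- rows[1]
    filopodium_orientation(c(tab$minus_x_px[r], tab$minus_y_px[r]),
                           c(tab$plus_x_px[r], tab$plus_y_px[r]), c(1, 0))
  })
  skip_if(length(per_track) < 25)
  expect_lt(abs(mean(per_track) - 45),
            3 * 90 / sqrt(12) / sqrt(length(per_track)))
})

test_that("any probability-map detector plugs into the same schema", {
  fr <- render_test_frame(c(40, 200), c(4, 3), seed = 8)
  isl <- segment_islets(fr$img, meta_px)
  # mock detector: paints the planted segments directly
  mock <- function(img) {
    m <- matrix(0, nrow(img), ncol(img))
    for (r in seq_len(nrow(fr$gt))) {
      tt <- seq(0, 1, length.out = 200)
      ys <- round(fr$gt$base_y[r] + tt * (fr$gt$tip_y[r] - fr$gt$base_y[r]))
      xs <- round(fr$gt$base_x[r] + tt * (fr$gt$tip_x[r] - fr$gt$base_x[r]))
      m[cbind(ys, xs)] <- 1
    }
    b <- filoscaffold:::gauss_blur2d(m, 1.5)
    b / max(b)
  }
  det <- detect_filopodia(fr$img, isl, meta_px, detector = mock,
                          score_high = 0.5, score_low = 0.2,
                          tip_trim_px = 3)
  expect_s3_class(det$table, "data.frame")
  expect_setequal(names(det$table),
                  c("frame", "id", "islet", "base_x_px", "base_y_px",
                    "tip_x_px", "tip_y_px", "length_um", "orientation_deg",
                    "width_um"))
  expect_gte(nrow(det$table), 1)
})

test_that("per-frame counts land in the tens on a wide field", {
  # the paper-style density (0.037 per um of perimeter) gives counts that
  # scale with islet perimeter: use a wide field with large islets
  kcfg <- calibrate_kinematics(movie_duration = 180)
  mv <- render_movie(parse_structure_name("l7L14-open"), kcfg,
                     render_config(), seed = 21, dims = c(1024, 1024),
                     n_islets = 3, islet_axes_um = c(26, 34))
  res <- detect_movie(mv$movie, mv$meta)
  counts <- tabulate(res$detections$table$frame, dim(mv$movie)[3])
  expect_gte(mean(counts >= 10 & counts <= 100), 0.9)
})
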