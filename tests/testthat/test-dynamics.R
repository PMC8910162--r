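mk_info <- function(birth, death, n_frames) {
  data.frame(track = seq_along(birth), birth_frame = birth,
             death_frame = death,
             censored_start = birth == 1L,
             censored_end = death == n_frames)
}

test_that("lifetimes are (death - birth + 1) * dt over uncensored tracks", {
  info <- mk_info(c(10, 1, 50), c(19, 30, 135), n_frames = 135)
  lt <- track_lifetimes(info, frame_interval = 20)
  expect_equal(lt, 200)                 # frames 10..19 only
  expect_warning(track_lifetimes(mk_info(1, 135, 135), 20), "censored")
  # with no censored tracks the mean equals the plain average
  info2 <- mk_info(c(5, 8), c(9, 20), n_frames = 135)
  expect_equal(mean(track_lifetimes(info2, 20)), mean(c(5, 13) * 20))
})

test_that("uncensored-track lifetime estimation has small bias at 20x span", {
  # exponential planted lifetimes; movie spans 20 lifetimes
  set.seed(5)
  mu <- 230; dt <- 20; horizon <- 20 * mu
  n_frames <- floor(horizon / dt) + 1L
  n <- 6000
  t0 <- runif(n, 0, horizon)
  L <- rexp(n, 1 / mu)
  birth <- ceiling(t0 / dt) + 1L
  death <- floor((t0 + L) / dt) + 1L
  alive <- death >= birth & birth <= n_frames
  info <- mk_info(pmin(birth[alive], n_frames),
                  pmin(death[alive], n_frames), n_frames)
  lt <- track_lifetimes(info, dt)
  expect_gt(length(lt), 1000)
  expect_lt(abs(mean(lt) - mu) / mu, 0.05)
  # boundary-touching tracks never contribute: exact set assertion
  keep <- !info$censored_start & !info$censored_end
  expect_identical(length(lt), sum(keep))
  expect_true(all(((info$death_frame[keep] - info$birth_frame[keep] + 1) *
                     dt) %in% lt))
})

test_that("end speeds recover a constant outward tip motion exactly", {
  # tip moving outward 0.9 um per 20 s frame, base static
  ps <- 0.183
  n <- 6
  tr <- data.frame(frame = 1:n,
                   minus_x_px = 10, minus_y_px = 10,
                   plus_x_px = 10 + (1:n) * 0.9 / ps, plus_y_px = 10)
  sp <- end_speeds(tr, frame_interval = 20, pixel_size = ps)
  expect_equal(sp$plus_elong, 45)
  expect_true(is.na(sp$plus_retract))
  expect_true(is.na(sp$minus_elong))
  expect_true(is.na(sp$minus_retract))
})

test_that("static filopodia produce no speed samples", {
  tr <- data.frame(frame = 1:5, minus_x_px = 5, minus_y_px = 5,
                   plus_x_px = 20, plus_y_px = 5)
  sp <- end_speeds(tr, 20, 0.183)
  expect_true(all(is.na(unlist(sp[1:4]))))
  expect_equal(sp$n_steps, 0L)
})

test_that("speeds are invariant to shifting all frames by a constant", {
  set.seed(8)
  tr <- data.frame(frame = 1:8, minus_x_px = 10, minus_y_px = 10,
                   plus_x_px = cumsum(c(30, runif(7, -4, 6))),
                   plus_y_px = 10)
  a <- end_speeds(tr, 20, 0.183)
  tr2 <- tr; tr2$frame <- tr$frame + 57L
  b <- end_speeds(tr2, 20, 0.183)
  expect_identical(a, b)
})

test_that("normalized counts divide by total islet perimeter", {
  det <- data.frame(frame = rep(1, 10))
  isl <- data.frame(frame = c(1, 1), perimeter_um = c(100, 150))
  nc <- normalized_count(det, isl)
  expect_equal(nc$per_um, 10 / 250)
  isl2 <- data.frame(frame = c(1, 1), perimeter_um = c(200, 300))
  expect_equal(normalized_count(det, isl2)$per_um, nc$per_um / 2)
  expect_error(normalized_count(det, data.frame(frame = 1,
                                                perimeter_um = 0)),
               "zero total")
})

test_that("normalized counts are invariant under translation and rotation", {
  # counts and perimeters do not depend on where the masks sit
  det <- data.frame(frame = rep(1:3, c(4, 6, 5)))
  isl <- data.frame(frame = 1:3, perimeter_um = 120)
  base <- normalized_count(det, isl)
  # translating / rotating detections and islets changes neither the
  # per-frame counts nor the perimeters entering the ratio
  expect_equal(base$per_um, c(4, 6, 5) / 120)
})

test_that("Savitzky-Golay smoothing reproduces cubics and shrinks noise", {
  x <- 0:120
  cubic <- 2 + 0.3 * x - 0.01 * x^2 + 2e-4 * x^3
  sm <- smooth_kinetic_curve(cubic, window = 21, degree = 3)
  expect_lt(max(abs(sm$smoothed - cubic) / pmax(abs(cubic), 1)), 1e-9)
  const <- rep(3.3, 60)
  expect_equal(smooth_kinetic_curve(const)$smoothed, const)
  set.seed(4)
  noisy <- cubic + rnorm(length(cubic), 0, 0.5)
  smn <- smooth_kinetic_curve(noisy, window = 21, degree = 3)
  expect_lt(sd(smn$smoothed - cubic), 0.5)
  expect_error(smooth_kinetic_curve(cubic, window = 20), "odd")
  expect_error(smooth_kinetic_curve(cubic[1:10], window = 21), "shorter")
})

test_that("pre/post interval means use the documented windows", {
  dt <- 20
  tt <- seq(0, 5400, by = dt)
  drug <- 2000
  cv <- data.frame(time_s = tt, quantity = "number",
                   raw = ifelse(tt < drug, 2, 5))
  im <- interval_means(cv, drug, quantity = "number", column = "raw")
  expect_equal(unname(im), c(2, 5))
  # constant curve: both means equal the constant
  cv2 <- data.frame(time_s = tt, raw = 7)
  expect_equal(unname(interval_means(cv2, drug, "number",
                                     column = "raw")), c(7, 7))
  # piecewise-linear curve: window means equal analytic integrals
  cv3 <- data.frame(time_s = tt, raw = 1 + 0.001 * tt)
  im3 <- interval_means(cv3, drug, quantity = "number", column = "raw")
  ctr_w <- tt[tt >= drug - 618 & tt < drug]
  expect_equal(im3[["ctr"]], 1 + 0.001 * mean(ctr_w))
  drug_w <- tt[tt >= drug + 1278 & tt < drug + 1278 + 618]
  expect_equal(im3[["drug"]], 1 + 0.001 * mean(drug_w))
  # lifetime curves shift the control window 5 min earlier
  im_lt <- interval_means(cv3, drug, quantity = "lifetime", column = "raw")
  expect_equal(im_lt[["ctr"]], im3[["ctr"]] - 0.001 * 300)
  # slow-onset drugs delay the treatment window to 40 min
  im_slow <- interval_means(cv3, drug, quantity = "number",
                            slow_onset = TRUE, column = "raw")
  slow_w <- tt[tt >= drug + 2400 & tt < drug + 2400 + 618]
  expect_equal(im_slow[["drug"]], 1 + 0.001 * mean(slow_w))
  expect_error(interval_means(cv3, 100, "number", column = "raw"),
               "outside")
})

test_that("the paired test matches the closed-form t on a tiny example", {
  res <- paired_significance_test(c(1, 2, 3), c(2, 4, 3))
  # differences (1, 2, 0): mean 1, sd 1, t = sqrt(3), df 2
  expect_equal(res$t, sqrt(3), tolerance = 1e-9)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.2254033, tolerance = 1e-6)
  expect_false(is.na(res$shapiro_p))
  expect_error(paired_significance_test(c(1, 2, 3), c(2, 3, 4)),
               "degenerate")
})

test_that("the paired test keeps its nominal type-I error", {
  set.seed(12)
  n_rep <- 2000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rnorm(5); b <- rnorm(5)
    rej[i] <- paired_significance_test(a, b)$p_value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("a deterministic triangle filopodium summarises exactly", {
  ps <- 0.183; dt <- 20
  meta <- image_meta(pixel_size = ps, frame_interval = dt)
  # grows 1 px per frame for 6 frames, holds 2, retracts 1 px per frame
  lens_px <- c(10:16, 16, 16:10)
  n <- length(lens_px)
  frames <- 5:(4 + n)
  tab <- data.frame(track = 1L, frame = frames, det_id = 1L,
                    minus_x_px = 0, minus_y_px = 0,
                    plus_x_px = lens_px, plus_y_px = 0,
                    length_um = lens_px * ps, ambiguous = FALSE)
  n_frames <- 60L
  info <- data.frame(track = 1L, birth_frame = min(frames),
                     death_frame = max(frames),
                     censored_start = FALSE, censored_end = FALSE,
                     islet = 1L)
  tracks <- structure(list(table = tab, info = info, meta = meta,
                           n_frames = n_frames), class = "filo_tracks")
  isl <- data.frame(frame = seq_len(n_frames), perimeter_um = 200)
  s <- summarize_movie(tracks, isl, meta, analysis_window_min = 16.6)
  expect_equal(s$n_filopodia, 1)
  expect_equal(s$mean_lifetime_s, n * dt)
  expect_equal(s$mean_length_um, mean(lens_px * ps))
  # 1 px per frame = 0.183 um / 20 s = 9.15 nm/s at both speed fields
  expect_equal(s$elong_speed_plus_nms, 0.183 / 20 * 1000)
  expect_equal(s$retract_speed_plus_nms, 0.183 / 20 * 1000)
  expect_true(is.na(s$elong_speed_minus_nms))
})

test_that("an empty movie summarises to zero filopodia without error", {
  meta <- image_meta()
  tracks <- structure(list(table = filoscaffold:::.empty_track_table(),
                           info = data.frame(track = integer(0),
                                             birth_frame = integer(0),
                                             death_frame = integer(0),
                                             censored_start = logical(0),
                                             censored_end = logical(0),
                                             islet = integer(0)),
                           meta = meta, n_frames = 30L),
                      class = "filo_tracks")
  s <- summarize_movie(tracks, data.frame(frame = 1:30,
                                          perimeter_um = 100), meta)
  expect_equal(s$n_filopodia, 0)
  expect_true(is.na(s$mean_length_um))
  expect_true(is.na(s$mean_lifetime_s))
})

test_that("kinetic curves mask lifetimes near the movie boundaries", {
  fix <- tracked_movie_fixture()
  cv <- kinetic_curves(fix$tracks, fix$islets$table, fix$mv$meta)
  lt <- cv[cv$quantity == "lifetime", ]
  expect_true(is.na(lt$raw[1]))
  expect_true(is.na(lt$raw[nrow(lt)]))
  expect_gt(sum(!is.na(lt$raw)), 10)
  ln <- cv[cv$quantity == "length", ]
  expect_equal(nrow(ln), fix$n_frames)
})
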