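test_that("IoU has its defining values and metric properties", {
  a <- rect_mask_idx(10, 10, 2, 5, 2, 5)
  expect_equal(mask_iou(a, a), 1)
  b <- rect_mask_idx(10, 10, 7, 9, 7, 9)
  expect_equal(mask_iou(a, b), 0)
  # 2x4 rectangles overlapping on 2x2 -> 4/12
  r1 <- rect_mask_idx(10, 10, 1, 2, 1, 4)
  r2 <- rect_mask_idx(10, 10, 1, 2, 3, 6)
  expect_equal(mask_iou(r1, r2), 1 / 3)
  expect_equal(mask_iou(r1, r2), mask_iou(r2, r1))   # symmetry
  expect_error(mask_iou(integer(0), integer(0)), "both masks empty")
  # matrix interface
  m1 <- matrix(FALSE, 4, 4); m1[1:2, 1:2] <- TRUE
  expect_equal(mask_iou(m1, m1), 1)
})

test_that("static detections link to themselves with total IoU n", {
  masks <- list(rect_mask_idx(20, 20, 1, 3, 1, 3),
                rect_mask_idx(20, 20, 8, 10, 8, 10),
                rect_mask_idx(20, 20, 15, 18, 15, 18))
  lk <- link_frames(masks, masks, dim = c(20, 20))
  expect_equal(lk$matches$i, 1:3)
  expect_equal(lk$matches$j, 1:3)
  expect_equal(sum(lk$matches$iou), 3)
  expect_length(lk$births, 0)
  expect_length(lk$deaths, 0)
})

test_that("unmatched detections become births and deaths", {
  masks <- list(rect_mask_idx(20, 20, 1, 3, 1, 3),
                rect_mask_idx(20, 20, 8, 10, 8, 10))
  lk <- link_frames(masks, list(), dim = c(20, 20))
  expect_equal(lk$deaths, 1:2)
  expect_length(lk$births, 0)
  lk <- link_frames(list(), masks, dim = c(20, 20))
  expect_equal(lk$births, 1:2)
})

test_that("linking matches the exhaustive-search optimum on random instances", {
  set.seed(77)
  ny <- nx <- 24
  for (trial in 1:200) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    gen <- function(n) lapply(seq_len(n), function(i) {
      y <- sample(1:(ny - 6), 1); x <- sample(1:(nx - 6), 1)
      rect_mask_idx(ny, nx, y, y + sample(2:5, 1), x, x + sample(2:5, 1))
    })
    m1 <- gen(n1); m2 <- gen(n2)
    iou <- matrix(0, n1, n2)
    for (i in seq_len(n1)) for (j in seq_len(n2))
      iou[i, j] <- mask_iou(m1[[i]], m2[[j]])
    lk <- link_frames(m1, m2, dim = c(ny, nx))
    expect_equal(sum(lk$matches$iou), dp_assignment_value(iou),
                 tolerance = 1e-7)
    # every match respects the IoU floor
    if (nrow(lk$matches)) expect_true(all(lk$matches$iou >= 0.2))
  }
})

# Build a detections object from a table of (frame, y, x) box positions.
make_dets <- function(boxes, ny = 40, nx = 40) {
  tab <- NULL; pixels <- list(); skeletons <- list(); keys <- NULL
  ids <- integer(0)
  for (r in seq_len(nrow(boxes))) {
    f <- boxes$frame[r]
    id <- sum(tab$frame == f) + 1L
    tab <- rbind(tab, data.frame(
      frame = f, id = id, islet = 1L,
      base_x_px = boxes$x[r], base_y_px = boxes$y[r],
      tip_x_px = boxes$x[r] + 4, tip_y_px = boxes$y[r],
      length_um = 4 * 0.183, orientation_deg = 0, width_um = 0.5))
    pixels[[length(pixels) + 1L]] <-
      rect_mask_idx(ny, nx, boxes$y[r], boxes$y[r] + 2,
                    boxes$x[r], boxes$x[r] + 4)
    skeletons[[length(skeletons) + 1L]] <-
      cbind(boxes$y[r] + 1L, boxes$x[r]:(boxes$x[r] + 4L))
    keys <- rbind(keys, c(f, id))
  }
  out <- list(table = tab, pixels = pixels, skeletons = skeletons,
              keys = keys, dim = c(ny, nx), meta = image_meta())
  class(out) <- "filo_detections"
  out
}

test_that("a detection present in all frames becomes one doubly censored track", {
  dets <- make_dets(data.frame(frame = 1:6, y = 10, x = 10))
  tr <- build_tracks(dets, n_frames = 6)
  expect_equal(nrow(tr$info), 1)
  expect_true(tr$info$censored_start)
  expect_true(tr$info$censored_end)
})

test_that("a two-frame gap splits a track unless gap closing allows it", {
  dets <- make_dets(data.frame(frame = c(2, 3, 6, 7), y = 10, x = 10))
  tr0 <- build_tracks(dets, n_frames = 9, max_gap = 0)
  expect_equal(nrow(tr0$info), 2)
  expect_false(any(tr0$info$censored_start | tr0$info$censored_end))
  tr2 <- build_tracks(dets, n_frames = 9, max_gap = 2)
  expect_equal(nrow(tr2$info), 1)
  expect_equal(tr2$info$birth_frame, 2)
  expect_equal(tr2$info$death_frame, 7)
})

test_that("every detection belongs to exactly one track", {
  fix <- tracked_movie_fixture()
  tab <- fix$tracks$table
  expect_equal(nrow(tab), nrow(fix$det$table))
  expect_false(any(duplicated(tab[, c("frame", "det_id")])))
  # at most one detection per frame within a track
  expect_false(any(duplicated(tab[, c("track", "frame")])))
})

test_that("reversing the movie yields the same track partition", {
  dets <- tracked_movie_fixture()$det
  nf <- tracked_movie_fixture()$n_frames
  fwd <- build_tracks(dets, n_frames = nf)
  rev_dets <- dets
  rev_dets$table$frame <- nf + 1L - rev_dets$table$frame
  rev_dets$keys[, 1] <- nf + 1L - rev_dets$keys[, 1]
  ord <- order(rev_dets$table$frame, rev_dets$table$id)
  rev_dets$table <- rev_dets$table[ord, ]
  bwd <- build_tracks(rev_dets, n_frames = nf)
  # same number of tracks, and identical partitions of detections
  expect_equal(nrow(bwd$info), nrow(fwd$info))
  key_f <- paste(fwd$table$frame, fwd$table$det_id)
  key_b <- paste(nf + 1L - bwd$table$frame, bwd$table$det_id)
  part_f <- split(key_f, fwd$table$track)
  part_b <- split(key_b, bwd$table$track)
  norm <- function(p) sort(vapply(p, function(v) paste(sort(v),
                                                       collapse = "|"), ""))
  expect_identical(unname(norm(part_f)), unname(norm(part_b)))
  # births and deaths swap roles
  expect_equal(sum(fwd$info$censored_start), sum(bwd$info$censored_end))
  expect_equal(sum(fwd$info$censored_end), sum(bwd$info$censored_start))
})

test_that("tracks cover the planted filopodia with high purity", {
  fix <- tracked_movie_fixture()
  gt <- fix$mv$gt
  det <- fix$det
  tab <- fix$tracks$table
  # map every detection to its GT filopodium by pixel overlap
  covered <- 0; pure <- 0; n_gt_ids <- 0
  for (id in unique(gt$id)) {
    g <- gt[gt$id == id, ]
    if (nrow(g) < 3) next
    n_gt_ids <- n_gt_ids + 1
    hits <- gt_overlap_hits(det, g, fix$det$dim[1])
    if (mean(hits) < 0.5) next
    # which tracks claim those frames?
    tr_ids <- c()
    for (r in which(hits)) {
      rows <- which(det$table$frame == g$frame[r])
      for (j in rows) {
        k <- which(det$keys[, 1] == g$frame[r] &
                   det$keys[, 2] == det$table$id[j])
        tt <- seq(0, 1, length.out = 40)
        ys <- round(g$base_y_px[r] + tt * (g$tip_y_px[r] - g$base_y_px[r]))
        xs <- round(g$base_x_px[r] + tt * (g$tip_x_px[r] - g$base_x_px[r]))
        gpix <- unique(ys + (xs - 1) * det$dim[1])
        if (length(intersect(gpix, det$pixels[[k]])) / length(gpix) > 0.3) {
          tr_ids <- c(tr_ids, tab$track[tab$frame == g$frame[r] &
                                        tab$det_id == det$table$id[j]])
        }
      }
    }
    covered <- covered + 1
    if (length(unique(tr_ids)) == 1L) pure <- pure + 1
  }
  expect_gte(covered / n_gt_ids, 0.9)
  expect_gte(pure / covered, 0.9)
})

test_that("extremities point away from the body and match planted tips", {
  fix <- tracked_movie_fixture()
  tab <- fix$tracks$table
  gt <- fix$mv$gt
  # per tracked row, the (+) end should be the planted tip when the row
  # overlaps a GT filopodium
  good <- 0; total <- 0
  for (rr in sample(seq_len(nrow(tab)), min(400, nrow(tab)))) {
    f <- tab$frame[rr]
    g <- gt[gt$frame == f, ]
    if (!nrow(g)) next
    d_tip <- sqrt((g$tip_x_px - tab$plus_x_px[rr])^2 +
                  (g$tip_y_px - tab$plus_y_px[rr])^2)
    d_base <- sqrt((g$base_x_px - tab$minus_x_px[rr])^2 +
                   (g$base_y_px - tab$minus_y_px[rr])^2)
    j <- which.min(d_tip + d_base)
    if (d_tip[j] + d_base[j] > 16) next   # not this filopodium
    total <- total + 1
    if (d_tip[j] < d_base[j] + 8) good <- good + 1
  }
  expect_gt(total, 50)
  expect_gte(good / total, 0.95)
})

test_that("a detached fragment is flagged ambiguous", {
  dets <- make_dets(data.frame(frame = 1:3, y = 30, x = 30))
  tr <- build_tracks(dets, n_frames = 3)
  labels <- replicate(3, {
    m <- matrix(0L, 40, 40); m[1:6, 1:6] <- 1L; m
  }, simplify = FALSE)
  tr <- assign_extremities(tr, labels)
  expect_true(all(tr$table$ambiguous))
})

test_that("a straight filopodium at a straight edge gets the right polarity", {
  # body occupying the left half; filopodium extending to the right
  dets <- make_dets(data.frame(frame = 1:4, y = 20, x = 12))
  tr <- build_tracks(dets, n_frames = 4)
  labels <- replicate(4, {
    m <- matrix(0L, 40, 40); m[, 1:10] <- 1L; m
  }, simplify = FALSE)
  tr <- assign_extremities(tr, labels)
  expect_false(any(tr$table$ambiguous))
  expect_true(all(tr$table$minus_x_px < tr$table$plus_x_px))
})
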