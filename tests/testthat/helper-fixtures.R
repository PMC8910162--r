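# Shared fixtures.  Heavy objects (a rendered movie with its detections and
# tracks) are built once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

# A paper-default movie, shortened to ~30 min, with detections and tracks.
tracked_movie_fixture <- function() {
  if (!is.null(.fixture_cache$tracked)) return(.fixture_cache$tracked)
  cfg <- paper_default_config()
  kcfg <- calibrate_kinematics(movie_duration = 1800)
  mv <- render_movie(parse_structure_name("l7L14-open"), kcfg, cfg$render,
                     seed = 11, dims = c(256, 256))
  res <- detect_movie(mv$movie, mv$meta)
  n_frames <- dim(mv$movie)[3]
  tracks <- build_tracks(res$detections, n_frames = n_frames)
  tracks <- assign_extremities(tracks, res$islets$labels)
  .fixture_cache$tracked <- list(mv = mv, det = res$detections,
                                 islets = res$islets, tracks = tracks,
                                 n_frames = n_frames)
  .fixture_cache$tracked
}

# Match detections against ground truth by pixel overlap along the planted
# segment; returns a logical hit vector over gt rows.
gt_overlap_hits <- function(det, gt, dim_y, min_overlap = 0.3) {
  hit <- logical(nrow(gt))
  for (r in seq_len(nrow(gt))) {
    f <- gt$frame[r]
    idx <- which(det$table$frame == f)
    if (!length(idx)) next
    tt <- seq(0, 1, length.out = 40)
    ys <- round(gt$base_y_px[r] + tt * (gt$tip_y_px[r] - gt$base_y_px[r]))
    xs <- round(gt$base_x_px[r] + tt * (gt$tip_x_px[r] - gt$base_x_px[r]))
    gpix <- unique(ys + (xs - 1) * dim_y)
    for (j in idx) {
      k <- which(det$keys[, 1] == f & det$keys[, 2] == det$table$id[j])
      ov <- length(intersect(gpix, det$pixels[[k]])) / length(gpix)
      if (ov > min_overlap) { hit[r] <- TRUE; break }
    }
  }
  hit
}

# Exact maximum-weight one-to-one assignment by bitmask dynamic programming
# (independent oracle for the linear-assignment linker).
dp_assignment_value <- function(w, floor = 0.2) {
  n1 <- nrow(w); n2 <- ncol(w)
  w[is.na(w) | w < floor] <- -Inf
  memo <- matrix(NA_real_, n1 + 1L, 2^n2)
  rec <- function(i, mask) {
    if (i > n1) return(0)
    if (!is.na(memo[i, mask + 1L])) return(memo[i, mask + 1L])
    best <- rec(i + 1L, mask)          # leave row i unmatched
    for (j in seq_len(n2)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L && is.finite(w[i, j])) {
        v <- w[i, j] + rec(i + 1L, bitwOr(mask, bit))
        if (v > best) best <- v
      }
    }
    memo[i, mask + 1L] <<- best
    best
  }
  rec(1L, 0L)
}

# Small binary masks as linear pixel index sets on a common grid.
rect_mask_idx <- function(ny, nx, y0, y1, x0, x1) {
  m <- matrix(FALSE, ny, nx)
  m[y0:y1, x0:x1] <- TRUE
  which(m)
}
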