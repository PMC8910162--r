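# Frame-to-frame track linking by linear assignment on an intersection-
# over-union cost, and (-)/(+) extremity classification by distance to the
# cell body.

#' Intersection over union of two pixel masks
#'
#' @param a,b logical matrices of identical shape, or integer vectors of
#'   linear pixel indices (interpreted on a common grid).
#' @return `|A intersect B| / |A union B|` in `[0, 1]`; an error if both
#'   masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (is.matrix(a) || is.array(a)) {
    stopifnot(identical(dim(a), dim(b)))
    a <- which(a != 0); b <- which(b != 0)
  }
  u <- length(a) + length(b) - (i <- length(intersect(a, b)))
  if (u == 0L) stop("IoU undefined: both masks empty")
  i / u
}

# Maximum-weight one-to-one assignment on a weight matrix with forbidden
# (NA or < floor) entries, via weighted maximum bipartite matching.
# Ties in total weight are broken deterministically by the caller's
# epsilon perturbations.
.max_weight_assignment <- function(w) {
  n1 <- nrow(w); n2 <- ncol(w)
  ok <- which(!is.na(w) & w > 0, arr.ind = TRUE)
  if (nrow(ok) == 0L)
    return(data.frame(i = integer(0), j = integer(0)))
  edges <- as.vector(t(cbind(ok[, 1], n1 + ok[, 2])))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n1), rep(TRUE, n2)),
                                    edges = edges, directed = FALSE)
  m <- igraph::max_bipartite_match(
    g, types = rep(c(FALSE, TRUE), c(n1, n2)),
    weights = w[ok])
  mt <- m$matching[seq_len(n1)]
  sel <- !is.na(mt)
  data.frame(i = which(sel), j = mt[sel] - n1)
}

#' Link detections between two consecutive frames
#'
#' One-to-one matching maximising total IoU; pairs with IoU below `iou_min`
#' are forbidden.  Unmatched detections in the earlier frame are candidate
#' deaths, unmatched ones in the later frame births.  Total-IoU ties are
#' broken by smaller centroid displacement, then by lower detection index,
#' so linking is deterministic.
#'
#' @param masks_t,masks_t1 lists of pixel-index masks (one per detection).
#' @param iou_min minimum IoU for an allowed link (default 0.2).
#' @param dim image dimensions (needed for the centroid tie-break; may be
#'   omitted, in which case ties fall back to index order).
#' @return list: `matches` (data.frame `i`, `j`, `iou`), `deaths` (indices
#'   in t), `births` (indices in t+1).
#' @export
link_frames <- function(masks_t, masks_t1, iou_min = 0.2, dim = NULL) {
  n1 <- length(masks_t); n2 <- length(masks_t1)
  if (n1 == 0L || n2 == 0L)
    return(list(matches = data.frame(i = integer(0), j = integer(0),
                                     iou = numeric(0)),
                deaths = seq_len(n1), births = seq_len(n2)))
  iou <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (length(masks_t[[i]]) == 0L && length(masks_t1[[j]]) == 0L) next
    iou[i, j] <- mask_iou(masks_t[[i]], masks_t1[[j]])
  }
  w <- iou
  w[w < iou_min] <- NA
  # deterministic tie-breaks, far below the IoU resolution of pixel masks
  if (!is.null(dim)) {
    ctr <- function(m) if (length(m)) colMeans(arrayInd(m, dim)) else c(0, 0)
    c1 <- t(vapply(masks_t, ctr, c(0, 0)))
    c2 <- t(vapply(masks_t1, ctr, c(0, 0)))
    dg <- sqrt(sum(dim^2))
    for (i in seq_len(n1)) {
      disp <- sqrt((c2[, 1] - c1[i, 1])^2 + (c2[, 2] - c1[i, 2])^2)
      w[i, ] <- w[i, ] + 1e-7 * (1 - pmin(disp / dg, 1))
    }
  }
  w <- sweep(w, 2L, 1e-10 * seq_len(n2) / n2, `-`)
  mt <- .max_weight_assignment(w)
  mt$iou <- iou[cbind(mt$i, mt$j)]
  list(matches = mt,
       deaths = setdiff(seq_len(n1), mt$i),
       births = setdiff(seq_len(n2), mt$j))
}

#' Build filopodium tracks across a movie
#'
#' Chains frame-to-frame linkings ([link_frames()]); a track ends when its
#' detection is unmatched for more than `max_gap` frames (default 0: no
#' gap closing).  Tracks alive at the first/last movie frame carry
#' censoring flags.
#'
#' @param dets a `filo_detections` over all frames ([detect_movie()]).
#' @param n_frames total number of movie frames.
#' @param iou_min minimum IoU for a link.
#' @param max_gap maximum number of missing frames bridged inside a track.
#' @return a `filo_tracks` list: `table` (long, one row per track-frame)
#'   and `info` (one row per track: `track`, `birth_frame`, `death_frame`,
#'   `censored_start`, `censored_end`, `islet`).
#' @export
build_tracks <- function(dets, n_frames = max(dets$table$frame, 1L),
                         iou_min = 0.2, max_gap = 0L) {
  tab <- dets$table
  track_of <- integer(nrow(tab))
  n_tracks <- 0L
  if (nrow(tab)) {
    rows_by_frame <- split(seq_len(nrow(tab)), factor(tab$frame,
                                                      levels = seq_len(n_frames)))
    active <- integer(0)       # row indices (current frame) -> track ids
    for (f in seq_len(n_frames)) {
      rows <- rows_by_frame[[f]]
      if (f == 1L || length(active) == 0L) {
        for (r in rows) {
          n_tracks <- n_tracks + 1L
          track_of[r] <- n_tracks
        }
        active <- rows
        next
      }
      prev_rows <- active
      m1 <- lapply(prev_rows, function(r) dets$pixels[[.det_row(dets, r)]])
      m2 <- lapply(rows, function(r) dets$pixels[[.det_row(dets, r)]])
      lk <- link_frames(m1, m2, iou_min = iou_min, dim = dets$dim)
      for (k in seq_len(nrow(lk$matches)))
        track_of[rows[lk$matches$j[k]]] <-
          track_of[prev_rows[lk$matches$i[k]]]
      for (b in lk$births) {
        n_tracks <- n_tracks + 1L
        track_of[rows[b]] <- n_tracks
      }
      active <- rows
    }
  }
  if (max_gap > 0L && n_tracks > 1L)
    track_of <- .close_gaps(dets, track_of, max_gap, iou_min)
  .assemble_tracks(dets, track_of, n_frames)
}

# row index within dets$table -> index into dets$pixels / dets$skeletons
.det_row <- function(dets, r) {
  .det_index(dets, dets$table$frame[r], dets$table$id[r])
}

.close_gaps <- function(dets, track_of, max_gap, iou_min) {
  tab <- dets$table
  repeat {
    info <- do.call(rbind, lapply(split(seq_len(nrow(tab)), track_of),
      function(rows) data.frame(first = rows[which.min(tab$frame[rows])],
                                last = rows[which.max(tab$frame[rows])])))
    info$track <- as.integer(rownames(info))
    cand <- expand.grid(a = seq_len(nrow(info)), b = seq_len(nrow(info)))
    cand <- cand[cand$a != cand$b, ]
    gap <- tab$frame[info$first[cand$b]] - tab$frame[info$last[cand$a]] - 1L
    cand <- cand[gap >= 1L & gap <= max_gap, ]
    if (!nrow(cand)) break
    cand$iou <- vapply(seq_len(nrow(cand)), function(k) {
      mask_iou(dets$pixels[[.det_row(dets, info$last[cand$a[k]])]],
               dets$pixels[[.det_row(dets, info$first[cand$b[k]])]])
    }, 0)
    cand <- cand[cand$iou >= iou_min, ]
    if (!nrow(cand)) break
    best <- cand[order(-cand$iou), ][1, ]
    track_of[track_of == info$track[best$b]] <- info$track[best$a]
  }
  track_of
}

.assemble_tracks <- function(dets, track_of, n_frames) {
  tab <- dets$table
  if (!nrow(tab)) {
    out <- list(table = .empty_track_table(),
                info = data.frame(track = integer(0), birth_frame = integer(0),
                                  death_frame = integer(0),
                                  censored_start = logical(0),
                                  censored_end = logical(0),
                                  islet = integer(0)),
                meta = dets$meta, n_frames = n_frames, dets = dets)
    class(out) <- "filo_tracks"
    return(out)
  }
  ids <- sort(unique(track_of))
  renum <- match(track_of, ids)
  info <- do.call(rbind, lapply(seq_along(ids), function(t) {
    rows <- which(renum == t)
    fr <- tab$frame[rows]
    data.frame(track = t, birth_frame = min(fr), death_frame = max(fr),
               censored_start = min(fr) == 1L,
               censored_end = max(fr) == n_frames,
               islet = tab$islet[rows[which.min(fr)]])
  }))
  long <- data.frame(track = renum, frame = tab$frame, det_id = tab$id,
                     minus_x_px = tab$base_x_px, minus_y_px = tab$base_y_px,
                     plus_x_px = tab$tip_x_px, plus_y_px = tab$tip_y_px,
                     length_um = tab$length_um, ambiguous = FALSE)
  long <- long[order(long$track, long$frame), ]
  long <- merge(long, info[, c("track", "birth_frame", "death_frame",
                               "censored_start", "censored_end")],
                by = "track", sort = TRUE)
  out <- list(table = long, info = info, meta = dets$meta,
              n_frames = n_frames, dets = dets)
  class(out) <- "filo_tracks"
  out
}

.empty_track_table <- function() {
  data.frame(track = integer(0), frame = integer(0), det_id = integer(0),
             minus_x_px = numeric(0), minus_y_px = numeric(0),
             plus_x_px = numeric(0), plus_y_px = numeric(0),
             length_um = numeric(0), ambiguous = logical(0),
             birth_frame = integer(0), death_frame = integer(0),
             censored_start = logical(0), censored_end = logical(0))
}

#' Assign (-)/(+) extremities along tracks
#'
#' Per frame, the skeleton endpoint nearer the islet body (Euclidean
#' distance transform) is the pointed (-) end and the farther one the
#' barbed (+) end; the labelling is stabilised along the track by majority
#' vote so single-frame flips cannot corrupt end-speed estimates.  Tracks
#' whose endpoints are equidistant within 0.5 px in more than half their
#' frames, or that never touch an islet, are flagged ambiguous.
#'
#' @param tracks a `filo_tracks` from [build_tracks()].
#' @param islet_labels list of per-frame islet label matrices.
#' @param adjacency_px maximum base distance (px) counted as touching.
#' @return `tracks` with `minus_*`/`plus_*` columns stabilised and the
#'   `ambiguous` flag set.
#' @export
assign_extremities <- function(tracks, islet_labels, adjacency_px = 3) {
  tab <- tracks$table
  if (!nrow(tab)) return(tracks)
  frames <- sort(unique(tab$frame))
  dmap <- list()
  for (f in frames) {
    lab <- islet_labels[[f]]
    dmap[[as.character(f)]] <- if (max(lab) > 0) {
      EBImage::distmap(matrix(as.numeric(lab == 0), nrow(lab)))
    } else NULL
  }
  for (t in unique(tab$track)) {
    rows <- which(tab$track == t)
    d_minus <- d_plus <- numeric(length(rows))
    for (k in seq_along(rows)) {
      r <- rows[k]
      dm <- dmap[[as.character(tab$frame[r])]]
      if (is.null(dm)) { d_minus[k] <- d_plus[k] <- Inf; next }
      d_minus[k] <- dm[round(tab$minus_y_px[r]), round(tab$minus_x_px[r])]
      d_plus[k] <- dm[round(tab$plus_y_px[r]), round(tab$plus_x_px[r])]
    }
    near_tie <- abs(d_minus - d_plus) < 0.5
    detached <- pmin(d_minus, d_plus) > adjacency_px
    ambiguous <- mean(near_tie) > 0.5 || all(detached)
    flip_votes <- sum(d_plus < d_minus)
    if (flip_votes > length(rows) / 2) {
      # majority says the stored "base" end is actually the far end
      for (cc in c("x", "y")) {
        a <- tab[rows, paste0("minus_", cc, "_px")]
        tab[rows, paste0("minus_", cc, "_px")] <-
          tab[rows, paste0("plus_", cc, "_px")]
        tab[rows, paste0("plus_", cc, "_px")] <- a
      }
    }
    tab$ambiguous[rows] <- ambiguous
  }
  tracks$table <- tab
  tracks
}
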