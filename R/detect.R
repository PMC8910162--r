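# Per-frame filopodia detection: islet segmentation, a pluggable detector
# producing a per-pixel detection map, and segmentation of that map into
# skeletonised filopodium objects.

#' Segment cell islets in one frame
#'
#' Otsu threshold, morphological opening with a disc (removing thin
#' protrusions such as filopodia), hole filling and a minimum-area filter.
#' Perimeters use Kulpa-weighted chain codes (near-unbiased digital
#' perimeter).
#'
#' @param frame numeric matrix `[y, x]`.
#' @param meta an [image_meta()].
#' @param opening_radius_um disc radius of the opening.
#' @param min_area_um2 smallest islet kept.
#' @param frame_index frame number recorded in the table.
#' @return list: `table` (`frame`, `label`, `perimeter_um`, `area_um2`)
#'   and `labels` (integer label matrix).  Blank frames give zero islets.
#' @export
segment_islets <- function(frame, meta = image_meta(),
                           opening_radius_um = 0.75, min_area_um2 = 20,
                           frame_index = 1L) {
  ps <- meta$pixel_size
  thr <- otsu_threshold(frame)
  mask <- frame > thr
  r <- max(1L, round(opening_radius_um / ps))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  m <- EBImage::opening(matrix(as.numeric(mask), nrow(frame)), brush)
  m <- EBImage::fillHull(m)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], max(lab))
    drop <- which(sizes * ps^2 < min_area_um2)
    if (length(drop)) lab[lab %in% drop] <- 0L
    ids <- sort(unique(lab[lab > 0]))
    lab2 <- lab
    lab2[lab > 0] <- match(lab[lab > 0], ids)
    lab <- lab2
  }
  n <- max(lab)
  if (n == 0L)
    return(list(table = data.frame(frame = integer(0), label = integer(0),
                                   perimeter_um = numeric(0),
                                   area_um2 = numeric(0)),
                labels = matrix(0L, nrow(frame), ncol(frame))))
  oc <- EBImage::ocontour(lab)
  tab <- data.frame(
    frame = frame_index, label = seq_len(n),
    perimeter_um = vapply(seq_len(n),
                          function(i) kulpa_perimeter(oc[[i]]) * ps, 0),
    area_um2 = vapply(seq_len(n), function(i) sum(lab == i) * ps^2, 0))
  list(table = tab, labels = lab)
}

#' Multiscale ridge detector
#'
#' Hessian-based tubeness (most negative eigenvalue of the scale-normalised
#' Hessian, maximum over scales), converted to a detection score in `[0, 1]`
#' via the squash `z / (z + z_scale)` of a robust z-score of the frame
#' (strictly increasing, so crest/valley structure is preserved).  This classical detector fills the
#' detection-map contract that a learned model can also satisfy: any
#' function mapping an image to a per-pixel score in `[0, 1]` plugs in.
#'
#' The frame is lightly pre-smoothed (sigma `presmooth_px`); bright ridges
#' on the dark background respond strongly, while cell-body interiors are
#' flat and their edges respond only in a thin band hugging the body,
#' which the downstream body margin removes.
#'
#' @param img numeric matrix.
#' @param sigmas_px ridge scales in pixels.
#' @param z_scale z-score giving score `1 - exp(-1)`.
#' @param presmooth_px pre-smoothing sigma in pixels.
#' @return matrix of scores in `[0, 1]`.
#' @export
ridge_detector <- function(img, sigmas_px = c(1, 2, 3), z_scale = 6,
                           presmooth_px = 1) {
  tb <- tubeness_map(gauss_blur2d(img, presmooth_px), sigmas_px)
  z <- pmax(robust_zscore(tb), 0)
  z / (z + z_scale)
}

#' Length of an ordered skeleton path
#'
#' Sum of pixel steps (1 for axial, sqrt(2) for diagonal) times the pixel
#' size.  A single-pixel path has length 0.
#'
#' @param path n x 2 matrix of ordered (y, x) pixels.
#' @param pixel_size micrometres per pixel.
#' @return micrometres.
#' @export
skeleton_length <- function(path, pixel_size) {
  if (is.null(path) || nrow(path) < 2L) return(0)
  d <- abs(diff(path))
  sum(ifelse(d[, 1] + d[, 2] == 2, sqrt(2), 1)) * pixel_size
}

#' Orientation of a filopodium against the reference axis
#'
#' Folded (axial) angle in `[0, 90]` degrees between the base-to-tip vector
#' and the reference axis.
#'
#' @param base,tip numeric length-2 `(x, y)` positions.
#' @param reference_axis unit 2D vector `(x, y)`.
#' @return degrees in `[0, 90]`.
#' @export
filopodium_orientation <- function(base, tip, reference_axis = c(1, 0)) {
  v <- c(tip[1] - base[1], tip[2] - base[2])
  if (all(v == 0)) stop("zero-length filopodium vector")
  ang <- atan2(v[2], v[1]) - atan2(reference_axis[2], reference_axis[1])
  fold_angle_deg(ang * 180 / pi)
}

#' Detect filopodia in one frame
#'
#' The detector's map is segmented with hysteresis thresholds (components
#' above `score_low` are kept if they contain a pixel above `score_high`)
#' and clipped to pixels outside the islet bodies (plus a small margin
#' where the body edge dominates the signal).  Because filopodia are
#' straight filaments, each component is decomposed into straight
#' centreline segments by deterministic robust line fitting (merged or
#' crossing filaments are recovered as separate segments; curved
#' leftovers fall back to morphological thinning), then filtered by
#' minimum length and maximum width.  The base is the endpoint nearest
#' the parent islet; the length runs from the body edge to the tip, so
#' the margin does not truncate lengths.
#'
#' @param frame numeric matrix.
#' @param islets result of [segment_islets()] for the same frame.
#' @param meta an [image_meta()].
#' @param detector function(image) -> score map in `[0, 1]`.
#' @param min_length_um,max_width_um detection filters.
#' @param tip_trim_px retraction applied to free filament ends,
#'   compensating the detector's end spread (about twice the largest
#'   ridge scale at the defaults).
#' @param base_pad_px inward correction of the measured body edge under
#'   an emanating filament (the filament brightens the edge outward by
#'   about the PSF width).
#' @param score_high,score_low hysteresis thresholds on the detection map.
#' @param min_high minimum number of pixels above `score_high` a fitted
#'   segment must own.
#' @param exclude_mask optional logical matrix of pixels to ignore (e.g.
#'   pillar autofluorescence), dilated by 1 px internally.
#' @param body_margin_px exclusion band around the islet bodies.
#' @param frame_index frame number recorded in the table.
#' @return a `filo_detections` list: `table` (detections schema), `pixels`
#'   (per-detection linear pixel indices), `skeletons` (ordered (y, x)
#'   paths, base first), `dim`, `meta`.
#' @export
detect_filopodia <- function(frame, islets, meta = image_meta(),
                             detector = ridge_detector,
                             min_length_um = 1, max_width_um = 1.5,
                             score_high = 0.75, score_low = 0.45,
                             exclude_mask = NULL, body_margin_px = 2L,
                             tip_trim_px = 6.8, base_pad_px = 1.4,
                             min_high = 3L, frame_index = 1L) {
  empty <- list(table = .empty_detections(), pixels = list(),
                skeletons = list(), keys = matrix(0L, 0, 2),
                dim = dim(frame), meta = meta)
  class(empty) <- "filo_detections"
  if (max(islets$labels) == 0L) return(empty)   # filopodia need a body
  map <- detector(frame)
  body <- islets$labels > 0L
  body_wide <- if (body_margin_px > 0) {
    EBImage::dilate(matrix(as.numeric(body), nrow(frame)),
                    EBImage::makeBrush(2L * as.integer(body_margin_px) + 1L,
                                       "disc")) > 0
  } else body
  keepable <- !body_wide
  if (!is.null(exclude_mask)) {
    ex <- EBImage::dilate(matrix(as.numeric(exclude_mask), nrow(frame)),
                          EBImage::makeBrush(3L, "box")) > 0
    keepable <- keepable & !ex
  }
  low <- map >= score_low & keepable
  high <- map >= score_high & keepable
  if (!any(high)) return(empty)
  lab <- label8(low)
  keep_ids <- unique(lab[high & lab > 0])
  if (!length(keep_ids)) return(empty)
  ps <- meta$pixel_size
  bg_level <- median(frame)
  ny <- nrow(frame); nx <- ncol(frame)
  # distance from every pixel to the nearest islet body pixel
  dist_body <- EBImage::distmap(matrix(as.numeric(!body), nrow(frame)))
  n_isl <- max(islets$labels)
  dist_each <- lapply(seq_len(n_isl), function(i)
    EBImage::distmap(matrix(as.numeric(islets$labels != i), nrow(frame))))
  # a thinning-derived path expressed as a straight segment (fallback for
  # components the straight-line extractor cannot explain)
  path_to_segment <- function(pg) {
    d <- pg[nrow(pg), ] - pg[1, ]
    nd <- sqrt(sum(d^2))
    if (nd < 2) return(NULL)
    list(ctr = (pg[1, ] + pg[nrow(pg), ]) / 2, dir = d / nd,
         t0 = -nd / 2, t1 = nd / 2)
  }
  tab <- list(); pixels <- list(); skeletons <- list()
  for (cid in keep_ids) {
    cpix <- which(lab == cid, arr.ind = TRUE)
    wts <- pmax(map[cpix] - score_low, 0)
    lines <- fit_line_segments(cpix, wts, high = high[cpix],
                               min_high = min_high)
    if (!length(lines)) {
      # curved or tiny component: fall back to a thinned skeleton
      y0 <- min(cpix[, 1]) - 1L; x0 <- min(cpix[, 2]) - 1L
      sub <- matrix(FALSE, max(cpix[, 1]) - y0 + 1L,
                    max(cpix[, 2]) - x0 + 1L)
      sub[cbind(cpix[, 1] - y0, cpix[, 2] - x0)] <- TRUE
      lines <- Filter(Negate(is.null), lapply(
        skeleton_paths(thin_mask(sub)),
        function(pg) path_to_segment(cbind(pg[, 1] + y0, pg[, 2] + x0))))
    }
    for (ln in lines) {
      # orient the segment: end A = nearer the body (base candidate)
      endpt <- function(t) pmin(pmax(round(ln$ctr + t * ln$dir), 1L),
                                c(ny, nx))
      eA <- endpt(ln$t0); eB <- endpt(ln$t1)
      dA <- dist_body[eA[1], eA[2]]; dB <- dist_body[eB[1], eB[2]]
      flip <- dB < dA
      tA <- if (flip) ln$t1 else ln$t0
      tB <- if (flip) ln$t0 else ln$t1
      if (flip) { tmp <- dA; dA <- dB; dB <- tmp }
      sgn <- sign(tB - tA)
      clipped_base <- dA <= body_margin_px + 2.5
      # sub-pixel end localisation: walk outward along the axis to the
      # interpolated score_low crossing, then retract by the detector's
      # end spread (~2 x largest ridge scale).  Applied to free ends;
      # the base end, when clipped by the body margin, is instead
      # extended along the axis to the body edge.
      locate_end <- function(t_end) {
        ts <- t_end + sgn * seq(-3, 9, by = 0.25)
        vv <- bilinear_at(map, ln$ctr[1] + ts * ln$dir[1],
                          ln$ctr[2] + ts * ln$dir[2])
        below <- which(vv < score_low)
        if (!length(below)) return(t_end)
        k <- below[1]
        if (k == 1L) return(t_end)
        frac <- (vv[k - 1L] - score_low) / max(vv[k - 1L] - vv[k], 1e-9)
        ts[k - 1L] + sgn * 0.25 * frac
      }
      tB <- locate_end(tB) - sgn * tip_trim_px
      if (!clipped_base) {
        # detached fragment: the A end is free too
        sgnA <- -sgn
        tsA <- tA + sgnA * seq(-3, 9, by = 0.25)
        vvA <- bilinear_at(map, ln$ctr[1] + tsA * ln$dir[1],
                           ln$ctr[2] + tsA * ln$dir[2])
        belowA <- which(vvA < score_low)
        if (length(belowA) && belowA[1] > 1L) {
          kk <- belowA[1]
          frac <- (vvA[kk - 1L] - score_low) /
            max(vvA[kk - 1L] - vvA[kk], 1e-9)
          tA <- tsA[kk - 1L] + sgnA * 0.25 * frac
        }
        tA <- tA - sgnA * tip_trim_px
      } else {
        # extend the base along the axis into the measured body edge;
        # the filament's own intensity pushes that edge outward by about
        # the PSF width, so step back in by base_pad_px
        tsA <- tA - sgn * seq(0, 2 * body_margin_px + 3, by = 0.25)
        yA <- pmin(pmax(round(ln$ctr[1] + tsA * ln$dir[1]), 1L), ny)
        xA <- pmin(pmax(round(ln$ctr[2] + tsA * ln$dir[2]), 1L), nx)
        inb <- which(body[cbind(yA, xA)])
        if (length(inb)) tA <- tsA[inb[1]] - sgn * base_pad_px
      }
      if (sgn * (tB - tA) < 2) next
      pA <- ln$ctr + tA * ln$dir             # (y, x), sub-pixel endpoints
      pB <- ln$ctr + tB * ln$dir
      tt <- seq(tA, tB, length.out = max(2L, ceiling(abs(tB - tA) / 0.5)))
      py <- pmin(pmax(round(ln$ctr[1] + tt * ln$dir[1]), 1L), ny)
      px <- pmin(pmax(round(ln$ctr[2] + tt * ln$dir[2]), 1L), nx)
      keep <- !duplicated(cbind(py, px))
      path <- unname(cbind(py, px)[keep, , drop = FALSE])
      if (nrow(path) < 3L) next
      # component pixels supporting this segment; the full (untrimmed)
      # support extent makes the tracking masks of consecutive frames
      # overlap generously even for short, fast-growing filaments
      ry <- cpix[, 1] - ln$ctr[1]; rx <- cpix[, 2] - ln$ctr[2]
      tproj <- (ry * ln$dir[1] + rx * ln$dir[2]) * sgn
      perp <- abs(ry * ln$dir[2] - rx * ln$dir[1])
      tlo <- min(sgn * ln$t0, sgn * ln$t1, sgn * tA)
      thi <- max(sgn * ln$t0, sgn * ln$t1, sgn * tB)
      selp <- perp <= 2.5 & tproj >= tlo - 1 & tproj <= thi + 1
      mypix <- cpix[selp, , drop = FALSE]
      if (nrow(mypix) < 3L) next
      # physical width: intensity-weighted FWHM of the cross profile
      wint <- pmax(frame[mypix] - bg_level, 0)
      if (sum(wint) <= 0) next
      sig_perp <- sqrt(sum(wint * perp[selp]^2) / sum(wint))
      width <- 2.355 * sig_perp * ps
      if (width > max_width_um) next
      eA <- path[1, ]; eB <- path[nrow(path), ]
      dA2 <- dist_body[eA[1], eA[2]]; dB2 <- dist_body[eB[1], eB[2]]
      # protrusions extend away from the body: the tip must stand off
      # farther than the base by a fraction of the segment length.  This
      # rejects residual body-edge ridges, which run parallel to the
      # boundary at constant distance.
      if (dB2 - dA2 < 0.3 * abs(tB - tA)) next
      len <- abs(tB - tA) * ps
      if (len < min_length_um) next
      e1 <- path[1, ]
      isl <- which.min(vapply(dist_each, function(d) d[e1[1], e1[2]], 0))
      id <- length(tab) + 1L
      tab[[id]] <- data.frame(
        frame = frame_index, id = id, islet = isl,
        base_x_px = pA[2], base_y_px = pA[1],
        tip_x_px = pB[2], tip_y_px = pB[1],
        length_um = len,
        orientation_deg = filopodium_orientation(
          c(pA[2], pA[1]), c(pB[2], pB[1]), c(1, 0)),
        width_um = width)
      pixels[[id]] <- sort(mypix[, 1] + (mypix[, 2] - 1L) * ny)
      skeletons[[id]] <- path
    }
  }
  if (!length(tab)) return(empty)
  tab <- do.call(rbind, tab)
  out <- list(table = tab, pixels = pixels, skeletons = skeletons,
              keys = cbind(tab$frame, tab$id), dim = dim(frame),
              meta = meta)
  class(out) <- "filo_detections"
  out
}

.empty_detections <- function() {
  data.frame(frame = integer(0), id = integer(0), islet = integer(0),
             base_x_px = numeric(0), base_y_px = numeric(0),
             tip_x_px = numeric(0), tip_y_px = numeric(0),
             length_um = numeric(0), orientation_deg = numeric(0),
             width_um = numeric(0))
}

#' Detect islets and filopodia across a whole movie
#'
#' @param movie counts array `[y, x, t]`.
#' @param meta an [image_meta()].
#' @param reference_axis unit 2D vector used for orientations.
#' @param ... passed to [detect_filopodia()].
#' @return list: `detections` (a `filo_detections` with all frames,
#'   per-frame ids), `islets` (list: `table` across frames, `labels` list
#'   of label matrices per frame).
#' @export
detect_movie <- function(movie, meta = image_meta(),
                         reference_axis = c(1, 0), ...) {
  n_frames <- dim(movie)[3]
  isl_tabs <- list(); isl_labels <- vector("list", n_frames)
  tabs <- list(); pixels <- list(); skeletons <- list(); keys <- list()
  for (f in seq_len(n_frames)) {
    fr <- movie[, , f]
    isl <- segment_islets(fr, meta, frame_index = f)
    isl_tabs[[f]] <- isl$table
    isl_labels[[f]] <- isl$labels
    det <- detect_filopodia(fr, isl, meta, frame_index = f, ...)
    if (nrow(det$table)) {
      det$table$orientation_deg <- vapply(seq_len(nrow(det$table)),
        function(i) filopodium_orientation(
          c(det$table$base_x_px[i], det$table$base_y_px[i]),
          c(det$table$tip_x_px[i], det$table$tip_y_px[i]),
          reference_axis), 0)
      tabs[[f]] <- det$table
      for (i in seq_len(nrow(det$table))) {
        keys[[length(keys) + 1L]] <- c(f, det$table$id[i])
        pixels[[length(pixels) + 1L]] <- det$pixels[[i]]
        skeletons[[length(skeletons) + 1L]] <- det$skeletons[[i]]
      }
    }
  }
  tab <- if (length(tabs)) do.call(rbind, tabs) else .empty_detections()
  dets <- list(table = tab, pixels = pixels, skeletons = skeletons,
               keys = if (length(keys)) do.call(rbind, keys)
                      else matrix(0L, 0, 2),
               dim = dim(movie)[1:2], meta = meta)
  class(dets) <- "filo_detections"
  list(detections = dets,
       islets = list(table = do.call(rbind, isl_tabs), labels = isl_labels))
}

# index of detection (frame f, id i) inside the flat pixel/skeleton lists
.det_index <- function(dets, f, i) {
  which(dets$keys[, 1] == f & dets$keys[, 2] == i)
}
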