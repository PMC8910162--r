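# 3D nuclei analysis: segmentation, in-plane orientation against the
# scaffold reference axis, and vertical engagement (bottom-z) statistics.

#' Segment nuclei in a 3D stack
#'
#' Gaussian pre-smoothing (default sigma 0.5 um), per-stack Otsu threshold,
#' 3D connected components (8-connected in-plane, face-connected in z), an
#' optional distance-transform marker split for touching nuclei, and a
#' minimum-volume filter.
#'
#' @param stack numeric array `[y, x, z]`.
#' @param meta an [image_meta()] (pixel size and z-step).
#' @param min_volume minimum object volume, cubic micrometres.
#' @param smooth_sigma_um pre-smoothing sigma in micrometres.
#' @param split_touching if `TRUE`, components are split at distance-
#'   transform maxima (nearest-marker assignment); intended for moderately
#'   sized objects such as touching ellipsoidal nuclei.
#' @return list of nucleus records; each has `label`, `voxels` (n x 3
#'   matrix of (y, x, z) indices), `centroid_um` (x, y, z), `bottom_z_um`,
#'   `volume_um3`, and the `meta` used.  Empty stacks yield an empty list.
#' @export
segment_nuclei_3d <- function(stack, meta = image_meta(),
                              min_volume = 50, smooth_sigma_um = 0.5,
                              split_touching = FALSE) {
  stopifnot(length(dim(stack)) == 3L)
  ps <- meta$pixel_size; zs <- meta$z_step
  sm <- stack
  sig_px <- smooth_sigma_um / ps
  for (k in seq_len(dim(stack)[3]))
    sm[, , k] <- gauss_blur2d(stack[, , k], sig_px)
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  # a background-only stack makes Otsu split the noise roughly in half;
  # nuclei never occupy anything near that fraction of the volume
  if (!any(mask) || mean(mask) > 0.25) return(list())
  lab <- label3d(mask)
  if (split_touching) lab <- .split_components(lab, meta)
  voxvol <- ps * ps * zs
  ids <- sort(unique(lab[lab > 0]))
  idx_by <- split(which(lab > 0), lab[lab > 0])
  out <- list()
  dm <- dim(stack)
  for (id in ids) {
    idx <- idx_by[[as.character(id)]]
    if (length(idx) * voxvol < min_volume) next
    vox <- arrayInd(idx, dm)
    rec <- list(label = NA_integer_, voxels = vox,
                centroid_um = c(x = (mean(vox[, 2]) - 0.5) * ps,
                                y = (mean(vox[, 1]) - 0.5) * ps,
                                z = (mean(vox[, 3]) - 0.5) * zs),
                bottom_z_um = (min(vox[, 3]) - 1) * zs,
                volume_um3 = length(idx) * voxvol,
                meta = meta)
    rec$label <- length(out) + 1L
    class(rec) <- "nucleus_record"
    out[[rec$label]] <- rec
  }
  out
}

# Split labelled components at L1 distance-transform maxima, assigning each
# voxel to its nearest marker (adequate for convex, ellipsoid-like nuclei).
.split_components <- function(lab, meta, min_sep_um = 4) {
  dm <- dim(lab)
  out <- array(0L, dm)
  nextid <- 0L
  for (id in sort(unique(lab[lab > 0]))) {
    idx <- which(lab == id)
    vox <- arrayInd(idx, dm)
    pad <- 2L
    rng <- lapply(1:3, function(d)
      max(1L, min(vox[, d]) - pad):min(dm[d], max(vox[, d]) + pad))
    sub <- lab[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] == id
    dt <- l1_distmap3d(sub)
    mx <- dt
    for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
      if (dy == 0 && dx == 0 && dz == 0) next
      sh <- array(0, dim(dt))
      src_y <- max(1, 1 - dy):min(dim(dt)[1], dim(dt)[1] - dy)
      src_x <- max(1, 1 - dx):min(dim(dt)[2], dim(dt)[2] - dx)
      src_z <- max(1, 1 - dz):min(dim(dt)[3], dim(dt)[3] - dz)
      sh[src_y, src_x, src_z] <-
        dt[src_y + dy, src_x + dx, src_z + dz, drop = FALSE]
      mx <- pmax(mx, sh)
    }
    peaks <- which(sub & dt >= mx & dt >= 2)
    if (!length(peaks)) peaks <- which.max(dt)
    # one marker per connected plateau of maxima, then suppress markers
    # closer together than a nucleus radius
    pkmask <- array(FALSE, dim(dt))
    pkmask[peaks] <- TRUE
    plab <- label3d(pkmask)
    nmk <- max(plab)
    pk <- t(vapply(seq_len(nmk), function(m) {
      vv <- arrayInd(which(plab == m), dim(dt))
      round(colMeans(vv))
    }, numeric(3)))
    pk_val <- vapply(seq_len(nmk), function(m) max(dt[plab == m]), 0)
    pk_um <- cbind(pk[, 2] * meta$pixel_size, pk[, 1] * meta$pixel_size,
                   pk[, 3] * meta$z_step)
    ord <- order(-pk_val)
    keep <- integer(0)
    for (i in ord) {
      if (!length(keep) ||
          min(sqrt(rowSums(sweep(pk_um[keep, , drop = FALSE], 2,
                                 pk_um[i, ])^2))) > min_sep_um)
        keep <- c(keep, i)
    }
    pk <- pk[keep, , drop = FALSE]
    svox <- arrayInd(which(sub), dim(dt))
    if (nrow(pk) <= 1L) {
      assign_id <- rep(1L, nrow(svox))
    } else {
      d2 <- matrix(0, nrow(svox), nrow(pk))
      scl <- c(meta$pixel_size, meta$pixel_size, meta$z_step)[c(1, 2, 3)]
      for (m in seq_len(nrow(pk)))
        d2[, m] <- ((svox[, 1] - pk[m, 1]) * scl[1])^2 +
                   ((svox[, 2] - pk[m, 2]) * scl[2])^2 +
                   ((svox[, 3] - pk[m, 3]) * scl[3])^2
      assign_id <- max.col(-d2, ties.method = "first")
    }
    gy <- rng[[1]][svox[, 1]]; gx <- rng[[2]][svox[, 2]]
    gz <- rng[[3]][svox[, 3]]
    out[cbind(gy, gx, gz)] <- nextid + assign_id
    nextid <- nextid + max(assign_id)
  }
  out
}

#' Fold an angle to the acute range 0-90 degrees
#'
#' Axial angles (a nucleus axis has no direction) are reduced modulo 180
#' and folded about 90.  Idempotent.
#'
#' @param theta_deg angle(s) in degrees.
#' @return folded angle(s) in `[0, 90]`.
#' @export
fold_angle_deg <- function(theta_deg) {
  a <- theta_deg %% 180
  ifelse(a > 90, 180 - a, a)
}

#' In-plane orientation of a nucleus against the reference axis
#'
#' The principal axis is the leading eigenvector of the xy covariance of
#' the voxels at or above `z_min` (only the top part of the nucleus is
#' considered, as the monolayer sits on top of the structures); the angle
#' to `reference_axis` is folded to `[0, 90]` degrees.
#'
#' @param record a nucleus record from [segment_nuclei_3d()].
#' @param reference_axis unit 2D vector (x, y).
#' @param z_min minimum height considered, micrometres.
#' @param anisotropy_min eigenvalue-ratio flag threshold: below it the
#'   angle is near-degenerate (round nucleus) and flagged.
#' @return list: `angle_deg` in `[0, 90]` (NA if undefined),
#'   `low_anisotropy`, `undefined` (fewer than 3 voxels above `z_min`),
#'   `eigen_ratio`.
#' @export
nucleus_orientation_angle <- function(record, reference_axis = c(1, 0),
                                      z_min = 4, anisotropy_min = 1.2) {
  meta <- record$meta
  zum <- (record$voxels[, 3] - 0.5) * meta$z_step
  sel <- zum >= z_min
  if (sum(sel) < 3L)
    return(list(angle_deg = NA_real_, low_anisotropy = TRUE,
                undefined = TRUE, eigen_ratio = NA_real_))
  xy <- cbind(record$voxels[sel, 2], record$voxels[sel, 1]) *
    meta$pixel_size                       # (x, y) um
  cv <- cov(xy)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1]
  ratio <- sqrt(max(eg$values[1], 0) / max(eg$values[2], 1e-12))
  ang_v <- atan2(v[2], v[1]) * 180 / pi
  ang_ax <- atan2(reference_axis[2], reference_axis[1]) * 180 / pi
  list(angle_deg = fold_angle_deg(ang_v - ang_ax),
       low_anisotropy = ratio < anisotropy_min,
       undefined = FALSE, eigen_ratio = ratio)
}

#' Bottom z position of a nucleus
#'
#' Height of the lowest voxel of the record above the substrate (z = 0 at
#' substrate contact).
#'
#' @param record a nucleus record from [segment_nuclei_3d()].
#' @param meta an [image_meta()]; defaults to the record's own.
#' @return micrometres.
#' @export
nucleus_bottom_z <- function(record, meta = record$meta) {
  (min(record$voxels[, 3]) - 1) * meta$z_step
}

#' Fraction of nuclei engaged below a height threshold
#'
#' @param records list of nucleus records, or a numeric vector of bottom-z
#'   values (micrometres).
#' @param threshold micrometres (default 5).
#' @return fraction in `[0, 1]`.
#' @export
engagement_fraction <- function(records, threshold = 5) {
  bz <- if (is.numeric(records)) records
        else vapply(records, function(r) r$bottom_z_um, 0)
  if (length(bz) == 0L) stop("engagement_fraction undefined for no nuclei")
  mean(bz < threshold)
}

#' Summary of nucleus orientation angles
#'
#' Arithmetic mean and SD plus a fixed 9-bin histogram (0-10, ..., 80-90
#' degrees).  A random orientation field has mean 45 degrees.
#'
#' @param angles_deg angles in `[0, 90]` degrees (NAs dropped).
#' @return list: `mean_deg`, `sd_deg`, `n`, `histogram` (named counts).
#' @export
orientation_summary <- function(angles_deg) {
  a <- angles_deg[!is.na(angles_deg)]
  if (length(a) == 0L) stop("no angles to summarise")
  if (any(a < 0 | a > 90)) stop("angles must lie in [0, 90] degrees")
  br <- seq(0, 90, by = 10)
  # right-open 10-degree bins; the last one includes 90 exactly
  h <- table(cut(a, br, include.lowest = TRUE, right = FALSE))
  list(mean_deg = mean(a), sd_deg = if (length(a) > 1) sd(a) else 0,
       n = length(a), histogram = as.integer(h))
}

#' Analyse a nuclei stack end to end
#'
#' Runs [segment_nuclei_3d()], measures orientation and bottom-z per
#' nucleus, and returns the tabular `nuclei` record set.
#'
#' @inheritParams segment_nuclei_3d
#' @inheritParams nucleus_orientation_angle
#' @return data.frame in the `nuclei` schema (see [write_records()]).
#' @export
analyze_nuclei_stack <- function(stack, meta = image_meta(),
                                 reference_axis = c(1, 0), z_min = 4,
                                 min_volume = 50, split_touching = FALSE) {
  recs <- segment_nuclei_3d(stack, meta, min_volume = min_volume,
                            split_touching = split_touching)
  if (!length(recs))
    return(data.frame(label = integer(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), centroid_z_um = numeric(0),
                      angle_deg = numeric(0), low_anisotropy = logical(0),
                      undefined_orientation = logical(0),
                      bottom_z_um = numeric(0), volume_um3 = numeric(0)))
  rows <- lapply(recs, function(r) {
    o <- nucleus_orientation_angle(r, reference_axis, z_min = z_min)
    data.frame(label = r$label,
               centroid_x_um = r$centroid_um[["x"]],
               centroid_y_um = r$centroid_um[["y"]],
               centroid_z_um = r$centroid_um[["z"]],
               angle_deg = o$angle_deg,
               low_anisotropy = o$low_anisotropy,
               undefined_orientation = o$undefined,
               bottom_z_um = r$bottom_z_um,
               volume_um3 = r$volume_um3)
  })
  do.call(rbind, rows)
}
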