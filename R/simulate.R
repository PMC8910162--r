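# Synthetic fluorescence-microscopy generator: scaffold lattices, oriented
# nuclei z-stacks, and bottom-plane filopodia timelapse movies with full
# ground truth.

#' Filopodium kinematic configuration
#'
#' Filopodia follow a piecewise-linear length profile: nucleation at
#' `min_length`, elongation at a per-filopodium speed drawn from a
#' truncated normal, an optional exponential plateau at the peak length
#' (drawn uniformly between `peak_min` and `max_length`), and retraction
#' back to `min_length`, where the filopodium dies.  With `min_length = 0`
#' and no plateau the lifetime of a deterministic filopodium is exactly
#' `2 * peak / speed`.
#'
#' @param birth_rate filopodia per micrometre of islet perimeter per second.
#' @param elongation_speed_mean,elongation_speed_sd nm/s.
#' @param retraction_speed_mean,retraction_speed_sd nm/s.
#' @param plateau_duration_mean seconds (exponential; 0 = no plateau).
#' @param max_length,peak_min,min_length micrometres; peak lengths are
#'   drawn from `U(peak_min, max_length)`; profiles start/end at
#'   `min_length`.
#' @param orientation_bias axial concentration toward the reference axis
#'   (inverse circular variance, rad^-2); 0 = isotropic.
#' @param frame_interval,movie_duration seconds.
#' @return object of class `kinematic_config`.
#' @export
kinematic_config <- function(birth_rate = 0.037 / 230,
                             elongation_speed_mean = 45.8,
                             elongation_speed_sd = 5.8,
                             retraction_speed_mean = 48.6,
                             retraction_speed_sd = 7.0,
                             plateau_duration_mean = 0,
                             max_length = 6.3, peak_min = 2,
                             min_length = 1,
                             orientation_bias = 0,
                             frame_interval = 20,
                             movie_duration = 2700) {
  stopifnot(elongation_speed_mean > 0, retraction_speed_mean > 0,
            birth_rate >= 0, frame_interval > 0, movie_duration > 0,
            min_length < max_length, peak_min > min_length,
            peak_min <= max_length, plateau_duration_mean >= 0,
            orientation_bias >= 0)
  structure(as.list(environment()), class = "kinematic_config")
}

#' Rendering configuration
#'
#' Camera model: `counts = background + photon_scale * intensity`, Poisson
#' shot noise on the counts, additive Gaussian read noise, rounded to the
#' 16-bit range.  Intensities are dimensionless (islet body 1.0, filopodium
#' centreline `filopodium_intensity`).
#'
#' @param psf_sigma Gaussian PSF sigma, micrometres.
#' @param background offset, counts.
#' @param photon_scale counts per unit intensity.
#' @param gaussian_read_noise_sd counts.
#' @param pillar_autofluorescence_amplitude intensity of pillar discs
#'   (0 = quenched, as after Sudan Black coating).
#' @param pixel_size,z_step micrometres.
#' @param filopodium_intensity,filopodium_width_um centreline intensity and
#'   Gaussian half-width of rendered filopodia.
#' @return object of class `render_config`.
#' @export
render_config <- function(psf_sigma = 0.25, background = 100,
                          photon_scale = 300, gaussian_read_noise_sd = 3,
                          pillar_autofluorescence_amplitude = 0,
                          pixel_size = 0.183, z_step = 0.3,
                          filopodium_intensity = 0.8,
                          filopodium_width_um = 0.3) {
  stopifnot(psf_sigma > 0, background >= 0, photon_scale >= 0,
            gaussian_read_noise_sd >= 0,
            pillar_autofluorescence_amplitude >= 0,
            pixel_size > 0, z_step > 0)
  structure(as.list(environment()), class = "render_config")
}

# Mean of 1/V for V ~ Normal(mu, sigma) truncated below at `lo`.
.inv_speed_mean <- function(mu, sigma, lo = 0.005) {
  if (sigma <= 0) return(1 / mu)
  z <- integrate(function(v) dnorm(v, mu, sigma), lo, Inf)$value
  integrate(function(v) dnorm(v, mu, sigma) / v, lo, Inf)$value / z
}

#' Calibrate kinematics to target ensemble statistics
#'
#' Solves numerically for the peak-length upper bound and the plateau mean
#' so that the ground-truth ensemble of the piecewise-linear model attains
#' a given duration-weighted mean length and mean lifetime: lifetime is an
#' emergent quantity of speeds, peak length and plateau, not set directly.
#'
#' @param target_length duration-weighted mean visible length, micrometres.
#' @param target_lifetime mean visible lifetime, seconds.
#' @param target_density filopodia per micrometre of islet perimeter
#'   (steady state); sets the birth rate as `target_density /
#'   target_lifetime`.
#' @param ... further arguments passed to [kinematic_config()].
#' @return a [kinematic_config()].
#' @export
calibrate_kinematics <- function(target_length = 3.36,
                                 target_lifetime = 230,
                                 target_density = 0.037, ...) {
  base <- kinematic_config(...)
  cc <- base$min_length
  a <- base$peak_min
  S <- .inv_speed_mean(base$elongation_speed_mean / 1000,
                       base$elongation_speed_sd / 1000) +
       .inv_speed_mean(base$retraction_speed_mean / 1000,
                       base$retraction_speed_sd / 1000)
  tau_of <- function(b) target_lifetime - ((a + b) / 2 - cc) * S
  f <- function(b) {
    el2 <- (a^2 + a * b + b^2) / 3
    ((el2 - cc^2) / 2) * S + ((a + b) / 2) * tau_of(b) -
      target_length * target_lifetime
  }
  bmax <- 2 * (cc + target_lifetime / S) - a - 1e-6
  if (f(a + 1e-3) * f(bmax) > 0)
    stop("kinematic calibration has no solution for these targets")
  b <- uniroot(f, c(a + 1e-3, bmax), tol = 1e-10)$root
  args <- list(...)
  args$max_length <- b
  args$plateau_duration_mean <- max(tau_of(b), 0)
  args$birth_rate <- target_density / target_lifetime
  do.call(kinematic_config, args)
}

#' Paper-default simulation preset
#'
#' Kinematics calibrated so that the ground-truth ensemble attains mean
#' length 3.36 um, mean lifetime ~230 s, elongation/retraction speeds of
#' ~45-49 nm/s and a steady-state density of 0.037 filopodia per um of
#' islet perimeter, at a 20 s frame interval over a 45 min movie.
#'
#' @return list with elements `kinematic` and `render`.
#' @export
paper_default_config <- function() {
  list(kinematic = calibrate_kinematics(),
       render = render_config())
}

rtnorm <- function(n, mean, sd, lo) {
  if (sd <= 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- x < lo
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo
  }
  x
}

#' Simulate one filopodium's kinematic life
#'
#' Draws per-filopodium speeds, peak length and plateau duration from the
#' configuration and returns the resulting piecewise-linear profile.
#' Randomness comes from the current RNG state (seed at the caller).
#'
#' @param config a [kinematic_config()].
#' @return list with speeds (um/s), `peak` (um), `plateau` (s), phase
#'   durations, total `lifetime` (s), the orientation angle (deg, in
#'   `[0, 180)`) and `length_at(t)` giving the length (um) at time `t` since
#'   birth.
#' @export
simulate_filopodium <- function(config) {
  stopifnot(inherits(config, "kinematic_config"))
  ve <- rtnorm(1, config$elongation_speed_mean,
               config$elongation_speed_sd, lo = 5) / 1000
  vr <- rtnorm(1, config$retraction_speed_mean,
               config$retraction_speed_sd, lo = 5) / 1000
  peak <- runif(1, config$peak_min, config$max_length)
  plateau <- if (config$plateau_duration_mean > 0)
    rexp(1, 1 / config$plateau_duration_mean) else 0
  theta <- if (config$orientation_bias > 0) {
    (rnorm(1, 0, (180 / pi) / sqrt(2 * config$orientation_bias))) %% 180
  } else runif(1, 0, 180)
  cc <- config$min_length
  t_el <- (peak - cc) / ve
  t_re <- (peak - cc) / vr
  lifetime <- t_el + plateau + t_re
  length_at <- function(t) {
    ifelse(t < 0 | t > lifetime, NA_real_,
      ifelse(t <= t_el, cc + ve * t,
        ifelse(t <= t_el + plateau, peak,
          peak - vr * (t - t_el - plateau))))
  }
  list(ve = ve, vr = vr, peak = peak, plateau = plateau,
       t_elong = t_el, t_retract = t_re, lifetime = lifetime,
       theta_deg = theta, length_at = length_at)
}

# ---- islets ----------------------------------------------------------------

# Random non-overlapping convex (elliptical) cell islets with a border
# margin.  Ground-truth perimeter is the rasterised-contour length so that
# normalized-number ground truth is self-consistent.
gen_islets <- function(dims, pixel_size, n_islets = 2,
                       axes_um = c(5, 10), margin_um = 7) {
  ny <- dims[1]; nx <- dims[2]
  tab <- data.frame()
  masks <- matrix(0L, ny, nx)
  tries <- 0L
  while (nrow(tab) < n_islets && tries < 500L) {
    tries <- tries + 1L
    ry <- runif(1, axes_um[1], axes_um[2]) / pixel_size
    rx <- runif(1, axes_um[1], axes_um[2]) / pixel_size
    th <- runif(1, 0, pi)
    mr <- margin_um / pixel_size + max(rx, ry)
    if (2 * mr >= min(nx, ny)) next
    cx <- runif(1, mr, nx - mr)
    cy <- runif(1, mr, ny - mr)
    ok <- TRUE
    for (r in seq_len(nrow(tab))) {
      d <- sqrt((cx - tab$cx_px[r])^2 + (cy - tab$cy_px[r])^2)
      if (d < max(rx, ry) + max(tab$rx_px[r], tab$ry_px[r]) + 2 / pixel_size)
        ok <- FALSE
    }
    if (!ok) next
    m <- filled_ellipse(ny, nx, cy, cx, ry, rx, th)
    id <- nrow(tab) + 1L
    masks[m] <- id
    oc <- EBImage::ocontour(matrix(as.numeric(m), ny))
    per <- kulpa_perimeter(oc[[1]]) * pixel_size
    tab <- rbind(tab, data.frame(
      islet = id, cx_px = cx, cy_px = cy, ry_px = ry, rx_px = rx,
      theta_rad = th, perimeter_um = per,
      area_um2 = sum(m) * pixel_size^2))
  }
  list(table = tab, labels = masks)
}

# Contour pixels of each islet, with outward normals (for base placement).
.islet_boundary <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- list()
  for (id in ids) {
    m <- labels == id
    oc <- EBImage::ocontour(matrix(as.numeric(m), nrow(labels)))[[1]] + 1L
    ctr <- colMeans(oc)
    nrm <- sweep(oc, 2L, ctr)
    nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-9)
    out[[as.character(id)]] <- list(pix = oc, normal = nrm)
  }
  out
}

# ---- movie ground truth ----------------------------------------------------

# Simulate the full ground-truth filopodia table for one movie.
# Births are a Poisson process on total islet perimeter, warmed up for
# `burn_in` seconds so the movie starts at steady state.
# Minimum distance (px) between two segments p1-p2 and q1-q2.
.seg_dist <- function(p1, p2, q1, q2) {
  tt <- seq(0, 1, length.out = 12)
  a <- cbind(p1[1] + tt * (p2[1] - p1[1]), p1[2] + tt * (p2[2] - p1[2]))
  b <- cbind(q1[1] + tt * (q2[1] - q1[1]), q1[2] + tt * (q2[2] - q1[2]))
  min(sqrt(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2))
}

simulate_movie_gt <- function(kcfg, islets, pixel_size, reference_axis,
                              burn_in = 900, clearance_um = 2) {
  n_frames <- floor(kcfg$movie_duration / kcfg$frame_interval) + 1L
  frame_times <- (seq_len(n_frames) - 1L) * kcfg$frame_interval
  perim <- sum(islets$table$perimeter_um)
  span <- kcfg$movie_duration + burn_in
  n_birth <- rpois(1, kcfg$birth_rate * perim * span)
  bounds <- .islet_boundary(islets$labels)
  axis_deg <- (atan2(reference_axis[2], reference_axis[1]) * 180 / pi) %% 180
  rows <- vector("list", n_birth)
  filo <- vector("list", n_birth)
  if (n_birth == 0L)
    return(list(table = .empty_gt(), filopodia = list(),
                n_frames = n_frames))
  t0 <- runif(n_birth, -burn_in, kcfg$movie_duration)
  wt <- islets$table$perimeter_um / perim
  isl_of <- sample(islets$table$islet, n_birth, replace = TRUE, prob = wt)
  placed <- list()     # accepted filopodia: base, tip extent, life span
  for (i in seq_len(n_birth)) {
    fp <- simulate_filopodium(kcfg)
    theta <- (fp$theta_deg + axis_deg) %% 180
    bd <- bounds[[as.character(isl_of[i])]]
    # pick a boundary pixel from which the (axial) direction points away
    # from the cell (within 40 degrees of the outward normal, as real
    # protrusions extend outward rather than hugging the body) and whose
    # full-extent filament keeps a clearance from every filopodium alive
    # at an overlapping time: concurrent filopodia splay apart rather
    # than crossing in the bottom plane
    dirv0 <- c(cos(theta * pi / 180), sin(theta * pi / 180))  # (x, y)
    ext_px <- fp$peak / pixel_size
    best <- NULL
    for (att in 1:80) {
      j <- sample(nrow(bd$pix), 1L)
      nrm <- bd$normal[j, c(2, 1)]                            # to (x, y)
      s <- sum(nrm * dirv0)
      if (abs(s) < 0.77) next
      dirv <- if (s < 0) -dirv0 else dirv0
      base <- bd$pix[j, ]                                     # (y, x) px
      tipmax <- c(base[1] + dirv[2] * ext_px, base[2] + dirv[1] * ext_px)
      clear <- TRUE
      for (pl in placed) {
        if (t0[i] > pl$t1 || t0[i] + fp$lifetime < pl$t0) next
        if (.seg_dist(base, tipmax, pl$base, pl$tip) <
            clearance_um / pixel_size) { clear <- FALSE; break }
      }
      best <- list(base = base, dirv = dirv, tip = tipmax)
      if (clear) break
    }
    if (is.null(best)) { rows[[i]] <- NULL; next }
    base <- best$base; dirv <- best$dirv
    placed[[length(placed) + 1L]] <-
      list(base = base, tip = best$tip, t0 = t0[i],
           t1 = t0[i] + fp$lifetime)
    alive <- which(frame_times >= t0[i] &
                   frame_times <= t0[i] + fp$lifetime)
    if (!length(alive)) { rows[[i]] <- NULL; next }
    len <- fp$length_at(frame_times[alive] - t0[i])
    tip_x <- base[2] + dirv[1] * len / pixel_size
    tip_y <- base[1] + dirv[2] * len / pixel_size
    rows[[i]] <- data.frame(
      id = i, islet = isl_of[i], frame = alive,
      base_x_px = base[2], base_y_px = base[1],
      tip_x_px = tip_x, tip_y_px = tip_y, length_um = len,
      birth_frame = min(alive), death_frame = max(alive))
    filo[[i]] <- c(fp[c("ve", "vr", "peak", "plateau", "lifetime")],
                   list(theta_deg = theta, t0 = t0[i]))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab)) tab <- .empty_gt()
  list(table = tab, filopodia = filo, n_frames = n_frames)
}

.empty_gt <- function() {
  data.frame(id = integer(0), islet = integer(0), frame = integer(0),
             base_x_px = numeric(0), base_y_px = numeric(0),
             tip_x_px = numeric(0), tip_y_px = numeric(0),
             length_um = numeric(0), birth_frame = integer(0),
             death_frame = integer(0))
}

#' Render a synthetic filopodia timelapse movie with ground truth
#'
#' Cell islets are bright convex bodies; filopodia are thin Gaussian-profile
#' ridges growing from the islet boundary following the kinematic model.
#' Frames are blurred with a Gaussian PSF and corrupted with Poisson shot
#' noise plus Gaussian read noise; optional pillar autofluorescence discs
#' are placed on the scaffold lattice.  Deterministic given `seed`.
#'
#' @param spec a [scaffold_spec()] (supplies the reference axis and, when
#'   autofluorescence is on, the pillar layout).
#' @param kcfg a [kinematic_config()].
#' @param rcfg a [render_config()].
#' @param seed integer RNG seed.
#' @param dims image size in pixels `c(ny, nx)`.
#' @param n_islets,islet_axes_um islet count and semi-axis range
#'   (micrometres).
#' @return list: `movie` (counts array `[y, x, t]`), `islets`
#'   (ground-truth table + label matrix), `gt` (per-frame filopodium
#'   table), `meta` ([image_meta()]), `kcfg`, `rcfg`, `seed`.
#' @export
render_movie <- function(spec, kcfg, rcfg, seed, dims = c(256, 256),
                         n_islets = 1, islet_axes_um = c(11, 15)) {
  stopifnot(inherits(kcfg, "kinematic_config"),
            inherits(rcfg, "render_config"))
  set.seed(seed)
  ny <- dims[1]; nx <- dims[2]
  ps <- rcfg$pixel_size
  margin <- kcfg$max_length + 1
  islets <- gen_islets(dims, ps, n_islets = n_islets,
                       axes_um = islet_axes_um, margin_um = margin)
  gt <- simulate_movie_gt(kcfg, islets, ps, spec$reference_axis)
  n_frames <- gt$n_frames
  base_int <- matrix(0, ny, nx)
  base_int[islets$labels > 0] <- 1
  if (rcfg$pillar_autofluorescence_amplitude > 0) {
    lat <- pillar_lattice(spec, extent = c(nx, ny) * ps)
    for (r in seq_len(nrow(lat$pillars))) {
      pm <- filled_ellipse(ny, nx, lat$pillars$y[r] / ps,
                           lat$pillars$x[r] / ps,
                           0.5 / ps, 0.5 / ps)
      base_int[pm] <- base_int[pm] + rcfg$pillar_autofluorescence_amplitude
    }
  }
  psf_px <- rcfg$psf_sigma / ps
  w_px <- rcfg$filopodium_width_um / ps
  movie <- array(0, c(ny, nx, n_frames))
  by_frame <- split(seq_len(nrow(gt$table)), gt$table$frame)
  for (f in seq_len(n_frames)) {
    int <- base_int
    for (r in by_frame[[as.character(f)]]) {
      int <- draw_segment(int,
                          c(gt$table$base_y_px[r], gt$table$base_x_px[r]),
                          c(gt$table$tip_y_px[r], gt$table$tip_x_px[r]),
                          w_px, rcfg$filopodium_intensity)
    }
    int <- gauss_blur2d(int, psf_px)
    lambda <- rcfg$background + rcfg$photon_scale * int
    counts <- if (rcfg$photon_scale > 0) {
      rpois(length(lambda), lambda)
    } else rep(rcfg$background, length(lambda))
    counts <- counts + rnorm(length(counts), 0, rcfg$gaussian_read_noise_sd)
    movie[, , f] <- pmin(pmax(round(counts), 0), 65535)
  }
  meta <- image_meta(pixel_size = ps, z_step = rcfg$z_step,
                     frame_interval = kcfg$frame_interval)
  list(movie = movie, islets = islets, gt = gt$table, meta = meta,
       kcfg = kcfg, rcfg = rcfg, seed = seed)
}

# ---- nuclei stacks ---------------------------------------------------------

#' Engagement presets: fraction of nuclei below 5 micrometres
#'
#' Bottom-z mixtures by structure: the engaged fraction sits at substrate
#' contact, the rest in the top monolayer (~7 um).
#'
#' @return named numeric vector of engaged fractions.
#' @export
engagement_presets <- function() {
  c("l7L14-open" = 0.62, "l7L14-closed" = 0.02,
    "D13.5-open" = 0.58, "D10-open" = 0.78, "D8.8-open" = 0.64,
    "D6.6-open" = 0.44, "D4.5-open" = 0.06)
}

#' Render a synthetic 3D nuclei stack with ground truth
#'
#' Nuclei are solid, non-overlapping ellipsoids.  Each is engaged (bottom at
#' substrate contact) with the preset's probability, otherwise it sits in
#' the top monolayer; in-plane major-axis angles follow the structure type
#' (oriented along the reference axis on elongated lattices, isotropic on
#' regular ones) unless given explicitly.
#'
#' @param spec a [scaffold_spec()].
#' @param n_nuclei number of nuclei to place.
#' @param engagement_preset name from [engagement_presets()], or a numeric
#'   fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param rcfg a [render_config()] (pixel size, z-step, noise).
#' @param extent_um lateral extent (square); default sized to fit
#'   `n_nuclei`.
#' @param angles_deg optional explicit in-plane angles (degrees, recycled).
#' @param angle_sd_deg spread of angles around the reference axis for
#'   elongated lattices.
#' @return list: `stack` (counts `[y, x, z]`), `gt` (ground-truth table),
#'   `meta`.
#' @export
render_nuclei_stack <- function(spec, n_nuclei, engagement_preset, seed,
                                rcfg = render_config(pixel_size = 0.3),
                                extent_um = NULL, angles_deg = NULL,
                                angle_sd_deg = 24) {
  set.seed(seed)
  frac <- if (is.numeric(engagement_preset)) {
    engagement_preset
  } else {
    pr <- engagement_presets()
    if (!engagement_preset %in% names(pr))
      stop("unknown engagement preset: ", engagement_preset)
    pr[[engagement_preset]]
  }
  stopifnot(frac >= 0, frac <= 1)
  ps <- rcfg$pixel_size; zs <- rcfg$z_step
  if (is.null(extent_um)) extent_um <- max(40, ceiling(sqrt(n_nuclei * 220)))
  npx <- ceiling(extent_um / ps)
  nz <- ceiling(11 / zs)
  a <- runif(n_nuclei, 3.8, 5.0)     # semi-axes, um
  b <- runif(n_nuclei, 2.2, 3.0)
  cv <- runif(n_nuclei, 1.4, 1.8)
  engaged <- runif(n_nuclei) < frac
  bottom <- ifelse(engaged, runif(n_nuclei, 0, 1.2),
                   pmin(pmax(rnorm(n_nuclei, 6.9, 0.35), 5.6), 7.6))
  zc <- bottom + cv
  ang <- if (!is.null(angles_deg)) {
    rep(angles_deg, length.out = n_nuclei) %% 180
  } else if (spec$shape == "elongated") {
    ax_deg <- (atan2(spec$reference_axis[2], spec$reference_axis[1]) *
               180 / pi) %% 180
    (ax_deg + rnorm(n_nuclei, 0, angle_sd_deg)) %% 180
  } else runif(n_nuclei, 0, 180)
  # sequential placement with overlap rejection (conservative bounding discs)
  xs <- ys <- numeric(n_nuclei)
  placed <- 0L
  for (i in seq_len(n_nuclei)) {
    ok <- FALSE
    for (att in 1:4000) {
      x <- runif(1, a[i] + 1, extent_um - a[i] - 1)
      y <- runif(1, a[i] + 1, extent_um - a[i] - 1)
      clash <- FALSE
      if (placed > 0L) {
        j <- seq_len(placed)
        near <- abs(zc[j] - zc[i]) < (cv[j] + cv[i])
        if (any(near)) {
          dd <- sqrt((xs[j][near] - x)^2 + (ys[j][near] - y)^2)
          clash <- any(dd < a[j][near] + a[i] + 0.3)
        }
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop("cannot place ", n_nuclei,
                  " non-overlapping nuclei in extent ", extent_um, " um")
    xs[i] <- x; ys[i] <- y
    placed <- i
  }
  stack <- array(0, c(npx, npx, nz))
  zmid <- (seq_len(nz) - 0.5) * zs
  for (i in seq_len(n_nuclei)) {
    th <- ang[i] * pi / 180
    kz <- which(abs(zmid - zc[i]) <= cv[i])
    yr <- pmax(1, floor((ys[i] - a[i]) / ps)):pmin(npx, ceiling((ys[i] + a[i]) / ps))
    xr <- pmax(1, floor((xs[i] - a[i]) / ps)):pmin(npx, ceiling((xs[i] + a[i]) / ps))
    gy <- (matrix(yr, length(yr), length(xr)) - 0.5) * ps - ys[i]
    gx <- (matrix(xr, length(yr), length(xr), byrow = TRUE) - 0.5) * ps - xs[i]
    u <- gx * cos(th) + gy * sin(th)
    w <- -gx * sin(th) + gy * cos(th)
    for (k in kz) {
      rz2 <- 1 - ((zmid[k] - zc[i]) / cv[i])^2
      if (rz2 <= 0) next
      inside <- (u / a[i])^2 + (w / b[i])^2 <= rz2
      sl <- stack[yr, xr, k]
      sl[inside] <- 400
      stack[yr, xr, k] <- sl
    }
  }
  psf_px <- rcfg$psf_sigma / ps
  for (k in seq_len(nz)) {
    int <- gauss_blur2d(stack[, , k], psf_px)
    lambda <- rcfg$background + int
    counts <- rpois(length(lambda), lambda) +
      rnorm(length(lambda), 0, rcfg$gaussian_read_noise_sd)
    stack[, , k] <- pmin(pmax(round(counts), 0), 65535)
  }
  gt <- data.frame(id = seq_len(n_nuclei), x_um = xs, y_um = ys, z_um = zc,
                   a_um = a, b_um = b, c_um = cv, angle_deg = ang,
                   bottom_z_um = bottom, engaged = engaged)
  meta <- image_meta(pixel_size = ps, z_step = zs)
  list(stack = stack, gt = gt, meta = meta)
}
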