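# Track-level dynamics: censored lifetimes, per-extremity speeds,
# perimeter-normalised counts, kinetic-curve smoothing, interval means and
# paired pre/post-treatment statistics.

#' Lifetimes of uncensored tracks
#'
#' A track's lifetime is `(death_frame - birth_frame + 1) * frame_interval`.
#' Tracks alive at the first or last movie frame have unknown lifetime and
#' are discarded (both censoring flags must be clear).
#'
#' @param tracks a `filo_tracks`, or a data.frame with columns
#'   `birth_frame`, `death_frame`, `censored_start`, `censored_end`.
#' @param frame_interval seconds between frames.
#' @param min_frames minimum persistence (frames) for a track to
#'   contribute; the default 1 keeps every uncensored track.  Image
#'   pipelines pass 2, as a single-frame object's "lifetime" is fixed by
#'   the sampling interval, not by the object.
#' @return numeric vector of lifetimes (seconds); empty, with a warning,
#'   when every track is censored.
#' @export
track_lifetimes <- function(tracks, frame_interval = 20, min_frames = 1L) {
  info <- if (inherits(tracks, "filo_tracks")) tracks$info else tracks
  if (inherits(tracks, "filo_tracks") && !is.null(tracks$meta))
    frame_interval <- tracks$meta$frame_interval
  keep <- !info$censored_start & !info$censored_end &
    (info$death_frame - info$birth_frame + 1) >= min_frames
  if (nrow(info) > 0L && !any(keep))
    warning("all tracks are censored; no lifetimes")
  (info$death_frame[keep] - info$birth_frame[keep] + 1) * frame_interval
}

#' Per-extremity elongation and retraction speeds of one track
#'
#' For each consecutive frame pair, each endpoint's displacement is
#' projected on the filopodium axis (minus-to-plus unit vector);
#' displacements below `min_step_um` are discarded as localisation jitter.
#' Projections that lengthen the filopodium (outward for the (+) end,
#' backward for the (-) end) count as elongation, the others as
#' retraction.  Because a growth or retraction phase rarely starts or
#' ends exactly on a frame, the first and last step of every contiguous
#' same-direction run are partial and under-sample the phase speed; runs
#' of three or more steps therefore contribute only their interior steps.
#' Per-track speeds summarise `|d| / frame_interval` over the retained
#' steps (median by default, robust to residual localisation jitter).
#'
#' @param track data.frame of one track's rows (long table) with
#'   `minus_*`/`plus_*` pixel columns, ordered by frame.
#' @param frame_interval seconds.
#' @param pixel_size micrometres per pixel.
#' @param min_step_um displacement noise floor (default one pixel).
#' @param average `"median"` (robust, default) or `"mean"` per-track
#'   summary of step speeds.
#' @return list of per-track speeds in nm/s (`NA` when no step qualifies):
#'   `plus_elong`, `plus_retract`, `minus_elong`, `minus_retract`, and
#'   step counts `n_*`.
#' @export
end_speeds <- function(track, frame_interval = 20, pixel_size = 0.183,
                       min_step_um = pixel_size,
                       average = c("median", "mean")) {
  average <- match.arg(average)
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < 2L) return(list(plus_elong = NA_real_, plus_retract = NA_real_,
                          minus_elong = NA_real_, minus_retract = NA_real_,
                          n_steps = 0L))
  pp <- pm <- rep(NA_real_, n - 1L)
  for (k in seq_len(n - 1L)) {
    if (track$frame[k + 1L] - track$frame[k] != 1L) next
    ax <- c(track$plus_x_px[k] - track$minus_x_px[k],
            track$plus_y_px[k] - track$minus_y_px[k])
    nr <- sqrt(sum(ax^2))
    if (nr == 0) next
    dplus <- c(track$plus_x_px[k + 1L] - track$plus_x_px[k],
               track$plus_y_px[k + 1L] - track$plus_y_px[k])
    dminus <- c(track$minus_x_px[k + 1L] - track$minus_x_px[k],
                track$minus_y_px[k + 1L] - track$minus_y_px[k])
    pp[k] <- sum(dplus * ax / nr) * pixel_size
    pm[k] <- sum(dminus * ax / nr) * pixel_size
  }
  # categorise steps, then drop the partial first/last step of runs >= 3
  run_pool <- function(d, pos_is_growth) {
    cat_of <- ifelse(is.na(d), "x",
              ifelse(d >= min_step_um, if (pos_is_growth) "E" else "R",
              ifelse(d <= -min_step_um, if (pos_is_growth) "R" else "E",
                     "0")))
    rl <- rle(cat_of)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- logical(length(d))
    for (q in seq_along(rl$values)) {
      if (!rl$values[q] %in% c("E", "R")) next
      idx <- starts[q]:ends[q]
      if (length(idx) >= 3L) {
        idx <- idx[-c(1L, length(idx))]
      } else {
        # both steps of a short run may be partial; the larger one is
        # the least-biased sample of the phase speed
        idx <- idx[which.max(abs(d[idx]))]
      }
      keep[idx] <- TRUE
    }
    list(elong = abs(d[keep & cat_of == "E"]),
         retract = abs(d[keep & cat_of == "R"]))
  }
  plus <- run_pool(pp, pos_is_growth = TRUE)
  minus <- run_pool(pm, pos_is_growth = FALSE)
  avg <- if (average == "median") median else mean
  val <- function(v) if (length(v)) avg(v) / frame_interval * 1000 else
    NA_real_
  list(plus_elong = val(plus$elong), plus_retract = val(plus$retract),
       minus_elong = val(minus$elong), minus_retract = val(minus$retract),
       n_steps = length(plus$elong) + length(plus$retract) +
         length(minus$elong) + length(minus$retract))
}

#' Perimeter-normalised filopodia count per frame
#'
#' @param det_table detections table (or tracks long table) with a `frame`
#'   column.
#' @param islet_table islets table with `frame` and `perimeter_um`.
#' @param frames frames to evaluate (default: all frames in
#'   `islet_table`).
#' @return data.frame `frame`, `count`, `perimeter_um`, `per_um`.
#' @export
normalized_count <- function(det_table, islet_table,
                             frames = sort(unique(islet_table$frame))) {
  out <- data.frame(frame = frames)
  out$count <- vapply(frames, function(f)
    sum(det_table$frame == f), 0L)
  out$perimeter_um <- vapply(frames, function(f)
    sum(islet_table$perimeter_um[islet_table$frame == f]), 0)
  if (any(out$perimeter_um <= 0))
    stop("zero total islet perimeter in frame(s) ",
         paste(head(out$frame[out$perimeter_um <= 0]), collapse = ", "))
  out$per_um <- out$count / out$perimeter_um
  out
}

#' Savitzky-Golay smoothing of a kinetic curve
#'
#' Local least-squares polynomial smoothing (window of 21 time intervals,
#' i.e. 7 min at 20 s, and a third-degree polynomial by default); series
#' ends are handled by polynomial fits on the end windows.  Polynomials up
#' to the filter degree are reproduced exactly.
#'
#' @param values numeric series (NAs allowed at the boundary mask are
#'   preserved).
#' @param time_s time grid in seconds (default `0, dt, ...`).
#' @param window odd window length, in samples.
#' @param degree polynomial degree (< window).
#' @param quantity label stored with the curve.
#' @return data.frame of class `kinetic_curve`: `time_s`, `quantity`,
#'   `raw`, `smoothed`.
#' @export
smooth_kinetic_curve <- function(values, time_s = NULL, window = 21L,
                                 degree = 3L, quantity = "value") {
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  if (degree >= window) stop("degree must be below the window size")
  ok <- !is.na(values)
  if (sum(ok) < window)
    stop("series shorter than the smoothing window")
  if (is.null(time_s)) time_s <- seq_along(values) - 1
  sm <- rep(NA_real_, length(values))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    if (length(idx) >= window)
      sm[idx] <- signal::sgolayfilt(values[idx], p = degree, n = window)
    else sm[idx] <- values[idx]
  }
  out <- data.frame(time_s = time_s, quantity = quantity, raw = values,
                    smoothed = sm)
  class(out) <- c("kinetic_curve", class(out))
  out
}

#' Pre/post-treatment interval means of a kinetic curve
#'
#' Control window: 10.3 min ending at drug addition (for lifetime curves,
#' ending 5 min before it, since lifetimes near the interruption cannot be
#' assessed).  Treatment window: 10.3 min starting 21.3 min after drug
#' addition, or 40 min for slow-onset drugs.
#'
#' @param curve a `kinetic_curve` (or data.frame with `time_s` and a value
#'   column).
#' @param drug_time_s time of drug addition, seconds.
#' @param quantity `"number"`, `"length"` or `"lifetime"`.
#' @param slow_onset use the 40 min delayed treatment window.
#' @param column value column to average (default `smoothed` if present).
#' @param window_min,delay_min,slow_delay_min,lifetime_guard_min interval
#'   definitions in minutes.
#' @return named numeric `c(ctr, drug)`.
#' @export
interval_means <- function(curve, drug_time_s,
                           quantity = c("number", "length", "lifetime"),
                           slow_onset = FALSE,
                           column = if ("smoothed" %in% names(curve))
                             "smoothed" else "raw",
                           window_min = 10.3, delay_min = 21.3,
                           slow_delay_min = 40, lifetime_guard_min = 5) {
  quantity <- match.arg(quantity)
  w <- window_min * 60
  ctr_end <- if (quantity == "lifetime")
    drug_time_s - lifetime_guard_min * 60 else drug_time_s
  ctr <- c(ctr_end - w, ctr_end)
  delay <- if (slow_onset) slow_delay_min * 60 else delay_min * 60
  drug <- c(drug_time_s + delay, drug_time_s + delay + w)
  t <- curve$time_s
  if (ctr[1] < min(t) || drug[2] > max(t) + 1e-9)
    stop("sampling interval outside the curve span")
  v <- curve[[column]]
  in_ctr <- t >= ctr[1] & t < ctr[2]
  in_drug <- t >= drug[1] & t < drug[2]
  c(ctr = mean(v[in_ctr], na.rm = TRUE),
    drug = mean(v[in_drug], na.rm = TRUE))
}

#' Paired pre/post significance test
#'
#' Shapiro-Wilk normality check on the paired differences, then a paired
#' t-test.  Normality failure is reported as a flag, not an automatic
#' fallback.
#'
#' @param ctr,drug equal-length paired samples (n >= 3).
#' @return list: `shapiro_p`, `normal` (at the 0.05 level), `t`, `df`,
#'   `p_value`, `mean_difference`.
#' @export
paired_significance_test <- function(ctr, drug) {
  stopifnot(length(ctr) == length(drug), length(ctr) >= 3L)
  d <- drug - ctr
  if (sd(d) == 0)
    stop("degenerate paired test: zero-variance differences")
  sw <- shapiro.test(d)
  tt <- t.test(drug, ctr, paired = TRUE)
  list(shapiro_p = sw$p.value, normal = sw$p.value >= 0.05,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d))
}

#' Per-movie dynamics summary
#'
#' Lengths, normalised numbers and the fraction of elongating filopodia
#' are averaged over a central analysis window (default 16.6 min,
#' systematically excluding the movie beginning and end); lifetimes use
#' uncensored tracks only; speeds are per-track means averaged over
#' tracks.  Birth/death event rates per minute are reported as convenience
#' fields.
#'
#' @param tracks a `filo_tracks`.
#' @param islet_table islets table (`frame`, `perimeter_um`).
#' @param meta an [image_meta()].
#' @param movie_id identifier recorded in the summary.
#' @param analysis_window_min central window for frame-wise quantities.
#' @param min_step_um noise floor for speeds/elongation calls.
#' @param min_track_frames persistence required for the lifetime
#'   statistic (see [track_lifetimes()]).
#' @return one-row data.frame in the `summary` schema.
#' @export
summarize_movie <- function(tracks, islet_table, meta = tracks$meta,
                            movie_id = 1L, analysis_window_min = 16.6,
                            min_step_um = meta$pixel_size,
                            min_track_frames = 2L) {
  tab <- tracks$table
  info <- tracks$info
  n_frames <- tracks$n_frames
  dt <- meta$frame_interval
  half <- round(analysis_window_min * 60 / dt / 2)
  mid <- (n_frames + 1) / 2
  win <- max(1L, floor(mid - half)):min(n_frames, ceiling(mid + half))
  empty <- nrow(tab) == 0L
  in_win <- if (empty) logical(0) else tab$frame %in% win
  mean_len <- if (any(in_win)) mean(tab$length_um[in_win]) else NA_real_
  med_len <- if (any(in_win)) median(tab$length_um[in_win]) else NA_real_
  lt <- if (nrow(info))
    suppressWarnings(track_lifetimes(tracks, dt,
                                     min_frames = min_track_frames))
  else numeric(0)
  mean_lt <- if (length(lt)) mean(lt) else NA_real_
  sp <- list(plus_elong = NA_real_, plus_retract = NA_real_,
             minus_elong = NA_real_, minus_retract = NA_real_)
  if (!empty) {
    per_track <- lapply(split(tab, tab$track), end_speeds,
                        frame_interval = dt, pixel_size = meta$pixel_size,
                        min_step_um = min_step_um)
    for (k in names(sp)) {
      v <- vapply(per_track, function(s) s[[k]], 0)
      sp[[k]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  nn <- if (!empty && nrow(islet_table)) {
    nc <- normalized_count(tab, islet_table,
                           frames = intersect(win,
                                              unique(islet_table$frame)))
    mean(nc$per_um)
  } else NA_real_
  frac_el <- NA_real_
  if (!empty) {
    els <- c()
    by_tr <- split(tab, tab$track)
    inc <- do.call(rbind, lapply(by_tr, function(tr) {
      tr <- tr[order(tr$frame), ]
      if (nrow(tr) < 2L) return(NULL)
      data.frame(frame = tr$frame[-1],
                 up = diff(tr$length_um) > min_step_um,
                 ok = diff(tr$frame) == 1L)
    }))
    if (!is.null(inc)) {
      inc <- inc[inc$ok & inc$frame %in% win, ]
      per_frame <- tapply(inc$up, inc$frame, mean)
      if (length(per_frame)) frac_el <- mean(per_frame)
    }
  }
  births <- if (nrow(info)) sum(!info$censored_start) else 0L
  deaths <- if (nrow(info)) sum(!info$censored_end) else 0L
  minutes <- (n_frames - 1) * dt / 60
  data.frame(movie = movie_id,
             mean_length_um = mean_len, median_length_um = med_len,
             mean_lifetime_s = mean_lt,
             elong_speed_plus_nms = sp$plus_elong,
             elong_speed_minus_nms = sp$minus_elong,
             retract_speed_plus_nms = sp$plus_retract,
             retract_speed_minus_nms = sp$minus_retract,
             normalized_number_per_um = nn,
             fraction_elongating = frac_el,
             n_filopodia = nrow(info), n_frames = n_frames,
             birth_rate_per_min = births / minutes,
             death_rate_per_min = deaths / minutes)
}

#' Kinetic time courses of a tracked movie
#'
#' Mean filopodium length, perimeter-normalised number and mean lifetime
#' of the (uncensored) filopodia present at each time point, with
#' Savitzky-Golay smoothing.  Lifetime values within one mean lifetime of
#' either movie boundary are masked (NA), since lifetimes there cannot be
#' assessed.
#'
#' @param tracks a `filo_tracks`.
#' @param islet_table islets table.
#' @param meta an [image_meta()].
#' @param window,degree smoothing parameters.
#' @return data.frame: rows of the three curves in the `curves` schema.
#' @export
kinetic_curves <- function(tracks, islet_table, meta = tracks$meta,
                           window = 21L, degree = 3L) {
  tab <- tracks$table
  info <- tracks$info
  n_frames <- tracks$n_frames
  dt <- meta$frame_interval
  times <- (seq_len(n_frames) - 1) * dt
  len <- vapply(seq_len(n_frames), function(f) {
    v <- tab$length_um[tab$frame == f]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  nn <- rep(NA_real_, n_frames)
  if (nrow(islet_table)) {
    nc <- normalized_count(tab, islet_table)
    nn[nc$frame] <- nc$per_um
  }
  lt_track <- (info$death_frame - info$birth_frame + 1) * dt
  unc <- !info$censored_start & !info$censored_end & lt_track >= 2 * dt
  lt <- vapply(seq_len(n_frames), function(f) {
    alive <- unc & info$birth_frame <= f & info$death_frame >= f
    if (any(alive)) mean(lt_track[alive]) else NA_real_
  }, 0)
  guard <- if (any(unc)) mean(lt_track[unc]) else 0
  lt[times < guard | times > max(times) - guard] <- NA_real_
  sm <- function(v, q) tryCatch(
    smooth_kinetic_curve(v, times, window, degree, quantity = q),
    error = function(e) data.frame(time_s = times, quantity = q, raw = v,
                                   smoothed = v))
  rbind(sm(len, "length"), sm(nn, "normalized_number"), sm(lt, "lifetime"))
}
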