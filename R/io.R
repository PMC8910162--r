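#' Image calibration metadata
#'
#' @param pixel_size lateral pixel size, micrometres per pixel.
#' @param z_step axial slice spacing, micrometres (z-stacks).
#' @param frame_interval time between frames, seconds (movies).
#' @param channels named character vector describing channel roles.
#' @return object of class `image_meta`.
#' @details Defaults: 0.183 um/px and a 20 s frame interval (one 7 min
#'   smoothing window = 21 intervals), 0.3 um z-step.
#' @export
image_meta <- function(pixel_size = 0.183, z_step = 0.3,
                       frame_interval = 20,
                       channels = c(main = "signal")) {
  stopifnot(pixel_size > 0, z_step > 0, frame_interval > 0)
  structure(list(pixel_size = pixel_size, z_step = z_step,
                 frame_interval = frame_interval, channels = channels),
            class = "image_meta")
}

#' @export
print.image_meta <- function(x, ...) {
  cat("<image_meta> ", x$pixel_size, " um/px, z-step ", x$z_step,
      " um, frame interval ", x$frame_interval, " s\n", sep = "")
  invisible(x)
}

#' Write an image stack or movie as a multi-page 16-bit TIFF
#'
#' Values are rounded and clamped to the unsigned 16-bit camera range
#' 0..65535; integer count stacks therefore round-trip bit-exactly.
#'
#' @param stack numeric array `[y, x, plane]` (a matrix is written as one
#'   page).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- round(stack[, , k])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  invisible(path)
}

#' Read a multi-page TIFF into an array
#'
#' @param path a multi-page TIFF written by [save_stack()] or any greyscale
#'   TIFF with identically shaped pages.
#' @param meta an [image_meta()] attached to the result as attribute
#'   `"meta"`.
#' @return numeric array `[y, x, plane]` in counts (0..65535).
#' @export
load_stack <- function(path, meta = image_meta()) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
    p
  })
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("inconsistent page shapes in ", path)
  out <- array(round(unlist(pages) * 65535),
               c(dims[[1]], length(pages)))
  attr(out, "meta") <- meta
  out
}

# ---- record tables ---------------------------------------------------------

# Mandatory columns per record type; column names carry units.
.filo_schemas <- list(
  nuclei = c("label", "centroid_x_um", "centroid_y_um", "centroid_z_um",
             "angle_deg", "low_anisotropy", "undefined_orientation",
             "bottom_z_um", "volume_um3"),
  islets = c("frame", "label", "perimeter_um", "area_um2"),
  detections = c("frame", "id", "islet", "base_x_px", "base_y_px",
                 "tip_x_px", "tip_y_px", "length_um", "orientation_deg",
                 "width_um"),
  tracks = c("track", "frame", "det_id", "minus_x_px", "minus_y_px",
             "plus_x_px", "plus_y_px", "length_um", "birth_frame",
             "death_frame", "censored_start", "censored_end", "ambiguous"),
  summary = c("movie", "mean_length_um", "median_length_um",
              "mean_lifetime_s", "elong_speed_plus_nms",
              "elong_speed_minus_nms", "retract_speed_plus_nms",
              "retract_speed_minus_nms", "normalized_number_per_um",
              "fraction_elongating", "n_filopodia", "n_frames"),
  filopodia_gt = c("id", "islet", "frame", "base_x_px", "base_y_px",
                   "tip_x_px", "tip_y_px", "length_um", "birth_frame",
                   "death_frame"),
  nuclei_gt = c("id", "x_um", "y_um", "z_um", "a_um", "b_um", "c_um",
                "angle_deg", "bottom_z_um", "engaged"),
  islets_gt = c("islet", "cx_px", "cy_px", "ry_px", "rx_px", "theta_rad",
                "perimeter_um", "area_um2"),
  curves = c("time_s", "quantity", "raw", "smoothed")
)

#' Write / read result tables as CSV
#'
#' Tables are written as plain CSV with a single comment line recording the
#' record type; column names carry units (`_um`, `_s`, `_px`, ...).
#' `read_records()` validates the mandatory columns of the declared type
#' and errors on a schema mismatch.  Round trips are lossless to the full
#' double precision that `write.csv` emits (>= 15 significant digits).
#'
#' @param records data.frame of one record type.
#' @param path CSV path.
#' @param type record type, one of `r paste(names(filoscaffold:::.filo_schemas), collapse=", ")`.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   the data.frame.
#' @export
write_records <- function(records, path, type) {
  type <- match.arg(type, names(.filo_schemas))
  stopifnot(is.data.frame(records))
  miss <- setdiff(.filo_schemas[[type]], names(records))
  if (length(miss))
    stop("records lack mandatory ", type, " columns: ",
         paste(miss, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# filoscaffold ", type), con)
  write.csv(records, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path, type) {
  type <- match.arg(type, names(.filo_schemas))
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(.filo_schemas[[type]], names(df))
  if (length(miss))
    stop("schema mismatch reading ", path, " as ", type,
         ": missing column(s) ", paste(miss, collapse = ", "))
  df
}

# Encode / decode pixel index vectors for CSV columns.
encode_pixels <- function(idx) paste(idx, collapse = ";")
decode_pixels <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}
encode_path <- function(p) paste(paste(p[, 1], p[, 2], sep = ","),
                                 collapse = ";")
decode_path <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(integer(0), 0, 2))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  do.call(rbind, lapply(parts, function(v) as.integer(v)))
}
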