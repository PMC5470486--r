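# Image/odometry stem-location chain: green-channel plant segmentation,
# inter-frame motion scale, and odometry-referenced stem locations.

#' Segment the plant from a side-view frame
#'
#' Classifies pixels as plant or soil by green dominance (the green channel
#' must exceed both red and blue by a margin), then removes specks by
#' erosion followed by morphological reconstruction (geodesic dilation of
#' the eroded mask under the original mask until stable). The stem column
#' is the median column of the bottom 20% of rows of the largest connected
#' component.
#'
#' @param image Numeric array `height x width x 3` with values in \[0, 1\],
#'   rows top to bottom (the region of interest, already cropped).
#' @param green_margin Minimum green dominance (default 0.1).
#' @param erode_radius Erosion radius in pixels (default 2).
#' @return A list of class `plant_mask`: `mask` (logical matrix),
#'   `stem_col` (pixel column of the stem), `component_size`.
#'   Signals a `rowsense_empty_mask` condition when no plant pixels remain.
#' @export
segment_plant <- function(image, green_margin = 0.1, erode_radius = 2) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    rs_invalid("image must be a height x width x 3 array")
  }
  g <- image[, , 2]
  dominance <- g - pmax(image[, , 1], image[, , 3])
  mask <- (dominance > green_margin) * 1

  if (!any(mask > 0)) rs_abort("no plant pixels found", "rowsense_empty_mask")

  brush <- EBImage::makeBrush(2 * erode_radius + 1, shape = "disc")
  marker <- EBImage::imageData(EBImage::erode(mask, brush))
  # reconstruction: geodesic dilation of the eroded marker under the mask
  kern <- EBImage::makeBrush(3, shape = "box")
  repeat {
    grown <- pmin(EBImage::imageData(EBImage::dilate(marker, kern)), mask)
    if (identical(grown, marker)) break
    marker <- grown
  }
  if (!any(marker > 0)) rs_abort("no plant pixels survive cleaning", "rowsense_empty_mask")

  labels <- EBImage::imageData(EBImage::bwlabel(marker))
  sizes <- tabulate(labels[labels > 0])
  comp <- which.max(sizes)
  px <- which(labels == comp, arr.ind = TRUE)
  rmax <- max(px[, 1]); rmin <- min(px[, 1])
  bottom <- px[px[, 1] >= rmax - 0.2 * (rmax - rmin), , drop = FALSE]
  structure(
    list(mask = marker > 0,
         stem_col = stats::median(bottom[, 2]),
         component_size = sizes[comp]),
    class = "plant_mask"
  )
}

#' Signed horizontal shift between two consecutive frames
#'
#' Estimates the translational displacement of the second frame's content
#' relative to the first by cross-correlating the column-mean intensity
#' profiles (an FFT correlation over all lags, then a normalized Pearson
#' check of the winning overlap). Positive values mean the content moved
#' toward larger column indices. Signals `rowsense_shift_failure` when no
#' lag correlates convincingly (e.g. structureless or non-overlapping
#' frames).
#'
#' @param frame_a,frame_b Numeric arrays (`h x w x 3` or plain matrices) of
#'   equal width.
#' @param min_corr Minimum Pearson correlation of the aligned overlap
#'   (default 0.6).
#' @return Signed shift in pixels (integer-valued).
#' @export
estimate_shift <- function(frame_a, frame_b, min_corr = 0.6) {
  profile <- function(f) {
    if (length(dim(f)) == 3) f <- f[, , 2]
    colMeans(f)
  }
  pa <- profile(frame_a); pb <- profile(frame_b)
  if (length(pa) != length(pb)) rs_invalid("frames must have equal width")
  n <- length(pa)
  a0 <- c(pa - mean(pa), rep(0, n))
  b0 <- c(pb - mean(pb), rep(0, n))
  cc <- Re(stats::fft(stats::fft(b0) * Conj(stats::fft(a0)), inverse = TRUE)) / (2 * n)
  lags <- c(0:(n - 1), -n:-1)
  # require at least a quarter-frame overlap
  ok <- abs(lags) <= 3 * n / 4
  best <- which(ok)[which.max(cc[ok])]
  shift <- lags[best]

  ia <- max(1, 1 - shift):min(n, n - shift)
  ib <- ia + shift
  if (length(ia) < 8) rs_abort("insufficient frame overlap", "rowsense_shift_failure")
  r <- suppressWarnings(stats::cor(pa[ia], pb[ib]))
  if (!is.finite(r) || r < min_corr) {
    rs_abort("no convincing registration between frames", "rowsense_shift_failure")
  }
  shift
}

#' Motion relation (image scale) from a frame pair
#'
#' The forward speed in mm per pixel: encoder distance between two
#' consecutive frames divided by the magnitude of their pixel displacement.
#'
#' @param pixel_shift Signed pixel displacement between the frames (non-zero).
#' @param encoder_delta_mm Encoder distance between the frames (mm).
#' @return mm per pixel. Signals `rowsense_no_motion` for a zero shift.
#' @examples
#' motion_relation(100, 50) # 0.5
#' @export
motion_relation <- function(pixel_shift, encoder_delta_mm) {
  if (pixel_shift == 0) rs_abort("zero pixel shift: no motion", "rowsense_no_motion")
  encoder_delta_mm / abs(pixel_shift)
}

#' Stem location from one frame
#'
#' The encoder value corresponds to the centre of the image; the stem's
#' signed pixel offset from the centre, scaled by the motion relation, is
#' added to it. Offsets are positive when the stem lies at larger
#' along-track positions than the image centre.
#'
#' @param encoder_mm Encoder value at the frame (mm).
#' @param offset_px Signed stem offset from the image centre (pixels).
#' @param mm_per_px Motion relation from [motion_relation()] (> 0).
#' @return Along-track stem location (mm).
#' @examples
#' stem_location(1000, 40, 0.5)  # 1020
#' stem_location(1000, -40, 0.5) #  980
#' @export
stem_location <- function(encoder_mm, offset_px, mm_per_px) {
  if (any(mm_per_px <= 0)) rs_invalid("mm_per_px must be > 0")
  encoder_mm + offset_px * mm_per_px
}

#' Locate plants from a sequence of frame observations
#'
#' Computes a per-frame stem location for every observation, groups
#' locations into plants (a gap larger than half the theoretical spacing
#' starts a new plant), and reports each plant's estimate as the mean of
#' its per-frame locations, with the standard deviation and the number of
#' contributing frames.
#'
#' @param frames Data.frame with columns `encoder_mm` and `stem_offset_px`
#'   (NA offsets are frames without a stem observation), and optionally
#'   `mm_per_px` per frame.
#' @param mm_per_px Image scale used for frames that carry none.
#' @param spacing_mm Theoretical plant spacing (mm), > 0.
#' @return A data.frame of class `image_plants`: `plant_id`,
#'   `location_mm`, `std_mm`, `n_frames`. Zero rows when there are no
#'   observations.
#' @export
locate_plants_from_frames <- function(frames, mm_per_px, spacing_mm) {
  if (!is.finite(spacing_mm) || spacing_mm <= 0) rs_invalid("spacing_mm must be > 0")
  empty <- data.frame(plant_id = integer(0), location_mm = numeric(0),
                      std_mm = numeric(0), n_frames = integer(0))
  class(empty) <- c("image_plants", "data.frame")
  obs <- frames[!is.na(frames$stem_offset_px), , drop = FALSE]
  if (nrow(obs) == 0) return(empty)
  scale <- if ("mm_per_px" %in% names(obs)) obs$mm_per_px else mm_per_px
  loc <- sort(stem_location(obs$encoder_mm, obs$stem_offset_px, scale))
  grp <- cumsum(c(1, diff(loc) > spacing_mm / 2))
  out <- data.frame(
    plant_id = seq_len(max(grp)),
    location_mm = as.vector(tapply(loc, grp, mean)),
    std_mm = as.vector(tapply(loc, grp, function(v) if (length(v) > 1) stats::sd(v) else 0)),
    n_frames = as.vector(tapply(loc, grp, length))
  )
  class(out) <- c("image_plants", "data.frame")
  out
}
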